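# Deterministic synthetic feature sets, so the full pipeline is testable
# with no external data.

#' Default synthetic type vocabulary
#'
#' Seven feature types chosen to exercise every glyph rule: metal binding
#' (circle), active site (diamond), lipidation (wave), glycosylation
#' (hexagon), modified residue (triangle), disulfide bond (bridge) and a
#' generic peptide region (rectangle). `region = FALSE` types are generated
#' as single-residue sites.
#'
#' @return A `data.frame` with columns `label`, `category`, `code`,
#'   `region`.
#' @export
default_type_vocabulary <- function() {
  data.frame(
    label = c("Peptide", "Disulfide bond", "Metal ion binding",
              "Active site", "Lipidation", "Glycosylation",
              "Modified residue"),
    category = c("Molecule processing", "Cross-link", "Binding site",
                 "Binding site", "PTM", "PTM", "PTM"),
    code = sprintf("SYN:%07d", 1:7),
    region = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Generate a reproducible synthetic feature set
#'
#' Draws `n_features` annotations on a sequence of `sequence_length`
#' residues using R's Mersenne-Twister generator under a caller-supplied
#' seed (the ambient RNG state is saved and restored, so generation never
#' perturbs other code). Start positions are uniform on the sequence;
#' region lengths are `1 + Geometric(p)` with mean about one twentieth of
#' the sequence (truncated at the sequence end); site types occupy a single
#' residue. A candidate that would push the overlap depth anywhere above
#' `max_depth` is rejected and redrawn, so the packed layout never needs
#' more than `max_depth` tracks. Synthetic features carry `SYN:*` type
#' codes and `evidence_text = "synthetic"`.
#'
#' @param n_features Number of features to generate.
#' @param sequence_length Sequence length in residues.
#' @param max_depth Maximum permitted overlap depth (minimum 1).
#' @param type_vocabulary A `data.frame` like [default_type_vocabulary()].
#' @param seed Integer seed; identical seeds give identical collections on
#'   every platform.
#' @return A list of [feature()] objects.
#' @export
#' @examples
#' fs <- generate_fixture(5, 200, max_depth = 2, seed = 42)
#' vapply(fs, function(f) f$type_label, character(1))
generate_fixture <- function(n_features, sequence_length, max_depth = 3,
                             type_vocabulary = default_type_vocabulary(),
                             seed = 1) {
  if (!is_count(n_features) || !is_count(sequence_length, 1L) ||
      !is_count(max_depth, 1L)) {
    ft_stop("n_features >= 0, sequence_length >= 1, max_depth >= 1 required",
            "ft_validation_error")
  }
  if (n_features > max_depth * sequence_length) {
    ft_stop(sprintf(
      "cannot fit %d features of depth <= %d on %d residues",
      n_features, max_depth, sequence_length), "ft_feasibility_error")
  }
  stopifnot(is.data.frame(type_vocabulary),
            all(c("label", "category", "code", "region") %in%
                  names(type_vocabulary)))

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  depth <- integer(sequence_length)
  p_len <- 1 / max(2, sequence_length / 20)
  out <- vector("list", n_features)
  for (i in seq_len(n_features)) {
    placed <- FALSE
    for (attempt in seq_len(1000L)) {
      t <- sample.int(nrow(type_vocabulary), 1L)
      if (type_vocabulary$region[t] && sequence_length > 1L) {
        # regions span at least two residues so they stay rectangles
        start <- sample.int(sequence_length - 1L, 1L)
        end <- min(start + 1L + stats::rgeom(1, p_len), sequence_length)
      } else {
        start <- sample.int(sequence_length, 1L)
        end <- start
      }
      if (max(depth[start:end]) < max_depth) {
        depth[start:end] <- depth[start:end] + 1L
        lab <- type_vocabulary$label[t]
        out[[i]] <- feature(
          feature_id = sprintf("SYN_%s_%d_%d_%04d",
                               gsub("[^A-Za-z]", "", lab), start, end, i),
          start = start, end = end,
          type_label = lab,
          type_code = type_vocabulary$code[t],
          type_category = type_vocabulary$category[t],
          feature_label = sprintf("%s %d-%d", lab, start, end),
          evidence_text = "synthetic"
        )
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      ft_stop(sprintf(
        "could not place feature %d of %d under max_depth %d (sequence too crowded)",
        i, n_features, max_depth), "ft_feasibility_error")
    }
  }
  out
}
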