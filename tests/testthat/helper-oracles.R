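# Independent oracles and feature factories used across the suite.

# Brute-force maximum overlap depth: count covering features at every
# residue. Deliberately naive and independent of the package's first-fit
# packing.
depth_oracle <- function(features) {
  if (length(features) == 0L) return(0L)
  ends <- vapply(features, function(f) f$end, integer(1))
  cover <- integer(max(ends))
  for (f in features) {
    cover[f$start:f$end] <- cover[f$start:f$end] + 1L
  }
  max(cover)
}

# Random interval features with no depth constraint (unlike the packaged
# generator), so packing is tested on arbitrary interval sets.
random_features <- function(n, sequence_length, p_site = 0.3) {
  labels <- c("Peptide", "Active site", "Metal ion binding", "Glycosylation",
              "Modified residue", "Lipidation", "Disulfide bond")
  lapply(seq_len(n), function(i) {
    start <- sample.int(sequence_length, 1L)
    end <- if (stats::runif(1) < p_site) start else {
      min(start + sample.int(max(2L, sequence_length %/% 5L), 1L) - 1L,
          sequence_length)
    }
    lab <- sample(labels, 1L)
    feature(sprintf("rf_%03d", i), start, end, type_label = lab,
            type_code = paste0("T:", lab), type_category = "Random")
  })
}

# The worked single-peptide example: segment Q8LAX3, 96 residues, one
# active peptide at 74-96.
q8lax3_feature <- function() {
  feature("UPKB_Q8LAX3_PEPTIDE_74_96", 74, 96,
          type_label = "active_peptide", type_code = "SO:0001064",
          type_category = "Molecule processing",
          feature_label = "Elicitor peptide 3",
          evidence_text = "UniProt", color = "#7DBAA4",
          shape_hint = "rect")
}

q8lax3_doc <- function(style = "nonOverlapping") {
  build_layout("Q8LAX3", list(q8lax3_feature()),
               layout_config(96, style = style))
}

extdata <- function(name) {
  system.file("extdata", name, package = "featuretracks", mustWork = TRUE)
}

svg_feature_groups <- function(svg) {
  x <- xml2::read_xml(svg)
  xml2::xml_find_all(
    x, "//*[local-name()='g'][starts-with(@id, 'feature-')]")
}
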