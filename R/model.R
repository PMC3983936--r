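# Domain types: features, glyph and style vocabularies, layout configuration.
# Validation lives here; all geometry computation lives in layout.R.

#' Glyph vocabulary
#'
#' The closed set of glyph kinds the renderer understands. Region features
#' are rectangles; single-residue sites are drawn as typed shapes: circles
#' for metal binding, diamonds for active sites, waves for lipidation,
#' hexagons for glycosylation, triangles for other modified residues, plus
#' an inverted-U bridge for disulfide bonds and a plain vertical line.
#'
#' @return Character vector of the eight recognised glyph kinds.
#' @export
#' @examples
#' glyph_kinds()
glyph_kinds <- function() {
  c("rect", "circle", "diamond", "triangle", "hexagon", "wave", "bridge",
    "line")
}

#' Render style vocabulary
#'
#' Three layouts are supported: `"nonOverlapping"` packs features into the
#' minimum number of horizontal tracks so no two features in a track share a
#' residue; `"rows"` gives each feature type its own row; `"centered"` draws
#' every feature centered on the single sequence line.
#'
#' @return Character vector of the three style names.
#' @export
render_styles <- function() {
  c("nonOverlapping", "rows", "centered")
}

#' Construct a validated sequence feature
#'
#' A feature is one position-based annotation on a protein sequence: an
#' interval (or single residue when `start == end`) with type labels and
#' display hints. Coordinates are 1-based and inclusive at both ends, the
#' UniProt and GFF3 convention; no shift is ever applied on read or write.
#'
#' @param feature_id Non-empty identifier, treated as opaque (case preserved,
#'   never normalized).
#' @param start,end Residue indices, 1-based inclusive; `start == end` marks
#'   a single-residue site, `start > end` is an error.
#' @param type_label Feature type, e.g. `"Peptide"` or `"Active Site"`.
#' @param type_code Ontology term string, e.g. `"SO:0001064"`.
#' @param type_category Grouping label, e.g. `"Molecule processing"`.
#' @param feature_label Human-readable display string.
#' @param evidence_text,evidence_code Provenance strings; may be empty.
#' @param color Optional color: `"#RRGGBB"` or a CSS-style name, stored
#'   verbatim.
#' @param shape_hint Optional glyph kind from [glyph_kinds()]; when absent
#'   the layout engine picks a glyph from the type label.
#' @return An object of class `ft_feature` (a named list).
#' @export
#' @examples
#' feature("UNIPROTKB_Q8LAX3_PEPTIDE_54_96", 54, 96, type_label = "Peptide")
feature <- function(feature_id, start, end,
                    type_label = "", type_code = "", type_category = "",
                    feature_label = "", evidence_text = "",
                    evidence_code = "", color = NULL, shape_hint = NULL) {
  if (!is_scalar_string(feature_id) || !nzchar(feature_id)) {
    ft_stop("feature_id must be a non-empty string", "ft_validation_error")
  }
  if (!is_count(start, min = 1L) || !is_count(end, min = 1L)) {
    ft_stop(sprintf("feature '%s': start and end must be positive integers",
                    feature_id),
            "ft_coordinate_error")
  }
  if (start > end) {
    ft_stop(sprintf("feature '%s': start (%d) > end (%d)",
                    feature_id, as.integer(start), as.integer(end)),
            "ft_coordinate_error")
  }
  if (!is.null(shape_hint)) {
    if (!is_scalar_string(shape_hint) || !shape_hint %in% glyph_kinds()) {
      ft_stop(sprintf("feature '%s': unknown glyph kind '%s'",
                      feature_id, as.character(shape_hint)[1]),
              "ft_vocabulary_error")
    }
  }
  if (!is.null(color) && !is_color_spec(color)) {
    ft_stop(sprintf("feature '%s': invalid color spec '%s'",
                    feature_id, as.character(color)[1]),
            "ft_validation_error")
  }
  for (s in list(type_label, type_code, type_category, feature_label,
                 evidence_text, evidence_code)) {
    if (!is_scalar_string(s)) {
      ft_stop(sprintf("feature '%s': text fields must be single strings",
                      feature_id),
              "ft_validation_error")
    }
  }
  structure(
    list(
      feature_id    = feature_id,
      start         = as.integer(start),
      end           = as.integer(end),
      type_label    = type_label,
      type_code     = type_code,
      type_category = type_category,
      feature_label = feature_label,
      evidence_text = evidence_text,
      evidence_code = evidence_code,
      color         = color,
      shape_hint    = shape_hint
    ),
    class = "ft_feature"
  )
}

#' @export
print.ft_feature <- function(x, ...) {
  cat(sprintf("<feature %s: %d-%d %s%s>\n",
              x$feature_id, x$start, x$end,
              if (nzchar(x$type_label)) x$type_label else "(untyped)",
              if (!is.null(x$shape_hint)) paste0(" [", x$shape_hint, "]")
              else ""))
  invisible(x)
}

#' @export
format.ft_feature <- function(x, ...) {
  sprintf("%s %d-%d %s", x$feature_id, x$start, x$end, x$type_label)
}

# Value-based equality over all fields (used by round-trip tests).
#' @export
`==.ft_feature` <- function(e1, e2) {
  isTRUE(all.equal(unclass(e1), unclass(e2)))
}

#' Layout configuration
#'
#' Canvas geometry, the residue window, and per-style drawing parameters.
#' Defaults mirror a 700 px wide canvas with 20 px margins, a ruler tick
#' every 50 px, and 10 px high tracks (40 px for the centered style, whose
#' glyphs straddle the sequence line). The sequence line sits at y = 54 px
#' for the stacked styles and y = 95 px for the centered style.
#'
#' @param sequence_length Length of the protein in residues.
#' @param style One of [render_styles()].
#' @param size_x Canvas width in pixels.
#' @param left_margin,right_margin Horizontal margins in pixels.
#' @param requested_start,requested_stop Residue window, 1-based inclusive;
#'   defaults to the full sequence.
#' @param pixels_division Pixels between ruler ticks.
#' @param ruler_y Ruler baseline y in pixels.
#' @param above_ruler,below_ruler Padding above the ruler / below the tracks.
#' @param sequence_line_y Sequence-line y in pixels; default depends on style.
#' @param track_height Glyph height (and twice the site-glyph radius) in
#'   pixels; default 40 for the centered style, 10 otherwise.
#' @param track_gap Vertical gap between stacked tracks in pixels.
#' @param show_vertical_grid,show_horizontal_grid Draw grid lines at ruler
#'   ticks / track boundaries.
#' @return An object of class `ft_config`.
#' @export
#' @examples
#' cfg <- layout_config(sequence_length = 96)
#' cfg$size_x - cfg$left_margin - cfg$right_margin  # usable ruler length
layout_config <- function(sequence_length,
                          style = "nonOverlapping",
                          size_x = 700,
                          left_margin = 20,
                          right_margin = 20,
                          requested_start = 1,
                          requested_stop = sequence_length,
                          pixels_division = 50,
                          ruler_y = 20,
                          above_ruler = 10,
                          below_ruler = 30,
                          sequence_line_y = if (style == "centered") 95 else 54,
                          track_height = if (style == "centered") 40 else 10,
                          track_gap = 2,
                          show_vertical_grid = FALSE,
                          show_horizontal_grid = FALSE) {
  if (!is_scalar_string(style) || !style %in% render_styles()) {
    ft_stop(sprintf("unknown render style '%s'", as.character(style)[1]),
            "ft_vocabulary_error")
  }
  if (!is_count(sequence_length, min = 1L)) {
    ft_stop("sequence_length must be a positive integer",
            "ft_validation_error")
  }
  for (v in list(size_x, left_margin, right_margin, pixels_division, ruler_y,
                 above_ruler, below_ruler, sequence_line_y, track_height,
                 track_gap)) {
    if (!is_scalar_number(v) || v < 0) {
      ft_stop("pixel parameters must be non-negative numbers",
              "ft_validation_error")
    }
  }
  if (size_x <= left_margin + right_margin) {
    ft_stop("size_x must exceed left_margin + right_margin",
            "ft_validation_error")
  }
  if (!is_count(requested_start, 1L) || !is_count(requested_stop, 1L) ||
      requested_start > requested_stop ||
      requested_stop > sequence_length) {
    ft_stop(sprintf(
      "window must satisfy 1 <= start <= stop <= sequence_length (got %s..%s of %s)",
      as.character(requested_start), as.character(requested_stop),
      as.character(sequence_length)),
      "ft_range_error")
  }
  if (pixels_division <= 0 || track_height <= 0) {
    ft_stop("pixels_division and track_height must be positive",
            "ft_validation_error")
  }
  structure(
    list(
      sequence_length = as.integer(sequence_length),
      style = style,
      size_x = as.numeric(size_x),
      left_margin = as.numeric(left_margin),
      right_margin = as.numeric(right_margin),
      requested_start = as.integer(requested_start),
      requested_stop = as.integer(requested_stop),
      pixels_division = as.numeric(pixels_division),
      ruler_y = as.numeric(ruler_y),
      above_ruler = as.numeric(above_ruler),
      below_ruler = as.numeric(below_ruler),
      sequence_line_y = as.numeric(sequence_line_y),
      track_height = as.numeric(track_height),
      track_gap = as.numeric(track_gap),
      show_vertical_grid = isTRUE(show_vertical_grid),
      show_horizontal_grid = isTRUE(show_horizontal_grid)
    ),
    class = "ft_config"
  )
}

#' @export
print.ft_config <- function(x, ...) {
  cat(sprintf(
    "<layout config: %s, canvas %gpx, margins %g/%g, window %d-%d of %d>\n",
    x$style, x$size_x, x$left_margin, x$right_margin,
    x$requested_start, x$requested_stop, x$sequence_length))
  invisible(x)
}

# Ensure a list of features is a list of valid ft_feature objects.
validate_feature_list <- function(features) {
  if (length(features) == 0L) return(list())
  if (inherits(features, "ft_feature")) features <- list(features)
  ok <- vapply(features, inherits, logical(1), what = "ft_feature")
  if (!all(ok)) {
    ft_stop("features must be a list of ft_feature objects (see feature())",
            "ft_validation_error")
  }
  features
}
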