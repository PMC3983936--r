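# The layout engine: sequence-to-pixel mapping, track/row assignment, the
# three rendering styles, ruler, legend, window zooming. Everything here is
# pure computation; serialization lives in featio.R and drawing in svg.R.

#' Derive horizontal geometry from a layout configuration
#'
#' The usable horizontal extent (ruler length) is the canvas width minus both
#' margins; the scale factor `unitsize` (pixels per residue) is the ruler
#' length divided by the window length in residues. `unitsize` is kept at
#' full double precision; rounding to whole pixels happens only when
#' individual coordinates are emitted.
#'
#' @param config An [layout_config()] object.
#' @return An object of class `ft_geometry` with elements `ruler_length`,
#'   `unitsize`, `window_length` and (once a document is built) `size_y`.
#' @export
#' @examples
#' g <- derive_geometry(layout_config(96))
#' g$ruler_length  # 660
#' g$unitsize      # 6.875
derive_geometry <- function(config) {
  stopifnot(inherits(config, "ft_config"))
  ruler_length <- config$size_x - config$left_margin - config$right_margin
  window_length <- config$requested_stop - config$requested_start + 1L
  structure(
    list(
      ruler_length = ruler_length,
      unitsize = ruler_length / window_length,
      window_length = as.integer(window_length),
      size_y = NA_real_
    ),
    class = "ft_geometry"
  )
}

#' Map a residue position to a pixel x coordinate
#'
#' `x(p) = left_margin + (p - requested_start + 1) * unitsize`, rounded half
#' up to a whole pixel. The mapping is anchored so that
#' `p = requested_start - 1` lands on the left margin and
#' `p = requested_stop` lands on the right end of the ruler; it is monotone
#' non-decreasing in `p`.
#'
#' @param p Residue position(s); must lie in
#'   `[requested_start - 1, requested_stop]`.
#' @param config An [layout_config()] object.
#' @param derived Output of [derive_geometry()] for `config`.
#' @return Integer pixel x coordinate(s).
#' @export
#' @examples
#' cfg <- layout_config(96)
#' position_to_pixel(74, cfg, derive_geometry(cfg))  # 529
position_to_pixel <- function(p, config, derived) {
  if (any(p < config$requested_start - 1L) ||
      any(p > config$requested_stop)) {
    ft_stop(sprintf(
      "position outside window %d..%d (clip features before mapping)",
      config$requested_start, config$requested_stop), "ft_range_error")
  }
  round_half_up(config$left_margin +
                  (p - config$requested_start + 1) * derived$unitsize)
}

#' Pixel width of a residue region
#'
#' `(end - start) * unitsize`, rounded half up. A single-residue feature
#' (`start == end`) has width 0: it is drawn as a site glyph, not a
#' rectangle.
#'
#' @param start,end Residue interval, `start <= end`.
#' @param unitsize Pixels per residue.
#' @return Integer pixel width.
#' @export
#' @examples
#' region_width(74, 96, 6.875)  # 151
region_width <- function(start, end, unitsize) {
  if (any(start > end)) {
    ft_stop("region_width: start > end", "ft_coordinate_error")
  }
  round_half_up((end - start) * unitsize)
}

#' Pack features into non-overlapping tracks
#'
#' Greedy first-fit interval partitioning: features are sorted by
#' `(start, end, feature_id)` and each is placed on the lowest-index track
#' whose last-placed feature ends strictly before this one starts. Intervals
#' are closed, so two features overlap iff `a.start <= b.end` and
#' `b.start <= a.end`. For intervals sorted by start, first-fit uses exactly
#' as many tracks as the maximum overlap depth of the set, which is optimal.
#' Track 0 is nearest the sequence line.
#'
#' @param features List of [feature()] objects.
#' @return Named integer vector mapping `feature_id` to 0-based track index.
#' @export
#' @examples
#' fs <- list(feature("a", 54, 96), feature("b", 74, 96), feature("c", 75, 96))
#' assign_tracks(fs)  # three mutually overlapping features: tracks 0, 1, 2
assign_tracks <- function(features) {
  features <- validate_feature_list(features)
  if (length(features) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  starts <- vapply(features, `[[`, integer(1), "start")
  ends <- vapply(features, `[[`, integer(1), "end")
  ids <- vapply(features, `[[`, character(1), "feature_id")
  ord <- order(starts, ends, ids, method = "radix")
  track_last_end <- integer(0)  # last occupied residue per track
  out <- integer(length(features))
  for (i in ord) {
    fit <- which(track_last_end < starts[i])
    if (length(fit) == 0L) {
      track_last_end <- c(track_last_end, ends[i])
      out[i] <- length(track_last_end) - 1L
    } else {
      t <- fit[1L]
      track_last_end[t] <- ends[i]
      out[i] <- t - 1L
    }
  }
  stats::setNames(out, ids)
}

#' Group features into one row per type
#'
#' Each distinct `type_label` gets its own row; rows are ordered
#' lexicographically by `(type_category, type_label)` (C locale, for
#' determinism). Features of the same type share a row and may overlap
#' within it.
#'
#' @param features List of [feature()] objects.
#' @return Named integer vector mapping `feature_id` to 0-based row index.
#' @export
assign_rows <- function(features) {
  features <- validate_feature_list(features)
  if (length(features) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  labels <- vapply(features, `[[`, character(1), "type_label")
  cats <- vapply(features, `[[`, character(1), "type_category")
  ids <- vapply(features, `[[`, character(1), "feature_id")
  # one row key per distinct label; category of first occurrence breaks
  # cross-category duplicates deterministically
  first <- !duplicated(labels)
  key_cat <- stats::setNames(cats[first], labels[first])
  ulabels <- labels[first]
  ord <- order(key_cat[ulabels], ulabels, method = "radix")
  row_of <- stats::setNames(seq_along(ulabels) - 1L, ulabels[ord])
  stats::setNames(as.integer(row_of[labels]), ids)
}

#' Default glyph for a feature type
#'
#' Case-insensitive substring rules on the type label and ontology code:
#' "metal" maps to a circle, "active site" to a diamond, "lipid" to a wave,
#' "glycosyl" to a hexagon, "modified residue" or "ptm" to a triangle, and
#' "disulfid" or "bridge" to a bridge. Anything else is a vertical line for
#' single-residue sites and a rectangle for regions.
#'
#' @param type_label,type_code Feature type strings.
#' @param site `TRUE` when `start == end`.
#' @return A glyph kind string (see [glyph_kinds()]).
#' @export
#' @examples
#' default_glyph("Active Site")        # "diamond"
#' default_glyph("metal ion binding")  # "circle"
#' default_glyph("Peptide")            # "rect"
default_glyph <- function(type_label, type_code = "", site = FALSE) {
  key <- tolower(paste(type_label, type_code))
  if (grepl("metal", key, fixed = TRUE)) return("circle")
  if (grepl("active site", key, fixed = TRUE)) return("diamond")
  if (grepl("lipid", key, fixed = TRUE)) return("wave")
  if (grepl("glycosyl", key, fixed = TRUE)) return("hexagon")
  if (grepl("modified residue", key, fixed = TRUE) ||
      grepl("ptm", key, fixed = TRUE)) return("triangle")
  if (grepl("disulfid", key, fixed = TRUE) ||
      grepl("bridge", key, fixed = TRUE)) return("bridge")
  if (isTRUE(site)) "line" else "rect"
}

#' Deterministic color for a feature type
#'
#' An explicit per-feature color always wins, verbatim. Otherwise the
#' ontology code is hashed (a 31-multiplier polynomial over its bytes) into
#' a fixed 12-color palette, so a given type code maps to the same color in
#' every run and on every platform.
#'
#' @param type_code Ontology term string (may be empty).
#' @param explicit_color Optional color carried by the feature.
#' @return A color string.
#' @export
#' @examples
#' assign_color("SO:0001064")            # palette color, stable across runs
#' assign_color("SO:0001064", "#33FF66") # explicit color wins
assign_color <- function(type_code, explicit_color = NULL) {
  if (!is.null(explicit_color)) {
    if (!is_color_spec(explicit_color)) {
      ft_stop(sprintf("invalid color spec '%s'", explicit_color),
              "ft_validation_error")
    }
    return(explicit_color)
  }
  palette <- type_palette()
  h <- 0
  for (b in utf8ToInt(as.character(type_code))) {
    h <- (h * 31 + b) %% 2147483647
  }
  palette[(h %% length(palette)) + 1L]
}

#' The fixed 12-color type palette
#'
#' Muted, print-safe hues used when a feature carries no explicit color.
#'
#' @return Character vector of 12 `#RRGGBB` colors.
#' @export
type_palette <- function() {
  c("#7DBAA4", "#C0504D", "#4F81BD", "#9BBB59", "#8064A2", "#F79646",
    "#1F6F6F", "#B87333", "#5B9BD5", "#A0516E", "#6B8E23", "#8B7355")
}

# Clip features to the configured window. Features wholly outside are
# dropped; partial overlaps are clipped with the truncated edge flagged so
# the renderer can mark it. Returns list(features, clipped_left,
# clipped_right).
clip_to_window <- function(features, config) {
  features <- validate_feature_list(features)
  keep <- list()
  cl <- logical(0)
  cr <- logical(0)
  for (f in features) {
    if (f$end < config$requested_start || f$start > config$requested_stop) {
      next
    }
    left <- f$start < config$requested_start
    right <- f$end > config$requested_stop
    if (left) f$start <- config$requested_start
    if (right) f$end <- config$requested_stop
    keep[[length(keep) + 1L]] <- f
    cl <- c(cl, left)
    cr <- c(cr, right)
  }
  list(features = keep, clipped_left = cl, clipped_right = cr)
}

# Empty placed-feature table with the full column set.
empty_placed <- function() {
  data.frame(
    feature_id = character(0), start = integer(0), end = integer(0),
    type_label = character(0), type_code = character(0),
    type_category = character(0), feature_label = character(0),
    evidence_text = character(0), evidence_code = character(0),
    glyph = character(0), x = integer(0), y = integer(0),
    width = integer(0), height = numeric(0), cx = integer(0),
    cy = numeric(0), r = numeric(0), track_index = integer(0),
    fill = character(0), stroke = character(0), fill_opacity = numeric(0),
    stroke_width = numeric(0), tooltip = character(0),
    clipped_left = logical(0), clipped_right = logical(0),
    stringsAsFactors = FALSE
  )
}

# Top edge of stacked track/row k: the first band sits track_gap below the
# sequence line, later bands follow at (track_height + track_gap) steps.
stack_y <- function(k, config) {
  config$sequence_line_y + config$track_gap +
    k * (config$track_height + config$track_gap)
}

#' Resolve pixel geometry for every feature
#'
#' Computes, for each (already window-clipped) feature, its horizontal
#' geometry (`x` from [position_to_pixel()], `width` from [region_width()]),
#' its glyph (the explicit shape hint, else [default_glyph()]), colors
#' ([assign_color()]), and its vertical position for the requested style:
#' centered features sit astride the sequence line
#' (`y = sequence_line_y - track_height / 2`); non-overlapping tracks and
#' per-type rows stack downwards from just below the sequence line with
#' `track_gap` pixels between bands. Site glyphs get
#' `cx = position_to_pixel(start)`, `r = track_height / 2`, and
#' `cy = y + height / 2`.
#'
#' @param features List of [feature()] objects, pre-clipped to the window.
#' @param config An [layout_config()] object.
#' @param derived Output of [derive_geometry()].
#' @param style Style to place for; defaults to `config$style`.
#' @param clipped_left,clipped_right Logical vectors flagging edges truncated
#'   by window clipping (see [zoom_layout()]).
#' @return A `data.frame` with one row per feature, sorted by
#'   `(track_index, x, feature_id)`.
#' @export
place_features <- function(features, config, derived,
                           style = config$style,
                           clipped_left = logical(length(features)),
                           clipped_right = logical(length(features))) {
  features <- validate_feature_list(features)
  if (!style %in% render_styles()) {
    ft_stop(sprintf("unknown render style '%s'", style),
            "ft_vocabulary_error")
  }
  n <- length(features)
  if (n == 0L) return(empty_placed())

  band <- switch(style,
    nonOverlapping = assign_tracks(features),
    rows = assign_rows(features),
    centered = {
      ids <- vapply(features, `[[`, character(1), "feature_id")
      stats::setNames(integer(n), ids)
    }
  )

  rows <- vector("list", n)
  right_edge <- round_half_up(config$left_margin + derived$ruler_length)
  for (i in seq_len(n)) {
    f <- features[[i]]
    k <- unname(band[[f$feature_id]])
    y <- if (style == "centered") {
      config$sequence_line_y - config$track_height / 2
    } else {
      stack_y(k, config)
    }
    y <- round_half_up(y)
    x <- position_to_pixel(f$start, config, derived)
    width <- region_width(f$start, f$end, derived$unitsize)
    # a true region is always visible, even below one pixel per residue
    if (f$end > f$start) width <- max(width, 1L)
    # independent rounding of x and width may overshoot the ruler end by one
    # pixel; clamp so glyphs never leave the drawable band
    width <- max(0L, min(width, right_edge - x))
    site <- f$start == f$end
    glyph <- f$shape_hint %||%
      default_glyph(f$type_label, f$type_code, site = site)
    color <- assign_color(f$type_code, f$color)
    height <- config$track_height
    rows[[i]] <- data.frame(
      feature_id = f$feature_id, start = f$start, end = f$end,
      type_label = f$type_label, type_code = f$type_code,
      type_category = f$type_category, feature_label = f$feature_label,
      evidence_text = f$evidence_text, evidence_code = f$evidence_code,
      glyph = glyph, x = x, y = y, width = width, height = height,
      cx = x, cy = y + height / 2, r = height / 2,
      track_index = k, fill = color, stroke = color,
      fill_opacity = 0.5, stroke_width = 1,
      tooltip = feature_tooltip(f),
      clipped_left = isTRUE(clipped_left[i]),
      clipped_right = isTRUE(clipped_right[i]),
      stringsAsFactors = FALSE
    )
  }
  placed <- do.call(rbind, rows)
  placed <- placed[order(placed$track_index, placed$x, placed$feature_id,
                         method = "radix"), , drop = FALSE]
  rownames(placed) <- NULL
  placed
}

feature_tooltip <- function(f) {
  lab <- if (nzchar(f$feature_label)) f$feature_label else f$feature_id
  ev <- if (nzchar(trimws(f$evidence_text))) {
    paste0(" [", f$evidence_text, "]")
  } else {
    ""
  }
  sprintf("%s — %s (%d–%d)%s", lab, f$type_label, f$start, f$end, ev)
}

#' Compute ruler ticks
#'
#' Ticks sit every `pixels_division` pixels from the left margin, plus a
#' terminal tick at exactly the right end of the ruler. Each tick is labeled
#' with the residue obtained by inverting the pixel mapping, clamped to the
#' window; the origin tick is labeled `requested_start` and the terminal
#' tick `requested_stop`. A label that would repeat its predecessor is
#' suppressed (`NA`), but the tick mark itself is kept.
#'
#' @param config An [layout_config()] object.
#' @param derived Output of [derive_geometry()].
#' @return A `data.frame` with integer columns `x_px` and `label`.
#' @export
compute_ruler <- function(config, derived) {
  right <- config$left_margin + derived$ruler_length
  xs <- seq(config$left_margin, right, by = config$pixels_division)
  if (xs[length(xs)] < right) xs <- c(xs, right)
  labels <- round_half_up((xs - config$left_margin) / derived$unitsize) +
    config$requested_start - 1L
  labels <- pmin(pmax(labels, config$requested_start), config$requested_stop)
  labels[1L] <- config$requested_start
  labels[length(labels)] <- config$requested_stop
  dup <- c(FALSE, diff(labels) == 0L)
  labels[dup] <- NA_integer_
  data.frame(x_px = round_half_up(xs), label = as.integer(labels))
}

#' Build the legend
#'
#' One entry per distinct `(type_label, color, glyph)` among the placed
#' features, ordered by `(type_category, type_label)`.
#'
#' @param placed Placed-feature table from [place_features()].
#' @return A `data.frame` with columns `type_label`, `type_category`,
#'   `color`, `glyph`.
#' @export
build_legend <- function(placed) {
  if (nrow(placed) == 0L) {
    return(data.frame(type_label = character(0), type_category = character(0),
                      color = character(0), glyph = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(placed$type_label, placed$fill, placed$glyph, sep = "\r")
  keep <- !duplicated(key)
  leg <- data.frame(
    type_label = placed$type_label[keep],
    type_category = placed$type_category[keep],
    color = placed$fill[keep],
    glyph = placed$glyph[keep],
    stringsAsFactors = FALSE
  )
  leg <- leg[order(leg$type_category, leg$type_label, leg$color, leg$glyph,
                   method = "radix"), , drop = FALSE]
  rownames(leg) <- NULL
  leg
}

legend_row_height <- function() 16
legend_height <- function(n_entries) {
  if (n_entries == 0L) 0 else 10 + legend_row_height() * n_entries
}

#' Build a complete layout document
#'
#' Composes the whole layout pipeline: derive geometry, clip features to the
#' window, assign tracks/rows, place features for the configured style,
#' compute the ruler and the legend. The resulting document is
#' self-sufficient: the renderer performs no layout math. Canvas height
#' `size_y` is the deepest glyph bottom plus the below-ruler padding plus
#' the legend block height.
#'
#' The document also records, per feature, the vertical geometry it would
#' have under each of the three styles (`alt_styles`), so a written layout
#' can be re-rendered in another style without recomputation.
#'
#' @param segment_id Identifier of the annotated sequence (e.g. a UniProt
#'   accession); stored verbatim.
#' @param features List of [feature()] objects.
#' @param config An [layout_config()] object.
#' @return An object of class `ft_layout`: a list with elements
#'   `segment_id`, `config`, `derived`, `placed`, `ticks`, `legend`,
#'   `alt_styles` and the original `features`.
#' @export
#' @examples
#' f <- feature("UPKB_Q8LAX3_PEPTIDE_74_96", 74, 96,
#'              type_label = "active_peptide", type_code = "SO:0001064",
#'              feature_label = "Elicitor peptide 3")
#' doc <- build_layout("Q8LAX3", list(f), layout_config(96))
#' doc$derived$unitsize   # 6.875
#' doc$placed$x           # 529
#' doc$placed$width       # 151
build_layout <- function(segment_id, features, config) {
  if (!is_scalar_string(segment_id) || !nzchar(segment_id)) {
    ft_stop("segment_id must be a non-empty string", "ft_validation_error")
  }
  stopifnot(inherits(config, "ft_config"))
  features <- validate_feature_list(features)
  derived <- derive_geometry(config)
  clip <- clip_to_window(features, config)
  placed <- place_features(clip$features, config, derived,
                           style = config$style,
                           clipped_left = clip$clipped_left,
                           clipped_right = clip$clipped_right)
  alt <- alt_style_geometry(clip$features, config, derived, placed)
  ticks <- compute_ruler(config, derived)
  legend <- build_legend(placed)
  bottom <- max(c(config$sequence_line_y, placed$y + placed$height))
  derived$size_y <- round_half_up(bottom + config$below_ruler +
                                    legend_height(nrow(legend)))
  structure(
    list(
      segment_id = segment_id,
      config = config,
      derived = derived,
      placed = placed,
      ticks = ticks,
      legend = legend,
      alt_styles = alt,
      features = features
    ),
    class = "ft_layout"
  )
}

# Per-feature (heightOrRadius, y) under each of the three styles, aligned
# with the rows of `placed`. Non-active styles use the style's default
# sequence line and track height.
alt_style_geometry <- function(clipped_features, config, derived, placed) {
  if (nrow(placed) == 0L) {
    return(data.frame(feature_id = character(0),
                      nonOverlapping_h = numeric(0), nonOverlapping_y = integer(0),
                      rows_h = numeric(0), rows_y = integer(0),
                      centered_h = numeric(0), centered_y = integer(0),
                      stringsAsFactors = FALSE))
  }
  cfg_for <- function(style) {
    if (style == config$style) return(config)
    layout_config(
      sequence_length = config$sequence_length, style = style,
      size_x = config$size_x, left_margin = config$left_margin,
      right_margin = config$right_margin,
      requested_start = config$requested_start,
      requested_stop = config$requested_stop,
      pixels_division = config$pixels_division, ruler_y = config$ruler_y,
      above_ruler = config$above_ruler, below_ruler = config$below_ruler,
      track_gap = config$track_gap,
      show_vertical_grid = config$show_vertical_grid,
      show_horizontal_grid = config$show_horizontal_grid
    )
  }
  out <- data.frame(feature_id = placed$feature_id, stringsAsFactors = FALSE)
  tracks <- assign_tracks(clipped_features)
  rows <- assign_rows(clipped_features)
  for (style in render_styles()) {
    cfg <- cfg_for(style)
    y <- switch(style,
      centered = rep(round_half_up(cfg$sequence_line_y - cfg$track_height / 2),
                     nrow(placed)),
      nonOverlapping = round_half_up(stack_y(unname(tracks[placed$feature_id]),
                                             cfg)),
      rows = round_half_up(stack_y(unname(rows[placed$feature_id]), cfg))
    )
    out[[paste0(style, "_h")]] <- rep(cfg$track_height, nrow(placed))
    out[[paste0(style, "_y")]] <- as.integer(y)
  }
  out
}

#' Zoom a layout document to a residue window
#'
#' Rebuilds the document from its original (unclipped) features with the
#' requested window. Features wholly outside the window are dropped;
#' features straddling a window edge are clipped and the truncated edge is
#' flagged (`clipped_left` / `clipped_right`), which the renderer draws as a
#' dashed edge. The pixel scale grows as the window shrinks. Zooming to the
#' full sequence reproduces the full-sequence document exactly, and zooming
#' to the current window is a no-op.
#'
#' @param doc An `ft_layout` from [build_layout()].
#' @param new_start,new_stop Residue window, 1-based inclusive, within
#'   `[1, sequence_length]`.
#' @return A new `ft_layout`.
#' @export
zoom_layout <- function(doc, new_start, new_stop) {
  stopifnot(inherits(doc, "ft_layout"))
  cfg <- doc$config
  if (!is_count(new_start, 1L) || !is_count(new_stop, 1L) ||
      new_start > new_stop || new_stop > cfg$sequence_length) {
    ft_stop(sprintf("invalid zoom window %s..%s (sequence length %d)",
                    as.character(new_start), as.character(new_stop),
                    cfg$sequence_length),
            "ft_range_error")
  }
  new_cfg <- cfg
  new_cfg$requested_start <- as.integer(new_start)
  new_cfg$requested_stop <- as.integer(new_stop)
  build_layout(doc$segment_id, doc$features, new_cfg)
}

# --- ft_layout methods --------------------------------------------------

#' @export
print.ft_layout <- function(x, ...) {
  cat(sprintf("<layout document: segment %s, %d placed feature%s>\n",
              x$segment_id, nrow(x$placed),
              if (nrow(x$placed) == 1L) "" else "s"))
  cat(sprintf("  style %s, window %d-%d of %d residues\n",
              x$config$style, x$config$requested_start,
              x$config$requested_stop, x$config$sequence_length))
  n_tracks <- if (nrow(x$placed)) max(x$placed$track_index) + 1L else 0L
  cat(sprintf("  canvas %g x %g px, unitsize %.4g px/residue, %d track%s\n",
              x$config$size_x, x$derived$size_y, x$derived$unitsize,
              n_tracks, if (n_tracks == 1L) "" else "s"))
  invisible(x)
}

#' @export
summary.ft_layout <- function(object, ...) {
  print(object)
  if (nrow(object$placed)) {
    tab <- table(object$placed$type_label)
    cat("  features by type:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  cat(sprintf("  %d ruler tick%s, %d legend entr%s\n",
              nrow(object$ticks),
              if (nrow(object$ticks) == 1L) "" else "s",
              nrow(object$legend),
              if (nrow(object$legend) == 1L) "y" else "ies"))
  invisible(object)
}

#' Sketch a layout document with base graphics
#'
#' A quick on-screen approximation of the SVG output (rectangles and points
#' in pixel coordinates, y axis flipped). For the faithful rendering use
#' [render_svg()].
#'
#' @param x An `ft_layout`.
#' @param ... Passed to [graphics::plot.default()].
#' @return `x`, invisibly.
#' @export
plot.ft_layout <- function(x, ...) {
  cfg <- x$config
  graphics::plot(NULL, xlim = c(0, cfg$size_x),
                 ylim = c(x$derived$size_y, 0), xlab = "px", ylab = "px",
                 main = x$segment_id, asp = 1, ...)
  graphics::segments(cfg$left_margin, cfg$ruler_y,
                     cfg$left_margin + x$derived$ruler_length, cfg$ruler_y)
  ok <- !is.na(x$ticks$label)
  graphics::segments(x$ticks$x_px, cfg$ruler_y, x$ticks$x_px, cfg$ruler_y + 4)
  graphics::text(x$ticks$x_px[ok], cfg$ruler_y + 12, x$ticks$label[ok],
                 cex = 0.6)
  p <- x$placed
  if (nrow(p)) {
    is_region <- p$glyph %in% c("rect", "bridge")
    graphics::rect(p$x[is_region], p$y[is_region] + p$height[is_region],
                   p$x[is_region] + p$width[is_region], p$y[is_region],
                   col = grDevices::adjustcolor(p$fill[is_region], 0.5),
                   border = p$stroke[is_region])
    graphics::points(p$cx[!is_region], p$cy[!is_region], pch = 19,
                     col = p$fill[!is_region])
  }
  invisible(x)
}
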