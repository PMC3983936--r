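# Readers and writers: the simple-features JSON dialect, GFF3, and the
# fully resolved layout-document JSON dialect.

# Accept either a file path or literal text; return one string of text.
slurp <- function(input, what = "input") {
  if (!is.character(input) || length(input) < 1L) {
    ft_stop(sprintf("%s must be text or a file path", what),
            "ft_parse_error")
  }
  if (length(input) == 1L && !grepl("[{\n\t]", input) &&
      !startsWith(input, "#")) {
    if (!file.exists(input)) {
      ft_stop(sprintf("%s: file not found: %s", what, input),
              "ft_io_error")
    }
    return(paste(readLines(input, warn = FALSE, encoding = "UTF-8"),
                 collapse = "\n"))
  }
  paste(input, collapse = "\n")
}

simple_feature_keys <- function() {
  c("featureId", "featureStart", "featureEnd", "typeLabel", "typeCode",
    "featureLabel", "typeCategory", "evidenceText", "evidenceCode",
    "color", "type")
}

#' Read a simple-features JSON document
#'
#' The simple dialect carries a sequence identifier, the sequence length,
#' and a flat features array whose elements use the keys `featureId`,
#' `featureStart`, `featureEnd`, `typeLabel`, `typeCode`, `featureLabel`,
#' `typeCategory`, `evidenceText`, `evidenceCode`, `color` and `type` (the
#' glyph shape hint). Unknown keys are ignored with a warning, for forward
#' compatibility. Coordinates are taken verbatim (1-based inclusive).
#' Missing colors and shapes stay absent here; defaults are resolved later
#' by the layout engine, not the reader.
#'
#' @param input JSON text or a file path.
#' @return A list with `segment_id`, `sequence_length` and `features` (a
#'   list of [feature()] objects).
#' @export
#' @examples
#' txt <- '{"sequenceId":"a4_human","sequenceLength":770,
#'          "features":[{"featureId":"f1","featureStart":54,"featureEnd":96,
#'                       "typeLabel":"Peptide"}]}'
#' read_simple_features(txt)$features[[1]]
read_simple_features <- function(input) {
  txt <- slurp(input, "simple-features JSON")
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) {
                    ft_stop(paste0("malformed JSON: ", conditionMessage(e)),
                            "ft_parse_error")
                  })
  for (k in c("sequenceId", "sequenceLength", "features")) {
    if (is.null(doc[[k]])) {
      ft_stop(sprintf("simple-features document lacks key '%s'", k),
              "ft_schema_error")
    }
  }
  feats <- vector("list", length(doc$features))
  unknown <- character(0)
  for (i in seq_along(doc$features)) {
    el <- doc$features[[i]]
    unknown <- union(unknown, setdiff(names(el), simple_feature_keys()))
    s <- el$featureStart
    e <- el$featureEnd
    if (is.null(s) || is.null(e)) {
      ft_stop(sprintf("feature element %d: missing featureStart/featureEnd",
                      i), "ft_parse_error")
    }
    if (!is.numeric(s) || !is.numeric(e)) {
      ft_stop(sprintf("feature element %d: non-numeric coordinates", i),
              "ft_parse_error")
    }
    feats[[i]] <- feature(
      feature_id = as.character(el$featureId %||% sprintf("feature_%d", i)),
      start = s, end = e,
      type_label = as.character(el$typeLabel %||% ""),
      type_code = as.character(el$typeCode %||% ""),
      type_category = as.character(el$typeCategory %||% ""),
      feature_label = as.character(el$featureLabel %||% ""),
      evidence_text = as.character(el$evidenceText %||% ""),
      evidence_code = as.character(el$evidenceCode %||% ""),
      color = el$color,
      shape_hint = el$type
    )
  }
  if (length(unknown)) {
    warning(sprintf("ignoring unknown simple-features key(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  list(
    segment_id = as.character(doc$sequenceId),
    sequence_length = as.integer(doc$sequenceLength),
    features = feats
  )
}

#' Write a simple-features JSON document
#'
#' Inverse of [read_simple_features()]; used by the fixture generator and
#' for round-trip testing.
#'
#' @param segment_id Sequence identifier.
#' @param sequence_length Sequence length in residues.
#' @param features List of [feature()] objects.
#' @param path Optional file path; when given the JSON is also written there.
#' @return The JSON text, invisibly when `path` is given.
#' @export
write_simple_features <- function(segment_id, sequence_length, features,
                                  path = NULL) {
  features <- validate_feature_list(features)
  arr <- lapply(features, function(f) {
    el <- list(
      featureId = f$feature_id,
      featureStart = f$start,
      featureEnd = f$end,
      typeLabel = f$type_label,
      typeCode = f$type_code,
      featureLabel = f$feature_label,
      typeCategory = f$type_category,
      evidenceText = f$evidence_text,
      evidenceCode = f$evidence_code
    )
    if (!is.null(f$color)) el$color <- f$color
    if (!is.null(f$shape_hint)) el$type <- f$shape_hint
    el
  })
  doc <- list(sequenceId = segment_id,
              sequenceLength = as.integer(sequence_length),
              features = arr)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- as.character(txt)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

# --- GFF3 ---------------------------------------------------------------

gff3_mapped_attrs <- function() {
  c("ID", "Note", "type_code", "type_category", "evidence_text",
    "evidence_code", "color", "shape_hint")
}

gff3_encode <- function(x) utils::URLencode(x, reserved = TRUE)
gff3_decode <- function(x) utils::URLdecode(x)

#' Read features from GFF3 text
#'
#' Plain 9-column GFF3 (a `##gff-version 3` header and comment lines are
#' tolerated). Coordinates are copied unshifted — GFF3 is 1-based inclusive,
#' the same convention used throughout. Column 3 becomes `type_label` (`.`
#' reads as empty), the `ID` attribute becomes `feature_id` (with a
#' deterministic fallback built from seqid, type and coordinates), `Note`
#' becomes `feature_label`, and the attributes `type_code`, `type_category`,
#' `evidence_text`, `evidence_code`, `color` and `shape_hint` map onto the
#' corresponding feature fields. Any other attribute is preserved,
#' `key=value`-style, in `evidence_text`. All features must sit on one
#' seqid: this reader models a single-protein view.
#'
#' @param input GFF3 text or a file path.
#' @return A list with `segment_id` (NA for a header-only file) and
#'   `features`.
#' @export
read_gff3 <- function(input) {
  txt <- slurp(input, "GFF3")
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  feats <- list()
  seg <- NA_character_
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    cols <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(cols) != 9L) {
      ft_stop(sprintf("GFF3 line %d: expected 9 tab-separated columns, got %d",
                      ln, length(cols)), "ft_parse_error")
    }
    start <- suppressWarnings(as.integer(cols[4]))
    end <- suppressWarnings(as.integer(cols[5]))
    if (is.na(start) || is.na(end)) {
      ft_stop(sprintf("GFF3 line %d: non-numeric start/end", ln),
              "ft_parse_error")
    }
    if (is.na(seg)) {
      seg <- cols[1]
    } else if (!identical(seg, cols[1])) {
      ft_stop(sprintf(
        "GFF3 line %d: seqid '%s' differs from '%s'; one segment per document",
        ln, cols[1], seg), "ft_multisegment_error")
    }
    attrs <- list()
    if (cols[9] != "." && nzchar(cols[9])) {
      for (pair in strsplit(cols[9], ";", fixed = TRUE)[[1]]) {
        if (!nzchar(pair)) next
        kv <- strsplit(pair, "=", fixed = TRUE)[[1]]
        if (length(kv) < 2L) {
          ft_stop(sprintf("GFF3 line %d: malformed attribute '%s'", ln, pair),
                  "ft_parse_error")
        }
        attrs[[kv[1]]] <- gff3_decode(paste(kv[-1], collapse = "="))
      }
    }
    extra <- setdiff(names(attrs), gff3_mapped_attrs())
    evidence <- attrs$evidence_text %||% ""
    if (length(extra)) {
      extras <- paste(sprintf("%s=%s", extra,
                              vapply(extra, function(k) attrs[[k]],
                                     character(1))),
                      collapse = "; ")
      evidence <- if (nzchar(evidence)) paste(evidence, extras, sep = "; ")
      else extras
    }
    type_label <- if (cols[3] == ".") "" else cols[3]
    feats[[length(feats) + 1L]] <- feature(
      feature_id = attrs$ID %||%
        sprintf("%s_%s_%d_%d_L%d", cols[1], cols[3], start, end, ln),
      start = start, end = end,
      type_label = type_label,
      type_code = attrs$type_code %||% "",
      type_category = attrs$type_category %||% "",
      feature_label = attrs$Note %||% "",
      evidence_text = evidence,
      evidence_code = attrs$evidence_code %||% "",
      color = attrs$color,
      shape_hint = attrs$shape_hint
    )
  }
  list(segment_id = seg, features = feats)
}

#' Write features as GFF3
#'
#' Inverse of [read_gff3()]: feature fields beyond the 9 columns travel in
#' column-9 attributes (percent-encoded), so a write/read round trip
#' reproduces the collection exactly.
#'
#' @param features List of [feature()] objects.
#' @param segment_id The seqid for column 1.
#' @param path Optional file path.
#' @return GFF3 text, invisibly when `path` is given.
#' @export
write_gff3 <- function(features, segment_id, path = NULL) {
  features <- validate_feature_list(features)
  header <- "##gff-version 3"
  lines <- vapply(features, function(f) {
    attrs <- c(sprintf("ID=%s", gff3_encode(f$feature_id)))
    add <- function(key, val) {
      if (!is.null(val) && nzchar(val)) {
        attrs <<- c(attrs, sprintf("%s=%s", key, gff3_encode(val)))
      }
    }
    add("Note", f$feature_label)
    add("type_code", f$type_code)
    add("type_category", f$type_category)
    add("evidence_text", f$evidence_text)
    add("evidence_code", f$evidence_code)
    add("color", f$color)
    add("shape_hint", f$shape_hint)
    sprintf("%s\tfeaturetracks\t%s\t%d\t%d\t.\t.\t.\t%s",
            segment_id,
            if (nzchar(f$type_label)) f$type_label else ".",
            f$start, f$end, paste(attrs, collapse = ";"))
  }, character(1))
  txt <- paste(c(header, lines), collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

# --- layout-document JSON ----------------------------------------------

#' Write a layout document as JSON
#'
#' Serializes a complete resolved drawing: `featuresArray` (one object per
#' placed feature, carrying flat geometry for the active style plus
#' `nonOverlappingStyle`/`centeredStyle`/`rowsStyle` blocks with each
#' style's `heightOrRadius` and `y`), `segment`, `legend`, `configuration`
#' (including `unitsize`, `rulerLength`, `requestedStart`/`Stop`, `style`),
#' a `ruler` tick array, and `sourceFeatures` (the original input features,
#' in the simple dialect, so a reader can re-layout or zoom). All pixel
#' fields are integers except `unitsize`, which keeps full precision. Output
#' is byte-deterministic for equal documents.
#'
#' @param doc An `ft_layout` from [build_layout()].
#' @param path Optional file path.
#' @param das_sources,das_reference Optional pass-through annotation-source
#'   strings carried for compatibility with existing documents; not used by
#'   this package.
#' @return JSON text, invisibly when `path` is given.
#' @export
write_layout_json <- function(doc, path = NULL, das_sources = NULL,
                              das_reference = NULL) {
  stopifnot(inherits(doc, "ft_layout"))
  p <- doc$placed
  a <- doc$alt_styles
  arr <- lapply(seq_len(nrow(p)), function(i) {
    list(
      featureId = p$feature_id[i],
      featureStart = p$start[i],
      featureEnd = p$end[i],
      featureTypeLabel = p$type_label[i],
      typeCode = p$type_code[i],
      typeCategory = p$type_category[i],
      featureLabel = p$feature_label[i],
      evidenceText = p$evidence_text[i],
      evidenceCode = p$evidence_code[i],
      type = p$glyph[i],
      fill = p$fill[i],
      stroke = p$stroke[i],
      fillOpacity = p$fill_opacity[i],
      strokeWidth = p$stroke_width[i],
      x = p$x[i], y = p$y[i], width = p$width[i], height = p$height[i],
      cx = p$cx[i], cy = p$cy[i], r = p$r[i],
      trackIndex = p$track_index[i],
      clippedLeft = p$clipped_left[i],
      clippedRight = p$clipped_right[i],
      tooltip = p$tooltip[i],
      nonOverlappingStyle = list(heightOrRadius = a$nonOverlapping_h[i],
                                 y = a$nonOverlapping_y[i]),
      centeredStyle = list(heightOrRadius = a$centered_h[i],
                           y = a$centered_y[i]),
      rowsStyle = list(heightOrRadius = a$rows_h[i], y = a$rows_y[i])
    )
  })
  cfg <- doc$config
  configuration <- list(
    style = cfg$style,
    sizeX = cfg$size_x,
    sizeY = doc$derived$size_y,
    leftMargin = cfg$left_margin,
    rightMargin = cfg$right_margin,
    requestedStart = cfg$requested_start,
    requestedStop = cfg$requested_stop,
    sequenceLength = cfg$sequence_length,
    pixelsDivision = cfg$pixels_division,
    rulerY = cfg$ruler_y,
    aboveRuler = cfg$above_ruler,
    belowRuler = cfg$below_ruler,
    sequenceLineY = cfg$sequence_line_y,
    heightOrRadius = cfg$track_height,
    trackGap = cfg$track_gap,
    rulerLength = doc$derived$ruler_length,
    unitsize = doc$derived$unitsize,
    verticalGrid = cfg$show_vertical_grid,
    horizontalGrid = cfg$show_horizontal_grid
  )
  if (!is.null(das_sources)) configuration$dasSources <- das_sources
  if (!is.null(das_reference)) configuration$dasReference <- das_reference
  legend <- lapply(seq_len(nrow(doc$legend)), function(i) {
    list(typeLabel = doc$legend$type_label[i],
         typeCategory = doc$legend$type_category[i],
         color = doc$legend$color[i],
         glyph = doc$legend$glyph[i])
  })
  ruler <- lapply(seq_len(nrow(doc$ticks)), function(i) {
    list(x = doc$ticks$x_px[i],
         label = if (is.na(doc$ticks$label[i])) NULL else doc$ticks$label[i])
  })
  src <- lapply(doc$features, function(f) {
    el <- list(featureId = f$feature_id, featureStart = f$start,
               featureEnd = f$end, typeLabel = f$type_label,
               typeCode = f$type_code, featureLabel = f$feature_label,
               typeCategory = f$type_category, evidenceText = f$evidence_text,
               evidenceCode = f$evidence_code)
    if (!is.null(f$color)) el$color <- f$color
    if (!is.null(f$shape_hint)) el$type <- f$shape_hint
    el
  })
  out <- list(
    segment = doc$segment_id,
    featuresArray = arr,
    legend = legend,
    configuration = configuration,
    ruler = ruler,
    sourceFeatures = src
  )
  txt <- as.character(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                                       null = "null", pretty = TRUE))
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

required_config_keys <- function() {
  c("style", "sizeX", "leftMargin", "rightMargin", "requestedStart",
    "requestedStop", "sequenceLength", "unitsize", "rulerLength")
}

#' Read a layout document from JSON
#'
#' Reconstructs a renderer-ready `ft_layout` from text produced by
#' [write_layout_json()] (or hand-written to the same schema). No layout
#' math is re-run: placed geometry, ruler ticks and legend are taken from
#' the document. Missing required keys raise a validation error that lists
#' them. When the optional `sourceFeatures` block is absent, original
#' features are reconstructed from `featuresArray`; when the `ruler` block
#' is absent, ticks are recomputed from the configuration.
#'
#' @param input JSON text or a file path.
#' @return An `ft_layout`.
#' @export
read_layout_json <- function(input) {
  txt <- slurp(input, "layout JSON")
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) {
                    ft_stop(paste0("malformed JSON: ", conditionMessage(e)),
                            "ft_parse_error")
                  })
  missing_top <- setdiff(c("segment", "featuresArray", "legend",
                           "configuration"), names(doc))
  cj <- doc$configuration
  missing_cfg <- if (is.null(cj)) required_config_keys()
  else setdiff(required_config_keys(), names(cj))
  if (length(missing_top) || length(missing_cfg)) {
    ft_stop(sprintf(
      "layout document missing key(s): %s",
      paste(c(missing_top,
              if (length(missing_cfg)) paste0("configuration.", missing_cfg)),
            collapse = ", ")), "ft_schema_error")
  }
  style <- as.character(cj$style)
  config <- layout_config(
    sequence_length = as.integer(cj$sequenceLength),
    style = style,
    size_x = as.numeric(cj$sizeX),
    left_margin = as.numeric(cj$leftMargin),
    right_margin = as.numeric(cj$rightMargin),
    requested_start = as.integer(cj$requestedStart),
    requested_stop = as.integer(cj$requestedStop),
    pixels_division = as.numeric(cj$pixelsDivision %||% 50),
    ruler_y = as.numeric(cj$rulerY %||% 20),
    above_ruler = as.numeric(cj$aboveRuler %||% 10),
    below_ruler = as.numeric(cj$belowRuler %||% 30),
    sequence_line_y = as.numeric(cj$sequenceLineY %||%
                                   (if (style == "centered") 95 else 54)),
    track_height = as.numeric(cj$heightOrRadius %||%
                                (if (style == "centered") 40 else 10)),
    track_gap = as.numeric(cj$trackGap %||% 2),
    show_vertical_grid = isTRUE(cj$verticalGrid),
    show_horizontal_grid = isTRUE(cj$horizontalGrid)
  )
  derived <- derive_geometry(config)
  derived$size_y <- as.numeric(cj$sizeY %||% NA_real_)
  fa <- doc$featuresArray
  placed <- if (length(fa) == 0L) empty_placed() else {
    rows <- lapply(seq_along(fa), function(i) {
      el <- fa[[i]]
      for (k in c("featureId", "featureStart", "featureEnd", "x", "y",
                  "width")) {
        if (is.null(el[[k]])) {
          ft_stop(sprintf("featuresArray[%d] missing key '%s'", i, k),
                  "ft_schema_error")
        }
      }
      data.frame(
        feature_id = as.character(el$featureId),
        start = as.integer(el$featureStart),
        end = as.integer(el$featureEnd),
        type_label = as.character(el$featureTypeLabel %||% ""),
        type_code = as.character(el$typeCode %||% ""),
        type_category = as.character(el$typeCategory %||% ""),
        feature_label = as.character(el$featureLabel %||% ""),
        evidence_text = as.character(el$evidenceText %||% ""),
        evidence_code = as.character(el$evidenceCode %||% ""),
        glyph = as.character(el$type %||% "rect"),
        x = as.integer(el$x), y = as.integer(el$y),
        width = as.integer(el$width),
        height = as.numeric(el$height %||% config$track_height),
        cx = as.integer(el$cx %||% el$x),
        cy = as.numeric(el$cy %||% (as.numeric(el$y) +
                                      as.numeric(el$height %||%
                                                   config$track_height) / 2)),
        r = as.numeric(el$r %||% (config$track_height / 2)),
        track_index = as.integer(el$trackIndex %||% 0L),
        fill = as.character(el$fill %||% type_palette()[1]),
        stroke = as.character(el$stroke %||% el$fill %||% type_palette()[1]),
        fill_opacity = as.numeric(el$fillOpacity %||% 0.5),
        stroke_width = as.numeric(el$strokeWidth %||% 1),
        tooltip = as.character(el$tooltip %||% ""),
        clipped_left = isTRUE(el$clippedLeft),
        clipped_right = isTRUE(el$clippedRight),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  alt <- if (length(fa) == 0L) {
    alt_style_geometry(list(), config, derived, placed)
  } else {
    blk <- function(el, block, key, default) {
      v <- el[[block]][[key]]
      if (is.null(v)) default else v
    }
    data.frame(
      feature_id = placed$feature_id,
      nonOverlapping_h = vapply(fa, blk, numeric(1), "nonOverlappingStyle",
                                "heightOrRadius", 10),
      nonOverlapping_y = as.integer(vapply(fa, blk, numeric(1),
                                           "nonOverlappingStyle", "y", 56)),
      rows_h = vapply(fa, blk, numeric(1), "rowsStyle", "heightOrRadius", 10),
      rows_y = as.integer(vapply(fa, blk, numeric(1), "rowsStyle", "y", 56)),
      centered_h = vapply(fa, blk, numeric(1), "centeredStyle",
                          "heightOrRadius", 40),
      centered_y = as.integer(vapply(fa, blk, numeric(1), "centeredStyle",
                                     "y", 75)),
      stringsAsFactors = FALSE
    )
  }
  ticks <- if (!is.null(doc$ruler)) {
    data.frame(
      x_px = vapply(doc$ruler, function(t) as.integer(t$x), integer(1)),
      label = vapply(doc$ruler, function(t) {
        if (is.null(t$label)) NA_integer_ else as.integer(t$label)
      }, integer(1))
    )
  } else {
    compute_ruler(config, derived)
  }
  legend <- if (length(doc$legend) == 0L) {
    build_legend(empty_placed())
  } else {
    out <- data.frame(
      type_label = vapply(doc$legend, function(l)
        as.character(l$typeLabel %||% ""), character(1)),
      type_category = vapply(doc$legend, function(l)
        as.character(l$typeCategory %||% ""), character(1)),
      color = vapply(doc$legend, function(l)
        as.character(l$color %||% ""), character(1)),
      glyph = vapply(doc$legend, function(l)
        as.character(l$glyph %||% "rect"), character(1)),
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    out
  }
  features <- if (!is.null(doc$sourceFeatures)) {
    lapply(doc$sourceFeatures, function(el) {
      feature(
        feature_id = as.character(el$featureId),
        start = as.integer(el$featureStart),
        end = as.integer(el$featureEnd),
        type_label = as.character(el$typeLabel %||% ""),
        type_code = as.character(el$typeCode %||% ""),
        type_category = as.character(el$typeCategory %||% ""),
        feature_label = as.character(el$featureLabel %||% ""),
        evidence_text = as.character(el$evidenceText %||% ""),
        evidence_code = as.character(el$evidenceCode %||% ""),
        color = el$color,
        shape_hint = el$type
      )
    })
  } else {
    lapply(seq_len(nrow(placed)), function(i) {
      feature(placed$feature_id[i], placed$start[i], placed$end[i],
              type_label = placed$type_label[i],
              type_code = placed$type_code[i],
              type_category = placed$type_category[i],
              feature_label = placed$feature_label[i],
              evidence_text = placed$evidence_text[i],
              evidence_code = placed$evidence_code[i])
    })
  }
  structure(
    list(
      segment_id = as.character(doc$segment),
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
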