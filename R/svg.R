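# SVG rendering. The renderer is deliberately "dumb": it draws exactly the
# geometry recorded in a layout document and performs no layout math of its
# own, so documents written by write_layout_json() render identically
# anywhere.

num <- function(x) {
  vapply(x, function(v) format(v, trim = TRUE, scientific = FALSE,
                               digits = 10), character(1))
}

#' Geometric outline of a glyph
#'
#' Resolves a glyph kind plus its geometry fields into a drawable
#' description: rectangles and circles keep their parametric form; diamond,
#' triangle (apex up) and regular hexagon become explicit vertex lists;
#' the wave becomes an SVG path of two joined semicircular arcs (crest then
#' trough) spanning `2r` horizontally; the bridge becomes an inverted-U
#' polyline rising from `(x, y + height)` to `(x, y)`, across to
#' `(x + width, y)` and back down — connecting two bonded residues above the
#' track; the line is a vertical segment at `cx` from `cy - r` to `cy + r`.
#'
#' @param kind A glyph kind from [glyph_kinds()].
#' @param cx,cy,r Center and radius for site glyphs.
#' @param x,y,width,height Box geometry for `rect` and `bridge`.
#' @return A list of class `ft_glyph_outline` with element `kind` plus the
#'   geometry: `points` (two-column matrix) for polygonal kinds, `path` for
#'   the wave, or the parametric fields.
#' @export
#' @examples
#' glyph_outline("diamond", cx = 0, cy = 0, r = 1)$points
glyph_outline <- function(kind, cx = NA, cy = NA, r = NA,
                          x = NA, y = NA, width = NA, height = NA) {
  if (!kind %in% glyph_kinds()) {
    ft_stop(sprintf("unknown glyph kind '%s'", kind), "ft_vocabulary_error")
  }
  need <- function(...) {
    vals <- c(...)
    if (any(!is.finite(vals))) {
      ft_stop(sprintf("glyph '%s': required geometry fields are missing",
                      kind), "ft_geometry_error")
    }
  }
  out <- switch(kind,
    rect = {
      need(x, y, width, height)
      list(kind = "rect", x = x, y = y, width = width, height = height)
    },
    circle = {
      need(cx, cy, r)
      list(kind = "circle", cx = cx, cy = cy, r = r)
    },
    diamond = {
      need(cx, cy, r)
      list(kind = "polygon",
           points = rbind(c(cx, cy - r), c(cx + r, cy),
                          c(cx, cy + r), c(cx - r, cy)))
    },
    triangle = {
      need(cx, cy, r)
      list(kind = "polygon",
           points = rbind(c(cx, cy - r), c(cx + r, cy + r),
                          c(cx - r, cy + r)))
    },
    hexagon = {
      need(cx, cy, r)
      th <- seq(0, 300, by = 60) * pi / 180
      list(kind = "polygon",
           points = cbind(cx + r * cos(th), cy - r * sin(th)))
    },
    wave = {
      need(cx, cy, r)
      hr <- r / 2
      list(kind = "path",
           path = sprintf("M %s %s A %s %s 0 0 1 %s %s A %s %s 0 0 0 %s %s",
                          num(cx - r), num(cy), num(hr), num(hr),
                          num(cx), num(cy), num(hr), num(hr),
                          num(cx + r), num(cy)))
    },
    bridge = {
      need(x, y, width, height)
      list(kind = "polyline",
           points = rbind(c(x, y + height), c(x, y),
                          c(x + width, y), c(x + width, y + height)))
    },
    line = {
      need(cx, cy, r)
      list(kind = "line", x1 = cx, y1 = cy - r, x2 = cx, y2 = cy + r)
    }
  )
  structure(c(out, list(glyph = kind)), class = "ft_glyph_outline")
}

points_attr <- function(points) {
  paste(sprintf("%s,%s", num(points[, 1]), num(points[, 2])), collapse = " ")
}

add_glyph_node <- function(parent, outline) {
  switch(outline$kind,
    rect = xml2::xml_add_child(parent, "rect",
                               x = num(outline$x), y = num(outline$y),
                               width = num(outline$width),
                               height = num(outline$height)),
    circle = xml2::xml_add_child(parent, "circle",
                                 cx = num(outline$cx), cy = num(outline$cy),
                                 r = num(outline$r)),
    polygon = xml2::xml_add_child(parent, "polygon",
                                  points = points_attr(outline$points)),
    polyline = xml2::xml_add_child(parent, "polyline",
                                   points = points_attr(outline$points),
                                   fill = "none"),
    path = xml2::xml_add_child(parent, "path", d = outline$path,
                               fill = "none"),
    line = xml2::xml_add_child(parent, "line",
                               x1 = num(outline$x1), y1 = num(outline$y1),
                               x2 = num(outline$x2), y2 = num(outline$y2))
  )
}

#' Render a layout document as SVG
#'
#' Produces a standalone SVG 1.1 document: the ruler with tick marks and
#' residue labels, the sequence line, one `<g>` group per placed feature
#' (stable id derived from the feature id; fill, stroke, opacity and stroke
#' width from the document; a `<title>` child carrying the tooltip text, so
#' standard viewers show it on hover), dashed edge markers on
#' window-clipped features, optional grid lines, and the legend block.
#' Output is byte-deterministic for equal documents and the document is
#' never mutated.
#'
#' @param doc An `ft_layout` from [build_layout()] or [read_layout_json()].
#' @param highlight Optional `feature_id` rendered in an emphasized
#'   (selected) style.
#' @return SVG text (a character scalar).
#' @export
#' @examples
#' f <- feature("f1", 74, 96, type_label = "Peptide")
#' svg <- render_svg(build_layout("Q8LAX3", list(f), layout_config(96)))
#' substr(svg, 1, 60)
render_svg <- function(doc, highlight = NULL) {
  stopifnot(inherits(doc, "ft_layout"))
  cfg <- doc$config
  der <- doc$derived
  size_y <- if (is.finite(der$size_y)) der$size_y else {
    round_half_up(cfg$sequence_line_y + cfg$below_ruler)
  }
  root <- xml2::xml_new_root(
    "svg",
    xmlns = "http://www.w3.org/2000/svg",
    version = "1.1",
    width = num(cfg$size_x), height = num(size_y),
    viewBox = sprintf("0 0 %s %s", num(cfg$size_x), num(size_y))
  )
  right <- cfg$left_margin + der$ruler_length
  p <- doc$placed
  tracks_bottom <- max(c(cfg$sequence_line_y,
                         if (nrow(p)) p$y + p$height))

  if (cfg$show_vertical_grid) {
    grid <- xml2::xml_add_child(root, "g", id = "vertical-grid",
                                stroke = "#DDDDDD", `stroke-width` = "1")
    for (tx in doc$ticks$x_px) {
      xml2::xml_add_child(grid, "line", x1 = num(tx), y1 = num(cfg$ruler_y),
                          x2 = num(tx), y2 = num(tracks_bottom))
    }
  }
  if (cfg$show_horizontal_grid && nrow(p)) {
    grid <- xml2::xml_add_child(root, "g", id = "horizontal-grid",
                                stroke = "#DDDDDD", `stroke-width` = "1")
    for (gy in sort(unique(p$y))) {
      xml2::xml_add_child(grid, "line", x1 = num(cfg$left_margin),
                          y1 = num(gy), x2 = num(right), y2 = num(gy))
    }
  }

  ruler <- xml2::xml_add_child(root, "g", id = "ruler", stroke = "#333333",
                               `stroke-width` = "1")
  xml2::xml_add_child(ruler, "line", x1 = num(cfg$left_margin),
                      y1 = num(cfg$ruler_y), x2 = num(right),
                      y2 = num(cfg$ruler_y))
  for (i in seq_len(nrow(doc$ticks))) {
    tx <- doc$ticks$x_px[i]
    xml2::xml_add_child(ruler, "line", x1 = num(tx), y1 = num(cfg$ruler_y),
                        x2 = num(tx), y2 = num(cfg$ruler_y + 4))
    if (!is.na(doc$ticks$label[i])) {
      lbl <- xml2::xml_add_child(ruler, "text", x = num(tx),
                                 y = num(cfg$ruler_y - 3),
                                 `text-anchor` = "middle",
                                 `font-size` = "9", stroke = "none",
                                 fill = "#333333")
      xml2::xml_set_text(lbl, as.character(doc$ticks$label[i]))
    }
  }

  xml2::xml_add_child(root, "line", id = "sequence-line",
                      x1 = num(cfg$left_margin), y1 = num(cfg$sequence_line_y),
                      x2 = num(right), y2 = num(cfg$sequence_line_y),
                      stroke = "#000000", `stroke-width` = "1")

  for (i in seq_len(nrow(p))) {
    hl <- !is.null(highlight) && identical(p$feature_id[i], highlight)
    gid <- sprintf("feature-%d-%s", i,
                   gsub("[^A-Za-z0-9_.-]", "_", p$feature_id[i]))
    g <- xml2::xml_add_child(
      root, "g", id = gid,
      fill = p$fill[i], stroke = p$stroke[i],
      `fill-opacity` = num(if (hl) 0.9 else p$fill_opacity[i]),
      `stroke-width` = num(p$stroke_width[i] + if (hl) 1 else 0)
    )
    if (hl) xml2::xml_set_attr(g, "class", "highlighted")
    title <- xml2::xml_add_child(g, "title")
    xml2::xml_set_text(title, p$tooltip[i])
    outline <- glyph_outline(p$glyph[i], cx = p$cx[i], cy = p$cy[i],
                             r = p$r[i], x = p$x[i], y = p$y[i],
                             width = p$width[i], height = p$height[i])
    add_glyph_node(g, outline)
    if (p$clipped_left[i]) {
      xml2::xml_add_child(g, "line", x1 = num(p$x[i]), y1 = num(p$y[i]),
                          x2 = num(p$x[i]), y2 = num(p$y[i] + p$height[i]),
                          `stroke-dasharray` = "3,2", class = "clipped-edge")
    }
    if (p$clipped_right[i]) {
      xr <- p$x[i] + p$width[i]
      xml2::xml_add_child(g, "line", x1 = num(xr), y1 = num(p$y[i]),
                          x2 = num(xr), y2 = num(p$y[i] + p$height[i]),
                          `stroke-dasharray` = "3,2", class = "clipped-edge")
    }
  }

  if (nrow(doc$legend)) {
    leg <- xml2::xml_add_child(root, "g", id = "legend", `font-size` = "10")
    y0 <- size_y - legend_height(nrow(doc$legend)) + 10
    for (i in seq_len(nrow(doc$legend))) {
      ly <- y0 + (i - 1) * legend_row_height()
      sw <- 10
      entry <- doc$legend[i, ]
      outline <- switch(entry$glyph,
        rect = glyph_outline("rect", x = cfg$left_margin, y = ly,
                             width = sw, height = sw),
        bridge = glyph_outline("bridge", x = cfg$left_margin, y = ly,
                               width = sw, height = sw),
        glyph_outline(entry$glyph, cx = cfg$left_margin + sw / 2,
                      cy = ly + sw / 2, r = sw / 2)
      )
      swatch <- xml2::xml_add_child(leg, "g", fill = entry$color,
                                    stroke = entry$color,
                                    `fill-opacity` = "0.5")
      add_glyph_node(swatch, outline)
      txt <- xml2::xml_add_child(
        leg, "text", x = num(cfg$left_margin + sw + 6),
        y = num(ly + sw - 1), fill = "#333333")
      xml2::xml_set_text(txt, if (nzchar(entry$type_category)) {
        sprintf("%s (%s)", entry$type_label, entry$type_category)
      } else {
        entry$type_label
      })
    }
  }

  as.character(root)
}

# locate a PNG rasterizer; NULL when none is available
png_backend <- function() {
  if (requireNamespace("rsvg", quietly = TRUE)) {
    return(function(svg, path, w, h) {
      rsvg::rsvg_png(charToRaw(svg), file = path, width = w, height = h)
    })
  }
  if (requireNamespace("magick", quietly = TRUE)) {
    return(function(svg, path, w, h) {
      img <- magick::image_read_svg(charToRaw(svg), width = w, height = h)
      magick::image_write(img, path, format = "png")
    })
  }
  conv <- Sys.which("rsvg-convert")
  if (nzchar(conv)) {
    return(function(svg, path, w, h) {
      tmp <- tempfile(fileext = ".svg")
      on.exit(unlink(tmp))
      writeLines(svg, tmp, useBytes = TRUE)
      system2(conv, c("-w", w, "-h", h, "-o", shQuote(path), shQuote(tmp)))
    })
  }
  NULL
}

#' Export rendered SVG to PNG
#'
#' Rasterizes SVG text at an integer scale factor. PNG export is an
#' optional capability: when no raster backend (the `rsvg` or `magick`
#' package, or the `rsvg-convert` tool) is available, a classed
#' `ft_capability_error` is raised with a remediation hint and output
#' remains SVG-only; nothing crashes.
#'
#' @param svg SVG text from [render_svg()].
#' @param path Output PNG path.
#' @param scale Multiplier applied to the SVG width and height.
#' @return `path`, invisibly.
#' @export
export_png <- function(svg, path, scale = 1) {
  backend <- png_backend()
  if (is.null(backend)) {
    ft_stop(paste0(
      "no SVG raster backend available; output remains SVG-only ",
      "(install the 'rsvg' R package or the rsvg-convert tool to enable ",
      "PNG export)"), "ft_capability_error")
  }
  x <- xml2::read_xml(svg)
  w <- round_half_up(as.numeric(xml2::xml_attr(x, "width")) * scale)
  h <- round_half_up(as.numeric(xml2::xml_attr(x, "height")) * scale)
  backend(svg, path, w, h)
  invisible(path)
}
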