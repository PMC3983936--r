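test_that("derived geometry matches hand-computed scales", {
  g <- derive_geometry(layout_config(96))
  expect_equal(g$ruler_length, 660)
  expect_equal(g$unitsize, 6.875)

  g2 <- derive_geometry(layout_config(100, size_x = 140))
  expect_equal(g2$unitsize, 1.0)

  cfg3 <- layout_config(96, requested_start = 54, requested_stop = 96)
  expect_equal(derive_geometry(cfg3)$unitsize, 660 / 43)
})

test_that("position-to-pixel mapping reproduces the anchored example", {
  cfg <- layout_config(96)
  g <- derive_geometry(cfg)
  expect_identical(position_to_pixel(74, cfg, g), 529L)  # 528.75 rounds up
  expect_identical(position_to_pixel(96, cfg, g), 680L)  # right ruler end
  expect_identical(position_to_pixel(0, cfg, g), 20L)    # origin
  expect_error(position_to_pixel(97, cfg, g), class = "ft_range_error")
  expect_error(position_to_pixel(-1, cfg, g), class = "ft_range_error")
})

test_that("pixel mapping is monotone with consistent endpoints", {
  set.seed(101)
  for (i in 1:50) {
    len <- sample(30:3000, 1)
    a <- sample.int(len, 1)
    b <- a + sample.int(len - a + 1L, 1) - 1L
    cfg <- layout_config(len, size_x = sample(200:1400, 1),
                         left_margin = sample(5:40, 1),
                         right_margin = sample(5:40, 1),
                         requested_start = a, requested_stop = b)
    g <- derive_geometry(cfg)
    ps <- sort(sample((a - 1):b, min(40, b - a + 2)))
    xs <- position_to_pixel(ps, cfg, g)
    expect_true(all(diff(xs) >= 0))
    span <- position_to_pixel(b, cfg, g) -
      position_to_pixel(a - 1, cfg, g)
    expect_lte(abs(span - g$ruler_length), 1)
  }
})

test_that("region widths round half-up from exact products", {
  expect_identical(region_width(74, 96, 6.875), 151L)  # 151.25 rounds down
  expect_identical(region_width(10, 10, 6.875), 0L)
  expect_identical(region_width(1, 97, 1.0), 96L)
  expect_error(region_width(9, 5, 1), class = "ft_coordinate_error")
})

test_that("mutually overlapping listing features occupy three tracks", {
  fs <- list(feature("a", 54, 96), feature("b", 74, 96), feature("c", 75, 96))
  tr <- assign_tracks(fs)
  expect_identical(unname(tr[c("a", "b", "c")]), c(0L, 1L, 2L))
  expect_identical(max(tr) + 1L, depth_oracle(fs))
})

test_that("disjoint features share track 0", {
  tr <- assign_tracks(list(feature("a", 1, 10), feature("b", 20, 30)))
  expect_identical(unname(tr), c(0L, 0L))
})

test_that("greedy packing is optimal and non-overlapping on random sets", {
  set.seed(202)
  for (i in 1:20) {
    fs <- random_features(sample(5:200, 1), sample(50:800, 1))
    tr <- assign_tracks(fs)
    expect_identical(max(tr) + 1L, depth_oracle(fs))
    # no two features on one track overlap (closed intervals)
    by_track <- split(fs, tr[vapply(fs, function(f) f$feature_id,
                                    character(1))])
    for (grp in by_track) {
      if (length(grp) < 2) next
      s <- vapply(grp, function(f) f$start, integer(1))
      e <- vapply(grp, function(f) f$end, integer(1))
      o <- order(s)
      expect_true(all(s[o][-1] > e[o][-length(e)]))
    }
  }
})

test_that("rows are one per type, ordered by category then label", {
  fs <- list(
    feature("p1", 5, 20, type_label = "Peptide",
            type_category = "Molecule processing"),
    feature("a1", 8, 8, type_label = "Active Site",
            type_category = "Molecule processing"),
    feature("p2", 30, 40, type_label = "Peptide",
            type_category = "Molecule processing")
  )
  rows <- assign_rows(fs)
  expect_identical(unname(rows[c("a1", "p1", "p2")]), c(0L, 1L, 1L))

  one <- assign_rows(list(feature("x", 1, 5, type_label = "Peptide")))
  expect_identical(unname(one), 0L)

  set.seed(7)
  fs2 <- random_features(60, 300)
  rows2 <- assign_rows(fs2)
  k <- length(unique(vapply(fs2, function(f) f$type_label, character(1))))
  expect_identical(length(unique(rows2)), k)
})

test_that("default glyphs follow the type-keyed shape rules", {
  expect_identical(default_glyph("Active Site"), "diamond")
  expect_identical(default_glyph("metal ion binding"), "circle")
  expect_identical(default_glyph("Lipidation"), "wave")
  expect_identical(default_glyph("N-linked Glycosylation"), "hexagon")
  expect_identical(default_glyph("Modified residue"), "triangle")
  expect_identical(default_glyph("Disulfide bond"), "bridge")
  expect_identical(default_glyph("Peptide"), "rect")
  expect_identical(default_glyph("Peptide", site = TRUE), "line")
  # rules also fire on the ontology code
  expect_identical(default_glyph("", "PTM:0001"), "triangle")
})

test_that("colors are explicit-first, then a stable hash into the palette", {
  expect_identical(assign_color("SO:0001064", "#33FF66"), "#33FF66")
  expect_identical(assign_color("SO:0001064"), assign_color("SO:0001064"))
  expect_true(assign_color("SO:0001064") %in% type_palette())
  # the synthetic vocabulary maps to more than one palette slot
  cols <- vapply(default_type_vocabulary()$code, assign_color, character(1))
  expect_gt(length(unique(cols)), 1L)
  expect_error(assign_color("x", "##bad"), class = "ft_validation_error")
})

test_that("ruler ticks cover the window with suppressed duplicate labels", {
  cfg <- layout_config(96)
  g <- derive_geometry(cfg)
  ticks <- compute_ruler(cfg, g)
  expect_identical(nrow(ticks), 15L)  # 14 at 20,70,...,670 plus final 680
  expect_identical(ticks$x_px, as.integer(c(seq(20, 670, by = 50), 680)))
  expect_true(all(diff(ticks$x_px) > 0))
  expect_identical(ticks$label[1], 1L)
  expect_identical(ticks$label[nrow(ticks)], 96L)

  wide <- layout_config(96, pixels_division = 1000)
  t2 <- compute_ruler(wide, derive_geometry(wide))
  expect_identical(nrow(t2), 2L)
  expect_identical(t2$x_px, c(20L, 680L))

  # zoomed to a single residue all labels clamp; duplicates are suppressed
  one <- layout_config(96, requested_start = 10, requested_stop = 10)
  t3 <- compute_ruler(one, derive_geometry(one))
  expect_identical(sum(!is.na(t3$label)), 1L)
})

test_that("placement resolves per-style vertical geometry", {
  cfg <- layout_config(96, style = "centered")
  g <- derive_geometry(cfg)
  placed <- place_features(list(q8lax3_feature()), cfg, g)
  expect_identical(placed$y, 75L)  # 95 - 40/2

  expect_identical(nrow(place_features(list(), cfg, g)), 0L)

  # stacked styles step down from the sequence line by track_gap
  cfg2 <- layout_config(96)
  g2 <- derive_geometry(cfg2)
  fs <- list(feature("a", 54, 96), feature("b", 74, 96))
  p2 <- place_features(fs, cfg2, g2)
  expect_identical(p2$y, c(56L, 68L))  # 54+2, then +10+2

  # site glyph center geometry
  site <- feature("m", 30, 30, type_label = "Metal ion binding")
  p3 <- place_features(list(site), cfg2, g2)
  expect_identical(p3$glyph, "circle")
  expect_identical(p3$width, 0L)
  expect_equal(p3$r, cfg2$track_height / 2)
  expect_equal(p3$cy, p3$y + p3$height / 2)
  expect_identical(p3$cx, position_to_pixel(30, cfg2, g2))
})

test_that("legend entries are unique on label, color and glyph", {
  cfg <- layout_config(770)
  g <- derive_geometry(cfg)
  # 3 features, 2 distinct types sharing color and glyph within type
  fs <- list(
    feature("p1", 5, 30, type_label = "Peptide", color = "blue"),
    feature("p2", 100, 130, type_label = "Peptide", color = "blue"),
    feature("a1", 50, 50, type_label = "Active Site", color = "#33FF66")
  )
  leg <- build_legend(place_features(fs, cfg, g))
  expect_identical(nrow(leg), 2L)
  expect_identical(leg$type_label, c("Active Site", "Peptide"))

  expect_identical(nrow(build_legend(place_features(list(), cfg, g))), 0L)

  # same label, different colors stay distinct
  fs2 <- list(
    feature("x", 1, 10, type_label = "Peptide", color = "blue"),
    feature("y", 20, 30, type_label = "Peptide", color = "red")
  )
  expect_identical(nrow(build_legend(place_features(fs2, cfg, g))), 2L)
})

test_that("the worked single-peptide document reproduces printed geometry", {
  doc <- q8lax3_doc()
  expect_equal(doc$derived$unitsize, 6.875)
  expect_equal(doc$derived$ruler_length, 660)
  expect_identical(doc$placed$x, 529L)
  expect_identical(doc$placed$width, 151L)
  expect_identical(doc$placed$y, 56L)
  expect_identical(doc$placed$fill, "#7DBAA4")
  expect_identical(doc$alt_styles$centered_y, 75L)
  expect_identical(doc$alt_styles$centered_h, 40)
})

test_that("an empty feature set yields a ruler-and-margins-only document", {
  doc <- build_layout("empty", list(), layout_config(200))
  expect_identical(nrow(doc$placed), 0L)
  expect_identical(nrow(doc$legend), 0L)
  expect_gt(nrow(doc$ticks), 1L)
  expect_true(is.finite(doc$derived$size_y))
})

test_that("zooming clips, rescales, and is idempotent", {
  doc <- q8lax3_doc()

  # zoom to the full sequence is the identity
  expect_equal(zoom_layout(doc, 1, 96), doc)

  z <- zoom_layout(doc, 74, 96)
  expect_equal(z$derived$unitsize, 660 / 23)
  # idempotent for a fixed window
  expect_equal(zoom_layout(z, 74, 96), z)

  # a feature straddling the left edge is clipped and flagged
  doc2 <- build_layout("s", list(feature("a", 54, 96)), layout_config(96))
  z2 <- zoom_layout(doc2, 74, 96)
  expect_identical(z2$placed$start, 74L)
  expect_true(z2$placed$clipped_left)
  expect_false(z2$placed$clipped_right)
  # zooming back out restores the original
  expect_equal(zoom_layout(z2, 1, 96), doc2)

  # features wholly outside the window are dropped
  z3 <- zoom_layout(doc2, 1, 20)
  expect_identical(nrow(z3$placed), 0L)

  expect_error(zoom_layout(doc, 50, 10), class = "ft_range_error")
  expect_error(zoom_layout(doc, 1, 200), class = "ft_range_error")
})

test_that("layout documents satisfy structural invariants on a big fixture", {
  fs <- generate_fixture(100, 1500, max_depth = 6, seed = 11)
  cfg <- layout_config(1500)
  doc <- build_layout("fixture", fs, cfg)
  p <- doc$placed
  expect_identical(nrow(p), 100L)
  # sorted by (track_index, x)
  expect_false(is.unsorted(p$track_index))
  for (t in unique(p$track_index)) {
    expect_false(is.unsorted(p$x[p$track_index == t]))
  }
  # horizontal bounds after clipping
  expect_true(all(p$x >= cfg$left_margin))
  expect_true(all(p$x + p$width <= cfg$left_margin +
                    doc$derived$ruler_length))
  # packing matches the independent depth oracle
  expect_identical(max(p$track_index) + 1L, depth_oracle(fs))
})

test_that("layout is deterministic: equal inputs give identical bytes", {
  fs <- generate_fixture(30, 400, seed = 5)
  a <- write_layout_json(build_layout("d", fs, layout_config(400)))
  b <- write_layout_json(build_layout("d", fs, layout_config(400)))
  expect_identical(a, b)
})
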