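test_that("the simple-features dialect parses the canonical 3-feature set", {
  sf <- read_simple_features(extdata("a4_human.json"))
  expect_identical(sf$segment_id, "a4_human")
  expect_identical(sf$sequence_length, 770L)
  expect_length(sf$features, 3L)
  f1 <- sf$features[[1]]
  expect_identical(f1$start, 54L)
  expect_identical(f1$end, 96L)
  expect_identical(f1$color, "blue")
  expect_null(f1$shape_hint)
  expect_identical(sf$features[[2]]$shape_hint, "diamond")
  expect_identical(sf$features[[3]]$shape_hint, "bridge")
  expect_identical(sf$features[[3]]$color, "#33FF66")
})

test_that("simple-features edge cases: empty array, unknown keys, errors", {
  empty <- read_simple_features(
    '{"sequenceId":"s","sequenceLength":10,"features":[]}')
  expect_length(empty$features, 0L)

  expect_warning(
    read_simple_features(paste0(
      '{"sequenceId":"s","sequenceLength":10,"features":',
      '[{"featureId":"f","featureStart":1,"featureEnd":2,"frobnicate":1}]}')),
    "frobnicate")

  expect_error(
    read_simple_features(paste0(
      '{"sequenceId":"s","sequenceLength":10,',
      '"features":[{"featureId":"f","featureEnd":2}]}')),
    regexp = "element 1", class = "ft_parse_error")
  expect_error(
    read_simple_features(paste0(
      '{"sequenceId":"s","sequenceLength":10,"features":',
      '[{"featureId":"f","featureStart":"one","featureEnd":2}]}')),
    class = "ft_parse_error")
  expect_error(read_simple_features('{"features":[]}'),
               class = "ft_schema_error")
  expect_error(read_simple_features('{"not json'), class = "ft_parse_error")
})

test_that("simple-features write/read is the identity", {
  fs <- generate_fixture(25, 600, max_depth = 4, seed = 9)
  txt <- write_simple_features("seg", 600, fs)
  back <- read_simple_features(txt)
  expect_identical(back$segment_id, "seg")
  expect_identical(back$sequence_length, 600L)
  expect_equal(back$features, fs)
})

test_that("GFF3 parses unshifted coordinates and mapped attributes", {
  r <- read_gff3("Q8LAX3\t.\tactive_peptide\t74\t96\t.\t.\t.\tID=f1")
  expect_identical(r$segment_id, "Q8LAX3")
  f <- r$features[[1]]
  expect_identical(f$start, 74L)
  expect_identical(f$end, 96L)
  expect_identical(f$type_label, "active_peptide")
  expect_identical(f$feature_id, "f1")

  ex <- read_gff3(extdata("example.gff3"))
  expect_length(ex$features, 3L)
  expect_identical(ex$features[[1]]$feature_label, "Elicitor peptide 3")
  expect_identical(ex$features[[2]]$type_category, "Binding site")

  # unmapped attributes are preserved in evidence_text
  r2 <- read_gff3("S\t.\tchain\t1\t9\t.\t.\t.\tID=c1;custom_key=hello")
  expect_match(r2$features[[1]]$evidence_text, "custom_key=hello",
               fixed = TRUE)
})

test_that("GFF3 errors carry line numbers and reject multiple segments", {
  expect_identical(length(read_gff3("##gff-version 3")$features), 0L)
  expect_error(read_gff3("##gff-version 3\nS\t.\tchain\t1"),
               regexp = "line 2", class = "ft_parse_error")
  expect_error(read_gff3("S\t.\tchain\tx\t9\t.\t.\t.\tID=a"),
               class = "ft_parse_error")
  expect_error(
    read_gff3("A\t.\tchain\t1\t9\t.\t.\t.\tID=a\nB\t.\tchain\t1\t9\t.\t.\t.\tID=b"),
    class = "ft_multisegment_error")
})

test_that("random features survive a GFF3 write/read round trip", {
  fs <- generate_fixture(20, 400, max_depth = 5, seed = 21)
  back <- read_gff3(write_gff3(fs, "SYN"))
  expect_identical(back$segment_id, "SYN")
  expect_equal(back$features, fs)

  # attribute values with reserved characters are percent-encoded
  tricky <- list(feature("id with space", 3, 9, type_label = "Peptide",
                         feature_label = "a;b=c, d%e",
                         evidence_text = "x; y"))
  expect_equal(read_gff3(write_gff3(tricky, "S"))$features, tricky)
})

test_that("layout JSON carries the printed geometry and round-trips", {
  doc <- q8lax3_doc()
  txt <- write_layout_json(doc)
  parsed <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  el <- parsed$featuresArray[[1]]
  expect_identical(el$x, 529L)
  expect_identical(el$width, 151L)
  expect_equal(parsed$configuration$unitsize, 6.875)
  expect_equal(parsed$configuration$rulerLength, 660L)
  expect_identical(parsed$segment, "Q8LAX3")
  expect_identical(el$centeredStyle$y, 75L)

  expect_equal(read_layout_json(txt), doc)

  # write -> read -> re-layout reproduces identical placed geometry
  back <- read_layout_json(txt)
  again <- build_layout(back$segment_id, back$features, back$config)
  expect_equal(again$placed, doc$placed)

  # empty document keeps a full configuration block
  d0 <- build_layout("none", list(), layout_config(50))
  p0 <- jsonlite::fromJSON(write_layout_json(d0), simplifyVector = FALSE)
  expect_length(p0$featuresArray, 0L)
  expect_true(all(c("style", "unitsize", "rulerLength") %in%
                    names(p0$configuration)))
  expect_equal(read_layout_json(write_layout_json(d0)), d0)
})

test_that("layout JSON validation lists missing keys", {
  doc <- q8lax3_doc()
  parsed <- jsonlite::fromJSON(write_layout_json(doc),
                               simplifyVector = FALSE)
  parsed$configuration$unitsize <- NULL
  broken <- jsonlite::toJSON(parsed, auto_unbox = TRUE, digits = NA)
  expect_error(read_layout_json(broken), regexp = "configuration.unitsize",
               fixed = TRUE, class = "ft_schema_error")
  expect_error(read_layout_json('{"segment":"s"}'),
               class = "ft_schema_error")
})

test_that("a hand-written document in the published form is renderer-ready", {
  doc <- read_layout_json(extdata("q8lax3_layout.json"))
  expect_identical(doc$segment_id, "Q8LAx3")  # ids are opaque, case kept
  expect_identical(nrow(doc$placed), 1L)
  expect_identical(doc$placed$x, 529L)
  expect_identical(doc$placed$width, 151L)
  expect_equal(doc$derived$unitsize, 6.875)
  # no re-layout: rendering consumes the stored geometry directly
  expect_s3_class(doc, "ft_layout")
  expect_silent(render_svg(doc))
})
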