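Package: featuretracks
Title: Layout and SVG Rendering of Position-Based Protein Sequence Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes pixel layouts for position-based protein sequence
    annotations (domains, sites, modified residues, disulfide bridges) and
    renders them as Scalable Vector Graphics. Features are packed into
    non-overlapping tracks by greedy interval partitioning, grouped into
    per-type rows, or drawn centered on the sequence line. Includes readers
    for GFF3 and a simple JSON annotation dialect, a writer and reader for
    fully resolved layout documents, a sequence ruler, typed glyph shapes
    (circle, diamond, triangle, hexagon, wave, bridge), window zooming with
    clipping, a deterministic synthetic-feature generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
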