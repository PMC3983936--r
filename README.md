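# featuretracks

Position-based annotations — domains, active sites, modified residues,
disulfide bridges — are the workhorse representation of protein function:
UniProt, Pfam and prediction servers all publish labeled intervals on the
residue axis. `featuretracks` is an R package for turning such annotations
into drawings. It computes a complete pixel layout for a set of features on
one protein and renders it as SVG, for bioinformaticians who need
publication-ready feature tracks or a layout engine to embed in a larger
pipeline.

## The method

All coordinates are 1-based and inclusive at both ends (the UniProt and
GFF3 convention). For a canvas of width `sizeX` with margins `leftMargin`
and `rightMargin` and a residue window `[requestedStart, requestedStop]`:

```
rulerLength = sizeX − leftMargin − rightMargin
unitsize    = rulerLength / (requestedStop − requestedStart + 1)   # px per residue
x(p)        = leftMargin + (p − requestedStart + 1) · unitsize     # round half-up
width(s,e)  = (e − s) · unitsize                                   # round half-up
```

`unitsize` keeps full floating precision; rounding to whole pixels happens
once, at emission. Three layout styles are supported:

* **nonOverlapping** — features are packed into the minimum number of
  horizontal tracks by greedy first-fit over start-sorted intervals. For
  closed intervals this greedy packing is optimal: the number of tracks it
  uses equals the maximum overlap depth of the interval set.
* **rows** — one row per feature type, ordered by (category, label).
* **centered** — every feature is drawn astride the single sequence line
  (`y = sequenceLineY − height/2`).

Single-residue sites are drawn as typed glyphs — circles for metal binding,
diamonds for active sites, waves for lipidation, hexagons for
glycosylation, triangles for other modified residues — and disulfide bonds
as an inverted-U bridge. A layout document is fully resolved before
drawing: the SVG renderer performs no layout math, so documents serialized
with `write_layout_json()` render identically anywhere.

## Worked example

One active peptide at residues 74–96 of the 96-residue segment Q8LAX3, on
the default 700 px canvas:

```r
library(featuretracks)
f <- feature("UPKB_Q8LAX3_PEPTIDE_74_96", 74, 96,
             type_label = "active_peptide", type_code = "SO:0001064",
             feature_label = "Elicitor peptide 3", color = "#7DBAA4")
doc <- build_layout("Q8LAX3", list(f), layout_config(96))
doc
#> <layout document: segment Q8LAX3, 1 placed feature>
#>   style nonOverlapping, window 1-96 of 96 residues
#>   canvas 700 x 122 px, unitsize 6.875 px/residue, 1 track
doc$placed[, c("x", "width", "y")]
#>     x width  y
#> 1 529   151 56
```

With 660 usable pixels over 96 residues the scale is 6.875 px/residue; the
peptide's left edge lands at `20 + 74 × 6.875 = 528.75 → 529` px and its
width is `22 × 6.875 = 151.25 → 151` px. Zooming rescales the window:

```r
zoom_layout(doc, 74, 96)$derived$unitsize
#> [1] 28.69565        # 660 / 23
writeLines(render_svg(doc), "q8lax3.svg")
```

A command-line wrapper covers the same pipeline
(`inst/cli/featuretracks render --input features.json --out-svg out.svg`),
and `generate_fixture()` produces deterministic synthetic feature sets for
testing.

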