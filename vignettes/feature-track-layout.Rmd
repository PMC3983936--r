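---
title: "Laying out protein feature tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laying out protein feature tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(featuretracks)
```

## The model

A *feature* is a labeled closed interval `[start, end]` on a protein
sequence, with 1-based inclusive coordinates throughout — the UniProt and
GFF3 convention, so nothing is shifted on read or write. `start == end` is
legal and marks a single-residue site; `start > end` is rejected (there is
no wrap-around). A drawing is produced in two strictly separated stages:

1. the **layout engine** resolves every feature to pixel geometry inside a
   *layout document*;
2. the **renderer** draws the document verbatim as SVG, performing no
   arithmetic beyond reading stored coordinates.

This split is what makes documents portable: `write_layout_json()` output
can be rendered by any consumer without reimplementing the layout rules.

### Coordinate mapping

For a canvas `size_x` pixels wide with margins `left_margin` and
`right_margin` and a residue window `[requested_start, requested_stop]`,

$$\mathrm{rulerLength} = \mathrm{sizeX} - \mathrm{leftMargin} - \mathrm{rightMargin},
\qquad u = \frac{\mathrm{rulerLength}}{\mathrm{stop} - \mathrm{start} + 1},$$

and a residue $p$ maps to
$x(p) = \mathrm{leftMargin} + (p - \mathrm{start} + 1)\,u$, rounded
half-up. The `+1` offset anchors the mapping so that
$x(\mathrm{start} - 1)$ is exactly the left margin and $x(\mathrm{stop})$
exactly the right end of the ruler. On the canonical 700 px canvas with
20 px margins and a 96-residue window this gives $u = 660/96 = 6.875$
px/residue, $x(74) = 20 + 74 \times 6.875 = 528.75 \to 529$, and a 74–96
region width of $22 \times 6.875 = 151.25 \to 151$ px — the reference
values the acceptance checks pin down.

Two numerical choices matter here. First, $u$ is never rounded; only final
pixel coordinates are. Second, rounding is half-*up* (`floor(x + 0.5)`)
rather than R's default half-to-even: both reference roundings above are
plain nearest-integer and do not discriminate, so the tie-break is a
convention; half-up is fixed so that output is bit-reproducible across
platforms. Because `x` and `width` are rounded independently, `x + width`
can overshoot the ruler end by one pixel in the worst case; widths are
clamped to the drawable band, which never alters the reference values.

### The three styles

* **nonOverlapping.** Features are sorted by `(start, end, feature_id)` and
  packed greedily: each goes to the lowest-index track whose last interval
  ends before this one starts (closed-interval test). For intervals sorted
  by start, first-fit attains the maximum overlap depth, which is a lower
  bound for any packing — so the track count is provably minimal. The test
  suite checks this against an independent brute-force depth oracle on
  hundreds of randomized interval sets.
* **rows.** One row per distinct type label, ordered lexicographically by
  `(type_category, type_label)` in the C locale. Overlaps within a row are
  permitted by design.
* **centered.** Every feature sits astride the sequence line:
  `y = sequence_line_y − track_height/2` (95 − 40/2 = 75 on the canonical
  centered canvas).

Stacked styles place track $k$ at
`sequence_line_y + track_gap + k (track_height + track_gap)`. The 2 px
`track_gap` default reflects the canonical stacked canvas, where the first
track top (56) sits 2 px below the sequence line (54); the vertical
stacking rule is a design choice of this package — reference documents
constrain the first track only indirectly, so the acceptance checks
deliberately avoid stacked `y` values.

### Glyphs, colors, ruler, legend

Single-residue sites are drawn as typed shapes keyed to the feature type by
case-insensitive substring rules (metal → circle, active site → diamond,
lipidation → wave, glycosylation → hexagon, modified residue/PTM →
triangle, disulfide/bridge → bridge); anything else is a vertical line for
sites and a rectangle for regions. An explicit shape hint on the feature
always wins. The wave has no canonical outline in the field, so it is
defined here as two joined semicircular arcs (crest then trough) spanning
`2r`; the bridge is an inverted-U polyline over its full residue span, and
it participates in track packing with that full span, as do sites with
their single-residue interval.

Explicit feature colors are kept verbatim (`#RRGGBB` or a CSS-style name,
validated by pattern, never normalized). Otherwise the ontology type code
is hashed — a 31-multiplier polynomial over its bytes, reduced into a fixed
12-color palette — so colors are stable across runs and platforms without
any global state.

Ruler ticks sit every `pixels_division` px (default 50) from the left
margin, plus a terminal tick at the exact ruler end. Labels invert the
pixel mapping and clamp to the window; the origin is labeled
`requested_start`, the terminus `requested_stop`, and a label equal to its
predecessor is suppressed while its tick mark is kept. The legend holds one
entry per distinct `(type_label, color, glyph)`, ordered by
`(type_category, type_label)`; its height is computed from the entry count
rather than carried as a separate configuration value.

### Zooming and clipping

`zoom_layout()` rebuilds the document from its original features under a
new window. Features wholly outside are dropped; straddling features are
clipped to the window and the truncated edge is flagged so the renderer
can mark it (a dashed edge line — reference documents are silent on
partial-window features, so flagging rather than restyling is this
package's choice). Zooming to the full sequence reproduces the original
document exactly, and zooming to the current window is a no-op; both are
property-tested.

## Tunable parameters

| parameter | unit | default | why |
|---|---|---|---|
| `size_x` | px | 700 | canonical canvas width |
| `left_margin`, `right_margin` | px | 20 | canonical margins; leave room for site glyph radii |
| `pixels_division` | px | 50 | canonical ruler spacing |
| `track_height` | px | 10 (40 centered) | glyph height; site radius is half of it |
| `track_gap` | px | 2 | separation between stacked tracks (see above) |
| `sequence_line_y` | px | 54 (95 centered) | baseline the styles anchor to |
| `requested_start/stop` | residue | full sequence | the visible window |

Canvas height `size_y` is derived: deepest glyph bottom + `below_ruler` +
legend height (16 px per entry plus 10 px padding).

## The synthetic-feature generator

`generate_fixture()` emulates a single annotated protein: uniform start
positions, region lengths `1 + Geometric(p)` with mean about 5% of the
sequence (regions always span at least two residues so they stay
rectangles), site types on single residues, and a rejection step that caps
the overlap depth at `max_depth` so packed layouts have a known track
budget. The default vocabulary covers all seven glyph-triggering type
labels, so every rendering path is exercised. It uses R's Mersenne–Twister
under an explicit seed and restores the ambient RNG state, giving
platform-stable fixtures.

What it does *not* emulate: real annotation length distributions (UniProt
regions are heavy-tailed and type-dependent), correlated placement
(PTM clusters, domain architecture), multi-source evidence, or fuzzy
endpoints. Passing tests therefore demonstrate the geometry and packing
logic, not fidelity to any particular database's annotation statistics.

## Degenerate inputs and edge cases

* Empty feature sets produce a valid ruler-and-margins document and SVG.
* A one-residue window makes every label clamp; duplicates collapse to a
  single labeled tick.
* At scales below one pixel per residue, a true region keeps a minimum
  width of 1 px so it never vanishes.
* Identifiers are opaque: case is preserved and never normalized, so
  documents whose segment and feature ids differ only in case round-trip
  unchanged.
* Unknown keys in the simple-features dialect warn and are ignored
  (forward compatibility); unknown glyph names are a hard error.

## Problem sizes used in the checks

The bundled suite exercises 500 randomized interval sets (3–25 intervals
each) for packing optimality, 200 randomized configurations for mapping
monotonicity, 50 zoom round trips, 15 rendered documents of up to 50
features, 20 serialization round trips per dialect, and one 1000-feature
end-to-end render — sizes chosen as representative of single-protein
annotation sets, which rarely exceed a few hundred features.

## Known limitations

* One segment (protein) per document; no multi-protein batch layout.
* No collision-avoiding label placement and no semantic zoom.
* Interactivity (hover, selection, dragging) is out of scope; tooltips are
  emitted as SVG `<title>` elements and selection as a static highlight
  style.
* PNG export depends on an optional raster backend; absent one, the
  package is deliberately SVG-only rather than shipping its own
  rasterizer.
* The by-rows style does not split a type label shared by two categories;
  the first category seen wins the ordering key.
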