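---
title: "Visualising homologous synteny blocks: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visualising homologous synteny blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synvis)
```

## The problem

Chromosome-scale genome assemblies make it practical to study chromosome
evolution directly: which segments stayed together, which were inverted,
which chromosomes fused or split along a lineage.  The unit of analysis
is the *homologous synteny block* (HSB): a contiguous interval of one
genome that aligns as a unit to a contiguous interval of another genome,
together with a relative orientation (`+` when the two segments run the
same way, `-` when one is reversed).  synvis consumes precomputed HSB
tables — it performs no alignment itself — and turns them into three
figure styles in which inter-chromosomal rearrangements (fissions,
fusions, translocations) and intra-chromosomal ones (inversions) can be
read off directly.

Two inputs drive everything:

* a **lengths file** (TSV: `chrom`, `length_bp`, `species`) giving every
  chromosome of every plotted species — the canvas each figure scales
  against, and the denominator for bounds-checking;
* one or more **alignment files** (TSV: `ref_chrom`, `ref_start`,
  `ref_end`, `tgt_chrom`, `tgt_start`, `tgt_end`, `orientation`,
  `ref_species`, `tgt_species`) of pairwise HSBs.

## Coordinate conventions

All user-facing coordinates are **1-based inclusive** base pairs, so a
block from 1 to 100 has length 100.  This matches the block files that
upstream synteny/reconstruction tools emit; the package never exposes
0-based coordinates.  Whether a given upstream file is 0- or 1-based is
rarely documented; we treat inputs as 1-based and document this as an
assumption — at figure scale a one-bp offset is far below one device
unit.

Internally every scaling step goes through an affine `coord_map`:
`device(b) = device_origin + (b − bp_origin)/bp_span × device_span`.
Rectangle edges use the continuous positions `start − 1` and `end`, so
adjacent blocks (…`–100`, `101–`…) tile without gap or overlap.  The map
is strictly monotone and inverts to within 0.5 bp over spans up to a
gigabase (tested); out-of-range positions raise an error rather than
being clamped silently, because a clamp here would mask upstream
validation failures.

### Orientation encoding

The reader accepts `+`, `-`, the typographic minus `−`, `1`, `-1`, and
`.` for "not given"; the writer emits only ASCII `+`/`-`.  Some block
dialects encode a reversed target segment by listing its coordinates
high-to-low instead of carrying a sign, so normalisation resolves the
two encodings: a reversed target interval with *no* explicit sign
becomes a `-` block with ascending coordinates; an explicit sign always
wins over coordinate order.  The one contradictory combination — target
coordinates reversed *and* an explicit `+` — is refused as a data error
rather than repaired, since silent repair would hide upstream bugs.  A
reversed *reference* interval is simply swapped without touching the
orientation: the reference is the coordinate frame and carries no strand
of its own.  Normalisation is idempotent (property-tested).

### Chromosome ordering

Karyotypes order chromosomes by natural sort: numeric names numerically
(`2` before `10`), then `X`, `Y`, and `MT`/`M` last in that order, with
a `chr` prefix ignored for comparison but preserved for display.  The
ordering is a display convention, chosen to match standard ideogram
practice; no input order is trusted, so the same data always produces
the same figure.

## Validation

`validate_table()` checks every block against the karyotypes before any
layout runs: a chromosome missing from its karyotype, an interval
exceeding the chromosome length, or `start > end` after normalisation
are **errors** (layouts refuse the table); overlapping blocks on the
same reference chromosome and chromosomes with no block at all are
**warnings** (the latter will simply render as blank/uncoloured
regions, which is itself informative — unaligned or unassembled
sequence).  Overlap warnings enumerate exactly the intersecting pairs,
verified in the suite against a brute-force O(n²) oracle.  A missing
karyotype is deliberately a *configuration* error with a distinct
condition class, because it indicates mis-wiring rather than bad data.

## The three styles

All three layout engines emit a backend-agnostic *scene* — rectangles,
segments, cubic paths and text in PostScript points (1/72 inch, y
growing downwards) — which `render_svg()` serialises deterministically
and `render_png()` rasterises.  Separating layout from rendering keeps
the geometry testable without parsing image files: every primitive
carries semantic metadata (`role`, block index, orientation, twist flag)
that `scene_query()` exposes.

### Evolution Highway (`layout_eh`)

One panel per reference chromosome, one vertical column per target
species in input order, any number of species.  Each HSB is a filled
rectangle spanning its reference interval: blue (`same_colour`,
`#2C7BB6`) for `+`, pink (`opposite_colour`, `#F17CB0`) for `-`; both
overridable.  The number inside each block is the target chromosome
name, which is how inter-chromosomal rearrangements are read.  Blocks
thinner than `min_label_height` (9 pt) get their label written beside
the column instead of dropped — the numbers are the point of the plot.
Panels tile left-to-right, wrapping to rows, and share one bp-to-point
scale (`axis_length`, 280 pt for the longest chromosome) so chromosome
sizes stay comparable; a light outline is drawn behind the blank
(unaligned) regions and can be disabled with `draw_outline = FALSE`.

### Chromosome painting (`layout_painting`)

Each target chromosome is a horizontal bar; each HSB within it is
painted with the colour of its homologous *reference* chromosome, from a
fixed categorical palette keyed in natural order (cycling with a
lightness shift past 20 chromosomes; fully overridable).  A diagonal
inside each segment encodes two things at once: its endpoint heights are
`ref_start/ref_length` and `ref_end/ref_length` — the HSB's relative
position within the reference chromosome — and its direction encodes
orientation, rising left-to-right for `+` and falling for `-`.  A fully
syntenic `+` chromosome is therefore traversed by a single line from
bottom-left to top-right.  For a `-` block the heights are *not*
mirrored, only the drawing direction reverses: the y-axis keeps meaning
"position in the reference chromosome" independent of strand.  (The
alternative reading — mirroring the heights as well — would make the
y-position strand-dependent; we chose the strand-independent convention
and flag it here.)  Vertical bars mark HSB boundaries, shared boundaries
drawn once; uncovered target bp stay uncoloured; a legend maps colour to
reference chromosome.

### Linear comparison (`layout_linear`)

Genomes are stacked top to bottom in the order of the pairwise tables,
which must chain (each table's target is the next table's reference;
`chain_check()` reports the first broken link by name).  Chromosomes lie
left-to-right with widths proportional to bp on one shared scale, so
genome-size differences stay visible.  The top genome's chromosomes are
colour-coded; all lower genomes are grey.  Each block becomes a ribbon
between adjacent tracks whose four anchors sit exactly at the mapped
block boundaries; an inversion is drawn as a twist — the left edge joins
ref-start to tgt-*end* — so counting twists counts inversions (tested
against planted ground truth).  Edges are cubic S-curves with vertical
tangents; the twist is purely an anchor pairing, so the renderer needs
no special case.  Ribbons default to 0.7 opacity so crossings stay
readable.

Colour propagation down a chain is a switch.  By default each ribbon
takes its own pair's reference-chromosome colour, because the colour
rule is defined for a single pairwise comparison.  With
`propagate_colours = TRUE` the block's midpoint is traced hop by hop to
the top genome through the tables' coordinate maps, and the ribbon
inherits that top chromosome's colour (grey when a hop has no covering
block).  Midpoint tracing is exact when blocks nest across levels and a
deliberate approximation when a lower-level block straddles two
upper-level blocks.  Chromosome order within a track is the karyotype's
natural order; no crossing-minimisation reordering is attempted.

## Rendering

SVG is the primary output: the writer formats every coordinate to a
fixed three decimals, emits no timestamps or generated ids, and sorts
primitives by z-order (stable in input order), so identical scenes give
byte-identical files — the property the snapshot and determinism tests
rely on.  Translucent fills are emitted as a 6-digit colour plus
`fill-opacity` for broad viewer compatibility.  Scene invariants
(finite coordinates, geometry within the page) are enforced at render
time with the offending primitive's index; text is exempt from the
bounds check because text extent depends on the viewer's font metrics —
layouts instead use a conservative fixed per-character width estimate
when composing, so nothing structural depends on installed fonts.  PNG
output rasterises the same scene through R's `png()` device at
`size × dpi/72` pixels.

## The synthetic generator

`generate_scenario()` is both the demo-data source and the test oracle.
It builds a reference karyotype (by default 5 chromosomes of 40–120 Mbp,
the scale of typical mammalian chromosomes), tiles each chromosome
completely with contiguous blocks (30 by default — coarse HSBs of the
size used in ancestral-reconstruction figures), and derives a target
genome by planting events with recorded ground truth: an inversion flips
one block's orientation; a fission splits one chromosome's blocks across
two target chromosomes; a fusion concatenates two chromosomes onto one;
a translocation moves a terminal block run onto another chromosome.
Target coordinates are then renumbered contiguously.  All randomness
flows from one explicit seed through a scoped RNG, so the same seed
reproduces the scenario byte-for-byte and the global RNG stream is never
touched.

Fission, fusion and translocation events are planted on *disjoint*
chromosome sets.  This is what makes the counts exactly recoverable:
counting `-` blocks recovers inversions; the excess of distinct target
chromosomes per reference chromosome recovers fissions; the converse
excess recovers fusions.  A translocation inherently adds one to *both*
inter-chromosomal counters (it splits its donor across two targets and
mixes two homologues on the recipient), so the recovery identities are
exact for fission/fusion only in scenarios without translocations — the
suite tests exactly that, plus the translocation bookkeeping separately.
Infeasible requests (more events than disjoint chromosomes, a fission on
a one-block chromosome) are refused up front.

What the generator does **not** emulate: unaligned gaps between blocks
(reference chromosomes are tiled completely), breakpoint microstructure,
repeat-driven ambiguity, and assembly error.  Passing tests therefore
demonstrate the correctness of parsing, validation, geometry and
rendering — not robustness to the coverage gaps and noise of real
alignment pipelines, which enter the figures only as blank regions.

## Numerical choices

* SVG coordinates are rounded to 3 decimals of a point (~1/200 mm);
  boundary-bar deduplication rounds to 6 decimals before `unique()`.
* The device unit is the PostScript point; page sizes are derived from
  content (panel grid for Evolution Highway, width-driven for the other
  two styles).
* Palette assignment is by natural-sort rank, so colours are stable
  under permutations of the input rows.
* Problem sizes in the test-suite (scenarios of 3–5 chromosomes and
  12–32 blocks; 1000 round-trip tables; 10⁴ coordinate-map draws) were
  chosen to exercise every code path with sub-minute wall time; the
  geometry is scale-free, so nothing changes qualitatively at
  chromosome counts of real genomes.

## A worked example

```{r example, eval = FALSE}
sc <- generate_scenario(7, n_chroms = 4, n_blocks = 20,
                        inversions = 3, fissions = 1, fusions = 1)
karyos <- list(ref = sc$ref_karyo, tgt = sc$tgt_karyo)
report_ok(validate_table(sc$table, karyos))
#> [1] TRUE
recover_events(sc$table)
#> inversions   fissions    fusions
#>          3          1          1

render_svg(layout_eh(sc$ref_karyo, list(sc$table)), "eh.svg")
render_svg(layout_painting(sc$tgt_karyo, sc$ref_karyo, sc$table), "painting.svg")
render_svg(layout_linear(list(sc$table), karyos), "linear.svg")
```

## Known limitations

* One reference genome per painting figure; no centromere or banding
  glyphs.
* No circular layouts or dot plots, by design: the linear styles exist
  precisely because small blocks and inversions are hard to read in
  circular plots.
* Ribbon colour propagation uses midpoint tracing (see above).
* The CARs/APCF reader covers the shared record shape
  (`>id` header, `genome.chrom:start-end sign` segments); dialect
  variants outside it surface as parse errors rather than guesses, and
  genome identifiers may not contain `.` (the first `.` separates
  genome from chromosome).
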