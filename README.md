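# synvis

Visualisation of homologous synteny blocks (HSBs) between genomes, for
comparative genomics and chromosome-evolution studies.

A homologous synteny block maps a contiguous interval of a *reference*
genome onto a contiguous interval of a *target* genome with a relative
orientation (`+` same strand arrangement, `-` reversed).  Given pairwise
HSB tables and a table of chromosome lengths, synvis validates the data
and lays out three complementary figure styles in which chromosome
rearrangements can be read directly:

* **Evolution Highway** — one panel per reference chromosome, one column
  per target species (any number of species).  Blocks are coloured by
  orientation (blue `+`, pink `-`) and labelled with the target
  chromosome number; unaligned regions stay blank.  Colour changes along
  a column reveal inversions; label changes reveal inter-chromosomal
  rearrangements.
* **Chromosome painting** — each target chromosome is a bar whose HSBs
  are painted by homologous reference chromosome.  A diagonal in each
  segment rises for `+` and falls for `-`, and its endpoint heights give
  the HSB's relative position (`ref_start/ref_length`,
  `ref_end/ref_length`) within the reference chromosome; vertical bars
  mark HSB boundaries.
* **Linear comparison** — genomes stacked top to bottom (the pairwise
  tables must chain: each target is the next reference), chromosomes
  scaled to bp, colour-coded ribbons joining homologous intervals.  An
  inversion appears as a twist in the ribbon.

Layout engines emit a backend-agnostic scene; `render_svg()` writes
deterministic, byte-stable SVG and `render_png()` rasterises the same
scene.  A converter imports block files in the inferCARs/DESCHRAMBLER
dialect (`>id` records with `genome.chrom:start-end sign` segments), and
a seeded synthetic-rearrangement generator plants inversions, fissions,
fusions and translocations with exact ground truth for demos and tests.

## Input formats

Both inputs are headerless TSV:

* lengths file: `chrom_name`, `length_bp`, `species_id` — one row per
  chromosome of every plotted species;
* alignment file: `ref_chrom`, `ref_start`, `ref_end`, `tgt_chrom`,
  `tgt_start`, `tgt_end`, `orientation`, `ref_species`, `tgt_species`.

Coordinates are 1-based inclusive bp.  The orientation column accepts
`+`, `-`, `−`, `1`, `-1`, or `.` (infer from coordinate order: a
reversed target interval encodes `-`).

## A worked example

```r
library(synvis)

# a seeded scenario: 4 chromosomes, 20 blocks, 3 inversions,
# 1 fission, 1 fusion -- with recorded ground truth
sc <- generate_scenario(7, n_chroms = 4, n_blocks = 20,
                        inversions = 3, fissions = 1, fusions = 1)
sc$ref_karyo
#> Karyotype of 'ref': 4 chromosome(s), 286 Mbp total
#>  chrom_name length_bp
#>           1 119112744
#>           2  71819636
#>           3  49255822
#>           4  45579894

karyos <- list(ref = sc$ref_karyo, tgt = sc$tgt_karyo)
report_ok(validate_table(sc$table, karyos))
#> [1] TRUE

# the planted events are recoverable from the emitted table:
recover_events(sc$table)
#> inversions   fissions    fusions
#>          3          1          1

s <- layout_linear(list(sc$table), karyos)
s
#> Scene 672 x 165 pt, 38 primitives (path: 20, rectangle: 8, text: 10)
render_svg(s, "linear.svg")

render_svg(layout_eh(sc$ref_karyo, list(sc$table)), "eh.svg")
render_svg(layout_painting(sc$tgt_karyo, sc$ref_karyo, sc$table),
           "painting.svg")
```

The three twisted ribbons in `linear.svg` are the three planted
inversions; the fused chromosome shows as one grey target bar receiving
ribbons of two colours.

Real data enter through `read_lengths()` and `read_alignment()`, or via
`read_cars()`/`convert_cars()` for inferCARs/DESCHRAMBLER block files.

## Command line

A thin wrapper over the same functions ships in `inst/cli/synvis`
(installed under `system.file("cli", "synvis", package = "synvis")`):

```sh
synvis synth --seed 7 --inversions 3 --out-prefix demo
synvis eh       --lengths demo.lengths.tsv --alignment demo.alignment.tsv --output eh.svg
synvis painting --lengths demo.lengths.tsv --alignment demo.alignment.tsv --output painting.svg
synvis linear   --lengths demo.lengths.tsv --alignment demo.alignment.tsv --output linear.svg
synvis reformat --cars blocks.txt --ref hg --tgt mm --output converted.tsv
```

Exit codes: 0 success, 1 data/validation error, 2 usage error.

## Documentation

See the vignette source in `vignettes/synteny-visualization.Rmd` for the
coordinate conventions, the semantics of each style, the design of the
synthetic generator, and known limitations.
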