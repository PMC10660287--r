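Package: synvis
Title: Visualisation of Homologous Synteny Blocks Between Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parses pairwise homologous-synteny-block (HSB) tables and
    chromosome-length tables, converts block files produced by ancestral
    genome reconstruction tools (inferCARs/DESCHRAMBLER dialects), and lays
    out three publication styles for comparative chromosome analysis:
    Evolution Highway panels (one panel per reference chromosome, one
    orientation-coloured column per target species), chromosome painting
    (target chromosomes painted by reference homologue with orientation
    diagonals), and linear multi-genome ribbon plots (inversions drawn as
    ribbon twists).  Layout engines emit a backend-agnostic scene that is
    rendered deterministically to SVG or rasterised to PNG.  A seeded
    synthetic rearrangement generator plants inversions, fissions, fusions
    and translocations with exact ground truth for testing and demos.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2,
    png,
    jsonlite
Config/testthat/edition: 3
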