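# Evolution Highway layout: per-chromosome panels, per-species columns,
# orientation colouring, blank regions.

eh_rects <- function(sc) scene_query(sc, role = "hsb")

test_that("a single full-length block fills the panel axis with the same-orientation colour", {
  rk <- karyotype("spsR", "1", 100)
  tab <- synteny_table(data.frame(
    ref_chrom = "1", ref_start = 1, ref_end = 100, tgt_chrom = "3",
    tgt_start = 1, tgt_end = 100, orientation = "+",
    stringsAsFactors = FALSE), "spsR", "spsT")
  style <- style_config("eh")
  sc <- layout_eh(rk, list(tab), style)

  rects <- eh_rects(sc)
  expect_length(rects, 1L)
  r <- rects[[1]]
  expect_equal(r$fill, style$same_colour)
  expect_equal(r$h, style$axis_length)  # longest (only) chromosome spans the axis

  labels <- scene_query(sc, role = "hsb_label")
  expect_length(labels, 1L)
  expect_equal(labels[[1]]$text, "3")
  expect_equal(labels[[1]]$meta$placement, "inside")

  # same block in opposite orientation only changes the fill colour
  tab2 <- tab; tab2$orientation <- "-"
  r2 <- eh_rects(layout_eh(rk, list(tab2), style))[[1]]
  expect_equal(r2$fill, style$opposite_colour)
  expect_equal(r2[c("x", "y", "w", "h")], r[c("x", "y", "w", "h")])
})

test_that("one column appears per target species, in input order", {
  rk <- karyotype("sps4", c("1", "2"), c(100, 80))
  mk <- function(tgt) synteny_table(data.frame(
    ref_chrom = c("1", "2"), ref_start = c(1, 1), ref_end = c(100, 80),
    tgt_chrom = c("5", "6"), tgt_start = c(1, 1), tgt_end = c(100, 80),
    orientation = "+", stringsAsFactors = FALSE), "sps4", tgt)
  tables <- list(mk("sps1"), mk("sps2"), mk("sps3"))
  sc <- layout_eh(rk, tables)
  for (ch in c("1", "2")) {
    cols <- unlist(meta_field(scene_query(sc, role = "hsb", ref_chrom = ch),
                              "target"))
    expect_equal(cols, c("sps1", "sps2", "sps3"))
  }
  headers <- scene_query(sc, role = "column_header")
  expect_equal(unique(unlist(meta_field(headers, "target"))),
               c("sps1", "sps2", "sps3"))
})

test_that("block rectangles land at the mapped reference coordinates", {
  # chromosome of 200 bp on a 100-pt axis: block 51-150 -> 25..75 pt
  rk <- karyotype("r", "1", 200)
  tab <- synteny_table(data.frame(
    ref_chrom = "1", ref_start = 51, ref_end = 150, tgt_chrom = "2",
    tgt_start = 1, tgt_end = 100, orientation = "+",
    stringsAsFactors = FALSE), "r", "t")
  sc <- layout_eh(rk, list(tab), style_config("eh", axis_length = 100))
  r <- eh_rects(sc)[[1]]
  outline <- scene_query(sc, role = "outline")[[1]]
  expect_equal(r$y - outline$y, 25)
  expect_equal(r$h, 50)
})

test_that("rectangle counts equal block counts per (chromosome, target) pair", {
  for (seed in c(3, 17)) {
    sc0 <- generate_scenario(seed, n_chroms = 4, n_blocks = 26,
                             inversions = 5, fissions = 1, fusions = 1)
    scn <- layout_eh(sc0$ref_karyo, list(sc0$table))
    for (ch in unique(sc0$table$ref_chrom)) {
      got <- length(scene_query(scn, role = "hsb", ref_chrom = ch))
      expect_equal(got, sum(sc0$table$ref_chrom == ch))
    }
    # colour is a pure function of orientation
    rects <- eh_rects(scn)
    ori <- unlist(meta_field(rects, "orientation"))
    fills <- vapply(rects, `[[`, character(1), "fill")
    expect_equal(unname(fills == style_config("eh")$same_colour),
                 unname(ori == "+"))
  }
})

test_that("flipping every orientation swaps the two colours and nothing else", {
  sc0 <- generate_scenario(23, n_chroms = 3, n_blocks = 15, inversions = 4)
  flipped <- sc0$table
  flipped$orientation <- ifelse(flipped$orientation == "+", "-", "+")
  flipped <- synteny_table(as.data.frame(flipped), "ref", "tgt")

  svg_a <- render_svg(layout_eh(sc0$ref_karyo, list(sc0$table)))
  svg_b <- render_svg(layout_eh(sc0$ref_karyo, list(flipped)))
  expect_equal(length(svg_a), length(svg_b))
  differing <- which(svg_a != svg_b)
  expect_gt(length(differing), 0)
  # differing lines must be identical once fill attributes are masked
  strip_fill <- function(x) gsub('fill="#[0-9A-Fa-f]{6}"', 'fill="*"', x)
  expect_equal(strip_fill(svg_a[differing]), strip_fill(svg_b[differing]))
})

test_that("uncovered reference intervals stay blank", {
  rk <- karyotype("r", "1", 1000)
  tab <- synteny_table(data.frame(
    ref_chrom = "1", ref_start = c(1, 701), ref_end = c(300, 900),
    tgt_chrom = c("1", "2"), tgt_start = c(1, 1), tgt_end = c(300, 200),
    orientation = "+", stringsAsFactors = FALSE), "r", "t")
  sc <- layout_eh(rk, list(tab), style_config("eh", axis_length = 100))
  rects <- eh_rects(sc)
  outline <- scene_query(sc, role = "outline")[[1]]
  # device interval of the uncovered 301-700 bp gap
  gap <- outline$y + c(300, 700) / 1000 * 100
  for (r in rects) {
    expect_true(r$y + r$h <= gap[1] + 1e-9 || r$y >= gap[2] - 1e-9)
  }
  # and the covered extent sums to the mapped block lengths
  expect_equal(sum(vapply(rects, `[[`, numeric(1), "h")),
               (300 + 200) / 1000 * 100)
})

test_that("labels of thin blocks move beside the column", {
  rk <- karyotype("r", "1", 1000)
  tab <- synteny_table(data.frame(
    ref_chrom = "1", ref_start = c(1, 995), ref_end = c(994, 1000),
    tgt_chrom = c("1", "9"), tgt_start = c(1, 1), tgt_end = c(994, 6),
    orientation = "+", stringsAsFactors = FALSE), "r", "t")
  sc <- layout_eh(rk, list(tab), style_config("eh", axis_length = 100))
  labs <- scene_query(sc, role = "hsb_label")
  placement <- unlist(meta_field(labs, "placement"))
  expect_equal(placement, c("inside", "beside"))
  beside <- labs[[2]]
  col_right <- scene_query(sc, role = "outline")[[1]]
  expect_gt(beside$x, col_right$x + col_right$w)
  expect_equal(beside$anchor, "start")
})

test_that("layout_eh rejects mismatched or unvalidatable input", {
  rk <- karyotype("r", "1", 100)
  tab <- synteny_table(data.frame(
    ref_chrom = "1", ref_start = 1, ref_end = 100, tgt_chrom = "1",
    tgt_start = 1, tgt_end = 100, orientation = "+",
    stringsAsFactors = FALSE), "OTHER", "t")
  expect_error(layout_eh(rk, list(tab)), class = "synvis_config_error")

  over <- synteny_table(data.frame(
    ref_chrom = "1", ref_start = 1, ref_end = 150, tgt_chrom = "1",
    tgt_start = 1, tgt_end = 150, orientation = "+",
    stringsAsFactors = FALSE), "r", "t")
  expect_error(layout_eh(rk, list(over)), class = "synvis_data_error")
})
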