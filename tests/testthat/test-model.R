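# Domain model: natural chromosome ordering, block normalisation,
# coordinate maps, table validation.

test_that("natural chromosome order is numeric-aware with X/Y/MT last", {
  nm <- c("10", "2", "X", "1")
  expect_equal(nm[natural_chrom_order(nm)], c("1", "2", "10", "X"))

  nm <- c("MT", "Y", "X", "3", "chr2", "21")
  expect_equal(nm[natural_chrom_order(nm)],
               c("chr2", "3", "21", "X", "Y", "MT"))

  # 'chr' prefix stripped for comparison, preserved for display
  nm <- c("chr10", "chr2")
  expect_equal(nm[natural_chrom_order(nm)], c("chr2", "chr10"))

  # non-canonical names: digit runs compared numerically
  nm <- c("scaffold_10", "scaffold_2", "scaffold_1")
  expect_equal(nm[natural_chrom_order(nm)],
               c("scaffold_1", "scaffold_2", "scaffold_10"))
})

test_that("karyotype enforces its invariants and orders chromosomes", {
  k <- karyotype("sps1", c("10", "2", "X"), c(50, 60, 70))
  expect_s3_class(k, "karyotype")
  expect_equal(k$chrom_name, c("2", "10", "X"))
  expect_error(karyotype("sps1", c("1", "1"), c(10, 20)),
               class = "synvis_data_error")
  expect_error(karyotype("sps1", "1", 0), class = "synvis_data_error")
  expect_error(karyotype("sps1", "a b", 10), class = "synvis_data_error")
})

test_that("normalize_blocks handles explicit and coordinate-encoded orientation", {
  raw <- data.frame(ref_chrom = "1", ref_start = 100, ref_end = 200,
                    tgt_chrom = "2", tgt_start = 500, tgt_end = 900,
                    orientation = "+", stringsAsFactors = FALSE)
  expect_identical(normalize_blocks(raw), raw)

  # reversed target with no explicit sign encodes a minus block
  raw2 <- transform(raw, tgt_start = 900, tgt_end = 500,
                    orientation = NA_character_)
  out2 <- normalize_blocks(raw2)
  expect_equal(c(out2$tgt_start, out2$tgt_end), c(500, 900))
  expect_equal(out2$orientation, "-")

  # reversed reference with an explicit sign: swap, keep the sign
  raw3 <- transform(raw, ref_start = 200, ref_end = 100, orientation = "-")
  out3 <- normalize_blocks(raw3)
  expect_equal(c(out3$ref_start, out3$ref_end), c(100, 200))
  expect_equal(out3$orientation, "-")

  # reversed target with an explicit '+' is contradictory, not repaired
  raw4 <- transform(raw, tgt_start = 900, tgt_end = 500)
  expect_error(normalize_blocks(raw4), "refusing to guess",
               class = "synvis_data_error")

  # malformed coordinates name the offending field
  raw5 <- transform(raw, ref_start = 0)
  expect_error(normalize_blocks(raw5), "ref_start",
               class = "synvis_data_error")
})

test_that("normalisation is idempotent on randomized raw blocks", {
  set.seed(421)
  for (rep in 1:20) {
    raw <- random_raw_blocks(40)
    once <- normalize_blocks(raw)
    expect_identical(normalize_blocks(once), once)
    expect_true(all(once$ref_start <= once$ref_end))
    expect_true(all(once$tgt_start <= once$tgt_end))
    expect_true(all(once$orientation %in% c("+", "-")))
  }
})

test_that("map_bp implements the affine map exactly", {
  cm <- coord_map(0, 100, 0, 50)
  expect_identical(map_bp(cm, 40), 20)
  expect_identical(map_bp(cm, 0), 0)   # origin fixed point
  expect_identical(map_bp(cm, 100), 50)

  cm2 <- coord_map(1, 199, 10, 100)
  expect_equal(map_bp(cm2, 100), 10 + 99 / 199 * 100, tolerance = 1e-12)

  expect_error(map_bp(cm, 101), class = "synvis_data_error")
  expect_error(map_bp(cm, -1), class = "synvis_data_error")
})

test_that("map_bp is strictly monotone and inverts to within 0.5 bp", {
  set.seed(99)
  for (rep in 1:50) {
    span <- sample(c(1e3, 1e6, 1e9), 1)
    origin <- sample(1e6, 1)
    cm <- coord_map(origin, span, runif(1, 0, 100), runif(1, 10, 1000))
    b <- sort(sample(span, 20)) + origin
    d <- map_bp(cm, b)
    expect_true(all(diff(d) > 0))
    expect_true(all(abs(unmap_bp(cm, d) - b) <= 0.5))
  }
})

test_that("validate_table flags bounds errors and blank chromosomes", {
  fx <- fixture_pair()
  expect_true(report_ok(validate_table(fx$tab, fx$karyos)))

  # block end beyond the chromosome length -> one error
  bad <- synteny_table(data.frame(
    ref_chrom = "1", ref_start = 1, ref_end = 150, tgt_chrom = "1",
    tgt_start = 1, tgt_end = 150, orientation = "+",
    stringsAsFactors = FALSE), "spsA", "spsB")
  rep <- validate_table(bad, fx$karyos)
  expect_false(report_ok(rep))
  expect_equal(sum(rep$severity == "error"), 1L)
  expect_match(rep$message[rep$severity == "error"], "exceeds")

  # chromosome with zero blocks -> warning mentioning blank regions
  expect_true(any(grepl("no aligned block",
                        rep$message[rep$severity == "warning"])))

  # chromosome missing from the karyotype -> error
  ghost <- synteny_table(data.frame(
    ref_chrom = "7", ref_start = 1, ref_end = 10, tgt_chrom = "1",
    tgt_start = 1, tgt_end = 10, orientation = "+",
    stringsAsFactors = FALSE), "spsA", "spsB")
  rep2 <- validate_table(ghost, fx$karyos)
  expect_true(any(grepl("absent from karyotype",
                        rep2$message[rep2$severity == "error"])))

  # missing karyotype is a configuration error, not a data issue
  expect_error(validate_table(fx$tab, fx$karyos["spsA"]),
               class = "synvis_config_error")
})

test_that("overlap warnings match the brute-force pairwise oracle", {
  # the spec'd two-block case: 10-50 and 40-80 on one chromosome
  tab <- synteny_table(data.frame(
    ref_chrom = c("2", "2"), ref_start = c(10, 40), ref_end = c(50, 80),
    tgt_chrom = c("1", "1"), tgt_start = c(10, 40), tgt_end = c(50, 80),
    orientation = c("+", "+"), stringsAsFactors = FALSE), "spsA", "spsB")
  karyos <- list(spsA = karyotype("spsA", "2", 200),
                 spsB = karyotype("spsB", "1", 200))
  rep <- validate_table(tab, karyos)
  expect_equal(sum(grepl("overlap", rep$message)), 1L)

  set.seed(7)
  for (reps in 1:15) {
    n <- sample(5:60, 1)
    starts <- sample(900, n, replace = TRUE)
    widths <- sample(60, n, replace = TRUE)
    df <- data.frame(
      ref_chrom = as.character(sample(3, n, replace = TRUE)),
      ref_start = starts, ref_end = pmin(starts + widths, 1000),
      tgt_chrom = "1", tgt_start = seq_len(n) * 2 - 1,
      tgt_end = seq_len(n) * 2, orientation = "+",
      stringsAsFactors = FALSE)
    tab <- synteny_table(df, "a", "b")
    karyos <- list(a = karyotype("a", c("1", "2", "3"), rep(1000, 3)),
                   b = karyotype("b", "1", 1e6))
    got <- sum(grepl("overlap", validate_table(tab, karyos)$message))
    expect_equal(got, brute_overlap_pairs(tab))
  }
})
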