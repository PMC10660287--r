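# Shared fixtures and independent oracles for the test-suite.  All
# fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# O(n^2) brute-force interval-intersection oracle for reference-side
# overlaps (1-based inclusive intervals), independent of validate_table's
# sweep.  Returns the number of overlapping block pairs.
brute_overlap_pairs <- function(table) {
  n <- nrow(table)
  hits <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (table$ref_chrom[i] == table$ref_chrom[j] &&
          table$ref_start[i] <= table$ref_end[j] &&
          table$ref_start[j] <= table$ref_end[i]) {
        hits <- hits + 1L
      }
    }
  }
  hits
}

# Random raw block rows (possibly reversed coordinates, NA orientation)
# for normalisation and round-trip tests; not karyotype-consistent.
random_raw_blocks <- function(n, max_coord = 1e6) {
  a <- sample(max_coord, n, replace = TRUE)
  b <- sample(max_coord, n, replace = TRUE)
  c_ <- sample(max_coord, n, replace = TRUE)
  d <- sample(max_coord, n, replace = TRUE)
  ori <- sample(c("+", "-", NA), n, replace = TRUE)
  # an explicit '+' with reversed target coordinates is contradictory by
  # contract, so force those targets ascending
  plus_rev <- !is.na(ori) & ori == "+" & c_ > d
  tmp <- c_[plus_rev]; c_[plus_rev] <- d[plus_rev]; d[plus_rev] <- tmp
  data.frame(ref_chrom = as.character(sample(5, n, replace = TRUE)),
             ref_start = a, ref_end = b,
             tgt_chrom = as.character(sample(5, n, replace = TRUE)),
             tgt_start = c_, tgt_end = d,
             orientation = ori, stringsAsFactors = FALSE)
}

# Small two-species fixture used across layout tests.
fixture_pair <- function() {
  rk <- karyotype("spsA", c("1", "2"), c(100, 200))
  tk <- karyotype("spsB", c("1", "2"), c(150, 160))
  tab <- synteny_table(data.frame(
    ref_chrom = c("1", "2", "2"),
    ref_start = c(1, 1, 101),
    ref_end = c(100, 100, 200),
    tgt_chrom = c("2", "1", "1"),
    tgt_start = c(1, 1, 51),
    tgt_end = c(100, 50, 150),
    orientation = c("+", "-", "+"),
    stringsAsFactors = FALSE), "spsA", "spsB")
  list(rk = rk, tk = tk, tab = tab,
       karyos = list(spsA = rk, spsB = tk))
}

# Serialise a synteny table into CARs-dialect text: one record per
# block, the reference segment always '+', the target segment's sign
# carrying the relative orientation.  Independent of read_cars's parser.
cars_text_from_table <- function(tab, ref, tgt) {
  unlist(lapply(seq_len(nrow(tab)), function(i) {
    c(sprintf(">block%d", i),
      sprintf("%s.%s:%d-%d +", ref, tab$ref_chrom[i],
              tab$ref_start[i], tab$ref_end[i]),
      sprintf("%s.%s:%d-%d %s", tgt, tab$tgt_chrom[i],
              tab$tgt_start[i], tab$tgt_end[i], tab$orientation[i]))
  }))
}

# Field-wise equality of two synteny tables including species attributes.
expect_same_table <- function(a, b) {
  expect_identical(attr(a, "ref_species"), attr(b, "ref_species"))
  expect_identical(attr(a, "tgt_species"), attr(b, "tgt_species"))
  cols <- c("ref_chrom", "ref_start", "ref_end", "tgt_chrom",
            "tgt_start", "tgt_end", "orientation")
  for (cl in cols) {
    expect_equal(unname(a[[cl]]), unname(b[[cl]]),
                 info = paste("column", cl))
  }
}

meta_field <- function(prims, field) {
  lapply(prims, function(p) p$meta[[field]])
}
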