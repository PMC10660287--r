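# Seeded synthetic rearrangement scenarios: the package's demo-data
# source and the ground-truth oracle for the layout invariants.
#
# The generator builds a reference karyotype, tiles each chromosome with
# contiguous blocks, then derives a target genome by applying planted
# events to a copy of the block list:
#   inversion      - flips one block's orientation,
#   fission        - splits one chromosome's blocks across two target
#                    chromosomes,
#   fusion         - joins two chromosomes' blocks onto one target
#                    chromosome,
#   translocation  - moves a terminal run of blocks onto another
#                    chromosome,
# and finally renumbers target coordinates contiguously.  Fission,
# fusion and translocation events are planted on disjoint chromosome
# sets so each planted count is exactly recoverable from the emitted
# table (see the invariants tested in the suite); inversions may fall on
# any block.

#' Generate a synthetic rearrangement scenario
#'
#' @param seed integer seed; the same seed always yields identical
#'   output, and no global RNG state is consumed or leaked.
#' @param n_chroms number of reference chromosomes.
#' @param chrom_length_range bp range chromosome lengths are drawn from.
#' @param n_blocks total number of HSBs tiling the reference (at least
#'   `n_chroms`; at least two land on every chromosome whenever
#'   `n_blocks >= 2 * n_chroms`, which fission and translocation donors
#'   require).
#' @param inversions,fissions,fusions,translocations planted event
#'   counts.
#' @param ref_species,tgt_species species identifiers for the emitted
#'   karyotypes and table.
#' @return A list with elements `ref_karyo`, `tgt_karyo`, `table` (a
#'   [synteny_table()], source `"synthetic"`) and `ground_truth` (planted
#'   event descriptions plus the planted counts).
#' @export
generate_scenario <- function(seed, n_chroms = 5, chrom_length_range =
                                c(4e7, 1.2e8), n_blocks = 30,
                              inversions = 0, fissions = 0, fusions = 0,
                              translocations = 0,
                              ref_species = "ref", tgt_species = "tgt") {
  counts <- c(inversions = inversions, fissions = fissions,
              fusions = fusions, translocations = translocations)
  if (any(counts < 0) || any(counts != floor(counts))) {
    sv_abort("synvis_scenario_error", "event counts must be non-negative integers")
  }
  if (n_blocks < n_chroms) {
    sv_abort("synvis_scenario_error",
             sprintf("n_blocks (%d) must be >= n_chroms (%d)",
                     n_blocks, n_chroms))
  }
  if (inversions > n_blocks) {
    sv_abort("synvis_scenario_error",
             "cannot plant more inversions than blocks")
  }
  need_chroms <- fissions + 2 * fusions + 2 * translocations
  if (need_chroms > n_chroms) {
    sv_abort("synvis_scenario_error", sprintf(
      paste0("fissions + 2*fusions + 2*translocations = %d chromosome(s) ",
             "needed, but only %d available"), need_chroms, n_chroms))
  }

  with_seed(seed, {
    lens <- round(stats::runif(n_chroms, chrom_length_range[1],
                               chrom_length_range[2]))
    chroms <- as.character(seq_len(n_chroms))
    ref_karyo <- karyotype(ref_species, chroms, lens)

    # distribute blocks: one per chromosome, two where possible, rest random
    per <- rep(1L, n_chroms)
    extra <- n_blocks - n_chroms
    if (extra >= n_chroms) {
      per <- per + 1L
      extra <- extra - n_chroms
    }
    if (extra > 0) {
      add <- sample(n_chroms, extra, replace = TRUE)
      per <- per + tabulate(add, n_chroms)
    }

    blocks <- do.call(rbind, lapply(seq_len(n_chroms), function(j) {
      k <- per[j]
      cuts <- if (k > 1) sort(sample(lens[j] - 1, k - 1)) else numeric()
      starts <- c(1, cuts + 1)
      ends <- c(cuts, lens[j])
      data.frame(ref_chrom = chroms[j], ref_start = starts, ref_end = ends,
                 orientation = "+", stringsAsFactors = FALSE)
    }))
    blocks$id <- seq_len(nrow(blocks))

    # target genome starts as one chromosome per reference chromosome
    tgt <- lapply(seq_len(n_chroms), function(j) blocks$id[blocks$ref_chrom == chroms[j]])
    events <- list()
    plant <- function(type, detail) {
      events[[length(events) + 1L]] <<- c(list(type = type), detail)
    }

    # disjoint chromosome pool for the inter-chromosomal events
    pool <- sample(n_chroms)
    take <- function(n, min_blocks = 1L) {
      ok <- pool[lengths(tgt[pool]) >= min_blocks]
      if (length(ok) < n) {
        sv_abort("synvis_scenario_error", sprintf(
          paste0("cannot plant event: need %d unused chromosome(s) with ",
                 ">= %d block(s); increase n_blocks or n_chroms"),
          n, min_blocks))
      }
      chosen <- ok[seq_len(n)]
      pool <<- setdiff(pool, chosen)
      chosen
    }

    for (e in seq_len(fissions)) {
      j <- take(1L, min_blocks = 2L)
      ids <- tgt[[j]]
      cut <- sample(length(ids) - 1L, 1L)
      tgt[[j]] <- ids[seq_len(cut)]
      tgt[[length(tgt) + 1L]] <- ids[-seq_len(cut)]
      plant("fission", list(ref_chrom = chroms[j], after_block = ids[cut]))
    }
    for (e in seq_len(fusions)) {
      jk <- take(2L)
      tgt[[jk[1]]] <- c(tgt[[jk[1]]], tgt[[jk[2]]])
      tgt[[jk[2]]] <- integer()
      plant("fusion", list(ref_chroms = chroms[jk]))
    }
    for (e in seq_len(translocations)) {
      donor <- take(1L, min_blocks = 2L)  # keeps the donor non-empty
      recip <- take(1L)
      run <- sample(length(tgt[[donor]]) - 1L, 1L)
      moved <- utils::tail(tgt[[donor]], run)
      tgt[[donor]] <- utils::head(tgt[[donor]], -run)
      tgt[[recip]] <- c(tgt[[recip]], moved)
      plant("translocation", list(from = chroms[donor], to = chroms[recip],
                                  blocks = moved))
    }
    tgt <- tgt[lengths(tgt) > 0L]

    if (inversions > 0) {
      inv_ids <- sample(blocks$id, inversions)
      blocks$orientation[blocks$id %in% inv_ids] <- "-"
      for (id in sort(inv_ids)) plant("inversion", list(block = id))
    }

    # renumber target coordinates contiguously per target chromosome
    out <- vector("list", length(tgt))
    for (tci in seq_along(tgt)) {
      ids <- tgt[[tci]]
      b <- blocks[match(ids, blocks$id), ]
      w <- b$ref_end - b$ref_start + 1
      ends <- cumsum(w)
      out[[tci]] <- data.frame(
        ref_chrom = b$ref_chrom, ref_start = b$ref_start,
        ref_end = b$ref_end, tgt_chrom = as.character(tci),
        tgt_start = ends - w + 1, tgt_end = ends,
        orientation = b$orientation, id = b$id,
        stringsAsFactors = FALSE)
    }
    rows <- do.call(rbind, out)
    rows <- rows[order(rows$id), setdiff(names(rows), "id")]
    tgt_lens <- vapply(out, function(d) max(d$tgt_end), numeric(1))
    tgt_karyo <- karyotype(tgt_species, as.character(seq_along(out)),
                           tgt_lens)
    table <- synteny_table(rows, ref_species, tgt_species,
                           source = "synthetic")
    list(ref_karyo = ref_karyo, tgt_karyo = tgt_karyo, table = table,
         ground_truth = list(events = events, counts = counts, seed = seed))
  })
}

#' Recover rearrangement event counts from a synteny table
#'
#' Inversions are counted as `-` blocks; fissions as the excess of
#' distinct target chromosomes per reference chromosome; fusions as the
#' excess of distinct reference chromosomes per target chromosome.  On
#' generator output these counters recover the planted inversion count
#' always, and the planted fission/fusion counts exactly when no
#' translocations were planted (a translocation contributes one to each
#' of the fission and fusion counters, since it both splits its donor
#' across two target chromosomes and mixes two reference homologues on
#' the recipient).
#'
#' @param table a [synteny_table()].
#' @return Named numeric vector `inversions`, `fissions`, `fusions`.
#' @export
recover_events <- function(table) {
  fis <- sum(vapply(split(table$tgt_chrom, table$ref_chrom),
                    function(x) length(unique(x)) - 1L, integer(1)))
  fus <- sum(vapply(split(table$ref_chrom, table$tgt_chrom),
                    function(x) length(unique(x)) - 1L, integer(1)))
  c(inversions = sum(table$orientation == "-"), fissions = fis,
    fusions = fus)
}
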