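# Domain model: karyotypes, synteny blocks/tables, coordinate maps,
# validation.  Coordinates are 1-based inclusive base pairs throughout the
# user-facing surface; block length is end - start + 1.

#' Natural chromosome ordering
#'
#' Orders chromosome names the way ideograms are conventionally drawn:
#' numeric names compared numerically (`"2"` before `"10"`), then `X`, `Y`
#' and the mitochondrial chromosome (`MT` or `M`) last in that order, then
#' any remaining names in natural (digit-aware) alphabetical order.  A
#' leading `"chr"` prefix is ignored for comparison but preserved in the
#' names themselves.
#'
#' @param chrom_names character vector of chromosome names.
#' @return An integer permutation such that
#'   `chrom_names[natural_chrom_order(chrom_names)]` is sorted.
#' @examples
#' natural_chrom_order(c("10", "2", "X", "1"))  # 4 2 1 3
#' @export
natural_chrom_order <- function(chrom_names) {
  stripped <- sub("^chr", "", chrom_names, ignore.case = TRUE)
  up <- toupper(stripped)
  grp <- ifelse(grepl("^[0-9]+$", stripped), 0L,
         ifelse(up == "X",  1L,
         ifelse(up == "Y",  2L,
         ifelse(up %in% c("MT", "M"), 3L, 4L))))
  # digit-aware key: every digit run zero-padded to fixed width
  natkey <- gsub("([0-9]+)", "~\\1~", stripped)
  natkey <- vapply(strsplit(natkey, "~", fixed = TRUE), function(tok) {
    dig <- grepl("^[0-9]+$", tok)
    tok[dig] <- sprintf("%020d", as.numeric(tok[dig]))
    paste(tok, collapse = "")
  }, character(1))
  order(grp, natkey, chrom_names, method = "radix")
}

#' Construct a karyotype
#'
#' A karyotype is the ordered set of one species' chromosomes with their
#' lengths in base pairs -- the canvas every layout draws on.  Chromosomes
#' are stored in natural sort order (see [natural_chrom_order()]).
#'
#' @param species_id single species identifier (no whitespace).
#' @param chrom_name character vector of chromosome names, unique, free of
#'   whitespace.
#' @param length_bp positive integer chromosome lengths, base pairs.
#' @return An object of class `karyotype`: a data frame with columns
#'   `chrom_name` and `length_bp` and attribute `species_id`.
#' @export
karyotype <- function(species_id, chrom_name, length_bp) {
  species_id <- as.character(species_id)
  chrom_name <- as.character(chrom_name)
  length_bp <- as.numeric(length_bp)
  if (length(species_id) != 1L || grepl("[[:space:]]", species_id)) {
    sv_data_error("`species_id` must be a single whitespace-free token")
  }
  if (length(chrom_name) != length(length_bp)) {
    sv_data_error("`chrom_name` and `length_bp` differ in length")
  }
  if (any(grepl("[[:space:]]", chrom_name))) {
    sv_data_error("chromosome names must not contain whitespace")
  }
  if (anyDuplicated(chrom_name)) {
    sv_data_error(sprintf("duplicate chromosome name(s) in karyotype '%s': %s",
                          species_id,
                          paste(unique(chrom_name[duplicated(chrom_name)]),
                                collapse = ", ")))
  }
  if (any(!is.finite(length_bp)) || any(length_bp < 1) ||
      any(length_bp != floor(length_bp))) {
    sv_data_error("chromosome lengths must be positive integers (bp)")
  }
  ord <- natural_chrom_order(chrom_name)
  out <- data.frame(chrom_name = chrom_name[ord],
                    length_bp = length_bp[ord],
                    stringsAsFactors = FALSE)
  attr(out, "species_id") <- species_id
  class(out) <- c("karyotype", "data.frame")
  out
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf("Karyotype of '%s': %d chromosome(s), %.3g Mbp total\n",
              attr(x, "species_id"), nrow(x), sum(x$length_bp) / 1e6))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

species_id <- function(x) attr(x, "species_id")

chrom_length <- function(karyo, chrom) {
  i <- match(chrom, karyo$chrom_name)
  karyo$length_bp[i]
}

ORIENT_TOKENS <- c("+" = "+", "-" = "-", "−" = "-", "1" = "+", "-1" = "-")

parse_orientation <- function(tok) {
  out <- unname(ORIENT_TOKENS[as.character(tok)])
  out
}

#' Normalise raw synteny blocks
#'
#' Brings raw block rows into canonical form: `start <= end` on both
#' genomes, orientation one of `"+"`/`"-"`.  Some upstream block formats
#' encode a reversed target segment by listing its coordinates high-to-low
#' instead of carrying a sign; when the orientation field is missing
#' (`NA`), a reversed target interval is therefore swapped and the
#' orientation set to `"-"`.  An explicit orientation always wins over
#' coordinate order, with one exception: a reversed *target* interval
#' combined with an explicit `"+"` is contradictory (two encodings
#' disagreeing) and raises a data error rather than being silently
#' repaired.  A reversed *reference* interval is always swapped without
#' touching the orientation, since the reference provides the coordinate
#' frame and carries no strand of its own.
#'
#' Normalisation is idempotent.
#'
#' @param blocks data frame with columns `ref_chrom`, `ref_start`,
#'   `ref_end`, `tgt_chrom`, `tgt_start`, `tgt_end`, `orientation`
#'   (`"+"`, `"-"`, or `NA` for "not given").
#' @return The same data frame with coordinates normalised and
#'   `orientation` filled in (`"+"`/`"-"`).
#' @export
normalize_blocks <- function(blocks) {
  need <- c("ref_chrom", "ref_start", "ref_end",
            "tgt_chrom", "tgt_start", "tgt_end", "orientation")
  missing_cols <- setdiff(need, names(blocks))
  if (length(missing_cols)) {
    sv_data_error(paste("missing block column(s):",
                        paste(missing_cols, collapse = ", ")))
  }
  for (f in c("ref_start", "ref_end", "tgt_start", "tgt_end")) {
    v <- blocks[[f]]
    bad <- !is.finite(v) | v < 1 | v != floor(v)
    if (any(bad)) {
      sv_data_error(sprintf(
        "malformed coordinate in field '%s' (row %d): must be an integer >= 1",
        f, which(bad)[1]), field = f, row = which(bad)[1])
    }
  }
  ori <- as.character(blocks$orientation)
  known <- !is.na(ori)
  if (any(known & !ori %in% c("+", "-"))) {
    bad <- which(known & !ori %in% c("+", "-"))[1]
    sv_data_error(sprintf("invalid orientation '%s' (row %d)", ori[bad], bad),
                  field = "orientation", row = bad)
  }

  ref_rev <- blocks$ref_start > blocks$ref_end
  if (any(ref_rev)) {
    tmp <- blocks$ref_start[ref_rev]
    blocks$ref_start[ref_rev] <- blocks$ref_end[ref_rev]
    blocks$ref_end[ref_rev] <- tmp
  }

  tgt_rev <- blocks$tgt_start > blocks$tgt_end
  contradictory <- tgt_rev & known & ori == "+"
  if (any(contradictory)) {
    bad <- which(contradictory)[1]
    sv_data_error(sprintf(
      paste0("row %d: target coordinates are reversed (%s > %s) but ",
             "orientation is an explicit '+'; refusing to guess"),
      bad, blocks$tgt_start[bad], blocks$tgt_end[bad]),
      field = "orientation", row = bad)
  }
  ori[tgt_rev & !known] <- "-"
  ori[!known & !tgt_rev] <- "+"
  if (any(tgt_rev)) {
    tmp <- blocks$tgt_start[tgt_rev]
    blocks$tgt_start[tgt_rev] <- blocks$tgt_end[tgt_rev]
    blocks$tgt_end[tgt_rev] <- tmp
  }
  blocks$orientation <- ori
  blocks
}

#' Construct a validated pairwise synteny table
#'
#' A synteny table is one species pair's collection of homologous synteny
#' blocks (HSBs): each row maps a reference interval to a target interval
#' with a relative orientation.
#'
#' @param blocks data frame of raw blocks (see [normalize_blocks()] for the
#'   required columns; `orientation` may contain `NA`).
#' @param ref_species,tgt_species species identifiers for the reference
#'   (coordinate frame) and target genomes.
#' @param source provenance note, e.g. a file path or `"synthetic"`.
#' @return An object of class `synteny_table`: a data frame of normalised
#'   blocks with attributes `ref_species`, `tgt_species`, `source`.
#' @export
synteny_table <- function(blocks, ref_species, tgt_species,
                          source = "in-memory") {
  if (nrow(blocks) == 0L) {
    sv_data_error("a synteny table must contain at least one block")
  }
  blocks <- normalize_blocks(blocks)
  blocks$ref_chrom <- as.character(blocks$ref_chrom)
  blocks$tgt_chrom <- as.character(blocks$tgt_chrom)
  for (f in c("ref_start", "ref_end", "tgt_start", "tgt_end")) {
    blocks[[f]] <- as.numeric(blocks[[f]])  # one storage mode for coordinates
  }
  rownames(blocks) <- NULL
  attr(blocks, "ref_species") <- as.character(ref_species)
  attr(blocks, "tgt_species") <- as.character(tgt_species)
  attr(blocks, "source") <- source
  class(blocks) <- c("synteny_table", "data.frame")
  blocks
}

#' @export
print.synteny_table <- function(x, ...) {
  cat(sprintf("Synteny table %s -> %s: %d block(s) [%s]\n",
              attr(x, "ref_species"), attr(x, "tgt_species"), nrow(x),
              attr(x, "source")))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

ref_species <- function(tab) attr(tab, "ref_species")
tgt_species <- function(tab) attr(tab, "tgt_species")

#' Validate a synteny table against karyotypes
#'
#' Chromosome lengths exist precisely so block intervals can be
#' bounds-checked and scaled; this check gates every layout engine.
#' Errors (any of which make layouts refuse the table): a block naming a
#' chromosome absent from its species' karyotype; a block end exceeding
#' the chromosome length; `start > end` after normalisation.  Warnings:
#' two blocks overlapping on the same reference chromosome; a karyotype
#' chromosome with no block at all (it will show as a blank/uncoloured
#' region).
#'
#' @param table a [synteny_table()].
#' @param karyos a named list of [karyotype()] objects covering both of the
#'   table's species (names are species ids).  A missing species is a
#'   configuration error, not a data issue.
#' @return An object of class `validation_report`: a data frame with
#'   columns `severity` (`"error"`/`"warning"`), `index` (block row, or
#'   `NA` for whole-table issues) and `message`.
#' @export
validate_table <- function(table, karyos) {
  rs <- ref_species(table); ts <- tgt_species(table)
  for (sp in c(rs, ts)) {
    if (!sp %in% names(karyos)) {
      sv_config_error(sprintf(
        "no karyotype supplied for species '%s' (have: %s)",
        sp, paste(names(karyos), collapse = ", ")))
    }
  }
  rk <- karyos[[rs]]; tk <- karyos[[ts]]
  issues <- list()
  add <- function(severity, index, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, index = index, message = message,
      stringsAsFactors = FALSE)
  }

  check_side <- function(chrom, start, end, karyo, side) {
    miss <- !(chrom %in% karyo$chrom_name)
    for (i in which(miss)) {
      add("error", i, sprintf("%s chromosome '%s' absent from karyotype '%s'",
                              side, chrom[i], species_id(karyo)))
    }
    len <- chrom_length(karyo, chrom)
    over <- !miss & end > len
    for (i in which(over)) {
      add("error", i, sprintf(
        "%s interval %d-%d exceeds chromosome '%s' length %d",
        side, start[i], end[i], chrom[i], len[i]))
    }
    inv <- start > end
    for (i in which(inv)) {
      add("error", i, sprintf("%s start %d > end %d", side, start[i], end[i]))
    }
  }
  check_side(table$ref_chrom, table$ref_start, table$ref_end, rk, "reference")
  check_side(table$tgt_chrom, table$tgt_start, table$tgt_end, tk, "target")

  # overlap warnings on the reference genome: one warning per overlapping
  # pair, found by a start-sorted scan per chromosome (for each block,
  # later-starting blocks are checked until their start passes its end,
  # which enumerates exactly the intersecting pairs)
  for (ch in unique(table$ref_chrom)) {
    idx <- which(table$ref_chrom == ch)
    if (length(idx) < 2L) next
    ord <- idx[order(table$ref_start[idx], table$ref_end[idx])]
    for (a in seq_len(length(ord) - 1L)) {
      i <- ord[a]
      for (b in (a + 1L):length(ord)) {
        j <- ord[b]
        if (table$ref_start[j] > table$ref_end[i]) break
        add("warning", max(i, j), sprintf(
          "blocks %d and %d overlap on reference chromosome '%s'",
          min(i, j), max(i, j), ch))
      }
    }
  }

  for (ch in setdiff(rk$chrom_name, table$ref_chrom)) {
    add("warning", NA_integer_, sprintf(
      "reference chromosome '%s' has no aligned block (will be blank)", ch))
  }
  for (ch in setdiff(tk$chrom_name, table$tgt_chrom)) {
    add("warning", NA_integer_, sprintf(
      "target chromosome '%s' has no aligned block (will be blank)", ch))
  }

  report <- if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(), index = integer(),
               message = character(), stringsAsFactors = FALSE)
  class(report) <- c("validation_report", "data.frame")
  report
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("Validation report: clean\n")
  } else {
    cat(sprintf("Validation report: %d error(s), %d warning(s)\n",
                sum(x$severity == "error"), sum(x$severity == "warning")))
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

#' @rdname validate_table
#' @param report a `validation_report`.
#' @export
report_ok <- function(report) !any(report$severity == "error")

# Raise unless the table validates with zero errors against `karyos`.
assert_valid <- function(table, karyos) {
  rep <- validate_table(table, karyos)
  if (!report_ok(rep)) {
    sv_data_error(paste0(
      "synteny table failed validation:\n  ",
      paste(rep$message[rep$severity == "error"], collapse = "\n  ")))
  }
  invisible(rep)
}

#' Affine genomic-to-device coordinate map
#'
#' Maps base-pair positions on one chromosome onto a device interval:
#' `device(b) = device_origin + (b - bp_origin) / bp_span * device_span`.
#' Every layout engine scales through these maps, so chromosome bars share
#' one bp-to-point ratio within a figure.
#'
#' @param bp_origin genomic coordinate mapped to `device_origin`.
#' @param bp_span positive span in bp.
#' @param device_origin,device_span device interval (points).
#' @param axis `"horizontal"` or `"vertical"` (metadata for layouts).
#' @return An object of class `coord_map`.
#' @export
coord_map <- function(bp_origin, bp_span, device_origin, device_span,
                      axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  if (!is.finite(bp_span) || bp_span <= 0) {
    sv_usage_error("`bp_span` must be positive")
  }
  structure(list(bp_origin = bp_origin, bp_span = bp_span,
                 device_origin = device_origin, device_span = device_span,
                 axis = axis),
            class = "coord_map")
}

#' Map base pairs to device units
#'
#' @param cm a [coord_map()].
#' @param b numeric vector of genomic positions; must lie within
#'   `[bp_origin, bp_origin + bp_span]` -- callers clamp or reject upstream,
#'   this function never does so silently.
#' @return Device coordinates (numeric).
#' @export
map_bp <- function(cm, b) {
  stopifnot(inherits(cm, "coord_map"))
  out_of_range <- b < cm$bp_origin | b > cm$bp_origin + cm$bp_span
  if (any(out_of_range)) {
    i <- which(out_of_range)[1]
    sv_data_error(sprintf(
      "position %s outside coordinate map span [%s, %s]",
      format(b[i], scientific = FALSE),
      format(cm$bp_origin, scientific = FALSE),
      format(cm$bp_origin + cm$bp_span, scientific = FALSE)))
  }
  cm$device_origin + (b - cm$bp_origin) / cm$bp_span * cm$device_span
}

#' @rdname map_bp
#' @param d device coordinates to map back to bp.
#' @export
unmap_bp <- function(cm, d) {
  stopifnot(inherits(cm, "coord_map"))
  cm$bp_origin + (d - cm$device_origin) / cm$device_span * cm$bp_span
}
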