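# Readers and writers for the two native input file types, plus a
# converter for inferCARs/DESCHRAMBLER-style block files.
#
# Native lengths file:   TSV, columns chrom, length, species  (no header)
# Native alignment file: TSV, columns ref_chrom, ref_start, ref_end,
#   tgt_chrom, tgt_start, tgt_end, orientation, ref_species, tgt_species
#   (no header)
#
# Coordinates must be plain base-10 integers: decimals, thousands
# separators and scientific notation are rejected, never coerced --
# block files are machine-written and leniency invites silent corruption.

read_text_lines <- function(source) {
  if (inherits(source, "connection")) return(readLines(source, warn = FALSE))
  if (is.character(source) && length(source) == 1L) {
    if (!file.exists(source)) {
      sv_parse_error(sprintf("input file not found: '%s'", source))
    }
    return(readLines(source, warn = FALSE))
  }
  sv_usage_error("`source` must be a file path or a connection")
}

INT_RE <- "^[0-9]+$"

parse_coord <- function(tok, line, field) {
  ok <- grepl(INT_RE, tok)
  if (!all(ok)) {
    i <- which(!ok)[1]
    sv_parse_error(sprintf(
      "line %d: field '%s' is not a plain positive integer: '%s'",
      line[i], field, tok[i]), line = line[i], field = field)
  }
  as.numeric(tok)
}

#' Read a chromosome-lengths file
#'
#' Parses the native lengths format: three tab-separated columns
#' `chrom_name`, `length_bp`, `species_id`, no header.  Blank lines and
#' lines starting with `#` are ignored.  Returns one [karyotype()] per
#' distinct species, chromosomes in natural sort order.
#'
#' @param source file path or connection.
#' @return Named list of `karyotype` objects (names = species ids).  An
#'   empty input yields an empty list with a warning.
#' @export
read_lengths <- function(source) {
  lines <- read_text_lines(source)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warning("lengths input contains no records; returning an empty set",
            call. = FALSE)
    return(structure(list(), names = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    i <- which(nf != 3L)[1]
    sv_parse_error(sprintf(
      "line %d: expected 3 tab-separated fields (chrom, length, species), got %d",
      lineno[i], nf[i]), line = lineno[i])
  }
  m <- do.call(rbind, fields)
  chrom <- m[, 1]; len_tok <- m[, 2]; sp <- m[, 3]
  len <- parse_coord(len_tok, lineno, "length")
  key <- paste(sp, chrom, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    sv_parse_error(sprintf(
      "line %d: duplicate record for species '%s' chromosome '%s'",
      lineno[i], sp[i], chrom[i]), line = lineno[i])
  }
  out <- lapply(unique(sp), function(s) {
    sel <- sp == s
    karyotype(s, chrom[sel], len[sel])
  })
  names(out) <- unique(sp)
  out
}

#' Read a pairwise alignment (HSB) file
#'
#' Parses the native nine-column alignment format (see the package
#' overview) and groups rows into one [synteny_table()] per
#' (`ref_species`, `tgt_species`) pair, in order of first appearance; row
#' order within each table is preserved.  Every block passes through
#' [normalize_blocks()].  The orientation column accepts `+`, `-`,
#' `−` (minus sign), `1`, `-1`, or `.` for "not given".
#'
#' @param source file path or connection.
#' @return List of `synteny_table` objects, named `"ref>tgt"`.
#' @export
read_alignment <- function(source) {
  src_label <- if (is.character(source)) source else "connection"
  lines <- read_text_lines(source)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    sv_parse_error("alignment input contains no records")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    i <- which(nf != 9L)[1]
    sv_parse_error(sprintf(
      "line %d: expected 9 tab-separated fields, got %d", lineno[i], nf[i]),
      line = lineno[i])
  }
  m <- do.call(rbind, fields)
  df <- data.frame(
    ref_chrom = m[, 1],
    ref_start = parse_coord(m[, 2], lineno, "ref_start"),
    ref_end   = parse_coord(m[, 3], lineno, "ref_end"),
    tgt_chrom = m[, 4],
    tgt_start = parse_coord(m[, 5], lineno, "tgt_start"),
    tgt_end   = parse_coord(m[, 6], lineno, "tgt_end"),
    orientation = NA_character_,
    stringsAsFactors = FALSE)
  otok <- m[, 7]
  known <- otok != "."
  parsed <- parse_orientation(otok)
  if (any(known & is.na(parsed))) {
    i <- which(known & is.na(parsed))[1]
    sv_parse_error(sprintf(
      "line %d: invalid orientation token '%s' in column 7 (expected +, -, 1, -1 or .)",
      lineno[i], otok[i]), line = lineno[i], field = "orientation")
  }
  df$orientation[known] <- parsed[known]
  rs <- m[, 8]; ts <- m[, 9]
  pair <- paste0(rs, ">", ts)
  out <- lapply(unique(pair), function(p) {
    sel <- pair == p
    tryCatch(
      synteny_table(df[sel, , drop = FALSE], rs[sel][1], ts[sel][1],
                    source = src_label),
      error = function(e) e)
  })
  # surface normalisation failures as parse errors with a line number
  for (k in seq_along(out)) {
    if (inherits(out[[k]], "error")) {
      sel <- pair == unique(pair)[k]
      row <- out[[k]]$row %||% 1L
      sv_parse_error(sprintf("line %d: %s",
                             lineno[sel][row], conditionMessage(out[[k]])),
                     line = lineno[sel][row])
    }
  }
  names(out) <- unique(pair)
  out
}

#' Serialise synteny tables to the native alignment format
#'
#' `format_alignment()` returns the nine-column tab-separated lines;
#' `write_alignment()` writes them to a file.  Reading the output back
#' with [read_alignment()] reproduces the tables exactly (coordinates,
#' orientation, block order).  Orientation is always emitted as ASCII
#' `+`/`-` regardless of what the reader accepted.
#'
#' @param tables list of [synteny_table()] objects.
#' @return `format_alignment()`: character vector of lines (possibly
#'   empty).
#' @export
format_alignment <- function(tables) {
  unlist(lapply(tables, function(tab) {
    sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%s\t%s",
            tab$ref_chrom, as.integer(tab$ref_start), as.integer(tab$ref_end),
            tab$tgt_chrom, as.integer(tab$tgt_start), as.integer(tab$tgt_end),
            tab$orientation, ref_species(tab), tgt_species(tab))
  }), use.names = FALSE) %||% character()
}

#' @rdname format_alignment
#' @param file output file path or connection.
#' @export
write_alignment <- function(tables, file) {
  writeLines(format_alignment(tables), file)
  invisible(NULL)
}

#' @rdname read_lengths
#' @param karyos named list of karyotypes to serialise.
#' @param file output path or connection.
#' @export
write_lengths <- function(karyos, file) {
  lines <- unlist(lapply(karyos, function(k) {
    sprintf("%s\t%d\t%s", k$chrom_name, as.integer(k$length_bp),
            species_id(k))
  }), use.names = FALSE) %||% character()
  writeLines(lines, file)
  invisible(NULL)
}

#' Read an inferCARs/DESCHRAMBLER-style block file
#'
#' Ancestral-genome reconstruction tools emit blocks as records: a header
#' line starting `>` naming the block (a contiguous ancestral region /
#' ancestral chromosome fragment), followed by one segment line per
#' genome of the shape `genome.chrom:start-end sign`.  Comment lines
#' (`#`) and blank lines are skipped.  Dialect details that diverge from
#' this shape surface as parse errors rather than being guessed.
#'
#' @param source file path or connection.
#' @return An object of class `cars_document`: a list with element
#'   `records`, each record a list with `block_id` and a data frame
#'   `segments` (`genome`, `chrom`, `start`, `end`, `orientation`).
#' @export
read_cars <- function(source) {
  lines <- read_text_lines(source)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  records <- list()
  cur <- NULL
  seg_re <- "^\\s*([^.\\s]+)\\.(\\S+):([0-9]+)-([0-9]+)\\s+(\\S+)\\s*$"
  flush <- function() {
    if (!is.null(cur)) {
      cur$segments <- if (length(cur$segs)) do.call(rbind, cur$segs) else
        data.frame(genome = character(), chrom = character(),
                   start = numeric(), end = numeric(),
                   orientation = character(), stringsAsFactors = FALSE)
      cur$segs <- NULL
      records[[length(records) + 1L]] <<- cur
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(trimws(ln), ">")) {
      flush()
      cur <- list(block_id = trimws(sub("^\\s*>", "", ln)), segs = list())
      next
    }
    if (is.null(cur)) {
      sv_parse_error(sprintf(
        "line %d: segment line before any '>' record header", lineno[i]),
        line = lineno[i])
    }
    m <- regmatches(ln, regexec(seg_re, ln))[[1]]
    if (length(m) == 0L) {
      sv_parse_error(sprintf(
        "line %d: cannot parse segment line '%s' (expected genome.chrom:start-end sign)",
        lineno[i], trimws(ln)), line = lineno[i])
    }
    sign <- parse_orientation(m[6])
    if (is.na(sign)) {
      sv_parse_error(sprintf(
        "line %d: invalid orientation sign '%s'", lineno[i], m[6]),
        line = lineno[i], field = "orientation")
    }
    cur$segs[[length(cur$segs) + 1L]] <- data.frame(
      genome = m[2], chrom = m[3],
      start = as.numeric(m[4]), end = as.numeric(m[5]),
      orientation = sign, stringsAsFactors = FALSE)
  }
  flush()
  structure(list(records = records), class = "cars_document")
}

#' Convert a CARs block document to a pairwise synteny table
#'
#' For every record holding exactly one segment for each of the two
#' requested genomes, emits one synteny block.  The reference genome's
#' coordinates are kept ascending; relative orientation is expressed on
#' the target: `"+"` when the two segments' signs agree, `"-"` when they
#' differ.  Segments of other genomes are ignored (multi-species
#' documents are legal); records missing either requested genome are
#' skipped and counted in the conversion summary.  Two segments for the
#' same genome within one record is an ambiguity error naming the block.
#'
#' @param doc a [read_cars()] document.
#' @param ref_genome,tgt_genome genome identifiers as used in the file.
#' @return A [synteny_table()]; attribute `conversion_summary` records the
#'   numbers of converted and skipped records.
#' @export
convert_cars <- function(doc, ref_genome, tgt_genome) {
  stopifnot(inherits(doc, "cars_document"))
  rows <- list(); skipped <- 0L
  for (rec in doc$records) {
    seg <- rec$segments
    ri <- which(seg$genome == ref_genome)
    ti <- which(seg$genome == tgt_genome)
    if (length(ri) > 1L || length(ti) > 1L) {
      sv_data_error(sprintf(
        "block '%s' holds %d segments for genome '%s': ambiguous record",
        rec$block_id,
        max(length(ri), length(ti)),
        if (length(ri) > 1L) ref_genome else tgt_genome))
    }
    if (length(ri) == 0L || length(ti) == 0L) { skipped <- skipped + 1L; next }
    agree <- seg$orientation[ri] == seg$orientation[ti]
    rows[[length(rows) + 1L]] <- data.frame(
      ref_chrom = seg$chrom[ri],
      ref_start = min(seg$start[ri], seg$end[ri]),
      ref_end   = max(seg$start[ri], seg$end[ri]),
      tgt_chrom = seg$chrom[ti],
      tgt_start = min(seg$start[ti], seg$end[ti]),
      tgt_end   = max(seg$start[ti], seg$end[ti]),
      orientation = if (agree) "+" else "-",
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    sv_data_error(sprintf(
      "no record contains segments for both '%s' and '%s'",
      ref_genome, tgt_genome))
  }
  tab <- synteny_table(do.call(rbind, rows), ref_genome, tgt_genome,
                       source = "cars")
  attr(tab, "conversion_summary") <- list(converted = length(rows),
                                          skipped = skipped)
  tab
}
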