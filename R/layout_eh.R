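# Evolution Highway style: one standalone panel per reference chromosome,
# one column per target species, blocks coloured by relative orientation
# (blue '+', pink '-'), target chromosome numbers written in the blocks.
# Reference regions with no aligned block stay blank.

#' Lay out an Evolution Highway figure
#'
#' Builds one panel per reference chromosome that carries at least one
#' block in at least one table.  Within a panel there is one vertical
#' column per target species, in the order the tables are supplied; any
#' number of target species is supported.  Each homologous synteny block
#' becomes a filled rectangle spanning its reference interval, coloured
#' `style$same_colour` for `+` orientation and `style$opposite_colour`
#' for `-`, and labelled with its target chromosome name (written beside
#' the block when the block is thinner than `style$min_label_height`).
#' All panels share one bp-to-point scale so chromosome sizes stay
#' comparable.
#'
#' @param ref_karyo [karyotype()] of the shared reference species.
#' @param tables list of [synteny_table()]s, one per target species, all
#'   with `ref_species` equal to `ref_karyo`'s species, already validated
#'   against the karyotypes (see [validate_table()]).
#' @param style a [style_config()] for style `"eh"`.
#' @return A [scene()].
#' @export
layout_eh <- function(ref_karyo, tables, style = style_config("eh")) {
  stopifnot(inherits(ref_karyo, "karyotype"), inherits(style, "style_config"))
  if (!length(tables)) sv_usage_error("no synteny tables supplied")
  for (tab in tables) {
    if (!identical(ref_species(tab), species_id(ref_karyo))) {
      sv_config_error(sprintf(
        "table %s -> %s does not use reference species '%s'",
        ref_species(tab), tgt_species(tab), species_id(ref_karyo)))
    }
    bad <- !(tab$ref_chrom %in% ref_karyo$chrom_name) |
      tab$ref_end > chrom_length(ref_karyo, tab$ref_chrom)
    bad[is.na(bad)] <- TRUE
    if (any(bad)) {
      sv_data_error(sprintf(
        "table %s -> %s contains blocks outside the reference karyotype; validate first",
        ref_species(tab), tgt_species(tab)))
    }
  }

  chroms <- ref_karyo$chrom_name
  has_block <- vapply(chroms, function(ch) {
    any(vapply(tables, function(tab) any(tab$ref_chrom == ch), logical(1)))
  }, logical(1))
  chroms <- chroms[has_block]
  if (!length(chroms)) sv_data_error("no reference chromosome has any block")

  n_tgt <- length(tables)
  u <- style$axis_length / max(ref_karyo$length_bp)  # points per bp, shared
  panel_w <- n_tgt * style$column_width + (n_tgt - 1) * style$column_gap
  title_h <- style$title_size + 4
  header_h <- style$font_size + 4
  panel_h <- title_h + header_h + style$axis_length

  n_panels <- length(chroms)
  per_row <- style$panels_per_row
  if (is.na(per_row)) per_row <- max(1L, ceiling(sqrt(n_panels)))
  per_row <- min(per_row, n_panels)
  n_rows <- ceiling(n_panels / per_row)

  width <- 2 * style$margin + per_row * panel_w +
    (per_row - 1) * style$panel_gap_x
  height <- 2 * style$margin + n_rows * panel_h +
    (n_rows - 1) * style$panel_gap_y

  prims <- list()
  push <- function(p) prims[[length(prims) + 1L]] <<- p

  for (pi in seq_along(chroms)) {
    ch <- chroms[pi]
    len <- chrom_length(ref_karyo, ch)
    row <- (pi - 1L) %/% per_row
    col <- (pi - 1L) %% per_row
    x0 <- style$margin + col * (panel_w + style$panel_gap_x)
    y0 <- style$margin + row * (panel_h + style$panel_gap_y)
    push(prim_text(x0 + panel_w / 2, y0 + style$title_size, ch,
                   size = style$title_size, anchor = "middle", z = 4L,
                   meta = list(role = "panel_title", ref_chrom = ch)))
    axis_y0 <- y0 + title_h + header_h
    cm <- coord_map(0, len, axis_y0, len * u, axis = "vertical")

    for (j in seq_len(n_tgt)) {
      tab <- tables[[j]]
      cx <- x0 + (j - 1) * (style$column_width + style$column_gap)
      push(prim_text(cx + style$column_width / 2,
                     y0 + title_h + style$font_size, tgt_species(tab),
                     size = style$font_size, anchor = "middle", z = 4L,
                     meta = list(role = "column_header",
                                 target = tgt_species(tab))))
      if (isTRUE(style$draw_outline)) {
        push(prim_rect(cx, axis_y0, style$column_width, len * u,
                       fill = NA, stroke = style$outline_colour,
                       stroke_width = style$outline_width, z = 0L,
                       meta = list(role = "outline", ref_chrom = ch,
                                   target = tgt_species(tab))))
      }
      rows <- which(tab$ref_chrom == ch)
      for (i in rows) {
        y1 <- map_bp(cm, tab$ref_start[i] - 1)
        y2 <- map_bp(cm, tab$ref_end[i])
        fill <- if (tab$orientation[i] == "+") style$same_colour else
          style$opposite_colour
        push(prim_rect(cx, y1, style$column_width, y2 - y1, fill = fill,
                       z = 1L,
                       meta = list(role = "hsb", ref_chrom = ch,
                                   target = tgt_species(tab), block = i,
                                   orientation = tab$orientation[i])))
        thin <- (y2 - y1) < style$min_label_height
        lx <- if (thin) cx + style$column_width + 2 else
          cx + style$column_width / 2
        push(prim_text(lx, (y1 + y2) / 2 + style$font_size * 0.35,
                       tab$tgt_chrom[i], size = style$font_size,
                       anchor = if (thin) "start" else "middle", z = 2L,
                       meta = list(role = "hsb_label", ref_chrom = ch,
                                   target = tgt_species(tab), block = i,
                                   placement = if (thin) "beside" else
                                     "inside")))
      }
    }
  }

  scene(width, height, prims,
        title = sprintf("Evolution Highway: reference %s",
                        species_id(ref_karyo)))
}
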