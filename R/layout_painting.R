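# Chromosome painting style: each target chromosome is a horizontal
# rectangle whose HSBs are painted by homologous reference chromosome.
# A diagonal inside each painted segment encodes the HSB's relative
# position within the reference chromosome (endpoint heights =
# ref_start/ref_length and ref_end/ref_length) and its orientation: the
# diagonal rises left-to-right for '+' and falls for '-'.  Vertical bars
# mark HSB boundaries; uncovered target bp stay uncoloured.

#' Lay out a chromosome painting figure
#'
#' @param tgt_karyo [karyotype()] of the target species (the chromosomes
#'   drawn as rectangles).
#' @param ref_karyo [karyotype()] of the reference species (decides fill
#'   colours and the y-position denominators).
#' @param table a validated [synteny_table()] with matching species.
#' @param style a [style_config()] for style `"painting"`.
#' @return A [scene()].
#' @details For a `-` block the segment's y-heights are *not* mirrored:
#'   the y-axis keeps meaning "relative position within the reference
#'   chromosome" independent of strand, and the reversal is expressed by
#'   drawing the diagonal right-to-left so that it falls.  A fully
#'   syntenic chromosome in `+` orientation is traversed by one line from
#'   bottom-left to top-right.
#' @export
layout_painting <- function(tgt_karyo, ref_karyo, table,
                            style = style_config("painting")) {
  stopifnot(inherits(tgt_karyo, "karyotype"), inherits(ref_karyo, "karyotype"),
            inherits(table, "synteny_table"), inherits(style, "style_config"))
  if (!identical(tgt_species(table), species_id(tgt_karyo)) ||
      !identical(ref_species(table), species_id(ref_karyo))) {
    sv_config_error(sprintf(
      "table %s -> %s does not match karyotypes '%s' (ref) / '%s' (target)",
      ref_species(table), tgt_species(table),
      species_id(ref_karyo), species_id(tgt_karyo)))
  }
  if (any(!table$ref_chrom %in% ref_karyo$chrom_name)) {
    miss <- setdiff(table$ref_chrom, ref_karyo$chrom_name)
    sv_data_error(sprintf(
      "reference chromosome(s) %s absent from karyotype '%s' (needed for relative positions)",
      paste(sQuote(miss), collapse = ", "), species_id(ref_karyo)))
  }
  if (any(!table$tgt_chrom %in% tgt_karyo$chrom_name) ||
      any(table$tgt_end > chrom_length(tgt_karyo, table$tgt_chrom))) {
    sv_data_error("table contains blocks outside the target karyotype; validate first")
  }

  pal <- chrom_palette(ref_karyo$chrom_name, style$palette_base)
  u <- style$plot_width / max(tgt_karyo$length_bp)
  x0 <- style$margin + style$label_gutter
  rh <- style$row_height

  prims <- list()
  push <- function(p) prims[[length(prims) + 1L]] <<- p

  for (ci in seq_len(nrow(tgt_karyo))) {
    ch <- tgt_karyo$chrom_name[ci]
    len <- tgt_karyo$length_bp[ci]
    y0 <- style$margin + (ci - 1) * (rh + style$row_gap)
    cm <- coord_map(0, len, x0, len * u, axis = "horizontal")
    push(prim_rect(x0, y0, len * u, rh, fill = NA,
                   stroke = style$outline_colour,
                   stroke_width = style$outline_width, z = 0L,
                   meta = list(role = "chrom_outline", tgt_chrom = ch)))
    push(prim_text(x0 - 6, y0 + rh / 2 + style$font_size * 0.35, ch,
                   size = style$font_size, anchor = "end", z = 4L,
                   meta = list(role = "chrom_label", tgt_chrom = ch)))

    rows <- which(table$tgt_chrom == ch)
    bounds <- numeric()
    for (i in rows) {
      x1 <- map_bp(cm, table$tgt_start[i] - 1)
      x2 <- map_bp(cm, table$tgt_end[i])
      rlen <- chrom_length(ref_karyo, table$ref_chrom[i])
      f_start <- table$ref_start[i] / rlen
      f_end <- table$ref_end[i] / rlen
      push(prim_rect(x1, y0, x2 - x1, rh, fill = pal[[table$ref_chrom[i]]],
                     z = 1L,
                     meta = list(role = "hsb", tgt_chrom = ch,
                                 ref_chrom = table$ref_chrom[i], block = i,
                                 orientation = table$orientation[i])))
      # heights measured from the rectangle bottom (device y grows down)
      y_of <- function(f) (y0 + rh) - f * rh
      plus <- table$orientation[i] == "+"
      ya <- if (plus) y_of(f_start) else y_of(f_end)
      yb <- if (plus) y_of(f_end) else y_of(f_start)
      push(prim_segment(x1, ya, x2, yb, stroke = style$diagonal_colour,
                        stroke_width = style$diagonal_width, z = 2L,
                        meta = list(role = "diagonal", block = i,
                                    orientation = table$orientation[i],
                                    f_start = f_start, f_end = f_end)))
      bounds <- c(bounds, x1, x2)
    }
    for (bx in sort(unique(round(bounds, 6)))) {
      push(prim_segment(bx, y0, bx, y0 + rh,
                        stroke = style$boundary_colour,
                        stroke_width = style$boundary_width, z = 3L,
                        meta = list(role = "boundary", tgt_chrom = ch)))
    }
  }

  body_h <- style$margin + nrow(tgt_karyo) * (rh + style$row_gap)
  width <- 2 * style$margin + style$label_gutter + style$plot_width

  # legend: colour -> reference chromosome, wrapped rows
  legend_h <- 0
  if (isTRUE(style$legend)) {
    sw <- style$legend_swatch
    lx <- x0; ly <- body_h + style$row_gap
    for (ch in ref_karyo$chrom_name) {
      entry_w <- sw + 4 + (nchar(ch) + 1) * style$font_size * 0.62 + 8
      if (lx + entry_w > width - style$margin) {
        lx <- x0; ly <- ly + sw + 6
      }
      push(prim_rect(lx, ly, sw, sw, fill = pal[[ch]], z = 1L,
                     meta = list(role = "legend_swatch", ref_chrom = ch)))
      push(prim_text(lx + sw + 3, ly + sw - 2, ch, size = style$font_size,
                     anchor = "start", z = 4L,
                     meta = list(role = "legend_label", ref_chrom = ch)))
      lx <- lx + entry_w
    }
    legend_h <- ly + sw + style$row_gap - body_h
  }

  scene(width, body_h + legend_h + style$margin, prims,
        title = sprintf("Chromosome painting: %s painted by %s",
                        species_id(tgt_karyo), species_id(ref_karyo)))
}
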