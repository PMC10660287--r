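# Linear comparison style: genomes stacked top to bottom in chain order,
# adjacent genomes connected by colour-coded ribbons.  The top genome's
# chromosomes are colour-coded; every lower genome is drawn grey.  An
# inversion shows as a twist: the ribbon's left edge joins ref-start to
# tgt-end instead of tgt-start.

#' Verify a chain of pairwise comparisons
#'
#' The linear style stacks genomes in the order the alignment tables are
#' supplied: the first table's reference is the top track, each table's
#' target must be the next table's reference.
#'
#' @param tables ordered list of [synteny_table()]s.
#' @return Character vector of species in track order (top to bottom).
#' @export
chain_check <- function(tables) {
  if (!length(tables)) sv_usage_error("at least one synteny table is required")
  sp <- ref_species(tables[[1]])
  for (i in seq_along(tables)) {
    if (i > 1L) {
      prev_tgt <- tgt_species(tables[[i - 1L]])
      cur_ref <- ref_species(tables[[i]])
      if (!identical(prev_tgt, cur_ref)) {
        sv_abort("synvis_chain_error", sprintf(
          paste0("broken comparison chain between tables %d and %d: ",
                 "target species '%s' does not match reference species '%s'"),
          i - 1L, i, prev_tgt, cur_ref))
      }
    }
    sp <- c(sp, tgt_species(tables[[i]]))
  }
  sp
}

# Horizontal slot coordinate maps for one genome track.
track_slots <- function(karyo, x0, u, gap) {
  xs <- x0
  slots <- list()
  for (i in seq_len(nrow(karyo))) {
    w <- karyo$length_bp[i] * u
    slots[[karyo$chrom_name[i]]] <-
      coord_map(0, karyo$length_bp[i], xs, w, axis = "horizontal")
    xs <- xs + w + gap
  }
  slots
}

# Trace a position on track `level` back to the top track's chromosome
# through the chain of tables.  Returns NA if any hop has no covering
# block (e.g. an unaligned region).
trace_to_top <- function(chrom, pos, level, tables) {
  while (level > 1L) {
    tab <- tables[[level - 1L]]
    hit <- which(tab$tgt_chrom == chrom & tab$tgt_start <= pos &
                 tab$tgt_end >= pos)
    if (!length(hit)) return(NA_character_)
    i <- hit[1]
    off <- pos - tab$tgt_start[i]
    pos <- if (tab$orientation[i] == "+") tab$ref_start[i] + off else
      tab$ref_end[i] - off
    chrom <- tab$ref_chrom[i]
    level <- level - 1L
  }
  chrom
}

#' Lay out a linear multi-genome comparison
#'
#' One horizontal track per species in chain order, chromosomes laid
#' left-to-right as slots whose widths are proportional to length in bp
#' with a fixed gap; all tracks share one bp-to-point scale.  For every
#' block of table *i* one ribbon connects the block's reference interval
#' on track *i* to its target interval on track *i + 1*; a `-` block is
#' drawn twisted.  Ribbon edges are smooth cubic curves anchored exactly
#' at the mapped block boundaries.  With
#' `style$propagate_colours = FALSE` (default) each ribbon takes the
#' colour of its own pair's reference chromosome; with `TRUE` colours are
#' traced through the chain to the top genome, so a ribbon keeps the
#' colour of the top-track chromosome it ultimately descends from
#' (untraceable regions fall back to grey).
#'
#' @param tables ordered list of validated [synteny_table()]s forming a
#'   chain (see [chain_check()]).
#' @param karyos named list of [karyotype()]s covering every chained
#'   species.
#' @param style a [style_config()] for style `"linear"`.
#' @return A [scene()].
#' @export
layout_linear <- function(tables, karyos, style = style_config("linear")) {
  stopifnot(inherits(style, "style_config"))
  species <- chain_check(tables)
  for (sp in species) {
    if (!sp %in% names(karyos)) {
      sv_config_error(sprintf("no karyotype supplied for species '%s'", sp))
    }
  }
  for (tab in tables) assert_valid(tab, karyos)

  kys <- karyos[species]
  # shared bp scale: the widest genome (bars + gaps) spans plot_width
  u <- min(vapply(kys, function(k) {
    (style$plot_width - (nrow(k) - 1) * style$chrom_gap) / sum(k$length_bp)
  }, numeric(1)))
  if (!is.finite(u) || u <= 0) {
    sv_usage_error("plot_width too small for the chromosome gaps")
  }

  x0 <- style$margin + style$label_gutter
  headroom <- style$font_size + 6
  track_y <- function(i) style$margin + headroom +
    (i - 1) * (style$track_height + style$track_gap)

  top_pal <- chrom_palette(kys[[1]]$chrom_name, style$palette_base)
  slots <- lapply(kys, track_slots, x0 = x0, u = u, gap = style$chrom_gap)

  prims <- list()
  push <- function(p) prims[[length(prims) + 1L]] <<- p

  for (ti in seq_along(species)) {
    sp <- species[ti]; k <- kys[[ti]]; y0 <- track_y(ti)
    push(prim_text(x0 - 8, y0 + style$track_height / 2 +
                     style$font_size * 0.35, sp, size = style$font_size,
                   anchor = "end", z = 4L,
                   meta = list(role = "track_label", species = sp)))
    for (ci in seq_len(nrow(k))) {
      ch <- k$chrom_name[ci]
      cm <- slots[[ti]][[ch]]
      fill <- if (ti == 1L) top_pal[[ch]] else style$grey
      push(prim_rect(cm$device_origin, y0, cm$device_span,
                     style$track_height, fill = fill,
                     stroke = style$outline_colour,
                     stroke_width = style$outline_width, z = 1L,
                     meta = list(role = "chrom", species = sp,
                                 chrom = ch, track = ti)))
      push(prim_text(cm$device_origin + cm$device_span / 2, y0 - 3, ch,
                     size = style$font_size, anchor = "middle", z = 4L,
                     meta = list(role = "chrom_label", species = sp,
                                 chrom = ch)))
    }
  }

  for (ti in seq_along(tables)) {
    tab <- tables[[ti]]
    pair_pal <- chrom_palette(kys[[ti]]$chrom_name, style$palette_base)
    y_top <- track_y(ti) + style$track_height
    y_bot <- track_y(ti + 1L)
    dy <- (y_bot - y_top) * 0.4
    for (i in seq_len(nrow(tab))) {
      cm_r <- slots[[ti]][[tab$ref_chrom[i]]]
      cm_t <- slots[[ti + 1L]][[tab$tgt_chrom[i]]]
      xr0 <- map_bp(cm_r, tab$ref_start[i] - 1)
      xr1 <- map_bp(cm_r, tab$ref_end[i])
      xt0 <- map_bp(cm_t, tab$tgt_start[i] - 1)
      xt1 <- map_bp(cm_t, tab$tgt_end[i])
      twisted <- tab$orientation[i] == "-"
      # left edge joins ref-start to tgt-start; twisted to tgt-end
      xl <- if (twisted) xt1 else xt0
      xr <- if (twisted) xt0 else xt1
      if (isTRUE(style$propagate_colours)) {
        mid <- (tab$ref_start[i] + tab$ref_end[i]) / 2
        top_chrom <- trace_to_top(tab$ref_chrom[i], mid, ti, tables)
        col <- if (is.na(top_chrom)) style$grey else top_pal[[top_chrom]]
      } else {
        col <- pair_pal[[tab$ref_chrom[i]]]
      }
      cmds <- list(
        list("M", xr0, y_top),
        list("C", xr0, y_top + dy, xl, y_bot - dy, xl, y_bot),
        list("L", xr, y_bot),
        list("C", xr, y_bot - dy, xr1, y_top + dy, xr1, y_top),
        list("Z"))
      push(prim_path(cmds, fill = with_alpha(col, style$ribbon_opacity),
                     z = 2L,
                     meta = list(role = "ribbon", table = ti, block = i,
                                 twisted = twisted,
                                 ref_anchor = c(xr0, xr1),
                                 tgt_anchor = c(xt0, xt1))))
    }
  }

  width <- 2 * style$margin + style$label_gutter + style$plot_width
  height <- track_y(length(species)) + style$track_height + style$margin
  scene(width, height, prims,
        title = paste("Linear synteny:", paste(species, collapse = " - ")))
}
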