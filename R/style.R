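# Style configuration: colours, dimensions and fonts for the three plot
# styles.  Every colour a renderer emits originates here or in the
# palette derived from here.

# Categorical base palette for colouring by reference chromosome
# (painting + linear styles).  20 well-separated hues; when a genome has
# more chromosomes the palette cycles with a progressive lightness shift.
SV_PALETTE20 <- c(
  "#4E79A7", "#F28E2B", "#E15759", "#76B7B2", "#59A14F",
  "#EDC948", "#B07AA1", "#FF9DA7", "#9C755F", "#BAB0AC",
  "#1170AA", "#FC7D0B", "#C85200", "#57606C", "#5FA2CE",
  "#A3ACB9", "#7B848F", "#A3CCE9", "#FFBC79", "#C8D0D9")

#' Style configuration for the three plot styles
#'
#' Returns a list of named style parameters with per-style defaults; any
#' parameter can be overridden through `...`.  Dimensions are in points
#' (1/72 inch), colours are hex RGB strings.
#'
#' Shared parameters: `font_size` (labels, pt), `title_size`, `margin`
#' (page margin, pt), `palette_base` (categorical colours keyed by
#' reference chromosome in natural order), `grey` (non-reference
#' chromosome fill in the linear style), `outline_colour`,
#' `outline_width`.
#'
#' Evolution Highway (`"eh"`): `same_colour` (blocks in `+` orientation,
#' default blue), `opposite_colour` (`-`, default pink), `axis_length`
#' (device length of the longest reference chromosome), `column_width`,
#' `column_gap`, `panel_gap_x`, `panel_gap_y`, `panels_per_row` (`NA` =
#' near-square grid), `min_label_height` (blocks thinner than this get
#' their chromosome number written beside, not inside, the block),
#' `draw_outline` (chromosome outline behind blank regions).
#'
#' Painting (`"painting"`): `plot_width` (device length of the longest
#' target chromosome), `row_height`, `row_gap`, `label_gutter`,
#' `diagonal_colour`, `boundary_colour`, `legend` (draw the colour ->
#' reference chromosome legend).
#'
#' Linear (`"linear"`): `plot_width` (device length of the longest
#' genome), `track_height`, `track_gap`, `chrom_gap`, `ribbon_opacity`
#' (default 0.7 so crossing ribbons stay distinguishable),
#' `propagate_colours` (`FALSE` = each ribbon takes its own pair's
#' reference-chromosome colour; `TRUE` = colours are traced through the
#' chain to the top genome).
#'
#' @param style one of `"eh"`, `"painting"`, `"linear"`.
#' @param ... overrides, e.g. `same_colour = "#0000FF"`.
#' @return An object of class `style_config`.
#' @export
style_config <- function(style = c("eh", "painting", "linear"), ...) {
  style <- match.arg(style)
  base <- list(
    style = style,
    font_size = 7,
    title_size = 10,
    margin = 24,
    palette_base = SV_PALETTE20,
    grey = "#C9C9C9",
    outline_colour = "#555555",
    outline_width = 0.6,
    text_colour = "#000000")
  per_style <- switch(style,
    eh = list(
      same_colour = "#2C7BB6",      # '+' orientation, blue
      opposite_colour = "#F17CB0",  # '-' orientation, pink
      axis_length = 280,
      column_width = 34,
      column_gap = 6,
      panel_gap_x = 34,
      panel_gap_y = 46,
      panels_per_row = NA_integer_,
      min_label_height = 9,
      draw_outline = TRUE),
    painting = list(
      plot_width = 540,
      row_height = 22,
      row_gap = 12,
      label_gutter = 56,
      diagonal_colour = "#1A1A1A",
      diagonal_width = 0.8,
      boundary_colour = "#1A1A1A",
      boundary_width = 0.8,
      legend = TRUE,
      legend_swatch = 10),
    linear = list(
      plot_width = 560,
      track_height = 13,
      track_gap = 78,
      chrom_gap = 10,
      label_gutter = 64,
      ribbon_opacity = 0.7,
      propagate_colours = FALSE))
  cfg <- utils::modifyList(c(base, per_style), list(...))
  unknown <- setdiff(names(list(...)), names(c(base, per_style)))
  if (length(unknown)) {
    sv_usage_error(paste("unknown style parameter(s):",
                         paste(unknown, collapse = ", ")))
  }
  structure(cfg, class = "style_config")
}

#' Categorical palette keyed by chromosome name
#'
#' Assigns one fill colour per chromosome in natural sort order.  When
#' chromosomes outnumber the base palette the palette cycles, each cycle
#' lightened towards white so repeats remain distinguishable.
#'
#' @param chrom_names chromosome names to colour.
#' @param base_palette hex colours to draw from.
#' @return Named character vector colour per chromosome.
#' @export
chrom_palette <- function(chrom_names, base_palette = SV_PALETTE20) {
  chrom_names <- unique(as.character(chrom_names))
  ordered <- chrom_names[natural_chrom_order(chrom_names)]
  n <- length(ordered); k <- length(base_palette)
  idx <- ((seq_len(n) - 1L) %% k) + 1L
  cycle <- (seq_len(n) - 1L) %/% k
  cols <- base_palette[idx]
  shift <- pmin(cycle * 0.35, 0.8)
  lift <- shift > 0
  if (any(lift)) cols[lift] <- lighten_hex(cols[lift], shift[lift])
  stats::setNames(cols, ordered)
}

# "#RRGGBB" + alpha in [0,1] -> "#RRGGBBAA"
with_alpha <- function(hex, alpha) {
  if (alpha >= 1) return(hex)
  paste0(hex, sprintf("%02X", as.integer(round(alpha * 255))))
}
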