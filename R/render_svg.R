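# Deterministic SVG writer.  Identical scene + package version =>
# byte-identical output: no timestamps, no generated ids, fixed 3-decimal
# coordinate formatting, primitives emitted in z-order then input order.

split_alpha <- function(hex) {
  # "#RRGGBBAA" -> list(colour, opacity); plain colours pass through
  if (is.na(hex)) return(list(col = NA_character_, op = NA_real_))
  if (nchar(hex) == 9L) {
    list(col = substr(hex, 1, 7),
         op = strtoi(substr(hex, 8, 9), base = 16L) / 255)
  } else {
    list(col = hex, op = NA_real_)
  }
}

fill_attrs <- function(fill) {
  fa <- split_alpha(fill)
  if (is.na(fa$col)) return('fill="none"')
  a <- sprintf('fill="%s"', fa$col)
  if (!is.na(fa$op)) a <- paste(a, sprintf('fill-opacity="%s"',
                                           fmt_num(fa$op)))
  a
}

stroke_attrs <- function(stroke, width) {
  sa <- split_alpha(stroke)
  if (is.na(sa$col)) return("")
  paste0(sprintf(' stroke="%s" stroke-width="%s"', sa$col, fmt_num(width)),
         if (!is.na(sa$op)) sprintf(' stroke-opacity="%s"', fmt_num(sa$op))
         else "")
}

path_d <- function(cmds) {
  paste(vapply(cmds, function(cmd) {
    if (cmd[[1]] == "Z") return("Z")
    paste(cmd[[1]], paste(fmt_num(as.numeric(cmd[-1])), collapse = " "))
  }, character(1)), collapse = " ")
}

svg_element <- function(p) {
  switch(p$kind,
    rectangle = sprintf('<rect x="%s" y="%s" width="%s" height="%s" %s%s/>',
      fmt_num(p$x), fmt_num(p$y), fmt_num(p$w), fmt_num(p$h),
      fill_attrs(p$fill), stroke_attrs(p$stroke, p$stroke_width)),
    segment = sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s"%s/>',
      fmt_num(p$x1), fmt_num(p$y1), fmt_num(p$x2), fmt_num(p$y2),
      stroke_attrs(p$stroke, p$stroke_width)),
    polygon = sprintf('<polygon points="%s" %s%s/>',
      paste(sprintf("%s,%s", fmt_num(p$xs), fmt_num(p$ys)), collapse = " "),
      fill_attrs(p$fill), stroke_attrs(p$stroke, p$stroke_width)),
    path = sprintf('<path d="%s" %s%s/>',
      path_d(p$cmds), fill_attrs(p$fill),
      stroke_attrs(p$stroke, p$stroke_width)),
    text = sprintf(
      '<text x="%s" y="%s" font-size="%s" text-anchor="%s" fill="%s" font-family="Helvetica,Arial,sans-serif">%s</text>',
      fmt_num(p$x), fmt_num(p$y), fmt_num(p$size), p$anchor, p$fill,
      xml_escape(p$text)),
    sv_data_error(sprintf("unknown primitive kind '%s'", p$kind)))
}

#' Render a scene to SVG
#'
#' Writes a standalone SVG 1.1 document.  Output is deterministic: the
#' same scene and package version always serialise to the same bytes
#' (fixed number formatting, no timestamps or random ids), which makes
#' SVG output snapshot-testable.  Primitives are emitted sorted by
#' `z_order`, ties in input order.
#'
#' @param sc a [scene()].
#' @param file output path or connection; `NULL` returns the lines
#'   invisibly without writing.
#' @return Invisibly, the character vector of SVG lines.
#' @export
render_svg <- function(sc, file = NULL) {
  check_scene(sc)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'width="%spt" height="%spt" viewBox="0 0 %s %s">'),
            fmt_num(sc$width), fmt_num(sc$height),
            fmt_num(sc$width), fmt_num(sc$height)),
    sprintf("<title>%s</title>", xml_escape(sc$metadata$title)),
    sprintf("<desc>%s</desc>", xml_escape(sc$metadata$generator)),
    vapply(ordered_prims(sc), svg_element, character(1)),
    "</svg>")
  if (!is.null(file)) writeLines(lines, file, useBytes = TRUE)
  invisible(lines)
}
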