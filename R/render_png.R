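# PNG rasteriser: the same scene drawn through R's png device.

bezier_points <- function(p0, p1, p2, p3, n = 24L) {
  t <- seq(0, 1, length.out = n)
  b <- function(a0, a1, a2, a3)
    (1 - t)^3 * a0 + 3 * (1 - t)^2 * t * a1 + 3 * (1 - t) * t^2 * a2 +
      t^3 * a3
  list(x = b(p0[1], p1[1], p2[1], p3[1]), y = b(p0[2], p1[2], p2[2], p3[2]))
}

# Flatten a cubic path into polygon vertices for base graphics.
flatten_path <- function(cmds) {
  xs <- numeric(); ys <- numeric(); cur <- c(NA_real_, NA_real_)
  for (cmd in cmds) {
    op <- cmd[[1]]
    v <- if (op != "Z") as.numeric(cmd[-1]) else numeric()
    if (op == "M" || op == "L") {
      cur <- v
      xs <- c(xs, v[1]); ys <- c(ys, v[2])
    } else if (op == "C") {
      bp <- bezier_points(cur, v[1:2], v[3:4], v[5:6])
      xs <- c(xs, bp$x[-1]); ys <- c(ys, bp$y[-1])
      cur <- v[5:6]
    }
  }
  list(x = xs, y = ys)
}

#' Render a scene to PNG
#'
#' Rasterises the same scene the SVG writer serialises, via the `png()`
#' device.  Pixel dimensions are `scene size in points * dpi / 72`,
#' rounded.
#'
#' @param sc a [scene()].
#' @param file output file path.
#' @param dpi positive resolution in dots per inch (72 reproduces the
#'   device-unit size 1:1).
#' @return Invisibly, the output path.
#' @export
render_png <- function(sc, file, dpi = 144) {
  if (!is.numeric(dpi) || length(dpi) != 1L || !is.finite(dpi) || dpi <= 0) {
    sv_usage_error("`dpi` must be a single positive number")
  }
  check_scene(sc)
  if (!capabilities("png")) {
    sv_config_error("this R build has no png device")
  }
  pw <- max(1L, as.integer(round(sc$width * dpi / 72)))
  ph <- max(1L, as.integer(round(sc$height * dpi / 72)))
  grDevices::png(file, width = pw, height = ph, units = "px", res = dpi,
                 bg = "white", type = "cairo")
  on.exit(grDevices::dev.off())
  graphics::par(mai = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, sc$width), ylim = c(sc$height, 0))
  lwd_of <- function(w) max(w, 0.1) * 96 / 72
  for (p in ordered_prims(sc)) {
    switch(p$kind,
      rectangle = graphics::rect(
        p$x, p$y + p$h, p$x + p$w, p$y,
        col = if (is.na(p$fill)) NA else p$fill,
        border = if (is.na(p$stroke)) NA else p$stroke,
        lwd = lwd_of(p$stroke_width)),
      segment = graphics::segments(
        p$x1, p$y1, p$x2, p$y2, col = p$stroke,
        lwd = lwd_of(p$stroke_width)),
      polygon = graphics::polygon(
        p$xs, p$ys, col = if (is.na(p$fill)) NA else p$fill,
        border = if (is.na(p$stroke)) NA else p$stroke,
        lwd = lwd_of(p$stroke_width)),
      path = {
        fp <- flatten_path(p$cmds)
        graphics::polygon(fp$x, fp$y,
                          col = if (is.na(p$fill)) NA else p$fill,
                          border = if (is.na(p$stroke)) NA else p$stroke,
                          lwd = lwd_of(p$stroke_width))
      },
      text = graphics::text(
        p$x, p$y, labels = p$text, col = p$fill,
        adj = switch(p$anchor, middle = c(0.5, 0), start = c(0, 0),
                     end = c(1, 0)),
        cex = p$size / 12))
  }
  invisible(file)
}
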