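# Backend-agnostic drawing instructions.  Layout engines produce a scene
# (device units = PostScript points, 1/72 inch, y growing downwards);
# renderers consume it.  Each primitive may carry a `meta` list with
# semantic annotations (block index, twist flag, ...) which renderers
# ignore but tests and downstream tooling can query.

new_prim <- function(kind, ..., fill = NA_character_, stroke = NA_character_,
                     stroke_width = 0, z = 0L, meta = NULL) {
  structure(list(kind = kind, ..., fill = fill, stroke = stroke,
                 stroke_width = stroke_width, z = as.integer(z), meta = meta),
            class = "scene_primitive")
}

prim_rect <- function(x, y, w, h, fill = NA, stroke = NA, stroke_width = 0,
                      z = 0L, meta = NULL) {
  new_prim("rectangle", x = x, y = y, w = w, h = h, fill = fill,
           stroke = stroke, stroke_width = stroke_width, z = z, meta = meta)
}

prim_segment <- function(x1, y1, x2, y2, stroke, stroke_width = 1, z = 0L,
                         meta = NULL) {
  new_prim("segment", x1 = x1, y1 = y1, x2 = x2, y2 = y2, stroke = stroke,
           stroke_width = stroke_width, z = z, meta = meta)
}

prim_polygon <- function(xs, ys, fill = NA, stroke = NA, stroke_width = 0,
                         z = 0L, meta = NULL) {
  new_prim("polygon", xs = xs, ys = ys, fill = fill, stroke = stroke,
           stroke_width = stroke_width, z = z, meta = meta)
}

# `cmds` is a list of path commands: list("M", x, y), list("L", x, y),
# list("C", x1, y1, x2, y2, x, y), list("Z").
prim_path <- function(cmds, fill = NA, stroke = NA, stroke_width = 0, z = 0L,
                      meta = NULL) {
  new_prim("path", cmds = cmds, fill = fill, stroke = stroke,
           stroke_width = stroke_width, z = z, meta = meta)
}

prim_text <- function(x, y, text, size = 8, anchor = c("middle", "start",
                      "end"), fill = "#000000", z = 0L, meta = NULL) {
  anchor <- match.arg(anchor)
  new_prim("text", x = x, y = y, text = as.character(text), size = size,
           anchor = anchor, fill = fill, z = z, meta = meta)
}

#' Construct a scene
#'
#' A scene is a page-sized list of drawing primitives (rectangles,
#' polygons, cubic paths, segments, text) in device units (points, y down)
#' produced by the layout engines and consumed by [render_svg()] and
#' [render_png()].
#'
#' @param width,height page size in points.
#' @param primitives list of primitives (internal constructors).
#' @param title figure title recorded in the scene metadata.
#' @return An object of class `scene`.
#' @export
scene <- function(width, height, primitives = list(), title = "") {
  structure(list(width = width, height = height, primitives = primitives,
                 metadata = list(title = title,
                                 generator = paste0("synvis ",
                                   as.character(utils::packageVersion("synvis"))))),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  kinds <- vapply(x$primitives, `[[`, character(1), "kind")
  cat(sprintf("Scene %g x %g pt, %d primitives (%s)\n", x$width, x$height,
              length(kinds),
              paste(sprintf("%s: %d", names(table(kinds)), table(kinds)),
                    collapse = ", ")))
  invisible(x)
}

# All device coordinates of one primitive, flattened (for validation and
# bounding boxes).
prim_coords <- function(p) {
  switch(p$kind,
    rectangle = list(x = c(p$x, p$x + p$w), y = c(p$y, p$y + p$h)),
    segment   = list(x = c(p$x1, p$x2), y = c(p$y1, p$y2)),
    polygon   = list(x = p$xs, y = p$ys),
    text      = list(x = p$x, y = p$y),
    path      = {
      xs <- c(); ys <- c()
      for (cmd in p$cmds) {
        if (cmd[[1]] == "Z") next
        v <- as.numeric(cmd[-1])
        xs <- c(xs, v[seq(1, length(v), 2)])
        ys <- c(ys, v[seq(2, length(v), 2)])
      }
      list(x = xs, y = ys)
    })
}

# Scene invariants: finite coordinates, bounding boxes within the page.
check_scene <- function(sc, tol = 1e-6) {
  stopifnot(inherits(sc, "scene"))
  for (i in seq_along(sc$primitives)) {
    co <- prim_coords(sc$primitives[[i]])
    if (any(!is.finite(c(co$x, co$y)))) {
      sv_data_error(sprintf("primitive %d has non-finite coordinates", i),
                    primitive = i)
    }
    if (sc$primitives[[i]]$kind != "text" &&
        (any(co$x < -tol) || any(co$x > sc$width + tol) ||
         any(co$y < -tol) || any(co$y > sc$height + tol))) {
      sv_data_error(sprintf(
        "primitive %d extends outside the %g x %g page", i,
        sc$width, sc$height), primitive = i)
    }
  }
  invisible(sc)
}

# Stable z-order: sort by z, ties in input order.
ordered_prims <- function(sc) {
  z <- vapply(sc$primitives, `[[`, integer(1), "z")
  sc$primitives[order(z)]
}

#' Query scene primitives by semantic tag
#'
#' Layout engines annotate primitives with `meta` fields (e.g. `role`,
#' `block`, `twisted`).  This helper returns the primitives whose `meta`
#' matches all supplied name/value pairs -- the hook the test-suite and
#' downstream tooling use to inspect layout semantics without parsing SVG.
#'
#' @param sc a [scene()].
#' @param ... name = value filters applied to each primitive's `meta`.
#' @return List of matching primitives.
#' @export
scene_query <- function(sc, ...) {
  filt <- list(...)
  Filter(function(p) {
    if (is.null(p$meta)) return(length(filt) == 0L)
    for (nm in names(filt)) {
      if (is.null(p$meta[[nm]]) || !identical(p$meta[[nm]], filt[[nm]]))
        return(FALSE)
    }
    TRUE
  }, sc$primitives)
}
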