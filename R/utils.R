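# Internal helpers: classed conditions, scoped RNG, colour arithmetic.

#' @keywords internal
#' @noRd
sv_abort <- function(class, msg, ..., call. = FALSE) {
  stop(structure(
    class = c(class, "synvis_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL, ...)
  ))
}

sv_parse_error  <- function(msg, line = NA_integer_, field = NA_character_) {
  sv_abort("synvis_parse_error", msg, line = line, field = field)
}
sv_data_error   <- function(msg, ...) sv_abort("synvis_data_error", msg, ...)
sv_config_error <- function(msg, ...) sv_abort("synvis_config_error", msg, ...)
sv_usage_error  <- function(msg, ...) sv_abort("synvis_usage_error", msg, ...)

# Run `expr` under a deterministic RNG stream seeded with `seed`, restoring
# any pre-existing global RNG state afterwards.  No global state leaks out.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    sv_usage_error("`seed` must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Fixed-precision coordinate formatter shared by the SVG writer so that
# identical scenes serialise to identical bytes.  Three decimals of a
# PostScript point is far below visual resolution.
fmt_num <- function(x) {
  x <- round(x, 3)
  x[x == 0] <- 0  # normalise -0
  sprintf("%.3f", x)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# Mix a hex colour towards white by `amount` in [0,1]; used for palette
# cycling when reference chromosomes outnumber the base palette.
lighten_hex <- function(hex, amount) {
  rgb <- grDevices::col2rgb(hex)
  rgb <- rgb + sweep(255 - rgb, 2, amount, "*")
  grDevices::rgb(rgb[1, ], rgb[2, ], rgb[3, ], maxColorValue = 255)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
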