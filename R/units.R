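#' Unit conversion helpers
#'
#' The package works in SI units internally (m, s, Pa s, N/m, m^3/s).
#' User-facing constructors accept the bench units common in droplet
#' microfluidics (uL/min, mPa s, mN/m, um) and convert on ingestion; these
#' helpers expose the conversions for scripting.
#'
#' @param x Numeric vector to convert.
#' @return Numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
ul_min_to_m3s <- function(x) x * 1e-9 / 60

#' @rdname units
#' @export
m3s_to_ul_min <- function(x) x * 60 / 1e-9

#' @rdname units
#' @export
m3_to_pl <- function(x) x * 1e15

#' @rdname units
#' @export
pl_to_m3 <- function(x) x * 1e-15

#' @rdname units
#' @export
um_to_m <- function(x) x * 1e-6

stopifnot_positive <- function(..., .allow_zero = FALSE) {
  vals <- list(...)
  nms <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    ok <- is.numeric(v) && all(is.finite(v)) &&
      if (.allow_zero) all(v >= 0) else all(v > 0)
    if (!ok) {
      stop(sprintf(
        "'%s' must be %s finite numeric",
        nms[i], if (.allow_zero) "a non-negative" else "a strictly positive"
      ), call. = FALSE)
    }
  }
  invisible(TRUE)
}
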