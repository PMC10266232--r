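`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

vnorm <- function(v) sqrt(sum(v^2))

#' Round half away from zero
#'
#' Decimal rounding where ties go up (0.05 -> 0.1), the convention used when
#' formatting percentages for display. Base \code{round()} rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

as_planar <- function(p, name = "point") {
  p <- as.numeric(p)
  if (length(p) != 2L || any(!is.finite(p)))
    stop(sprintf("'%s' must be a finite length-2 (u, z) point", name), call. = FALSE)
  p
}

as_world <- function(p, name = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || any(!is.finite(p)))
    stop(sprintf("'%s' must be a finite length-3 (x, y, z) point", name), call. = FALSE)
  p
}
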