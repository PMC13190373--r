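# Internal numerical helpers shared across modules.

#' Wrap an angle to (-pi, pi]
#'
#' Bearings are stored wrapped; wrapping is applied after every update so that
#' circular quantities never drift out of range.
#'
#' @param theta numeric vector of angles in radians.
#' @return numeric vector in (-pi, pi].
#' @export
wrap_angle <- function(theta) {
  theta - 2 * pi * ceiling((theta - pi) / (2 * pi))
}

# Trapezoid rule on a (possibly non-uniform) grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Central finite differences of a scalar field, step scaled by |x|.
fd_gradient <- function(f, x, h = 1e-5) {
  step <- h * (1 + abs(x))
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- step[i]
    (f(x + e) - f(x - e)) / (2 * step[i])
  }, numeric(1))
}

# log of modified Bessel I_0, stable for large arguments.
log_bessel_i0 <- function(z) {
  log(besselI(z, 0, expon.scaled = TRUE)) + z
}

# log of I_{1/2}(z) = sqrt(2/(pi z)) sinh(z), stable for large z.
log_bessel_i05 <- function(z) {
  0.5 * (log(2) - log(pi) - log(z)) + z + log1p(-exp(-2 * z)) - log(2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}
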