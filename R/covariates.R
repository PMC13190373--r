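#' Spatial covariates
#'
#' A covariate is a scalar field \eqn{c_k(x)} over locations in \eqn{R^d},
#' together with its gradient. The utilisation distribution is built from a
#' linear combination of such fields (see [target_linexp()]). Covariates here
#' are analytic functions rather than rasters: the package models selection on
#' smooth (or piecewise-smooth) resource surfaces, with the gradient available
#' everywhere it is needed by the movement dynamics.
#'
#' @param value function mapping a length-`d` numeric location to a scalar.
#' @param gradient function mapping a location to its length-`d` gradient, or
#'   `NULL` to fall back on central finite differences with step
#'   `1e-5 * (1 + |x|)`.
#' @param name label used in printing and configs.
#' @param grad_norm_bound optional function `(p0, p1)` returning an upper
#'   bound on the Euclidean norm of the gradient along the segment from `p0`
#'   to `p1`; used by the event-thinning engine. Built-in covariates supply
#'   exact bounds.
#' @param config optional list describing the covariate family and parameters
#'   for serialisation.
#' @return an object of class `mvt_covariate`.
#' @seealso [cov_laplace()], [cov_minlaplace()], [cov_gaussian()],
#'   [cov_quadratic()]
#' @export
covariate <- function(value, gradient = NULL, name = "covariate",
                      grad_norm_bound = NULL, config = NULL) {
  stopifnot(is.function(value))
  grad <- gradient %||% function(x) fd_gradient(value, x)
  structure(
    list(value = value, gradient = grad, name = name,
         grad_norm_bound = grad_norm_bound, config = config),
    class = "mvt_covariate")
}

#' @export
print.mvt_covariate <- function(x, ...) {
  cat("<covariate:", x$name, ">\n")
  invisible(x)
}

#' Laplace-shaped covariate
#'
#' \deqn{c(x) = \tau \exp(-|x - \mu| / (2\tau))}
#' a unimodal resource peak of height \eqn{\tau} at \eqn{\mu}, with
#' exponential decay on the scale \eqn{2\tau}. Used with a selection
#' coefficient \eqn{\beta} it yields a Laplace-like marginal utilisation
#' distribution. The gradient has a kink at \eqn{x = \mu}, where it is defined
#' as 0 (the kink is a measure-zero set never hit by the simulations).
#'
#' @param mu numeric location of the peak (any dimension).
#' @param tau positive scale; also the peak height.
#' @return an `mvt_covariate`.
#' @export
cov_laplace <- function(mu, tau) {
  stopifnot_scalar(tau, "tau", positive = TRUE)
  mu <- as.numeric(mu)
  covariate(
    value = function(x) tau * exp(-sqrt(sum((x - mu)^2)) / (2 * tau)),
    gradient = function(x) {
      r <- sqrt(sum((x - mu)^2))
      if (r == 0) return(numeric(length(x)))
      val <- tau * exp(-r / (2 * tau))
      -(x - mu) / r * val / (2 * tau)
    },
    name = sprintf("laplace(mu=%s, tau=%g)", paste(mu, collapse = ","), tau),
    # |grad c| = c / (2 tau) <= tau/(2 tau) = 1/2 everywhere
    grad_norm_bound = function(p0, p1) 0.5,
    config = list(family = "laplace", mu = mu, tau = tau))
}

#' Bimodal min-Laplace covariate
#'
#' \deqn{c(x) = \exp(-\min(|x-\mu_A|, |x-\mu_B|) / (2\tau))}
#' equal peaks of height 1 at the two centres; the gradient points towards
#' the nearer centre and is defined as 0 on the equidistant midline and at
#' the centres themselves.
#'
#' @param muA,muB centre locations.
#' @param tau positive scale.
#' @return an `mvt_covariate`.
#' @export
cov_minlaplace <- function(muA, muB, tau) {
  stopifnot_scalar(tau, "tau", positive = TRUE)
  muA <- as.numeric(muA); muB <- as.numeric(muB)
  covariate(
    value = function(x) {
      r <- min(sqrt(sum((x - muA)^2)), sqrt(sum((x - muB)^2)))
      exp(-r / (2 * tau))
    },
    gradient = function(x) {
      rA <- sqrt(sum((x - muA)^2)); rB <- sqrt(sum((x - muB)^2))
      if (rA == rB) return(numeric(length(x)))
      mu <- if (rA < rB) muA else muB
      r <- min(rA, rB)
      if (r == 0) return(numeric(length(x)))
      -(x - mu) / r * exp(-r / (2 * tau)) / (2 * tau)
    },
    name = sprintf("minlaplace(muA=%s, muB=%s, tau=%g)",
                   paste(muA, collapse = ","), paste(muB, collapse = ","), tau),
    # c <= 1 so |grad c| <= 1/(2 tau)
    grad_norm_bound = function(p0, p1) 1 / (2 * tau),
    config = list(family = "minlaplace", muA = muA, muB = muB, tau = tau))
}

#' Gaussian-shaped covariate
#'
#' \deqn{c(x) = \exp(-|x - \mu|^2 / (2 r^2))}
#'
#' @param mu centre location.
#' @param range positive length scale `r`.
#' @return an `mvt_covariate`.
#' @export
cov_gaussian <- function(mu, range) {
  stopifnot_scalar(range, "range", positive = TRUE)
  mu <- as.numeric(mu)
  covariate(
    value = function(x) exp(-sum((x - mu)^2) / (2 * range^2)),
    gradient = function(x) -(x - mu) / range^2 * exp(-sum((x - mu)^2) / (2 * range^2)),
    name = sprintf("gaussian(mu=%s, range=%g)", paste(mu, collapse = ","), range),
    # |grad c| maximised at |x-mu| = range: exp(-1/2)/range
    grad_norm_bound = function(p0, p1) exp(-0.5) / range,
    config = list(family = "gaussian", mu = mu, range = range))
}

#' Centred quadratic covariate
#'
#' \deqn{c(x) = -|x - \mu|^2 / 2}; with selection coefficient \eqn{\beta} the
#' resulting utilisation distribution is isotropic normal with variance
#' \eqn{1/\beta}. Convenient for exact checks and for parameter-recovery
#' experiments.
#'
#' @param mu centre location.
#' @return an `mvt_covariate`.
#' @export
cov_quadratic <- function(mu) {
  mu <- as.numeric(mu)
  covariate(
    value = function(x) -sum((x - mu)^2) / 2,
    gradient = function(x) -(x - mu),
    name = sprintf("quadratic(mu=%s)", paste(mu, collapse = ",")),
    # |grad c| = |x - mu|, linear along a segment so maximal at an endpoint
    grad_norm_bound = function(p0, p1) {
      max(sqrt(sum((p0 - mu)^2)), sqrt(sum((p1 - mu)^2)))
    },
    config = list(family = "quadratic", mu = mu))
}

cov_from_config <- function(cfg) {
  switch(cfg$family,
    laplace    = cov_laplace(cfg$mu, cfg$tau),
    minlaplace = cov_minlaplace(cfg$muA, cfg$muB, cfg$tau),
    gaussian   = cov_gaussian(cfg$mu, cfg$range),
    quadratic  = cov_quadratic(cfg$mu),
    stop("unknown covariate family: ", cfg$family, call. = FALSE))
}
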