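#' Utilisation-distribution targets
#'
#' A target represents an animal's utilisation distribution \eqn{\pi(x)} up to
#' an additive constant on the log scale; all movement models in the package
#' use only log-density differences and gradients, so the constant is fixed at
#' zero by convention. Three families are provided:
#'
#' * `target_linexp()`: the log-linear (linear-exponential) habitat-selection
#'   form \eqn{L(x) = \sum_k \beta_k c_k(x)}, so \eqn{\pi(x) \propto e^{L(x)}}.
#' * `target_product()`: a product of univariate margins, one per axis.
#' * `target_multistate()`: a joint location-state distribution
#'   \eqn{\pi(x, s) \propto \exp(\beta_{s0} + \sum_k \beta_{sk} c_k(x))}.
#'
#' @param covariates list of [covariate()] objects (length K).
#' @param beta numeric selection coefficients, length K (`target_linexp`) or an
#'   S-by-K matrix (`target_multistate`).
#' @param dim spatial dimension d of locations.
#' @param intercept additive constant in L(x); irrelevant for single-state
#'   dynamics but kept so state-conditional targets retain their intercepts.
#' @return an object of class `mvt_target`.
#' @export
target_linexp <- function(covariates, beta, dim, intercept = 0) {
  if (inherits(covariates, "mvt_covariate")) covariates <- list(covariates)
  stopifnot(length(covariates) == length(beta),
            all(vapply(covariates, inherits, logical(1), "mvt_covariate")))
  structure(
    list(covariates = covariates, beta = as.numeric(beta), dim = dim,
         intercept = intercept),
    class = c("linexp_target", "mvt_target"))
}

#' @rdname target_linexp
#' @param margins list of margin objects ([margin_normal()] etc.), one per
#'   axis.
#' @export
target_product <- function(margins) {
  if (inherits(margins, "mvt_margin")) margins <- list(margins)
  stopifnot(all(vapply(margins, inherits, logical(1), "mvt_margin")))
  structure(
    list(margins = margins, dim = length(margins)),
    class = c("product_target", "mvt_target"))
}

#' @rdname target_linexp
#' @param beta0 length-S state intercepts \eqn{\beta_{s0}}.
#' @export
target_multistate <- function(beta0, beta, covariates, dim) {
  beta <- rbind(beta)
  if (inherits(covariates, "mvt_covariate")) covariates <- list(covariates)
  stopifnot(length(beta0) >= 2, nrow(beta) == length(beta0),
            ncol(beta) == length(covariates))
  structure(
    list(beta0 = as.numeric(beta0), beta = beta, covariates = covariates,
         dim = dim, n_states = length(beta0)),
    class = c("multistate_target", "mvt_target"))
}

#' @export
print.mvt_target <- function(x, ...) {
  cat("<", class(x)[1], "> d =", x$dim, "\n")
  if (!is.null(x$covariates))
    for (cv in x$covariates) cat("  ", cv$name, "\n")
  if (!is.null(x$margins))
    for (m in x$margins) cat("  ", m$name, "\n")
  invisible(x)
}

check_dim <- function(target, x) {
  if (length(x) != target$dim)
    stop(sprintf("location has length %d but target dimension is %d",
                 length(x), target$dim), call. = FALSE)
  invisible(x)
}

#' Log-density and gradient of a target
#'
#' `log_density()` returns \eqn{L(x) = \log \pi(x)} up to the package's
#' zero-constant convention; `grad_log_density()` returns
#' \eqn{\nabla L(x) = -\nabla U(x)} where \eqn{U = -\log\pi} is the potential.
#' Gradients are analytic whenever the covariates supply them.
#'
#' @param target an `mvt_target`.
#' @param x numeric location of length `target$dim`.
#' @return a scalar (`log_density`) or a length-d vector
#'   (`grad_log_density`).
#' @export
log_density <- function(target, x) UseMethod("log_density")

#' @export
log_density.linexp_target <- function(target, x) {
  check_dim(target, x)
  target$intercept +
    sum(target$beta * vapply(target$covariates, function(cv) cv$value(x),
                             numeric(1)))
}

#' @export
log_density.product_target <- function(target, x) {
  check_dim(target, x)
  sum(vapply(seq_along(x), function(i) target$margins[[i]]$logpdf(x[i]),
             numeric(1)))
}

#' @rdname log_density
#' @export
grad_log_density <- function(target, x) UseMethod("grad_log_density")

#' @export
grad_log_density.linexp_target <- function(target, x) {
  check_dim(target, x)
  g <- numeric(target$dim)
  for (k in seq_along(target$beta))
    g <- g + target$beta[k] * target$covariates[[k]]$gradient(x)
  g
}

#' @export
grad_log_density.product_target <- function(target, x) {
  check_dim(target, x)
  vapply(seq_along(x), function(i) target$margins[[i]]$dlogpdf(x[i]),
         numeric(1))
}

#' @export
grad_log_density.default <- function(target, x) {
  fd_gradient(function(z) log_density(target, z), x)
}

# --- multi-state -----------------------------------------------------------

# Per-state linear predictors beta_{s0} + sum_k beta_{sk} c_k(x).
state_linpred <- function(target, x) {
  cv <- vapply(target$covariates, function(c) c$value(x), numeric(1))
  target$beta0 + drop(target$beta %*% cv)
}

#' State posterior of a multi-state target
#'
#' The conditional distribution \eqn{\pi(s | x)} of the behavioural state
#' given location: the softmax of the per-state linear predictors (computed
#' with a log-sum-exp shift so it is stable for large predictors).
#'
#' @param target an object from [target_multistate()].
#' @param x location.
#' @return length-S probability vector.
#' @export
state_posterior <- function(target, x) {
  check_dim(target, x)
  lp <- state_linpred(target, x)
  w <- exp(lp - max(lp))
  w / sum(w)
}

#' Conditional target for one behavioural state
#'
#' Extracts \eqn{\pi(x | s)} as a linear-exponential target with that state's
#' coefficient row (and intercept); within-state movement dynamics are built
#' on this conditional.
#'
#' @inheritParams state_posterior
#' @param s state index in 1..S.
#' @return a `linexp_target`.
#' @export
conditional_target <- function(target, s) {
  stopifnot(inherits(target, "multistate_target"), s >= 1,
            s <= target$n_states)
  target_linexp(target$covariates, target$beta[s, ], target$dim,
                intercept = target$beta0[s])
}

#' @export
log_density.multistate_target <- function(target, x) {
  # joint log pi(x, s) requires a state; direct calls use the state-marginal
  # log sum over states (up to the usual constant)
  check_dim(target, x)
  lp <- state_linpred(target, x)
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

#' @export
grad_log_density.multistate_target <- function(target, x) {
  check_dim(target, x)
  post <- state_posterior(target, x)
  g <- numeric(target$dim)
  for (k in seq_along(target$covariates))
    g <- g + sum(post * target$beta[, k]) * target$covariates[[k]]$gradient(x)
  g
}

# --- support hints and marginal quadrature --------------------------------

# A per-axis interval expected to contain essentially all target mass;
# used to set quadrature grids for diagnostics and interaction integrals.
target_support <- function(target) UseMethod("target_support")

#' @export
target_support.product_target <- function(target) {
  vapply(target$margins, function(m) m$support, numeric(2))
}

#' @export
target_support.linexp_target <- function(target) {
  centres <- unlist(lapply(target$covariates, function(cv) {
    cfg <- cv$config
    c(cfg$mu, cfg$muA, cfg$muB)
  }))
  if (is.null(centres)) centres <- 0
  centres <- matrix(centres, nrow = target$dim)
  scales <- vapply(target$covariates, function(cv) {
    cfg <- cv$config
    max(cfg$tau %||% 1, cfg$range %||% 1, 1)
  }, numeric(1))
  pad <- 3 * max(scales) + 10
  rbind(apply(centres, 1, min) - pad, apply(centres, 1, max) + pad)
}

#' @export
target_support.multistate_target <- function(target) {
  target_support.linexp_target(target)
}

# Quadrature-normalised marginal density and CDF along one axis of a target.
# For product targets the margin is analytic; otherwise (1-D only) the
# log-density is normalised by the trapezoid rule on `n` grid points.
marginal_cdf <- function(target, axis = 1, n = 4001, support = NULL) {
  if (inherits(target, "product_target")) {
    return(target$margins[[axis]]$cdf)
  }
  if (target$dim != 1L)
    stop("quadrature marginals only available for 1-D non-product targets",
         call. = FALSE)
  support <- support %||% target_support(target)[, 1]
  grid <- seq(support[1], support[2], length.out = n)
  logd <- vapply(grid, function(g) log_density(target, g), numeric(1))
  d <- exp(logd - max(logd))
  h <- diff(grid)
  cum <- c(0, cumsum(h * (d[-1] + d[-n]) / 2))
  cum <- cum / cum[n]
  function(q) stats::approx(grid, cum, xout = q, yleft = 0, yright = 1,
                            rule = 2)$y
}

# --- thinning bound --------------------------------------------------------

# Upper bound on ||grad U|| along the straight segment from p0 to p1.
# Built-in targets give analytic bounds; the fallback samples the segment
# and doubles the maximum (any underestimate is caught as a hard error by
# the thinning engine).
grad_norm_bound <- function(target, p0, p1) UseMethod("grad_norm_bound")

#' @export
grad_norm_bound.product_target <- function(target, p0, p1) {
  b <- vapply(seq_len(target$dim), function(i) {
    lo <- min(p0[i], p1[i]); hi <- max(p0[i], p1[i])
    target$margins[[i]]$score_bound(lo, hi)
  }, numeric(1))
  sqrt(sum(b^2))
}

#' @export
grad_norm_bound.linexp_target <- function(target, p0, p1) {
  bounds <- lapply(target$covariates, function(cv) cv$grad_norm_bound)
  if (all(!vapply(bounds, is.null, logical(1)))) {
    return(sum(abs(target$beta) *
                 vapply(seq_along(bounds), function(k) bounds[[k]](p0, p1),
                        numeric(1))))
  }
  grad_norm_bound.default(target, p0, p1)
}

#' @export
grad_norm_bound.default <- function(target, p0, p1) {
  ts <- seq(0, 1, length.out = 65)
  g <- vapply(ts, function(t) {
    sqrt(sum(grad_log_density(target, p0 + t * (p1 - p0))^2))
  }, numeric(1))
  2 * max(g)
}

# --- config interface ------------------------------------------------------

#' Build a target from a configuration block
#'
#' Targets round-trip through plain lists (and hence JSON): the block names
#' the family (`"linexp"`, `"product"`, `"multistate"`) and the analytic
#' covariate or margin specs.
#'
#' @param config a list, or a JSON string/path understood by
#'   [jsonlite::fromJSON()].
#' @return an `mvt_target`.
#' @examples
#' tg <- target_from_config(list(
#'   type = "linexp", dim = 1,
#'   covariates = list(list(family = "laplace", mu = -10, tau = 10)),
#'   beta = 2))
#' log_density(tg, -10)  # 2 * tau = 20
#' @export
target_from_config <- function(config) {
  if (is.character(config))
    config <- jsonlite::fromJSON(config, simplifyDataFrame = FALSE)
  switch(config$type,
    linexp = target_linexp(
      lapply(config$covariates, cov_from_config),
      unlist(config$beta), config$dim,
      intercept = config$intercept %||% 0),
    product = target_product(lapply(config$margins, margin_from_config)),
    multistate = {
      bm <- config$beta
      if (!is.matrix(bm)) bm <- do.call(rbind, lapply(bm, unlist))
      target_multistate(unlist(config$beta0), bm,
                        lapply(config$covariates, cov_from_config),
                        config$dim)
    },
    stop("unknown target type: ", config$type, call. = FALSE))
}

target_config <- function(target) UseMethod("target_config")

#' @export
target_config.linexp_target <- function(target) {
  list(type = "linexp", dim = target$dim,
       covariates = lapply(target$covariates, function(cv) cv$config),
       beta = target$beta, intercept = target$intercept)
}

#' @export
target_config.product_target <- function(target) {
  list(type = "product",
       margins = lapply(target$margins, function(m) m$config))
}

#' @export
target_config.multistate_target <- function(target) {
  list(type = "multistate", dim = target$dim, beta0 = target$beta0,
       beta = lapply(seq_len(target$n_states), function(s) target$beta[s, ]),
       covariates = lapply(target$covariates, function(cv) cv$config))
}
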