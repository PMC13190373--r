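# Univariate margins for product-form targets. Each margin carries its
# log-density (up to an additive constant), score, CDF, and a bound on the
# score used by the event-thinning engine.

new_margin <- function(logpdf, dlogpdf, cdf, score_bound, name, config,
                       support) {
  structure(
    list(logpdf = logpdf, dlogpdf = dlogpdf, cdf = cdf,
         score_bound = score_bound, name = name, config = config,
         support = support),
    class = "mvt_margin")
}

#' Univariate margins for product-form targets
#'
#' Margins define per-axis log-densities for [target_product()]. Available
#' families: normal, logistic, and a finite mixture of logistics (the
#' bimodal x-margin used throughout the velocity-jump examples).
#'
#' @param mean,sd normal parameters.
#' @return an `mvt_margin`.
#' @export
margin_normal <- function(mean = 0, sd = 1) {
  stopifnot_scalar(sd, "sd", positive = TRUE)
  new_margin(
    logpdf = function(x) -(x - mean)^2 / (2 * sd^2),
    dlogpdf = function(x) -(x - mean) / sd^2,
    cdf = function(q) stats::pnorm(q, mean, sd),
    # score is linear, so its max over an interval is at an endpoint;
    # the factor 1.5 is a safety margin kept for uniformity with the engine
    score_bound = function(lo, hi) 1.5 * max(abs(lo - mean), abs(hi - mean)) / sd^2,
    name = sprintf("normal(%g, %g)", mean, sd),
    config = list(family = "normal", mean = mean, sd = sd),
    support = c(mean - 10 * sd, mean + 10 * sd))
}

#' @rdname margin_normal
#' @param location,scale logistic parameters.
#' @export
margin_logistic <- function(location = 0, scale = 1) {
  stopifnot_scalar(scale, "scale", positive = TRUE)
  new_margin(
    logpdf = function(x) stats::dlogis(x, location, scale, log = TRUE),
    dlogpdf = function(x) (1 - 2 * stats::plogis((x - location) / scale)) / scale,
    cdf = function(q) stats::plogis(q, location, scale),
    score_bound = function(lo, hi) 1 / scale,
    name = sprintf("logistic(%g, %g)", location, scale),
    config = list(family = "logistic", location = location, scale = scale),
    support = c(location - 25 * scale, location + 25 * scale))
}

#' @rdname margin_normal
#' @param locations,scales,weights mixture components; `weights` need not be
#'   normalised.
#' @export
margin_logistic_mixture <- function(locations, scales, weights) {
  stopifnot(length(locations) == length(scales),
            length(locations) == length(weights), all(scales > 0),
            all(weights > 0))
  w <- weights / sum(weights)
  mix_sum <- function(x, f) {
    out <- 0
    for (j in seq_along(w)) out <- out + w[j] * f(x, locations[j], scales[j])
    out
  }
  dens <- function(x) mix_sum(x, stats::dlogis)
  new_margin(
    logpdf = function(x) log(dens(x)),
    dlogpdf = function(x) {
      # mixture score: posterior-weighted average of component scores
      num <- 0
      for (j in seq_along(w)) {
        dj <- w[j] * stats::dlogis(x, locations[j], scales[j])
        sj <- (1 - 2 * stats::plogis((x - locations[j]) / scales[j])) /
          scales[j]
        num <- num + dj * sj
      }
      num / dens(x)
    },
    cdf = function(q) mix_sum(q, stats::plogis),
    # |score| <= max_j 1/scale_j (convex combination of component scores)
    score_bound = function(lo, hi) 1 / min(scales),
    name = sprintf("logistic_mixture(%s)", paste(locations, collapse = ",")),
    config = list(family = "logistic_mixture", locations = locations,
                  scales = scales, weights = w),
    support = c(min(locations) - 25 * max(scales),
                max(locations) + 25 * max(scales)))
}

margin_from_config <- function(cfg) {
  switch(cfg$family,
    normal = margin_normal(cfg$mean, cfg$sd),
    logistic = margin_logistic(cfg$location, cfg$scale),
    logistic_mixture = margin_logistic_mixture(cfg$locations, cfg$scales,
                                               cfg$weights),
    stop("unknown margin family: ", cfg$family, call. = FALSE))
}
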