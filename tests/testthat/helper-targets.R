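# Shared fixture builders; everything is generated in code.

std_normal_1d <- function() target_product(margin_normal())

flat_target <- function(dim = 2) target_linexp(list(), numeric(0), dim)

# anisotropic bivariate normal used by the polar-model examples
bivn_aniso <- function() {
  target_product(list(margin_normal(0, sqrt(2)), margin_normal(0, 1)))
}

# bimodal logistic-mixture x margin, logistic y margin
bimodal_2d <- function() {
  target_product(list(
    margin_logistic_mixture(c(1, -1), c(1, 1), c(0.6, 0.4)),
    margin_logistic(0, 1)))
}

bimodal_x_cdf <- function(q) {
  0.6 * stats::plogis(q, 1, 1) + 0.4 * stats::plogis(q, -1, 1)
}

# two-state Laplace-covariate switching target (selection peaks at -10/+10)
two_state_target <- function() {
  target_multistate(
    beta0 = c(log(5 / 3), 0),
    beta = rbind(c(2, 0), c(0, 2)),
    covariates = list(cov_laplace(-10, 10), cov_laplace(10, 10)),
    dim = 1)
}

# bimodal min-Laplace single-covariate target for the interaction examples
bimodal_minlaplace <- function() {
  target_linexp(cov_minlaplace(-10, 10, 10), 2, 1)
}

# standard isotropic normal in d dimensions via a quadratic covariate
gaussian_linexp <- function(d, beta = 1) {
  target_linexp(cov_quadratic(rep(0, d)), beta, d)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
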