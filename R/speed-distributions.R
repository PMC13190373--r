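# Speed and bearing laws used by the velocity-jump event updates. Bessel
# factors are evaluated in log space throughout so large arguments do not
# overflow; samplers use constructive norm-of-Gaussian representations, which
# are exact.

#' Rice distribution
#'
#' Density and sampler for the Rice (Rician) distribution with noncentrality
#' \eqn{\nu \ge 0} and scale \eqn{b > 0}:
#' \deqn{f(s) = \frac{s}{b^2}\exp\!\Big(-\frac{s^2+\nu^2}{2b^2}\Big)
#'   I_0\!\Big(\frac{s\nu}{b^2}\Big), \quad s \ge 0.}
#' It is the length of a 2-D Gaussian vector with mean of norm \eqn{\nu} and
#' isotropic standard deviation \eqn{b}; `rice_sample()` draws it exactly via
#' that representation. \eqn{\nu = 0} reduces to Rayleigh(b); \eqn{b = 0}
#' degenerates to a point mass at \eqn{\nu}.
#'
#' @param s speed (vectorised), `s >= 0`.
#' @param nu noncentrality, `nu >= 0`.
#' @param b scale, `b >= 0` (strictly positive for the density).
#' @return `rice_density()`: densities; `rice_sample()`: `n` draws.
#' @export
rice_density <- function(s, nu, b) {
  stopifnot(nu >= 0, b > 0, all(s >= 0))
  z <- s * nu / b^2
  logI <- ifelse(z > 0, log_bessel_i0(z), 0)
  out <- exp(log(s) - 2 * log(b) - (s^2 + nu^2) / (2 * b^2) + logI)
  out[s == 0] <- 0
  out
}

#' @rdname rice_density
#' @param n number of draws.
#' @export
rice_sample <- function(n, nu, b) {
  stopifnot(nu >= 0, b >= 0)
  sqrt((nu + b * stats::rnorm(n))^2 + (b * stats::rnorm(n))^2)
}

#' Size-biased speed density (Maxwell-Boltzmann)
#'
#' The speed law seen at event times of a velocity-jump process is the
#' size-biased version \eqn{p^*(s) \propto s\,p(s)} of the stationary speed
#' law. For Rayleigh(\eqn{\sigma}) speeds this is the Maxwell-Boltzmann
#' density
#' \deqn{p^*(s) = \sqrt{2/\pi}\; s^2 \sigma^{-3} \exp(-s^2 / 2\sigma^2),}
#' equivalently a scaled \eqn{\chi_3} law.
#'
#' @param s speeds.
#' @param sigma velocity scale.
#' @export
sizebiased_speed_density <- function(s, sigma) {
  stopifnot_scalar(sigma, "sigma", positive = TRUE)
  sqrt(2 / pi) * s^2 / sigma^3 * exp(-s^2 / (2 * sigma^2))
}

# varsigma^2 of the correlated speed update. Derived from the correlated
# trivariate-normal construction with per-component variance sigma^2: it is
# the value for which the size-biased balance identity
# int s' q(s|s') p(s') ds' = s p(s) holds exactly (verified by quadrature
# in the test suite).
speed_update_varsigma2 <- function(sigma, rho) sigma^2 * (1 - rho^2)

#' Correlated speed update at reorientation events
#'
#' The conditional speed law \eqn{q(s'|s)} of a symmetric bivariate
#' construction whose both margins are the size-biased (Maxwell-Boltzmann)
#' speed density: a scaled noncentral \eqn{\chi_3} distribution,
#' \deqn{q(s'|s) = \frac{(s')^{3/2}}{\varsigma^2\sqrt{\rho s}}
#'   \exp\!\Big(-\frac{(s')^2 + (\rho s)^2}{2\varsigma^2}\Big)
#'   I_{1/2}\!\Big(\frac{s' s \rho}{\varsigma^2}\Big),}
#' with \eqn{\varsigma^2 = \sigma^2(1-\rho^2)}. It satisfies the balance
#' identity \eqn{\int s' q(s|s')p(s')\,ds' = s\,p(s)} with respect to the
#' Rayleigh(\eqn{\sigma}) speed law, which is exactly what a non-canonical
#' reorientation rate requires. Sampling is by the constructive
#' representation \eqn{s' = \|\rho s\,e + \varsigma\,\xi\|} with \eqn{\xi} a
#' standard 3-D normal vector. At \eqn{\rho = 0} the update is an independent
#' Maxwell-Boltzmann(\eqn{\sigma}) draw.
#'
#' @param s_new,s new and current speed, both positive.
#' @param sigma stationary velocity scale.
#' @param rho speed correlation, `0 <= rho < 1`.
#' @export
speed_update_density <- function(s_new, s, sigma, rho) {
  stopifnot(all(s > 0), rho >= 0, rho < 1)
  vs2 <- speed_update_varsigma2(sigma, rho)
  if (rho == 0) return(sizebiased_speed_density(s_new, sigma))
  n <- max(length(s_new), length(s))
  s_new <- rep_len(s_new, n)
  lam <- rho * rep_len(s, n)
  z <- s_new * lam / vs2
  out <- numeric(n)
  pos <- s_new > 0
  out[pos] <- exp(1.5 * log(s_new[pos]) - log(vs2) - 0.5 * log(lam[pos]) -
                    (s_new[pos]^2 + lam[pos]^2) / (2 * vs2) +
                    log_bessel_i05(z[pos]))
  out
}

#' @rdname speed_update_density
#' @export
speed_update_sample <- function(s, sigma, rho) {
  stopifnot(s > 0, rho >= 0, rho < 1)
  vs <- sqrt(speed_update_varsigma2(sigma, rho))
  mu <- c(rho * s, 0, 0)
  sqrt(sum((mu + vs * stats::rnorm(3))^2))
}

#' Autocorrelated speed refreshment
#'
#' Refreshment events resample speed from the conditional of a correlated
#' bivariate Rayleigh law with equal Rayleigh(\eqn{\sigma}) margins:
#' \eqn{s' | s \sim \mathrm{Rice}(s\eta, \sigma\sqrt{1-\eta^2})}. The update
#' is in detailed balance with Rayleigh(\eqn{\sigma}), so chained refreshes
#' preserve the stationary speed law; \eqn{\eta = 0} gives an independent
#' Rayleigh draw and \eqn{\eta \to 1} concentrates at the current speed.
#'
#' @param s current speed.
#' @param sigma stationary velocity scale.
#' @param eta speed autocorrelation, `0 <= eta < 1`.
#' @export
rice_refresh_speed <- function(s, sigma, eta) {
  stopifnot(eta >= 0, eta < 1)
  rice_sample(1, s * eta, sigma * sqrt(1 - eta^2))
}

#' von Mises bearing update
#'
#' Draws a new bearing from a von Mises distribution centred on the current
#' bearing with concentration `kappa`, wrapped to \eqn{(-\pi, \pi]};
#' `kappa = 0` is the uniform circular law. Any symmetric circular kernel
#' preserves the uniform bearing distribution, which is what refreshment
#' requires. Sampling uses the Best-Fisher wrapped-Cauchy envelope rejection
#' algorithm.
#'
#' @param theta current bearing (radians).
#' @param kappa concentration, `kappa >= 0`.
#' @export
vonmises_turn <- function(theta, kappa) {
  stopifnot(kappa >= 0)
  wrap_angle(theta + rvonmises_centred(1L, kappa))
}

# n draws from von Mises(0, kappa); Best & Fisher (1979) rejection sampler.
rvonmises_centred <- function(n, kappa) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    z <- cos(pi * stats::runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- sign(stats::runif(1) - 0.5) * acos(pmin(1, pmax(-1, f)))
    }
  }
  out
}
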