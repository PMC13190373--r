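#' Velocity-jump event primitives
#'
#' Building blocks of the piecewise deterministic (velocity-jump) movement
#' models: the canonical bounce rate, the deterministic and stochastic bounce
#' kernels, and the reorientation rate/kernel family. The process moves in
#' straight lines between events; the event machinery is what makes the
#' long-run location distribution equal the target.
#'
#' @name pdmp
NULL

#' Canonical bounce rate
#'
#' \eqn{\lambda(x, v) = \max\{0, \nabla U(x)\cdot v\}}: events occur only
#' while moving against the target gradient (towards lower utilisation
#' density), at a rate proportional to how fast the potential is increasing.
#' This is the minimal rate preserving the target for bounce-type samplers.
#'
#' @param target an `mvt_target`.
#' @param x location.
#' @param v velocity.
#' @export
canonical_rate <- function(target, x, v) {
  max(0, sum(-grad_log_density(target, x) * v))
}

#' Deterministic bounce (specular reflection)
#'
#' Reflects the component of `v` parallel to the gradient `g`, keeping the
#' orthogonal component: \eqn{v' = -v_1 + v_2}. Preserves speed exactly and
#' is an involution.
#'
#' @param v velocity.
#' @param g gradient of the potential at the event location (non-zero).
#' @export
bps_reflect <- function(v, g) {
  ng2 <- sum(g^2)
  if (ng2 == 0) stop("cannot bounce on a zero gradient", call. = FALSE)
  v - 2 * sum(v * g) / ng2 * g
}

#' Randomised bounce (generalised BPS)
#'
#' Negates the parallel component and replaces the orthogonal component with
#' a fresh draw \eqn{u \sim N(0, \sigma^2 I_{d-1})} in the hyperplane
#' orthogonal to `g`.
#'
#' @inheritParams bps_reflect
#' @param sigma orthogonal noise scale.
#' @export
gbps_bounce <- function(v, g, sigma) {
  d <- length(v)
  if (d < 2) stop("gbps bounce requires d >= 2", call. = FALSE)
  ng2 <- sum(g^2)
  if (ng2 == 0) stop("cannot bounce on a zero gradient", call. = FALSE)
  u_hat <- g / sqrt(ng2)
  v_par <- sum(v * u_hat) * u_hat
  if (d == 2L) {
    perp <- c(-u_hat[2], u_hat[1])
    return(-v_par + sigma * stats::rnorm(1) * perp)
  }
  basis <- qr.Q(qr(cbind(u_hat, diag(d))))[, 2:d, drop = FALSE]
  -v_par + drop(basis %*% (sigma * stats::rnorm(d - 1)))
}

#' Bounce configuration
#'
#' Parameters of the half-space bounce kernel and of the refreshment
#' process. `rho` correlates the gradient-parallel speed before and after a
#' bounce (the parallel component always changes sign); `omega` is the
#' autoregressive coefficient of the orthogonal velocity component;
#' `refresh_rate` is the constant rate \eqn{\lambda_0} of refreshment
#' events, at which speed is resampled with autocorrelation `refresh_eta`
#' and bearing turned by a von Mises kernel with concentration
#' `refresh_kappa`. Full support of the post-bounce velocity on the
#' half-space requires \eqn{0 \le \rho < 1} and \eqn{-1 < \omega < 1}; the
#' boundary values are accepted because they recover the classical samplers
#' (\eqn{\rho = 1, \omega = 1}: deterministic reflection;
#' \eqn{\rho = 1, \omega = 0}: the generalised BPS).
#'
#' @param sigma stationary velocity scale.
#' @param rho parallel-speed correlation in `[0, 1]`.
#' @param omega orthogonal-velocity correlation in `[-1, 1]`.
#' @param refresh_rate refreshment rate, `>= 0`.
#' @param refresh_eta speed autocorrelation at refreshment, in `[0, 1)`.
#' @param refresh_kappa von Mises concentration of the turn at refreshment.
#' @export
bounce_config <- function(sigma = 1, rho = 0, omega = 0, refresh_rate = 0,
                          refresh_eta = 0, refresh_kappa = 0) {
  stopifnot_scalar(sigma, "sigma", positive = TRUE)
  stopifnot(rho >= 0, rho <= 1, omega >= -1, omega <= 1,
            refresh_rate >= 0, refresh_eta >= 0, refresh_eta < 1,
            refresh_kappa >= 0)
  structure(list(sigma = sigma, rho = rho, omega = omega,
                 refresh_rate = refresh_rate, refresh_eta = refresh_eta,
                 refresh_kappa = refresh_kappa),
            class = "mvt_bounce_config")
}

#' Half-space bounce
#'
#' The bounce kernel with support on the whole half-plane of velocities
#' whose gradient-parallel component has flipped sign. The incoming velocity
#' is decomposed along the unit gradient \eqn{u} and its orthogonal
#' \eqn{u^\perp} (rotation by \eqn{+\pi/2}); the outgoing parallel speed is
#' Rice-distributed, correlated with the incoming one through `rho`, and the
#' orthogonal component is autoregressive with coefficient `omega`:
#' \deqn{v' = -r_1 u + [\omega v_2 + \sqrt{1-\omega^2}\,\sigma\xi]\,u^\perp,
#'   \quad r_1 \sim \mathrm{Rice}(\rho s_1, \sigma\sqrt{1-\rho^2}).}
#' With canonical rates this is exactly the family of updates that preserve
#' the target; \eqn{\rho=\omega=1} recovers [bps_reflect()] and
#' \eqn{\rho=1,\omega=0} the GBPS.
#'
#' @param v incoming velocity (d = 2), with \eqn{g\cdot v > 0}.
#' @param g potential gradient at the event location.
#' @param cfg a [bounce_config()].
#' @export
halfspace_bounce <- function(v, g, cfg) {
  if (length(v) != 2L) stop("half-space bounce is defined for d = 2",
                            call. = FALSE)
  ng <- sqrt(sum(g^2))
  if (ng == 0) stop("cannot bounce on a zero gradient", call. = FALSE)
  u <- g / ng
  u_perp <- c(-u[2], u[1])
  s1 <- sum(v * u)
  if (s1 <= 0)
    stop("half-space bounce requires grad U . v > 0 at the event",
         call. = FALSE)
  v2 <- sum(v * u_perp)
  r1 <- rice_sample(1, cfg$rho * s1, cfg$sigma * sqrt(1 - cfg$rho^2))
  v2_new <- cfg$omega * v2 +
    sqrt(1 - cfg$omega^2) * cfg$sigma * stats::rnorm(1)
  -r1 * u + v2_new * u_perp
}

#' Reorientation configuration
#'
#' The smooth velocity-update family: reorientation events occur at rate
#' \eqn{\lambda(x, v) = s\,\|\nabla U(x)\|\,(1 + h\cos\theta)} where
#' \eqn{\theta} is the bearing relative to the gradient direction, and the
#' new relative bearing is drawn from
#' \eqn{q(\theta'|\theta) = \frac{1}{2\pi}[1 + a\cos\theta' +
#' b\cos(\theta'-\theta)]}. Consistency with the target requires the
#' constraint \eqn{h - a - bh/2 = 1} together with the positivity bounds
#' \eqn{|h| \le 1}, \eqn{|a|+|b| \le 1}; the constructor enforces all three.
#' Speed is updated independently through the correlated size-biased law
#' ([speed_update_sample()]) with correlation `rho_speed`, and the
#' refreshment process of [bounce_config()] is retained.
#'
#' @param a coefficient of \eqn{\cos\theta'} (attraction towards or away
#'   from the gradient direction; negative values bias the new bearing
#'   towards higher utilisation density).
#' @param b coefficient of \eqn{\cos(\theta'-\theta)} (persistence of the
#'   current bearing).
#' @param h modulation of the event rate by the current relative bearing.
#' @param sigma stationary velocity scale.
#' @param rho_speed speed correlation across a reorientation, in `[0, 1)`.
#' @inheritParams bounce_config
#' @export
reorient_config <- function(a, b, h, sigma = 1, rho_speed = 0,
                            refresh_rate = 0, refresh_eta = 0,
                            refresh_kappa = 0) {
  stopifnot_scalar(sigma, "sigma", positive = TRUE)
  if (abs(h) > 1 + 1e-12)
    stop("|h| <= 1 is required for a non-negative rate", call. = FALSE)
  if (abs(a) + abs(b) > 1 + 1e-12)
    stop("|a| + |b| <= 1 is required for a non-negative kernel",
         call. = FALSE)
  if (abs(h - a - b * h / 2 - 1) > 1e-12)
    stop("coefficients must satisfy the consistency constraint ",
         "h - a - b*h/2 = 1", call. = FALSE)
  stopifnot(rho_speed >= 0, rho_speed < 1, refresh_rate >= 0,
            refresh_eta >= 0, refresh_eta < 1, refresh_kappa >= 0)
  structure(list(a = a, b = b, h = h, sigma = sigma, rho_speed = rho_speed,
                 refresh_rate = refresh_rate, refresh_eta = refresh_eta,
                 refresh_kappa = refresh_kappa),
            class = "mvt_reorient_config")
}

#' Solve the reorientation consistency constraint
#'
#' Given two of the three coefficients of the reorientation family, returns
#' the third from \eqn{h - a - bh/2 = 1}.
#'
#' @param a,b,h exactly one must be `NULL`.
#' @return the missing coefficient.
#' @export
solve_reorient_constraint <- function(a = NULL, b = NULL, h = NULL) {
  missing_n <- sum(vapply(list(a, b, h), is.null, logical(1)))
  if (missing_n != 1L)
    stop("exactly one of a, b, h must be NULL", call. = FALSE)
  if (is.null(a)) return(h - b * h / 2 - 1)
  if (is.null(b)) {
    if (h == 0) stop("b is undetermined when h = 0", call. = FALSE)
    return(2 * (h - a - 1) / h)
  }
  (1 + a) / (1 - b / 2)
}

#' Named extremal solutions of the reorientation family
#'
#' The vertices of the feasible coefficient region plus the isotropic
#' boundary case, as a tibble of `(a, b, h)` rows with behavioural
#' interpretations.
#'
#' @export
reorient_solutions <- function() {
  tibble::tibble(
    case = c("i", "ii", "iii", "iv", "v"),
    a = c(-1/3, -1, 0, 1/3, 0),
    b = c(2/3, 0, -1, -2/3, 0),
    h = c(1, 0, 2/3, 1, 1),
    interpretation = c(
      "towards higher density and current bearing; rate increases with cos(theta)",
      "towards higher density, independent of current bearing; rate independent of theta",
      "independent of density, away from current bearing; rate increases with cos(theta)",
      "away from higher density and current bearing; rate increases with cos(theta)",
      "isotropic reorientation; rate increases with cos(theta)"))
}

#' Reorientation rate
#'
#' \eqn{\lambda = s\|\nabla U(x)\|(1 + h\cos\theta)} with \eqn{\theta} the
#' bearing of `v` relative to \eqn{\nabla U(x)}; zero where the gradient
#' vanishes (at an exact mode only refreshment operates).
#'
#' @inheritParams canonical_rate
#' @param cfg a [reorient_config()].
#' @export
reorientation_rate <- function(target, x, v, cfg) {
  gU <- -grad_log_density(target, x)
  ng <- sqrt(sum(gU^2))
  if (ng == 0) return(0)
  s <- sqrt(sum(v^2))
  theta <- atan2(v[2], v[1]) - atan2(gU[2], gU[1])
  max(0, s * ng * (1 + cfg$h * cos(theta)))
}

#' Reorientation bearing kernel
#'
#' `reorientation_bearing_density()` evaluates
#' \eqn{q(\theta'|\theta) = \frac{1}{2\pi}[1 + a\cos\theta' +
#' b\cos(\theta'-\theta)]} where both bearings are measured relative to the
#' gradient direction at the event location.
#' `reorientation_bearing_sample()` takes and returns absolute bearings,
#' converting to the gradient-relative frame internally, and samples by
#' rejection from the uniform circular law with bound
#' \eqn{(1+|a|+|b|)/2\pi}.
#'
#' @param theta_new,theta new and current gradient-relative bearing.
#' @param cfg a [reorient_config()].
#' @export
reorientation_bearing_density <- function(theta_new, theta, cfg) {
  (1 + cfg$a * cos(theta_new) + cfg$b * cos(theta_new - theta)) / (2 * pi)
}

#' @rdname reorientation_bearing_density
#' @param theta_abs current absolute bearing.
#' @param target,x target and event location (define the gradient frame).
#' @param max_attempts rejection cap.
#' @export
reorientation_bearing_sample <- function(theta_abs, x, target, cfg,
                                         max_attempts = 1e5) {
  gU <- -grad_log_density(target, x)
  frame <- atan2(gU[2], gU[1])
  theta_rel <- wrap_angle(theta_abs - frame)
  bound <- 1 + abs(cfg$a) + abs(cfg$b)
  for (i in seq_len(max_attempts)) {
    prop <- stats::runif(1, -pi, pi)
    dens <- 1 + cfg$a * cos(prop) + cfg$b * cos(prop - theta_rel)
    if (stats::runif(1) * bound < dens)
      return(wrap_angle(prop + frame))
  }
  stop(sprintf("bearing rejection sampler exhausted %d attempts",
               max_attempts), call. = FALSE)
}
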