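#' Location-dependent switching generators
#'
#' Multi-state movement couples a behavioural state \eqn{s} with location
#' \eqn{x}: within each state the movement targets the conditional
#' utilisation distribution \eqn{\pi(x|s)}, and switches between states
#' occur at location-dependent rates forming a generator \eqn{\Lambda(x)}
#' that preserves the state posterior, \eqn{\pi(\cdot|x)\Lambda(x) = 0}.
#' Four constructions are provided; all use the joint density only through
#' ratios, so the unnormalised linear predictors suffice.
#'
#' `rates_symmetric()`: \eqn{\lambda_{ij} = \psi_{ij}\sqrt{\pi(x,j)/\pi(x,i)}}
#' with symmetric \eqn{\psi}; satisfies detailed balance exactly.
#'
#' `rates_gibbs()`: \eqn{\lambda_{ij} = \kappa(x)\,\pi(j|x)}, the
#' continuous-time analogue of a Gibbs update on the state.
#'
#' `rates_mh()` / `rates_barker()`: proposal rates \eqn{q_{ij}} thinned by
#' the Metropolis-Hastings acceptance
#' \eqn{\min\{1, \pi_j q_{ji}/(\pi_i q_{ij})\}} or the smooth Barker rule
#' \eqn{\pi_j q_{ji}/(\pi_i q_{ij} + \pi_j q_{ji})}.
#'
#' @param target a [target_multistate()].
#' @param x location.
#' @param psi symmetric matrix of baseline exchange rates (or a scalar,
#'   recycled to all off-diagonal pairs), or a function of `x` returning
#'   such a matrix.
#' @return an S-by-S generator matrix: non-negative off-diagonals, rows
#'   summing to zero.
#' @export
rates_symmetric <- function(target, x, psi) {
  S <- target$n_states
  psi <- resolve_rate_matrix(psi, x, S, symmetric = TRUE)
  lp <- state_linpred(target, x)
  lam <- psi * exp(outer(lp, lp, function(a, b) (b - a) / 2))
  finish_generator(lam)
}

#' @rdname rates_symmetric
#' @param kappa_rate overall nominal switching rate \eqn{\kappa(x)}: a
#'   positive scalar or a function of `x`.
#' @export
rates_gibbs <- function(target, x, kappa_rate) {
  kap <- if (is.function(kappa_rate)) kappa_rate(x) else kappa_rate
  stopifnot(kap > 0)
  post <- state_posterior(target, x)
  S <- target$n_states
  lam <- kap * matrix(post, S, S, byrow = TRUE)
  finish_generator(lam)
}

#' @rdname rates_symmetric
#' @param q matrix of proposal rates \eqn{q_{ij} \ge 0} (or a function of
#'   `x`); `q_ij = 0` with `q_ji > 0` gives a one-way rate of zero, which
#'   still balances.
#' @export
rates_mh <- function(target, x, q) {
  S <- target$n_states
  q <- resolve_rate_matrix(q, x, S, symmetric = FALSE)
  lp <- state_linpred(target, x)
  lam <- matrix(0, S, S)
  for (i in seq_len(S)) for (j in seq_len(S)) {
    if (i == j || q[i, j] == 0) next
    ratio <- exp(lp[j] - lp[i]) * q[j, i] / q[i, j]
    lam[i, j] <- q[i, j] * min(1, ratio)
  }
  finish_generator(lam)
}

#' @rdname rates_symmetric
#' @export
rates_barker <- function(target, x, q) {
  S <- target$n_states
  q <- resolve_rate_matrix(q, x, S, symmetric = FALSE)
  lp <- state_linpred(target, x)
  lam <- matrix(0, S, S)
  for (i in seq_len(S)) for (j in seq_len(S)) {
    if (i == j || q[i, j] == 0) next
    r <- exp(lp[j] - lp[i]) * q[j, i]
    lam[i, j] <- q[i, j] * r / (q[i, j] + r)
  }
  finish_generator(lam)
}

#' Non-reversible 3-state generator
#'
#' For S = 3 the whole space of stationarity-preserving generators is
#' parameterised by three free rates around the cycle
#' \eqn{1 \to 2 \to 3 \to 1} plus a circulation parameter \eqn{\epsilon}:
#' \deqn{\lambda_{21} = \frac{\pi_1}{\pi_2}\lambda_{12} + \epsilon/\pi_2,
#' \quad \lambda_{32} = \frac{\pi_2}{\pi_3}\lambda_{23} + \epsilon/\pi_3,
#' \quad \lambda_{13} = \frac{\pi_3}{\pi_1}\lambda_{31} + \epsilon/\pi_1,}
#' with \eqn{\pi_s = \pi(s|x)}. \eqn{\epsilon = 0} gives detailed balance;
#' any \eqn{\epsilon \ge -\min\{\pi_1\lambda_{12}, \pi_2\lambda_{23},
#' \pi_3\lambda_{31}\}} gives a valid generator that preserves
#' \eqn{\pi(\cdot|x)} while carrying a steady probability circulation
#' around the cycle.
#'
#' @inheritParams rates_symmetric
#' @param lam12,lam23,lam31 free cycle rates (non-negative).
#' @param eps circulation; validated against its lower bound.
#' @export
generator_3state <- function(target, x, lam12, lam23, lam31, eps = 0) {
  stopifnot(target$n_states == 3L, lam12 >= 0, lam23 >= 0, lam31 >= 0)
  post <- state_posterior(target, x)
  if (any(post <= 0))
    stop("all three states need positive posterior probability at x",
         call. = FALSE)
  lower <- -min(post[1] * lam12, post[2] * lam23, post[3] * lam31)
  if (eps < lower - 1e-12)
    stop(sprintf("eps = %.6g below its bound %.6g at this location",
                 eps, lower), call. = FALSE)
  lam <- matrix(0, 3, 3)
  lam[1, 2] <- lam12; lam[2, 3] <- lam23; lam[3, 1] <- lam31
  lam[2, 1] <- post[1] / post[2] * lam12 + eps / post[2]
  lam[3, 2] <- post[2] / post[3] * lam23 + eps / post[3]
  lam[1, 3] <- post[3] / post[1] * lam31 + eps / post[1]
  lam[lam < 0] <- 0   # clamp roundoff at the boundary eps
  finish_generator(lam)
}

# Optimised per-row rate evaluation for the shorthand specs; avoids building
# the full generator (and its validation) inside the simulation loop.
make_row_rates <- function(target, spec) {
  S <- target$n_states
  vals <- lapply(target$covariates, function(cv) cv$value)
  K <- length(vals)
  beta0 <- target$beta0
  B <- target$beta
  lpfun <- function(x) {
    cv <- numeric(K)
    for (k in seq_len(K)) cv[k] <- vals[[k]](x)
    beta0 + drop(B %*% cv)
  }
  type <- spec$type %||% stop("rate spec needs a type", call. = FALSE)
  if (type == "symmetric") {
    psi <- spec$psi
    if (length(psi) == 1L) psi <- matrix(psi, S, S)
    stopifnot(max(abs(psi - t(psi))) < 1e-12)
    return(function(x, s) {
      lp <- lpfun(x)
      r <- psi[s, ] * exp((lp - lp[s]) / 2)
      r[s] <- 0
      r
    })
  }
  if (type == "gibbs") {
    kap <- spec$kappa
    return(function(x, s) {
      lp <- lpfun(x)
      w <- exp(lp - max(lp))
      r <- kap * w / sum(w)
      r[s] <- 0
      r
    })
  }
  stop("unknown shorthand rate type: ", type, call. = FALSE)
}

resolve_rate_matrix <- function(m, x, S, symmetric) {
  if (is.function(m)) m <- m(x)
  if (length(m) == 1L) m <- matrix(m, S, S)
  stopifnot(nrow(m) == S, ncol(m) == S, all(m[row(m) != col(m)] >= 0))
  if (symmetric && max(abs(m - t(m))) > 1e-12)
    stop("psi must be symmetric", call. = FALSE)
  m
}

finish_generator <- function(lam) {
  diag(lam) <- 0
  diag(lam) <- -rowSums(lam)
  lam
}

#' Baseline exchange rates in linear-exponential form
#'
#' Builds \eqn{\psi_{ij}(x) = \exp(\alpha_{ij0} + \sum_k \alpha_{ijk}
#' c_k(x))} for use with [rates_symmetric()], so the switching rates can
#' themselves respond to covariates beyond what stationarity requires.
#'
#' @param alpha0 symmetric S-by-S matrix of intercepts.
#' @param alpha list (length K) of symmetric S-by-S coefficient matrices,
#'   or `NULL` for covariate-free rates.
#' @param covariates list of covariates matching `alpha`.
#' @return a function of `x` returning the symmetric rate matrix.
#' @export
psi_linexp <- function(alpha0, alpha = NULL, covariates = NULL) {
  stopifnot(max(abs(alpha0 - t(alpha0))) < 1e-12)
  if (!is.null(alpha)) {
    stopifnot(length(alpha) == length(covariates))
    for (a in alpha) stopifnot(max(abs(a - t(a))) < 1e-12)
  }
  function(x) {
    lp <- alpha0
    for (k in seq_along(alpha)) lp <- lp + alpha[[k]] * covariates[[k]]$value(x)
    exp(lp)
  }
}

#' Per-state kinetic Langevin movement for a multi-state target
#'
#' Convenience builder: one kinetic Langevin spec per behavioural state,
#' each targeting that state's conditional utilisation distribution.
#'
#' @param target a [target_multistate()].
#' @param gamma,alpha kinetic Langevin parameters, recycled across states.
#' @return list of `mvt_diffusion_spec`, one per state.
#' @export
switching_kinetic_specs <- function(target, gamma, alpha) {
  gamma <- rep(gamma, length.out = target$n_states)
  alpha <- rep(alpha, length.out = target$n_states)
  lapply(seq_len(target$n_states), function(s)
    kinetic_langevin_spec(conditional_target(target, s), gamma[s], alpha[s]))
}

#' Simulate a multi-state movement process
#'
#' Operator splitting: each time step performs one Euler-Maruyama move under
#' the current state's diffusion spec, then switches state with probability
#' \eqn{1 - \exp(-\lambda_{tot}\,dt)} (destination proportional to the
#' off-diagonal rates at the new location). The splitting is accurate when
#' \eqn{\lambda_{tot}\,dt} is small; a warning is issued the first time it
#' exceeds 0.1.
#'
#' @param target a [target_multistate()].
#' @param rates either a function of `x` returning the S-by-S generator
#'   (e.g. `function(x) rates_symmetric(target, x, psi)`), or a shorthand
#'   list such as `list(type = "symmetric", psi = ...)` /
#'   `list(type = "gibbs", kappa = ...)`, for which an optimised rate-row
#'   evaluation is used (the simulation only ever needs the current
#'   state's row).
#' @param movement_specs list of per-state `mvt_diffusion_spec` sharing one
#'   state layout (see [switching_kinetic_specs()]).
#' @param x0 initial movement state (full layout of the specs).
#' @param s0 initial behavioural state.
#' @param dt step size.
#' @param t_end horizon.
#' @param seed optional seed.
#' @param thin record every `thin`-th step.
#' @return an `mvt_trajectory` tibble with an integer `state` column.
#' @export
simulate_switching <- function(target, rates, movement_specs, x0, s0, dt,
                               t_end, seed = NULL, thin = 1L) {
  if (!is.null(seed)) set.seed(seed)
  thin <- as.integer(thin)
  S <- target$n_states
  stopifnot(length(movement_specs) == S, s0 >= 1, s0 <= S)
  layout <- movement_specs[[1]]$state_names
  d <- movement_specs[[1]]$d
  drifts <- lapply(movement_specs, function(sp) sp$drift)
  noises <- lapply(movement_specs, function(sp) sp$noise)
  steps <- lapply(movement_specs, function(sp) sp$step)
  row_rates <- if (is.function(rates)) {
    function(x, s) {
      r <- rates(x)[s, ]
      r[s] <- 0
      r
    }
  } else {
    make_row_rates(target, rates)
  }
  n <- floor(t_end / dt + 1e-9)
  sq <- sqrt(dt)
  D <- length(x0)
  pos_idx <- seq_len(d)
  n_rec <- floor(n / thin) + 1L
  out <- matrix(NA_real_, n_rec, D)
  st <- integer(n_rec)
  out[1L, ] <- x <- as.numeric(x0)
  st[1L] <- s <- as.integer(s0)
  rec <- 1L
  warned <- FALSE
  chunk <- 8192L
  zi <- chunk; zbuf <- NULL
  for (k in seq_len(n)) {
    if (zi == chunk) {
      zbuf <- matrix(stats::rnorm(chunk * D), chunk, D)
      zi <- 0L
    }
    zi <- zi + 1L
    x <- if (is.null(steps[[s]])) {
      x + drifts[[s]](x) * dt + noises[[s]](x) * sq * zbuf[zi, ]
    } else {
      steps[[s]](x, dt, sq, zbuf[zi, ])
    }
    if (!all(is.finite(x)))
      stop(sprintf("non-finite state at step %d", k), call. = FALSE)
    r <- row_rates(x[pos_idx], s)
    ltot <- sum(r)
    if (!warned && ltot * dt > 0.1) {
      warning("switching probability per step exceeds 0.1; ",
              "reduce dt to limit splitting bias", call. = FALSE)
      warned <- TRUE
    }
    if (ltot > 0 && stats::runif(1) < -expm1(-ltot * dt)) {
      s <- if (S == 2L) 3L - s else sample.int(S, 1L, prob = r)
    }
    if (k %% thin == 0L) {
      rec <- rec + 1L
      out[rec, ] <- x
      st[rec] <- s
    }
  }
  colnames(out) <- layout
  tr <- dplyr::bind_cols(
    tibble::tibble(t = seq(0, by = dt * thin, length.out = n_rec)),
    tibble::as_tibble(out),
    tibble::tibble(state = st))
  attr(tr, "dt") <- dt
  attr(tr, "thin") <- thin
  attr(tr, "seed") <- seed
  attr(tr, "kind") <- "switching"
  class(tr) <- c("mvt_trajectory", class(tr))
  tr
}
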