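#' Stationarity diagnostics for simulated movement
#'
#' Checks that the long-run location distribution of a simulated trajectory
#' matches the target utilisation distribution it was built for: per
#' coordinate, a one-sample Kolmogorov-Smirnov test against the
#' quadrature-normalised target marginal, plus empirical versus target
#' moments. For switching runs a per-state conditional check and an
#' occupancy summary (with batch-means standard errors) are added; for
#' velocity-jump paths the path is resampled on a regular grid first and
#' event-rate summaries are reported.
#'
#' The KS test assumes (approximately) independent samples, so the
#' trajectory is thinned to `thin_interval` time units after discarding the
#' `burn_in` fraction; choose the interval long relative to the model's
#' mixing time.
#'
#' @param traj an `mvt_trajectory` (or an `mvt_pdmp_path`).
#' @param target the `mvt_target` the simulation was built on.
#' @param burn_in fraction of the record discarded from the start.
#' @param thin_interval spacing, in time units, between retained samples.
#' @param alpha significance level used for the `pass` summary.
#' @param grid_dt resampling step for velocity-jump paths.
#' @return an `mvt_diagnosis` list: `position` tibble (coordinate, KS
#'   statistic and p-value, moments), optional `states` and `occupancy`
#'   tibbles, optional `events` summary, `n_used`, and `pass`.
#' @export
diagnose <- function(traj, target, burn_in = 0.2, thin_interval = 1,
                     alpha = 0.01, grid_dt = NULL) {
  events <- NULL
  if (inherits(traj, "mvt_pdmp_path")) {
    path <- traj
    horizon <- path$t_end - path$t0
    events <- tibble::tibble(
      kind = names(table(path$events$kind)),
      count = as.integer(table(path$events$kind)),
      rate = as.numeric(table(path$events$kind)) / horizon)
    traj <- path_to_trajectory(path, grid_dt %||% thin_interval)
  }
  tt <- traj$t
  keep <- tt >= (min(tt) + burn_in * (max(tt) - min(tt)))
  traj <- traj[keep, ]
  tt <- traj$t
  step <- if (length(tt) > 1) tt[2] - tt[1] else 1
  stride <- max(1L, round(thin_interval / step))
  traj <- traj[seq(1, nrow(traj), by = stride), ]
  if (nrow(traj) < 500)
    stop(sprintf("only %d post-burn-in samples; need at least 500",
                 nrow(traj)), call. = FALSE)

  coords <- intersect(coord_names(target$dim), names(traj))
  if (length(coords) == 0)
    stop("trajectory has no position columns matching the target",
         call. = FALSE)

  pos <- purrr::map_dfr(seq_along(coords), function(i) {
    xs <- traj[[coords[i]]]
    cdf <- marginal_cdf(target, axis = i)
    ks <- suppressWarnings(stats::ks.test(xs, cdf))
    mom <- target_axis_moments(target, i)
    tibble::tibble(coordinate = coords[i],
                   n = length(xs),
                   ks_stat = unname(ks$statistic),
                   p_value = ks$p.value,
                   emp_mean = mean(xs), emp_var = stats::var(xs),
                   target_mean = mom[1], target_var = mom[2])
  })

  states <- NULL; occupancy <- NULL
  if ("state" %in% names(traj) && inherits(target, "multistate_target")) {
    states <- purrr::map_dfr(seq_len(target$n_states), function(s) {
      xs <- traj$x[traj$state == s]
      if (length(xs) < 100) {
        return(tibble::tibble(state = s, n = length(xs),
                              ks_stat = NA_real_, p_value = NA_real_))
      }
      cdf <- marginal_cdf(conditional_target(target, s))
      ks <- suppressWarnings(stats::ks.test(xs, cdf))
      tibble::tibble(state = s, n = length(xs),
                     ks_stat = unname(ks$statistic), p_value = ks$p.value)
    })
    occupancy <- occupancy_summary(traj$state, target)
  }

  res <- structure(
    list(position = pos, states = states, occupancy = occupancy,
         events = events, n_used = nrow(traj), alpha = alpha,
         pass = all(pos$p_value > alpha) &&
           (is.null(states) ||
              all(states$p_value > alpha, na.rm = TRUE))),
    class = "mvt_diagnosis")
  res
}

# Long-run state probabilities by quadrature, with batch-means SEs on the
# empirical occupancy. Plain binomial SEs would be far too small because
# sojourns span many samples; batches must also be longer than a typical
# sojourn, so the batch count adapts to the number of observed transitions.
occupancy_summary <- function(state_seq, target, n_batch = NULL) {
  n_trans <- sum(diff(state_seq) != 0)
  if (is.null(n_batch))
    n_batch <- max(4L, min(20L, floor(n_trans / 2)))
  support <- target_support(target)[, 1]
  grid <- seq(support[1], support[2], length.out = 4001)
  lp <- t(vapply(grid, function(g) state_linpred(target, g),
                 numeric(target$n_states)))
  mx <- max(lp)
  mass <- vapply(seq_len(target$n_states), function(s)
    trapz(grid, exp(lp[, s] - mx)), numeric(1))
  pi_s <- mass / sum(mass)
  batches <- split(state_seq,
                   cut(seq_along(state_seq), n_batch, labels = FALSE))
  emp <- vapply(seq_len(target$n_states), function(s)
    mean(state_seq == s), numeric(1))
  se_batch <- vapply(seq_len(target$n_states), function(s) {
    bs <- vapply(batches, function(b) mean(b == s), numeric(1))
    stats::sd(bs) / sqrt(length(bs))
  }, numeric(1))
  # Score-test floor: when a run contains only a handful of sojourn cycles
  # the batch estimator can report a near-zero SE for a chain stuck in one
  # state. Under the null occupancy pi_s, the sampling SD of the empirical
  # occupancy of an alternating-renewal process with N complete cycles is
  # of order pi_s(1-pi_s) * sqrt(2/N); the reported SE never drops below it.
  n_cycles <- max(1, floor(n_trans / 2))
  se <- pmax(se_batch, pi_s * (1 - pi_s) * sqrt(2 / n_cycles))
  tibble::tibble(state = seq_len(target$n_states), occupancy = emp,
                 target = pi_s, se = se, n_transitions = n_trans)
}

# mean and variance of one axis marginal by quadrature
target_axis_moments <- function(target, axis) {
  if (inherits(target, "product_target")) {
    m <- target$margins[[axis]]
    grid <- seq(m$support[1], m$support[2], length.out = 4001)
    d <- exp(m$logpdf(grid) - max(m$logpdf(grid)))
  } else if (target$dim == 1L) {
    support <- target_support(target)[, 1]
    grid <- seq(support[1], support[2], length.out = 4001)
    ld <- vapply(grid, function(g) log_density(target, g), numeric(1))
    d <- exp(ld - max(ld))
  } else {
    return(c(NA_real_, NA_real_))
  }
  Z <- trapz(grid, d)
  mu <- trapz(grid, grid * d) / Z
  c(mu, trapz(grid, (grid - mu)^2 * d) / Z)
}

#' @export
print.mvt_diagnosis <- function(x, ...) {
  cat("Stationarity diagnosis (", x$n_used, "samples )\n")
  print(x$position)
  if (!is.null(x$states)) {
    cat("State-conditional checks:\n"); print(x$states)
    cat("Occupancy:\n"); print(x$occupancy)
  }
  if (!is.null(x$events)) {
    cat("Event rates:\n"); print(x$events)
  }
  cat(if (isTRUE(x$pass)) "PASS" else "FAIL",
      "at alpha =", x$alpha, "\n")
  invisible(x)
}

#' Serialise a diagnosis report to JSON
#'
#' @param x an `mvt_diagnosis`.
#' @return a JSON string.
#' @export
diagnosis_json <- function(x) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                   null = "null", dataframe = "rows")
}
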