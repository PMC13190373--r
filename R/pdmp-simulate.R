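#' Exact simulation of velocity-jump movement models
#'
#' Simulates the bounce and reorientation processes by uniformisation /
#' thinning: along each straight segment, candidate event times are drawn
#' from a homogeneous Poisson process at a dominating rate \eqn{\bar\Lambda}
#' computed over a finite lookahead horizon, and a candidate at time `t` is
#' accepted with probability \eqn{\lambda(x(t), v)/\bar\Lambda}. The
#' dominating rate uses analytic gradient-norm bounds for the built-in
#' targets; if the true rate ever exceeds the bound the simulation stops
#' with an error rather than clipping, so accepted paths are exact draws
#' from the model. Refreshment events come from an independent constant-rate
#' exponential clock.
#'
#' @param target an `mvt_target`.
#' @param model one of `"bps"`, `"gbps"`, `"halfspace"`, `"reorient"`.
#' @param cfg a [bounce_config()] (bounce models) or [reorient_config()]
#'   (reorientation model).
#' @param x0 initial position.
#' @param v0 initial velocity; defaults to a draw from
#'   \eqn{N(0, \sigma^2 I)}, the stationary velocity law.
#' @param t_end time horizon.
#' @param seed optional integer seed; identical seeds give identical event
#'   lists.
#' @param t0 start time.
#' @param lookahead horizon (time units) over which the dominating rate is
#'   computed; segments with no event are advanced deterministically.
#' @return an `mvt_pdmp_path`: initial state, ordered event records
#'   (time, kind, position, velocity before/after), final state.
#' @export
simulate_pdmp <- function(target, model = c("bps", "gbps", "halfspace",
                                            "reorient"),
                          cfg, x0, v0 = NULL, t_end, seed = NULL, t0 = 0,
                          lookahead = 1) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  d <- target$dim
  if (model %in% c("halfspace", "reorient") && d != 2L)
    stop(model, " model is defined for d = 2", call. = FALSE)
  if (model == "reorient") {
    stopifnot(inherits(cfg, "mvt_reorient_config"))
  } else {
    stopifnot(inherits(cfg, "mvt_bounce_config"))
  }
  x <- as.numeric(x0)
  check_dim(target, x)
  v <- if (is.null(v0)) cfg$sigma * stats::rnorm(d) else as.numeric(v0)
  grad_fn <- make_grad_fn(target)
  gradU <- function(p) -grad_fn(p)
  h_coef <- if (model == "reorient") abs(cfg$h) else NULL

  rate_at <- if (model == "reorient") {
    function(p, vel) {
      gU <- gradU(p); ng <- sqrt(sum(gU^2))
      if (ng == 0) return(0)
      s <- sqrt(sum(vel^2))
      th <- atan2(vel[2], vel[1]) - atan2(gU[2], gU[1])
      max(0, s * ng * (1 + cfg$h * cos(th)))
    }
  } else {
    function(p, vel) max(0, sum(gradU(p) * vel))
  }
  bound_for <- function(p, vel, hh) {
    B <- grad_norm_bound(target, p, p + vel * hh)
    s <- sqrt(sum(vel^2))
    if (model == "reorient") s * (1 + h_coef) * B else s * B
  }

  # event storage, grown by doubling
  cap <- 1024L
  ev_time <- numeric(cap); ev_kind <- character(cap)
  ev_x <- matrix(NA_real_, cap, d)
  ev_vb <- matrix(NA_real_, cap, d); ev_va <- matrix(NA_real_, cap, d)
  n_ev <- 0L
  push_event <- function(tt, kind, p, vb, va) {
    if (n_ev == cap) {
      cap <<- cap * 2L
      ev_time <<- c(ev_time, numeric(cap / 2L))
      ev_kind <<- c(ev_kind, character(cap / 2L))
      ev_x <<- rbind(ev_x, matrix(NA_real_, cap / 2L, d))
      ev_vb <<- rbind(ev_vb, matrix(NA_real_, cap / 2L, d))
      ev_va <<- rbind(ev_va, matrix(NA_real_, cap / 2L, d))
    }
    n_ev <<- n_ev + 1L
    ev_time[n_ev] <<- tt; ev_kind[n_ev] <<- kind
    ev_x[n_ev, ] <<- p; ev_vb[n_ev, ] <<- vb; ev_va[n_ev, ] <<- va
  }

  apply_event <- function(kind, p, vel) {
    if (kind == "refresh") {
      if (d == 2L) {
        s <- sqrt(sum(vel^2))
        s_new <- rice_refresh_speed(s, cfg$sigma, cfg$refresh_eta)
        th_new <- vonmises_turn(atan2(vel[2], vel[1]), cfg$refresh_kappa)
        return(s_new * c(cos(th_new), sin(th_new)))
      }
      return(cfg$sigma * stats::rnorm(d))
    }
    g <- gradU(p)
    switch(model,
      bps = bps_reflect(vel, g),
      gbps = gbps_bounce(vel, g, cfg$sigma),
      halfspace = halfspace_bounce(vel, g, cfg),
      reorient = {
        th_new <- reorientation_bearing_sample(atan2(vel[2], vel[1]), p,
                                               target, cfg)
        s_new <- speed_update_sample(sqrt(sum(vel^2)), cfg$sigma,
                                     cfg$rho_speed)
        s_new * c(cos(th_new), sin(th_new))
      })
  }

  lam0 <- cfg$refresh_rate
  t_now <- t0
  t_ref <- if (lam0 > 0) t0 + stats::rexp(1, lam0) else Inf
  ev_label <- if (model == "reorient") "reorientation" else "bounce"

  while (t_now < t_end) {
    seg_end <- min(t_now + lookahead, t_end)
    lam_bar <- bound_for(x, v, seg_end - t_now)
    t_cand <- Inf
    if (lam_bar > 0) {
      tc <- t_now
      repeat {
        tc <- tc + stats::rexp(1, lam_bar)
        if (tc >= seg_end) break
        lam <- rate_at(x + (tc - t_now) * v, v)
        if (lam > lam_bar * (1 + 1e-9))
          stop(sprintf(paste0("thinning bound violated: rate %.6g exceeds ",
                              "bound %.6g at t = %.6g"),
                       lam, lam_bar, tc), call. = FALSE)
        if (stats::runif(1) * lam_bar < lam) { t_cand <- tc; break }
      }
    }
    t_next <- min(t_cand, t_ref, seg_end)
    if (t_next >= t_end) {  # finish the final deterministic stretch
      x <- x + (t_end - t_now) * v
      t_now <- t_end
      break
    }
    if (t_next == t_cand || t_next == t_ref) {
      kind <- if (t_next == t_cand) ev_label else "refresh"
      x_ev <- x + (t_next - t_now) * v
      v_new <- apply_event(kind, x_ev, v)
      push_event(t_next, kind, x_ev, v, v_new)
      x <- x_ev; v <- v_new; t_now <- t_next
      if (kind == "refresh") {
        t_ref <- t_now + stats::rexp(1, lam0)
      } else if (t_ref <= t_now) {
        t_ref <- t_now + stats::rexp(1, lam0)
      }
    } else {
      # window exhausted: advance along the segment
      x <- x + (seg_end - t_now) * v
      t_now <- seg_end
    }
  }

  idx <- seq_len(n_ev)
  events <- tibble::tibble(time = ev_time[idx], kind = ev_kind[idx])
  xcols <- coord_names(d)
  for (j in seq_len(d)) {
    events[[xcols[j]]] <- ev_x[idx, j]
    events[[paste0("v", xcols[j], "_before")]] <- ev_vb[idx, j]
    events[[paste0("v", xcols[j], "_after")]] <- ev_va[idx, j]
  }
  structure(
    list(t0 = t0, x0 = as.numeric(x0), v0 = v, t_end = t_end,
         events = events, final_x = x, final_v = v, model = model,
         cfg = cfg, seed = seed, d = d,
         v0_initial = if (is.null(v0)) NULL else as.numeric(v0)),
    class = "mvt_pdmp_path")
}

#' @export
print.mvt_pdmp_path <- function(x, ...) {
  cat("<velocity-jump path:", x$model, "> events:", nrow(x$events),
      " horizon: [", x$t0, ",", x$t_end, "]\n")
  print(table(x$events$kind))
  invisible(x)
}

# Knot representation: times, positions and outgoing velocities including
# the initial state.
path_knots <- function(path) {
  d <- path$d
  xcols <- coord_names(d)
  ev <- path$events
  n <- nrow(ev)
  times <- c(path$t0, ev$time)
  pos <- rbind(path$x0,
               as.matrix(ev[, xcols, drop = FALSE]))
  # v0 as recorded before the first event (or final v if no events)
  v_first <- if (n > 0) {
    unlist(ev[1, paste0("v", xcols, "_before")], use.names = FALSE)
  } else path$final_v
  vel <- rbind(v_first,
               if (n > 0) as.matrix(ev[, paste0("v", xcols, "_after"),
                                       drop = FALSE]) else NULL)
  list(times = times, pos = pos, vel = vel)
}

#' Position of a velocity-jump path at given times
#'
#' Piecewise-linear interpolation between events.
#'
#' @param path an `mvt_pdmp_path`.
#' @param t times within the simulated horizon (vectorised).
#' @return a matrix with one row per time and one column per coordinate
#'   (a plain vector for a single 1-D query).
#' @export
path_position_at <- function(path, t) {
  if (any(t < path$t0 - 1e-12) || any(t > path$t_end + 1e-12))
    stop("query times outside the simulated horizon", call. = FALSE)
  k <- path_knots(path)
  seg <- findInterval(t, k$times, rightmost.closed = TRUE)
  seg[seg < 1L] <- 1L
  out <- k$pos[seg, , drop = FALSE] +
    (t - k$times[seg]) * k$vel[seg, , drop = FALSE]
  colnames(out) <- coord_names(path$d)
  out
}

#' Resample a velocity-jump path on a regular time grid
#'
#' @inheritParams path_position_at
#' @param dt grid spacing.
#' @return an `mvt_trajectory` tibble compatible with the diffusion output.
#' @export
path_to_trajectory <- function(path, dt) {
  tt <- seq(path$t0, path$t_end, by = dt)
  pos <- path_position_at(path, tt)
  tr <- dplyr::bind_cols(tibble::tibble(t = tt), tibble::as_tibble(pos))
  attr(tr, "dt") <- dt
  attr(tr, "kind") <- paste0("pdmp_", path$model)
  attr(tr, "seed") <- path$seed
  class(tr) <- c("mvt_trajectory", class(tr))
  tr
}

#' Write a velocity-jump path to CSV with a JSON sidecar
#'
#' @inheritParams path_position_at
#' @param file output CSV path for the event table.
#' @export
write_pdmp_path <- function(path, file) {
  utils::write.csv(as.data.frame(path$events), file, row.names = FALSE)
  meta <- list(model = path$model, cfg = unclass(path$cfg),
               seed = path$seed, t0 = path$t0, t_end = path$t_end,
               x0 = path$x0)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(file)
}
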