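test_that("canonical rate clips the gradient-velocity product at zero", {
  tg <- gaussian_linexp(2, beta = 1)     # grad U = x
  expect_equal(canonical_rate(tg, c(1, 0), c(1, 0)), 1)
  expect_equal(canonical_rate(tg, c(1, 0), c(0, 1)), 0)   # orthogonal
  expect_equal(canonical_rate(tg, c(1, 0), c(-1, 0)), 0)  # downhill
})

test_that("specular reflection negates the parallel component only", {
  g <- c(2, 1)
  v_par <- 3 * g
  expect_equal(bps_reflect(v_par, g), -v_par)
  v_orth <- c(-1, 2)                      # orthogonal to g
  expect_equal(bps_reflect(v_orth, g), v_orth)
  set.seed(71)
  for (i in 1:20) {
    v <- stats::rnorm(2); g <- stats::rnorm(2)
    r <- bps_reflect(v, g)
    expect_equal(bps_reflect(r, g), v, tolerance = 1e-12)   # involution
    expect_equal(sum(r^2), sum(v^2), tolerance = 1e-12)     # speed kept
  }
  expect_error(bps_reflect(c(1, 1), c(0, 0)), "zero gradient")
})

test_that("randomised bounce negates the parallel part and renews the orthogonal", {
  set.seed(72)
  g <- c(1, 2); u <- g / sqrt(sum(g^2)); u_perp <- c(-u[2], u[1])
  v <- c(0.7, 0.4); sigma <- 1.3
  n <- 1e5
  draws <- t(replicate(n, gbps_bounce(v, g, sigma)))
  par_comp <- draws %*% u
  expect_lt(max(abs(par_comp + sum(v * u))), 1e-12)
  orth <- drop(draws %*% u_perp)
  ks <- suppressWarnings(stats::ks.test(orth, function(q)
    stats::pnorm(q, 0, sigma)))
  expect_gt(ks$p.value, 0.01)
  # vanishing noise keeps only the reflected parallel part
  expect_equal(gbps_bounce(v, g, 0), -sum(v * u) * u, tolerance = 1e-12)
})

test_that("half-space bounce reduces to BPS and GBPS at the boundary parameters", {
  set.seed(73)
  g <- c(1, -1); sigma <- 1
  v <- c(2, 0.5)                     # g . v > 0
  # rho = 1, omega = 1: deterministic specular reflection
  cfg <- bounce_config(sigma, rho = 1, omega = 1)
  expect_equal(halfspace_bounce(v, g, cfg), bps_reflect(v, g),
               tolerance = 1e-12)
  # rho = 1, omega = 0: the parallel part is still deterministic and the
  # orthogonal part is a fresh normal draw
  cfg0 <- bounce_config(sigma, rho = 1, omega = 0)
  u <- g / sqrt(sum(g^2)); u_perp <- c(-u[2], u[1])
  draws <- t(replicate(2e4, halfspace_bounce(v, g, cfg0)))
  expect_lt(max(abs(drop(draws %*% u) + sum(v * u))), 1e-12)
  expect_gt(suppressWarnings(stats::ks.test(drop(draws %*% u_perp),
                                            "pnorm"))$p.value, 0.01)
  # general parameters: the parallel component always changes sign
  cfgh <- bounce_config(sigma, rho = 0.5, omega = 0.5)
  signs <- replicate(1e5, sum(halfspace_bounce(v, g, cfgh) * g))
  expect_true(all(signs < 0))
  expect_error(halfspace_bounce(c(-1, -1), g, cfgh), "grad U . v > 0",
               fixed = TRUE)
})

test_that("reorientation rate follows the cosine modulation", {
  tg <- gaussian_linexp(2, beta = 1)        # grad U = x
  x <- c(3, 0)                              # ||grad U|| = 3
  # h = 0: rate independent of bearing
  cfg0 <- reorient_config(a = -1, b = 0, h = 0)
  r1 <- reorientation_rate(tg, x, c(2, 0), cfg0)
  r2 <- reorientation_rate(tg, x, c(0, 2), cfg0)
  expect_equal(r1, 2 * 3)
  expect_equal(r2, 2 * 3)
  # h = 1: vanishes against the gradient, maximal along it
  cfg1 <- reorient_config(a = 0, b = 0, h = 1)
  expect_equal(reorientation_rate(tg, x, c(-2, 0), cfg1), 0)
  expect_equal(reorientation_rate(tg, x, c(2, 0), cfg1), 12)
  # zero gradient: no reorientation pressure
  expect_equal(reorientation_rate(tg, c(0, 0), c(1, 1), cfg1), 0)
})

test_that("reorientation configs accept the extremal solutions and reject others", {
  tab <- reorient_solutions()
  for (i in seq_len(nrow(tab))) {
    expect_s3_class(reorient_config(tab$a[i], tab$b[i], tab$h[i]),
                    "mvt_reorient_config")
    expect_lt(abs(tab$h[i] - tab$a[i] - tab$b[i] * tab$h[i] / 2 - 1), 1e-12)
  }
  expect_error(reorient_config(0, 0, 0.5), "constraint")
  expect_error(reorient_config(0.9, 0.4, solve_reorient_constraint(
    a = 0.9, b = 0.4)), "non-negative")
  expect_error(reorient_config(-2.5, 3, 1), "non-negative")
})

test_that("solving the consistency constraint reproduces each withheld coefficient", {
  tab <- reorient_solutions()
  for (i in seq_len(nrow(tab))) {
    a <- tab$a[i]; b <- tab$b[i]; h <- tab$h[i]
    expect_equal(solve_reorient_constraint(b = b, h = h), a,
                 tolerance = 1e-12)
    if (h != 0)
      expect_equal(solve_reorient_constraint(a = a, h = h), b,
                   tolerance = 1e-12)
    expect_equal(solve_reorient_constraint(a = a, b = b), h,
                 tolerance = 1e-12)
  }
})

test_that("bearing kernel normalises and balances the rate on the circle", {
  tab <- reorient_solutions()
  thetas <- seq(-pi, pi, length.out = 65)[-65]
  grid <- seq(-pi, pi, length.out = 2049)
  w <- rep(diff(grid)[1], length(grid)); w[c(1, length(grid))] <- w[1] / 2
  for (i in seq_len(nrow(tab))) {
    cfg <- reorient_config(tab$a[i], tab$b[i], tab$h[i])
    for (th in c(-2, 0.4, 3)) {
      total <- sum(w * reorientation_bearing_density(grid, th, cfg))
      expect_equal(total, 1, tolerance = 1e-8)
    }
    # balance identity: kappa(theta) - int kappa(theta') q(theta|theta')
    # dtheta' = cos(theta), uniformly on a 64-point grid
    kap <- function(th) 1 + cfg$h * cos(th)
    for (th in thetas) {
      integral <- sum(w * kap(grid) *
                        reorientation_bearing_density(th, grid, cfg))
      expect_equal(kap(th) - integral, cos(th), tolerance = 1e-8)
    }
  }
  # isotropic case: uniform; a = -1 biases straight up the density gradient
  cfg_iso <- reorient_config(0, 0, 1)
  expect_equal(reorientation_bearing_density(c(-1, 0, 2), 0.3, cfg_iso),
               rep(1 / (2 * pi), 3))
  cfg_grad <- reorient_config(-1, 0, 0)
  dens <- reorientation_bearing_density(grid, 0, cfg_grad)
  expect_equal(abs(grid[which.max(dens)]), pi, tolerance = 0.01)
})

test_that("with a flat target only refreshment fires, at exponential times", {
  tg <- flat_target(2)
  cfg <- bounce_config(sigma = 1, refresh_rate = 2)
  path <- simulate_pdmp(tg, "bps", cfg, c(0, 0), c(1, 0), t_end = 5000,
                        seed = 74)
  expect_true(all(path$events$kind == "refresh"))
  gaps <- diff(c(path$t0, path$events$time))
  expect_gt(length(gaps), 8000)
  ks <- suppressWarnings(stats::ks.test(gaps, function(q)
    stats::pexp(q, rate = 2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("event simulation is reproducible and respects the half-space property", {
  tg <- bimodal_2d()
  cfg <- bounce_config(sigma = 1, rho = 0.5, omega = 0.5, refresh_rate = 0.2,
                       refresh_eta = 0.5, refresh_kappa = 1)
  p1 <- simulate_pdmp(tg, "halfspace", cfg, c(1, 0), c(1, 0), t_end = 300,
                      seed = 75)
  p2 <- simulate_pdmp(tg, "halfspace", cfg, c(1, 0), c(1, 0), t_end = 300,
                      seed = 75)
  expect_identical(p1$events, p2$events)
  ev <- p1$events[p1$events$kind == "bounce", ]
  expect_gt(nrow(ev), 50)
  for (i in seq_len(nrow(ev))) {
    gU <- -grad_log_density(tg, c(ev$x[i], ev$y[i]))
    expect_gt(sum(gU * c(ev$vx_before[i], ev$vy_before[i])), 0)
    expect_lt(sum(gU * c(ev$vx_after[i], ev$vy_after[i])), 0)
  }
})

test_that("piecewise-linear interpolation is consistent with the event list", {
  tg <- bimodal_2d()
  cfg <- bounce_config(sigma = 1, rho = 1, omega = 1, refresh_rate = 0.5)
  path <- simulate_pdmp(tg, "bps", cfg, c(1, 0), c(1, 0), t_end = 50,
                        seed = 76)
  ev <- path$events
  # positions at event times match the records
  for (i in seq_len(min(nrow(ev), 20))) {
    expect_equal(drop(path_position_at(path, ev$time[i])),
                 c(x = ev$x[i], y = ev$y[i]), tolerance = 1e-10)
  }
  # segment midpoints are the mean of the endpoints
  knots <- movetarget:::path_knots(path)
  for (i in seq_len(min(length(knots$times) - 1, 10))) {
    tm <- (knots$times[i] + knots$times[i + 1]) / 2
    expect_equal(drop(path_position_at(path, tm)),
                 c(x = mean(knots$pos[i:(i + 1), 1]),
                   y = mean(knots$pos[i:(i + 1), 2])), tolerance = 1e-10)
  }
  # regular-grid slopes recover the stored velocities
  tr <- path_to_trajectory(path, 1e-3)
  k <- 500   # inside the first segment if it is long enough
  if (ev$time[1] > (k + 1) * 1e-3) {
    slope <- c(diff(tr$x[k + 0:1]), diff(tr$y[k + 0:1])) / 1e-3
    v0 <- c(ev$vx_before[1], ev$vy_before[1])
    expect_equal(slope, v0, tolerance = 1e-6)
  }
  expect_error(path_position_at(path, 51), "horizon")
})

test_that("reorientation model runs and pools speeds at the size-biased law", {
  tg <- bimodal_2d()
  cfg <- reorient_config(a = -1 / 3, b = 2 / 3, h = 1, sigma = 1,
                         rho_speed = 0.5, refresh_rate = 0.2,
                         refresh_eta = 0.5, refresh_kappa = 1)
  path <- simulate_pdmp(tg, "reorient", cfg, c(1, 0), c(1, 0), t_end = 2000,
                        seed = 77)
  ev <- path$events
  expect_true(all(c("reorientation", "refresh") %in% ev$kind))
  # speeds drawn at reorientation events follow the size-biased law
  re <- ev[ev$kind == "reorientation", ]
  sp <- sqrt(re$vx_after^2 + re$vy_after^2)
  cdf <- function(q) vapply(q, function(s)
    stats::integrate(sizebiased_speed_density, 0, s, sigma = 1)$value,
    numeric(1))
  ks <- suppressWarnings(stats::ks.test(sp, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("post-refresh velocities are stationary normal", {
  tg <- bimodal_2d()
  cfg <- bounce_config(sigma = 1, rho = 0.5, omega = 0.5, refresh_rate = 0.5,
                       refresh_eta = 0.5, refresh_kappa = 1)
  path <- simulate_pdmp(tg, "halfspace", cfg, c(1, 0), NULL, t_end = 4000,
                        seed = 78)
  ev <- path$events[path$events$kind == "refresh", ]
  expect_gt(nrow(ev), 1000)
  expect_gt(suppressWarnings(stats::ks.test(ev$vx_after, "pnorm"))$p.value,
            0.01)
  expect_gt(suppressWarnings(stats::ks.test(ev$vy_after, "pnorm"))$p.value,
            0.01)
})
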