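test_that("Langevin drift is half the diffusivity times the score", {
  sn <- std_normal_1d()
  sp1 <- langevin_spec(sn, 1)
  expect_equal(sp1$drift(0), 0)
  expect_equal(sp1$drift(2), -1)
  expect_equal(sp1$noise(2), 1)
  # doubling gamma doubles the drift and the squared noise scale
  sp2 <- langevin_spec(sn, 2)
  expect_equal(sp2$drift(2), 2 * sp1$drift(2))
  expect_equal(sp2$noise(0)^2, 2 * sp1$noise(0)^2)
})

test_that("kinetic Langevin drift has the friction/forcing structure", {
  tg <- gaussian_linexp(1, beta = 1)          # U = x^2/2, grad U = x
  sp <- kinetic_langevin_spec(tg, gamma = 5, alpha = 1)
  # dv = -2.5 grad U - 0.2 v; at the mode with zero velocity nothing moves
  expect_equal(sp$drift(c(0, 0)), c(0, 0))
  st <- c(1.5, -0.7)
  expect_equal(sp$drift(st), c(-0.7, -2.5 * 1.5 - 0.2 * (-0.7)))
  expect_equal(sp$noise(st), c(0, 1))
})

test_that("kinetic Langevin velocity reaches its stationary variance gamma/2", {
  # free motion (flat target): velocity is an OU process
  tg <- flat_target(1)
  gamma <- 3; alpha <- 1.5
  sp <- kinetic_langevin_spec(tg, gamma, alpha)
  tr <- simulate_em(sp, c(0, 0), dt = 0.01, t_end = 8000, seed = 61,
                    thin = 40)
  v <- tr$vx[tr$t > 400]
  expect_lt(abs(stats::var(v) - gamma / 2) / (gamma / 2), 0.1)
})

test_that("the generic D/Q construction reproduces both Langevin models", {
  tg <- bivn_aniso()
  gamma <- 1.6
  grad_H <- function(x) -grad_log_density(tg, x)
  # D = (gamma/2) I on position, Q = 0: first-order Langevin
  sp_ma <- ma_spec(grad_H, function(x) diag(gamma / 2, 2),
                   function(x) matrix(0, 2, 2), 2)
  sp_l <- langevin_spec(tg, gamma)
  set.seed(62)
  for (i in 1:100) {
    x <- stats::runif(2, -4, 4)
    expect_lt(max(abs(sp_ma$drift(x) - sp_l$drift(x))), 1e-10)
    expect_lt(max(abs(sp_ma$noise(x) - sp_l$noise(x))), 1e-12)
  }
  # second-order block form: kinetic Langevin.
  # With H(x, v) = U(x) + |v|^2 / gamma (velocity variance gamma/2),
  # D = diag(0, alpha/2) and the symplectic-like Q with gamma/2 blocks
  # recover the kinetic drift.
  alpha <- 0.8
  grad_H2 <- function(z) {
    c(-grad_log_density(tg, z[1:2]), 2 * z[3:4] / gamma)
  }
  D2 <- function(z) diag(c(0, 0, alpha / 2, alpha / 2))
  Q2 <- function(z) rbind(cbind(matrix(0, 2, 2), diag(-gamma / 2, 2)),
                          cbind(diag(gamma / 2, 2), matrix(0, 2, 2)))
  sp_ma2 <- ma_spec(grad_H2, D2, Q2, 4)
  sp_k <- kinetic_langevin_spec(tg, gamma, alpha)
  set.seed(63)
  for (i in 1:100) {
    z <- stats::runif(4, -3, 3)
    expect_lt(max(abs(sp_ma2$drift(z) - sp_k$drift(z))), 1e-10)
    expect_lt(max(abs(sp_ma2$noise(z) - sp_k$noise(z))), 1e-12)
  }
  # constant coefficients have zero divergence correction
  spc <- ma_spec(grad_H, function(x) diag(0.5, 2),
                 function(x) matrix(c(0, 1, -1, 0), 2), 2)
  expect_equal(spc$drift(c(1, 2)),
               drop(-(diag(0.5, 2) + matrix(c(0, 1, -1, 0), 2)) %*%
                      grad_H(c(1, 2))), tolerance = 1e-9)
  # invalid parts are rejected
  expect_error(ma_spec(grad_H, function(x) matrix(c(1, 2, 0, 1), 2),
                       function(x) matrix(0, 2, 2), 2), "symmetric")
  expect_error(ma_spec(grad_H, function(x) diag(1, 2),
                       function(x) matrix(c(0, 1, 1, 0), 2), 2), "skew")
})

test_that("position-dependent diffusion has inverse-density rate and no drift", {
  sn <- std_normal_1d()
  sp <- position_dependent_spec(sn, alpha = 1)
  expect_equal(sp$drift(0), 0)
  expect_equal(sp$drift(2), 0)
  expect_equal(sp$noise(0), 1)                 # L(0) = 0
  expect_equal(sp$noise(2), exp(1))            # exp(-L/2) = exp(x^2/4)
  # constant rate delta = 0, delta0 = log(gamma) collapses to Langevin
  tg <- gaussian_linexp(1, beta = 1)
  gamma <- 1.7
  spc <- position_dependent_spec(tg, delta = 0, delta0 = log(gamma))
  spl <- langevin_spec(tg, gamma)
  for (x in c(-2, 0.3, 1.9)) {
    expect_equal(spc$drift(x), spl$drift(x), tolerance = 1e-12)
    expect_equal(spc$noise(x), spl$noise(x), tolerance = 1e-12)
  }
})

test_that("polar velocity model steers the bearing by the perpendicular gradient", {
  tg <- bivn_aniso()
  sp <- polar_velocity_spec(tg, sigma = 1, gamma_s = 1, alpha_theta = 0.5)
  # at (0,2) with s = 1, theta = 0: grad U = (0, 2), drift = -s cos(theta)*2
  dr <- sp$drift(c(0, 2, 1, 0))
  expect_equal(dr[1], 1)        # dx = s cos(theta)
  expect_equal(dr[2], 0)
  expect_equal(dr[4], -2)
  # flat target: bearing is driftless (pure circular Brownian motion)
  spf <- polar_velocity_spec(flat_target(2), sigma = 1, gamma_s = 1,
                             alpha_theta = 0.5)
  expect_equal(spf$drift(c(3, -1, 1.2, 0.7))[4], 0)
  # Rayleigh-targeting speed drift: -(gamma_s/2)(s/sigma^2 - 1/s)
  expect_equal(sp$drift(c(0, 0, 2, 0))[3], -(1 / 2) * (2 - 1 / 2))
  # constant-speed runs conserve the speed exactly
  spc <- polar_velocity_spec(tg, sigma = 1, alpha_theta = 2.5,
                             constant_speed = TRUE)
  tr <- simulate_em(spc, c(2, 0, 1, 0), dt = 0.01, t_end = 50, seed = 64)
  expect_equal(range(tr$s), c(1, 1))
})

test_that("the integrator is deterministic, exact when noiseless, and aborts on blow-up", {
  sn <- std_normal_1d()
  sp <- langevin_spec(sn, 1)
  t1 <- simulate_em(sp, 0.5, 0.01, 20, seed = 65)
  t2 <- simulate_em(sp, 0.5, 0.01, 20, seed = 65)
  expect_identical(t1$x, t2$x)
  # zero drift and zero noise: constant path
  null_spec <- movetarget:::new_diffusion_spec(
    drift = function(x) 0, noise = function(x) 0,
    state_names = "x", d = 1, kind = "null")
  tr <- simulate_em(null_spec, 1.23, 0.1, 10)
  expect_true(all(tr$x == 1.23))
  # exploding drift aborts with a step index
  bad <- movetarget:::new_diffusion_spec(
    drift = function(x) x^3, noise = function(x) 0.1,
    state_names = "x", d = 1, kind = "bad")
  expect_error(simulate_em(bad, 3, 0.5, 50, seed = 66), "non-finite state")
})

test_that("Langevin long-run position variance matches the target", {
  sn <- std_normal_1d()
  tr <- simulate_em(langevin_spec(sn, 1), 0, 0.01, 1e4, seed = 67, thin = 10)
  xs <- tr$x[tr$t > 1000]
  expect_lt(abs(stats::var(xs) - 1), 0.1)
})

test_that("trajectories round-trip through CSV with their sidecar", {
  sn <- std_normal_1d()
  tr <- simulate_em(langevin_spec(sn, 1), 0, 0.01, 5, seed = 68)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f)
  expect_equal(tr2$x, tr$x, tolerance = 1e-12)
  expect_equal(attr(tr2, "dt"), attr(tr, "dt"))
  expect_equal(attr(tr2, "seed"), attr(tr, "seed"))
  unlink(c(f, paste0(f, ".json")))
})
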