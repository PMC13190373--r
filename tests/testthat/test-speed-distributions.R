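test_that("Rice density normalises, reduces to Rayleigh, and matches its sampler", {
  for (pars in list(c(0, 1), c(2, 0.7), c(5, 1.3))) {
    nu <- pars[1]; b <- pars[2]
    total <- stats::integrate(function(s) rice_density(s, nu, b), 0, Inf,
                              rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
  }
  # nu = 0 is Rayleigh(b)
  s <- seq(0.01, 6, by = 0.07)
  b <- 1.4
  expect_equal(rice_density(s, 0, b), s / b^2 * exp(-s^2 / (2 * b^2)),
               tolerance = 1e-12)
  expect_equal(rice_density(0, 3, 1), 0)
  # sample mean agrees with the quadrature mean to 3 standard errors
  set.seed(51)
  nu <- 2; b <- 0.8; n <- 1e5
  draws <- rice_sample(n, nu, b)
  qmean <- stats::integrate(function(s) s * rice_density(s, nu, b), 0, Inf,
                            rel.tol = 1e-10)$value
  qvar <- stats::integrate(function(s) (s - qmean)^2 * rice_density(s, nu, b),
                           0, Inf, rel.tol = 1e-10)$value
  expect_lt(abs(mean(draws) - qmean), 3 * sqrt(qvar / n))
  # large-argument stability of the log-space Bessel evaluation
  expect_true(is.finite(rice_density(500, 500, 1)))
})

test_that("size-biased speed law is Maxwell-Boltzmann with mode sigma*sqrt(2)", {
  sigma <- 1.7
  total <- stats::integrate(function(s) sizebiased_speed_density(s, sigma),
                            0, Inf, rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-8)
  # equals s * Rayleigh(s; sigma) / mean with mean sigma*sqrt(pi/2)
  s <- seq(0.05, 8, by = 0.11)
  ray <- s / sigma^2 * exp(-s^2 / (2 * sigma^2))
  expect_equal(sizebiased_speed_density(s, sigma),
               s * ray / (sigma * sqrt(pi / 2)), tolerance = 1e-12)
  opt <- stats::optimize(function(s) sizebiased_speed_density(s, sigma),
                         c(0, 8), maximum = TRUE)
  expect_equal(opt$maximum, sigma * sqrt(2), tolerance = 1e-5)
})

test_that("speed update satisfies the size-biased balance identity", {
  # int s' q(s | s') p(s') ds' = s p(s) with p = Rayleigh(sigma)
  sigma <- 1.2
  p_ray <- function(s) s / sigma^2 * exp(-s^2 / (2 * sigma^2))
  for (rho in c(0, 0.5, 0.9)) {
    for (s in sigma * c(0.5, 1, 2)) {
      lhs <- stats::integrate(function(sp)
        sp * speed_update_density(s, sp, sigma, rho) * p_ray(sp),
        0, Inf, rel.tol = 1e-10)$value
      expect_equal(lhs, s * p_ray(s), tolerance = 1e-6)
    }
  }
})

test_that("speed update conditional normalises and its joint is symmetric", {
  sigma <- 1; rho <- 0.6
  for (s in c(0.4, 1, 2.5)) {
    total <- stats::integrate(function(sp)
      speed_update_density(sp, s, sigma, rho), 0, Inf,
      rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
  }
  # joint q(s, s') = q(s'|s) p*(s) is exchange-symmetric
  grid <- expand.grid(s = c(0.5, 1.1, 2), sp = c(0.7, 1.6, 2.4))
  for (i in seq_len(nrow(grid))) {
    a <- speed_update_density(grid$sp[i], grid$s[i], sigma, rho) *
      sizebiased_speed_density(grid$s[i], sigma)
    b <- speed_update_density(grid$s[i], grid$sp[i], sigma, rho) *
      sizebiased_speed_density(grid$sp[i], sigma)
    expect_equal(a, b, tolerance = 1e-10)
  }
  # rho = 0: independent size-biased draw
  sp <- seq(0.1, 5, by = 0.3)
  expect_equal(speed_update_density(sp, 1.3, sigma, 0),
               sizebiased_speed_density(sp, sigma), tolerance = 1e-12)
  # sampler matches the density's first two moments (3 SE)
  set.seed(52)
  s0 <- 1.5; n <- 2e4
  draws <- replicate(n, speed_update_sample(s0, sigma, rho))
  qm <- stats::integrate(function(sp)
    sp * speed_update_density(sp, s0, sigma, rho), 0, Inf)$value
  qv <- stats::integrate(function(sp)
    (sp - qm)^2 * speed_update_density(sp, s0, sigma, rho), 0, Inf)$value
  expect_lt(abs(mean(draws) - qm), 3 * sqrt(qv / n))
})

test_that("Rice refreshment is in detailed balance with the Rayleigh speed law", {
  sigma <- 1.1; eta <- 0.6
  b <- sigma * sqrt(1 - eta^2)
  p_ray <- function(s) s / sigma^2 * exp(-s^2 / (2 * sigma^2))
  q <- function(sp, s) rice_density(sp, s * eta, b)
  grid <- expand.grid(s = c(0.3, 0.9, 1.7, 3), sp = c(0.5, 1.2, 2.2))
  for (i in seq_len(nrow(grid))) {
    s <- grid$s[i]; sp <- grid$sp[i]
    lhs <- p_ray(s) * q(sp, s)
    rhs <- p_ray(sp) * q(s, sp)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  # chained updates preserve Rayleigh(sigma)
  set.seed(53)
  n <- 1e5
  s <- sigma * sqrt(-2 * log(stats::runif(1)))
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- rice_refresh_speed(s, sigma, eta)
    out[i] <- s
  }
  ks <- suppressWarnings(stats::ks.test(out, function(q)
    1 - exp(-q^2 / (2 * sigma^2))))
  expect_gt(ks$p.value, 0.01)
  # eta = 0: independent Rayleigh draw; eta -> 1: concentrates at s
  set.seed(54)
  d0 <- replicate(2000, rice_refresh_speed(2, sigma, 0))
  expect_gt(suppressWarnings(stats::ks.test(d0, function(q)
    1 - exp(-q^2 / (2 * sigma^2))))$p.value, 0.01)
  d1 <- replicate(200, rice_refresh_speed(2, sigma, 0.9999))
  expect_lt(max(abs(d1 - 2)), 0.1)
})

test_that("von Mises turns are symmetric, centred, and uniform at kappa 0", {
  set.seed(55)
  n <- 1e5
  u <- vapply(seq_len(n), function(i) vonmises_turn(0.3, 0), numeric(1))
  ks <- suppressWarnings(stats::ks.test(u, function(q) (q + pi) / (2 * pi)))
  expect_gt(ks$p.value, 0.01)
  # concentrated: circular mean close to the current bearing
  th0 <- 2.0
  d <- vapply(seq_len(2e4), function(i) vonmises_turn(th0, 20), numeric(1))
  cm <- atan2(mean(sin(d)), mean(cos(d)))
  expect_lt(abs(cm - th0), 0.02)
  # symmetry of the turn about zero
  turns <- wrap_angle(d - th0)
  expect_gt(suppressWarnings(stats::ks.test(turns, -turns))$p.value, 0.01)
})
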