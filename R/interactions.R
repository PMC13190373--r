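#' Joint utilisation distributions for interacting individuals
#'
#' The naive way to couple n individuals - adding a pairwise attraction
#' term to the joint log-density ([naive_joint_log_density()]) - changes
#' each individual's marginal distribution, destroying the interpretation
#' of the selection coefficients. The latent-kernel construction used here
#' preserves the marginals exactly: with a symmetric spatially homogeneous
#' interaction kernel \eqn{\psi(\cdot|z)} (Gaussian with scale \eqn{\varsigma}),
#' \deqn{\pi(x_1,\ldots,x_n) = \prod_i \pi(x_i)\;
#'   \int_z \frac{\prod_i \psi(x_i|z)^{n-1}}
#'              {m_{n-1}\,\Psi_{n-1}(z)^{n-1}}\,dz,}
#' where \eqn{\Psi_{n-1}(z) = \int \pi(u)\psi(u|z)^{n-1}du} and
#' \eqn{m_{n-1} = \int \psi(u|0)^{n-1}du} (analytic for the Gaussian
#' kernel). Integrating out all individuals but one returns \eqn{\pi}
#' exactly. The z-integral is evaluated by the trapezoid rule on a fixed
#' grid, stabilised by log-sum-exp.
#'
#' Restricted to 1-D base targets; the construction is dimension-free but
#' the quadrature validation is only practical in one dimension.
#'
#' @param base a 1-D `mvt_target`, the per-individual utilisation
#'   distribution.
#' @param n number of individuals (>= 2).
#' @param kernel_scale Gaussian kernel scale \eqn{\varsigma}; smaller values
#'   give stronger cohesion.
#' @param grid_n number of quadrature points for the latent z integral.
#' @param grid_range numeric length-2 range for z (default: the base
#'   target's effective support widened by \eqn{6\varsigma}).
#' @return an object of class `mvt_joint_target`.
#' @export
interaction_target <- function(base, n = 2, kernel_scale, grid_n = 2001,
                               grid_range = NULL) {
  stopifnot(base$dim == 1L, n >= 2)
  stopifnot_scalar(kernel_scale, "kernel_scale", positive = TRUE)
  vs <- kernel_scale
  rng <- grid_range %||% (target_support(base)[, 1] + c(-6, 6) * vs)
  z <- seq(rng[1], rng[2], length.out = grid_n)
  hz <- z[2] - z[1]
  wz <- rep(hz, grid_n); wz[c(1, grid_n)] <- hz / 2
  logpi_z <- vapply(z, function(u) log_density(base, u), numeric(1))
  logZ <- log(trapz(z, exp(logpi_z - max(logpi_z)))) + max(logpi_z)
  # Psi_{n-1}(z) = int pi(u) psi(u|z)^{n-1} du on the same grid
  m1 <- n - 1
  logPsi <- vapply(seq_len(grid_n), function(k) {
    lt <- (logpi_z - logZ) + m1 * (-0.5 * log(2 * pi * vs^2) -
                                     (z - z[k])^2 / (2 * vs^2)) + log(wz)
    mx <- max(lt)
    mx + log(sum(exp(lt - mx)))
  }, numeric(1))
  log_m <- (2 - n) / 2 * log(2 * pi * vs^2) - 0.5 * log(n - 1)
  structure(
    list(base = base, n = n, kernel_scale = vs, z = z, z2 = z^2, wz = wz,
         logPsi = logPsi, log_m = log_m, logZ = logZ,
         grid_n = grid_n, grid_range = rng,
         # constant parts of the z integrand, precomputed for the
         # per-step gradient evaluations of the simulators
         lt_const = log(wz) - log_m - m1 * logPsi -
           n * m1 * 0.5 * log(2 * pi * vs^2),
         base_grad = make_grad_fn(base)),
    class = "mvt_joint_target")
}

#' @export
print.mvt_joint_target <- function(x, ...) {
  cat("<joint target> n =", x$n, " kernel scale =", x$kernel_scale,
      " z grid:", x$grid_n, "points on [",
      round(x$grid_range[1], 2), ",", round(x$grid_range[2], 2), "]\n")
  invisible(x)
}

# log weights of the z integrand at locations xs (before normalisation).
# sum_i log psi(x_i|z)^{n-1} collapses to a single quadratic in z, so the
# whole integrand costs three fused vector operations on the grid.
joint_z_logterms <- function(jt, xs) {
  m1 <- jt$n - 1
  c1 <- m1 / (2 * jt$kernel_scale^2)
  jt$lt_const - c1 * (sum(xs^2) - 2 * jt$z * sum(xs) + jt$n * jt$z2)
}

#' Joint log-density of the interacting system
#'
#' Exchange-symmetric by construction; each individual's marginal is the
#' base utilisation distribution. A warning is raised when the z-integrand
#' carries non-negligible mass at the edge of the quadrature grid.
#'
#' @param jt an [interaction_target()].
#' @param xs numeric vector of the n individuals' (1-D) locations.
#' @return scalar log-density (normalised up to the base target's own
#'   constant convention).
#' @export
joint_log_density <- function(jt, xs) {
  stopifnot(length(xs) == jt$n)
  lt <- joint_z_logterms(jt, xs)
  mx <- max(lt)
  tot <- sum(exp(lt - mx))
  edge <- max(exp(lt[1] - mx), exp(lt[jt$grid_n] - mx)) * jt$grid_n
  if (edge / tot > 1e-3)
    warning("z-quadrature grid may be too narrow for these locations; ",
            "widen grid_range", call. = FALSE)
  base_ld <- sum(vapply(xs, function(x) log_density(jt$base, x),
                        numeric(1))) - jt$n * jt$logZ
  base_ld + mx + log(tot)
}

#' Gradient of the joint log-density
#'
#' One length-n gradient entry per individual. The base score is analytic;
#' the interaction term's derivative is evaluated inside the same
#' z-quadrature (exact for the Gaussian kernel), so simulation steps do not
#' pay for fresh finite differencing.
#'
#' @inheritParams joint_log_density
#' @export
joint_grad <- function(jt, xs) {
  stopifnot(length(xs) == jt$n)
  lt <- joint_z_logterms(jt, xs)
  w <- exp(lt - max(lt))
  m1 <- jt$n - 1
  vs2 <- jt$kernel_scale^2
  zbar <- sum(w * jt$z) / sum(w)
  vapply(seq_len(jt$n), function(i) {
    jt$base_grad(xs[i]) + m1 * (zbar - xs[i]) / vs2
  }, numeric(1))
}

#' Naive pairwise-potential joint density
#'
#' \deqn{\log\pi(x_1,\ldots,x_n) = \sum_i L(x_i) +
#'   \beta_{Int}\sum_{i<j}\zeta(x_i, x_j) + const,}
#' with a Gaussian-shaped attraction \eqn{\zeta(x, y) =
#' \exp(-(x-y)^2/2\varsigma_\zeta^2)}. Simple and log-linear, but the
#' marginals it induces differ from \eqn{\pi}; provided to quantify that
#' distortion.
#'
#' @param base the per-individual target.
#' @param zeta_scale interaction length scale \eqn{\varsigma_\zeta}.
#' @param beta_int interaction strength \eqn{\beta_{Int}}.
#' @param xs individuals' locations.
#' @export
naive_joint_log_density <- function(base, zeta_scale, beta_int, xs) {
  ld <- sum(vapply(xs, function(x) log_density(base, x), numeric(1)))
  n <- length(xs)
  inter <- 0
  if (n >= 2) {
    pr <- utils::combn(n, 2)
    inter <- sum(exp(-(xs[pr[1, ]] - xs[pr[2, ]])^2 / (2 * zeta_scale^2)))
  }
  ld + beta_int * inter
}

#' Quadrature marginal of a pair of interacting individuals
#'
#' Integrates the n = 2 joint density over the partner's location on a
#' grid, returning the (normalised) marginal density of one individual;
#' used to verify marginal preservation.
#'
#' @param jt an [interaction_target()] with `n = 2`.
#' @param xgrid evaluation grid for the kept individual.
#' @param ygrid integration grid for the partner (defaults to the z grid).
#' @return tibble with columns `x`, `marginal`, and the base density
#'   `target` (both normalised over `xgrid`).
#' @export
interaction_marginal <- function(jt, xgrid, ygrid = NULL) {
  stopifnot(jt$n == 2L)
  ygrid <- ygrid %||% jt$z
  vs2 <- jt$kernel_scale^2
  # A[i,k] = psi(x_i | z_k); B[j,k] = psi(y_j | z_k)
  A <- exp(-outer(xgrid, jt$z, "-")^2 / (2 * vs2)) / sqrt(2 * pi * vs2)
  B <- exp(-outer(ygrid, jt$z, "-")^2 / (2 * vs2)) / sqrt(2 * pi * vs2)
  pix <- exp(vapply(xgrid, function(u) log_density(jt$base, u), numeric(1)) -
               jt$logZ)
  piy <- exp(vapply(ygrid, function(u) log_density(jt$base, u), numeric(1)) -
               jt$logZ)
  core <- sweep(A, 2, jt$wz / exp(jt$logPsi), "*") %*% t(B)  # I(x, y)
  joint <- core * outer(pix, piy)
  ny <- length(ygrid)
  wy <- c(diff(ygrid)[1] / 2,
          (ygrid[3:ny] - ygrid[1:(ny - 2)]) / 2,
          diff(ygrid)[ny - 1] / 2)
  marg <- drop(joint %*% wy)
  tibble::tibble(x = xgrid, marginal = marg, target = pix)
}

#' @rdname interaction_marginal
#' @param base,zeta_scale,beta_int see [naive_joint_log_density()].
#' @export
naive_marginal <- function(base, zeta_scale, beta_int, xgrid, ygrid) {
  Lx <- vapply(xgrid, function(u) log_density(base, u), numeric(1))
  Ly <- vapply(ygrid, function(u) log_density(base, u), numeric(1))
  lz <- outer(xgrid, ygrid, function(a, b)
    beta_int * exp(-(a - b)^2 / (2 * zeta_scale^2)))
  lj <- outer(Lx, Ly, "+") + lz
  J <- exp(lj - max(lj))
  ny <- length(ygrid)
  wy <- c(diff(ygrid)[1] / 2,
          (ygrid[3:ny] - ygrid[1:(ny - 2)]) / 2,
          diff(ygrid)[ny - 1] / 2)
  marg <- drop(J %*% wy)
  marg <- marg / trapz(xgrid, marg)
  tgt <- exp(Lx - max(Lx))
  tgt <- tgt / trapz(xgrid, tgt)
  tibble::tibble(x = xgrid, marginal = marg, target = tgt)
}

#' Simulate interacting individuals
#'
#' Treats the n individuals as a single point in \eqn{R^n} and integrates
#' a targeted diffusion (first-order or kinetic Langevin) built on the
#' joint log-density gradient, so the stationary law of the system is the
#' joint distribution of [interaction_target()] and each individual's
#' long-run marginal is the base utilisation distribution.
#'
#' @param jt an [interaction_target()].
#' @param movement `"kinetic"` or `"langevin"`.
#' @param gamma,alpha movement parameters (alpha only for kinetic).
#' @param x0s initial locations (length n).
#' @param dt,t_end,seed,thin integrator settings, as in [simulate_em()].
#' @return an `mvt_trajectory` with columns `x1 ... xn` (plus velocities
#'   for the kinetic model).
#' @export
simulate_interacting <- function(jt, movement = c("kinetic", "langevin"),
                                 gamma, alpha = NULL, x0s, dt, t_end,
                                 seed = NULL, thin = 1L) {
  movement <- match.arg(movement)
  n <- jt$n
  stopifnot(length(x0s) == n)
  xn <- paste0("x", seq_len(n))
  if (movement == "langevin") {
    ns <- rep(sqrt(gamma), n)
    spec <- new_diffusion_spec(
      drift = function(x) (gamma / 2) * joint_grad(jt, x),
      noise = function(x) ns,
      state_names = xn, d = n, kind = "interacting_langevin")
    return(simulate_em(spec, x0s, dt, t_end, seed = seed, thin = thin))
  }
  stopifnot(!is.null(alpha))
  ip <- seq_len(n); iv <- n + ip
  fric <- alpha / gamma
  ns <- c(rep(0, n), rep(sqrt(alpha), n))
  sa <- sqrt(alpha)
  spec <- new_diffusion_spec(
    drift = function(z) {
      v <- z[iv]
      c(v, (gamma / 2) * joint_grad(jt, z[ip]) - fric * v)
    },
    noise = function(z) ns,
    step = function(z, dt, sqdt, xi) {
      x <- z[ip]; v <- z[iv]
      v <- v + ((gamma / 2) * joint_grad(jt, x) - fric * v) * dt +
        sa * sqdt * xi[iv]
      c(x + v * dt, v)
    },
    state_names = c(xn, paste0("v", xn)), d = n,
    kind = "interacting_kinetic")
  simulate_em(spec, c(x0s, rep(0, n)), dt, t_end, seed = seed, thin = thin)
}
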