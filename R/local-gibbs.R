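#' Movement kernels for the local Gibbs step
#'
#' Symmetric, spatially homogeneous kernels \eqn{\psi(\cdot | x)} used by the
#' discrete-time local Gibbs movement model. `kernel_uniform_disc()` is
#' uniform on a disc (or interval in 1-D) of radius `r`; `kernel_normal()` is
#' isotropic normal with standard deviation `sd`; `kernel_point()` is the
#' degenerate identity kernel (useful only for checks).
#'
#' @param r disc radius.
#' @param dim spatial dimension.
#' @return a kernel object with a `sample(x)` method and a support radius
#'   used to grid the acceptance bound.
#' @export
kernel_uniform_disc <- function(r, dim = 2) {
  stopifnot_scalar(r, "r", positive = TRUE)
  sample_fn <- if (dim == 1) {
    function(x) x + stats::runif(1, -r, r)
  } else {
    function(x) {
      repeat {
        z <- stats::runif(dim, -r, r)
        if (sum(z^2) <= r^2) return(x + z)
      }
    }
  }
  structure(list(sample = sample_fn, radius = r, dim = dim,
                 name = sprintf("uniform_disc(r=%g)", r)),
            class = "mvt_kernel")
}

#' @rdname kernel_uniform_disc
#' @param sd kernel standard deviation per coordinate.
#' @export
kernel_normal <- function(sd, dim = 2) {
  stopifnot_scalar(sd, "sd", positive = TRUE)
  structure(list(sample = function(x) x + stats::rnorm(dim, 0, sd),
                 radius = 6 * sd, dim = dim,
                 name = sprintf("normal(sd=%g)", sd)),
            class = "mvt_kernel")
}

#' @rdname kernel_uniform_disc
#' @export
kernel_point <- function(dim = 2) {
  structure(list(sample = function(x) x, radius = 0, dim = dim,
                 name = "point"),
            class = "mvt_kernel")
}

#' One step of the local Gibbs movement model
#'
#' The discrete-time, rejection-free two-stage construction: draw a latent
#' point \eqn{z \sim \psi(\cdot | x)}, then draw the next location from
#' \eqn{\psi(\cdot | z)\,\pi(\cdot)} renormalised over the kernel's support.
#' If the current location is distributed according to \eqn{\pi}, so is the
#' next one; iterating the step therefore has the utilisation distribution as
#' its stationary law. The second stage is performed by exact rejection
#' sampling: proposals from \eqn{\psi(\cdot|z)} are accepted with probability
#' \eqn{\pi(x')/M_z}, where \eqn{M_z} bounds \eqn{\pi} over a grid on the
#' kernel support inflated by a 1.2 safety factor.
#'
#' @param target an `mvt_target`.
#' @param kernel a kernel from [kernel_uniform_disc()] and friends.
#' @param x current location.
#' @param max_attempts rejection-sampling cap; exceeding it is an error that
#'   names the bound in use.
#' @return the next location (numeric vector).
#' @export
local_gibbs_step <- function(target, kernel, x, max_attempts = 1e5) {
  check_dim(target, x)
  local_gibbs_step_impl(make_logdens_fn(target), target$dim, kernel, x,
                        max_attempts)
}

local_gibbs_step_impl <- function(ld, dim, kernel, x, max_attempts) {
  z <- kernel$sample(x)
  if (kernel$radius == 0) return(z)
  log_m <- local_gibbs_log_bound(ld, dim, kernel, z)
  n_try <- 0L
  while (n_try < max_attempts) {
    n_try <- n_try + 1L
    prop <- kernel$sample(z)
    if (log(stats::runif(1)) < ld(prop) - log_m) return(prop)
  }
  stop(sprintf(
    "local Gibbs rejection sampler exhausted %d attempts (log bound %.6g)",
    max_attempts, log_m), call. = FALSE)
}

# log of M_z: grid maximum of log pi over the kernel support around z,
# plus log(1.2) safety.
local_gibbs_log_bound <- function(ld, dim, kernel, z) {
  r <- kernel$radius
  if (dim == 1) {
    offs <- seq(-r, r, length.out = 41)
    lo <- vapply(offs, function(g) ld(z + g), numeric(1))
  } else {
    g1 <- seq(-r, r, length.out = 21)
    pts <- as.matrix(expand.grid(g1, g1))
    lo <- apply(pts, 1, function(p) ld(z + p))
  }
  max(lo) + log(1.2)
}

#' Iterate the local Gibbs model
#'
#' @inheritParams local_gibbs_step
#' @param x0 starting location.
#' @param n_steps number of steps.
#' @param seed optional RNG seed for reproducibility.
#' @return a tibble with columns `step` and one column per coordinate.
#' @export
simulate_local_gibbs <- function(target, kernel, x0, n_steps, seed = NULL,
                                 max_attempts = 1e5) {
  if (!is.null(seed)) set.seed(seed)
  d <- target$dim
  ld <- make_logdens_fn(target)
  out <- matrix(NA_real_, n_steps + 1L, d)
  out[1, ] <- x <- as.numeric(x0)
  for (j in seq_len(n_steps)) {
    x <- local_gibbs_step_impl(ld, d, kernel, x, max_attempts)
    out[j + 1L, ] <- x
  }
  colnames(out) <- coord_names(d)
  dplyr::bind_cols(tibble::tibble(step = 0:n_steps),
                   tibble::as_tibble(out))
}

coord_names <- function(d) {
  if (d == 1) "x" else if (d == 2) c("x", "y") else paste0("x", seq_len(d))
}
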