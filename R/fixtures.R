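#' Built-in study configurations
#'
#' Ready-made run configurations reproducing the package's reference
#' simulation setups: the drift-free position-dependent diffusion on a
#' standard normal target (`fig1`), the constant-speed polar model on an
#' anisotropic bivariate normal with three bearing diffusivities
#' (`fig2a`-`fig2c`), four velocity-jump variants on a bimodal
#' logistic-mixture target (`fig3a`-`fig3d`), the two-state kinetic
#' Langevin switching model on Laplace-shaped covariates (`fig4`), and a
#' pair of interacting individuals on a bimodal min-Laplace target
#' (`fig5`). Parameters printed in the corresponding model descriptions are
#' used verbatim; horizons and step sizes are package choices recorded in
#' the config.
#'
#' @param name fixture id; see [fixture_names()].
#' @return a run-configuration list that serialises losslessly to JSON.
#' @export
make_fixture <- function(name) {
  ms <- function(dt, t_end, seed) list(dt = dt, t_end = t_end, seed = seed)
  bimodal2d <- list(type = "product", margins = list(
    list(family = "logistic_mixture", locations = c(1, -1),
         scales = c(1, 1), weights = c(0.6, 0.4)),
    list(family = "logistic", location = 0, scale = 1)))
  cfg <- switch(name,
    fig1 = list(
      name = "fig1", model = "diffusion", kind = "position_dependent",
      target = list(type = "product", margins = list(
        list(family = "normal", mean = 0, sd = 1))),
      params = list(alpha = 1),
      sim = ms(0.001, 100, 1), x0 = 0),
    fig2a = ,
    fig2b = ,
    fig2c = list(
      name = name, model = "diffusion", kind = "polar_velocity",
      target = list(type = "product", margins = list(
        list(family = "normal", mean = 0, sd = sqrt(2)),
        list(family = "normal", mean = 0, sd = 1))),
      params = list(sigma = 1, constant_speed = TRUE,
                    alpha_theta = c(fig2a = 0.1, fig2b = 0.5,
                                    fig2c = 2.5)[[name]]),
      sim = ms(0.01, 100, 2), x0 = c(2, 0, 1, 0)),
    fig3a = list(
      name = "fig3a", model = "pdmp", kind = "bps", target = bimodal2d,
      params = list(sigma = 1, rho = 1, omega = 1, refresh_rate = 0.5,
                    refresh_eta = 0, refresh_kappa = 0),
      sim = list(t_end = 200, seed = 3), x0 = c(1, 0)),
    fig3b = list(
      name = "fig3b", model = "pdmp", kind = "gbps", target = bimodal2d,
      params = list(sigma = 1, rho = 1, omega = 0, refresh_rate = 0,
                    refresh_eta = 0, refresh_kappa = 0),
      sim = list(t_end = 200, seed = 3), x0 = c(1, 0)),
    fig3c = list(
      name = "fig3c", model = "pdmp", kind = "halfspace",
      target = bimodal2d,
      params = list(sigma = 1, rho = 0.5, omega = 0.5, refresh_rate = 0.2,
                    refresh_eta = 0.5, refresh_kappa = 1),
      sim = list(t_end = 200, seed = 3), x0 = c(1, 0)),
    fig3d = list(
      name = "fig3d", model = "pdmp", kind = "halfspace",
      target = bimodal2d,
      params = list(sigma = 1, rho = 0.5, omega = 0.5, refresh_rate = 2,
                    refresh_eta = 0.5, refresh_kappa = 20),
      sim = list(t_end = 200, seed = 3), x0 = c(1, 0)),
    fig4 = list(
      name = "fig4", model = "switching",
      target = list(type = "multistate", dim = 1,
                    beta0 = c(log(5 / 3), 0),
                    beta = list(c(2, 0), c(0, 2)),
                    covariates = list(
                      list(family = "laplace", mu = -10, tau = 10),
                      list(family = "laplace", mu = 10, tau = 10))),
      params = list(psi = sqrt(0.0015), gamma = 5, alpha = 1),
      sim = ms(0.02, 20000, 4), x0 = c(-10, 0), s0 = 1),
    fig5 = list(
      name = "fig5", model = "interaction",
      target = list(type = "linexp", dim = 1,
                    covariates = list(
                      list(family = "minlaplace", muA = -10, muB = 10,
                           tau = 10)),
                    beta = 2),
      params = list(kernel_scale = 2, gamma = 0.05, alpha = 0.01, n = 2),
      sim = ms(0.05, 2000, 5), x0 = c(-10, -10)),
    stop("unknown fixture: ", name, call. = FALSE))
  cfg
}

#' @rdname make_fixture
#' @export
fixture_names <- function() {
  c("fig1", "fig2a", "fig2b", "fig2c", "fig3a", "fig3b", "fig3c", "fig3d",
    "fig4", "fig5")
}

#' Validate a run configuration
#'
#' Checks the minimal schema shared by all fixtures: a model id, a target
#' block understood by [target_from_config()], a parameter block and a
#' simulation block with horizon and seed.
#'
#' @param cfg a configuration list.
#' @return `TRUE` invisibly; errors describe the violation.
#' @export
validate_fixture <- function(cfg) {
  need <- c("name", "model", "target", "params", "sim")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("config missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!cfg$model %in% c("diffusion", "pdmp", "switching", "interaction"))
    stop("unknown model id: ", cfg$model, call. = FALSE)
  if (is.null(cfg$sim$t_end) || is.null(cfg$sim$seed))
    stop("sim block must include t_end and seed", call. = FALSE)
  if (cfg$model != "pdmp" && is.null(cfg$sim$dt))
    stop("sim block must include dt", call. = FALSE)
  invisible(target_from_config(cfg$target))
  invisible(TRUE)
}

#' Execute a run configuration
#'
#' Builds the target and model described by the config and runs the
#' appropriate simulator. `t_end` and `seed` can be overridden without
#' touching the config (handy for smoke runs).
#'
#' @param cfg a configuration list from [make_fixture()] (or a fixture
#'   name).
#' @param t_end,seed,thin optional overrides.
#' @return an `mvt_trajectory` or an `mvt_pdmp_path` depending on the
#'   model.
#' @export
run_fixture <- function(cfg, t_end = NULL, seed = NULL, thin = 1L) {
  if (is.character(cfg)) cfg <- make_fixture(cfg)
  validate_fixture(cfg)
  target <- target_from_config(cfg$target)
  t_end <- t_end %||% cfg$sim$t_end
  seed <- seed %||% cfg$sim$seed
  p <- cfg$params
  switch(cfg$model,
    diffusion = {
      spec <- switch(cfg$kind,
        position_dependent = position_dependent_spec(target, p$alpha),
        polar_velocity = polar_velocity_spec(
          target, sigma = p$sigma, alpha_theta = p$alpha_theta,
          constant_speed = isTRUE(p$constant_speed)),
        langevin = langevin_spec(target, p$gamma),
        kinetic_langevin = kinetic_langevin_spec(target, p$gamma, p$alpha),
        stop("unknown diffusion kind: ", cfg$kind, call. = FALSE))
      simulate_em(spec, unlist(cfg$x0), cfg$sim$dt, t_end, seed = seed,
                  thin = thin)
    },
    pdmp = {
      bc <- bounce_config(sigma = p$sigma, rho = p$rho, omega = p$omega,
                          refresh_rate = p$refresh_rate,
                          refresh_eta = p$refresh_eta,
                          refresh_kappa = p$refresh_kappa)
      simulate_pdmp(target, model = cfg$kind, cfg = bc,
                    x0 = unlist(cfg$x0), t_end = t_end, seed = seed)
    },
    switching = {
      simulate_switching(
        target,
        rates = list(type = "symmetric", psi = p$psi),
        movement_specs = switching_kinetic_specs(target, p$gamma, p$alpha),
        x0 = unlist(cfg$x0), s0 = cfg$s0, dt = cfg$sim$dt, t_end = t_end,
        seed = seed, thin = thin)
    },
    interaction = {
      jt <- interaction_target(target, n = p$n,
                               kernel_scale = p$kernel_scale)
      simulate_interacting(jt, movement = "kinetic", gamma = p$gamma,
                           alpha = p$alpha, x0s = unlist(cfg$x0),
                           dt = cfg$sim$dt, t_end = t_end, seed = seed,
                           thin = thin)
    })
}
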