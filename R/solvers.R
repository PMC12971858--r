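#' Simulation grid
#'
#' A uniform time grid for the forward-Euler / RK4 delay integrators. Delays
#' are represented as integer multiples of `dt`, so kernels must be
#' discretised at the same step (see [discretize_density()]).
#'
#' @param t_end Horizon (h, > 0).
#' @param dt Step (h, > 0).
#' @return An object of class `simulation_grid` with `t_end`, `dt`, `n_steps`.
#' @export
simulation_grid <- function(t_end, dt) {
  if (!is.finite(t_end) || t_end <= 0) stop("simulation_grid: t_end must be > 0")
  if (!is.finite(dt) || dt <= 0) stop("simulation_grid: dt must be > 0")
  n_steps <- as.integer(round(t_end / dt))
  if (n_steps < 1) stop("simulation_grid: horizon shorter than one step")
  structure(list(t_end = n_steps * dt, dt = dt, n_steps = n_steps),
            class = "simulation_grid")
}

new_trajectory <- function(times, U, I, P, model, dt, n_floored = 0L,
                           meta = list()) {
  structure(list(times = times, U = U, I = I, P = P, model = model,
                 dt = dt, n_floored = n_floored, meta = meta),
            class = "phage_trajectory")
}

#' @export
print.phage_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Phage-bacteria trajectory (%s): %d points, dt = %g h, horizon %g h\n",
              x$model, n, x$dt, x$times[n]))
  cat(sprintf("  final state: U = %.4g, I = %.4g, P = %.4g\n",
              x$U[n], x$I[n], x$P[n]))
  if (x$n_floored > 0) {
    cat(sprintf("  note: %d negative-state floorings during integration\n",
                x$n_floored))
  }
  invisible(x)
}

#' @export
as.data.frame.phage_trajectory <- function(x, ...) {
  data.frame(time_h = x$times, U = x$U, I = x$I, P = x$P)
}

#' Plot a simulated trajectory
#'
#' Plots uninfected bacteria, infected bacteria and free phage on a log10
#' concentration axis.
#'
#' @param x A `phage_trajectory`.
#' @param floor Concentrations below this are clipped for the log axis.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.phage_trajectory <- function(x, floor = 1e-2, ...) {
  M <- cbind(U = pmax(x$U, floor), I = pmax(x$I, floor), P = pmax(x$P, floor))
  graphics::matplot(x$times, log10(M), type = "l", lty = 1,
                    col = c("forestgreen", "darkorange", "navy"),
                    xlab = "time (h)", ylab = "log10 concentration (/mL)",
                    main = sprintf("%s model", x$model), ...)
  graphics::legend("topright", legend = c("uninfected (U)", "infected (I)",
                                          "phage (P)"),
                   col = c("forestgreen", "darkorange", "navy"), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' Columns `time_h, U, I, P`; optionally writes a JSON sidecar with the model
#' label and any metadata attached to the trajectory, for provenance.
#'
#' @param traj A `phage_trajectory`.
#' @param path Output CSV path.
#' @param provenance If `TRUE`, also writes `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, provenance = FALSE) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  if (provenance) {
    jsonlite::write_json(
      c(list(model = traj$model, dt = traj$dt, n_floored = traj$n_floored),
        traj$meta),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Simulate the fixed-delay (DDE) phage model
#'
#' Integrates the classic three-state model with a single fixed latent period
#' `tau_fixed`: uninfected cells grow logistically and are adsorbed at the
#' saturable rate; cells infected at `t - tau` lyse at `t` (if they survived,
#' probability `exp(-delta_I * tau)`) releasing `beta_0_mean` phage each.
#' History before `t = 0` carries no infections.
#'
#' @param params A [kinetic_params()].
#' @param tau_fixed Fixed latent period (h, >= 0); rounded to the nearest grid
#'   node.
#' @param grid A [simulation_grid()].
#' @param stepper `"euler"` (default) or `"rk4"`.
#' @return A `phage_trajectory`.
#' @export
simulate_dde <- function(params, tau_fixed, grid, stepper = c("euler", "rk4")) {
  stopifnot(inherits(params, "kinetic_params"), inherits(grid, "simulation_grid"))
  stepper <- match.arg(stepper)
  if (!is.finite(tau_fixed) || tau_fixed < 0) {
    stop("simulate_dde: tau_fixed must be >= 0")
  }
  k <- as.integer(round(tau_fixed / grid$dt))
  tau_grid <- k * grid$dt
  res <- cpp_sim_dde(params$U_init, params$P_init, grid$dt, grid$n_steps,
                     params$r_max, params$K_C, params$phi_max, params$P_50,
                     params$delta_U, params$delta_I, params$delta_P,
                     k, params$beta_0_mean, exp(-params$delta_I * tau_grid),
                     stepper == "rk4")
  new_trajectory(seq(0, by = grid$dt, length.out = grid$n_steps + 1),
                 res$U, res$I, res$P, "DDE", grid$dt, res$n_floored,
                 meta = list(tau_fixed = tau_grid, stepper = stepper))
}

#' Simulate the distributed-delay (DDDE) phage model
#'
#' Integrates the canonical distributed-delay model: the lysis terms are
#' convolutions of the infection history `phi(s) U(s) P(s)` with the
#' discretised latent-period kernel, weighted by the survival factor
#' `exp(-delta_I * tau)` (I-equation outflow) and additionally by the mean
#' burst size `beta_0(tau)` (P-equation source).
#'
#' @param params A [kinetic_params()].
#' @param kernel A [discretize_density()] kernel; its `dt` must equal the
#'   grid's.
#' @param burst A [burst_profile()]; in latent-dependent mode `beta_max`
#'   should come from [normalize_beta_max()] for the same distribution.
#' @param grid A [simulation_grid()].
#' @param stepper `"euler"` (default) or `"rk4"`.
#' @return A `phage_trajectory`.
#' @export
simulate_ddde <- function(params, kernel, burst, grid,
                          stepper = c("euler", "rk4")) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(kernel, "discretized_kernel"),
            inherits(burst, "burst_profile"),
            inherits(grid, "simulation_grid"))
  stepper <- match.arg(stepper)
  if (abs(kernel$dt - grid$dt) > 1e-12 * grid$dt) {
    stop("simulate_ddde: kernel.dt must equal grid.dt")
  }
  tau_k <- kernel$offsets * kernel$dt
  surv <- exp(-params$delta_I * tau_k)
  beta_k <- mean_burst_size(tau_k, burst, params$r_beta, params$D,
                            params$beta_tau50)
  res <- cpp_sim_ddde(params$U_init, params$P_init, grid$dt, grid$n_steps,
                      params$r_max, params$K_C, params$phi_max, params$P_50,
                      params$delta_U, params$delta_I, params$delta_P,
                      kernel$offsets, surv * kernel$weights,
                      beta_k * surv * kernel$weights, stepper == "rk4")
  new_trajectory(seq(0, by = grid$dt, length.out = grid$n_steps + 1),
                 res$U, res$I, res$P, "DDDE", grid$dt, res$n_floored,
                 meta = list(stepper = stepper, burst_mode = burst$mode))
}

#' Transit-compartment configuration from a latent-period distribution
#'
#' Moment-matches an Erlang latency: `N = round(1 / rsd_tau^2)` compartments
#' and transit rate `k_tr = N / tau_0`, the linear-chain-trick equivalence.
#'
#' @param tau_0 Mean latent period (h, > 0).
#' @param rsd_tau Relative standard deviation in `(0, 1]`.
#' @return An object of class `transit_config` with fields `N`, `k_tr`.
#' @export
tc_config_from_distribution <- function(tau_0, rsd_tau) {
  if (!is.finite(rsd_tau) || rsd_tau <= 0 || rsd_tau > 1) {
    stop("tc_config_from_distribution: rsd_tau must be in (0, 1] (0 implies an infinite chain)")
  }
  if (!is.finite(tau_0) || tau_0 <= 0) {
    stop("tc_config_from_distribution: tau_0 must be > 0")
  }
  N <- max(1L, as.integer(round(1 / rsd_tau^2)))
  transit_config(N, N / tau_0)
}

#' @rdname tc_config_from_distribution
#' @param N Number of transit compartments (>= 1).
#' @param k_tr Transit rate (/h, > 0).
#' @export
transit_config <- function(N, k_tr) {
  if (N < 1 || N != round(N)) stop("transit_config: N must be a positive integer")
  if (!is.finite(k_tr) || k_tr <= 0) stop("transit_config: k_tr must be > 0")
  structure(list(N = as.integer(N), k_tr = k_tr), class = "transit_config")
}

#' Simulate the transit-compartment (TC) phage model
#'
#' The latent period is represented by a chain of `N` infected-stage
#' compartments traversed at rate `k_tr` (an Erlang-distributed latency with
#' mean `N / k_tr` and relative SD `1/sqrt(N)`). The burst size is the
#' constant population mean `beta_0_mean`; the TC structure cannot carry a
#' latent-period-dependent burst nor a nonzero minimal latent period, which is
#' what makes it an approximation of the distributed-delay model.
#'
#' @param params A [kinetic_params()].
#' @param tc A [transit_config()] (e.g. from [tc_config_from_distribution()]).
#' @param grid A [simulation_grid()].
#' @return A `phage_trajectory` whose `I` series is the sum over compartments.
#' @export
simulate_tc <- function(params, tc, grid) {
  stopifnot(inherits(params, "kinetic_params"), inherits(tc, "transit_config"),
            inherits(grid, "simulation_grid"))
  res <- cpp_sim_tc(params$U_init, params$P_init, grid$dt, grid$n_steps,
                    params$r_max, params$K_C, params$phi_max, params$P_50,
                    params$delta_U, params$delta_I, params$delta_P,
                    tc$N, tc$k_tr, params$beta_0_mean)
  new_trajectory(seq(0, by = grid$dt, length.out = grid$n_steps + 1),
                 res$U, res$I, res$P, "TC", grid$dt, res$n_floored,
                 meta = list(N = tc$N, k_tr = tc$k_tr))
}

# thin a trajectory to every `by`-th grid node (used to compare dt vs dt/2)
thin_trajectory <- function(traj, by) {
  idx <- seq(1, length(traj$times), by = by)
  new_trajectory(traj$times[idx], traj$U[idx], traj$I[idx], traj$P[idx],
                 traj$model, traj$dt * by, traj$n_floored, traj$meta)
}

# TRUE when either load is still moving in the last 10% of the horizon by
# more than `tol` relative to the series peak
tail_active <- function(traj, tol = 1e-3) {
  n <- length(traj$times)
  win <- seq(max(1L, floor(0.9 * n)), n)
  for (x in list(traj$U + traj$I, traj$P)) {
    peak <- max(x)
    if (peak <= 0) next
    if ((max(x[win]) - min(x[win])) / peak > tol) return(TRUE)
  }
  FALSE
}

#' Simulate with automatic step-halving convergence control
#'
#' Repeatedly halves the step size, re-simulates, and compares successive
#' solutions with the normalised area-between-curves metric on both the
#' bacterial load (`U + I`) and the viral load (`P`). Convergence is declared
#' when both differences fall below `criterion` percent (default 1%).
#'
#' An optional horizon-extension phase (`max_extensions > 0`) doubles `t_end`
#' (at the initial step size) while either load is still changing by more
#' than 0.1% of its peak over the final 10% of the window. It is off by
#' default: once bacterial densities fall below one cell per mL the continuum
#' model no longer describes anything physical, and long extended windows let
#' such sub-cell densities regrow and dominate the area-between-curves
#' metric, while the phage series contributes only an exponential decay tail.
#' The 48 h default horizon comfortably contains the infection transient for
#' growth rates above 0.5/h and latent periods below 3 h.
#'
#' Non-convergence within `max_halvings` is a reported outcome, not an error:
#' the Monte Carlo layer responds by resampling the parameter set.
#'
#' @param sim_fun `function(dt, t_end)` returning a `phage_trajectory`
#'   (typically a closure over a scenario; see [scenario_sim_fun()]).
#' @param dt_init Initial step (h); default 0.01.
#' @param criterion Convergence criterion in percent; default 1.
#' @param max_halvings Maximum number of step halvings; default 5.
#' @param t_end Horizon (h); default 48.
#' @param max_extensions Maximum number of horizon doublings; default 0
#'   (fixed horizon; see Details).
#' @param fixed_horizon If `TRUE`, skip the horizon-extension phase and use
#'   `t_end` as given (used when comparing against a reference whose horizon
#'   is already resolved).
#' @return A list with `trajectory` (the finest run), `dt_final`, `t_end`,
#'   `converged` (logical), `n_halvings`, and `errors` (the last pair of
#'   bacterial/viral percent differences).
#' @export
run_with_convergence <- function(sim_fun, dt_init = 0.01, criterion = 1,
                                 max_halvings = 5L, t_end = 48,
                                 max_extensions = 0L, fixed_horizon = FALSE) {
  if (dt_init <= 0) stop("run_with_convergence: dt_init must be > 0")
  if (criterion <= 0) stop("run_with_convergence: criterion must be > 0")

  prev <- sim_fun(dt_init, t_end)
  if (!fixed_horizon) {
    ext <- 0L
    while (ext < max_extensions && tail_active(prev)) {
      t_end <- 2 * t_end
      ext <- ext + 1L
      prev <- sim_fun(dt_init, t_end)
    }
  }

  dt <- dt_init
  errs <- c(bacterial = NA_real_, viral = NA_real_)
  for (h in seq_len(max_halvings)) {
    dt <- dt / 2
    cur <- sim_fun(dt, t_end)
    coarse <- thin_trajectory(cur, 2L)
    errs <- c(bacterial = curve_error(prev, coarse, "bacterial"),
              viral = curve_error(prev, coarse, "viral"))
    if (all(errs < criterion)) {
      return(list(trajectory = cur, dt_final = dt, t_end = t_end,
                  converged = TRUE, n_halvings = h, errors = errs))
    }
    prev <- cur
  }
  list(trajectory = prev, dt_final = dt, t_end = t_end,
       converged = FALSE, n_halvings = max_halvings, errors = errs)
}
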