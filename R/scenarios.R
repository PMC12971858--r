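#' Scenario specification
#'
#' A scenario names one model structure to simulate against a common kinetic
#' parameter set:
#'
#' * `"ddde-lognormal"`, `"ddde-normal"`, `"ddde-gamma"`: the distributed-delay
#'   model with the named latent-period family (`"ddde-normal"` uses the
#'   truncated normal).
#' * `"fixed-mean"`, `"fixed-median"`, `"fixed-early"`: the fixed-delay model
#'   with the latent period set to the mean, the median, or the
#'   first-observed-lysis (infective-center doubling) time of `dist`.
#' * `"tc"`: the transit-compartment model with `N = round(1/rsd^2)` and
#'   `k_tr = N / tau_0` derived from `dist`.
#'
#' @param label Scenario label (see above).
#' @param dist A [latent_distribution()]: the reference kernel shape for DDDE
#'   labels, and the source of latent-period statistics for fixed/TC labels.
#' @param burst_mode `"latent-dependent"` (default) or `"constant"`; applies
#'   to DDDE labels and to the burst profile used when locating first lysis.
#'   The TC and fixed-delay simulations always burst at the constant
#'   population mean, which is part of what those approximations assume.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(label = c("ddde-lognormal", "ddde-normal", "ddde-gamma",
                                    "fixed-mean", "fixed-median", "fixed-early",
                                    "tc"),
                          dist, burst_mode = c("latent-dependent", "constant")) {
  label <- match.arg(label)
  burst_mode <- match.arg(burst_mode)
  stopifnot(inherits(dist, "latent_distribution"))
  ddde_family <- c("ddde-lognormal" = "lognormal",
                   "ddde-normal" = "truncated-normal",
                   "ddde-gamma" = "gamma")
  if (label %in% names(ddde_family) && dist$family != ddde_family[[label]] &&
      dist$family != "point-mass") {
    stop(sprintf("scenario_spec: label %s requires a %s distribution",
                 label, ddde_family[[label]]))
  }
  structure(list(label = label, dist = dist, burst_mode = burst_mode),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario %s (%s burst): %s latent period, tau_0 = %g h, rsd = %g\n",
              x$label, x$burst_mode, x$dist$family, x$dist$tau_0, x$dist$rsd_tau))
  invisible(x)
}

# Burst profile a scenario's reference kernel uses, normalising beta_max once.
scenario_burst <- function(scn, params) {
  if (scn$burst_mode == "constant") {
    burst_profile("constant", params$beta_0_mean)
  } else {
    bmax <- normalize_beta_max(params$beta_0_mean, scn$dist, params$r_beta,
                               params$D, params$beta_tau50)
    burst_profile("latent-dependent", params$beta_0_mean, bmax)
  }
}

#' Build a simulation closure for a scenario
#'
#' Resolves everything that does not depend on the grid (burst normalisation,
#' fixed latent value, transit configuration) once, and returns a
#' `function(dt, t_end)` producing a `phage_trajectory` — the shape
#' [run_with_convergence()] consumes.
#'
#' @param scn A [scenario_spec()].
#' @param params A [kinetic_params()].
#' @param stepper Stepper for the delay solvers.
#' @return A function of `(dt, t_end)`.
#' @export
scenario_sim_fun <- function(scn, params, stepper = "euler") {
  stopifnot(inherits(scn, "scenario_spec"), inherits(params, "kinetic_params"))
  if (startsWith(scn$label, "ddde")) {
    burst <- scenario_burst(scn, params)
    dist <- scn$dist
    function(dt, t_end) {
      grid <- simulation_grid(t_end, dt)
      kernel <- discretize_density(dist, dt)
      simulate_ddde(params, kernel, burst, grid, stepper)
    }
  } else if (scn$label == "tc") {
    tc <- tc_config_from_distribution(scn$dist$tau_0, scn$dist$rsd_tau)
    function(dt, t_end) simulate_tc(params, tc, simulation_grid(t_end, dt))
  } else {
    mode <- sub("^fixed-", "", scn$label)
    burst <- scenario_burst(scn, params)
    tau <- fixed_latent_value(scn$dist, mode, params, burst)
    function(dt, t_end) simulate_dde(params, tau, simulation_grid(t_end, dt), stepper)
  }
}

#' Simulate a single-step (one-round) growth experiment
#'
#' Emulates the classical synchronized-infection assay: every inoculated phage
#' is adsorbed at `t = 0` (`I(0) = P_init`, `U(0) = 0`, `P(0) = 0`) and
#' re-adsorption is disabled, so exactly one round of lysis is observed. Each
#' infected cell lyses after its latent period (drawn from `kernel_or_tau`),
#' surviving to lysis with probability `exp(-delta_I * tau)` and releasing
#' `beta_0(tau)` phage; released phage decay at `delta_P`. The observable is
#' the infective-center count `C(t) = P(t) + I(t)` (every free phage or
#' infected cell forms one plaque).
#'
#' @param params A [kinetic_params()].
#' @param kernel_or_tau Either a [discretize_density()] kernel (distributed
#'   latent period) or a single number (fixed latent period, h).
#' @param burst A [burst_profile()].
#' @param grid A [simulation_grid()]; the kernel's `dt` must match.
#' @param decay If `FALSE`, sets `delta_I = delta_P = 0` (didactic switch).
#' @return A `phage_trajectory` with `U = 0`; infective centers are `P + I`.
#' @export
single_step_growth <- function(params, kernel_or_tau, burst, grid, decay = TRUE) {
  stopifnot(inherits(params, "kinetic_params"), inherits(grid, "simulation_grid"))
  if (inherits(kernel_or_tau, "discretized_kernel")) {
    kernel <- kernel_or_tau
    if (abs(kernel$dt - grid$dt) > 1e-12 * grid$dt) {
      stop("single_step_growth: kernel.dt must equal grid.dt")
    }
  } else {
    if (!is.numeric(kernel_or_tau) || kernel_or_tau < 0) {
      stop("single_step_growth: kernel_or_tau must be a kernel or a nonnegative time")
    }
    k <- max(1L, as.integer(round(kernel_or_tau / grid$dt)))
    kernel <- structure(list(dt = grid$dt, offsets = k, weights = 1.0),
                        class = "discretized_kernel")
  }
  dI <- if (decay) params$delta_I else 0
  dP <- if (decay) params$delta_P else 0
  I0 <- params$P_init
  n <- grid$n_steps
  times <- seq(0, by = grid$dt, length.out = n + 1)

  tau_k <- kernel$offsets * kernel$dt
  beta_k <- mean_burst_size(tau_k, burst, params$r_beta, params$D,
                            params$beta_tau50)
  # cohort bookkeeping on the grid: still-latent fraction and lysis releases
  Fcum <- rep(0, n + 1)                     # kernel mass with tau_k <= t
  release <- rep(0, n + 1)                  # phage released exactly at node
  idx <- kernel$offsets + 1L
  keep <- idx <= n + 1L
  release[idx[keep]] <- I0 * kernel$weights[keep] * exp(-dI * tau_k[keep]) *
    beta_k[keep]
  w_at <- rep(0, n + 1)
  w_at[idx[keep]] <- kernel$weights[keep]
  Fcum <- cumsum(w_at)

  I <- I0 * exp(-dI * times) * (1 - Fcum)
  P <- numeric(n + 1)
  dec <- exp(-dP * grid$dt)
  for (i in seq_len(n)) P[i + 1] <- P[i] * dec + release[i + 1]
  new_trajectory(times, rep(0, n + 1), I, P, "single-step", grid$dt,
                 meta = list(I0 = I0))
}

#' Time of first observed lysis (infective-center doubling)
#'
#' The classical operational definition of the latent period: the earliest
#' time at which the infective-center count `C(t) = P(t) + I(t)` of a
#' single-step growth experiment reaches twice its initial value, linearly
#' interpolated between bracketing grid nodes. Because the earliest-lysing
#' cells double the count before the mean cell has lysed, this time
#' systematically underestimates the mean latent period when the latent
#' period is distributed.
#'
#' @param trajectory A trajectory from [single_step_growth()] with `C(0) > 0`.
#' @return Doubling time (h), or `NA_real_` when doubling is never reached
#'   (burst too small or decay too heavy); callers constructing a Fixed-Early
#'   scenario treat `NA` as an explicit failure.
#' @export
first_lysis_time <- function(trajectory) {
  C <- trajectory$P + trajectory$I
  if (C[1] <= 0) stop("first_lysis_time: C(0) must be > 0")
  target <- 2 * C[1]
  hit <- which(C >= target)
  if (length(hit) == 0) return(NA_real_)
  i <- hit[1]
  if (i == 1) return(trajectory$times[1])
  t0 <- trajectory$times[i - 1]; t1 <- trajectory$times[i]
  c0 <- C[i - 1]; c1 <- C[i]
  t0 + (target - c0) / (c1 - c0) * (t1 - t0)
}

#' Latent period for a fixed-delay approximation scenario
#'
#' Resolves the fixed latent period a DDE approximation uses: the mean of the
#' distribution (`tau_0`), its median, or the first-observed-lysis time from a
#' simulated single-step growth experiment with that distribution's kernel and
#' the scenario's burst profile (computed per parameter set, since the
#' doubling time depends on the burst law and decay rates).
#'
#' @param dist A [latent_distribution()].
#' @param mode `"mean"`, `"median"` or `"early"`.
#' @param params A [kinetic_params()] (used by `"early"`).
#' @param burst A [burst_profile()] (used by `"early"`).
#' @param dt_early Grid step of the single-step simulation for `"early"`.
#' @return The fixed latent period (h).
#' @export
fixed_latent_value <- function(dist, mode = c("mean", "median", "early"),
                               params = NULL, burst = NULL,
                               dt_early = NULL) {
  mode <- match.arg(mode)
  if (mode == "mean") return(dist$tau_0)
  if (mode == "median") return(distribution_median(dist))

  stopifnot(inherits(params, "kinetic_params"), inherits(burst, "burst_profile"))
  if (is.null(dt_early)) dt_early <- min(0.002, dist$tau_0 / 500)
  horizon <- if (dist$family == "point-mass") {
    2 * dist$tau_0
  } else {
    dist_quantile(dist, 1 - 1e-6) + dist$tau_0
  }
  grid <- simulation_grid(horizon, dt_early)
  kern <- if (dist$family == "point-mass") {
    dist$tau_0
  } else {
    discretize_density(dist, dt_early)
  }
  traj <- single_step_growth(params, kern, burst, grid)
  t_early <- first_lysis_time(traj)
  if (is.na(t_early)) {
    stop(structure(
      class = c("phagedyn_undefined_lysis", "phagedyn_invalid_params",
                "error", "condition"),
      list(message = paste0("fixed_latent_value: infective centers never double ",
                            "(effective burst <= 2 after decay); the Fixed-Early ",
                            "scenario is undefined for this parameter set"),
           call = sys.call(-1))))
  }
  t_early
}
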