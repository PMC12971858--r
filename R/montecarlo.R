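#' Sampling ranges for randomized kinetic parameter sets
#'
#' Default ranges for the Monte Carlo experiments. Each entry carries a low
#' bound, a high bound and a sampling scale (`"uniform"` or `"log-uniform"`;
#' log-uniform is used for quantities spanning orders of magnitude). Dependent
#' bounds are closures of the already-drawn values and are resolved in the
#' listed order:
#'
#' * `P_50 >= r_max / phi_max` (phage killing can outpace bacterial growth),
#' * `tau_min <= tau_0 / 2`,
#' * `D <= tau_0` (replication starts before lysis is possible),
#' * `beta_tau50` in `[D, 3]`,
#' * `U_init <= K_C * (1 - delta_U / r_max)` (below the stationary load).
#'
#' @return An object of class `parameter_ranges`: a named list of
#'   `{low, high, scale}` entries in dependency order.
#' @export
parameter_ranges <- function() {
  structure(list(
    r_max       = list(low = 0.5,  high = 2.5,   scale = "uniform"),
    K_C         = list(low = 1e8,  high = 1e10,  scale = "log-uniform"),
    phi_max     = list(low = 1e-9, high = 1e-7,  scale = "log-uniform"),
    delta_U     = list(low = 0.1,  high = 0.25,  scale = "uniform"),
    delta_I     = list(low = 0.1,  high = 0.25,  scale = "uniform"),
    delta_P     = list(low = 0.05, high = 0.15,  scale = "uniform"),
    P_50        = list(low = function(d) d$r_max / d$phi_max,
                       high = 1e10, scale = "log-uniform"),
    tau_0       = list(low = 0.25, high = 3,     scale = "uniform"),
    tau_min     = list(low = 0, high = function(d) d$tau_0 / 2,
                       scale = "uniform"),
    beta_0_mean = list(low = 10,   high = 500,   scale = "log-uniform"),
    r_beta      = list(low = 1,    high = 10,    scale = "uniform"),
    D           = list(low = 0, high = function(d) d$tau_0, scale = "uniform"),
    beta_tau50  = list(low = function(d) d$D, high = 3, scale = "uniform"),
    U_init      = list(low = 1e3,
                       high = function(d) d$K_C * (1 - d$delta_U / d$r_max),
                       scale = "log-uniform"),
    P_init      = list(low = 1e3,  high = 1e9,   scale = "log-uniform")
  ), class = "parameter_ranges")
}

#' Draw one randomized parameter set
#'
#' Draws every parameter on its scale (uniform, or uniform in log for
#' log-uniform entries), resolving dependent bounds against the values already
#' drawn. Uses the current R RNG stream; seed it for reproducibility.
#'
#' @param ranges A [parameter_ranges()].
#' @return A list of class `sampled_parameter_set` with elements `params`
#'   (a [kinetic_params()]) and the sampled latent-period statistics `tau_0`
#'   and `tau_min` (which parameterise the latent distribution, not the rate
#'   constants).
#' @export
sample_parameter_set <- function(ranges = parameter_ranges()) {
  stopifnot(inherits(ranges, "parameter_ranges"))
  d <- list()
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    lo <- if (is.function(r$low)) r$low(d) else r$low
    hi <- if (is.function(r$high)) r$high(d) else r$high
    if (lo > hi) stop(sprintf("sample_parameter_set: empty range for %s", nm))
    d[[nm]] <- if (r$scale == "log-uniform") {
      exp(stats::runif(1, log(lo), log(hi)))
    } else {
      stats::runif(1, lo, hi)
    }
  }
  params <- kinetic_params(
    r_max = d$r_max, K_C = d$K_C, phi_max = d$phi_max, P_50 = d$P_50,
    delta_U = d$delta_U, delta_I = d$delta_I, delta_P = d$delta_P,
    beta_0_mean = d$beta_0_mean, r_beta = d$r_beta, D = d$D,
    beta_tau50 = d$beta_tau50, U_init = d$U_init, P_init = d$P_init)
  structure(list(params = params, tau_0 = d$tau_0, tau_min = d$tau_min),
            class = "sampled_parameter_set")
}

# Build a concrete scenario_spec for a label at a given latent-period setting.
# Fixed-delay and TC labels take their tau statistics from the lognormal
# reference shape, mirroring how the comparison study reports its results.
make_scenario <- function(label, tau_0, rsd_tau, tau_min,
                          burst_mode = "latent-dependent") {
  family <- switch(label,
    "ddde-lognormal" = "lognormal",
    "ddde-normal" = "truncated-normal",
    "ddde-gamma" = "gamma",
    "lognormal")                      # fixed-*, tc: reference shape
  dist <- latent_distribution(family, tau_0, rsd_tau, tau_min)
  mode <- if (label == "tc") "constant" else burst_mode
  scenario_spec(label, dist, mode)
}

#' Monte Carlo comparison study between two scenarios
#'
#' For each relative standard deviation in `rsd_grid` and each of `n_sets`
#' randomized parameter sets, builds both scenarios, simulates each with
#' step-halving convergence control (the comparator reuses the horizon
#' resolved for the reference), and records the normalised area-between-curves
#' error on bacterial and viral load. Parameter sets for which a scenario is
#' infeasible (degenerate burst normalisation, unattainable truncated-normal
#' moments, undefined first lysis) or for which convergence fails are
#' discarded and a fresh set is drawn from the same stream; resamples are
#' counted per cell.
#'
#' @param pair Character vector of two scenario labels
#'   (see [scenario_spec()]); the first is the reference.
#' @param rsd_grid Relative standard deviations of the latent period to sweep.
#' @param n_sets Converged parameter sets required per cell (paper-scale
#'   default 500; reduced runs are routine).
#' @param ranges A [parameter_ranges()].
#' @param master_seed Master seed; each cell derives its own substream, so
#'   identical seeds give bit-identical results.
#' @param burst_mode Burst mode of the DDDE reference.
#' @param dt_init,criterion,max_halvings,t_end Passed to
#'   [run_with_convergence()].
#' @param bacterial_as See [curve_error()].
#' @param resample_factor Budget of attempts per cell, as a multiple of
#'   `n_sets`; exhausting it aborts the cell with a diagnostic.
#' @param stepper Stepper for the delay solvers.
#' @param progress Print one line per completed cell.
#' @return An object of class `comparison_study`: `records` (one row per
#'   converged set: set id, rsd, errors, resample count) and `summary`
#'   (median/IQR per cell and load, from [compile_summary()]).
#' @export
run_comparison_study <- function(pair, rsd_grid, n_sets = 500L,
                                 ranges = parameter_ranges(),
                                 master_seed = 120659L,
                                 burst_mode = "latent-dependent",
                                 dt_init = 0.01, criterion = 1,
                                 max_halvings = 5L, t_end = 48,
                                 bacterial_as = "U+I",
                                 resample_factor = 10L,
                                 stepper = "euler",
                                 progress = FALSE) {
  stopifnot(length(pair) == 2, n_sets >= 1)
  records <- vector("list", length(rsd_grid) * n_sets)
  ri <- 0L
  for (ci in seq_along(rsd_grid)) {
    rsd <- rsd_grid[ci]
    set.seed((as.integer(master_seed) + 7919L * ci) %% 2147483647L)
    converged_n <- 0L
    attempts <- 0L
    budget <- resample_factor * n_sets
    while (converged_n < n_sets) {
      if (attempts >= budget) {
        stop(sprintf(paste0("run_comparison_study: resample budget (%d) ",
                            "exhausted in cell rsd = %g with %d/%d converged"),
                     budget, rsd, converged_n, n_sets))
      }
      attempts <- attempts + 1L
      sset <- sample_parameter_set(ranges)
      row <- tryCatch({
        err <- compare_scenario_pair(pair, sset, rsd, burst_mode = burst_mode,
                                     dt_init = dt_init, criterion = criterion,
                                     max_halvings = max_halvings, t_end = t_end,
                                     bacterial_as = bacterial_as,
                                     stepper = stepper)
        data.frame(set_id = converged_n + 1L, attempt = attempts, rsd_tau = rsd,
                   scenario_a = pair[1], scenario_b = pair[2],
                   bacterial_error_pct = err$bacterial_error_pct,
                   viral_error_pct = err$viral_error_pct,
                   horizon = err$horizon, converged = TRUE,
                   resamples = attempts - (converged_n + 1L))
      },
      phagedyn_invalid_params = function(e) NULL,
      phagedyn_not_converged = function(e) NULL)
      if (!is.null(row)) {
        converged_n <- converged_n + 1L
        ri <- ri + 1L
        records[[ri]] <- row
      }
    }
    if (progress) {
      message(sprintf("cell rsd = %g done: %d sets, %d attempts", rsd, n_sets,
                      attempts))
    }
  }
  records <- do.call(rbind, records[seq_len(ri)])
  structure(list(records = records, summary = compile_summary(records),
                 settings = list(pair = pair, rsd_grid = rsd_grid,
                                 n_sets = n_sets, master_seed = master_seed,
                                 burst_mode = burst_mode, dt_init = dt_init,
                                 criterion = criterion,
                                 max_halvings = max_halvings, t_end = t_end,
                                 bacterial_as = bacterial_as)),
            class = "comparison_study")
}

# One parameter set, one scenario pair: simulate both to convergence and
# compare. Raises phagedyn_not_converged when step halving fails.
compare_scenario_pair <- function(pair, sset, rsd, burst_mode = "latent-dependent",
                                  dt_init = 0.01, criterion = 1,
                                  max_halvings = 5L, t_end = 48,
                                  bacterial_as = "U+I", stepper = "euler") {
  scn_a <- make_scenario(pair[1], sset$tau_0, rsd, sset$tau_min, burst_mode)
  scn_b <- make_scenario(pair[2], sset$tau_0, rsd, sset$tau_min, burst_mode)
  fun_a <- scenario_sim_fun(scn_a, sset$params, stepper)
  fun_b <- scenario_sim_fun(scn_b, sset$params, stepper)
  res_a <- run_with_convergence(fun_a, dt_init, criterion, max_halvings, t_end)
  if (!res_a$converged) signal_not_converged(pair[1], rsd)
  res_b <- run_with_convergence(fun_b, dt_init, criterion, max_halvings,
                                t_end = res_a$t_end, fixed_horizon = TRUE)
  if (!res_b$converged) signal_not_converged(pair[2], rsd)
  compare_trajectories(res_a$trajectory, res_b$trajectory, bacterial_as)
}

signal_not_converged <- function(label, rsd) {
  stop(structure(
    class = c("phagedyn_not_converged", "error", "condition"),
    list(message = sprintf("step-halving did not converge for %s at rsd = %g",
                           label, rsd),
         call = NULL)))
}

#' Summarise a comparison study
#'
#' Long-format medians by cell: one row per (scenario pair, rsd, load) with
#' the median error, interquartile range and number of converged sets — the
#' table behind grouped bar charts of approximation error.
#'
#' @param result A `comparison_study` or its `records` data frame.
#' @return A data.frame with columns `scenario_a`, `scenario_b`, `rsd_tau`,
#'   `load`, `median_error_pct`, `iqr_error_pct`, `n`.
#' @export
compile_summary <- function(result) {
  records <- if (inherits(result, "comparison_study")) result$records else result
  if (is.null(records) || nrow(records) == 0) stop("compile_summary: empty result")
  records <- records[records$converged, , drop = FALSE]
  out <- list()
  for (load in c("bacterial", "viral")) {
    col <- if (load == "bacterial") "bacterial_error_pct" else "viral_error_pct"
    agg <- stats::aggregate(records[[col]],
                            by = list(scenario_a = records$scenario_a,
                                      scenario_b = records$scenario_b,
                                      rsd_tau = records$rsd_tau),
                            FUN = function(x) c(median = stats::median(x),
                                                iqr = stats::IQR(x),
                                                n = length(x)))
    out[[load]] <- data.frame(agg[1:3], load = load,
                              median_error_pct = agg$x[, "median"],
                              iqr_error_pct = agg$x[, "iqr"],
                              n = as.integer(agg$x[, "n"]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$rsd_tau, res$load), ]
}

#' @export
print.comparison_study <- function(x, ...) {
  s <- x$settings
  cat(sprintf("Comparison study: %s vs %s, %d sets per cell, seed %d\n",
              s$pair[1], s$pair[2], s$n_sets, s$master_seed))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Bar chart of median approximation errors
#'
#' @param x A `comparison_study`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.comparison_study <- function(x, ...) {
  s <- x$summary
  for (load in unique(s$load)) {
    sl <- s[s$load == load, ]
    graphics::barplot(sl$median_error_pct, names.arg = sprintf("%g", sl$rsd_tau),
                      xlab = "rsd of latent period", ylab = "median error (%)",
                      main = sprintf("%s vs %s: %s load", sl$scenario_a[1],
                                     sl$scenario_b[1], load), ...)
  }
  invisible(x)
}

# Shared engine for the multi-scenario studies: per converged parameter set,
# run the reference scenario to convergence (resolving the horizon once), run
# every comparator at that horizon, and hand the trajectories to `record_fun`.
run_multi_scenario <- function(labels_ref, labels_cmp, rsd, n_sets, ranges,
                               cell_seed, burst_mode, dt_init, criterion,
                               max_halvings, t_end, bacterial_as, stepper,
                               resample_factor, record_fun) {
  set.seed(cell_seed)
  rows <- vector("list", n_sets)
  converged_n <- 0L
  attempts <- 0L
  budget <- resample_factor * n_sets
  while (converged_n < n_sets) {
    if (attempts >= budget) {
      stop(sprintf(paste0("study: resample budget (%d) exhausted at rsd = %g ",
                          "with %d/%d converged"), budget, rsd, converged_n,
                   n_sets))
    }
    attempts <- attempts + 1L
    sset <- sample_parameter_set(ranges)
    row <- tryCatch({
      trajs <- list()
      horizon <- t_end
      for (li in seq_along(labels_ref)) {
        lab <- labels_ref[li]
        scn <- make_scenario(lab, sset$tau_0, rsd, sset$tau_min, burst_mode)
        fun <- scenario_sim_fun(scn, sset$params, stepper)
        res <- run_with_convergence(fun, dt_init, criterion, max_halvings,
                                    t_end = horizon,
                                    fixed_horizon = (li > 1L))
        if (!res$converged) signal_not_converged(lab, rsd)
        horizon <- res$t_end
        trajs[[lab]] <- res$trajectory
      }
      for (lab in labels_cmp) {
        scn <- make_scenario(lab, sset$tau_0, rsd, sset$tau_min, burst_mode)
        fun <- scenario_sim_fun(scn, sset$params, stepper)
        res <- run_with_convergence(fun, dt_init, criterion, max_halvings,
                                    t_end = horizon, fixed_horizon = TRUE)
        if (!res$converged) signal_not_converged(lab, rsd)
        trajs[[lab]] <- res$trajectory
      }
      record_fun(trajs, converged_n + 1L, attempts)
    },
    phagedyn_invalid_params = function(e) NULL,
    phagedyn_not_converged = function(e) NULL)
    if (!is.null(row)) {
      converged_n <- converged_n + 1L
      rows[[converged_n]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Distribution-shape sensitivity study
#'
#' Quantifies how much the choice of latent-period distribution family
#' matters: for each randomized parameter set, simulates the
#' distributed-delay model with lognormal, truncated-normal and gamma
#' kernels sharing the same mean, relative SD and minimal latent period, and
#' records the pairwise area-between-curves errors for both loads.
#'
#' @inheritParams run_comparison_study
#' @param rsd_tau Relative standard deviation of the latent period.
#' @return A `comparison_study` whose records hold one row per set and shape
#'   pair.
#' @export
run_shape_study <- function(rsd_tau, n_sets = 500L, ranges = parameter_ranges(),
                            master_seed = 120659L,
                            burst_mode = "latent-dependent",
                            dt_init = 0.01, criterion = 1, max_halvings = 5L,
                            t_end = 48, bacterial_as = "U+I",
                            resample_factor = 10L, stepper = "rk4") {
  labels <- c("ddde-lognormal", "ddde-normal", "ddde-gamma")
  pairs <- utils::combn(labels, 2)
  record_fun <- function(trajs, set_id, attempt) {
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(pi) {
      err <- compare_trajectories(trajs[[pairs[1, pi]]], trajs[[pairs[2, pi]]],
                                  bacterial_as)
      data.frame(set_id = set_id, attempt = attempt, rsd_tau = rsd_tau,
                 scenario_a = pairs[1, pi], scenario_b = pairs[2, pi],
                 bacterial_error_pct = err$bacterial_error_pct,
                 viral_error_pct = err$viral_error_pct,
                 horizon = err$horizon, converged = TRUE,
                 resamples = attempt - set_id)
    }))
  }
  records <- run_multi_scenario(labels, character(0), rsd_tau, n_sets, ranges,
                                (as.integer(master_seed) + 104729L) %% 2147483647L,
                                burst_mode, dt_init, criterion, max_halvings,
                                t_end, bacterial_as, stepper, resample_factor,
                                record_fun)
  structure(list(records = records, summary = compile_summary(records),
                 settings = list(pair = c("ddde-shapes", "pairwise"),
                                 rsd_grid = rsd_tau, n_sets = n_sets,
                                 master_seed = master_seed,
                                 burst_mode = burst_mode, dt_init = dt_init,
                                 criterion = criterion,
                                 max_halvings = max_halvings, t_end = t_end,
                                 bacterial_as = bacterial_as)),
            class = "comparison_study")
}

#' Fixed-delay / transit-compartment approximation study
#'
#' The reference is the distributed-delay model with a lognormal latent
#' period; each comparator in `comparators` is simulated on the same
#' randomized parameter sets and horizon, and the area-between-curves errors
#' against the reference are recorded for both loads.
#'
#' @inheritParams run_comparison_study
#' @param comparators Subset of
#'   `c("fixed-mean", "fixed-median", "fixed-early", "tc")`.
#' @param rsd_tau Relative standard deviation of the latent period.
#' @return A `comparison_study` whose records hold one row per set and
#'   comparator.
#' @export
run_approximation_study <- function(comparators, rsd_tau, n_sets = 500L,
                                    ranges = parameter_ranges(),
                                    master_seed = 120659L,
                                    burst_mode = "latent-dependent",
                                    dt_init = 0.01, criterion = 1,
                                    max_halvings = 5L, t_end = 48,
                                    bacterial_as = "U+I",
                                    resample_factor = 10L, stepper = "rk4") {
  stopifnot(all(comparators %in% c("fixed-mean", "fixed-median", "fixed-early",
                                   "tc")))
  ref <- "ddde-lognormal"
  record_fun <- function(trajs, set_id, attempt) {
    do.call(rbind, lapply(comparators, function(lab) {
      err <- compare_trajectories(trajs[[ref]], trajs[[lab]], bacterial_as)
      data.frame(set_id = set_id, attempt = attempt, rsd_tau = rsd_tau,
                 scenario_a = ref, scenario_b = lab,
                 bacterial_error_pct = err$bacterial_error_pct,
                 viral_error_pct = err$viral_error_pct,
                 horizon = err$horizon, converged = TRUE,
                 resamples = attempt - set_id)
    }))
  }
  records <- run_multi_scenario(ref, comparators, rsd_tau, n_sets, ranges,
                                (as.integer(master_seed) +
                                   7919L * as.integer(round(1000 * rsd_tau))) %%
                                  2147483647L,
                                burst_mode, dt_init, criterion, max_halvings,
                                t_end, bacterial_as, stepper, resample_factor,
                                record_fun)
  structure(list(records = records, summary = compile_summary(records),
                 settings = list(pair = c(ref, paste(comparators, collapse = "+")),
                                 rsd_grid = rsd_tau, n_sets = n_sets,
                                 master_seed = master_seed,
                                 burst_mode = burst_mode, dt_init = dt_init,
                                 criterion = criterion,
                                 max_halvings = max_halvings, t_end = t_end,
                                 bacterial_as = bacterial_as)),
            class = "comparison_study")
}
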