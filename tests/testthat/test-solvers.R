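test_that("without phage the solvers reproduce the logistic closed form", {
  p <- base_params(P_init = 0, delta_U = 0)
  for (sim in list(
    function(g) simulate_dde(p, 1, g),
    function(g) simulate_ddde(p, discretize_density(
      latent_distribution("lognormal", 1, 0.3, 0), g$dt),
      burst_profile("constant", 100), g),
    function(g) simulate_tc(p, transit_config(4, 4), g))) {
    tr <- sim(simulation_grid(10, 0.002))
    Uex <- logistic_closed_form(tr$times, 1e6, 1, 1e9)
    expect_lt(max(abs(tr$U - Uex) / Uex), 5e-3)
  }
  # Euler is first-order: a factor-4 finer grid meets 1e-3 pointwise
  tr <- simulate_dde(p, 1, simulation_grid(10, 0.00025))
  Uex <- logistic_closed_form(tr$times, 1e6, 1, 1e9)
  expect_lt(max(abs(tr$U - Uex) / Uex), 1e-3)
  # RK4 is exact to solver precision at dt = 1e-3
  tr4 <- simulate_dde(p, 1, simulation_grid(10, 0.001), stepper = "rk4")
  Uex4 <- logistic_closed_form(tr4$times, 1e6, 1, 1e9)
  expect_lt(max(abs(tr4$U - Uex4) / Uex4), 1e-10)
})

test_that("without hosts phage decay exponentially", {
  p <- base_params(U_init = 0)
  tr <- simulate_dde(p, 1, simulation_grid(10, 0.001))
  Pex <- 1e5 * exp(-0.05 * tr$times)
  expect_lt(max(abs(tr$P - Pex) / Pex), 1e-3)
  expect_true(all(tr$U == 0) && all(tr$I == 0))
})

test_that("with decay but no phage bacteria settle at the depressed ceiling", {
  p <- base_params(P_init = 0, delta_U = 0.2, U_init = 1e8)
  tr <- simulate_dde(p, 1, simulation_grid(60, 0.01))
  expect_equal(tr$U[length(tr$U)], 1e9 * (1 - 0.2 / 1), tolerance = 1e-4)
})

test_that("a point-mass kernel collapses the distributed model onto the fixed-delay model", {
  set.seed(21)
  for (i in 1:20) {
    s <- sample_parameter_set()
    g <- simulation_grid(12, 0.01)
    tau <- round(s$tau_0 / g$dt) * g$dt
    dde <- simulate_dde(s$params, tau, g)
    pm <- latent_distribution("point-mass", tau, 0)
    ddde <- simulate_ddde(s$params, discretize_density(pm, g$dt),
                          burst_profile("constant", s$params$beta_0_mean), g)
    expect_lt(max_rel_diff(dde$U, ddde$U), 1e-6)
    expect_lt(max_rel_diff(dde$I, ddde$I), 1e-6)
    expect_lt(max_rel_diff(dde$P, ddde$P), 1e-6)
    expect_true(all(ddde$U >= 0) && all(ddde$I >= 0) && all(ddde$P >= 0))
  }
})

test_that("a two-point kernel equals the hand-built two-delay oracle", {
  p <- base_params()
  g <- simulation_grid(8, 0.01)
  k <- structure(list(dt = g$dt, offsets = c(80L, 120L), weights = c(0.5, 0.5)),
                 class = "discretized_kernel")
  ddde <- simulate_ddde(p, k, burst_profile("constant", 100), g)
  orc <- oracle_multi_delay(p, c(80L, 120L), c(0.5, 0.5), c(100, 100),
                            g$dt, g$n_steps)
  expect_lt(max_rel_diff(ddde$U, orc$U), 1e-12)
  expect_lt(max_rel_diff(ddde$I, orc$I), 1e-12)
  expect_lt(max_rel_diff(ddde$P, orc$P), 1e-12)
})

test_that("discrete burst and adsorption mixtures reduce to their means", {
  # mixture-expanded system vs the mean-parameter solver: the heterogeneity
  # in beta (given tau) and phi enters the equations only through the means
  p <- base_params()
  g <- simulation_grid(8, 0.01)
  d <- latent_distribution("gamma", 1, 0.3, 0.2)
  k <- discretize_density(d, g$dt)
  bmax <- normalize_beta_max(100, d, p$r_beta, p$D, p$beta_tau50)
  b <- burst_profile("latent-dependent", 100, bmax)
  ddde <- simulate_ddde(p, k, b, g)

  beta0 <- function(tau) mean_burst_size(tau, b, p$r_beta, p$D, p$beta_tau50)
  orc <- oracle_mixture_expanded(
    p, k$offsets, k$weights,
    phi_factors = c(0.4, 1.9), phi_probs = c(0.6, 0.4),     # mean factor 1
    beta_funs = list(function(tau) 0.5 * beta0(tau),        # mean beta0(tau)
                     function(tau) 1.5 * beta0(tau)),
    beta_probs = c(0.5, 0.5),
    dt = g$dt, n_steps = g$n_steps)
  expect_lt(max_rel_diff(ddde$U, orc$U), 1e-8)
  expect_lt(max_rel_diff(ddde$I, orc$I), 1e-8)
  expect_lt(max_rel_diff(ddde$P, orc$P), 1e-8)
})

test_that("the transit chain matches the gamma-kernel distributed model", {
  p <- base_params(delta_I = 0.02)
  for (N in c(4, 16, 25)) {
    rsd <- 1 / sqrt(N)
    d <- latent_distribution("gamma", 1, rsd, 0)
    sim_ddde <- function(dt, t_end) {
      simulate_ddde(p, discretize_density(d, dt),
                    burst_profile("constant", p$beta_0_mean),
                    simulation_grid(t_end, dt), "rk4")
    }
    sim_tc <- function(dt, t_end) {
      simulate_tc(p, tc_config_from_distribution(1, rsd),
                  simulation_grid(t_end, dt))
    }
    ra <- run_with_convergence(sim_ddde, t_end = 24)
    rb <- run_with_convergence(sim_tc, t_end = 24)
    expect_true(ra$converged && rb$converged)
    cmp <- compare_trajectories(ra$trajectory, rb$trajectory)
    expect_lt(cmp$bacterial_error_pct, 1)
    expect_lt(cmp$viral_error_pct, 1)
  }
})

test_that("transit configuration arithmetic and guards", {
  tc <- tc_config_from_distribution(1, 0.25)
  expect_equal(tc$N, 16L); expect_equal(tc$k_tr, 16)
  tc <- tc_config_from_distribution(2, 0.10)
  expect_equal(tc$N, 100L); expect_equal(tc$k_tr, 50)
  tc <- tc_config_from_distribution(1, 0.50)
  expect_equal(tc$N, 4L); expect_equal(tc$k_tr, 4)
  expect_error(tc_config_from_distribution(1, 0), "infinite chain")
})

test_that("euler and rk4 agree within the convergence criterion", {
  p <- base_params()
  d <- latent_distribution("lognormal", 1, 0.3, 0)
  bmax <- normalize_beta_max(100, d, p$r_beta, p$D, p$beta_tau50)
  b <- burst_profile("latent-dependent", 100, bmax)
  mk <- function(st) function(dt, t_end) {
    simulate_ddde(p, discretize_density(d, dt), b, simulation_grid(t_end, dt), st)
  }
  re <- run_with_convergence(mk("euler"), t_end = 24, max_halvings = 6L)
  rr <- run_with_convergence(mk("rk4"), t_end = 24)
  expect_true(re$converged && rr$converged)
  cmp <- compare_trajectories(re$trajectory, rr$trajectory)
  expect_lt(cmp$bacterial_error_pct, 1)
  expect_lt(cmp$viral_error_pct, 1)
})

test_that("successive grid halvings shrink the step-to-step distance", {
  p <- base_params()
  d <- latent_distribution("lognormal", 1, 0.3, 0)
  b <- burst_profile("constant", 100)
  sim <- function(dt) {
    simulate_ddde(p, discretize_density(d, dt), b, simulation_grid(24, dt))
  }
  dts <- 0.02 / 2^(0:3)
  trajs <- lapply(dts, sim)
  errs <- sapply(1:3, function(i) {
    curve_error(trajs[[i]], phagedyn:::thin_trajectory(trajs[[i + 1]], 2L),
                "viral")
  })
  expect_true(all(diff(errs) < 0))
})

test_that("convergence control reports its contract cases", {
  p <- base_params(P_init = 0, delta_U = 0)
  sim <- function(dt, t_end) simulate_dde(p, 1, simulation_grid(t_end, dt))
  res <- run_with_convergence(sim, dt_init = 0.1, t_end = 10)
  expect_true(res$converged)
  expect_lte(res$n_halvings, 3)

  # a trivially loose criterion accepts the first halving
  res100 <- run_with_convergence(sim, dt_init = 0.1, criterion = 100, t_end = 10)
  expect_true(res100$converged)
  expect_identical(res100$n_halvings, 1L)

  # exhausting the halving budget is a reported outcome, not an error
  p2 <- base_params()
  d <- latent_distribution("lognormal", 1, 0.3, 0)
  sim2 <- function(dt, t_end) {
    simulate_ddde(p2, discretize_density(d, dt), burst_profile("constant", 100),
                  simulation_grid(t_end, dt))
  }
  res_hard <- run_with_convergence(sim2, criterion = 1e-6, max_halvings = 1L,
                                   t_end = 12)
  expect_false(res_hard$converged)
  expect_true(all(res_hard$errors > 1e-6))
})

test_that("kernel/grid step mismatch is rejected", {
  p <- base_params()
  d <- latent_distribution("lognormal", 1, 0.3, 0)
  k <- discretize_density(d, 0.01)
  expect_error(simulate_ddde(p, k, burst_profile("constant", 100),
                             simulation_grid(10, 0.02)),
               "kernel.dt")
})

test_that("horizon extension engages only while a load is still moving", {
  # slow-growing culture: still climbing at 12 h, quiet by 48 h
  p <- base_params(P_init = 0, U_init = 1e4, r_max = 0.6, delta_U = 0.1)
  sim <- function(dt, t_end) simulate_dde(p, 1, simulation_grid(t_end, dt))
  res <- run_with_convergence(sim, t_end = 12, max_extensions = 3L)
  expect_gt(res$t_end, 12)
  expect_false(phagedyn:::tail_active(res$trajectory))
  # fixed_horizon suppresses extension entirely
  res_fix <- run_with_convergence(sim, t_end = 12, max_extensions = 3L,
                                  fixed_horizon = TRUE)
  expect_equal(res_fix$t_end, 12)
})
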