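test_that("gamma and lognormal families match targets in closed form", {
  g <- latent_distribution("gamma", tau_0 = 1, rsd_tau = 0.5, tau_min = 0)
  expect_equal(g$internal_params$shape, 4)
  expect_equal(g$internal_params$scale, 0.25)

  ln <- latent_distribution("lognormal", tau_0 = 1, rsd_tau = 0.3, tau_min = 0)
  expect_equal(ln$internal_params$sdlog^2, log(1.09), tolerance = 1e-12)
  expect_equal(ln$internal_params$meanlog, -log(1.09) / 2, tolerance = 1e-12)

  pm <- latent_distribution("point-mass", tau_0 = 1.5, rsd_tau = 0)
  expect_equal(pm$internal_params$location, 1.5)
  expect_equal(distribution_median(pm), 1.5)
})

test_that("rsd 0 and the point-mass family imply each other", {
  expect_error(latent_distribution("gamma", 1, 0), "point-mass")
  expect_error(latent_distribution("point-mass", 1, 0.2), "rsd_tau = 0")
})

test_that("truncated-normal parent parameters reproduce the target moments", {
  # negligible truncation: parent parameters are the targets themselves
  ps <- solve_truncated_normal_params(1, 0.1, tau_min = 0)
  expect_equal(unname(ps["parent_mean"]), 1, tolerance = 1e-6)
  expect_equal(unname(ps["parent_sd"]), 0.1, tolerance = 1e-6)

  # strong truncation, checked against an independent rejection sampler
  d <- latent_distribution("truncated-normal", 1, 0.5, 0)
  ip <- d$internal_params
  set.seed(11)
  x <- rnorm(3e6, ip$parent_mean, ip$parent_sd)
  x <- x[x >= 0][1:1e6]
  expect_lt(abs(mean(x) - 1), 3 * sd(x) / sqrt(length(x)))
  s2 <- var(x)
  se_s2 <- sqrt((mean((x - mean(x))^4) - s2^2) / length(x))
  expect_lt(abs(s2 - 0.25), 3 * se_s2)

  # strong truncation above zero, checked by quadrature of the truncated
  # density (sd = mean - bound is the unreachable exponential limit of the
  # family, so 0.4 is close to the strongest feasible truncation here)
  d2 <- latent_distribution("truncated-normal", 1, 0.4, 0.5)
  m <- phagedyn:::dist_moments_quadrature(d2)
  expect_equal(unname(m["mean"]), 1, tolerance = 1e-8)
  expect_equal(unname(m["sd"]), 0.4, tolerance = 1e-8)
  expect_error(latent_distribution("truncated-normal", 1, 0.5, 0.5),
               class = "phagedyn_invalid_params")
})

test_that("every feasible family/target combination moment-matches to 1e-6", {
  for (tau_0 in c(0.25, 1, 3)) {
    for (rsd in c(0.1, 0.3, 0.5)) {
      for (tau_min in c(0, tau_0 / 4, tau_0 / 2)) {
        for (fam in c("lognormal", "gamma", "truncated-normal")) {
          sd_target <- rsd * tau_0
          if (fam == "truncated-normal" && sd_target >= 0.95 * (tau_0 - tau_min)) {
            expect_error(latent_distribution(fam, tau_0, rsd, tau_min),
                         class = "phagedyn_invalid_params")
            next
          }
          d <- latent_distribution(fam, tau_0, rsd, tau_min)
          m <- phagedyn:::dist_moments_quadrature(d)
          expect_lt(abs(m[["mean"]] - tau_0) / tau_0, 1e-6)
          expect_lt(abs(m[["sd"]] - sd_target) / sd_target, 1e-6)
          expect_equal(dist_density(d, tau_min - 1e-9), 0)
        }
      }
    }
  }
})

test_that("discretised kernels conserve mass and the first moment", {
  # commensurate point mass: one node, weight one
  pm <- latent_distribution("point-mass", 1.5, 0)
  k <- discretize_density(pm, dt = 0.01)
  expect_equal(k$offsets, 150L)
  expect_equal(k$weights, 1.0)

  g <- latent_distribution("gamma", 1, 0.3, 0)
  k <- discretize_density(g, dt = 0.001)
  expect_lt(abs(sum(k$weights) - 1), 1e-10)
  m1 <- sum(k$offsets * k$dt * k$weights)
  expect_lt(abs(m1 - 1), 0.002)
  expect_true(all(k$offsets >= 1))

  # CDF-difference binning conserves the mean to the tail-truncation floor
  # at any dt; grid refinement shows up in the second moment, where halving
  # dt at least halves the error
  err <- sapply(c(0.1, 0.05, 0.025), function(dt) {
    kk <- discretize_density(g, dt)
    m1 <- sum(kk$offsets * kk$dt * kk$weights)
    abs(sqrt(sum((kk$offsets * kk$dt - m1)^2 * kk$weights)) - 0.3)
  })
  expect_lt(err[2], 0.6 * err[1])
  expect_lt(err[3], 0.6 * err[2])
})

test_that("kernels collapse to the point mass as rsd shrinks", {
  dt <- 0.01
  for (fam in c("lognormal", "gamma", "truncated-normal")) {
    d <- latent_distribution(fam, 1, 0.005, 0)
    k <- suppressWarnings(discretize_density(d, dt))
    tau_k <- k$offsets * dt
    expect_gt(sum(k$weights[abs(tau_k - 1) <= 3 * dt]), 0.999)
  }
})

test_that("a grid step above the sd triggers a resolution warning", {
  d <- latent_distribution("gamma", 1, 0.1, 0)
  expect_warning(discretize_density(d, dt = 0.2), "near-degenerate")
})

test_that("medians follow the closed forms", {
  ln <- latent_distribution("lognormal", 1, 0.3, 0)
  expect_equal(distribution_median(ln), 1 / sqrt(1.09), tolerance = 1e-12)
  # near-symmetric truncated normal: median at the mean
  tn <- latent_distribution("truncated-normal", 2, 0.1, 0)
  expect_equal(distribution_median(tn), 2, tolerance = 1e-6)
})

test_that("inverse-CDF sampling matches the analytic CDF", {
  d <- latent_distribution("gamma", 1.5, 0.4, 0.3)
  set.seed(3)
  x <- dist_random(d, 2e4)
  expect_true(all(x >= 0.3))
  ks <- suppressWarnings(stats::ks.test(x, function(q) dist_cdf(d, q)))
  expect_gt(ks$p.value, 0.01)
})
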