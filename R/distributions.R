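#' Latent-period distributions
#'
#' Constructs a latent-period distribution with target mean `tau_0`, relative
#' standard deviation `rsd_tau` and minimal latent period `tau_min`. Four
#' families are supported:
#'
#' * `"truncated-normal"`: a normal truncated to `[tau_min, Inf)`; the parent
#'   mean/sd are solved by Newton-Raphson so that the truncated moments hit
#'   the targets exactly (see [solve_truncated_normal_params()]).
#' * `"lognormal"`, `"gamma"`: shifted by `tau_min` (support `[tau_min, Inf)`)
#'   with the shifted variable moment-matched in closed form.
#' * `"point-mass"`: all mass at `tau_0` (the `rsd_tau = 0` limit).
#'
#' @param family Distribution family.
#' @param tau_0 Target mean latent period (h), `tau_0 > tau_min`.
#' @param rsd_tau Target relative standard deviation `sd/tau_0` in `[0, 1)`.
#'   `rsd_tau = 0` forces (and requires) the point-mass family.
#' @param tau_min Minimal possible latent period (h, >= 0). Density is exactly
#'   zero below it.
#' @return An object of class `latent_distribution`.
#' @examples
#' d <- latent_distribution("gamma", tau_0 = 1, rsd_tau = 0.5, tau_min = 0)
#' d$internal_params   # shape 4, scale 0.25
#' distribution_median(d)
#' @export
latent_distribution <- function(family = c("truncated-normal", "lognormal",
                                           "gamma", "point-mass"),
                                tau_0, rsd_tau, tau_min = 0) {
  family <- match.arg(family)
  if (!is.finite(tau_0) || !is.finite(rsd_tau) || !is.finite(tau_min)) {
    stop("latent_distribution: non-finite arguments")
  }
  if (tau_min < 0) stop("latent_distribution: tau_min must be >= 0")
  if (tau_0 <= tau_min) stop("latent_distribution: tau_0 must exceed tau_min")
  if (rsd_tau < 0 || rsd_tau >= 1) stop("latent_distribution: rsd_tau must be in [0, 1)")
  if (rsd_tau == 0 && family != "point-mass") {
    stop("latent_distribution: rsd_tau = 0 requires family = 'point-mass'")
  }
  if (family == "point-mass" && rsd_tau != 0) {
    stop("latent_distribution: point-mass requires rsd_tau = 0")
  }

  sd <- rsd_tau * tau_0
  internal <- switch(family,
    "point-mass" = list(location = tau_0),
    "gamma" = {
      m <- tau_0 - tau_min
      shape <- (m / sd)^2
      scale <- sd^2 / m
      list(shape = shape, scale = scale)
    },
    "lognormal" = {
      m <- tau_0 - tau_min
      sigma2 <- log1p((sd / m)^2)
      list(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
    },
    "truncated-normal" = {
      if (sd >= 0.95 * (tau_0 - tau_min)) {
        stop(structure(
          class = c("phagedyn_invalid_params", "error", "condition"),
          list(message = paste0(
            "latent_distribution: truncated normal cannot realise sd ",
            sprintf("%.4g with mean %.4g above truncation %.4g ", sd, tau_0, tau_min),
            "(the family's sd is bounded by mean - tau_min)"),
            call = sys.call(-1))))
      }
      ps <- solve_truncated_normal_params(tau_0, sd, tau_min)
      list(parent_mean = ps[["parent_mean"]], parent_sd = ps[["parent_sd"]])
    })

  structure(list(family = family, tau_0 = tau_0, rsd_tau = rsd_tau,
                 tau_min = tau_min, internal_params = internal),
            class = "latent_distribution")
}

#' @export
print.latent_distribution <- function(x, ...) {
  cat(sprintf("Latent-period distribution: %s\n", x$family))
  cat(sprintf("  mean tau_0 = %g h, rsd = %g, tau_min = %g h\n",
              x$tau_0, x$rsd_tau, x$tau_min))
  ip <- x$internal_params
  cat("  internal:", paste(sprintf("%s = %.6g", names(ip), unlist(ip)),
                           collapse = ", "), "\n")
  invisible(x)
}

# Mills-ratio-stable hazard of the standard normal, lambda(a) = phi(a)/(1-Phi(a))
.norm_hazard <- function(a) {
  exp(stats::dnorm(a, log = TRUE) - stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
}

# Mean and sd of a normal(mu, sigma) truncated to [a, Inf), analytic.
.truncnorm_moments <- function(mu, sigma, a) {
  al <- (a - mu) / sigma
  lam <- .norm_hazard(al)
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + al * lam - lam^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

#' Solve truncated-normal parent parameters by Newton-Raphson
#'
#' Finds the parent normal `(mu, sigma)` such that the normal truncated to
#' `[tau_min, Inf)` has mean `tau_0` and standard deviation `sd`. Uses damped
#' Newton-Raphson on the two analytic moment equations (in `(mu, log sigma)`
#' coordinates so `sigma` stays positive), starting from the untruncated guess
#' `(tau_0, sd)`.
#'
#' @param tau_0 Target truncated mean (h), `tau_0 > tau_min`.
#' @param sd Target truncated standard deviation (> 0).
#' @param tau_min Lower truncation bound (h).
#' @param tol Convergence tolerance on both moment residuals.
#' @param max_iter Iteration cap; non-convergence raises an error reporting the
#'   final residual.
#' @return Named vector `c(parent_mean, parent_sd)`.
#' @export
solve_truncated_normal_params <- function(tau_0, sd, tau_min,
                                          tol = 1e-10, max_iter = 100L) {
  if (tau_0 <= tau_min) stop("solve_truncated_normal_params: tau_0 must exceed tau_min")
  if (sd <= 0) stop("solve_truncated_normal_params: sd must be > 0")

  resid <- function(theta) {
    m <- .truncnorm_moments(theta[1], exp(theta[2]), tau_min)
    c(m[["mean"]] - tau_0, m[["sd"]] - sd)
  }
  theta <- c(tau_0, log(sd))
  f <- resid(theta)
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < tol) {
      return(c(parent_mean = theta[1], parent_sd = exp(theta[2])))
    }
    # numeric Jacobian, central differences
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      h <- 1e-6 * max(1, abs(theta[j]))
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      J[, j] <- (resid(tp) - resid(tm)) / (2 * h)
    }
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      stop(sprintf(paste0("solve_truncated_normal_params: singular Jacobian at ",
                          "iteration %d, residual %.3g"), it, max(abs(f))))
    }
    # damped update: backtrack until the residual norm does not blow up
    lambda <- 1
    repeat {
      theta_new <- theta - lambda * step
      f_new <- resid(theta_new)
      if (all(is.finite(f_new)) &&
          (sum(f_new^2) < sum(f^2) || lambda < 1e-4)) break
      lambda <- lambda / 2
    }
    theta <- theta_new
    f <- f_new
  }
  stop(sprintf(paste0("solve_truncated_normal_params: no convergence after %d ",
                      "iterations; final residual %.3g"), max_iter, max(abs(f))))
}

# ---- density / cdf / quantile / sampling on the natural scale ---------------

#' Density, CDF, quantile and sampling of a latent distribution
#'
#' Accessors on the natural (hours) scale: density is zero below `tau_min`;
#' `dist_random` samples by inverse-CDF.
#'
#' @param dist A [latent_distribution()].
#' @param x,q Evaluation points (h).
#' @param p Probabilities.
#' @param n Number of draws.
#' @name dist_accessors
NULL

#' @rdname dist_accessors
#' @export
dist_density <- function(dist, x) {
  ip <- dist$internal_params
  out <- switch(dist$family,
    "point-mass" = stop("dist_density: point-mass has no density"),
    "gamma" = stats::dgamma(x - dist$tau_min, shape = ip$shape, scale = ip$scale),
    "lognormal" = stats::dlnorm(x - dist$tau_min, meanlog = ip$meanlog, sdlog = ip$sdlog),
    "truncated-normal" = {
      z <- stats::pnorm(dist$tau_min, ip$parent_mean, ip$parent_sd, lower.tail = FALSE)
      ifelse(x < dist$tau_min, 0,
             stats::dnorm(x, ip$parent_mean, ip$parent_sd) / z)
    })
  out[x < dist$tau_min] <- 0
  out
}

#' @rdname dist_accessors
#' @export
dist_cdf <- function(dist, q) {
  ip <- dist$internal_params
  out <- switch(dist$family,
    "point-mass" = as.numeric(q >= dist$tau_0),
    "gamma" = stats::pgamma(pmax(q - dist$tau_min, 0), shape = ip$shape, scale = ip$scale),
    "lognormal" = stats::plnorm(pmax(q - dist$tau_min, 0), meanlog = ip$meanlog,
                                sdlog = ip$sdlog),
    "truncated-normal" = {
      z <- stats::pnorm(dist$tau_min, ip$parent_mean, ip$parent_sd, lower.tail = FALSE)
      pmin(pmax((stats::pnorm(q, ip$parent_mean, ip$parent_sd) -
                 stats::pnorm(dist$tau_min, ip$parent_mean, ip$parent_sd)) / z, 0), 1)
    })
  out
}

#' @rdname dist_accessors
#' @export
dist_quantile <- function(dist, p) {
  ip <- dist$internal_params
  switch(dist$family,
    "point-mass" = rep(dist$tau_0, length(p)),
    "gamma" = dist$tau_min + stats::qgamma(p, shape = ip$shape, scale = ip$scale),
    "lognormal" = dist$tau_min + stats::qlnorm(p, meanlog = ip$meanlog, sdlog = ip$sdlog),
    "truncated-normal" = {
      p0 <- stats::pnorm(dist$tau_min, ip$parent_mean, ip$parent_sd)
      stats::qnorm(p0 + p * (1 - p0), ip$parent_mean, ip$parent_sd)
    })
}

#' @rdname dist_accessors
#' @export
dist_random <- function(dist, n) {
  dist_quantile(dist, stats::runif(n))
}

#' Median latent period
#'
#' The 0.5 quantile of the (shifted/truncated) latent-period distribution,
#' used by the "Fixed Median" approximation scenario.
#'
#' @param dist A [latent_distribution()].
#' @return Median latent period (h).
#' @export
distribution_median <- function(dist) {
  dist_quantile(dist, 0.5)
}

# Quadrature mean and sd of the distribution on its truncated support;
# used by validity tests, not by the solvers.
dist_moments_quadrature <- function(dist, rel_tol = 1e-10) {
  if (dist$family == "point-mass") return(c(mean = dist$tau_0, sd = 0))
  lo <- dist$tau_min
  hi <- dist_quantile(dist, 1 - 1e-13)
  m1 <- stats::integrate(function(x) x * dist_density(dist, x), lo, hi,
                         rel.tol = rel_tol, abs.tol = 0, subdivisions = 2000L)$value
  m2 <- stats::integrate(function(x) (x - m1)^2 * dist_density(dist, x), lo, hi,
                         rel.tol = rel_tol, abs.tol = 0, subdivisions = 2000L)$value
  c(mean = m1, sd = sqrt(m2))
}

#' Discretise a latent-period density onto a simulation grid
#'
#' Produces the grid-aligned probability weights the distributed-delay solver
#' convolves against the infection history. Node `k` (delay `k * dt`) receives
#' the probability mass of the bin `[k*dt - dt/2, k*dt + dt/2]` (CDF
#' differences, so probability is conserved even for narrow densities); any
#' mass below half a step is merged into the first node, the support is cut at
#' `tail_quantile`, and the weights are renormalised to sum to one.
#'
#' @param dist A [latent_distribution()].
#' @param dt Grid step (h, > 0).
#' @param tail_quantile Upper support cut as a probability; default `1 - 1e-6`.
#' @return An object of class `discretized_kernel` with fields `dt`, `offsets`
#'   (integer delay indices, all >= 1) and `weights` (summing to 1).
#' @export
discretize_density <- function(dist, dt, tail_quantile = 1 - 1e-6) {
  stopifnot(inherits(dist, "latent_distribution"))
  if (dt <= 0) stop("discretize_density: dt must be > 0")
  if (tail_quantile <= 0 || tail_quantile >= 1) {
    stop("discretize_density: tail_quantile must be in (0, 1)")
  }

  if (dist$family == "point-mass") {
    k <- max(1L, as.integer(round(dist$tau_0 / dt)))
    kern <- list(dt = dt, offsets = k, weights = 1.0)
    return(structure(kern, class = "discretized_kernel"))
  }

  sd <- dist$rsd_tau * dist$tau_0
  if (dt > sd) {
    warning(sprintf(paste0("discretize_density: dt = %g exceeds the distribution ",
                           "sd = %g; kernel is near-degenerate"), dt, sd))
  }
  k_hi <- max(1L, as.integer(ceiling(dist_quantile(dist, tail_quantile) / dt)))
  k <- seq_len(k_hi)
  edges_hi <- (k + 0.5) * dt
  edges_lo <- (k - 0.5) * dt
  w <- dist_cdf(dist, edges_hi) - dist_cdf(dist, edges_lo)
  w[1] <- w[1] + dist_cdf(dist, edges_lo[1])   # merge sub-half-step mass
  keep <- which(w > 0)
  if (length(keep) == 0) stop("discretize_density: kernel has no mass on the grid")
  k <- k[min(keep):max(keep)]
  w <- w[min(keep):max(keep)]
  w <- w / sum(w)
  structure(list(dt = dt, offsets = as.integer(k), weights = w),
            class = "discretized_kernel")
}

#' @export
print.discretized_kernel <- function(x, ...) {
  m1 <- sum(x$offsets * x$dt * x$weights)
  cat(sprintf("Discretised latent-period kernel: %d nodes, dt = %g h\n",
              length(x$offsets), x$dt))
  cat(sprintf("  support [%g, %g] h, first moment %.5g h\n",
              min(x$offsets) * x$dt, max(x$offsets) * x$dt, m1))
  invisible(x)
}
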