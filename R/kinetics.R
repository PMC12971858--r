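#' Kinetic parameters of the phage-bacteria model
#'
#' Bundles the population-level rate constants and inoculums used by all three
#' model structures (fixed-delay DDE, distributed-delay DDDE, transit
#' compartments). All rates are per hour, concentrations per mL.
#'
#' @param r_max Maximal bacterial growth rate (/h).
#' @param K_C Ceiling (carrying) bacterial concentration (bacteria/mL).
#' @param phi_max Maximal adsorption rate (mL/cell/h).
#' @param P_50 Phage concentration at half-maximal adsorption (phage/mL).
#' @param delta_U,delta_I,delta_P Decay rates of uninfected bacteria, infected
#'   bacteria and free phage (/h).
#' @param beta_0_mean Population mean burst size (phage/bacterium).
#' @param r_beta Intracellular phage replication rate (/h).
#' @param D Burst-onset delay: latent periods at or below `D` release no phage (h).
#' @param beta_tau50 Latent period at half-maximal burst size (h); must be >= `D`.
#' @param U_init,P_init Initial inoculums (bacteria/mL, phage/mL).
#'
#' @return An object of class `kinetic_params` (a validated named list).
#' @examples
#' p <- kinetic_params(r_max = 1, K_C = 1e9, phi_max = 1e-8, P_50 = 1e9,
#'                     delta_U = 0.1, delta_I = 0.1, delta_P = 0.05,
#'                     beta_0_mean = 100, r_beta = 5, D = 0.2, beta_tau50 = 0.8,
#'                     U_init = 1e6, P_init = 1e5)
#' p
#' @export
kinetic_params <- function(r_max, K_C, phi_max, P_50,
                           delta_U, delta_I, delta_P,
                           beta_0_mean, r_beta, D, beta_tau50,
                           U_init, P_init) {
  p <- list(r_max = r_max, K_C = K_C, phi_max = phi_max, P_50 = P_50,
            delta_U = delta_U, delta_I = delta_I, delta_P = delta_P,
            beta_0_mean = beta_0_mean, r_beta = r_beta, D = D,
            beta_tau50 = beta_tau50, U_init = U_init, P_init = P_init)
  vals <- unlist(p)
  if (any(!is.finite(vals))) {
    stop("kinetic_params: all fields must be finite numbers; offending: ",
         paste(names(p)[!is.finite(vals)], collapse = ", "))
  }
  if (any(vals < 0)) {
    stop("kinetic_params: all fields must be nonnegative; offending: ",
         paste(names(p)[vals < 0], collapse = ", "))
  }
  if (p$K_C <= 0) stop("kinetic_params: K_C must be > 0")
  if (p$P_50 <= 0) stop("kinetic_params: P_50 must be > 0")
  if (p$beta_tau50 < p$D) stop("kinetic_params: beta_tau50 must be >= D")
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (phage-bacteria model)\n")
  cat(sprintf("  growth:     r_max = %g /h, K_C = %.3g bact/mL\n", x$r_max, x$K_C))
  cat(sprintf("  adsorption: phi_max = %.3g mL/cell/h, P_50 = %.3g phage/mL\n",
              x$phi_max, x$P_50))
  cat(sprintf("  burst:      beta_0_mean = %g, r_beta = %g /h, D = %g h, beta_tau50 = %g h\n",
              x$beta_0_mean, x$r_beta, x$D, x$beta_tau50))
  cat(sprintf("  decay:      delta_U = %g, delta_I = %g, delta_P = %g /h\n",
              x$delta_U, x$delta_I, x$delta_P))
  cat(sprintf("  inoculums:  U_init = %.3g bact/mL, P_init = %.3g phage/mL\n",
              x$U_init, x$P_init))
  invisible(x)
}

#' Logistic bacterial growth rate
#'
#' Per-capita growth rate `r_max * (1 - (U + I) / K_C)`. Both uninfected and
#' infected cells occupy the niche; the rate is negative above the ceiling.
#'
#' @param r_max Maximal growth rate (/h).
#' @param K_C Ceiling concentration (> 0).
#' @param U,I Uninfected and infected bacterial concentrations (>= 0).
#' @return Growth rate (/h); vectorised over `U` and `I`.
#' @export
logistic_growth_rate <- function(r_max, K_C, U, I) {
  if (!all(is.finite(c(r_max, K_C, U, I)))) {
    stop("logistic_growth_rate: non-finite input")
  }
  if (K_C <= 0) stop("logistic_growth_rate: K_C must be > 0")
  if (any(U < 0) || any(I < 0)) stop("logistic_growth_rate: U, I must be >= 0")
  r_max * (1 - (U + I) / K_C)
}

#' Saturable phage adsorption rate
#'
#' Adsorption rate `phi_max * P_50 / (P_50 + P)`: half-maximal at `P = P_50`,
#' approaching zero as free phage saturate the available receptors.
#'
#' @param phi_max Maximal adsorption rate (mL/cell/h).
#' @param P_50 Phage concentration at half-maximal adsorption (> 0).
#' @param P Free phage concentration (>= 0); vectorised.
#' @return Adsorption rate in (0, phi_max].
#' @export
saturable_adsorption_rate <- function(phi_max, P_50, P) {
  if (!all(is.finite(c(phi_max, P_50))) || any(!is.finite(P) & !is.infinite(P))) {
    stop("saturable_adsorption_rate: non-finite input")
  }
  if (P_50 <= 0) stop("saturable_adsorption_rate: P_50 must be > 0")
  if (any(P < 0)) stop("saturable_adsorption_rate: P must be >= 0")
  phi_max * P_50 / (P_50 + P)
}

#' Burst-size profile
#'
#' The mean burst size conditional on the latent period is either constant
#' (`beta_0(tau) = beta_0_mean` for every tau, the assumption the transit
#' compartment model makes) or latent-period dependent through a saturating
#' sigmoid governed by the intracellular replication rate.
#'
#' @param mode `"latent-dependent"` or `"constant"`.
#' @param beta_0_mean Population mean burst size.
#' @param beta_max Maximal burst size; required in latent-dependent mode
#'   (usually produced by [normalize_beta_max()]).
#' @return An object of class `burst_profile`.
#' @seealso [mean_burst_size()], [normalize_beta_max()]
#' @export
burst_profile <- function(mode = c("latent-dependent", "constant"),
                          beta_0_mean, beta_max = NULL) {
  mode <- match.arg(mode)
  if (!is.finite(beta_0_mean) || beta_0_mean < 0) {
    stop("burst_profile: beta_0_mean must be a nonnegative number")
  }
  if (mode == "latent-dependent") {
    if (is.null(beta_max) || !is.finite(beta_max) || beta_max <= 0) {
      stop("burst_profile: latent-dependent mode requires beta_max > 0")
    }
  }
  structure(list(mode = mode, beta_0_mean = beta_0_mean, beta_max = beta_max),
            class = "burst_profile")
}

#' @export
print.burst_profile <- function(x, ...) {
  if (x$mode == "constant") {
    cat(sprintf("Burst profile: constant, beta_0 = %g phage/cell\n", x$beta_0_mean))
  } else {
    cat(sprintf("Burst profile: latent-dependent, beta_max = %g, population mean = %g\n",
                x$beta_max, x$beta_0_mean))
  }
  invisible(x)
}

# Bracketed sigmoid of the burst law with beta_max = 1, evaluated stably.
# g(tau) = (e^x - 1) / (e^a + e^x - 2), x = r_beta*(tau - D), a = r_beta*(beta_tau50 - D),
# rewritten as (1 - e^-x) / (1 + (e^a - 2) e^-x) so large x saturates to 1
# instead of overflowing. Zero at and below tau = D.
burst_fraction <- function(tau, r_beta, D, beta_tau50) {
  x <- r_beta * (tau - D)
  a <- r_beta * (beta_tau50 - D)
  ea <- exp(a)                      # bounded: r_beta <= ~10, beta_tau50 <= ~3
  emx <- exp(-pmax(x, 0))
  g <- (1 - emx) / (1 + (ea - 2) * emx)
  g[tau <= D] <- 0
  g
}

#' Mean burst size at a given latent period
#'
#' In latent-dependent mode the mean burst size rises sigmoidally with the
#' latent period: zero at and below the burst-onset delay `D`, half of
#' `beta_max` at `tau = beta_tau50`, saturating at `beta_max`. In constant mode
#' the population mean is returned regardless of `tau`. Evaluation is
#' numerically stable for arbitrarily large `r_beta * tau`.
#'
#' @param tau Latent period(s), hours (>= 0); vectorised.
#' @param burst A [burst_profile()].
#' @param r_beta Intracellular replication rate (/h).
#' @param D Burst-onset delay (h).
#' @param beta_tau50 Latent period of half-maximal burst (h, >= D).
#' @return Mean burst size(s), phage/bacterium.
#' @export
mean_burst_size <- function(tau, burst, r_beta, D, beta_tau50) {
  stopifnot(inherits(burst, "burst_profile"))
  if (any(tau < 0)) stop("mean_burst_size: tau must be >= 0")
  if (beta_tau50 < D) stop("mean_burst_size: beta_tau50 must be >= D")
  if (burst$mode == "constant") {
    return(rep(burst$beta_0_mean, length(tau)))
  }
  burst$beta_max * burst_fraction(tau, r_beta, D, beta_tau50)
}

#' Normalise the maximal burst size to a target population mean
#'
#' The quantity estimated from single-step growth curves is the population
#' mean burst size, the average of the latent-dependent burst law over the
#' latent-period density. This solves for `beta_max` such that
#' `E[beta_0(tau)] = beta_0_mean`, i.e. divides the target mean by the
#' quadrature integral of the unit-amplitude burst fraction against the
#' density over `[tau_min, Inf)`.
#'
#' @param beta_0_mean Target population mean burst size.
#' @param dist A [latent_distribution()].
#' @param r_beta,D,beta_tau50 Burst-law parameters as in [mean_burst_size()].
#' @param rel_tol Relative tolerance of the adaptive quadrature.
#' @return `beta_max` such that the density-weighted mean burst equals
#'   `beta_0_mean`.
#' @details The integral is evaluated adaptively up to the `1 - 1e-8` quantile
#'   of the distribution. If essentially all density mass lies at or below the
#'   burst-onset delay `D` the normalisation is ill-posed and an error of class
#'   `phagedyn_invalid_params` is raised; the Monte Carlo layer treats that as
#'   an invalid parameter set and resamples.
#' @export
normalize_beta_max <- function(beta_0_mean, dist, r_beta, D, beta_tau50,
                               rel_tol = 1e-9) {
  stopifnot(inherits(dist, "latent_distribution"))
  if (beta_tau50 < D) stop("normalize_beta_max: beta_tau50 must be >= D")
  if (dist$family == "point-mass") {
    denom <- burst_fraction(dist$tau_0, r_beta, D, beta_tau50)
  } else {
    upper <- dist_quantile(dist, 1 - 1e-8)
    lower <- max(dist$tau_min, 0)
    denom <- stats::integrate(
      function(x) burst_fraction(x, r_beta, D, beta_tau50) * dist_density(dist, x),
      lower = lower, upper = upper,
      rel.tol = rel_tol, abs.tol = 0, subdivisions = 2000L
    )$value
  }
  if (!is.finite(denom) || denom < 1e-12) {
    stop(structure(
      class = c("phagedyn_invalid_params", "error", "condition"),
      list(message = sprintf(
        paste0("normalize_beta_max: burst normalisation integral is ",
               "degenerate (%.3g); distribution mass lies at or below the ",
               "burst-onset delay D"), denom),
        call = sys.call(-1))))
  }
  beta_0_mean / denom
}
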