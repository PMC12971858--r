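# Independent reference integrators, kept deliberately naive (plain R Euler
# loops, explicit sums) so they share no code path with the package solvers.

# Fixed-delay Euler oracle with an arbitrary list of (delay index, weight)
# terms: lysis outflow sum_k w_k * exp(-dI*tau_k) * H[n-k], phage source
# sum_k beta_k * exp(-dI*tau_k) * w_k * H[n-k].
oracle_multi_delay <- function(params, k_delays, weights, betas, dt, n_steps) {
  p <- params
  U <- I <- P <- H <- numeric(n_steps + 1)
  U[1] <- p$U_init; P[1] <- p$P_init
  surv <- exp(-p$delta_I * k_delays * dt)
  for (n in 0:(n_steps - 1)) {
    i <- n + 1
    phi <- p$phi_max * p$P_50 / (p$P_50 + P[i])
    H[i] <- phi * U[i] * P[i]
    avail <- k_delays <= n
    hdel <- ifelse(avail, H[pmax(i - k_delays, 1)], 0)
    convI <- sum(weights * surv * hdel)
    convP <- sum(betas * weights * surv * hdel)
    r <- p$r_max * (1 - (U[i] + I[i]) / p$K_C)
    U[i + 1] <- max(0, U[i] + dt * (r * U[i] - H[i] - p$delta_U * U[i]))
    I[i + 1] <- max(0, I[i] + dt * (H[i] - convI - p$delta_I * I[i]))
    P[i + 1] <- max(0, P[i] + dt * (convP - phi * (U[i] + I[i]) * P[i] -
                                      p$delta_P * P[i]))
  }
  list(U = U, I = I, P = P)
}

# Mixture-expanded Euler oracle: the adsorption rate is a discrete mixture of
# multiplicative factors c_j (probabilities q_j) around the saturable mean,
# and the burst size given tau is a discrete mixture {beta1(tau), beta2(tau)}
# (probabilities pb). Every delay/adsorption/burst combination is expanded
# explicitly, the naive form of the heterogeneous model before its reduction
# to mean adsorption and conditional-mean burst.
oracle_mixture_expanded <- function(params, k_delays, weights,
                                    phi_factors, phi_probs,
                                    beta_funs, beta_probs,
                                    dt, n_steps) {
  p <- params
  U <- I <- P <- numeric(n_steps + 1)
  nj <- length(phi_factors)
  Hj <- matrix(0, n_steps + 1, nj)   # per-adsorption-component history
  U[1] <- p$U_init; P[1] <- p$P_init
  tau_k <- k_delays * dt
  surv <- exp(-p$delta_I * tau_k)
  beta_mat <- sapply(beta_funs, function(f) f(tau_k))  # n_k x n_components
  if (is.null(dim(beta_mat))) beta_mat <- matrix(beta_mat, nrow = length(tau_k))
  for (n in 0:(n_steps - 1)) {
    i <- n + 1
    phi0 <- p$phi_max * p$P_50 / (p$P_50 + P[i])
    for (j in seq_len(nj)) Hj[i, j] <- phi_factors[j] * phi0 * U[i] * P[i]
    adsorb <- sum(phi_probs * Hj[i, ])           # mixture-mean adsorption loss
    avail <- k_delays <= n
    convI <- 0; convP <- 0
    for (j in seq_len(nj)) {
      hdel <- ifelse(avail, Hj[pmax(i - k_delays, 1), j], 0)
      convI <- convI + phi_probs[j] * sum(weights * surv * hdel)
      for (b in seq_along(beta_probs)) {
        convP <- convP + phi_probs[j] * beta_probs[b] *
          sum(beta_mat[, b] * weights * surv * hdel)
      }
    }
    r <- p$r_max * (1 - (U[i] + I[i]) / p$K_C)
    sink_j <- sum(phi_probs * phi_factors) * phi0 * (U[i] + I[i]) * P[i]
    U[i + 1] <- max(0, U[i] + dt * (r * U[i] - adsorb - p$delta_U * U[i]))
    I[i + 1] <- max(0, I[i] + dt * (adsorb - convI - p$delta_I * I[i]))
    P[i + 1] <- max(0, P[i] + dt * (convP - sink_j - p$delta_P * P[i]))
  }
  list(U = U, I = I, P = P)
}
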