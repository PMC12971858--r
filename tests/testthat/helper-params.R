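# Shared fixtures: a benign baseline parameter set plus small random draws.

base_params <- function(...) {
  args <- list(r_max = 1, K_C = 1e9, phi_max = 1e-8, P_50 = 1e9,
               delta_U = 0.1, delta_I = 0.1, delta_P = 0.05,
               beta_0_mean = 100, r_beta = 5, D = 0.2, beta_tau50 = 0.8,
               U_init = 1e6, P_init = 1e5)
  mods <- list(...)
  args[names(mods)] <- mods
  do.call(kinetic_params, args)
}

# closed-form logistic growth from U0 with rate r and ceiling K
logistic_closed_form <- function(t, U0, r, K) {
  K * U0 * exp(r * t) / (K + U0 * (exp(r * t) - 1))
}

# max |a - b| scaled by the peak of the reference series
max_rel_diff <- function(a, b) {
  max(abs(a - b)) / max(abs(a), 1e-300)
}
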