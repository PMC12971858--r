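# phagedyn

Simulators for bacteriophage–bacteria population dynamics that take
cell-to-cell heterogeneity in the latent period seriously.

## The problem

Classical phage pharmacodynamic models track uninfected bacteria `U`,
infected bacteria `I` and free phage `P` with three parameters per phage:
an adsorption rate φ, a latent period τ between infection and lysis, and a
burst size β of progeny released per lysed cell. They assume every cell
lyses after exactly the same τ. Single-cell experiments show instead that τ
varies substantially between cells (relative standard deviations of 10–50%),
that burst size grows with the latent period, and that single-step growth
curves rise gradually rather than as a step. Whether, and when, this
heterogeneity changes population-level predictions determines whether the
cheap classical models are safe to use — a practical question for anyone
fitting or simulating phage therapy kinetics.

phagedyn implements, in one framework:

* the **fixed-delay (DDE) model** — the classical structure, with logistic
  bacterial growth `r(t) = r_max (1 − (U+I)/K_C)`, saturable adsorption
  `φ(t) = φ_max P_50/(P_50 + P)`, per-population decay rates, survival
  `exp(−δ_I τ)` to lysis, and burst size β per lysed cell;
* the **distributed-delay (DDDE) model** — the reference structure: lysis
  terms are convolutions of the infection history `φ(s)U(s)P(s)` with a
  latent-period density (truncated normal, lognormal, gamma, or point
  mass), and the conditional mean burst size rises sigmoidally with τ,
  normalised so that its population mean equals the experimentally
  accessible `beta_0_mean`;
* the **transit-compartment (TC) model** — the latent stage as an Erlang
  chain with `N = round(1/rsd²)` compartments and `k_tr = N/τ₀` (linear
  chain trick), which cannot carry the burst–τ correlation;
* the **single-step growth assay** and the *first observed lysis* time
  (infective-center doubling), the operational latent-period estimate whose
  bias the package quantifies;
* a **normalised area-between-curves error** (0–200%) for comparing any
  two simulated load profiles;
* a **Monte Carlo framework** that draws kinetic parameter sets from
  literature-typical ranges and compiles median approximation errors per
  latent-period variability level, with step-halving convergence control
  and deterministic seeding.

Solver cores are in C++ (forward Euler and RK4 adapted to distributed
delays); everything else is base R.

## A worked example

How much does ignoring a 30%-wide lognormal latent period cost?

```r
library(phagedyn)

p <- kinetic_params(r_max = 1, K_C = 1e9, phi_max = 1e-8, P_50 = 1e9,
                    delta_U = 0.1, delta_I = 0.1, delta_P = 0.05,
                    beta_0_mean = 100, r_beta = 5, D = 0.2, beta_tau50 = 0.8,
                    U_init = 1e6, P_init = 1e5)
d <- latent_distribution("lognormal", tau_0 = 1, rsd_tau = 0.3, tau_min = 0)
bmax <- normalize_beta_max(100, d, p$r_beta, p$D, p$beta_tau50)
#> bmax = 151.08: a beta_max of ~151 gives a population mean burst of 100
burst <- burst_profile("latent-dependent", 100, bmax)

ref <- run_with_convergence(function(dt, t_end)
  simulate_ddde(p, discretize_density(d, dt), burst,
                simulation_grid(t_end, dt), "rk4"))
ref$trajectory
#> Phage-bacteria trajectory (DDDE): 9601 points, dt = 0.005 h, horizon 48 h
#>   final state: U = 4.154e-120, I = 0, P = 1.478e+09

fix <- run_with_convergence(function(dt, t_end)
  simulate_dde(p, fixed_latent_value(d, "mean"),
               simulation_grid(t_end, dt), "rk4"),
  t_end = ref$t_end, fixed_horizon = TRUE)
compare_trajectories(ref$trajectory, fix$trajectory)
#> Curve error over [0, 48] h: bacterial 2.62%, viral 1.31%
```

Fixing τ at the distribution *mean* is nearly harmless here. Fixing it at
the classical *first observed lysis* time is not — for this parameter set
the infective centers double at 0.58 h, far below the median (0.96 h) and
mean (1.0 h) latent period, because the earliest-lysing cells dominate the
onset of the assay:

```r
ss <- single_step_growth(p, discretize_density(d, 0.002), burst,
                         simulation_grid(5, 0.002))
first_lysis_time(ss)
#> [1] 0.5801
```

Study-level functions repeat such comparisons over hundreds of randomized
parameter sets: `run_shape_study()` (does the distribution family matter?),
`run_approximation_study()` (what do Fixed-Mean / Fixed-Median /
Fixed-Early / TC cost?), and the general `run_comparison_study()`. Results
come back as record tables plus median/IQR summaries.

A command-line front end lives at `inst/cli/phagedyn`
(`simulate`, `single-step`, `compare`, `montecarlo` subcommands, YAML/JSON
configs).

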