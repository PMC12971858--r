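---
title: "Modelling phage-bacteria dynamics with distributed latent periods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling phage-bacteria dynamics with distributed latent periods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagedyn)
```

## The model

phagedyn simulates the predator-prey interaction between lytic
bacteriophages and their host bacteria. Three concentrations evolve in time:
uninfected bacteria $U(t)$, infected bacteria $I(t)$ and free phage $P(t)$
(all per mL). The kinetic building blocks are

* logistic growth of uninfected cells,
  $r(t) = r_{\max}\,(1 - (U + I)/K_C)$, with ceiling $K_C$;
* saturable adsorption, $\varphi(t) = \varphi_{\max}\,P_{50}/(P_{50} + P)$,
  half-maximal at phage density $P_{50}$;
* first-order decay of each population at rates $\delta_U$, $\delta_I$,
  $\delta_P$;
* lysis after a latent period $\tau$, releasing $\beta$ phage per cell.

In the classical fixed-delay (DDE) model every cell lyses exactly $\tau$
hours after infection. Single-cell experiments instead show broad
cell-to-cell variation in $\tau$, and one-round ("single-step") growth
curves rise gradually rather than as a step. The package's reference model
is therefore a *distributed-delay* (DDDE) system: cells infected at time
$t - \tau$ lyse at time $t$ with probability density $f_\tau(\tau)$, so the
lysis terms become convolutions of the infection history
$H(s) = \varphi(s)U(s)P(s)$ with $f_\tau$, weighted by the survival factor
$e^{-\delta_I \tau}$ (an infected cell must survive its latent period to
burst). Heterogeneity in the burst size $\beta$ (given $\tau$) and in the
adsorption rate $\varphi$ enters the population equations only through the
conditional means $\beta_0(\tau)$ and $\varphi_0(t)$; the package verifies
this reduction numerically against an explicitly mixture-expanded solver
(it holds because every $\beta$- and $\varphi$-dependent term is linear in
those quantities).

The burst size grows with the latent period — a cell that waits longer
before lysing has assembled more virions:
$$\beta_0(\tau) = \beta_{\max}\,
  \frac{e^{r_\beta(\tau - D)} - 1}
       {e^{r_\beta(\beta\tau_{50} - D)} + e^{r_\beta(\tau - D)} - 2},$$
zero at and below the onset delay $D$, half-maximal at
$\tau = \beta\tau_{50}$, saturating at $\beta_{\max}$ with the
intracellular replication rate $r_\beta$. What an experiment measures from
a single-step curve is the *population mean* burst size
$\beta_{0,\text{mean}} = \int \beta_0(\tau) f_\tau(\tau)\,d\tau$, so
`normalize_beta_max()` rescales $\beta_{\max}$ by adaptive quadrature such
that the density-weighted mean equals the requested
$\beta_{0,\text{mean}}$. Evaluation uses the rearrangement
$(1 - e^{-x})/(1 + (e^a - 2)e^{-x})$ so that large $r_\beta \tau$ saturates
instead of overflowing.

## Latent-period distributions

`latent_distribution()` supports truncated-normal, lognormal, gamma and
point-mass families, parameterised by the mean $\tau_0$ (hours), the
relative standard deviation $rsd_\tau = sd_\tau/\tau_0$ (10-50% covers the
experimentally reported range) and a minimal latent period $\tau_{\min}$
below which the density is exactly zero (a phage cannot lyse its host
instantly). The truncated normal solves for parent parameters by damped
Newton-Raphson on the analytic truncated moments (start $(\tau_0, sd)$,
tolerance $10^{-10}$, at most 100 iterations); lognormal and gamma are
shifted by $\tau_{\min}$ and moment-matched in closed form. Shifting
preserves the exact moment targets and the hard support bound, mirroring
the truncated-normal treatment; the truncation bound is $\tau_{\min}$
itself. Note one structural limit: a normal truncated to
$[\tau_{\min}, \infty)$ cannot realise $sd \ge \tau_0 - \tau_{\min}$ (the
exponential limit of the family), so wide-and-strongly-truncated targets
are rejected as infeasible — the Monte Carlo layer simply redraws such
parameter sets.

For the solvers the density is discretised onto the simulation grid by CDF
differences over bins $[k\,dt - dt/2,\, k\,dt + dt/2]$, renormalised to sum
to one, and cut at the $1 - 10^{-6}$ quantile (the resulting truncation
error is orders of magnitude below the 1% convergence criterion). Binning
by CDF differences conserves probability exactly and keeps the kernel mean
accurate even for narrow densities; kernel moments converge at second
order in $dt$.

## Numerical integration

All three model structures (DDE, DDDE, transit compartments) are integrated
with fixed-step explicit schemes on a uniform grid, implemented in C++:

* **Forward Euler**, the default for single simulations, with the delay
  integrals computed as discrete convolutions of the stored history.
* **Classical RK4**. The delayed terms depend only on history, never on the
  current stage state; with all kernel offsets at least one step, the
  convolutions at $t_n$ and $t_n + dt$ use known history and the half-step
  value is exactly their average under linear interpolation, so RK4 costs
  only one new convolution per step. Because the kernel representation is
  second-order accurate, RK4's observed convergence is roughly second
  order, and the comparison studies use it by default: it reaches the
  step-halving criterion one to two halvings earlier than Euler at a
  fraction of the cost. Both steppers agree within the convergence
  criterion at converged $dt$ (tested).

States are floored at zero after every step and the number of floorings is
recorded on the returned trajectory. A non-finite state aborts with the
offending step. History before $t = 0$ carries no infections
($\varphi U P \equiv 0$), which together with the initial conditions fully
determines the system.

**Step-halving control.** `run_with_convergence()` repeatedly halves $dt$
(from 0.01 h, at most 5 halvings) and accepts the solution when the
area-between-curves difference between successive refinements is below 1%
for both the bacterial load $U + I$ and the viral load $P$. Five halvings
bound the worst-case cost of the $O(n_\text{steps} \times n_\text{kernel})$
convolution (each halving quadruples it) while comfortably covering the
smooth dynamics generated by the sampled parameter ranges; a set that fails
to converge within the budget is reported as such and redrawn by the Monte
Carlo layer rather than silently accepted.

**Horizon.** Simulations run on a fixed 48 h window by default. With
maximal growth rates of 0.5-2.5/h, latent periods up to 3 h and decay
rates of 0.05-0.25/h, the infection transient — growth, phage expansion,
collapse — completes well inside 48 h. An optional tail-activity extension
(doubling the window while either load still moves by more than 0.1% of
its peak over the final 10%) exists but is off by default: below one cell
per mL the continuum equations describe nothing physical, and on long
windows such sub-cell densities can regrow and dominate the error metric,
while the phage series contributes only an exponential decay tail. The
comparison error is evaluated on the common (shorter) horizon of the two
trajectories.

## Comparison scenarios and the error metric

Two profiles $X_A, X_B$ are compared by the normalised area between the
curves,
$$\text{Error}(\%) = 100 \cdot
  \frac{2\int |X_A - X_B|\,dt}{\int X_A\,dt + \int X_B\,dt},$$
a symmetric, scale-invariant quantity between 0 and 200%. "Bacterial load"
is $U + I$ by default — the colony count an experiment would observe — with
a `bacterial_as = "U"` switch for sensitivity analyses; "viral load" is
free phage $P$. Integrals use the trapezoid rule on the simulation grid
(error $O(dt^2)$, negligible against the 1% convergence criterion).

The approximation scenarios all share the reference's kinetics and differ
only in how the latent period is handled:

* **Fixed Mean / Fixed Median** — the DDE with $\tau$ at the mean or median
  of the reference distribution;
* **Fixed Early** — the DDE with $\tau$ at the *first observed lysis* time:
  the classical operational estimate, computed per parameter set as the
  moment the infective-center count $C(t) = P(t) + I(t)$ doubles in a
  simulated single-step growth experiment (synchronised infection at
  $t = 0$: $I(0) = P_{\text{init}}$, $U(0) = P(0) = 0$, re-adsorption off;
  each free phage or infected cell forms one plaque, hence $C = P + I$;
  decay stays on for consistency with the main model). For any spread
  distribution the earliest-lysing cells double the count before the mean
  cell has lysed, so this estimate is biased low — the bias the comparison
  quantifies. When the effective burst never doubles the count the scenario
  is undefined and the set is redrawn.
* **Transit compartments (TC)** — the latent stage as a chain of
  $N = \mathrm{round}(1/rsd_\tau^2)$ compartments with transit rate
  $k_{tr} = N/\tau_0$ (an Erlang latency; the linear chain trick). The TC
  structure cannot represent $\tau_{\min} \neq 0$ nor a latent-dependent
  burst; it bursts at the constant population mean, which is exactly why it
  is an approximation of the full model. With a constant burst and a gamma
  kernel the TC and DDDE solutions agree below the 1% criterion (tested for
  $N \in \{4, 16, 25\}$).

## The randomized-parameter studies

`run_comparison_study()`, `run_approximation_study()` and
`run_shape_study()` draw kinetic parameter sets from ranges typical of
reported phage-bacteria systems: $r_{\max} \in [0.5, 2.5]$/h,
$\delta_U, \delta_I \in [0.1, 0.25]$/h, $\delta_P \in [0.05, 0.15]$/h,
$\tau_0 \in [0.25, 3]$ h, $\tau_{\min} \in [0, \tau_0/2]$,
$r_\beta \in [1, 10]$/h, $D \in [0, \tau_0]$,
$\beta\tau_{50} \in [D, 3]$ h drawn uniformly, and
$K_C \in [10^8, 10^{10}]$/mL, $\varphi_{\max} \in [10^{-9}, 10^{-7}]$
mL/cell/h, $P_{50} \in [r_{\max}/\varphi_{\max}, 10^{10}]$/mL (phage
killing can outpace growth), $\beta_{0,\text{mean}} \in [10, 500]$,
$U_{\text{init}} \in [10^3, K_C(1 - \delta_U/r_{\max})]$/mL,
$P_{\text{init}} \in [10^3, 10^9]$/mL drawn log-uniformly (they span orders
of magnitude). Dependent bounds are resolved in dependency order. The
population mean burst size is the sampled quantity (it is the
experimentally accessible one); the latent-period width $rsd_\tau$ is a
controlled grid variable of each study rather than a sampled parameter, so
that error can be reported as a function of variability.

Each study cell derives its RNG substream deterministically from the master
seed, so identical seeds give bit-identical result tables. A set whose
scenario construction is infeasible (degenerate burst normalisation,
unattainable truncated-normal moments, undefined first lysis) or whose
step-halving fails is discarded and redrawn from the same stream, with the
count logged per record; a cell aborts if resampling exceeds ten times the
requested number of sets. The default study size is 500 converged sets per
cell; the test suite runs 100-set versions of the headline cells, sized so
the whole suite stays in the minutes range on one core, and judges medians
by bootstrap confidence intervals.

## What the generator emulates — and what it does not

The randomized studies probe the *model space* of classical lytic
phage-bacteria kinetics under realistic rate ranges. They do not emulate
measurement noise, plating error, spatial structure, resistance evolution,
multiplicity-of-infection saturation, or bimodal/empirical single-cell
latent-period distributions; passing tests therefore demonstrate the
numerical and structural claims about the models, not agreement with any
particular experimental system. Parameter combinations are sampled
independently (within the dependent bounds) and need not correspond to a
real phage.

## Numerical choices and known limitations

* Delays are rounded to the nearest grid node; kernels and grids must share
  $dt$ (enforced).
* Burst normalisation integrates to the $1 - 10^{-8}$ quantile at relative
  tolerance $10^{-9}$; a normalisation integral below $10^{-12}$ (all
  density at or below the onset delay $D$) marks the set invalid.
* The area metric is evaluated on a finite window; its value for strongly
  diverging profiles depends on that window. The 48 h default weights the
  infection transient; studies on other horizons are available through
  `t_end` and `max_extensions`.
* Forward Euler with flooring can reach exact extinction where the true
  solution is merely tiny; this is intentional (sub-cell densities are not
  physical) but means long-horizon regrowth behaviour is a numerical
  artifact rather than a prediction.
* Median errors across random parameter sets have heavy-tailed, near-bimodal
  distributions (many near-zero, some near-saturation values); medians from
  a few hundred sets carry sampling error of several percentage points, and
  reduced runs proportionally more.

## A worked example

```{r example, eval = FALSE}
p <- kinetic_params(r_max = 1, K_C = 1e9, phi_max = 1e-8, P_50 = 1e9,
                    delta_U = 0.1, delta_I = 0.1, delta_P = 0.05,
                    beta_0_mean = 100, r_beta = 5, D = 0.2, beta_tau50 = 0.8,
                    U_init = 1e6, P_init = 1e5)
d <- latent_distribution("lognormal", tau_0 = 1, rsd_tau = 0.3, tau_min = 0)
bmax <- normalize_beta_max(100, d, p$r_beta, p$D, p$beta_tau50)
burst <- burst_profile("latent-dependent", 100, bmax)

ref <- run_with_convergence(function(dt, t_end) {
  simulate_ddde(p, discretize_density(d, dt), burst,
                simulation_grid(t_end, dt), "rk4")
})
fix <- run_with_convergence(function(dt, t_end) {
  simulate_dde(p, fixed_latent_value(d, "mean"),
               simulation_grid(t_end, dt), "rk4")
}, t_end = ref$t_end, fixed_horizon = TRUE)

compare_trajectories(ref$trajectory, fix$trajectory)
plot(ref$trajectory)
```
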