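---
title: "Methods: stochastic multistage cell lineages with cytokine feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic multistage cell lineages with cytokine feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineagesde)
```

## The model

A lineage of `n >= 2` compartments carries cell densities
`c_1, ..., c_n` from the self-renewing stem cells to post-mitotic mature
cells. Differentiation proceeds one stage at a time: a stage-`i` cell
divides at rate `p_i`, a fraction `a_i s` of its progeny stays at stage
`i` and the rest moves to stage `i+1`; every stage dies at rate `mu_i`.
The regulating cytokine is cleared by mature cells, so its concentration
`s` obeys `ds/dt = mu_s (1 - s - k s c_n)`; because cytokine kinetics are
fast compared with cell population dynamics, the model replaces `s` by its
quasi-steady state `s_k = 1/(1 + k c_n)`. Feedback may act on the
self-renewal fraction (constant `k1`) and on the proliferation rate
(constant `k2`); both channels are evaluated at the mature-cell density.

Admissibility is exactly the sign structure of the biology: `a_i` in
`[0, 1]` (symmetric self-renewal through symmetric differentiation),
`p_i >= 0`, `mu_i >= 0` for immature stages, and `mu_n > 0` — mature
cells must die, otherwise no homeostasis is possible. Mature cells
neither self-renew nor proliferate, so `a` and `p` have length `n - 1`.

The stochastic version perturbs each compartment with independent
multiplicative noise,

    d xi_i = f_i(xi) dt + alpha_i xi_i dW_i ,

where `f` is the deterministic drift with feedback acting on self-renewal
only (`k2 = 0`) and the `W_i` are uncorrelated Wiener processes. Noise
proportional to the state is the standard representation of an
*environmental* perturbation acting on death and proliferation; it
vanishes at extinction, so the origin stays absorbing. Correlated driving
noises are out of scope.

One printed form of the two-compartment influx term carries a bare `p`
where the general system has `p_1`; the package reads it as `p_1`,
consistent with the `n`-compartment model. Likewise the existence
conditions are printed with symbols `d_i` where the dynamics use `mu_i`;
the package identifies the two (the reduced form below confirms this
reading).

## Steady states and their existence

A unique positive steady state exists when (i) `mu_1 < (2 a_1 - 1) p_1`
— the stem-cell pool can sustain itself at full feedback — and (ii) for
every intermediate stage `0 < 2 a_1 p_1 (mu_i + p_i) - 2 a_i p_i (mu_1 +
p_1)`: the feedback level that balances the stem cells leaves every
downstream stage strictly dependent on influx. With all immature death
rates zero this reduces to `a_1 > 1/2` and `a_1 > a_i`, which the test
suite verifies against the general form on 1000 random parameter sets.

`positive_steady_state_n()` solves the stage-1 balance
`(2 a_1 s_{k1}(c_n) - 1) p_1 s_{k2}(c_n) = mu_1` for the mature density
by bracketed root-finding (`uniroot`, relative tolerance `1e-12`, upper
bracket `10 (2 max(a) - 1)/k1` — the feedback scale at which the
left-hand side is already negative; the function is strictly decreasing
in `c_n` under the admissibility constraints, so the bracket is valid
whenever condition (i) holds). With the feedback signals frozen at that
root every compartment is a fixed multiple of its predecessor, and the
mature-cell balance fixes the absolute scale. For `n = 2` the closed form
`xi_2* = (2a - 1)/k`, `xi_1* = mu xi_2*/p` is exposed separately and the
two code paths agree to `1e-10` relative. Because the model depends on
`k1`, `k2` only through `k c_n`, scaling both constants by 10 scales the
steady state by 1/10 — a property test.

## Stability versus extinction

For the two-compartment stochastic model the stem-cell compartment is
sandwiched pathwise between two constant-coefficient processes driven by
the *same* Brownian motion: `M_1` (drift `-p`) and `N_1` (drift
`(2a - 1) p`), both geometric Brownian motions with exact solutions
`x(0) exp{(r - alpha_1^2/2) t + alpha_1 W_t}`. The long-run growth
exponent of `N_1`,

    lambda = (2a - 1) p - alpha_1^2 / 2 ,

separates two regimes: `lambda > 0` — the joint distribution converges
to a unique stationary distribution; `lambda < 0` — the stem cells, and
with them the mature cells, tend to zero almost surely.
`stability_exponent()` reports `lambda` and its sign classification
(critical within `1e-12` of zero); the package characterises the
stationary regime only empirically, through long-run ensembles — no
density-evolution (Fokker–Planck) machinery is included.

`lyapunov_estimate()` estimates the exponent as the cross-path mean of
`t^{-1} log(x(t)/x(0))`; on exact GBM draws its expectation is exactly
`r - alpha^2/2` with standard error `alpha / sqrt(t n)`, which is the
oracle used in the tests and the acceptance script. Extinction is
operationalised as threshold-crossing at a horizon — both are explicit
arguments, because the almost-sure statement is a limit, not a
finite-time event.

## Numerical choices

**Deterministic integration.** Adaptive Dormand–Prince RK4(5) via
`deSolve` with defaults `rtol = 1e-8`, `atol = 1e-10` (no integrator is
prescribed by the theory; any non-stiff adaptive method reproduces the
same curves, and a grid-refinement test bounds the endpoint sensitivity).
The continuous model preserves non-negativity, so negative values can
only be solver overshoot; they are clamped to zero in reported output
only, never mid-integration, to keep the solver's error control intact.
The explicit cytokine system becomes stiff for large `mu_s`; tests use
`method = "lsoda"` there. The quasi-steady-state approximation is checked
by driving `mu_s` through 10–10^4 and watching the sup-norm distance to
the algebraic-feedback model fall below 1% — the distance is monotone in
`mu_s`.

**Stochastic integration.** Explicit Euler–Maruyama on a uniform grid
(the strong-order analysis assumes uniformity). Negative proposals are
clamped to zero and counted — consistent with the absorbing origin —
and a clamp fraction above 0.1% flags the step as too coarse (a report,
not an error). On the shipped presets at their default steps the clamp
never fires. The scheme's strong order is measured against the exact GBM
on shared Brownian paths (coarse increments are block sums of fine ones):
slope ≈ 0.5 with noise, ≈ 1 without. Per-path seeds are `base_seed + i`,
so any ensemble member can be regenerated alone; every stochastic
function is a pure function of its inputs and seed, and leaves the
caller's RNG state untouched.

**Quartiles and histograms.** The summary protocol (mean, q1, q3 of 150
trajectories, final-time histograms) does not pin down an estimator, so
the package declares one: quantile type 7 (linear interpolation between
order statistics; `{1,2,3,4}` gives `q1 = 1.75`, `q3 = 3.25`) and 20
equal-width bins spanning the final-time range. Mean may leave the
interquartile band; only `q1 <= q3` is guaranteed.

**Stationarity diagnostic.** A two-sample Kolmogorov–Smirnov test
between the cross-path marginals at two late times, pass = p-value above
0.01. On genuinely i.i.d. stationary ensembles its type-I rate stays at
the nominal level (checked over 100 repetitions); on a single ensemble
the two samples share paths, so the test is a diagnostic, not a formal
hypothesis test.

## Presets: what they emulate, and what they do not

The four presets encode the published simulation scenarios: an 8-stage
white-blood-cell lineage (`a = 0.735, ..., 0.3675`;
`p = 0.006, ..., 1.5`; immature death rates zero, `mu_8 = 2.77`;
`k = 1.28e-9`) with three noise patterns — small everywhere
(`alpha = 0.011 ... 0.025`), large on stages 1–3 (`0.185, 0.18, 0.1`,
small elsewhere), large on stages 5–8 (`0.18, 0.5, 0.6, 1`) — and the
two-compartment reduction (`a = 0.7`, `p = 0.6`, `mu = 2.77`,
`k = 1.28e-9`). Each preset's `provenance` field flags what is published
and what the package had to reconstruct:

- *Initial state*: not published. Default: a regeneration scenario with
  compartment 1 at 1% of its steady-state value and all later stages
  empty — the configuration the feedback is meant to repair, and the one
  that exercises the whole cascade.
- *Step size*: not published. Defaults (`dt = 0.005` for the 8-stage
  presets over `t_end = 50`, `dt = 0.01` for the 2-d preset) were chosen
  so the explicit-Euler bias is below 1% and the clamp gate passes;
  every manifest records the step actually used.
- *Proliferation feedback*: the `n`-compartment deterministic model has
  both channels, the stochastic system only the self-renewal one.
  Whether the published figures used both is not stated; presets default
  to `k2 = 0` (matching the stochastic model as printed) and expose
  `k2_mode = "match_k1"`.
- *2-d noise level and horizon*: not published; reconstructed as
  `alpha = (0.02, 0.02)` ("relatively small" perturbations) and
  `t_end = 100`, flagged accordingly.

Ensembles of these presets emulate environmental noise acting
independently and proportionally on each subpopulation around a smooth
regulated cascade. They do not emulate demographic (birth–death)
stochasticity, correlated perturbations across stages, cell-cycle
structure, or parameter heterogeneity between paths — so passing tests
say nothing about data in which those effects dominate.

## Protocol checks and problem sizes

The acceptance-style suite (`test-acceptance.R`) runs, at sizes chosen to
keep the whole suite in minutes on one CPU: the existence-threshold
bisection (`a_1` critical value 1/2 to `1e-9`); the critical-noise growth
exponent (closed form, plus 10^4 Monte-Carlo draws at `t = 100`); the
drift-factor infimum `-1`; the strong-order study (500 paths,
`dt = 2^-4 ... 2^-10`); the pathwise sandwich under refinement
(`dt = 1e-2, 1e-3, 1e-4`, 20 seeds, horizon 10); the extinction
dichotomy (500 paths, `t = 200`, noise grid straddling
`alpha_1 = sqrt(0.48)`, threshold `1e-3` of the steady state); 2-d
steady-state relaxation to `1e-4` relative; and the 150-path 8-stage
protocol with the small-noise and perturbed-noise presets.

Two checks needed statistical care rather than a direct reading:

- *Ensemble mean vs deterministic trajectory.* The Euler–Maruyama mean
  carries the scheme's `O(dt)` weak bias, while the ensemble standard
  error at early times is orders of magnitude smaller — comparing
  against an adaptive-RK solution therefore measures the integrator, not
  the noise. The deterministic reference is instead the zero-noise limit
  of the same scheme on the same grid (matched discretisation), with a
  separate check that this Euler path agrees with the RK solution to 2%.
- *Simultaneous 3-standard-error bands.* A pointwise 3-SE band demanded
  simultaneously at ~100 times × 8 compartments fails by chance alone
  with appreciable probability for a perfectly calibrated model. The
  check therefore allows chance-level pointwise exceedances (≤ 1% of
  points, against an expected 0.27%) and bounds the worst deviation by
  the Bonferroni-corrected simultaneous band (4.5 SE at ~800
  comparisons). A genuinely biased comparison fails both margins by
  orders of magnitude.

The noise-damping conclusion — perturbations injected at one end of the
lineage are damped at the far end — is asserted ordinally only
(deviation of stage 8 below stage 1 under early-stage noise, stages 1–3
below 5–8 under late-stage noise), since the published figures print no
numeric outputs to match.

## Known limitations

- Plain Euler–Maruyama only; no Milstein or higher-order schemes, so
  strong accuracy is `O(sqrt(dt))` and very large `alpha_i` require small
  steps (watch the clamp fraction in the manifest).
- The stationary distribution is characterised only through long-run
  ensembles and the KS diagnostic; no spectral or density-evolution
  analysis.
- The `n`-compartment stochastic system inherits the pathwise sandwich
  argument only for `n = 2`; for larger `n` the comparison utilities are
  not applicable and stability is explored numerically.
- The cascade steady-state solver requires `k1 > 0`; without feedback
  the model has no positive equilibrium to find.

## A small worked run

```{r example, eval = FALSE}
pre <- load_preset("fig4_2d")
ens <- run_ensemble(pre$params, pre$noise, pre$c0,
                    times = seq(0, pre$t_end, pre$dt),
                    n_paths = 150, base_seed = 1, thin = 100)
sm <- summary(ens)
tail(sm$mean, 1)            # near the steady state (1.44e9, 3.125e8)
stationarity_diagnostic(ens, 50, 100)
```
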