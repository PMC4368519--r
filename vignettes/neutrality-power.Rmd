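---
title: "Detecting non-neutrality in species abundance data: models, test, and power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting non-neutrality in species abundance data: models, test, and power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sadpower)
```

## The question

Species abundance distributions (SADs) — the multiset of per-species counts
in a community census — are often statistically consistent with Hubbell's
standard neutral model (SNM), in which all individuals have identical
demographic rates. Consistency is weak evidence: many non-neutral processes
produce SADs that look neutral. The useful question is therefore one of
statistical *power*: if a community were generated by a specific non-neutral
process of a given strength, what is the probability that a likelihood-based
test of the SNM would detect it, at a given census size `J`?

`sadpower` implements the full pipeline needed to answer this: simulators
for non-neutral community models, the exact SNM likelihood and its
maximization, a parametric-bootstrap test of neutrality, power estimation
with binomial confidence intervals, and a search that matches model
parameters to the summary statistics of real censuses.

## Community models

All local models share the SNM's skeleton: a local community of exactly `J`
individuals (strict zero-sum dynamics), in which a fraction `m` of recruits
are immigrants drawn from a static metacommunity with relative abundances
`P_i`. They differ in how birth and death depend on species identity.

**HL (density-dependent mortality, sequential).** The probability that the
next death is of species `i` is proportional to
`[(1 - γ) + γ n_i/J] n_i/J`; the recruit is an immigrant with probability
`m`, otherwise a copy of a uniformly chosen survivor. One generation is `J`
such elemental updates (a Moran-type process). `γ = 0` is neutral; `γ → 1`
penalizes abundant species and promotes coexistence; `γ > 1` would make
mortality weights negative and is rejected. `hl_params_from_rates()` maps
the rates of a multispecies stochastic Lotka–Volterra competition model
(density-independent birth/death rates, carrying capacity, interaction
asymmetry α, immigration rate) onto `(γ, m)` in closed form.

**PC (Ricker fecundity competition, synchronous).** The local propagule
share of species `i` is `n_i exp(-c n_i/J) / Σ_k n_k exp(-c n_k/J)`, and the
next generation is one multinomial draw of size `J` from
`R_i = m P_i + (1 - m) L_i` (a Wright–Fisher-type update, orders of
magnitude faster than sequential updating at large `J`). `c = 0` is neutral.

**IF (intrinsic fitness differences, synchronous).** Each species receives
an i.i.d. fitness `f_i ~ Gamma(shape 1/k, scale k)` (mean 1, coefficient of
variation `√k`) once per realisation; propagule shares are
`f_i n_i / Σ f_k n_k`. `k = 0` is neutral; `k = Inf` is the strong-selection
limit in which the highest-fitness species takes every local recruitment.

**Metacommunities.** `meta_logseries(theta)` draws relative abundances
whose species-frequency density is the continuum logseries
`f(x) = θ x⁻¹ (1-x)^{θ-1}` — the metacommunity of the SNM — via
stick-breaking (GEM) truncated at `S_T` species (default 2000, effectively
infinite: the untruncated tail mass is `(θ/(1+θ))^{S_T}`). `meta_even(S_T)`
is the maximally even pool, the metacommunity limit of the local models
themselves. `meta_infinite()` is the `S_T → ∞` even pool: every immigrant
founds a species new to the local community, so immigration acts as
speciation.

A fresh metacommunity (and, for IF, a fresh fitness assignment) is drawn for
every replicate dataset by default (`redraw_meta = TRUE`); sharing one pool
across replicates is available because the literature is not explicit about
which ensemble is intended, and the choice is recorded in each sample's
metadata.

### Initial condition and burn-in

The initial community is `J` i.i.d. draws from the metacommunity — unbiased
with respect to the local dynamics and already exact in the `m = 1` limit.
Equilibration is detected, not assumed: richness and Shannon index are
recorded each generation, and once the most recent half of both
trajectories shows no Mann–Kendall trend across `window = 8` window means
(at level 0.05), that time `T` is recorded and the run continues to
`burn_factor × T` (default 10) generations. Exceeding `max_gen` raises a
`sadpower_convergence_error` carrying diagnostics. The detector was
validated against the exactly known neutral-limit law: HL at `γ = 0`
(J = 300, θ = 50, m = 0.01) is KS-indistinguishable from direct urn samples.

### Sequential versus synchronous updating

The two update schemes are *not* interchangeable at matched parameters: a
Wright–Fisher generation compresses the drift a Moran process accumulates
over `J` elemental steps into one multinomial draw, which doubles the
effective immigration-to-drift ratio. The neutral limit of HL reproduces
the urn law at the same `(θ, m, J)`, while the neutral limit of PC/IF
reproduces it at the effective `I_eff = 2 m (J-1)/(1-m)`. At the family
level both neutral limits *are* SNM laws (with different fitted `m`), which
is why the neutrality test's rejection rate at `c = 0` or `k = 0` equals
the significance level — the property that matters for power calculations.
The test suite checks both correspondences explicitly.

## The neutrality test

The likelihood of an abundance configuration `D = (n_1, …, n_S)` under the
SNM at `(θ, m)` is computed exactly from the sampling formula

$$P(D \mid \theta, m, J) = \frac{J!}{\prod_i n_i \prod_j \Phi_j!}
\frac{\theta^S}{(I)_J} \sum_{A=S}^{J} K(D, A)\, \frac{I^A}{(\theta)_A},
\qquad I = \frac{m (J-1)}{1-m},$$

where `K(D, A)` is a convolution of per-species arrays of unsigned Stirling
numbers of the first kind. These coefficients span hundreds to thousands of
orders of magnitude, so everything is computed in log space (C++, with
Stirling rows cached across calls); `Σ_D P(D) = 1` holds to 10⁻¹⁰ at small
`J` by direct enumeration, and the likelihood is finite for all valid
inputs. `m = 1` is handled as the Ewens limit. Sampling from the same law
uses the two-stage urn: individuals join immigrant-ancestor lineages with
probability `I/(I + j - 1)`, ancestors found species with probability
`θ/(θ + a - 1)`.

`fit_neutral()` maximizes over `(log θ, logit m)` from a 5 × 5 log-spaced
grid (θ in `[1, J]`, m in `[10⁻⁴, 0.99]`) refined by Nelder–Mead from the
three best starts (relative tolerance 10⁻⁶). The multi-start design is
deliberate: the surface is often bimodal, with a low-θ/high-m and a
high-θ/low-m optimum of nearly equal height, and single-start optimization
silently picks one. Monodominant samples drive `m` to its lower boundary
(they are exactly what the SNM produces as `m → 0`); the fit flags this.

`neutrality_test()` is the five-step parametric bootstrap: fit the sample;
draw `u` urn datasets at the fitted parameters (default `u = 1000`); fit
each by the identical procedure; the p-value is the fraction of null
maximized log-likelihoods *below* the sample's (a poorly fitting sample has
an atypically low maximized likelihood, so low `p` is evidence against
neutrality — the direction is chosen so that the test rejects misfit, and
exact ties, which occur at tiny `J`, count one half); reject when
`p < 0.05`.

## Power estimation

`estimate_power()` simulates `n_datasets` equilibrium samples from a
generating model, tests each, and reports the rejection fraction with an
equal-tailed Jeffreys interval (`Beta(x + ½, n - x + ½)` quantiles; the
interval is clamped to 0/1 at the endpoints). When the generating model is
the SNM itself the estimate is the type-I error and must match the nominal
level — this calibration is the suite's primary end-to-end check.
`power_sweep()` runs a declarative grid of cells with per-cell TSV
checkpointing, because realistic sweeps are expensive: each dataset costs
`u + 1` likelihood maximizations.

Reference problem sizes: the defaults are `n_datasets = 400`, `u = 1000`,
appropriate for cluster-scale studies. The package's desk-scale profiles, used throughout the test
suite so that the full suite runs in tens of minutes on one core, are
`n = 100, u = 200` for the type-I calibration at `J = 200`, `n = 60,
u = 100` for the competition-strength sweep, and `n = 40, u = 60` for the
community-size sweep up to `J = 5000`. These reduce only Monte-Carlo
resolution, not the procedure; all qualitative power comparisons are made
through non-overlapping Jeffreys intervals.

## Stability of the even fixed point of the PC map

For large `J` and small `m`, the PC relative abundances follow the
deterministic map `r_i' = r_i e^{-c r_i} / Σ_k r_k e^{-c r_k}`. At the
uniform fixed point `r_i = 1/S_T` every zero-sum perturbation mode has
multiplier `λ = 1 - c/S_T`, so the fixed point is stable exactly when
`c < 2 S_T` and gives way to period-two cycles and chaos beyond. The
critical *dimensionless* combination is therefore the ratio `c/S_T = 2`,
independent of `S_T` — note that it is the ratio, not the product `c·S_T`,
that is critical, as direct iteration confirms for `S_T ∈ {2, 10, 50}`.
`pc_stability_boundary()` locates the threshold empirically by bisection on
`c/S_T` with an iterate-a-perturbation criterion and recovers 2 to three
decimal places. `community_model()` warns when a PC/EVEN specification is
at or beyond the boundary.

## Matching real censuses

`fit_to_targets()` finds model parameters `(m, θ)` or `(m, S_T)` such that
the Monte-Carlo mean richness and mean Shannon index of equilibrium samples
match empirical targets (e.g. the shipped `forest_targets()` table of three
large tropical-forest plots). The search nests a bisection on `m` against
the Shannon target — mean Shannon diversity is monotone increasing in `m`
in practice, and the code verifies this from the endpoint evaluations,
falling back to a profiled grid with interpolation when it fails — inside a
log-grid scan over diversity against the richness target. Every sign change
is refined, so zero, one, or two solutions are reported; two genuinely
distinct solutions (low-θ/high-m vs high-θ/low-m) occur for weak intrinsic
fitness differences. For even pools whose richness stays below target at
the largest finite `S_T`, the infinite pool is tried as the boundary
solution. All evaluations share one seed (common random numbers), so
residual noise reflects only the per-evaluation budget (default 50
replicates; tolerance 0.5 species and 0.01 nats, both configurable). When
no solution exists the report carries the achievable Shannon envelope,
distinguishing "model always above target" from "always below".

## Numerical choices, degenerate inputs, limitations

* `J = 1` samples have likelihood 1 for all parameters; the fit returns a
  flat optimum rather than failing.
* The likelihood at `m = 1` uses the Ewens formula directly instead of the
  divergent `I`.
* Perfectly even samples (`n_i` all equal) reject neutrality strongly;
  monodominant samples never can, because they arise from the SNM as
  `m → 0`. Both extremes are exercised in tests.
* Bootstrap replicates whose fit fails are retried once, then dropped with
  a warning and counted in the result; simulated datasets that fail
  burn-in are likewise dropped and counted by `estimate_power()`.
* The synthetic data emulate well-mixed, zero-sum communities with static
  metacommunities. They do not emulate spatial clumping, temporal
  environmental fluctuation, trophic structure, or measurement error in
  real censuses — a passing suite therefore validates the *method*, not
  any claim that real forests satisfy the models' assumptions.
* Power estimates for census-scale communities (`J` in the tens of
  thousands with `u = 1000`) are supported by `power_sweep()` with
  checkpointing, but they are cluster-scale computations; the package's
  tests validate such configurations without executing them.
* All computation is sequential from R's global RNG: a single `set.seed()`
  reproduces any run bit for bit.
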