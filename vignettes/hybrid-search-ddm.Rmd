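---
title: "Modelling hybrid visual search: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hybrid visual search: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hybridsearch)
```

## The problem

In hybrid search an observer holds several potential targets in memory (the
memory set, MSS items) and searches a display (the visual set, VSS items)
for any of them. Two reaction-time signatures are robust across the
literature: mean RT grows approximately **linearly in the visual set size**
and approximately **logarithmically in the memory set size**. This package
implements the full analysis chain for such experiments — trial-level
cleaning rules, per-participant set-size regressions, random-intercept
mixed models, a drift-diffusion process model whose parameters map onto the
experimental conditions, and individual-difference measures (Cowan's K,
signal detection theory d′ and criterion c) — together with seeded
generators so that every stage is testable end to end without any
downloaded data.

## The diffusion model

The core decision model is the minimal three-parameter Wiener process:
evidence starts at 0 between absorbing boundaries at +B ("present"
response) and −B ("absent"), accumulating with drift μ (evidence/s) and
diffusion coefficient σ (evidence/√s, fixed at 1 — it only sets the
evidence scale). The observed RT is the boundary-crossing time plus a
non-decision time t0 (s); trials not absorbed within the 7 s response
deadline are non-responses. There is no starting-point bias and no
across-trial parameter variability: the aim is interpretability of three
parameters, not maximal fit.

Closed forms used throughout: the absorption probability at +B is
`1/(1 + exp(−2μB/σ²))` and the mean decision time is `(B/μ)·tanh(μB/σ²)`.
The first-passage-time density is evaluated by the classic pair of series
expansions (small-time and large-time), switched at the accuracy-matched
crossover with truncation chosen for ~1e−12 absolute error; the density at
the upper boundary under drift μ equals the density at the lower boundary
under −μ (reflection through the symmetric start), which the tests assert
to 1e−10.

**Robust likelihood.** Each trial contributes
`(1 − λ)·f(rt) + λ / (2(t_max − t0))`, where f is the defective density at
the response boundary and the second term is a uniform contaminant over
response times and boundaries. The floor keeps the likelihood finite for
RTs the diffusion process cannot produce (anticipations faster than t0,
stray outliers). λ defaults to 0.02 and can be fitted or fixed;
non-responses are excluded from the likelihood rather than treated as
censored, matching the treatment of timeouts in the RT analyses.

**Fitting.** Parameters are estimated by differential evolution
(rand/1/bin; population 15 per free parameter, crossover 0.7, F dithered
on [0.5, 1) per generation, relative tolerance 1e−6, seeded and therefore
reproducible). A global population-based optimiser is deliberate: the
robust likelihood surface has plateaus (e.g. in t0 near min(rt)) where
gradient methods stall.

## The condition-to-parameter mapping

The hybrid model ties one diffusion process per design cell to a small
shared coefficient set:

* drift `μ(MSS, context) = μ0 / (1 + γ·ln MSS) + δ·[context]`,
* boundary `B(VSS) = a0 + a1·VSS`,
* t0 constant across conditions.

With mean decision time ≈ B/μ for moderate drift, an inverse-log drift
yields the logarithmic RT×MSS growth and a linear boundary yields linear
RT×VSS growth. The drift's attenuation was described in the source
literature both as a "multiplicative inverse" and as falling
"logarithmically" with MSS; only the inverse-log form reproduces
logarithmic RT growth, so `inverse_log_mss` is the default and a plain
`inverse_mss` form (`μ0/(1 + γ(MSS − 1))`) is available behind the
`drift_form` switch. The context term enters the drift additively and
signed — nothing constrains its direction; the calibrated default is
negative (context slows evidence accumulation, raising intercepts).

Two conventions deserve explicit statement:

* **Response coding.** The upper boundary is the "present" response. On
  target-present trials the drift is the mapped (positive) value; on
  target-absent trials its sign is reversed, i.e. the same memory/context
  mechanism drives evidence toward the correct "absent" response. The
  extended model lets the boundary and non-decision time differ on
  target-absent trials (`a0_ta`, `a1_ta`, `t0_ta`).
* **What data enter the fit.** The joint fit uses *all answered
  target-present trials*, errors included. The two-boundary defective
  density is a proper likelihood only then; conditioning on correctness
  truncates away the error mass and measurably biases the drift and
  boundary upward (the package's recovery tests demonstrate clean recovery
  under the inclusive convention).

A pooled fit has a known blind spot that the analysis scripts surface:
when non-decision time genuinely varies across participants, the pooled t0
is forced below the fastest participants' effective t0 (the density is
zero for rt < t0), so it underestimates the population mean. The model is
a model of condition effects, not of between-subject variability.

## The synthetic experiment

`generate_experiment()` emulates the reference design: 110 participants ×
112 trials; memory and visual set sizes {1, 2, 4, 8} fully crossed with 7
trials per pair; scene context on half the trials and target presence on
half, balanced within set-size pairs up to the rotation of a remainder;
every participant sees the same 112 unique stimuli in an independently
randomised order; responses and RTs are drawn from the mapped diffusion
process (Euler–Maruyama, dt = 0.005 s for bulk synthesis) with a 7 s
deadline producing genuine timeouts.

Calibrated defaults `μ0 = 2, γ = 0.8, δ = −0.4, a0 = 0.8, a1 = 0.15,
t0 = 0.35 s, λ = 0.02` give mean RTs in the 1–2.5 s range with linear
VSS growth (~0.19 s/item at MSS 4) and logarithmic MSS growth (~0.37 s per
log-unit) — the magnitudes of the behavioural signatures the analyses are
designed to detect.

**Participant heterogeneity** enters as a Gaussian additive shift of t0
(truncated so every effective t0 stays positive) — the simplest mechanism
that produces a random intercept on RT. The shift SD is not hand-set: the
shipped default (0.5625 s) was produced by `calibrate_participant_sd()`,
which bisects the SD until the random-intercept mixed model fitted to the
generated data reaches a requested intraclass correlation (target 0.15),
using common random numbers so the bisection target is deterministic.
Calibration was run at the full design size; at 40 participants the
between-participant variance estimate is too noisy to bisect against.

What the generator does **not** emulate: scene semantics and syntax (no
image content at all), stimulus-level difficulty differences (stimuli are
exchangeable unless an outlier is injected), speed–accuracy strategy
shifts, practice and fatigue. Accuracy is whatever the diffusion process
produces — with a boundary that grows with VSS, accuracy *rises* with
visual set size while RT grows, unlike in human data where accuracy falls
with both set sizes. Passing tests therefore certify the statistical
machinery and the model's RT signatures, not a full behavioural
replication. One emergent property matches the reference simulations: a
significant VSS × context interaction appears in the mixed models fitted
to DDM-generated data even though the generating drift is additive in
context, because context scales the drift while the boundary scales with
VSS and the two interact nonlinearly in the mean decision time.

Two injection hooks exercise the cleaning rules end to end: a stimulus
outlier (+3 s on one stimulus, capped just below the deadline) that the
screening ANOVA must single out, and a low-accuracy participant (responses
rewritten to a fixed accuracy) that the 3-SD exclusion rule must catch.

The change-detection generator draws each participant's true capacity
K ~ N(2.31, 0.82) truncated at 0 and uses the standard single-probe model
(probe in memory with probability min(1, K/N); remembered probes answered
correctly, the rest guessed "change" at rate 0.1) — exactly the model that
Cowan's `K = N(H − FA)` inverts, so the population mean is recoverable.
The go/no-go generator draws criterion c ~ N(−0.23, 0.58) and sensitivity
d′ ~ N(2.5, 0.6) (truncated at 0.2; the reference reports only the c
distribution, so the d′ population is the package's own realistic choice)
and responds via the equal-variance SDT model: P(respond | go) =
Φ(d′/2 − c), P(respond | no-go) = Φ(−d′/2 − c).

## Cleaning rules

* **RT filter:** timeouts removed, only correct trials kept, sub-200 ms
  responses retained; all removals are counted in the table's provenance.
* **Participant exclusion:** overall accuracy (raw data; unanswered trials
  count as errors) below mean − 3·SD across participants. If the SD is
  zero nobody is excluded. k is tunable; k = ∞ is the identity.
* **Stimulus screening:** per condition cell (context × MSS × VSS ×
  target), one-way ANOVA of correct-trial RT on stimulus identity; if
  F > 20 with p < 0.05, Tukey HSD is computed and the stimulus whose mean
  RT deviates most from the mean of the cell's other stimuli is discarded —
  at most one per cell, to preserve design balance. Whether screening
  should use correct-only or all answered trials is not settled in the
  source; correct-only keeps screening consistent with the analysis
  dataset and is the package's choice. In two-stimulus cells the deviation
  criterion is perfectly symmetric, so exact ties go to the *slower*
  stimulus (RT screening exists to catch abnormally slow images).

## Mixed models

The Gaussian random-intercept model is fitted by full maximum likelihood
(not REML — fixed-effect structures are compared by likelihood-ratio
tests, which REML would invalidate). For a given between/within variance
ratio the fixed effects and the residual variance are profiled out in
closed form via the groupwise Woodbury identity, leaving a one-dimensional
bounded search over the log ratio; the zero-variance boundary is checked
explicitly. AIC counts all fixed effects plus two variance parameters.
Confidence intervals and p-values are Wald (normal) — the reference does
not state its method, and the outputs label this. The accuracy analysis
uses a random-intercept logistic model whose marginal likelihood is
integrated by adaptive Gauss–Hermite quadrature (20 nodes; per-group mode
and curvature by Newton steps), with a `fix_sigma_b` escape hatch that
collapses it exactly onto ordinary logistic regression at σ_b → 0. Both
implementations are cross-checked against an independent reference
implementation in the test suite (log-likelihood agreement ~1e−4 or
better).

Per-participant curve fits follow the complementary protocol: cell-mean RT
per set-size level (the other axis fixed at 4), ordinary least squares on
the level and on its natural log, both forms reported with R² and Gaussian
AIC. Natural log throughout — the base only rescales the slope.

## Numerical choices

* Density series truncated for 1e−12 absolute error; quadrature checks at
  1e−4.
* The Euler–Maruyama simulator adds a Brownian-bridge within-step crossing
  check: plain Euler misses crossings that return within a step, an
  O(√dt) bias (~0.02 s at dt = 0.001) large enough to break the package's
  own simulator–density agreement bound (KS < 0.01 at n = 10⁵). With the
  bridge correction the KS distance is ~0.003 at dt = 0.001 and ~0.008 at
  dt = 0.005.
* dt defaults: 0.001 s for validation-grade simulation, 0.005 s for bulk
  experiment synthesis.
* Differential evolution: out-of-bounds trial components are reflected
  back into the box; convergence is declared when the population's
  objective spread falls below 1e−6 relative.
* All stochastic entry points take explicit seeds and restore the global
  RNG state; identical seeds give byte-identical outputs.

## Problem sizes

The test suite and the acceptance script run everything at the sizes the
analyses are designed for: 10⁵ simulated paths for density validation,
5,000 trials for single-process recovery (three seeds), one full 110 × 112
synthetic experiment for mapping recovery and for the mixed-model battery,
500 reduced-size replicates (20 participants × 32 trials) for the
likelihood-ratio type-I calibration, and 20 replicates each for AIC form
selection and fixed-effect CI coverage.

## Known limitations

* The DDM is pooled: no hierarchical per-participant parameters, so the
  fitted t0 is biased toward the fastest participants when non-decision
  time varies (see above).
* The generator's accuracy-by-set-size pattern is a model consequence, not
  a match to human data.
* No random slopes, no Satterthwaite/Kenward–Roger degrees of freedom, no
  collapsing boundaries or across-trial variability parameters.
* Screening power is limited in cells with very few stimuli; cells with a
  single stimulus are skipped and logged.
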