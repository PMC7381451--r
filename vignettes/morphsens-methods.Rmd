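---
title: "Measuring and comparing sensitivity to diluted facial expressions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and comparing sensitivity to diluted facial expressions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphsens)
```

## The measurement problem

An observer watches two brief faces in sequence: one neutral, one showing an
emotional expression morph-diluted toward neutral, and reports which
interval held the expressive face. Because the stimulus continuum runs from
the full expression (0% dilution) to pure neutral (100% dilution),
sensitivity can be summarised as the largest dilution at which the observer
still picks the expressive interval on 75% of trials. `morphsens`
implements that measurement — the psychometric model, its maximum-likelihood
fit, and the threshold — together with an individual-level test of whether
two conditions (two emotions, two sessions, two stimulus variants) genuinely
differ within one observer, and a simulator that stands in for behavioral
data when designing or validating such experiments.

## The model

All fitting happens on the *intensity* scale, $x = 100 - \text{dilution}$,
so that performance increases with $x$ and the slope is positive. Expected
proportion correct is

$$\psi(x) = \gamma + (1 - \gamma - \lambda)\, F_L(x;\alpha,\beta), \qquad
F_L(x) = \frac{1}{1 + e^{-\beta (x - \alpha)}}.$$

* $\gamma$, the guess rate, is fixed at 0.5: a two-interval forced choice is
  correct half the time by guessing alone. With $\gamma = 0.5$ and
  $\lambda = 0$, $\psi(\alpha) = 0.75$ exactly, so the location parameter
  *is* the 75%-correct threshold. This is why the package treats the plain
  logistic's midpoint and the 75% criterion as the same point: the chance
  floor is absorbed by the wrapper, not by redefining $F_L$.
* $\lambda$, the lapse rate, defaults to 0 (no stimulus-independent errors)
  but is configurable everywhere; fits hold it fixed rather than estimating
  it, because 7-level data rarely constrain a free lapse and the comparison
  machinery needs both conditions fit under identical assumptions.
* $\alpha$ (intensity percent) and $\beta$ (per percent intensity) are the
  free parameters. Reported thresholds are mirrored back to the dilution
  scale, `threshold_dilution()` $= 100 - x^*$ with $\psi(x^*)$ at the
  criterion, so that a *larger* threshold means the observer tolerates more
  dilution — greater sensitivity. The mirroring lives in exactly one
  function and is tested in both directions.

## Fitting

`fit_pf()` minimises the exact binomial negative log-likelihood
(`pf_nll()`) over $(\alpha, \log\beta)$ with Nelder–Mead from five starts:
$\alpha$ begins at the level where the observed proportions cross the
criterion (linear interpolation), and slopes are log-spaced across the
plausible range. The search is confined to $\alpha \in [-50, 150]$
intensity and $\beta \in [10^{-3}, 10]$ by a soft quadratic penalty; inside
the logs, $\psi$ is clamped to $[10^{-10}, 1 - 10^{-10}]$ so a lapse-free
saturated level cannot produce an infinite objective. The fit is implemented
in C++ because the bootstrap test below refits tens of thousands of
simulated datasets; the R-level `pf_nll()` is the reference definition, and
the test suite asserts that every fit's reported log-likelihood equals it
and that no point of a 201 × 201 grid around the optimum attains a lower
value.

A unit is declared *unfittable* — `fittable = FALSE`, thresholds refused —
when (a) no level reaches the criterion proportion correct, (b) responses
are identical at every level, or (c) the optimum sits on the search bounds.
These cases are reported with reasons instead of raising errors, because
study-level analyses must carry on past an undiscriminable unique face or a
chance-level condition.

## The within-observer comparison

`pf_lr_test()` decides whether two conditions share one psychometric
function. The nested models are fit by maximum likelihood — 1PF: one
$(\alpha, \beta)$ for the pooled data; 2PF: separate $(\alpha, \beta)$ per
condition, guess and lapse fixed in both — giving the likelihood ratio
$\mathrm{LR} = \exp(\ell_{1PF} - \ell_{2PF}) \le 1$. Its null distribution
is built by parametric bootstrap: each replicate simulates both conditions
as binomial draws from the *1PF (null) fit* at the observed levels and
trial counts, then refits both models with identical optimizer settings.
Choices worth knowing:

* **p value.** $p = \#\{\mathrm{LR}_{sim} < \mathrm{LR}_{obs}\}/n_{sims}$,
  with a *strict* inequality (ties favour the null) and no $+1$ correction
  — so at 10,000 simulations, 499 smaller ratios give $p = 0.0499 < .05$
  and 500 give exactly .05. A count of zero is printed as
  $p < 1/n_{sims}$.
* **Failed refits.** A simulated dataset whose refit fails (bound hit, no
  level at criterion, or the pooled fit beating the separate fits beyond
  tolerance) is retried with jittered starts up to three times, then
  redrawn; redraws are counted and a warning is raised if they exceed 1% of
  replicates.
* **Determinism.** All draws run under R's RNG; a `seed` argument makes
  `n_smaller`, `p_value` and the whole simulated-LR vector bit-identical
  across runs.
* **Calibration.** The test suite measures the type-I error under a true
  shared function (200 null pairs, 500 inner simulations each) and requires
  it to land in $[0.02, 0.10]$ at nominal .05; the strict-inequality
  convention makes the test slightly conservative (observed around 0.03).

Default $n_{sims}$ is 10,000; the test suite and examples use a few hundred
for speed, which only coarsens the p-value grid, not the calibration.

## The synthetic observer

The simulator emulates the experimental design the analysis expects:

* **Schedules** (`generate_schedule()`) are complete shuffled passes over
  the levels × faces set — every pair occurs $n$ times before any occurs
  $n+1$ times — with the test stimulus assigned to interval 1 by an
  independent fair coin. The default design is 7 dilution levels × 6 unique
  faces × 40 repeats = 1680 trials, i.e. 240 observations per level.
* **Observers** (`observer_spec()`) respond correctly with probability
  $\psi$ at the trial's intensity. Per-face heterogeneity is modelled as
  additive threshold offsets (centred on zero, slopes shared) — the
  simplest mechanism that produces face-level scatter — and session effects
  as a threshold shift per additional session. At 100% dilution the test
  and comparison stimuli are physically identical, so the success
  probability is exactly $\gamma$ regardless of the fitted curve's value at
  zero intensity.
* **Presented levels.** Real dilutions come from a morphing ladder — 2–98%
  in steps of 2 or 1–99% in steps of 1 (`dilution_ladder()`) — and each
  simulated observer's seven levels are snapped to the ladder so that
  expected performance spans roughly 57–99% correct around their true
  threshold (`levels_spanning()`), mimicking per-participant tailoring. The
  fixed set (68, 80, 86, 90, 94, 96, 98) is used for the group curve,
  where each participant's *fitted* function is evaluated and averaged —
  pooling predictions, not raw trials, keeps differently tailored designs
  comparable.
* **Study presets** (`study_preset()`). The `exp1` preset draws 11 true
  happy thresholds from $N(92,\ 0.57\sqrt{11})$ and fear thresholds from
  $N(86,\ 1.23\sqrt{11})$ dilution percent — group mean and standard error
  converted to a between-subject SD — with slope 0.3 per percent intensity,
  a value that spreads the seven levels over the informative part of the
  curve and fits reliably at 240 trials per level. `retest`, `faces`,
  `durations` and `sizes` vary sessions, per-face offsets and metadata on
  the same core. Emotions are simulated as separate blocks (each condition
  gets its own schedule), matching session-length constraints of real
  testing.
* **RNG streams.** Truths, schedules and responses each draw from a stream
  derived from the study seed and the cell's identifiers, so adding a
  participant or condition never perturbs existing cells, and a full study
  is bit-reproducible.

What the simulator deliberately does *not* reproduce: sequential
dependencies (learning, fatigue, response bias drift), reaction times,
lapses unless configured, non-logistic true curves, and any image-level
properties of the stimuli. Passing tests therefore demonstrate that the
estimator and test are correct and calibrated *under the stated response
model*, not that real observers satisfy that model.

## Group-level analysis

`analyze_study()` fits every participant × condition, extracts thresholds,
runs the within-observer comparison (and test–retest comparisons when two
sessions are present), and summarises: mean ± SEM (SD/$\sqrt{n}$) of
thresholds per condition, the group curve at the fixed dilution set, and a
two-sided paired t test between conditions with effect size
$r = \sqrt{t^2/(t^2 + df)}$ — the formula is chosen because it is the
standard paired-design conversion, and `r_from_t()` exposes it directly.
Group statistics use only participants fittable in both conditions;
exclusions are enumerated with reasons so counts always reconcile.
Thresholds are printed to one decimal place (one digit more than integer
reporting, avoiding tie ambiguity in scatter plots).

## Problem sizes and numerical tolerances

The package's own validation uses sizes chosen to make Monte-Carlo noise
small relative to the assertions: noiseless expected-count refits recover
$(\alpha, \beta)$ to $10^{-3}$ relative; threshold/criterion round-trips
hold to $10^{-9}$; calibration and power properties use 200 null pairs and
30–50 replicates per condition at 500 inner simulations; the acceptance
script averages 20 replicates of the full 11-observer study per condition.
Degenerate inputs (flat-at-chance data, saturated data, empty groups,
criterion outside $(\gamma, 1-\lambda)$) are exercised explicitly and must
fail softly (unfittable flags) or loudly (validation errors naming row and
column) as documented.

## Known limitations

* Only the logistic form is offered; Weibull/Gumbel alternatives and free
  guess/lapse estimation are out of scope.
* The comparison handles exactly two conditions per test; multi-condition
  families need repeated pairwise tests, and no multiplicity correction is
  applied.
* Asymptotic $\chi^2$ p-values are intentionally not provided — with 7
  levels and bounded parameters the bootstrap reference distribution is the
  defensible choice.
* The bootstrap p has resolution $1/n_{sims}$; studies needing $p < 10^{-4}$
  claims must raise `n_sims` accordingly.
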