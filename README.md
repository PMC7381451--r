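# morphsens

Psychometric sensitivity to morph-diluted facial expressions.

`morphsens` is for psychophysicists and affective-science researchers who
measure how well an individual observer discriminates an emotional facial
expression (e.g. happy or fearful) from neutral, using a temporal
two-interval forced-choice (2IFC) task and the method of constant stimuli.
Stimuli are morphs between a full expression (0% dilution) and the neutral
face (100% dilution); the question is how much dilution an observer can
tolerate while still picking the expressive interval on 75% of trials.

The package provides:

- **Maximum-likelihood psychometric fits.** Performance is modelled as

  ψ(x) = γ + (1 − γ − λ) · F_L(x; α, β),  F_L(x) = 1 / (1 + exp(−β(x − α)))

  with intensity x = 100 − dilution, guess rate γ = 0.5 (2IFC chance) and
  lapse rate λ = 0 by default, so ψ(α) = 0.75 and α is the threshold.
  Threshold and slope are estimated by multi-start Nelder–Mead on the exact
  binomial likelihood (in C++ for speed); thresholds are reported on the
  dilution scale, where *larger = more sensitive*.
- **An individual-level (n-of-1) significance test.** Whether two conditions
  (happy vs fear, session 1 vs 2, ...) differ *within one observer* is
  decided by a parametric-bootstrap likelihood-ratio test: the data are fit
  as one shared function (1PF) and as two separate functions (2PF), and the
  observed likelihood ratio LR = L(1PF)/L(2PF) is ranked against 10,000
  simulations from the null fit; p = #{LR_sim < LR_obs} / n_sims, so at
  10,000 simulations fewer than 500 smaller ratios means p < .05.
- **A synthetic-observer simulator.** Method-of-constant-stimuli schedules
  (complete shuffled passes over levels × faces, fair-coin interval
  assignment) and Bernoulli observers with per-face and per-session effects,
  plus study presets, so the whole pipeline can be exercised, calibrated and
  power-analysed without collecting data.
- **Study-level analysis and a CLI**: binning, per-participant and per-face
  fits, group curves at a fixed dilution set, the paired t test with effect
  size r = √(t²/(t² + df)), and `simulate` / `fit` / `compare` / `analyze`
  subcommands.

## Worked example

Simulate the default study preset — 11 observers, happy and fear, seven
tailored dilution levels, 240 trials per level — and run the full analysis
with 500 bootstrap simulations per comparison:

```r
library(morphsens)
trials <- make_synthetic_study("exp1", seed = 7)
report <- analyze_study(trials, n_sims = 500, seed = 7)
report
#> <group_report> 11 participants, conditions happy vs fear
#>   fear: mean threshold 84.4% dilution (SEM 1.29, n = 11)
#>   happy: mean threshold 92.8% dilution (SEM 0.60, n = 11)
#>   paired t(10) = 7.21, p = 2.89e-05, r = 0.92
#>   individual comparisons significant at .05: 11 of 11
```

The group means sit near the preset's generating thresholds (92% happy, 86%
fear; this seed drew a fear sample a little low — the fear truths have an
11-observer between-subject SD of about 4 dilution points). Every observer
tolerates more dilution for happy than for fear, and each within-observer
comparison is individually significant. One observer's test in detail:

```r
report$participants$P01$comparison
#> <pf_lr_test> happy vs fear (parametric bootstrap, 500 simulations)
#>   thresholds: happy = 94.3%, fear = 84.6% dilution
#>   likelihood ratio = 1.346e-64 (TLR = 294.137)
#>   0 of 500 simulated ratios smaller than observed: p < 0.002
```

The same analyses are available from the shell via the installed script
(`system.file("scripts", "morphsens", package = "morphsens")`), e.g.
`morphsens simulate --preset exp1 --seed 7 --out trials.csv` followed by
`morphsens analyze --trials trials.csv --n-sims 10000 --seed 7`.

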