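# Shared fixtures, all built in code.

FIXED_LEVELS <- c(68, 80, 86, 90, 94, 96, 98)

# Noiseless dataset: expected correct counts under `params`.
exact_binned <- function(params, levels = FIXED_LEVELS, n = 240) {
  psi <- pf_performance(100 - levels, params)
  binned_data(levels, rep(n, length(levels)), n * psi)
}

# Bernoulli-sampled dataset (uses the current RNG state).
sim_binned <- function(params, levels = FIXED_LEVELS, n = 240) {
  psi <- pf_performance(100 - levels, params)
  binned_data(levels, rep(n, length(levels)), rbinom(length(levels), n, psi))
}

# Independent R-side likelihood oracle: same definition as pf_nll but
# written directly, used to cross-check fits on evaluation grids.
grid_nll <- function(alpha, beta, data, gamma = 0.5, lambda = 0) {
  psi <- gamma + (1 - gamma - lambda) *
    plogis(beta * (data$intensity_pct - alpha))
  psi <- pmin(pmax(psi, 1e-10), 1 - 1e-10)
  -sum(data$n_correct * log(psi) +
         (data$n_trials - data$n_correct) * log1p(-psi))
}

# Small study configuration for fast pipeline tests: 3 observers,
# 10 repeats per face (60 observations per level).
small_study_config <- function(n_participants = 3, repeats = 10,
                               happy_mean = 92, fear_mean = 86) {
  cfg <- study_preset("exp1")
  cfg$participants <- sprintf("P%02d", seq_len(n_participants))
  cfg$schedule$repeats_per_face <- repeats
  cfg$conditions$happy$threshold_mean <- happy_mean
  cfg$conditions$fear$threshold_mean <- fear_mean
  cfg
}

# exp1 preset trials, generated once per test file.
.exp1_cache <- new.env(parent = emptyenv())
exp1_trials <- function(seed = 101) {
  key <- paste0("s", seed)
  if (is.null(.exp1_cache[[key]]))
    .exp1_cache[[key]] <- make_synthetic_study("exp1", seed = seed)
  .exp1_cache[[key]]
}
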