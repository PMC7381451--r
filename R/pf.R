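#' Psychometric-function parameters
#'
#' Bundles the four parameters of the 2IFC performance function
#' \deqn{\psi(x) = \gamma + (1 - \gamma - \lambda)\,F_L(x;\alpha,\beta),}
#' where \eqn{F_L(x) = 1/(1 + e^{-\beta(x-\alpha)})} is the logistic and
#' \eqn{x} is expression intensity in percent (100 minus dilution).
#' In a two-interval forced-choice task the guess rate \eqn{\gamma} is 0.5,
#' so with \eqn{\lambda = 0} performance at \eqn{x = \alpha} is exactly 75%
#' correct and \eqn{\alpha} is the threshold.
#'
#' @param alpha Threshold location, intensity percent.
#' @param beta Slope, per percent intensity; must be positive.
#' @param gamma Guess rate (lower asymptote); 0.5 for 2IFC.
#' @param lambda Lapse rate (1 minus the upper asymptote).
#' @return An object of class `pf_params`.
#' @examples
#' p <- pf_params(alpha = 8, beta = 0.3)
#' pf_performance(8, p) # 0.75
#' @export
pf_params <- function(alpha, beta, gamma = 0.5, lambda = 0) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, is.finite(alpha),
            is.numeric(beta), length(beta) == 1, is.finite(beta))
  if (beta <= 0) stop("`beta` must be > 0", call. = FALSE)
  if (gamma < 0 || gamma >= 1) stop("`gamma` must be in [0, 1)", call. = FALSE)
  if (lambda < 0 || lambda >= 1) stop("`lambda` must be in [0, 1)", call. = FALSE)
  if (gamma + lambda >= 1) stop("`gamma` + `lambda` must be < 1", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, lambda = lambda),
            class = "pf_params")
}

#' @export
print.pf_params <- function(x, ...) {
  cat(sprintf(
    "<pf_params> alpha = %.3f (intensity %%), beta = %.4f, gamma = %.2f, lambda = %.3f\n",
    x$alpha, x$beta, x$gamma, x$lambda))
  invisible(x)
}

#' Logistic function
#'
#' The plain logistic \eqn{F_L(x) = 1/(1+e^{-\beta(x-\alpha)})}, the core of
#' the psychometric model. \eqn{F_L(\alpha) = 0.5} and
#' \eqn{F_L(\alpha + \ln 3/\beta) = 0.75}.
#'
#' @param x Stimulus intensity (percent expression), vectorised.
#' @param alpha Location parameter, same units as `x`.
#' @param beta Slope, per unit of `x`; must be positive.
#' @return Probabilities in (0, 1), strictly increasing in `x`.
#' @examples
#' logistic_fun(0:4, alpha = 2, beta = 1)
#' @export
logistic_fun <- function(x, alpha, beta) {
  if (!is.numeric(beta) || any(beta <= 0))
    stop("`beta` must be > 0", call. = FALSE)
  plogis(beta * (x - alpha))
}

#' 2IFC performance function
#'
#' Evaluates expected proportion correct
#' \eqn{\psi(x) = \gamma + (1-\gamma-\lambda) F_L(x;\alpha,\beta)}
#' at intensity `x`. Bounded in \eqn{[\gamma, 1-\lambda]} and monotone
#' increasing in intensity (hence decreasing in dilution).
#'
#' @param x Intensity percent (100 - dilution), vectorised.
#' @param params A [pf_params()] object.
#' @return Expected proportion correct.
#' @examples
#' p <- pf_params(alpha = 14, beta = 0.3)
#' pf_performance(c(2, 14, 40), p)
#' @export
pf_performance <- function(x, params) {
  stopifnot(inherits(params, "pf_params"))
  params$gamma + (1 - params$gamma - params$lambda) *
    logistic_fun(x, params$alpha, params$beta)
}

#' Binned 2IFC data for one fitting unit
#'
#' Aggregated trial counts per stimulus-dilution level for one participant x
#' condition (or any other fitting unit). Levels are stored sorted by
#' dilution, carrying both the dilution and the derived intensity scale.
#'
#' @param dilution_pct Distinct dilution levels in \[0, 100\].
#' @param n_trials Nonnegative trial counts per level.
#' @param n_correct Correct counts, `0 <= n_correct <= n_trials`. Expected
#'   (non-integer) counts are accepted, e.g. for noiseless refit checks.
#' @return A `binned_data` tibble with columns `dilution_pct`,
#'   `intensity_pct`, `n_trials`, `n_correct`.
#' @examples
#' binned_data(c(90, 94, 98), n_trials = c(40, 40, 40), n_correct = c(38, 30, 21))
#' @export
binned_data <- function(dilution_pct, n_trials, n_correct) {
  stopifnot(is.numeric(dilution_pct), is.numeric(n_trials), is.numeric(n_correct))
  if (length(dilution_pct) < 1)
    stop("at least one level is required", call. = FALSE)
  if (length(n_trials) != length(dilution_pct) ||
      length(n_correct) != length(dilution_pct))
    stop("`dilution_pct`, `n_trials` and `n_correct` must have equal length",
         call. = FALSE)
  if (any(dilution_pct < 0 | dilution_pct > 100))
    stop("`dilution_pct` must lie in [0, 100]", call. = FALSE)
  if (anyDuplicated(dilution_pct))
    stop("dilution levels must be distinct", call. = FALSE)
  if (any(n_trials < 0) || any(n_correct < 0) || any(n_correct > n_trials))
    stop("counts must satisfy 0 <= n_correct <= n_trials", call. = FALSE)
  if (!any(n_trials > 0))
    stop("at least one level must have trials", call. = FALSE)
  ord <- order(dilution_pct)
  dil <- dilution_pct[ord]
  out <- tibble::tibble(
    dilution_pct = dil,
    intensity_pct = .intensity(dil),
    n_trials = n_trials[ord],
    n_correct = n_correct[ord]
  )
  class(out) <- c("binned_data", class(out))
  out
}

.assert_binned <- function(data) {
  if (!inherits(data, "binned_data")) {
    if (is.data.frame(data) &&
        all(c("dilution_pct", "n_trials", "n_correct") %in% names(data))) {
      return(binned_data(data$dilution_pct, data$n_trials, data$n_correct))
    }
    stop("`data` must be a binned_data object (see binned_data())",
         call. = FALSE)
  }
  data
}

#' Negative binomial log-likelihood of a psychometric function
#'
#' \eqn{-\sum_i [k_i \ln\psi(x_i) + (n_i-k_i)\ln(1-\psi(x_i))]} over levels,
#' with \eqn{\psi} clamped to \eqn{[10^{-10}, 1-10^{-10}]} inside the logs so
#' the value stays finite when a lapse-free function saturates. The binomial
#' coefficients are omitted (they do not depend on the parameters), so the
#' value is nonnegative and additive over disjoint level sets.
#'
#' @param data A [binned_data()] object.
#' @param params A [pf_params()] object.
#' @return Nonnegative scalar.
#' @examples
#' d <- binned_data(98, 10, 5)
#' pf_nll(d, pf_params(alpha = 2, beta = 1e-3)) # ~ 10 * log(2)
#' @export
pf_nll <- function(data, params) {
  data <- .assert_binned(data)
  stopifnot(inherits(params, "pf_params"))
  psi <- pf_performance(data$intensity_pct, params)
  psi <- pmin(pmax(psi, 1e-10), 1 - 1e-10)
  keep <- data$n_trials > 0
  -sum(data$n_correct[keep] * log(psi[keep]) +
         (data$n_trials[keep] - data$n_correct[keep]) * log1p(-psi[keep]))
}

.new_pf_fit <- function(params, log_likelihood, converged, fittable, reason,
                        n_levels_used, data, criterion, joint = FALSE) {
  structure(list(
    params = params,
    log_likelihood = log_likelihood,
    free = c(alpha = TRUE, beta = TRUE, gamma = FALSE, lambda = FALSE),
    converged = converged,
    fittable = fittable,
    reason = reason,
    n_levels_used = n_levels_used,
    data = data,
    criterion = criterion,
    joint = joint
  ), class = "pf_fit")
}

#' Maximum-likelihood psychometric-function fit
#'
#' Fits threshold `alpha` and slope `beta` of the 2IFC performance function
#' to binned data by minimising [pf_nll()], with the guess and lapse rates
#' held fixed. The search runs Nelder-Mead from `n_starts` starting points
#' (alpha at the observed criterion crossing, slopes log-spaced) inside the
#' box alpha in \[-50, 150\] intensity, beta in \[1e-3, 10\].
#'
#' A fit is declared unfittable -- `fittable = FALSE`, no threshold
#' interpretation -- when no level reaches the criterion proportion correct
#' or when the optimum sits on the box boundary (e.g. performance flat at
#' chance, or all levels saturated).
#'
#' @param data A [binned_data()] object (or data frame with the same columns).
#' @param gamma,lambda Fixed guess and lapse rates.
#' @param n_starts Number of optimizer starts (>= 1; 5 is robust for 7-level
#'   data).
#' @param criterion Performance criterion used for the fittability check and
#'   downstream threshold extraction; 0.75 throughout.
#' @return A `pf_fit` object: `params` ([pf_params()]), `log_likelihood`
#'   (exact binomial log-likelihood at `params`, \eqn{\le 0} up to constant),
#'   `free`, `converged`, `fittable`, `reason`, `n_levels_used`.
#' @examples
#' truth <- pf_params(alpha = 8, beta = 0.3)
#' d <- binned_data(c(68, 80, 86, 90, 94, 96, 98), rep(240, 7),
#'                  round(240 * pf_performance(100 - c(68, 80, 86, 90, 94, 96, 98), truth)))
#' fit <- fit_pf(d)
#' threshold_dilution(fit)
#' @export
fit_pf <- function(data, gamma = 0.5, lambda = 0, n_starts = 5,
                   criterion = 0.75) {
  data <- .assert_binned(data)
  chk <- pf_params(1, 1, gamma, lambda) # validates gamma/lambda
  stopifnot(n_starts >= 1)
  if (criterion <= gamma || criterion >= 1 - lambda)
    stop("`criterion` must lie in (gamma, 1 - lambda)", call. = FALSE)

  res <- .fit_ab_cpp(data$intensity_pct, data$n_trials, data$n_correct,
                     gamma, lambda,
                     .ALPHA_BOUNDS[1], .ALPHA_BOUNDS[2],
                     .BETA_BOUNDS[1], .BETA_BOUNDS[2],
                     as.integer(n_starts), criterion, 0)
  params <- pf_params(res$alpha, res$beta, gamma, lambda)
  reason <- NA_character_
  fittable <- TRUE
  used <- data$n_trials > 0
  if (res$max_prop < criterion) {
    fittable <- FALSE
    reason <- "no level reaches the criterion proportion correct"
  } else if (all(data$n_correct[used] == data$n_trials[used]) ||
             all(data$n_correct[used] == 0)) {
    fittable <- FALSE
    reason <- "responses are identical at every level"
  } else if (res$at_bound) {
    fittable <- FALSE
    reason <- "optimizer terminated at a parameter bound"
  } else if (!res$converged) {
    fittable <- FALSE
    reason <- "optimizer did not converge"
  }
  .new_pf_fit(params, -res$nll, res$converged, fittable, reason,
              sum(data$n_trials > 0), data, criterion)
}

#' @export
print.pf_fit <- function(x, ...) {
  kind <- if (isTRUE(x$joint)) "joint (1PF)" else "single-condition"
  cat(sprintf("<pf_fit> %s logistic psychometric fit\n", kind))
  cat(sprintf("  alpha = %.2f (intensity %%), beta = %.4f, gamma = %.2f, lambda = %.3f\n",
              x$params$alpha, x$params$beta, x$params$gamma, x$params$lambda))
  cat(sprintf("  log-likelihood = %.3f over %d levels\n",
              x$log_likelihood, x$n_levels_used))
  if (x$fittable) {
    cat(sprintf("  threshold = %.1f%% dilution at %.0f%% correct\n",
                threshold_dilution(x), 100 * x$criterion))
  } else {
    cat(sprintf("  UNFITTABLE: %s\n", x$reason))
  }
  invisible(x)
}

#' Dilution threshold at a performance criterion
#'
#' Inverts the fitted performance function at the criterion (default 75%
#' correct) and reports the result on the dilution scale, `100 - x*` where
#' \eqn{\psi(x^*) = } criterion. With `gamma = 0.5`, `lambda = 0` and
#' criterion 0.75 this is exactly `100 - alpha`. Larger values mean the
#' observer tolerates more dilution, i.e. greater sensitivity.
#'
#' @param fit A fittable `pf_fit` (or bare [pf_params()]).
#' @param criterion Proportion correct defining the threshold; must lie
#'   strictly between the guess rate and `1 - lambda`.
#' @return Threshold on the dilution scale (percent neutral).
#' @examples
#' threshold_dilution(pf_params(alpha = 14, beta = 0.3)) # 86
#' @export
threshold_dilution <- function(fit, criterion = 0.75) {
  if (inherits(fit, "pf_fit")) {
    if (!fit$fittable)
      stop("cannot extract a threshold from an unfittable fit: ", fit$reason,
           call. = FALSE)
    params <- fit$params
  } else if (inherits(fit, "pf_params")) {
    params <- fit
  } else {
    stop("`fit` must be a pf_fit or pf_params object", call. = FALSE)
  }
  if (criterion <= params$gamma || criterion >= 1 - params$lambda)
    stop(sprintf(
      "criterion %.3f is unattainable: performance is bounded in (%.3f, %.3f)",
      criterion, params$gamma, 1 - params$lambda), call. = FALSE)
  q <- (criterion - params$gamma) / (1 - params$gamma - params$lambda)
  x_star <- params$alpha + qlogis(q) / params$beta
  .dilution(x_star)
}

#' Parametric-bootstrap confidence interval for the fitted threshold
#'
#' Simulates `n_boot` datasets from the fitted performance function at the
#' observed levels and trial counts, refits each, and returns percentile
#' intervals for the threshold (dilution scale) and slope.
#'
#' @param fit A fittable `pf_fit`.
#' @param n_boot Number of bootstrap datasets.
#' @param level Interval coverage.
#' @param seed Optional integer seed.
#' @return A list with `threshold_ci`, `beta_ci`, and the bootstrap draws.
#' @export
pf_bootstrap <- function(fit, n_boot = 400, level = 0.95, seed = NULL) {
  stopifnot(inherits(fit, "pf_fit"), fit$fittable)
  data <- fit$data
  psi <- pf_performance(data$intensity_pct, fit$params)
  draw <- function() {
    k <- rbinom(nrow(data), data$n_trials, psi)
    f <- fit_pf(binned_data(data$dilution_pct, data$n_trials, k),
                gamma = fit$params$gamma, lambda = fit$params$lambda,
                criterion = fit$criterion)
    if (f$fittable) c(threshold_dilution(f, fit$criterion), f$params$beta)
    else c(NA_real_, NA_real_)
  }
  runs <- function() {
    draws <- replicate(n_boot, draw())
    a <- (1 - level) / 2
    list(
      threshold_ci = quantile(draws[1, ], c(a, 1 - a), na.rm = TRUE, names = FALSE),
      beta_ci = quantile(draws[2, ], c(a, 1 - a), na.rm = TRUE, names = FALSE),
      thresholds = draws[1, ], betas = draws[2, ],
      n_unfittable = sum(is.na(draws[1, ]))
    )
  }
  if (is.null(seed)) runs() else withr::with_seed(seed, runs())
}
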