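#' Joint (1PF) psychometric fit to two conditions
#'
#' Fits a single threshold and slope to the pooled likelihood of two
#' conditions' binned data -- the null model of the within-observer
#' comparison, under which both conditions share one psychometric function.
#' The summed log-likelihood over both datasets is maximised; this equals an
#' ordinary fit to the concatenated level sets.
#'
#' @param data_a,data_b [binned_data()] objects for the two conditions.
#' @inheritParams fit_pf
#' @return A `pf_fit` object flagged as joint; its `log_likelihood` is the
#'   summed log-likelihood over both conditions.
#' @export
fit_pf_joint <- function(data_a, data_b, gamma = 0.5, lambda = 0,
                         n_starts = 5, criterion = 0.75) {
  data_a <- .assert_binned(data_a)
  data_b <- .assert_binned(data_b)
  pooled <- dplyr::bind_rows(data_a, data_b)
  res <- .fit_ab_cpp(pooled$intensity_pct, pooled$n_trials, pooled$n_correct,
                     gamma, lambda,
                     .ALPHA_BOUNDS[1], .ALPHA_BOUNDS[2],
                     .BETA_BOUNDS[1], .BETA_BOUNDS[2],
                     as.integer(n_starts), criterion, 0)
  params <- pf_params(res$alpha, res$beta, gamma, lambda)
  fittable <- TRUE
  reason <- NA_character_
  if (res$max_prop < criterion) {
    fittable <- FALSE
    reason <- "no level reaches the criterion proportion correct"
  } else if (res$at_bound) {
    fittable <- FALSE
    reason <- "optimizer terminated at a parameter bound"
  } else if (!res$converged) {
    fittable <- FALSE
    reason <- "optimizer did not converge"
  }
  fit <- .new_pf_fit(params, -res$nll, res$converged, fittable, reason,
                     sum(pooled$n_trials > 0), pooled, criterion, joint = TRUE)
  fit
}

#' Likelihood ratio of nested psychometric models
#'
#' Converts the maximised log-likelihoods of the one-function (1PF, null)
#' and two-function (2PF, alternative) models into the likelihood ratio
#' `lr = exp(ll_1pf - ll_2pf)` and the deviance-scale statistic
#' `tlr = -2 (ll_1pf - ll_2pf)`. Nesting guarantees `lr <= 1`; small `lr`
#' means the shared-function model fits poorly.
#'
#' @param ll_1pf,ll_2pf Maximised log-likelihoods of the nested models.
#' @return A list with `lr` in (0, 1\] and `tlr >= 0`.
#' @examples
#' likelihood_ratio(-10, -8) # lr = exp(-2), tlr = 4
#' @export
likelihood_ratio <- function(ll_1pf, ll_2pf) {
  if (ll_1pf > ll_2pf + 1e-9)
    stop("ll_1pf exceeds ll_2pf: the nested (1PF) model cannot fit better; ",
         "refit with more starts", call. = FALSE)
  d <- min(ll_1pf - ll_2pf, 0)
  list(lr = exp(d), tlr = -2 * d)
}

#' Convert a bootstrap count to a p value
#'
#' `p = n_smaller / n_sims`, the proportion of simulated likelihood ratios
#' strictly smaller than the observed one. No continuity correction is
#' applied, so with 10,000 simulations a count of 499 gives p = 0.0499
#' (significant at .05) and 500 gives exactly .05.
#'
#' @param n_smaller Simulations with a smaller likelihood ratio than observed.
#' @param n_sims Total number of simulations (>= 1).
#' @return The p value, `n_smaller / n_sims`.
#' @examples
#' count_to_p(499, 10000)
#' @export
count_to_p <- function(n_smaller, n_sims) {
  stopifnot(length(n_smaller) == 1, length(n_sims) == 1, n_sims >= 1)
  if (n_smaller < 0 || n_smaller > n_sims)
    stop("`n_smaller` must lie in [0, n_sims]", call. = FALSE)
  n_smaller / n_sims
}

#' Within-observer psychometric-function comparison
#'
#' Tests whether two conditions measured in the same observer follow
#' genuinely different psychometric functions, using a parametric-bootstrap
#' likelihood-ratio test: the data are fit once as a single shared function
#' (1PF) and once as two separate functions (2PF, threshold and slope free
#' per condition, guess and lapse rates fixed); `n_sims` synthetic observers
#' are then simulated from the 1PF (null) fit at the observed levels and
#' trial counts, each is refit both ways, and the p value is the proportion
#' of simulated likelihood ratios strictly smaller than the observed one.
#'
#' @param data_a,data_b [binned_data()] for the two conditions (e.g. happy
#'   and fear). Both must be fittable on their own.
#' @param labels Length-2 character vector naming the conditions.
#' @param n_sims Number of bootstrap simulations (10,000 in full analyses;
#'   smaller values are fine for exploration).
#' @param seed Optional integer seed; with a seed the result is exactly
#'   reproducible.
#' @param gamma,lambda Fixed guess and lapse rates, shared by observed and
#'   simulated fits.
#' @param n_starts Optimizer starts per fit (observed and simulated fits use
#'   identical settings).
#' @return A `pf_lr_test` object: `fit_1pf`, `fits_2pf` (named by `labels`),
#'   `lr`, `tlr`, `n_sims`, `n_smaller`, `p_value = n_smaller/n_sims`,
#'   `n_redraws`, `seed`.
#' @examples
#' truth <- pf_params(alpha = 10, beta = 0.3)
#' lv <- c(78, 84, 88, 90, 92, 96, 98)
#' sim <- function() {
#'   psi <- pf_performance(100 - lv, truth)
#'   binned_data(lv, rep(60, 7), rbinom(7, 60, psi))
#' }
#' set.seed(1)
#' pf_lr_test(sim(), sim(), labels = c("happy", "fear"), n_sims = 50, seed = 2)
#' @export
pf_lr_test <- function(data_a, data_b, labels = c("A", "B"), n_sims = 10000,
                       seed = NULL, gamma = 0.5, lambda = 0, n_starts = 5) {
  data_a <- .assert_binned(data_a)
  data_b <- .assert_binned(data_b)
  stopifnot(length(labels) == 2, n_sims >= 1)
  if (labels[1] == labels[2])
    stop("condition labels must be distinct", call. = FALSE)

  fit_a <- fit_pf(data_a, gamma, lambda, n_starts)
  fit_b <- fit_pf(data_b, gamma, lambda, n_starts)
  if (!fit_a$fittable)
    stop(sprintf("condition '%s' is unfittable: %s", labels[1], fit_a$reason),
         call. = FALSE)
  if (!fit_b$fittable)
    stop(sprintf("condition '%s' is unfittable: %s", labels[2], fit_b$reason),
         call. = FALSE)
  fit_1 <- fit_pf_joint(data_a, data_b, gamma, lambda, n_starts)

  ll2 <- fit_a$log_likelihood + fit_b$log_likelihood
  if (fit_1$log_likelihood > ll2 + 1e-9) {
    # 2PF optimum missed; retry with a denser start grid before failing
    fit_a <- fit_pf(data_a, gamma, lambda, n_starts * 3)
    fit_b <- fit_pf(data_b, gamma, lambda, n_starts * 3)
    ll2 <- fit_a$log_likelihood + fit_b$log_likelihood
  }
  ratio <- likelihood_ratio(fit_1$log_likelihood, ll2)

  run_boot <- function() {
    .lr_boot_cpp(data_a$intensity_pct, data_a$n_trials,
                 data_b$intensity_pct, data_b$n_trials,
                 fit_1$params$alpha, fit_1$params$beta,
                 gamma, lambda, ratio$lr,
                 as.integer(n_sims), as.integer(n_starts),
                 .ALPHA_BOUNDS[1], .ALPHA_BOUNDS[2],
                 .BETA_BOUNDS[1], .BETA_BOUNDS[2],
                 0.75, 3L)
  }
  boot <- if (is.null(seed)) run_boot() else withr::with_seed(seed, run_boot())
  if (boot$n_redraws > 0.01 * n_sims)
    warning(sprintf(
      "%d of %d bootstrap replicates had to be redrawn after failed refits",
      boot$n_redraws, n_sims), call. = FALSE)

  structure(list(
    labels = labels,
    fit_1pf = fit_1,
    fits_2pf = setNames(list(fit_a, fit_b), labels),
    lr = ratio$lr,
    tlr = ratio$tlr,
    n_sims = as.integer(n_sims),
    n_smaller = as.integer(boot$n_smaller),
    p_value = count_to_p(boot$n_smaller, n_sims),
    lr_sims = boot$lr_sims,
    n_redraws = as.integer(boot$n_redraws),
    seed = seed
  ), class = "pf_lr_test")
}

#' @export
print.pf_lr_test <- function(x, ...) {
  cat(sprintf("<pf_lr_test> %s vs %s (parametric bootstrap, %d simulations)\n",
              x$labels[1], x$labels[2], x$n_sims))
  thr <- vapply(x$fits_2pf, threshold_dilution, numeric(1))
  cat(sprintf("  thresholds: %s = %.1f%%, %s = %.1f%% dilution\n",
              x$labels[1], thr[1], x$labels[2], thr[2]))
  cat(sprintf("  likelihood ratio = %.4g (TLR = %.3f)\n", x$lr, x$tlr))
  p_txt <- if (x$n_smaller == 0) sprintf("p < %g", 1 / x$n_sims)
           else sprintf("p = %.4g", x$p_value)
  cat(sprintf("  %d of %d simulated ratios smaller than observed: %s\n",
              x$n_smaller, x$n_sims, p_txt))
  invisible(x)
}
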