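test_that("logistic function satisfies its closed form and symmetries", {
  # midpoint and the 75% point at alpha + ln(3)/beta
  for (p in list(c(0, 1), c(8, 0.3), c(-5, 2.5))) {
    expect_equal(logistic_fun(p[1], p[1], p[2]), 0.5)
    expect_equal(logistic_fun(p[1] + log(3) / p[2], p[1], p[2]), 0.75)
  }
  # closed-form oracle at x = 2, alpha = 0, beta = 1
  expect_equal(logistic_fun(2, 0, 1), 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(logistic_fun(2, 0, 1), 0.880797077977882, tolerance = 1e-12)

  # symmetry F(alpha + d) + F(alpha - d) = 1, and strict monotonicity
  set.seed(11)
  for (i in 1:20) {
    alpha <- runif(1, -20, 120)
    beta <- exp(runif(1, log(0.01), log(5)))
    d <- runif(5, 0, 40)
    expect_equal(logistic_fun(alpha + d, alpha, beta) +
                   logistic_fun(alpha - d, alpha, beta),
                 rep(1, 5), tolerance = 1e-12)
    xs <- sort(runif(10, -50, 150))
    expect_true(all(diff(logistic_fun(xs, alpha, beta)) >= 0))
    # strictly increasing wherever the double-precision range allows
    xs2 <- alpha + seq(-2, 2, by = 0.5) / beta
    expect_true(all(diff(logistic_fun(xs2, alpha, beta)) > 0))
  }
  expect_error(logistic_fun(1, 0, 0), "beta")
  expect_error(logistic_fun(1, 0, -1), "beta")
})

test_that("2IFC performance wrapper has the right asymptotes and midpoint", {
  p <- pf_params(alpha = 10, beta = 0.4, gamma = 0.5, lambda = 0)
  expect_equal(pf_performance(10, p), 0.75)          # 75% correct at threshold
  expect_equal(pf_performance(-1e4, p), 0.5, tolerance = 1e-12)  # guess floor
  pl <- pf_params(alpha = 10, beta = 0.4, gamma = 0.5, lambda = 0.02)
  expect_equal(pf_performance(1e4, pl), 0.98, tolerance = 1e-12) # 1 - lapse

  # monotone nondecreasing in intensity, nonincreasing in dilution
  set.seed(12)
  for (i in 1:10) {
    p <- pf_params(runif(1, 0, 50), exp(runif(1, log(.02), log(3))),
                   gamma = 0.5, lambda = runif(1, 0, 0.05))
    x <- seq(-20, 120, length.out = 80)
    expect_true(all(diff(pf_performance(x, p)) >= 0))
    expect_true(all(diff(pf_performance(100 - x, p)) <= 0))
  }

  expect_error(pf_params(1, 1, gamma = 0.6, lambda = 0.5), "gamma")
  expect_error(pf_params(1, -2), "beta")
})

test_that("negative log-likelihood matches hand computations and is additive", {
  # one level, 5/10 correct at psi exactly 0.5 (gamma 0, x at alpha)
  d1 <- binned_data(90, 10, 5)
  p1 <- pf_params(alpha = 10, beta = 0.7, gamma = 0, lambda = 0)
  expect_equal(pf_nll(d1, p1), 10 * log(2), tolerance = 1e-12)

  # one level, 10/10 correct at psi exactly 0.75 (2IFC, x at alpha)
  d2 <- binned_data(90, 10, 10)
  p2 <- pf_params(alpha = 10, beta = 0.7, gamma = 0.5, lambda = 0)
  expect_equal(pf_nll(d2, p2), -10 * log(0.75), tolerance = 1e-12)

  # additivity over disjoint level sets
  p <- pf_params(8, 0.3)
  da <- binned_data(c(68, 86, 94), c(50, 60, 70), c(49, 50, 44))
  db <- binned_data(c(80, 90, 98), c(40, 40, 40), c(37, 31, 22))
  dab <- binned_data(c(da$dilution_pct, db$dilution_pct),
                     c(da$n_trials, db$n_trials),
                     c(da$n_correct, db$n_correct))
  expect_equal(pf_nll(dab, p), pf_nll(da, p) + pf_nll(db, p),
               tolerance = 1e-12)

  # clamping keeps the value finite when a lapse-free function saturates
  dsat <- binned_data(2, 10, 9)
  psat <- pf_params(alpha = 2, beta = 10, gamma = 0.5, lambda = 0)
  expect_true(is.finite(pf_nll(dsat, psat)))
})

test_that("ML fit recovers generating parameters from expected counts", {
  for (truth in list(pf_params(8, 0.3), pf_params(14, 0.2),
                     pf_params(5, 0.8))) {
    lv <- levels_spanning(100 - truth$alpha, truth$beta)
    d <- exact_binned(truth, levels = lv)
    f <- fit_pf(d)
    expect_true(f$fittable)
    expect_equal(f$params$alpha, truth$alpha, tolerance = 1e-3)
    expect_equal(f$params$beta, truth$beta, tolerance = 1e-3)
    # reported log-likelihood is the exact binomial log-likelihood
    expect_equal(-f$log_likelihood, pf_nll(d, f$params), tolerance = 1e-9)
  }
})

test_that("fitting is invariant to the order of levels", {
  set.seed(21)
  truth <- pf_params(8, 0.3)
  psi <- pf_performance(100 - FIXED_LEVELS, truth)
  k <- rbinom(7, 240, psi)
  perm <- sample(7)
  f1 <- fit_pf(binned_data(FIXED_LEVELS, rep(240, 7), k))
  f2 <- fit_pf(binned_data(FIXED_LEVELS[perm], rep(240, 7)[perm], k[perm]))
  expect_identical(f1$params, f2$params)
  expect_identical(f1$log_likelihood, f2$log_likelihood)
})

test_that("degenerate data are declared unfittable, not errors", {
  flat <- binned_data(FIXED_LEVELS, rep(40, 7), rep(20, 7))
  f <- fit_pf(flat)
  expect_false(f$fittable)
  expect_match(f$reason, "criterion")
  expect_error(threshold_dilution(f), "unfittable")

  allcorrect <- binned_data(FIXED_LEVELS, rep(40, 7), rep(40, 7))
  expect_false(fit_pf(allcorrect)$fittable)
})

test_that("threshold extraction inverts the fitted function exactly", {
  # with gamma = 0.5, lambda = 0 the 75% threshold is 100 - alpha
  expect_equal(threshold_dilution(pf_params(14, 0.3)), 86)
  expect_equal(threshold_dilution(pf_params(8, 0.3)), 92)

  # round-trip: performance at the returned threshold equals the criterion
  set.seed(31)
  for (i in 1:10) {
    truth <- pf_params(runif(1, 4, 20), exp(runif(1, log(0.1), log(1))))
    d <- sim_binned(truth, levels = levels_spanning(100 - truth$alpha,
                                                    truth$beta))
    f <- fit_pf(d)
    if (!f$fittable) next
    for (crit in c(0.6, 0.75, 0.9)) {
      thr <- threshold_dilution(f, crit)
      expect_equal(pf_performance(100 - thr, f$params), crit,
                   tolerance = 1e-9)
    }
  }

  # unattainable criteria are refused
  expect_error(threshold_dilution(pf_params(8, 0.3, lambda = 0.02), 0.99),
               "unattainable")
  expect_error(threshold_dilution(pf_params(8, 0.3), 0.5), "unattainable")
})

test_that("no coarse-grid point attains a lower NLL than the optimizer", {
  set.seed(41)
  for (i in 1:5) {
    truth <- pf_params(runif(1, 5, 15), exp(runif(1, log(0.15), log(0.6))))
    d <- sim_binned(truth)
    f <- fit_pf(d)
    expect_true(f$fittable)
    width <- log(3) / f$params$beta
    alphas <- seq(f$params$alpha - 3 * width, f$params$alpha + 3 * width,
                  length.out = 201)
    betas <- exp(seq(log(f$params$beta / 4), log(4 * f$params$beta),
                     length.out = 201))
    grid_min <- min(vapply(betas, function(b)
      min(vapply(alphas, grid_nll, numeric(1), beta = b, data = d)),
      numeric(1)))
    expect_gte(grid_min, -f$log_likelihood - 1e-6)
  }
})

test_that("bootstrap intervals cover the generating threshold", {
  truth <- pf_params(8, 0.3) # true threshold 92% dilution
  psi <- pf_performance(100 - FIXED_LEVELS, truth)
  set.seed(51)
  covered <- 0
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    d <- binned_data(FIXED_LEVELS, rep(240, 7), rbinom(7, 240, psi))
    f <- fit_pf(d)
    expect_true(f$fittable)
    ci <- pf_bootstrap(f, n_boot = 120, seed = 7000 + i)$threshold_ci
    if (ci[1] <= 92 && 92 <= ci[2]) covered <- covered + 1
  }
  expect_gte(covered / n_rep, 0.90)
})
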