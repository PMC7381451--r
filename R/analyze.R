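#' Bin trial records into per-unit count data
#'
#' Aggregates trial-level records into [binned_data()] objects, one per
#' combination of the grouping keys. The counts partition the input exactly:
#' summing `n_trials` over all groups recovers the number of input rows.
#'
#' @param trials A trial tibble (see [read_trials()] for the dialect).
#' @param by Grouping columns, any subset of participant / session /
#'   condition / face / metadata columns.
#' @return A tibble with the `by` columns plus a list-column `data` of
#'   `binned_data` objects. Empty input gives an empty tibble.
#' @examples
#' trials <- make_synthetic_study("exp1", seed = 1)
#' bin_trials(trials, by = c("participant_id", "condition"))
#' @export
bin_trials <- function(trials, by = c("participant_id", "condition")) {
  stopifnot(is.data.frame(trials))
  need <- unique(c(by, "dilution_pct", "correct"))
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0)
    stop("trials are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(trials) == 0) {
    out <- tibble::as_tibble(setNames(rep(list(character(0)), length(by)), by))
    out$data <- list()
    return(out)
  }
  meta_cols <- intersect(c("duration_ms", "image_size_deg", "software"),
                         setdiff(names(trials), by))
  agg <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "dilution_pct")))) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     n_correct = sum(.data$correct), .groups = "drop")
  if (length(meta_cols) > 0) {
    mixed <- trials |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(meta_cols),
                                     dplyr::n_distinct), .groups = "drop")
    if (any(as.matrix(mixed[, meta_cols]) > 1))
      warning("some groups mix multiple values of ",
              paste(meta_cols, collapse = "/"),
              "; consider adding them to `by`", call. = FALSE)
  }
  agg |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      data = list(binned_data(.data$dilution_pct, .data$n_trials,
                              .data$n_correct)),
      .groups = "drop")
}

.binned_for <- function(binned_tbl, ...) {
  sel <- rep(TRUE, nrow(binned_tbl))
  keys <- list(...)
  for (nm in names(keys)) sel <- sel & binned_tbl[[nm]] == keys[[nm]]
  if (sum(sel) != 1) return(NULL)
  binned_tbl$data[[which(sel)]]
}

#' Analyze one participant's sessions
#'
#' Runs the full within-observer analysis for a single participant: one
#' psychometric fit per condition (pooling faces and sessions), threshold
#' extraction at the 75% criterion, the parametric-bootstrap comparison
#' between the two analysis conditions, an optional test-retest comparison
#' per condition when exactly two sessions are present, and optional
#' per-face fits. Units that cannot be fit are flagged with a reason rather
#' than failing the analysis.
#'
#' @param trials Trial records for exactly one participant.
#' @param conditions Length-2 character vector naming the conditions to
#'   compare; defaults to the first two conditions present.
#' @param n_sims Bootstrap simulations per comparison.
#' @param seed Optional integer seed; sub-seeds for each comparison are
#'   derived from it.
#' @param gamma,lambda Fixed guess and lapse rates.
#' @param per_face If `TRUE`, also fit each condition x unique face, when at
#'   least 40 trials per level per face are available.
#' @return A `participant_report`: `fits`, `thresholds`, `comparison`
#'   (a [pf_lr_test()] or `NULL`), `retest` (list by condition or `NULL`),
#'   `face_fits` (optional tibble), `unfittable` (tibble of unit/reason).
#' @export
analyze_participant <- function(trials, conditions = NULL, n_sims = 10000,
                                seed = NULL, gamma = 0.5, lambda = 0,
                                per_face = FALSE) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0)
  pid <- unique(trials$participant_id)
  if (length(pid) != 1)
    stop("`trials` must contain exactly one participant", call. = FALSE)
  present <- unique(trials$condition)
  if (length(present) < 2)
    stop("at least two conditions are required", call. = FALSE)
  if (is.null(conditions)) conditions <- present[1:2]
  stopifnot(length(conditions) == 2, all(conditions %in% present))

  sub_seed <- function(key) if (is.null(seed)) NULL else .derive_seed(seed, key)
  unfittable <- list()
  note_unfittable <- function(unit, reason) {
    unfittable[[length(unfittable) + 1]] <<-
      tibble::tibble(unit = unit, reason = reason)
  }

  binned <- bin_trials(trials, by = "condition")
  fits <- list()
  for (cond in present) {
    f <- fit_pf(.binned_for(binned, condition = cond), gamma, lambda)
    fits[[cond]] <- f
    if (!f$fittable) note_unfittable(paste0("condition ", cond), f$reason)
  }
  thresholds <- tibble::tibble(
    condition = present,
    fittable = vapply(fits[present], function(f) f$fittable, logical(1)),
    threshold = vapply(fits[present], function(f)
      if (f$fittable) threshold_dilution(f) else NA_real_, numeric(1))
  )

  comparison <- NULL
  if (fits[[conditions[1]]]$fittable && fits[[conditions[2]]]$fittable) {
    comparison <- pf_lr_test(
      .binned_for(binned, condition = conditions[1]),
      .binned_for(binned, condition = conditions[2]),
      labels = conditions, n_sims = n_sims,
      seed = sub_seed(paste("cmp", conditions[1], conditions[2])),
      gamma = gamma, lambda = lambda)
  } else {
    note_unfittable(paste("comparison", conditions[1], "vs", conditions[2]),
                    "skipped: a condition is unfittable")
  }

  retest <- NULL
  sessions <- unique(trials$session_id)
  if (length(sessions) == 2) {
    retest <- list()
    by_sess <- bin_trials(trials, by = c("condition", "session_id"))
    for (cond in conditions) {
      d1 <- .binned_for(by_sess, condition = cond, session_id = sessions[1])
      d2 <- .binned_for(by_sess, condition = cond, session_id = sessions[2])
      ok <- !is.null(d1) && !is.null(d2) &&
        fit_pf(d1, gamma, lambda)$fittable && fit_pf(d2, gamma, lambda)$fittable
      if (ok) {
        retest[[cond]] <- pf_lr_test(
          d1, d2, labels = as.character(sessions), n_sims = n_sims,
          seed = sub_seed(paste("retest", cond)),
          gamma = gamma, lambda = lambda)
      } else {
        note_unfittable(paste("retest", cond),
                        "skipped: a session is unfittable")
      }
    }
  }

  face_fits <- NULL
  if (isTRUE(per_face)) {
    by_face <- bin_trials(trials, by = c("condition", "face_id"))
    enough <- all(vapply(by_face$data, function(d) min(d$n_trials) >= 40,
                         logical(1)))
    if (!enough) {
      note_unfittable("per-face analysis",
                      "skipped: fewer than 40 trials per level per face")
    } else {
      rows <- lapply(seq_len(nrow(by_face)), function(i) {
        f <- fit_pf(by_face$data[[i]], gamma, lambda)
        if (!f$fittable)
          note_unfittable(paste0("face ", by_face$face_id[i], " (",
                                 by_face$condition[i], ")"), f$reason)
        tibble::tibble(
          condition = by_face$condition[i], face_id = by_face$face_id[i],
          fittable = f$fittable,
          threshold = if (f$fittable) threshold_dilution(f) else NA_real_,
          beta = f$params$beta, fit = list(f))
      })
      face_fits <- dplyr::bind_rows(rows)
    }
  }

  structure(list(
    participant_id = pid,
    conditions = conditions,
    fits = fits,
    thresholds = thresholds,
    comparison = comparison,
    retest = retest,
    face_fits = face_fits,
    unfittable = if (length(unfittable) > 0) dplyr::bind_rows(unfittable)
                 else tibble::tibble(unit = character(0), reason = character(0))
  ), class = "participant_report")
}

#' @export
print.participant_report <- function(x, ...) {
  cat(sprintf("<participant_report> %s\n", x$participant_id))
  for (i in seq_len(nrow(x$thresholds))) {
    if (x$thresholds$fittable[i])
      cat(sprintf("  %s: threshold %.1f%% dilution\n",
                  x$thresholds$condition[i], x$thresholds$threshold[i]))
    else
      cat(sprintf("  %s: unfittable\n", x$thresholds$condition[i]))
  }
  if (!is.null(x$comparison)) {
    p <- x$comparison$p_value
    cat(sprintf("  %s vs %s: p %s\n", x$conditions[1], x$conditions[2],
                if (x$comparison$n_smaller == 0)
                  sprintf("< %g", 1 / x$comparison$n_sims)
                else sprintf("= %.4g", p)))
  }
  if (nrow(x$unfittable) > 0)
    cat(sprintf("  notes: %s\n",
                paste(x$unfittable$unit, x$unfittable$reason, sep = " - ",
                      collapse = "; ")))
  invisible(x)
}

#' Group performance curve at fixed dilutions
#'
#' Evaluates each participant's fitted performance function at a fixed set
#' of dilutions and averages the predicted percent correct across
#' participants -- the across-observer summary that makes differently
#' tailored per-participant dilution sets comparable.
#'
#' @param fits List of fittable `pf_fit` objects, one per participant.
#' @param dilutions Fixed dilution set; defaults to
#'   68, 80, 86, 90, 94, 96, 98.
#' @return A tibble with `dilution_pct`, `mean_pct`, `sem_pct`, `n`.
#' @export
group_curve <- function(fits, dilutions = c(68, 80, 86, 90, 94, 96, 98)) {
  fits <- Filter(function(f) inherits(f, "pf_fit") && f$fittable, fits)
  if (length(fits) < 1)
    stop("at least one fittable fit is required", call. = FALSE)
  pred <- vapply(fits, function(f)
    100 * pf_performance(.intensity(dilutions), f$params),
    numeric(length(dilutions)))
  pred <- matrix(pred, nrow = length(dilutions))
  n <- ncol(pred)
  tibble::tibble(
    dilution_pct = dilutions,
    mean_pct = rowMeans(pred),
    sem_pct = if (n > 1) apply(pred, 1, sd) / sqrt(n) else rep(0, length(dilutions)),
    n = n
  )
}

#' Effect size r from a t statistic
#'
#' \eqn{r = \sqrt{t^2 / (t^2 + df)}}, the point-biserial effect size of a
#' paired t test.
#'
#' @param t t statistic.
#' @param df Degrees of freedom.
#' @return Effect size in \[0, 1\].
#' @examples
#' round(r_from_t(5.06, 10), 2) # 0.85
#' @export
r_from_t <- function(t, df) sqrt(t^2 / (t^2 + df))

#' Paired comparison of per-participant thresholds
#'
#' Two-sided paired-samples t test on per-participant dilution thresholds
#' from two conditions, with the effect size
#' \eqn{r = \sqrt{t^2/(t^2 + df)}}.
#'
#' @param thresholds_a,thresholds_b Equal-length paired numeric vectors
#'   (dilution percent), `n >= 2`, no missing values.
#' @return A list with `t`, `df`, `p_value`, `r`, `mean_diff`.
#' @examples
#' paired_threshold_test(c(92, 93, 91), c(86, 88, 85))
#' @export
paired_threshold_test <- function(thresholds_a, thresholds_b) {
  if (length(thresholds_a) != length(thresholds_b))
    stop("threshold vectors must be paired (equal length)", call. = FALSE)
  if (length(thresholds_a) < 2)
    stop("at least two pairs are required", call. = FALSE)
  if (anyNA(thresholds_a) || anyNA(thresholds_b))
    stop("thresholds must not contain missing values", call. = FALSE)
  d <- thresholds_a - thresholds_b
  if (sd(d) == 0 && mean(d) == 0) {
    n <- length(d)
    return(list(t = 0, df = n - 1, p_value = 1, r = 0, mean_diff = 0))
  }
  tt <- t.test(thresholds_a, thresholds_b, paired = TRUE)
  t <- unname(tt$statistic)
  df <- unname(tt$parameter)
  list(t = t, df = df, p_value = tt$p.value, r = r_from_t(t, df),
       mean_diff = unname(tt$estimate))
}

#' Analyze a whole study
#'
#' Per-participant analyses plus the group summary: mean and SEM of the
#' dilution thresholds by condition, the group performance curve at a fixed
#' dilution set, and the paired t test (with effect size r) between the two
#' analysis conditions. Group statistics use only participants whose fits
#' are fittable in both conditions; excluded participants are enumerated
#' with reasons.
#'
#' @inheritParams analyze_participant
#' @param trials Trial records for one or more participants.
#' @param dilutions Fixed dilution set for the group curve.
#' @return A `group_report`: `participants` (list of
#'   [analyze_participant()] reports), `thresholds` (participant x condition
#'   tibble), `group_stats`, `group_curves`, `paired_test`, `excluded`.
#' @examples
#' \donttest{
#' trials <- make_synthetic_study("exp1", seed = 1)
#' rep <- analyze_study(trials, n_sims = 200, seed = 1)
#' rep$group_stats
#' }
#' @export
analyze_study <- function(trials, conditions = NULL, n_sims = 10000,
                          seed = NULL, gamma = 0.5, lambda = 0,
                          per_face = FALSE,
                          dilutions = c(68, 80, 86, 90, 94, 96, 98)) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0)
  pids <- unique(trials$participant_id)
  reports <- lapply(pids, function(pid) {
    analyze_participant(trials[trials$participant_id == pid, , drop = FALSE],
                        conditions = conditions, n_sims = n_sims,
                        seed = if (is.null(seed)) NULL
                               else .derive_seed(seed, pid),
                        gamma = gamma, lambda = lambda, per_face = per_face)
  })
  names(reports) <- pids
  conditions <- reports[[1]]$conditions

  thr <- dplyr::bind_rows(lapply(reports, function(r)
    dplyr::mutate(r$thresholds, participant_id = r$participant_id)))
  thr <- thr[thr$condition %in% conditions, ]

  ok_both <- vapply(pids, function(pid) {
    rows <- thr[thr$participant_id == pid, ]
    all(rows$fittable)
  }, logical(1))
  complete <- pids[ok_both]
  excluded <- tibble::tibble(
    participant_id = pids[!ok_both],
    reason = "unfittable fit in at least one condition")

  thr_c <- thr[thr$participant_id %in% complete, ]
  group_stats <- thr_c |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_threshold = mean(.data$threshold),
                     sem_threshold = sd(.data$threshold) / sqrt(dplyr::n()),
                     .groups = "drop")

  group_curves <- lapply(setNames(conditions, conditions), function(cond) {
    fits <- lapply(reports[complete], function(r) r$fits[[cond]])
    group_curve(fits, dilutions)
  })

  paired_test <- NULL
  if (length(complete) >= 2) {
    a <- thr_c$threshold[thr_c$condition == conditions[1]][
      match(complete, thr_c$participant_id[thr_c$condition == conditions[1]])]
    b <- thr_c$threshold[thr_c$condition == conditions[2]][
      match(complete, thr_c$participant_id[thr_c$condition == conditions[2]])]
    paired_test <- paired_threshold_test(a, b)
  }

  structure(list(
    conditions = conditions,
    participants = reports,
    thresholds = thr,
    group_stats = group_stats,
    group_curves = group_curves,
    paired_test = paired_test,
    excluded = excluded
  ), class = "group_report")
}

#' @export
print.group_report <- function(x, ...) {
  cat(sprintf("<group_report> %d participants, conditions %s vs %s\n",
              length(x$participants), x$conditions[1], x$conditions[2]))
  for (i in seq_len(nrow(x$group_stats))) {
    g <- x$group_stats[i, ]
    cat(sprintf("  %s: mean threshold %.1f%% dilution (SEM %.2f, n = %d)\n",
                g$condition, g$mean_threshold, g$sem_threshold, g$n))
  }
  if (!is.null(x$paired_test)) {
    pt <- x$paired_test
    cat(sprintf("  paired t(%d) = %.2f, p = %.3g, r = %.2f\n",
                as.integer(pt$df), pt$t, pt$p_value, pt$r))
  }
  n_sig <- sum(vapply(x$participants, function(r)
    !is.null(r$comparison) && r$comparison$p_value < 0.05, logical(1)))
  cat(sprintf("  individual comparisons significant at .05: %d of %d\n",
              n_sig, length(x$participants)))
  if (nrow(x$excluded) > 0)
    cat(sprintf("  excluded: %s\n",
                paste(x$excluded$participant_id, collapse = ", ")))
  invisible(x)
}
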