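#' Method-of-constant-stimuli schedule specification
#'
#' Describes one condition's trial schedule: which dilution levels are
#' presented, for which unique faces, and how often. Trials are organised as
#' complete shuffled passes over the level x face set, so every member of
#' the set is presented n times before any member is presented n + 1 times.
#' The test (expressive) stimulus appears in the first interval with
#' probability 0.5, fixed by the 2IFC design.
#'
#' @param dilution_levels Distinct dilution percentages; default is the
#'   fixed seven-level group-curve set.
#' @param face_ids Unique-face labels; default three female (FF1-FF3) and
#'   three male (MF1-MF3) identities.
#' @param repeats_per_face Complete passes; 40 gives 240 observations per
#'   level with six faces.
#' @param condition Emotion label attached to every trial.
#' @param metadata Named list of condition metadata carried onto trials
#'   (e.g. `duration_ms`, `image_size_deg`, `software`).
#' @return A `schedule_spec` object.
#' @examples
#' schedule_spec(condition = "happy")
#' @export
schedule_spec <- function(dilution_levels = c(68, 80, 86, 90, 94, 96, 98),
                          face_ids = c("FF1", "FF2", "FF3", "MF1", "MF2", "MF3"),
                          repeats_per_face = 40,
                          condition = "happy",
                          metadata = list(duration_ms = 200,
                                          image_size_deg = "19x27",
                                          software = "norrkross")) {
  if (length(dilution_levels) < 1 || length(face_ids) < 1)
    stop("`dilution_levels` and `face_ids` must be non-empty", call. = FALSE)
  if (any(dilution_levels < 0 | dilution_levels > 100))
    stop("`dilution_levels` must lie in [0, 100]", call. = FALSE)
  if (anyDuplicated(dilution_levels))
    stop("`dilution_levels` must be distinct", call. = FALSE)
  if (repeats_per_face < 1)
    stop("`repeats_per_face` must be >= 1", call. = FALSE)
  structure(list(
    dilution_levels = sort(dilution_levels),
    face_ids = as.character(face_ids),
    repeats_per_face = as.integer(repeats_per_face),
    condition = as.character(condition),
    test_first_prob = 0.5,
    metadata = metadata
  ), class = "schedule_spec")
}

#' Generate a randomized trial schedule
#'
#' Expands a [schedule_spec()] into an ordered list of trial slots:
#' `repeats_per_face` complete shuffled passes over the level x face set,
#' each slot assigned a test interval by an independent fair coin.
#'
#' @param spec A [schedule_spec()].
#' @param seed Optional integer seed; the schedule is deterministic given
#'   the seed and does not disturb the global RNG.
#' @return A tibble with columns `trial`, `pass`, `face_id`, `dilution_pct`,
#'   `intensity_pct`, `condition`, `test_interval`, plus metadata columns.
#' @examples
#' sched <- generate_schedule(schedule_spec(), seed = 1)
#' nrow(sched) # 7 levels x 6 faces x 40 repeats = 1680
#' @export
generate_schedule <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "schedule_spec"))
  build <- function() {
    set <- expand.grid(face_id = spec$face_ids,
                       dilution_pct = spec$dilution_levels,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    m <- nrow(set)
    passes <- lapply(seq_len(spec$repeats_per_face), function(p) {
      s <- set[sample.int(m), , drop = FALSE]
      s$pass <- p
      s
    })
    out <- dplyr::bind_rows(passes)
    out$trial <- seq_len(nrow(out))
    out$intensity_pct <- .intensity(out$dilution_pct)
    out$condition <- spec$condition
    out$test_interval <- ifelse(runif(nrow(out)) < spec$test_first_prob, 1L, 2L)
    out <- tibble::as_tibble(out)[, c("trial", "pass", "face_id",
                                      "dilution_pct", "intensity_pct",
                                      "condition", "test_interval")]
    for (nm in names(spec$metadata)) out[[nm]] <- spec$metadata[[nm]]
    out
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Synthetic-observer specification
#'
#' The generating truth for simulation: one set of psychometric parameters
#' per condition, optional per-face threshold offsets (dilution points,
#' centred on zero so faces average out to the condition threshold), and an
#' optional session shift applied per additional session (dilution points;
#' 0 models a stable observer).
#'
#' @param params Named list of [pf_params()] (intensity-space parameters),
#'   one entry per condition label.
#' @param face_offsets Optional named numeric vector of per-face threshold
#'   offsets in dilution points; re-centred to sum to zero.
#' @param session_shift Threshold shift (dilution points) per additional
#'   session; session s uses `threshold + (s - 1) * session_shift`.
#' @return An `observer_spec` object.
#' @examples
#' observer_spec(list(happy = pf_params(8, 0.3), fear = pf_params(14, 0.3)))
#' @export
observer_spec <- function(params, face_offsets = NULL, session_shift = 0) {
  if (!is.list(params) || is.null(names(params)) || any(names(params) == ""))
    stop("`params` must be a named list of pf_params, one per condition",
         call. = FALSE)
  for (nm in names(params)) {
    if (!inherits(params[[nm]], "pf_params"))
      stop(sprintf("`params$%s` is not a pf_params object", nm), call. = FALSE)
  }
  if (!is.null(face_offsets)) {
    if (is.null(names(face_offsets)))
      stop("`face_offsets` must be named by face_id", call. = FALSE)
    face_offsets <- face_offsets - mean(face_offsets)
  }
  structure(list(params = params, face_offsets = face_offsets,
                 session_shift = session_shift),
            class = "observer_spec")
}

# Generating parameters for one trial: per-face offset and session shift act
# on the threshold (dilution scale), slopes are shared.
.trial_params <- function(observer, condition, face_id, session_index) {
  base <- observer$params[[condition]]
  if (is.null(base))
    stop(sprintf("observer has no parameters for condition '%s'", condition),
         call. = FALSE)
  shift_dil <- 0
  if (!is.null(observer$face_offsets) && face_id %in% names(observer$face_offsets))
    shift_dil <- shift_dil + observer$face_offsets[[face_id]]
  shift_dil <- shift_dil + (session_index - 1) * observer$session_shift
  # +shift on the dilution threshold is -shift on intensity alpha
  pf_params(base$alpha - shift_dil, base$beta, base$gamma, base$lambda)
}

#' Simulate a synthetic observer on a schedule
#'
#' Draws one Bernoulli response per schedule slot: the trial is correct with
#' probability \eqn{\psi(} intensity \eqn{)} under the observer's (per-face
#' adjusted) performance function, and the reported interval is the test
#' interval when correct, the other interval otherwise. At 100% dilution the
#' test stimulus is identical to the neutral comparison, so the success
#' probability is exactly the guess rate regardless of the other parameters.
#'
#' @param schedule A tibble from [generate_schedule()].
#' @param observer An [observer_spec()] with parameters for the schedule's
#'   condition.
#' @param participant_id,session_id Identifiers stamped on every trial.
#' @param session_index 1-based session number used for the session shift.
#' @param seed Optional integer seed.
#' @return A trial-record tibble: `participant_id`, `session_id`,
#'   `condition`, `face_id`, `dilution_pct`, `test_interval`,
#'   `response_interval`, `correct`, plus metadata columns.
#' @examples
#' obs <- observer_spec(list(happy = pf_params(8, 0.3)))
#' trials <- simulate_observer(generate_schedule(schedule_spec(), seed = 1),
#'                             obs, seed = 2)
#' mean(trials$correct)
#' @export
simulate_observer <- function(schedule, observer, participant_id = "P01",
                              session_id = "S1", session_index = 1,
                              seed = NULL) {
  stopifnot(inherits(observer, "observer_spec"), is.data.frame(schedule))
  condition <- schedule$condition[1]
  run <- function() {
    psi <- numeric(nrow(schedule))
    combos <- unique(schedule[, c("condition", "face_id")])
    for (j in seq_len(nrow(combos))) {
      p <- .trial_params(observer, combos$condition[j], combos$face_id[j],
                         session_index)
      idx <- schedule$condition == combos$condition[j] &
        schedule$face_id == combos$face_id[j]
      psi[idx] <- pf_performance(schedule$intensity_pct[idx], p)
      # at 100% dilution the test equals the comparison stimulus: the trial
      # carries no information and the response is a pure guess
      psi[idx & schedule$intensity_pct <= 0] <- p$gamma
    }
    correct <- runif(nrow(schedule)) < psi
    out <- tibble::tibble(
      participant_id = participant_id,
      session_id = as.character(session_id),
      condition = schedule$condition,
      face_id = schedule$face_id,
      dilution_pct = schedule$dilution_pct,
      test_interval = schedule$test_interval,
      response_interval = ifelse(correct, schedule$test_interval,
                                 3L - schedule$test_interval),
      correct = correct
    )
    meta_cols <- setdiff(names(schedule),
                         c("trial", "pass", "face_id", "dilution_pct",
                           "intensity_pct", "condition", "test_interval"))
    for (nm in meta_cols) out[[nm]] <- schedule[[nm]]
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Pick presented levels spanning a threshold
#'
#' Chooses seven dilution levels from a morphing ladder so that expected
#' 2IFC performance spans roughly 57% to 99% correct around a known (or
#' anticipated) threshold -- the way per-participant dilution sets were
#' tailored to each observer. Offsets are expressed in intensity units and
#' scaled inversely with the slope, then snapped to the ladder grid.
#'
#' @param threshold Anticipated 75%-correct threshold, dilution percent.
#' @param beta Anticipated slope (per percent intensity).
#' @param ladder Ladder name passed to [dilution_ladder()].
#' @return Seven distinct dilution levels, sorted increasing.
#' @examples
#' levels_spanning(92) # a 7-level set bracketing 92% dilution
#' @export
levels_spanning <- function(threshold, beta = 0.3, ladder = "norrkross") {
  grid <- dilution_ladder(ladder)
  alpha_int <- .intensity(threshold)
  offsets <- c(-6, -4, -2, 0, 3, 6, 12) * (0.3 / beta)
  want <- .dilution(alpha_int + offsets)
  picked <- integer(0)
  for (w in sort(want, decreasing = TRUE)) {
    i <- which.min(abs(grid - w))
    # resolve collisions by stepping to the nearest free grid point below
    while (i %in% picked && i > 1) i <- i - 1
    if (!(i %in% picked)) picked <- c(picked, i)
  }
  lv <- sort(grid[picked])
  if (length(lv) < 7)
    stop("could not place 7 distinct levels on the ladder", call. = FALSE)
  lv
}
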