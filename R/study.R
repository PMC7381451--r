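#' Built-in synthetic-study presets
#'
#' Ready-made configurations for [make_synthetic_study()] emulating the
#' designs the analysis pipeline is meant for. All presets share the 2IFC
#' method-of-constant-stimuli core: 7 dilution levels per condition snapped
#' to a morphing ladder and tailored to each observer's true threshold, 6
#' unique faces, 40 repeats per face (240 observations per level), guess
#' rate 0.5, lapse rate 0, slope 0.3 per percent intensity.
#'
#' * `"exp1"`: 11 participants, happy and fear, true thresholds drawn from
#'   Normal(92, 0.57 * sqrt(11)) and Normal(86, 1.23 * sqrt(11)) dilution
#'   percent (between-subject SD recovered from the group standard errors).
#' * `"retest"`: 3 participants tested in two identical sessions (no true
#'   session effect).
#' * `"faces"`: 6 participants with per-face threshold offsets
#'   (SD 2 dilution points, centred) producing face-level variability.
#' * `"durations"`: 3 participants, the whole design repeated at stimulus
#'   durations 8, 83 and 200 ms (metadata only; same generating truth).
#' * `"sizes"`: 3 participants, repeated at image sizes 19x27, 5x7 and
#'   2.5x3.5 degrees.
#'
#' @param name Preset name.
#' @return A configuration list accepted by [make_synthetic_study()].
#' @examples
#' str(study_preset("exp1"), max.level = 1)
#' @export
study_preset <- function(name = c("exp1", "retest", "faces", "durations",
                                  "sizes")) {
  name <- match.arg(name)
  base <- list(
    name = name,
    participants = sprintf("P%02d", 1:11),
    sessions = 1L,
    conditions = list(
      happy = list(threshold_mean = 92, threshold_sd = 0.57 * sqrt(11),
                   beta = 0.3, gamma = 0.5, lambda = 0),
      fear = list(threshold_mean = 86, threshold_sd = 1.23 * sqrt(11),
                  beta = 0.3, gamma = 0.5, lambda = 0)
    ),
    schedule = list(levels = "span", ladder = "norrkross",
                    face_ids = c("FF1", "FF2", "FF3", "MF1", "MF2", "MF3"),
                    repeats_per_face = 40L),
    face_offset_sd = 0,
    session_shift = 0,
    metadata = list(duration_ms = 200, image_size_deg = "19x27",
                    software = "norrkross"),
    variants = NULL
  )
  switch(name,
    exp1 = base,
    retest = modifyList(base, list(participants = sprintf("P%02d", 1:3),
                                   sessions = 2L)),
    faces = modifyList(base, list(participants = sprintf("P%02d", 1:6),
                                  face_offset_sd = 2)),
    durations = modifyList(base, list(
      participants = sprintf("P%02d", 1:3),
      variants = list(duration_ms = c(8, 83, 200)))),
    sizes = modifyList(base, list(
      participants = sprintf("P%02d", 1:3),
      variants = list(image_size_deg = c("19x27", "5x7", "2.5x3.5"))))
  )
}

.validate_study_config <- function(config) {
  need <- function(cond, path) {
    if (!cond) stop("invalid study config at `", path, "`", call. = FALSE)
  }
  need(is.list(config), "")
  need(length(config$participants) >= 1, "participants")
  need(is.numeric(config$sessions) && config$sessions >= 1, "sessions")
  need(is.list(config$conditions) && length(config$conditions) >= 1 &&
         !is.null(names(config$conditions)), "conditions")
  for (nm in names(config$conditions)) {
    cc <- config$conditions[[nm]]
    p <- paste0("conditions.", nm)
    need(is.list(cc), p)
    need(is.numeric(cc$threshold_mean) &&
           cc$threshold_mean > 0 && cc$threshold_mean < 100,
         paste0(p, ".threshold_mean"))
    need(is.numeric(cc$threshold_sd) && cc$threshold_sd >= 0,
         paste0(p, ".threshold_sd"))
    need(is.numeric(cc$beta) && cc$beta > 0, paste0(p, ".beta"))
  }
  sc <- config$schedule
  need(is.list(sc), "schedule")
  need(identical(sc$levels, "span") ||
         (is.numeric(sc$levels) && length(sc$levels) >= 1), "schedule.levels")
  need(length(sc$face_ids) >= 1, "schedule.face_ids")
  need(is.numeric(sc$repeats_per_face) && sc$repeats_per_face >= 1,
       "schedule.repeats_per_face")
  if (!is.null(config$variants)) {
    need(is.list(config$variants) && length(config$variants) == 1 &&
           !is.null(names(config$variants)), "variants")
  }
  invisible(config)
}

#' Generate a complete synthetic study
#'
#' Draws generating truths and simulates every participant x session x
#' condition (x metadata variant) cell of a study design, producing a
#' trial-level table ready for [analyze_study()] or [write_trials()].
#' Per-unit RNG streams are derived deterministically from `seed` and the
#' cell's identifiers, so adding participants or conditions never perturbs
#' the trials of existing ones, and the whole table is bit-reproducible.
#'
#' @param config A preset name (see [study_preset()]) or a configuration
#'   list of the same shape.
#' @param seed Integer seed for the whole study.
#' @return A trial tibble (the [read_trials()] dialect). The generating
#'   truth is attached as `attr(x, "truth")`: one row per participant x
#'   condition with the true threshold, slope, guess and lapse rates.
#' @examples
#' trials <- make_synthetic_study("exp1", seed = 7)
#' dplyr::count(trials, condition)
#' @export
make_synthetic_study <- function(config = "exp1", seed = 1) {
  if (is.character(config)) config <- study_preset(config)
  .validate_study_config(config)
  stopifnot(is.numeric(seed), length(seed) == 1)

  conds <- names(config$conditions)
  variants <- config$variants
  variant_vals <- if (is.null(variants)) list(NULL) else
    as.list(variants[[1]])
  variant_key <- if (is.null(variants)) "" else names(variants)

  truth <- list()
  blocks <- list()
  for (pid in config$participants) {
    # per-participant generating truth, one stream per participant x condition
    obs_params <- list()
    levels_by_cond <- list()
    for (cond in conds) {
      cc <- config$conditions[[cond]]
      thr <- withr::with_seed(
        .derive_seed(seed, paste("truth", pid, cond)),
        rnorm(1, cc$threshold_mean, cc$threshold_sd))
      thr <- min(max(thr, 5), 99)
      gamma <- if (is.null(cc$gamma)) 0.5 else cc$gamma
      lambda <- if (is.null(cc$lambda)) 0 else cc$lambda
      obs_params[[cond]] <- pf_params(.intensity(thr), cc$beta, gamma, lambda)
      levels_by_cond[[cond]] <-
        if (identical(config$schedule$levels, "span"))
          levels_spanning(thr, cc$beta, config$schedule$ladder)
        else config$schedule$levels
      truth[[paste(pid, cond)]] <- tibble::tibble(
        participant_id = pid, condition = cond, threshold_true = thr,
        beta = cc$beta, gamma = gamma, lambda = lambda)
    }
    face_offsets <- NULL
    if (config$face_offset_sd > 0) {
      off <- withr::with_seed(
        .derive_seed(seed, paste("faces", pid)),
        rnorm(length(config$schedule$face_ids), 0, config$face_offset_sd))
      face_offsets <- setNames(off, config$schedule$face_ids)
    }
    observer <- observer_spec(obs_params, face_offsets,
                              session_shift = config$session_shift)

    for (s in seq_len(config$sessions)) {
      for (cond in conds) {
        for (vv in variant_vals) {
          meta <- config$metadata
          vlab <- ""
          if (!is.null(vv)) {
            meta[[variant_key]] <- vv
            vlab <- paste0(variant_key, "=", vv)
          }
          spec <- schedule_spec(
            dilution_levels = levels_by_cond[[cond]],
            face_ids = config$schedule$face_ids,
            repeats_per_face = config$schedule$repeats_per_face,
            condition = cond, metadata = meta)
          key <- paste(pid, s, cond, vlab)
          sched <- generate_schedule(spec,
                                     seed = .derive_seed(seed, paste("sched", key)))
          blocks[[key]] <- simulate_observer(
            sched, observer, participant_id = pid,
            session_id = paste0("S", s), session_index = s,
            seed = .derive_seed(seed, paste("resp", key)))
        }
      }
    }
  }
  out <- dplyr::bind_rows(blocks)
  attr(out, "truth") <- dplyr::bind_rows(truth)
  out
}
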