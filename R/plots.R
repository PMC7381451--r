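# Auxiliary figures (ggplot2 is suggested, not required).

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("install ggplot2 to use the plotting helpers", call. = FALSE)
}

#' Plot the group performance curve
#'
#' Mean predicted percent correct (with SEM bars) at the fixed dilution set,
#' one line per condition, mirrored so performance falls as dilution grows.
#'
#' @param report A `group_report` from [analyze_study()].
#' @return A ggplot object.
#' @export
plot_group_curve <- function(report) {
  .need_ggplot()
  stopifnot(inherits(report, "group_report"))
  curves <- dplyr::bind_rows(lapply(names(report$group_curves), function(cn)
    dplyr::mutate(report$group_curves[[cn]], condition = cn)))
  ggplot2::ggplot(curves, ggplot2::aes(.data$dilution_pct, .data$mean_pct,
                                       colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_pct - .data$sem_pct,
      ymax = .data$mean_pct + .data$sem_pct)) +
    ggplot2::geom_hline(yintercept = 75, linetype = "dotted") +
    ggplot2::labs(x = "Stimulus dilution (%)", y = "Correct (%)",
                  colour = NULL) +
    ggplot2::coord_cartesian(ylim = c(50, 100)) +
    ggplot2::theme_minimal()
}

#' Scatter of per-participant thresholds for two conditions
#'
#' One point per participant, first condition on the y axis, with the
#' identity diagonal: points above the line mean greater sensitivity to the
#' first condition.
#'
#' @param report A `group_report` from [analyze_study()].
#' @return A ggplot object.
#' @export
plot_threshold_scatter <- function(report) {
  .need_ggplot()
  stopifnot(inherits(report, "group_report"))
  thr <- report$thresholds
  thr <- thr[thr$fittable, ]
  wide <- tidyr_pivot(thr)
  ggplot2::ggplot(wide, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(shape = 0, size = 3) +
    ggplot2::labs(x = paste0(report$conditions[2], " threshold (% dilution)"),
                  y = paste0(report$conditions[1], " threshold (% dilution)")) +
    ggplot2::theme_minimal()
}

# minimal wide reshape without importing tidyr
tidyr_pivot <- function(thr) {
  conds <- unique(thr$condition)[1:2]
  a <- thr[thr$condition == conds[1], c("participant_id", "threshold")]
  b <- thr[thr$condition == conds[2], c("participant_id", "threshold")]
  m <- merge(a, b, by = "participant_id", suffixes = c("_y", "_x"))
  tibble::tibble(participant_id = m$participant_id,
                 y = m$threshold_y, x = m$threshold_x)
}
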