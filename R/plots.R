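#' Plot an ROC curve
#'
#' The cross-validated ROC curve with its Youden-optimal operating point and
#' the chance diagonal.
#'
#' @param object An `ica_roc` from [roc_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ica_roc <- function(object, ...) {
  crv <- tidy(object)
  crv <- crv[order(1 - crv$specificity, crv$sensitivity), ]
  op <- glance(object)
  ggplot2::ggplot(crv, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_step(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::geom_point(data = op, colour = "#b2182b", size = 2.5) +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "Sensitivity",
      title = sprintf("Impairment classification ROC (AUC = %.1f%%)", 100 * object$auc),
      subtitle = sprintf("Operating point: sensitivity %.1f%%, specificity %.1f%%",
                         100 * object$sensitivity, 100 * object$specificity)
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot the time course of a scored session
#'
#' Running accuracy (cumulative proportion correct) and per-trial reaction
#' times over the main task, with removed outlier trials marked.
#'
#' @param session An `ica_session`.
#' @param cfg A [scoring_config()].
#' @return A ggplot object.
#' @export
plot_session_timecourse <- function(session, cfg = scoring_config()) {
  assert_that(inherits(session, "ica_session"), "not an ica_session")
  main <- session$records[session$records$phase == "main", ]
  responded <- main$response != "none"
  fences <- remove_rt_outliers(main$rt_ms[responded], w = cfg$whisker_w)
  df <- dplyr::mutate(
    main,
    running_accuracy = 100 * cumsum(.data$correct) / seq_len(nrow(main)),
    outlier = responded & (.data$rt_ms < fences$lower | .data$rt_ms > fences$upper)
  )
  long <- dplyr::bind_rows(
    tibble::tibble(trial_index = df$trial_index, value = df$running_accuracy,
                   what = "Running accuracy (%)", outlier = FALSE),
    tibble::tibble(trial_index = df$trial_index, value = df$rt_ms,
                   what = "Reaction time (ms)", outlier = df$outlier)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trial_index, y = .data$value)) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$what == "Running accuracy (%)"),
                       colour = "#2166ac") +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, .data$what == "Reaction time (ms)"),
                        ggplot2::aes(colour = .data$outlier), size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "#b2182b"),
                                 name = "RT outlier") +
    ggplot2::facet_wrap(~what, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Trial", y = NULL,
                  title = sprintf("Session time course: %s", session$subject_id)) +
    ggplot2::theme_minimal()
}

#' Plot cohort score distributions by group
#'
#' @param cohort An `ica_cohort` from [simulate_cohort()].
#' @param measure Result column to plot (default `"ica_score"`).
#' @return A ggplot object.
#' @export
plot_cohort_scores <- function(cohort, measure = "ica_score") {
  assert_that(inherits(cohort, "ica_cohort"), "not an ica_cohort")
  df <- dplyr::inner_join(cohort$results, cohort$subjects, by = "subject_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data[[measure]],
                                   colour = .data$impaired)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "black", linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = measure,
                  title = "Simulated cohort scores by group",
                  colour = "Impaired") +
    ggplot2::theme_minimal()
}
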