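#' Scoring configuration
#'
#' Constants of the scoring pipeline. The speed transform maps the mean
#' correct reaction time (ms) to a 0-100 scale via
#' `min(cap, 100 * exp(-meanRT / tau_ms + offset))`; with the defaults the
#' transform sits exactly at the cap for mean RTs up to
#' `tau_ms * offset = 349.525` ms and decreases beyond it. Reaction-time
#' outliers are removed with Tukey fences at whisker width `whisker_w`; a
#' session whose outlier percentage exceeds `invalid_outlier_pct` is flagged
#' invalid.
#'
#' @param tau_ms Exponential time constant of the speed transform (ms).
#' @param offset Additive constant in the exponent of the speed transform.
#' @param speed_cap Upper bound of the speed scale.
#' @param whisker_w Tukey whisker width `w`: fences at `q1 - w*IQR` and
#'   `q3 + w*IQR`, quartiles by linear interpolation (type 7).
#' @param invalid_outlier_pct Maximum tolerated percentage of outlier trials;
#'   a session is still valid at exactly this percentage.
#' @param trend_window Minimum number of usable trials required before a
#'   trend slope is estimated.
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(tau_ms = 1025, offset = 0.341, speed_cap = 100,
                           whisker_w = 1.5, invalid_outlier_pct = 40,
                           trend_window = 10) {
  assert_that(all(c(tau_ms, offset, speed_cap, whisker_w, trend_window) > 0),
              "all scoring constants must be positive")
  assert_that(invalid_outlier_pct > 0 && invalid_outlier_pct < 100,
              "invalid_outlier_pct must be in (0, 100)")
  structure(list(tau_ms = tau_ms, offset = offset, speed_cap = speed_cap,
                 whisker_w = whisker_w, invalid_outlier_pct = invalid_outlier_pct,
                 trend_window = trend_window),
            class = "scoring_config")
}

#' Remove reaction-time outliers with Tukey fences
#'
#' Flags reaction times strictly above `q3 + w * (q3 - q1)` or strictly below
#' `q1 - w * (q3 - q1)` as outliers, with quartiles computed by linear
#' interpolation between order statistics (R quantile type 7). With a
#' degenerate IQR of zero nothing is removed (the inequalities are strict).
#'
#' @param rts Vector of positive reaction times (ms).
#' @param w Whisker width (default 1.5).
#' @return A list with `kept`, `removed`, and the fences `lower` / `upper`.
#' @export
#' @examples
#' remove_rt_outliers(c(400, 420, 440, 460, 3000))
remove_rt_outliers <- function(rts, w = 1.5) {
  assert_that(length(rts) > 0, "rts must be non-empty")
  assert_that(all(rts > 0), "reaction times must be positive")
  q <- quantile(rts, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lower <- q[1] - w * iqr
  upper <- q[2] + w * iqr
  out <- rts < lower | rts > upper
  list(kept = rts[!out], removed = rts[out], lower = lower, upper = upper)
}

#' Accuracy of a set of main-phase trials
#'
#' Percentage of correct categorizations among the supplied trials. The
#' denominator is every trial given (after outlier trials have been dropped
#' upstream); non-responses count as incorrect.
#'
#' @param records Main-phase trial-record tibble.
#' @return Accuracy in percent.
#' @export
compute_accuracy <- function(records) {
  assert_that(nrow(records) > 0, "records must be non-empty")
  assert_that(all(records$phase == "main"), "accuracy is computed on main-phase trials only")
  100 * sum(records$correct) / nrow(records)
}

#' Speed transform of the mean correct reaction time
#'
#' `min(cap, 100 * exp(-meanRT / tau + offset))`: 100 for mean RTs at or below
#' `tau * offset` ms (349.525 ms with defaults), strictly decreasing and
#' positive beyond.
#'
#' @param mean_correct_rt_ms Mean reaction time over correctly categorized,
#'   non-outlier trials (ms).
#' @param cfg A [scoring_config()].
#' @return Speed on (0, 100].
#' @export
#' @examples
#' compute_speed(1025) # 51.74
compute_speed <- function(mean_correct_rt_ms, cfg = scoring_config()) {
  assert_that(length(mean_correct_rt_ms) == 1 && is.finite(mean_correct_rt_ms) &&
                mean_correct_rt_ms > 0,
              "mean_correct_rt_ms must be a single positive number")
  min(cfg$speed_cap, 100 * exp(-mean_correct_rt_ms / cfg$tau_ms + cfg$offset))
}

#' Composite summary score from speed and accuracy
#'
#' `(speed/100) * (accuracy/100) * 100`.
#'
#' @param speed,accuracy Values in [0, 100].
#' @return The composite score in [0, 100].
#' @export
compute_ica_score <- function(speed, accuracy) {
  assert_that(all(speed >= 0 & speed <= 100), "speed must be in [0, 100]")
  assert_that(all(accuracy >= 0 & accuracy <= 100), "accuracy must be in [0, 100]")
  (speed / 100) * (accuracy / 100) * 100
}

#' Within-session accuracy and speed trends
#'
#' Ordinary-least-squares slopes over the time course of the main task:
#' per-trial correctness (0/1) against trial index, and the per-trial speed
#' transform (the speed formula applied to each correct trial's reaction time)
#' against trial index. Positive slopes mean performance improved during the
#' test; negative slopes indicate fatigue.
#'
#' @param records Main-phase trial records (outlier trials already removed).
#' @param cfg A [scoring_config()]; `cfg$trend_window` is the minimum number
#'   of trials required.
#' @return A list with `accuracy_trend` and `speed_trend` (per-trial slopes;
#'   `speed_trend` is `NA` with fewer than two correct responded trials).
#' @export
compute_trends <- function(records, cfg = scoring_config()) {
  assert_that(nrow(records) >= cfg$trend_window,
              "need at least %d trials for trend estimation (got %d)",
              cfg$trend_window, nrow(records))
  accuracy_trend <- ols_slope(records$trial_index, as.numeric(records$correct))
  corr <- records[records$correct & records$response != "none", ]
  speed_trend <- if (nrow(corr) >= 2) {
    per_trial_speed <- pmin(cfg$speed_cap,
                            100 * exp(-corr$rt_ms / cfg$tau_ms + cfg$offset))
    ols_slope(corr$trial_index, per_trial_speed)
  } else {
    NA_real_
  }
  list(accuracy_trend = accuracy_trend, speed_trend = speed_trend)
}

#' Score a session
#'
#' The full scoring pipeline: practice trials are discarded; Tukey fences over
#' the responded main-trial reaction times flag outlier trials, which are
#' removed from both the accuracy denominator and the reaction-time pool;
#' accuracy, speed and the composite score are computed on what remains; the
#' session is flagged invalid when the outlier percentage (over all observed
#' main trials) exceeds `cfg$invalid_outlier_pct`.
#'
#' @param session An `ica_session` (must not be aborted).
#' @param cfg A [scoring_config()].
#' @return A one-row tibble of class `ica_result`: `subject_id`, `accuracy`,
#'   `speed`, `ica_score`, `mean_correct_rt_ms`, `n_outliers_removed`,
#'   `outlier_pct`, `valid`, `accuracy_trend`, `speed_trend`, `n_main`.
#' @export
score_session <- function(session, cfg = scoring_config()) {
  assert_that(inherits(session, "ica_session"), "not an ica_session")
  if (session$practice_outcome == "aborted") {
    rlang::abort(sprintf("session %s was aborted at the practice gate and cannot be scored",
                         session$subject_id),
                 class = "icatest_aborted_session")
  }
  main <- session$records[session$records$phase == "main", ]
  assert_that(nrow(main) > 0, "session has no main-phase records")

  responded <- main$response != "none"
  fences <- remove_rt_outliers(main$rt_ms[responded], w = cfg$whisker_w)
  is_outlier <- responded &
    (main$rt_ms < fences$lower | main$rt_ms > fences$upper) &
    !is.na(main$rt_ms)
  kept <- main[!is_outlier, ]

  n_outliers <- sum(is_outlier)
  outlier_pct <- 100 * n_outliers / nrow(main)

  accuracy <- compute_accuracy(kept)
  corr_rt <- kept$rt_ms[kept$correct & kept$response != "none"]
  mean_rt <- if (length(corr_rt) > 0) mean(corr_rt) else NA_real_
  speed <- if (is.na(mean_rt)) 0 else compute_speed(mean_rt, cfg)
  trends <- compute_trends(kept, cfg)

  tibble::new_tibble(
    tibble::tibble(
      subject_id = session$subject_id,
      accuracy = accuracy,
      speed = speed,
      ica_score = compute_ica_score(speed, accuracy),
      mean_correct_rt_ms = mean_rt,
      n_outliers_removed = n_outliers,
      outlier_pct = outlier_pct,
      valid = outlier_pct <= cfg$invalid_outlier_pct,
      accuracy_trend = trends$accuracy_trend,
      speed_trend = trends$speed_trend,
      n_main = nrow(main)
    ),
    class = "ica_result"
  )
}

#' Score many sessions into a cohort result table
#'
#' @param sessions A list of `ica_session` objects.
#' @param cfg A [scoring_config()].
#' @return A tibble with one [score_session()] row per session.
#' @export
score_sessions <- function(sessions, cfg = scoring_config()) {
  dplyr::bind_rows(purrr::map(sessions, score_session, cfg = cfg))
}
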