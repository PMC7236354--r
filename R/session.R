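#' Trial records and sessions
#'
#' A *session* is one administration of the test: up to two 10-trial practice
#' blocks followed, if the practice gate is passed, by the 100 main trials.
#' Trial records are plain tibbles with columns `trial_index`, `image_id`,
#' `true_label`, `phase`, `response`, `correct`, `rt_ms` (`NA` when no
#' response was given; non-responses count as incorrect).
#'
#' @param subject_id Subject identifier.
#' @param records A trial-record tibble covering the practice and (if reached)
#'   main phases.
#' @param practice_outcome One of `"passed_first"`, `"passed_second"`,
#'   `"aborted"`.
#' @param schedule_ref Identifier of the schedule used.
#' @return An object of class `ica_session`.
#' @export
new_session <- function(subject_id, records, practice_outcome,
                        schedule_ref = NA_character_) {
  records <- validate_trial_records(records)
  assert_that(practice_outcome %in% c("passed_first", "passed_second", "aborted"),
              "unknown practice_outcome '%s'", practice_outcome)
  if (practice_outcome == "aborted") {
    assert_that(!any(records$phase == "main"),
                "aborted sessions cannot contain main-phase records")
  }
  n_practice <- table(records$phase[records$phase != "main"])
  assert_that(all(n_practice == 10) && length(n_practice) <= 2,
              "practice blocks must be exactly 10 records each, at most 2 blocks")
  structure(
    list(subject_id = subject_id, records = records,
         practice_outcome = practice_outcome, schedule_ref = schedule_ref,
         format_version = 1L),
    class = "ica_session"
  )
}

#' @export
print.ica_session <- function(x, ...) {
  cat(sprintf("<ica_session> subject %s: %d trials (%d main), practice %s\n",
              x$subject_id, nrow(x$records), sum(x$records$phase == "main"),
              x$practice_outcome))
  invisible(x)
}

#' @noRd
validate_trial_records <- function(records, context = "records") {
  needed <- c("trial_index", "image_id", "true_label", "phase", "response",
              "correct", "rt_ms")
  missing <- setdiff(needed, names(records))
  assert_that(length(missing) == 0, "%s: missing column(s) %s", context,
              paste(missing, collapse = ", "))
  assert_that(all(records$phase %in% c("practice_1", "practice_2", "main")),
              "%s: phase must be practice_1 / practice_2 / main", context)
  assert_that(all(records$response %in% c("animal", "non_animal", "none")),
              "%s: response must be animal / non_animal / none", context)
  bad <- which(records$response == "none" & !is.na(records$rt_ms))
  assert_that(length(bad) == 0, "%s: trial %s has rt_ms but response 'none'",
              context, paste(records$trial_index[bad], collapse = ","))
  bad <- which(records$response != "none" & is.na(records$rt_ms))
  assert_that(length(bad) == 0, "%s: trial %s responded but rt_ms is missing",
              context, paste(records$trial_index[bad], collapse = ","))
  assert_that(all(is.na(records$rt_ms) | records$rt_ms > 0),
              "%s: rt_ms must be positive", context)
  bad <- which(records$correct != (records$response == records$true_label))
  assert_that(length(bad) == 0,
              "%s: trial %s has correct flag inconsistent with response vs true_label",
              context, paste(records$trial_index[bad], collapse = ","))
  tibble::as_tibble(records)
}

#' Evaluate one practice block against the above-chance gate
#'
#' A practice block passes only when strictly more than half of its 10 trials
#' are correct; performance at chance (5/10) or below fails.
#'
#' @param block A trial-record tibble with exactly 10 rows.
#' @return `"pass"` or `"fail"`.
#' @export
#' @examples
#' blk <- tibble::tibble(
#'   trial_index = 1:10, image_id = sprintf("p%02d", 1:10),
#'   true_label = "animal", phase = "practice_1",
#'   response = rep(c("animal", "non_animal"), c(6, 4)),
#'   correct = rep(c(TRUE, FALSE), c(6, 4)), rt_ms = 500
#' )
#' evaluate_practice(blk)
evaluate_practice <- function(block) {
  assert_that(nrow(block) == 10, "practice block must have exactly 10 records (got %d)",
              nrow(block))
  block <- validate_trial_records(block, "practice block")
  if (sum(block$correct) / 10 > 0.5) "pass" else "fail"
}

#' Resolve the two-attempt practice outcome
#'
#' Passing the first block continues straight to the main task
#' (`"passed_first"`); a failed first block earns one retry with a new image
#' set (`"passed_second"` if it passes); failing both aborts the session.
#'
#' @param block1 First practice block (10 records).
#' @param block2 Second practice block, only when `block1` failed.
#' @return `"passed_first"`, `"passed_second"` or `"aborted"`.
#' @export
resolve_practice_outcome <- function(block1, block2 = NULL) {
  first <- evaluate_practice(block1)
  if (first == "pass") {
    assert_that(is.null(block2),
                "block2 must not be supplied when the first practice block passed")
    return("passed_first")
  }
  if (is.null(block2)) return("aborted")
  if (evaluate_practice(block2) == "pass") "passed_second" else "aborted"
}

#' Save or load a session as versioned JSON
#'
#' `save_session()` writes a schema-versioned JSON file; `load_session()`
#' reads one back, validating the schema and every trial record (a missing
#' `rt_ms` on a responded trial, for instance, is reported with its trial
#' index). The round trip is lossless.
#'
#' @param session An `ica_session`.
#' @param path File path.
#' @return `save_session()` returns `path` invisibly; `load_session()` returns
#'   the `ica_session`.
#' @export
save_session <- function(session, path) {
  assert_that(inherits(session, "ica_session"), "not an ica_session")
  recs <- session$records
  recs$rt_ms[is.na(recs$rt_ms)] <- NA  # jsonlite encodes as null
  jsonlite::write_json(
    list(format_version = session$format_version,
         subject_id = session$subject_id,
         schedule_ref = session$schedule_ref,
         practice_outcome = session$practice_outcome,
         records = recs),
    path, auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows"
  )
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    rlang::abort(sprintf("cannot parse session file %s: %s",
                                         path, conditionMessage(e)),
                                 class = "icatest_parse_error")
                  })
  needed <- c("format_version", "subject_id", "practice_outcome", "records")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    rlang::abort(sprintf("session file %s: missing field(s) %s", path,
                         paste(missing, collapse = ", ")),
                 class = "icatest_parse_error")
  }
  recs <- tibble::as_tibble(raw$records)
  if (!"rt_ms" %in% names(recs)) recs$rt_ms <- NA_real_
  recs$rt_ms <- as.numeric(recs$rt_ms)
  recs <- tryCatch(validate_trial_records(recs, sprintf("session file %s", path)),
                   error = function(e) {
                     rlang::abort(conditionMessage(e), class = "icatest_parse_error")
                   })
  new_session(raw$subject_id, recs, raw$practice_outcome,
              raw$schedule_ref %||% NA_character_)
}

#' Export trial records to CSV
#'
#' @param session An `ica_session`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(session, path) {
  assert_that(inherits(session, "ica_session"), "not an ica_session")
  utils::write.csv(session$records, path, row.names = FALSE, na = "")
  invisible(path)
}
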