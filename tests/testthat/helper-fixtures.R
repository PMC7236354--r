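# Shared fixtures, built in code. Small canvases keep the suite fast; nothing
# under test depends on image resolution.

fixture_pool <- function(seed = 7) generate_mask_pool(64, seed = seed)

fixture_stimset <- function(seed = 1) generate_stimulus_set(seed = seed, size_px = 32)

fixture_schedule <- function(stimset = fixture_stimset(), pool = fixture_pool(),
                             order_seed = 11) {
  build_trial_schedule(stimset, pool, order_seed = order_seed)
}

# A main-phase trial-record tibble with prescribed correctness and RTs.
make_main_records <- function(correct, rt_ms, labels = NULL) {
  n <- length(correct)
  labels <- labels %||% rep(c("animal", "non_animal"), length.out = n)
  other <- ifelse(labels == "animal", "non_animal", "animal")
  tibble::tibble(
    trial_index = seq_len(n),
    image_id = sprintf("img_%03d", seq_len(n)),
    true_label = labels,
    phase = "main",
    response = ifelse(correct, labels, other),
    correct = as.logical(correct),
    rt_ms = rt_ms
  )
}

# A practice block with k of 10 correct.
make_practice_block <- function(k, phase = "practice_1") {
  rec <- make_main_records(rep(c(TRUE, FALSE), c(k, 10 - k)), rep(500, 10))
  rec$phase <- phase
  rec$image_id <- sprintf("%s_%02d", phase, 1:10)
  rec
}

# Full session: a passing practice block plus prescribed main trials.
make_session <- function(correct, rt_ms, subject_id = "fixture") {
  recs <- dplyr::bind_rows(make_practice_block(8),
                           make_main_records(correct, rt_ms))
  new_session(subject_id, recs, "passed_first", schedule_ref = "fixture_sched")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
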