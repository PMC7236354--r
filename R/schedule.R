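#' Build a per-administration trial schedule
#'
#' Lays out one administration of the main task: every main image exactly
#' once, in a fresh random order per administration (`order_seed`), each trial
#' carrying the default presentation timings — 100 ms image, 20 ms
#' inter-stimulus interval, 250 ms dynamic mask — and its own freshly sampled
#' 8-frame mask sequence.
#'
#' @param stimset A `stimulus_set` from [generate_stimulus_set()].
#' @param pool A `mask_pool` from [generate_mask_pool()].
#' @param order_seed Integer seed for the presentation order and the mask
#'   draws.
#' @param image_ms,isi_ms,mask_ms Presentation timings in milliseconds.
#' @return A tibble of class `trial_schedule` with one row per main trial:
#'   `trial_index`, `image_id`, `label`, `difficulty`, `image_ms`, `isi_ms`,
#'   `mask_ms`, and a `mask` list-column of mask-sequence tibbles
#'   (see [sample_mask_sequence()]). The `order_seed` and a `schedule_id`
#'   are stored as attributes.
#' @export
#' @examples
#' stim <- generate_stimulus_set(seed = 1, size_px = 32)
#' pool <- generate_mask_pool(64, seed = 7)
#' sched <- build_trial_schedule(stim, pool, order_seed = 11)
#' sched[1, c("image_id", "image_ms", "isi_ms", "mask_ms")]
build_trial_schedule <- function(stimset, pool, order_seed,
                                 image_ms = 100, isi_ms = 20, mask_ms = 250) {
  validate_stimulus_set(stimset)
  validate_mask_pool(pool)

  main <- stimset$manifest[stimset$manifest$role == "main", ]
  mask_total_ms <- mask_ms
  sched <- with_seed(order_seed, {
    ord <- sample(nrow(main))
    tibble::tibble(
      trial_index = seq_len(nrow(main)),
      image_id = main$image_id[ord],
      label = main$label[ord],
      difficulty = main$difficulty[ord],
      image_ms = image_ms,
      isi_ms = isi_ms,
      mask_ms = mask_ms,
      mask = purrr::map(seq_len(nrow(main)),
                        function(i) sample_mask_sequence(pool, total_ms = mask_total_ms))
    )
  })
  attr(sched, "order_seed") <- as.integer(order_seed)
  attr(sched, "schedule_id") <- sprintf("sched_%d_%d", stimset$seed, as.integer(order_seed))
  class(sched) <- c("trial_schedule", class(sched))
  sched
}
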