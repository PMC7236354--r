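#' Generate the backward-masking noise frame pool
#'
#' Draws one white-noise image, low-pass filters it at four octave-spaced
#' spatial scales (Gaussian blur, sigma = 8, 4, 2, 1 px at a 256 px canvas,
#' scaled proportionally for other sizes; scale 1 is the coarsest), thresholds
#' each filtered image at its own median into a high-contrast binary pattern,
#' and expands each scale into four variants (90 and 180 degree rotations,
#' horizontal and vertical mirror) for a pool of 16 frames. Dynamic masks are
#' then assembled from this pool by [sample_mask_sequence()].
#'
#' @param size_px Side length of the square frames in pixels (>= 32).
#' @param seed Integer seed; the pool is bit-identical for a fixed seed.
#' @return An object of class `mask_pool`: a list with `frames` (list of 16
#'   matrices with values in \{0, 255\}), a `manifest` tibble (`frame`,
#'   `scale`, `variant`, `sigma_px`), `size_px` and `seed`.
#' @export
#' @examples
#' pool <- generate_mask_pool(64, seed = 7)
#' pool$manifest
generate_mask_pool <- function(size_px, seed) {
  assert_that(is.numeric(size_px) && length(size_px) == 1 && size_px >= 32,
              "size_px must be a single number >= 32 (got %s)",
              paste(size_px, collapse = ","))
  size_px <- as.integer(size_px)

  sigmas <- c(8, 4, 2, 1) * size_px / 256
  variants <- c("rot90", "rot180", "mirror_h", "mirror_v")

  noise <- with_seed(seed, matrix(runif(size_px^2), size_px, size_px))

  frames <- list()
  manifest <- list()
  k <- 0L
  for (s in seq_along(sigmas)) {
    low <- EBImage::gblur(noise, sigma = sigmas[s])
    bin <- matrix(0, size_px, size_px)
    bin[low > stats::median(low)] <- 255
    for (v in variants) {
      k <- k + 1L
      frames[[k]] <- transform_frame(bin, v)
      manifest[[k]] <- tibble::tibble(frame = k, scale = s, variant = v,
                                      sigma_px = sigmas[s])
    }
  }

  structure(
    list(frames = frames, manifest = dplyr::bind_rows(manifest),
         size_px = size_px, seed = as.integer(seed)),
    class = "mask_pool"
  )
}

#' @noRd
transform_frame <- function(m, variant) {
  switch(variant,
    rot90 = t(m)[, nrow(m):1, drop = FALSE],
    rot180 = m[nrow(m):1, ncol(m):1, drop = FALSE],
    mirror_h = m[, ncol(m):1, drop = FALSE],
    mirror_v = m[nrow(m):1, , drop = FALSE],
    stop_bad_arg("unknown frame variant '%s'", variant)
  )
}

#' @noRd
validate_mask_pool <- function(pool) {
  ok <- inherits(pool, "mask_pool") &&
    length(pool$frames) == 16 &&
    nrow(pool$manifest) == 16 &&
    all(table(pool$manifest$scale) == 4)
  assert_that(ok, "malformed mask pool: expected 16 frames, 4 per scale")
  invisible(pool)
}

#' @export
print.mask_pool <- function(x, ...) {
  cat(sprintf("<mask_pool> 16 binary frames, %d x %d px, 4 spatial scales, seed %d\n",
              x$size_px, x$size_px, x$seed))
  invisible(x)
}

#' Sample a dynamic mask sequence from a frame pool
#'
#' Draws the 8-frame dynamic mask shown after every stimulus: two frames from
#' each of the four spatial scales (variants chosen uniformly), in random
#' order. Uses the current RNG stream, so successive calls give different
#' sequences; seed the stream for reproducibility.
#'
#' @param pool A `mask_pool` from [generate_mask_pool()].
#' @param total_ms Total mask duration in ms, split evenly over the 8 frames
#'   (default 250, i.e. 31.25 ms per frame).
#' @return A tibble with 8 rows: `position`, `frame`, `scale`, `variant`,
#'   `frame_duration_ms`.
#' @export
sample_mask_sequence <- function(pool, total_ms = 250) {
  validate_mask_pool(pool)
  assert_that(is.numeric(total_ms) && total_ms > 0, "total_ms must be positive")

  frame_v <- pool$manifest$frame
  scale_v <- pool$manifest$scale
  picks <- c(sample(frame_v[scale_v == 1], 2), sample(frame_v[scale_v == 2], 2),
             sample(frame_v[scale_v == 3], 2), sample(frame_v[scale_v == 4], 2))
  picks <- sample(picks)

  i <- match(picks, frame_v)
  tibble::new_tibble(list(
    position = 1:8,
    frame = frame_v[i],
    scale = scale_v[i],
    variant = pool$manifest$variant[i],
    frame_duration_ms = rep(total_ms / 8, 8)
  ), nrow = 8L)
}

#' Write a mask pool to PNG files with a JSON manifest
#'
#' @param pool A `mask_pool`.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly; frames land in
#'   `dir/mask_sXX_variant.png` plus `dir/manifest.json`.
#' @export
write_mask_pool <- function(pool, dir) {
  validate_mask_pool(pool)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- pool$manifest
  man$file <- sprintf("mask_s%02d_%s.png", man$scale, man$variant)
  for (i in seq_len(nrow(man))) {
    png::writePNG(pool$frames[[man$frame[i]]] / 255,
                  file.path(dir, man$file[i]))
  }
  jsonlite::write_json(
    list(size_px = pool$size_px, seed = pool$seed,
         frames = as.list(man[c("file", "frame", "scale", "variant", "sigma_px")])),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(man)
}
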