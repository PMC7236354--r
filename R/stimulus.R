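#' Generate a procedural animal / non-animal stimulus set
#'
#' Builds the labelled grayscale image set the categorization task presents:
#' 100 main images (50 per label) plus two disjoint 10-image practice sets
#' (5 per label). Targets are procedurally drawn silhouettes — organic
#' radial-harmonic blobs with limb-like lobes for the "animal" class,
#' straight-edged geometric figures (rectangle, triangle, cross) for the
#' "non-animal" class — composited over low-pass-filtered noise clutter. Each
#' image carries a difficulty scalar in [0, 1]; harder images have smaller,
#' lower-contrast targets in heavier clutter, emulating the distant /
#' cluttered photographs of the real test. Difficulties are spread evenly over
#' [0.05, 0.95] within each label so every administration samples the full
#' difficulty range.
#'
#' @param seed Integer seed; pixel content is deterministic given the seed.
#' @param size_px Image side length in pixels (default 64).
#' @return An object of class `stimulus_set`: list with `images` (named list
#'   of matrices in [0, 1]) and `manifest`, a tibble with columns `image_id`,
#'   `label` (`"animal"`/`"non_animal"`), `difficulty`, `role`
#'   (`"practice_1"`, `"practice_2"`, `"main"`).
#' @export
#' @examples
#' stim <- generate_stimulus_set(seed = 1, size_px = 32)
#' dplyr::count(stim$manifest, role, label)
generate_stimulus_set <- function(seed, size_px = 64) {
  assert_that(size_px >= 16, "size_px must be >= 16")
  roles <- c(rep("practice_1", 10), rep("practice_2", 10), rep("main", 100))
  labels <- c(rep(c("animal", "non_animal"), each = 5),
              rep(c("animal", "non_animal"), each = 5),
              rep(c("animal", "non_animal"), each = 50))

  manifest <- tibble::tibble(
    image_id = sprintf("img_%03d", seq_along(roles)),
    label = labels,
    role = roles
  )
  # even difficulty coverage within each role x label cell
  manifest <- dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(manifest, .data$role, .data$label),
    difficulty = seq(0.05, 0.95, length.out = dplyr::n())
  ))
  manifest <- manifest[order(manifest$image_id), ]

  images <- with_seed(seed, {
    purrr::map(seq_len(nrow(manifest)), function(i) {
      draw_stimulus(manifest$label[i], manifest$difficulty[i], size_px)
    })
  })
  names(images) <- manifest$image_id

  structure(list(images = images, manifest = manifest, size_px = size_px,
                 seed = as.integer(seed)),
            class = "stimulus_set")
}

# One stimulus: clutter background + silhouette target. Difficulty shrinks the
# target, reduces its contrast against the background, and raises clutter.
#' @noRd
draw_stimulus <- function(label, difficulty, size_px) {
  g <- expand.grid(x = seq(-1, 1, length.out = size_px),
                   y = seq(-1, 1, length.out = size_px))
  clutter <- EBImage::gblur(matrix(runif(size_px^2), size_px, size_px),
                            sigma = max(1, size_px / 32))
  clutter <- (clutter - min(clutter)) / (max(clutter) - min(clutter) + 1e-12)
  bg <- 0.55 + (0.1 + 0.5 * difficulty) * (clutter - 0.5)

  radius <- 0.55 - 0.33 * difficulty
  cx <- runif(1, -0.2, 0.2)
  cy <- runif(1, -0.2, 0.2)
  inside <- if (label == "animal") {
    blob_mask(g$x - cx, g$y - cy, radius)
  } else {
    geometric_mask(g$x - cx, g$y - cy, radius)
  }
  target_val <- 0.5 - (0.45 - 0.3 * difficulty)  # darker than mean background
  img <- bg
  img[matrix(inside, size_px, size_px)] <- target_val
  pmin(pmax(img, 0), 1)
}

# Organic closed shape: radial harmonics r(theta) with random lobes.
#' @noRd
blob_mask <- function(x, y, radius) {
  th <- atan2(y, x)
  r <- sqrt(x^2 + y^2)
  amp <- runif(4, 0.05, 0.22)
  ph <- runif(4, 0, 2 * pi)
  rb <- radius * (1 + amp[1] * cos(2 * th + ph[1]) + amp[2] * cos(3 * th + ph[2]) +
                    amp[3] * cos(4 * th + ph[3]) + amp[4] * cos(5 * th + ph[4]))
  r < rb
}

# Straight-edged figure: rectangle, triangle or cross, randomly rotated.
#' @noRd
geometric_mask <- function(x, y, radius) {
  a <- runif(1, 0, pi)
  xr <- cos(a) * x - sin(a) * y
  yr <- sin(a) * x + cos(a) * y
  switch(sample(c("rect", "tri", "cross"), 1),
    rect = abs(xr) < radius * runif(1, 0.5, 1) & abs(yr) < radius * runif(1, 0.5, 1),
    tri = yr > -radius / 2 & (abs(xr) < (radius - yr) * 0.6) & yr < radius,
    cross = (abs(xr) < radius * 0.3 & abs(yr) < radius) |
      (abs(yr) < radius * 0.3 & abs(xr) < radius)
  )
}

#' @export
print.stimulus_set <- function(x, ...) {
  n <- table(x$manifest$role)
  cat(sprintf("<stimulus_set> %d images (%d main, %d + %d practice), %d x %d px, seed %d\n",
              nrow(x$manifest), n[["main"]], n[["practice_1"]], n[["practice_2"]],
              x$size_px, x$size_px, x$seed))
  invisible(x)
}

#' @noRd
validate_stimulus_set <- function(stimset) {
  m <- stimset$manifest
  ok <- inherits(stimset, "stimulus_set") &&
    sum(m$role == "main") == 100 &&
    sum(m$role == "main" & m$label == "animal") == 50 &&
    all(table(m$role[m$role != "main"], m$label[m$role != "main"]) == 5)
  assert_that(ok, "malformed stimulus set: expected 100 main (50/50) and two 10-image practice sets (5/5)")
  invisible(stimset)
}

#' Write a stimulus set to PNG files with a CSV manifest
#'
#' @param stimset A `stimulus_set`.
#' @param dir Output directory.
#' @return The manifest tibble, invisibly.
#' @export
write_stimulus_set <- function(stimset, dir) {
  validate_stimulus_set(stimset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(stimset$images)) {
    png::writePNG(stimset$images[[id]], file.path(dir, paste0(id, ".png")))
  }
  man <- stimset$manifest
  man$file <- paste0(man$image_id, ".png")
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
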