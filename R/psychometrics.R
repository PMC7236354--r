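#' Label cognitive impairment from norm-referenced subtest scores
#'
#' A subject is labelled cognitively impaired when at least one battery
#' subtest falls 2 or more SD below its norm (severe abnormality), or at
#' least two subtests fall 1 or more SD below their norms (mild abnormality
#' in two tests). Boundaries are inclusive. Vectorized over subjects.
#'
#' @param subjects Tibble with numeric columns `sdmt`, `bvmtr`, `cvlt2`
#'   (all required per subject).
#' @param norms Norms tibble (`measure`, `norm_mean`, `norm_sd`), see
#'   [default_norms()].
#' @return Logical vector, `TRUE` = impaired.
#' @export
#' @examples
#' nt <- default_norms()
#' subj <- tibble::tibble(sdmt = 54.73 - 2.1 * 9.77, bvmtr = 23.69, cvlt2 = 58.28)
#' label_impairment(subj, nt)
label_impairment <- function(subjects, norms = default_norms()) {
  tests <- c("sdmt", "bvmtr", "cvlt2")
  missing_col <- setdiff(tests, names(subjects))
  assert_that(length(missing_col) == 0, "subjects table lacks subtest column(s): %s",
              paste(missing_col, collapse = ", "))
  assert_that(all(tests %in% norms$measure), "norms table must cover sdmt, bvmtr, cvlt2")
  assert_that(all(norms$norm_sd > 0), "norm_sd must be positive")

  z <- vapply(tests, function(tst) {
    score <- subjects[[tst]]
    assert_that(!anyNA(score), "subtest '%s' has missing scores; all three subtests are required", tst)
    i <- match(tst, norms$measure)
    (score - norms$norm_mean[i]) / norms$norm_sd[i]
  }, numeric(nrow(subjects)))
  z <- matrix(z, nrow = nrow(subjects))

  severe <- rowSums(z <= -2) >= 1
  mild2 <- rowSums(z <= -1) >= 2
  severe | mild2
}

#' Cohen's d between two groups
#'
#' Standardized mean difference `(mean(b) - mean(a)) / s_p` with the
#' simple-average pooled SD `s_p = sqrt((sd_a^2 + sd_b^2) / 2)` (n-1
#' denominators). By this orientation a positive d means group `b` scores
#' higher.
#'
#' @param a,b Numeric vectors (each of length >= 2, non-degenerate).
#' @return Cohen's d.
#' @export
cohens_d <- function(a, b) {
  assert_that(length(a) >= 2 && length(b) >= 2, "both groups need >= 2 observations")
  sa <- sd(a)
  sb <- sd(b)
  assert_that(sa > 0 || sb > 0, "both groups are degenerate (zero variance)")
  (mean(b) - mean(a)) / sqrt((sa^2 + sb^2) / 2)
}

#' Cohen's d from printed summary statistics
#'
#' Same estimator as [cohens_d()], computed from reported group means and SDs
#' rather than raw data — the form needed to reproduce published group
#' comparisons.
#'
#' @param mean_a,sd_a,mean_b,sd_b Group summary statistics.
#' @return Cohen's d, positive when group `b` scores higher.
#' @export
#' @examples
#' cohens_d_summary(41.04, 11.02, 54.73, 9.77) # 1.31
cohens_d_summary <- function(mean_a, sd_a, mean_b, sd_b) {
  assert_that(all(c(sd_a, sd_b) >= 0) && any(c(sd_a, sd_b) > 0),
              "sds must be non-negative and not both zero")
  (mean_b - mean_a) / sqrt((sd_a^2 + sd_b^2) / 2)
}

#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation; the p-value comes from the exact t transform
#' `t = r * sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return A list with `r`, `p` and `n`.
#' @export
pearson_r <- function(x, y) {
  assert_that(length(x) == length(y), "x and y differ in length")
  assert_that(length(x) >= 3, "need at least 3 paired observations")
  assert_that(sd(x) > 0 && sd(y) > 0, "constant vector: correlation undefined")
  if (isTRUE(all.equal(cor(x, y)^2, 1))) {
    # perfectly collinear: cor.test's t statistic degenerates
    return(list(r = sign(cor(x, y)) * 1.0, p = 0, n = length(x)))
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Battery composite z-score per subject
#'
#' Each subtest is z-scored against the cohort's own mean and SD, and the
#' three z-scores are averaged. The composite has cohort mean 0 by
#' construction.
#'
#' @param cohort Tibble with columns `sdmt`, `bvmtr`, `cvlt2` (n >= 2).
#' @return Numeric vector of per-subject composite z-scores.
#' @export
composite_z <- function(cohort) {
  tests <- c("sdmt", "bvmtr", "cvlt2")
  assert_that(all(tests %in% names(cohort)), "cohort must have sdmt, bvmtr, cvlt2 columns")
  assert_that(nrow(cohort) >= 2, "need at least 2 subjects")
  z <- vapply(tests, function(tst) {
    v <- cohort[[tst]]
    assert_that(sd(v) > 0, "subtest '%s' has zero variance in this cohort", tst)
    (v - mean(v)) / sd(v)
  }, numeric(nrow(cohort)))
  rowMeans(matrix(z, nrow = nrow(cohort)))
}

#' Two-group or paired comparison with effect size
#'
#' Student t-test (pooled-variance two-sample, or paired) with a two-sided
#' p-value, plus Cohen's d: simple-average pooled SD for independent groups,
#' mean difference over the SD of differences when paired. Differences are
#' oriented `b - a`, so swapping the groups flips the signs of t and d.
#' Degenerate null cases (identical paired vectors) report `d = 0` with
#' `t = NA` rather than failing.
#'
#' @param a,b Numeric vectors; equal length when `paired`.
#' @param paired Paired comparison?
#' @return A tibble row: `t`, `p`, `d`, `n_a`, `n_b`, `paired`.
#' @export
group_compare <- function(a, b, paired = FALSE) {
  assert_that(length(a) >= 2 && length(b) >= 2, "need n >= 2 per group")
  if (paired) {
    assert_that(length(a) == length(b), "paired comparison needs equal lengths")
    diffs <- b - a
    # degenerate guard with a float tolerance: (a + 1) - a is not exactly
    # constant in doubles, but t.test would still refuse it
    if (sd(diffs) <= 1e-9 * max(1, abs(mean(diffs)))) {
      d0 <- if (all(diffs == 0)) 0 else sign(mean(diffs)) * Inf
      return(tibble::tibble(t = NA_real_, p = if (all(diffs == 0)) 1 else 0,
                            d = d0, n_a = length(a), n_b = length(b),
                            paired = TRUE))
    }
    tt <- t.test(b, a, paired = TRUE)
    d <- mean(diffs) / sd(diffs)
  } else {
    tt <- t.test(b, a, var.equal = TRUE)
    d <- cohens_d(a, b)
  }
  tibble::tibble(t = unname(tt$statistic), p = tt$p.value, d = d,
                 n_a = length(a), n_b = length(b), paired = paired)
}

#' Test-retest reliability
#'
#' Pearson correlation between two administrations of the same test, banded
#' by the conventional reliability thresholds: above 0.80 is "good", above
#' 0.70 "adequate" (both strict), anything else "poor".
#'
#' @param scores_t1,scores_t2 Paired score vectors (>= 3 pairs).
#' @return A list with `r`, `p`, `n`, `band`.
#' @export
test_retest <- function(scores_t1, scores_t2) {
  res <- pearson_r(scores_t1, scores_t2)
  res$band <- reliability_band(res$r)
  res
}

# strict thresholds: exactly 0.70 / 0.80 do not qualify
#' @noRd
reliability_band <- function(r) {
  if (r > 0.80) "good" else if (r > 0.70) "adequate" else "poor"
}
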