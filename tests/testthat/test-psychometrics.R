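# exactly representable norms so z-profiles survive the score round trip
clean_norms <- function() {
  tibble::tibble(measure = c("sdmt", "bvmtr", "cvlt2"),
                 norm_mean = c(50, 20, 60), norm_sd = c(10, 5, 8))
}

# subjects at given z-profiles relative to clean_norms()
subjects_at_z <- function(...) {
  profiles <- list(...)
  nt <- clean_norms()
  at <- function(tst, z) {
    i <- match(tst, nt$measure)
    nt$norm_mean[i] + z * nt$norm_sd[i]
  }
  dplyr::bind_rows(lapply(profiles, function(z) {
    tibble::tibble(sdmt = at("sdmt", z[1]), bvmtr = at("bvmtr", z[2]),
                   cvlt2 = at("cvlt2", z[3]))
  }))
}

test_that("impairment labelling implements the severe / two-mild rule", {
  subj <- subjects_at_z(
    c(-2.1, 0, 0),     # severe on one subtest
    c(-1.2, -1.2, 0),  # mild on two
    c(-1.2, 0, 0),     # single mild: not impaired
    c(0, 0, 0),
    c(-2, 0, 0),       # boundary: exactly -2 counts
    c(-1, -1, 0)       # boundary: exactly -1 twice counts
  )
  expect_equal(label_impairment(subj, clean_norms()),
               c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))

  missing <- subj[1, ]
  missing$bvmtr <- NA
  expect_error(label_impairment(missing, clean_norms()), "bvmtr")
})

test_that("impairment labelling is monotone: lower scores never clear a label", {
  withr::with_seed(14, {
    for (i in 1:30) {
      z <- runif(3, -3, 1)
      subj <- subjects_at_z(z)
      if (label_impairment(subj, clean_norms())) {
        worse <- subjects_at_z(z - runif(3, 0, 2))
        expect_true(label_impairment(worse, clean_norms()))
      }
    }
  })
})

test_that("Cohen's d reproduces the published group comparisons from summaries", {
  expect_equal(round(cohens_d_summary(41.04, 11.02, 54.73, 9.77), 2), 1.31)
  expect_equal(round(cohens_d_summary(21.89, 6.95, 23.69, 5.17), 2), 0.29)
  expect_equal(round(cohens_d_summary(84.97, 11.66, 89.57, 5.79), 2), 0.50)
  expect_equal(round(cohens_d_summary(63.67, 13.30, 78.43, 9.86), 2), 1.26)
})

test_that("Cohen's d on raw data is zero for identical groups and antisymmetric", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(cohens_d(x, x), 0)
  y <- x + 2
  expect_equal(cohens_d(x, y), -cohens_d(y, x))
  expect_equal(cohens_d(x, y), 2 / sd(x))
  expect_error(cohens_d(rep(1, 3), rep(1, 3)), class = "icatest_invalid_argument")
  expect_error(cohens_d(1, c(1, 2)), class = "icatest_invalid_argument")
})

test_that("Pearson correlation matches hand computation and the t-transform p", {
  expect_equal(pearson_r(1:10, 2 * (1:10))$r, 1.0)
  expect_equal(pearson_r(1:10, -(1:10) + 5)$r, -1.0)
  r <- pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$r, 0.6, tolerance = 1e-12)
  ct <- cor.test(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$p, ct$p.value)
  expect_error(pearson_r(rep(1, 5), 1:5), class = "icatest_invalid_argument")
  expect_error(pearson_r(1:3, 1:4), class = "icatest_invalid_argument")
})

test_that("composite z averages within-cohort subtest z-scores", {
  withr::with_seed(6, {
    cohort <- tibble::tibble(sdmt = rnorm(40, 50, 10), bvmtr = rnorm(40, 22, 6),
                             cvlt2 = rnorm(40, 55, 9))
  })
  cz <- composite_z(cohort)
  oracle <- rowMeans(scale(as.matrix(cohort)))
  expect_equal(cz, unname(oracle), tolerance = 1e-12)
  expect_lt(abs(mean(cz)), 1e-10)

  # a subject exactly +1 cohort-SD on every subtest scores 1 against the rest
  mu <- colMeans(cohort); s <- apply(cohort, 2, sd)
  probe <- dplyr::bind_rows(cohort, tibble::as_tibble(as.list(mu + s)))
  cz2 <- composite_z(probe)
  z_by_hand <- mean((unlist(probe[41, ]) - colMeans(probe)) / apply(probe, 2, sd))
  expect_equal(cz2[41], z_by_hand, tolerance = 1e-12)

  flat <- cohort
  flat$sdmt <- 50
  expect_error(composite_z(flat), "sdmt")
})

test_that("group comparisons report t, p and d with the documented orientation", {
  withr::with_seed(3, {
    a <- rnorm(30, 10, 2)
    b <- rnorm(30, 12, 2)
  })
  g <- group_compare(a, b)
  tt <- t.test(b, a, var.equal = TRUE)
  expect_equal(g$t, unname(tt$statistic))
  expect_equal(g$p, tt$p.value)
  expect_equal(g$d, cohens_d(a, b))

  swapped <- group_compare(b, a)
  expect_equal(swapped$t, -g$t)
  expect_equal(swapped$d, -g$d)

  # identical paired vectors: degenerate-safe report
  g0 <- group_compare(a, a, paired = TRUE)
  expect_equal(g0$d, 0)
  expect_true(is.na(g0$t))
  # constant nonzero difference: direction preserved
  expect_equal(group_compare(a, a + 1, paired = TRUE)$d, Inf)
})

test_that("simulated groups at the published SDMT parameters land near d = 1.31", {
  withr::with_seed(8, {
    ms <- rnorm(91, 41.04, 11.02)
    hc <- rnorm(83, 54.73, 9.77)
  })
  g <- group_compare(ms, hc)
  expect_lt(abs(g$d - 1.31), 0.35)
})

test_that("test-retest reliability bands use strict thresholds", {
  x <- c(61.2, 70.5, 48.3, 83.1, 66.0, 74.9)
  tr <- test_retest(x, x)
  expect_equal(tr$r, 1.0)
  expect_equal(tr$band, "good")

  withr::with_seed(10, {
    t1 <- rnorm(1000)
    t2 <- rnorm(1000)
  })
  tr0 <- test_retest(t1, t2)
  expect_lt(abs(tr0$r), 0.07)
  expect_equal(tr0$band, "poor")

  expect_equal(icatest:::reliability_band(0.70), "poor")
  expect_equal(icatest:::reliability_band(0.700001), "adequate")
  expect_equal(icatest:::reliability_band(0.80), "adequate")
  expect_equal(icatest:::reliability_band(0.800001), "good")
})
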