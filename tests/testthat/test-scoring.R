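test_that("Tukey fences remove the worked-example outlier and respect degenerate IQRs", {
  r <- remove_rt_outliers(c(400, 420, 440, 460, 3000), w = 1.5)
  expect_equal(r$removed, 3000)
  expect_equal(r$kept, c(400, 420, 440, 460))
  expect_equal(c(r$lower, r$upper), c(360, 520))

  # zero IQR + strict inequalities: nothing removed
  r0 <- remove_rt_outliers(rep(500, 10))
  expect_length(r0$removed, 0)
  expect_length(r0$kept, 10)

  expect_error(remove_rt_outliers(numeric(0)), class = "icatest_invalid_argument")
})

test_that("outlier removal conserves the input multiset", {
  set.seed(31)
  for (i in 1:50) {
    rts <- rexp(sample(5:80, 1), 1 / 500) + 150
    r <- remove_rt_outliers(rts, w = 1.5)
    expect_equal(sort(c(r$kept, r$removed)), sort(rts))
  }
})

test_that("accuracy is percent correct over the trials supplied", {
  expect_equal(compute_accuracy(make_main_records(rep(c(TRUE, FALSE), c(90, 10)),
                                                  rep(500, 100))), 90)
  expect_equal(compute_accuracy(make_main_records(rep(FALSE, 100), rep(500, 100))), 0)
  # reduced denominator after outlier-trial removal
  expect_equal(compute_accuracy(make_main_records(rep(c(TRUE, FALSE), c(47, 43)),
                                                  rep(500, 90))),
               100 * 47 / 90, tolerance = 1e-12)
  expect_error(compute_accuracy(make_main_records(TRUE, 500)[0, ]),
               class = "icatest_invalid_argument")
})

test_that("speed transform is capped at 100 up to 349.525 ms and decreasing beyond", {
  expect_equal(compute_speed(349.525), 100)
  expect_equal(compute_speed(200), 100)   # raw value 115.7 capped
  expect_equal(compute_speed(1025), 51.74, tolerance = 5e-3)
  expect_equal(compute_speed(1025), 100 * exp(-1 + 0.341), tolerance = 1e-12)

  grid <- seq(1, 3000, by = 7)
  sp <- vapply(grid, compute_speed, numeric(1))
  expect_true(all(diff(sp) <= 0))
  expect_true(all(sp[grid <= 349.525] == 100))
  expect_true(all(sp[grid > 349.6] < 100))
  expect_true(all(sp > 0))

  expect_error(compute_speed(0), class = "icatest_invalid_argument")
})

test_that("the composite score is the normalized product of speed and accuracy", {
  expect_equal(compute_ica_score(100, 100), 100)
  expect_equal(compute_ica_score(50, 80), 40)
  expect_equal(compute_ica_score(71.04, 90), 63.94, tolerance = 5e-3)
  expect_error(compute_ica_score(101, 50), class = "icatest_invalid_argument")
  expect_error(compute_ica_score(50, -1), class = "icatest_invalid_argument")

  # bounded at 100; zero iff accuracy is zero
  set.seed(4)
  s <- runif(200, 0, 100); a <- runif(200, 0, 100)
  ica <- compute_ica_score(s, a)
  expect_true(all(ica <= 100))
  expect_true(all((ica == 0) == (a == 0 | s == 0)))
})

test_that("trend slopes match the closed-form OLS values", {
  cfg <- scoring_config(trend_window = 4)
  rec <- make_main_records(c(FALSE, FALSE, TRUE, TRUE), rep(500, 4))
  expect_equal(compute_trends(rec, cfg)$accuracy_trend, 0.4, tolerance = 1e-12)

  flat <- make_main_records(rep(TRUE, 20), rep(500, 20))
  expect_equal(compute_trends(flat, scoring_config())$accuracy_trend, 0)

  # strictly speeding up within the session -> positive speed trend
  faster <- make_main_records(rep(TRUE, 20), seq(1200, 400, length.out = 20))
  expect_gt(compute_trends(faster, scoring_config())$speed_trend, 0)

  expect_error(compute_trends(rec, scoring_config(trend_window = 10)),
               class = "icatest_invalid_argument")
})

test_that("score_session composes the pipeline and flags validity", {
  # all correct at the cap boundary RT: composite exactly 100
  sess <- make_session(rep(TRUE, 100), rep(349.525, 100))
  res <- score_session(sess)
  expect_equal(res$accuracy, 100)
  expect_equal(res$speed, 100)
  expect_equal(res$ica_score, 100)
  expect_true(res$valid)
  expect_equal(res$n_outliers_removed, 0)

  # 41 contaminated trials split over both tails: flagged and invalid
  rts <- c(runif(59, 495, 505), runif(21, 8000, 10000), runif(20, 1, 5))
  sess41 <- make_session(rep(TRUE, 100), rts)
  res41 <- score_session(sess41)
  expect_equal(res41$n_outliers_removed, 41)
  expect_false(res41$valid)

  # 15% one-sided contamination: removed but still valid
  rts15 <- c(rnorm(85, 500, 30), runif(15, 8000, 10000))
  res15 <- score_session(make_session(rep(TRUE, 100), rts15))
  expect_true(res15$valid)
  expect_gte(res15$n_outliers_removed, 15)
  expect_lte(res15$outlier_pct, 40)

  # outlier trials leave both the accuracy denominator and the RT pool
  correct <- rep(c(TRUE, FALSE), c(47, 53))
  rts_mix <- c(rnorm(90, 500, 20), runif(10, 8000, 10000))
  sess_mix <- make_session(correct[order(runif(100))], rts_mix)
  res_mix <- score_session(sess_mix)
  kept_n <- 100 - res_mix$n_outliers_removed
  expect_equal(res_mix$accuracy * kept_n / 100, round(res_mix$accuracy * kept_n / 100))

  expect_error(
    score_session(new_session("s", make_practice_block(3), "aborted")),
    class = "icatest_aborted_session"
  )
})

test_that("practice trials never reach the scorer", {
  sess <- make_session(rep(TRUE, 100), rep(400, 100))
  # corrupt the practice block: if it leaked into scoring, accuracy < 100
  sess$records$correct[sess$records$phase != "main"] <- FALSE
  sess$records$response[sess$records$phase != "main"] <-
    ifelse(sess$records$true_label[sess$records$phase != "main"] == "animal",
           "non_animal", "animal")
  res <- score_session(new_session("s", sess$records, "passed_second"))
  expect_equal(res$accuracy, 100)
})

test_that("scoring is permutation-invariant except for the trends", {
  set.seed(12)
  correct <- runif(100) < 0.8
  rts <- 250 + rlnorm(100, log(300), 0.3)
  res1 <- score_session(make_session(correct, rts))

  perm <- sample(100)
  res2 <- score_session(make_session(correct[perm], rts[perm]))
  expect_equal(res2$accuracy, res1$accuracy)
  expect_equal(res2$speed, res1$speed)
  expect_equal(res2$ica_score, res1$ica_score)
  expect_equal(res2$n_outliers_removed, res1$n_outliers_removed)
  expect_false(isTRUE(all.equal(res2$accuracy_trend, res1$accuracy_trend)))
})
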