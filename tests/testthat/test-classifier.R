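# small labelled feature set with a signal in one column
toy_features <- function(n = 40, seed = 2, sep = 1.5) {
  withr::with_seed(seed, {
    y <- rep(c("cognitively_normal", "cognitively_impaired"), length.out = n)
    x <- tibble::tibble(
      ica_score = ifelse(y == "cognitively_impaired", 60, 60 + sep * 10) + rnorm(n, 0, 8),
      accuracy_trend = rnorm(n, 0, 0.001),
      speed_trend = rnorm(n, 0, 0.03),
      age = runif(n, 20, 60),
      gender = rbinom(n, 1, 0.7),
      education = runif(n, 8, 20)
    )
    list(x = x, y = factor(y, levels = c("cognitively_normal", "cognitively_impaired")))
  })
}

test_that("feature extraction returns the six features in fixed order", {
  res <- score_session(make_session(rep(TRUE, 100), rep(400, 100)))
  subj <- tibble::tibble(subject_id = "fixture", age = 37, gender = "female",
                         education = 14)
  f <- extract_features(res, subj)
  expect_named(f, c("subject_id", "ica_score", "accuracy_trend", "speed_trend",
                    "age", "gender", "education"))
  expect_equal(f$gender, 1)
  expect_equal(f$ica_score, res$ica_score)
  expect_identical(f, extract_features(res, subj))

  res_bad <- res
  res_bad$valid <- FALSE
  expect_error(extract_features(res_bad, subj), class = "icatest_invalid_argument")
})

test_that("the fitted classifier recovers the sign of a separable feature", {
  x <- data.frame(x = c(-2, -1, 1, 2))
  y <- c("a", "a", "b", "b")
  m <- fit_mlr(x, y, reg_lambda = 0.5)
  expect_gt(m$weights["b", "x"], 0)
  expect_lt(m$weights["a", "x"], 0)

  expect_error(fit_mlr(x, rep("a", 4)), "single class")
  x2 <- cbind(x, cst = 1)
  expect_error(fit_mlr(x2, y), "cst")
})

test_that("a null model predicts 0.5 for both classes", {
  tf <- toy_features()
  m <- fit_mlr(tf$x, tf$y)
  m$weights[] <- 0
  pr <- predict_proba(m, tf$x[1:5, ])
  expect_equal(pr$probability, rep(0.5, 5))
  expect_equal(pr$p_cognitively_impaired + pr$p_cognitively_normal, rep(1, 5))
})

test_that("duplicating the training set leaves the decision boundary unchanged", {
  tf <- toy_features(n = 30)
  m1 <- fit_mlr(tf$x, tf$y, reg_lambda = 1.0)
  m2 <- fit_mlr(dplyr::bind_rows(tf$x, tf$x), c(tf$y, tf$y), reg_lambda = 1.0)
  # identical objective in exact arithmetic; solver noise only
  expect_equal(m2$weights, m1$weights, tolerance = 1e-5)
  expect_equal(predict_proba(m2, tf$x)$probability,
               predict_proba(m1, tf$x)$probability, tolerance = 1e-6)
})

test_that("the penalized fit agrees with an independent ridge-logistic solver", {
  skip_if_not_installed("glmnet")
  tf <- toy_features(n = 60, seed = 9)
  lambda <- 0.4
  m <- fit_mlr(tf$x, tf$y, reg_lambda = lambda)

  # same objective in glmnet's parametrization: binary coefficient
  # beta = w_pos - w_neg on (population-SD) standardized features,
  # penalty lambda/2
  xm <- as.matrix(tf$x)
  z <- sweep(sweep(xm, 2, colMeans(xm)), 2,
             sqrt(colMeans(sweep(xm, 2, colMeans(xm))^2)), "/")
  g <- glmnet::glmnet(z, as.numeric(tf$y == "cognitively_impaired"),
                      family = "binomial", alpha = 0, lambda = lambda / 2,
                      standardize = FALSE, thresh = 1e-14)
  beta_mine <- m$weights["cognitively_impaired", -1] -
    m$weights["cognitively_normal", -1]
  expect_equal(unname(beta_mine), as.numeric(g$beta), tolerance = 1e-4)

  p_mine <- predict_proba(m, tf$x)$p_cognitively_impaired
  p_glmnet <- as.numeric(predict(g, newx = z, type = "response"))
  expect_equal(p_mine, p_glmnet, tolerance = 1e-4)
})

test_that("predicted probabilities are monotone in a positively weighted feature", {
  tf <- toy_features()
  m <- fit_mlr(tf$x, tf$y)
  w_ica <- m$weights["cognitively_impaired", "ica_score"]
  expect_lt(w_ica, 0)  # higher score, less likely impaired

  probe <- tf$x[rep(1, 50), ]
  probe$ica_score <- seq(30, 95, length.out = 50)
  p <- predict_proba(m, probe)$p_cognitively_impaired
  expect_true(all(diff(p) < 0))

  expect_error(predict_proba(m, tf$x[, 1:3]), "missing feature")
})

test_that("leave-one-out produces one leak-free held-out probability per subject", {
  tf <- toy_features(n = 10)
  cv <- loocv(tf$x, tf$y, positive = "cognitively_impaired")
  expect_equal(nrow(cv), 10)
  expect_equal(cv$row, 1:10)

  # fold equivalence: row i must equal a manual fit without subject i,
  # whose scaler cannot depend on the held-out row -- even an extreme one
  tf$x$ica_score[3] <- 500
  cv2 <- loocv(tf$x, tf$y, positive = "cognitively_impaired")
  m3 <- fit_mlr(tf$x[-3, ], tf$y[-3])
  expect_equal(cv2$prob[3],
               predict_proba(m3, tf$x[3, ])$p_cognitively_impaired,
               tolerance = 1e-12)
  expect_equal(m3$scaler, fit_mlr(tf$x[-3, ], tf$y[-3])$scaler)

  # order invariance
  perm <- withr::with_seed(5, sample(10))
  cvp <- loocv(tf$x[perm, ], tf$y[perm], positive = "cognitively_impaired")
  expect_equal(cvp$prob[match(1:10, perm)], cv2$prob, tolerance = 1e-8)

  expect_error(loocv(tf$x[1:2, ], tf$y[1:2]), class = "icatest_invalid_argument")
})

test_that("a perfectly separable cohort is classified perfectly under LOOCV", {
  withr::with_seed(11, {
    y <- rep(c("cognitively_normal", "cognitively_impaired"), each = 10)
    x <- tibble::tibble(ica_score = ifelse(y == "cognitively_impaired",
                                           runif(20, 30, 50), runif(20, 70, 95)),
                        age = runif(20, 20, 60))
  })
  cv <- loocv(x, y, positive = "cognitively_impaired")
  expect_identical(cv$label, cv$truth)
})

test_that("ROC analysis reproduces hand-counted AUCs and degenerate cases", {
  r <- roc_analysis(c(0.9, 0.8, 0.2, 0.4), c(1, 0, 0, 1))
  expect_equal(r$auc, 0.75)

  perfect <- roc_analysis(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1.0)
  expect_equal(perfect$sensitivity, 1.0)
  expect_equal(perfect$specificity, 1.0)

  expect_error(roc_analysis(c(0.2, 0.8), c(1, 1)), class = "icatest_invalid_argument")
})

test_that("trapezoid AUC equals pairwise concordance and matches pROC", {
  concordance <- function(p, y) {
    pos <- p[y]; neg <- p[!y]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  withr::with_seed(21, {
    for (i in 1:40) {
      n <- sample(6:60, 1)
      y <- c(TRUE, FALSE, runif(n - 2) > 0.5)
      p <- round(runif(n), sample(c(1, 2, 6), 1))  # force ties sometimes
      expect_equal(roc_analysis(p, y)$auc, concordance(p, y), tolerance = 1e-12)
    }
  })

  skip_if_not_installed("pROC")
  withr::with_seed(33, {
    y <- runif(80) > 0.4
    p <- plogis(rnorm(80) + 2 * y)
    expect_equal(roc_analysis(p, y)$auc,
                 as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))),
                 tolerance = 1e-12)
  })
})

test_that("AUC is at chance for labels independent of the scores", {
  withr::with_seed(17, {
    p <- runif(10000)
    y <- runif(10000) > 0.5
  })
  expect_lt(abs(roc_analysis(p, y)$auc - 0.5), 0.02)
})

test_that("models serialize to JSON and back without changing predictions", {
  tf <- toy_features()
  m <- fit_mlr(tf$x, tf$y)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(back$weights, m$weights, tolerance = 1e-12)
  expect_equal(predict_proba(back, tf$x), predict_proba(m, tf$x), tolerance = 1e-12)
})

test_that("tidy and glance summarize fitted models and ROC objects", {
  tf <- toy_features()
  m <- fit_mlr(tf$x, tf$y)
  td <- tidy(m)
  expect_equal(nrow(td), 2 * 7)
  expect_true(all(c("class", "term", "estimate", "scale_mean", "scale_sd") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$n, 40)
  expect_equal(gl$n_features, 6)

  r <- roc_analysis(c(0.9, 0.8, 0.2, 0.4), c(1, 0, 0, 1))
  expect_true(all(c("threshold", "sensitivity", "specificity", "youden_j") %in%
                    names(tidy(r))))
  expect_equal(glance(r)$auc, 0.75)
})
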