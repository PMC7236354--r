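#' Assemble the classifier feature table
#'
#' Joins scored sessions to subject demographics in the fixed feature order
#' the impairment classifier expects: composite score, accuracy trend, speed
#' trend, age, gender (0 = male, 1 = female), education (years). Sessions
#' flagged invalid by the scorer are refused.
#'
#' @param results An `ica_result` tibble from [score_session()] /
#'   [score_sessions()].
#' @param subjects A subject tibble with `subject_id`, `age`, `gender`
#'   (`"female"`/`"male"` or 0/1), `education`.
#' @return A tibble with `subject_id` and the six feature columns
#'   `ica_score`, `accuracy_trend`, `speed_trend`, `age`, `gender`,
#'   `education`.
#' @export
extract_features <- function(results, subjects) {
  assert_that(all(results$valid),
              "cannot extract features from invalid sessions (subjects: %s)",
              paste(results$subject_id[!results$valid], collapse = ", "))
  assert_that(all(results$subject_id %in% subjects$subject_id),
              "subjects table is missing demographic rows for some sessions")
  gender_num <- function(g) {
    if (is.numeric(g)) return(as.numeric(g))
    as.numeric(g == "female")
  }
  subj <- dplyr::mutate(
    subjects[c("subject_id", "age", "gender", "education")],
    gender = gender_num(.data$gender)
  )
  out <- dplyr::inner_join(
    results[c("subject_id", "ica_score", "accuracy_trend", "speed_trend")],
    subj, by = "subject_id"
  )
  feat <- out[feature_names()]
  assert_that(all(vapply(feat, function(x) all(is.finite(x)), logical(1))),
              "feature table contains non-finite values")
  out
}

#' @noRd
feature_names <- function() {
  c("ica_score", "accuracy_trend", "speed_trend", "age", "gender", "education")
}

#' Fit the L2-regularized multinomial logistic classifier
#'
#' Features are z-scored by their training means and population SDs
#' (n denominator), then class weights
#' are estimated by minimizing the per-observation mean negative multinomial
#' log-likelihood plus an L2 penalty `reg_lambda/2 * ||W||^2` on the
#' (non-intercept) weights. The softmax formulation is kept so the same
#' machinery covers more than two cognitive-status labels; the problem is
#' convex and solved deterministically by BFGS with an analytic gradient.
#' Averaging the likelihood makes the fitted boundary invariant to duplicating
#' the training set.
#'
#' @param x Feature matrix or tibble (columns in a fixed order), one row per
#'   subject.
#' @param y Class labels (factor or character); at least two subjects per
#'   class.
#' @param reg_lambda L2 penalty strength on standardized features
#'   (default 1.0).
#' @param tol Relative convergence tolerance of the optimizer.
#' @return An object of class `ica_mlr`: `weights` (classes x features+1
#'   matrix, intercept first), `scaler` (per-feature mean and sd), `classes`,
#'   `reg_lambda`, `loglik`, `n`.
#' @export
fit_mlr <- function(x, y, reg_lambda = 1.0, tol = 1e-10) {
  x <- as.matrix(as.data.frame(x))
  storage.mode(x) <- "double"
  y <- as.factor(y)
  classes <- levels(droplevels(y))
  y <- droplevels(y)
  n <- nrow(x)
  assert_that(length(classes) >= 2, "y contains a single class ('%s'); need at least two",
              classes[1])
  assert_that(all(table(y) >= 2), "need at least 2 subjects per class")
  assert_that(reg_lambda >= 0, "reg_lambda must be non-negative")

  mu <- colMeans(x)
  # population SD (n denominator): makes the fit invariant to duplicating
  # the training set, which sample SD would break
  sdev <- sqrt(colMeans(sweep(x, 2, mu)^2))
  const <- which(sdev == 0)
  assert_that(length(const) == 0, "constant feature(s): %s",
              paste(colnames(x)[const], collapse = ", "))
  z <- sweep(sweep(x, 2, mu), 2, sdev, "/")

  k <- length(classes)
  p <- ncol(z)
  ymat <- outer(y, classes, "==") * 1
  zi <- cbind(1, z)  # intercept column first

  unpack <- function(par) matrix(par, nrow = k, ncol = p + 1)
  objective <- function(par) {
    w <- unpack(par)
    eta <- zi %*% t(w)
    eta <- eta - apply(eta, 1, max)
    logp <- eta - log(rowSums(exp(eta)))
    -(1 / n) * sum(ymat * logp) + reg_lambda / 2 * sum(w[, -1]^2)
  }
  gradient <- function(par) {
    w <- unpack(par)
    eta <- zi %*% t(w)
    eta <- eta - apply(eta, 1, max)
    pr <- exp(eta)
    pr <- pr / rowSums(pr)
    g <- -(1 / n) * t(ymat - pr) %*% zi
    g[, -1] <- g[, -1] + reg_lambda * w[, -1]
    as.vector(g)
  }
  fit <- optim(rep(0, k * (p + 1)), objective, gradient, method = "BFGS",
               control = list(reltol = tol, maxit = 1000))
  w <- unpack(fit$par)
  dimnames(w) <- list(classes, c("(intercept)", colnames(x)))

  eta <- zi %*% t(w)
  logp <- eta - log(rowSums(exp(eta - apply(eta, 1, max)))) - apply(eta, 1, max)

  structure(
    list(weights = w,
         scaler = tibble::tibble(feature = colnames(x), mean = unname(mu),
                                 sd = unname(sdev)),
         classes = classes, reg_lambda = reg_lambda,
         loglik = sum(ymat * logp), n = n,
         feature_names = colnames(x)),
    class = "ica_mlr"
  )
}

#' @export
print.ica_mlr <- function(x, ...) {
  cat(sprintf("<ica_mlr> %d-class softmax classifier, %d features, lambda = %g, n = %d\n",
              length(x$classes), length(x$feature_names), x$reg_lambda, x$n))
  print(round(x$weights, 4))
  invisible(x)
}

#' Class probabilities and predicted labels from a fitted classifier
#'
#' Applies the training-set standardization stored in the model, then the
#' softmax over class scores. The predicted label is the argmax class and the
#' reported probability is that class's softmax value (the engine's
#' confidence).
#'
#' @param model An `ica_mlr` from [fit_mlr()].
#' @param newdata Matrix or tibble with the model's feature columns.
#' @return A tibble with `label`, `probability`, and one `p_<class>` column
#'   per class.
#' @export
predict_proba <- function(model, newdata) {
  assert_that(inherits(model, "ica_mlr"), "not an ica_mlr model")
  newdata <- as.data.frame(newdata)
  missing <- setdiff(model$feature_names, names(newdata))
  assert_that(length(missing) == 0, "newdata is missing feature(s): %s",
              paste(missing, collapse = ", "))
  x <- as.matrix(newdata[model$feature_names])
  storage.mode(x) <- "double"
  z <- sweep(sweep(x, 2, model$scaler$mean), 2, model$scaler$sd, "/")
  eta <- cbind(1, z) %*% t(model$weights)
  eta <- eta - apply(eta, 1, max)
  pr <- exp(eta)
  pr <- pr / rowSums(pr)
  colnames(pr) <- model$classes
  idx <- max.col(pr, ties.method = "first")
  out <- tibble::tibble(
    label = model$classes[idx],
    probability = pr[cbind(seq_len(nrow(pr)), idx)]
  )
  dplyr::bind_cols(out, tibble::as_tibble(pr, .name_repair = ~ paste0("p_", .x)))
}

#' Leave-one-out cross-validated class probabilities
#'
#' Every subject is scored by a classifier fitted to all other subjects
#' (standardization statistics recomputed per fold, so no information leaks
#' from the held-out subject). Deterministic; independent of row order.
#'
#' @param x Feature matrix or tibble.
#' @param y Class labels.
#' @param positive Class whose probability is reported (default: the second
#'   level of `y`).
#' @param reg_lambda Passed to [fit_mlr()].
#' @return A tibble with one row per subject: `row`, `truth`, `prob`
#'   (held-out probability of the `positive` class), `label` (held-out
#'   predicted label).
#' @export
loocv <- function(x, y, reg_lambda = 1.0, positive = NULL) {
  x <- as.data.frame(x)
  y <- as.factor(y)
  n <- nrow(x)
  assert_that(n >= 3, "leave-one-out needs at least 3 subjects (got %d)", n)
  positive <- positive %||% levels(y)[length(levels(y))]
  assert_that(positive %in% levels(y), "positive class '%s' not in labels", positive)

  folds <- purrr::map(seq_len(n), function(i) {
    m <- fit_mlr(x[-i, , drop = FALSE], y[-i], reg_lambda = reg_lambda)
    pr <- predict_proba(m, x[i, , drop = FALSE])
    tibble::tibble(row = i, truth = as.character(y[i]),
                   prob = pr[[paste0("p_", positive)]], label = pr$label)
  })
  out <- dplyr::bind_rows(folds)
  attr(out, "positive") <- positive
  out
}

#' ROC curve, AUC and Youden-optimal operating point
#'
#' Sweeps a decision threshold over the unique predicted probabilities,
#' computing sensitivity and specificity for the positive class at each;
#' the AUC is the trapezoidal area under the resulting curve (identical to
#' the pairwise concordance probability with ties counted one half) and the
#' reported operating point maximizes Youden's J = sensitivity +
#' specificity - 1.
#'
#' @param probs Predicted probabilities of the positive class.
#' @param labels True labels: logical, 0/1, or characters matched against
#'   `positive`.
#' @param positive The positive class value (default `1`/`TRUE`; required for
#'   character labels).
#' @return An object of class `ica_roc`: list with `curve` (tibble of
#'   `threshold`, `sensitivity`, `specificity`), `auc`, `sensitivity`,
#'   `specificity`, `threshold` (Youden point), `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_analysis(c(0.9, 0.8, 0.2, 0.4), c(1, 0, 0, 1))$auc
roc_analysis <- function(probs, labels, positive = NULL) {
  assert_that(length(probs) == length(labels), "probs and labels differ in length")
  if (is.character(labels) || is.factor(labels)) {
    assert_that(!is.null(positive),
                "positive class must be named for character labels")
    pos <- as.character(labels) == positive
  } else {
    pos <- as.logical(labels)
  }
  assert_that(any(pos) && any(!pos), "both classes must be present in labels")

  thresholds <- sort(unique(probs))
  # classify positive when prob >= threshold; add a supra-maximal threshold
  # so the curve reaches (0, 0)
  thresholds <- c(thresholds, max(probs) + 1)
  curve <- tibble::tibble(
    threshold = thresholds,
    sensitivity = vapply(thresholds, function(t) mean(probs[pos] >= t), 0),
    specificity = vapply(thresholds, function(t) mean(probs[!pos] < t), 0)
  )
  fpr <- 1 - curve$specificity
  tpr <- curve$sensitivity
  ord <- order(fpr, tpr)
  fpr <- c(0, fpr[ord], 1)
  tpr <- c(0, tpr[ord], 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

  j <- curve$sensitivity + curve$specificity - 1
  best <- which.max(j)
  structure(
    list(curve = curve, auc = auc,
         sensitivity = curve$sensitivity[best],
         specificity = curve$specificity[best],
         threshold = curve$threshold[best],
         n_pos = sum(pos), n_neg = sum(!pos)),
    class = "ica_roc"
  )
}

#' @export
print.ica_roc <- function(x, ...) {
  cat(sprintf("<ica_roc> AUC = %.1f%% (n = %d pos / %d neg); Youden point: sensitivity %.1f%%, specificity %.1f%% at threshold %.3f\n",
              100 * x$auc, x$n_pos, x$n_neg, 100 * x$sensitivity,
              100 * x$specificity, x$threshold))
  invisible(x)
}

#' Serialize or restore a fitted classifier as JSON
#'
#' @param model An `ica_mlr`.
#' @param path File path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  assert_that(inherits(model, "ica_mlr"), "not an ica_mlr model")
  jsonlite::write_json(
    list(format_version = 1L, classes = model$classes,
         feature_names = model$feature_names,
         weights = model$weights, scaler = as.list(model$scaler),
         reg_lambda = model$reg_lambda, loglik = model$loglik, n = model$n),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- matrix(unlist(raw$weights), nrow = length(raw$classes), byrow = FALSE)
  # rowmajor written: read_json simplifies to a classes x (p+1) matrix already
  if (is.matrix(raw$weights)) w <- raw$weights
  dimnames(w) <- list(raw$classes, c("(intercept)", raw$feature_names))
  structure(
    list(weights = w,
         scaler = tibble::as_tibble(raw$scaler),
         classes = raw$classes, reg_lambda = raw$reg_lambda,
         loglik = raw$loglik, n = raw$n, feature_names = raw$feature_names),
    class = "ica_mlr"
  )
}
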