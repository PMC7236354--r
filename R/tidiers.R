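#' Tidy a fitted impairment classifier
#'
#' One row per (class, term): the standardized-scale weight, plus the
#' training-set mean and SD the term was standardized with (intercept rows
#' carry `NA` scaler entries).
#'
#' @param x An `ica_mlr` from [fit_mlr()].
#' @param ... Unused.
#' @return A tibble with columns `class`, `term`, `estimate`, `scale_mean`,
#'   `scale_sd`.
#' @export
tidy.ica_mlr <- function(x, ...) {
  w <- x$weights
  long <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(w), class = rownames(w)),
    -"class", names_to = "term", values_to = "estimate"
  )
  dplyr::left_join(long,
                   dplyr::rename(x$scaler, term = "feature",
                                 scale_mean = "mean", scale_sd = "sd"),
                   by = "term")
}

#' @rdname tidy.ica_mlr
#' @return `glance()` returns a one-row tibble: `n`, `n_classes`,
#'   `n_features`, `reg_lambda`, `loglik`.
#' @export
glance.ica_mlr <- function(x, ...) {
  tibble::tibble(n = x$n, n_classes = length(x$classes),
                 n_features = length(x$feature_names),
                 reg_lambda = x$reg_lambda, loglik = x$loglik)
}

#' Tidy an ROC analysis
#'
#' @param x An `ica_roc` from [roc_analysis()].
#' @param ... Unused.
#' @return `tidy()` returns the threshold-by-threshold curve (`threshold`,
#'   `sensitivity`, `specificity`, `youden_j`); `glance()` a one-row summary
#'   (`auc`, `sensitivity`, `specificity`, `threshold`, `n_pos`, `n_neg`).
#' @export
tidy.ica_roc <- function(x, ...) {
  dplyr::mutate(x$curve, youden_j = .data$sensitivity + .data$specificity - 1)
}

#' @rdname tidy.ica_roc
#' @export
glance.ica_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, sensitivity = x$sensitivity,
                 specificity = x$specificity, threshold = x$threshold,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}
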