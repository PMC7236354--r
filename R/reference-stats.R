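#' Published reference summary statistics for MS and HC validation cohorts
#'
#' Group-level means and standard deviations reported for a validation study
#' of the rapid-categorization test: the three BICAMS subtests (SDMT, BVMT-R,
#' CVLT-II) and the test's own accuracy, speed and composite score, for 91
#' multiple-sclerosis patients and 83 matched healthy controls. These numbers
#' are the default calibration targets of [simulate_cohort()] and the worked
#' inputs of [cohens_d_summary()].
#'
#' @return A tibble with one row per (measure, group): columns `measure`,
#'   `group` (`"MS"`/`"HC"`), `n`, `mean`, `sd`.
#' @export
#' @examples
#' reference_group_stats()
reference_group_stats <- function() {
  tibble::tribble(
    ~measure,    ~group, ~n,  ~mean, ~sd,
    "sdmt",      "MS",   91L, 41.04, 11.02,
    "sdmt",      "HC",   83L, 54.73, 9.77,
    "bvmtr",     "MS",   91L, 21.89, 6.95,
    "bvmtr",     "HC",   83L, 23.69, 5.17,
    "cvlt2",     "MS",   91L, 48.96, 11.13,
    "cvlt2",     "HC",   83L, 58.28, 6.59,
    "ica_score", "MS",   91L, 63.67, 13.30,
    "ica_score", "HC",   83L, 78.43, 9.86,
    "accuracy",  "MS",   91L, 84.97, 11.66,
    "accuracy",  "HC",   83L, 89.57, 5.79,
    "speed",     "MS",   91L, 74.54, 12.26,
    "speed",     "HC",   83L, 87.76, 10.11
  )
}

#' Reference cohort demographics
#'
#' Demographic summary statistics (age, education, percent female) for the
#' same two validation groups as [reference_group_stats()]; defaults for the
#' demographic sampler in [simulate_cohort()].
#'
#' @return A tibble with columns `group`, `n`, `age_mean`, `age_sd`,
#'   `edu_mean`, `edu_sd`, `pct_female`.
#' @export
reference_demographics <- function() {
  tibble::tribble(
    ~group, ~n,  ~age_mean, ~age_sd, ~edu_mean, ~edu_sd, ~pct_female,
    "MS",   91L, 37.24,     10.2,    14.21,     3.16,    0.82,
    "HC",   83L, 36.00,     10.0,    14.81,     2.50,    0.70
  )
}

#' Default normative table for impairment labelling
#'
#' Per-subtest normative means and SDs used by [label_impairment()]. The
#' default is the healthy-control group statistics from
#' [reference_group_stats()]; studies with external norms should supply their
#' own table.
#'
#' @return A tibble with columns `measure`, `norm_mean`, `norm_sd` covering
#'   `sdmt`, `bvmtr`, `cvlt2`.
#' @export
#' @examples
#' default_norms()
default_norms <- function() {
  ref <- reference_group_stats()
  ref <- ref[ref$group == "HC" & ref$measure %in% c("sdmt", "bvmtr", "cvlt2"), ]
  tibble::tibble(
    measure = ref$measure,
    norm_mean = ref$mean,
    norm_sd = ref$sd
  )
}

#' Read or write a norms table as JSON
#'
#' @param path File path.
#' @param norms A norms tibble as returned by [default_norms()].
#' @return `read_norms()` returns the norms tibble; `write_norms()` returns
#'   `path` invisibly.
#' @export
read_norms <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  assert_that(
    all(c("measure", "norm_mean", "norm_sd") %in% names(raw)),
    "norms file %s must have fields measure, norm_mean, norm_sd", path
  )
  out <- tibble::as_tibble(raw[c("measure", "norm_mean", "norm_sd")])
  assert_that(all(out$norm_sd > 0), "norms file %s: norm_sd must be > 0", path)
  out
}

#' @rdname read_norms
#' @export
write_norms <- function(norms, path) {
  jsonlite::write_json(as.list(norms), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
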