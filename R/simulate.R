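#' Per-subject response-model parameters
#'
#' The generative model behind the synthetic subjects: accuracy follows a
#' lapse-diluted logistic in ability minus logit-scaled image difficulty,
#' `P(correct) = (1 - lapse) * plogis(ability - dscale*(d - 0.5)) + lapse/2`;
#' reaction times are shifted lognormal,
#' `RT = rt_shift_ms + exp(rt_mu + gamma*d + drift + eps)` with
#' `eps ~ N(0, rt_sigma^2)`; with probability `outlier_prob` a trial's RT is
#' replaced by a uniform contaminant on [3000, 10000] ms (exercising the
#' fence/validity machinery). The optional fatigue drifts move ability (logits
#' per trial) and log-RT (log-ms per trial) linearly over the time course of
#' the test, centered so the session means stay at `ability` / `rt_mu`.
#'
#' @param ability Categorization ability in logit units.
#' @param rt_mu Location of the lognormal RT component (log-ms).
#' @param rt_sigma Lognormal scale (> 0).
#' @param rt_shift_ms Non-decision shift (ms, >= 0).
#' @param lapse_prob Lapse rate in [0, 0.2]: a lapsed trial is a coin flip.
#' @param outlier_prob Contaminant probability in [0, 0.5].
#' @param ability_drift Per-trial linear change in ability (logits/trial).
#' @param rt_drift Per-trial linear change in log-RT (log-ms/trial).
#' @return A one-row tibble of validated parameters.
#' @export
subject_params <- function(ability, rt_mu, rt_sigma = 0.25, rt_shift_ms = 200,
                           lapse_prob = 0.02, outlier_prob = 0.01,
                           ability_drift = 0, rt_drift = 0) {
  assert_that(all(rt_sigma > 0), "rt_sigma must be > 0")
  assert_that(all(rt_shift_ms >= 0), "rt_shift_ms must be >= 0")
  assert_that(all(lapse_prob >= 0 & lapse_prob <= 0.2), "lapse_prob must be in [0, 0.2]")
  assert_that(all(outlier_prob >= 0 & outlier_prob <= 0.5), "outlier_prob must be in [0, 0.5]")
  tibble::tibble(ability = ability, rt_mu = rt_mu, rt_sigma = rt_sigma,
                 rt_shift_ms = rt_shift_ms, lapse_prob = lapse_prob,
                 outlier_prob = outlier_prob, ability_drift = ability_drift,
                 rt_drift = rt_drift)
}

#' Simulator configuration
#'
#' Study-scale defaults: 91 patients and 83 controls with demographics,
#' battery-score and test-score distributions set to the published group
#' summary statistics bundled in [reference_group_stats()] and
#' [reference_demographics()]. A single latent cognitive factor drives the
#' battery subtests (loading `bicams_loading`), the task parameters, and the
#' fatigue drifts; it loads negatively on age and positively on education so
#' the simulated score-age and score-education correlations match the
#' published ones. Serum NfL for patients is linear in the composite score
#' plus Gaussian noise, with the noise SD set so the population correlation is
#' about -0.79.
#'
#' @param n_ms,n_hc Group sizes.
#' @param ms_params,hc_params Group parameter distributions (class
#'   `subject_params_dist`), by default pre-calibrated to the bundled
#'   reference score table; see [calibrate_group_params()].
#' @param demographics Demographic targets, as [reference_demographics()].
#' @param bicams_loading Latent-factor loading of each battery subtest.
#' @param age_loading,edu_loading Latent-factor loadings of (standardized)
#'   age and education.
#' @param acc_fatigue,rt_fatigue Fatigue-drift scales: per-trial ability /
#'   log-RT drift equals `-acc_fatigue * plogis(-z)` / `rt_fatigue *
#'   plogis(-z)` for latent score z, so low-ability subjects tire more.
#' @param nfl_beta0,nfl_beta1,nfl_noise_sd NfL model (intercept, slope on the
#'   composite score — negative, noise SD).
#' @param edss_mean,edss_sd Patient disability-score distribution.
#' @param stim_seed,pool_seed Seeds of the shared stimulus set and mask pool.
#' @param seed Master seed; fixes the whole cohort bit-exactly.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_ms = 91, n_hc = 83,
                       ms_params = group_params_defaults("MS"),
                       hc_params = group_params_defaults("HC"),
                       demographics = reference_demographics(),
                       bicams_loading = 0.8, age_loading = 0.45,
                       edu_loading = 0.25,
                       acc_fatigue = 0.012, rt_fatigue = 0.002,
                       nfl_beta0 = 65, nfl_beta1 = -0.62, nfl_noise_sd = 6.4,
                       edss_mean = 1.27, edss_sd = 1.8,
                       stim_seed = 101, pool_seed = 202, seed = 1) {
  assert_that(n_ms > 0 && n_hc > 0, "group sizes must be positive")
  assert_that(nfl_beta1 <= 0, "nfl_beta1 must be non-positive (higher scores, lower NfL)")
  assert_that(bicams_loading > 0 && bicams_loading < 1, "bicams_loading must be in (0,1)")
  assert_that(age_loading^2 + edu_loading^2 < 1, "demographic loadings too large")
  structure(
    list(n_ms = n_ms, n_hc = n_hc, ms_params = ms_params, hc_params = hc_params,
         demographics = demographics, bicams_loading = bicams_loading,
         age_loading = age_loading, edu_loading = edu_loading,
         acc_fatigue = acc_fatigue, rt_fatigue = rt_fatigue,
         nfl_beta0 = nfl_beta0, nfl_beta1 = nfl_beta1,
         nfl_noise_sd = nfl_noise_sd, edss_mean = edss_mean, edss_sd = edss_sd,
         stim_seed = stim_seed, pool_seed = pool_seed, seed = seed,
         dscale = 4, rt_gamma = 0.3),
    class = "sim_config"
  )
}

#' Group-level parameter distributions pre-calibrated to the reference table
#'
#' Means and latent spreads of ability and log-RT per group, obtained by
#' running [calibrate_group_params()] against the bundled reference score
#' means/SDs (patients 63.67 +- 13.30, controls 78.43 +- 9.86) at the default
#' model constants.
#'
#' @param group `"MS"` or `"HC"`.
#' @return A `subject_params_dist` list.
#' @export
group_params_defaults <- function(group = c("MS", "HC")) {
  group <- match.arg(group)
  # values produced by calibrate_group_params() at the defaults; see the
  # methods vignette for the procedure
  if (group == "MS") {
    new_subject_params_dist(ability_mu = 2.4034, ability_spread = 1.0465,
                            rtmu_mu = 5.9250, rtmu_spread = 0.2279)
  } else {
    new_subject_params_dist(ability_mu = 2.8712, ability_spread = 0.8786,
                            rtmu_mu = 5.4773, rtmu_spread = 0.1913)
  }
}

#' @noRd
new_subject_params_dist <- function(ability_mu, ability_spread, rtmu_mu,
                                    rtmu_spread, rt_sigma = 0.25,
                                    rt_shift_ms = 200, lapse_prob = 0.02,
                                    outlier_prob = 0.01, achieved = NULL) {
  structure(
    list(ability_mu = ability_mu, ability_spread = ability_spread,
         rtmu_mu = rtmu_mu, rtmu_spread = rtmu_spread, rt_sigma = rt_sigma,
         rt_shift_ms = rt_shift_ms, lapse_prob = lapse_prob,
         outlier_prob = outlier_prob, achieved = achieved),
    class = "subject_params_dist"
  )
}

#' @export
print.subject_params_dist <- function(x, ...) {
  cat(sprintf("<subject_params_dist> ability %.3f (spread %.3f), log-RT %.3f (spread %.3f)\n",
              x$ability_mu, x$ability_spread, x$rtmu_mu, x$rtmu_spread))
  if (!is.null(x$achieved)) {
    cat(sprintf("  achieved score moments: mean %.2f, sd %.2f\n",
                x$achieved$mean, x$achieved$sd))
  }
  invisible(x)
}

# Subject params from latent scores under a group distribution + fatigue model.
#' @noRd
params_from_latent <- function(dist, z, cfg) {
  fatigue <- plogis(-z)
  subject_params(
    ability = dist$ability_mu + dist$ability_spread * z,
    rt_mu = dist$rtmu_mu - dist$rtmu_spread * z,
    rt_sigma = dist$rt_sigma, rt_shift_ms = dist$rt_shift_ms,
    lapse_prob = dist$lapse_prob, outlier_prob = dist$outlier_prob,
    ability_drift = -cfg$acc_fatigue * fatigue,
    rt_drift = cfg$rt_fatigue * fatigue
  )
}

# Vectorized trial model: n subjects (rows of `params`) x m trials.
# `difficulty` is a length-m vector (one presentation order shared by all
# rows). Returns logical `correct` and numeric `rt` matrices. Uses the
# current RNG stream.
#' @noRd
sim_trials_matrix <- function(params, difficulty, dscale = 4, rt_gamma = 0.3) {
  n <- nrow(params)
  m <- length(difficulty)
  tc <- seq_len(m) - (m + 1) / 2  # centered trial index
  eta <- outer(params$ability, rep(1, m)) +
    outer(params$ability_drift, tc) -
    outer(rep(1, n), dscale * (difficulty - 0.5))
  p <- (1 - params$lapse_prob) * plogis(eta) + params$lapse_prob / 2
  correct <- matrix(runif(n * m), n, m) < p

  logrt <- outer(params$rt_mu, rep(1, m)) +
    outer(rep(1, n), rt_gamma * difficulty) +
    outer(params$rt_drift, tc) +
    matrix(rnorm(n * m, sd = rep(params$rt_sigma, m)), n, m)
  rt <- params$rt_shift_ms + exp(logrt)
  contaminate <- matrix(runif(n * m), n, m) < params$outlier_prob
  rt[contaminate] <- runif(sum(contaminate), 3000, 10000)
  list(correct = correct, rt = rt)
}

# Fast scoring of simulated trial matrices with the same fences / formulas as
# score_session(); used by the calibration loop where building full session
# objects would dominate the run time.
#' @noRd
score_trials_fast <- function(correct, rt, cfg = scoring_config()) {
  n <- nrow(correct)
  out <- vapply(seq_len(n), function(i) {
    f <- remove_rt_outliers(rt[i, ], w = cfg$whisker_w)
    keep <- rt[i, ] >= f$lower & rt[i, ] <= f$upper
    acc <- 100 * sum(correct[i, keep]) / sum(keep)
    cr <- rt[i, keep & correct[i, ]]
    sp <- if (length(cr) > 0) compute_speed(mean(cr), cfg) else 0
    c(acc, sp, compute_ica_score(sp, acc))
  }, numeric(3))
  tibble::tibble(accuracy = out[1, ], speed = out[2, ], ica_score = out[3, ])
}

# One fast Monte-Carlo evaluation of a group distribution: simulate n_sim
# subjects' main tasks and score them.
#' @noRd
eval_params_dist <- function(dist, cfg, difficulty, n_sim, seed) {
  with_seed(seed, {
    z <- rnorm(n_sim)
    params <- params_from_latent(dist, z, cfg)
    tr <- sim_trials_matrix(params, difficulty, cfg$dscale, cfg$rt_gamma)
    score_trials_fast(tr$correct, tr$rt)
  })
}

#' Simulate one test administration for a subject
#'
#' Generates a full session under the response model in [subject_params()]:
#' the first 10-image practice block, a second one if the first fails the
#' above-chance gate, and — unless both fail — the 100 main trials in the
#' schedule's order. Responses are always given (the simulated subject never
#' times out); a lapsed or incorrect trial responds with the wrong label.
#'
#' @param params A one-row [subject_params()] tibble.
#' @param stimset The `stimulus_set` (supplies the practice images).
#' @param schedule A `trial_schedule` for the main phase.
#' @param seed Integer seed; the session is bit-identical for a fixed seed.
#' @param subject_id Subject identifier stored in the session.
#' @return An `ica_session`.
#' @export
simulate_session <- function(params, stimset, schedule, seed,
                             subject_id = "sim_subject") {
  assert_that(nrow(params) == 1, "params must be a single-subject row")
  validate_stimulus_set(stimset)

  with_seed(seed, {
    man <- stimset$manifest
    block1 <- sim_block(params, man[man$role == "practice_1", ], "practice_1")
    records <- block1
    if (evaluate_practice(block1) == "pass") {
      outcome <- "passed_first"
    } else {
      block2 <- sim_block(params, man[man$role == "practice_2", ], "practice_2")
      records <- dplyr::bind_rows(records, block2)
      outcome <- resolve_practice_outcome(block1, block2)
    }
    if (outcome != "aborted") {
      main <- sim_main_block(params, schedule)
      records <- dplyr::bind_rows(records, main)
    }
    new_session(subject_id, records, outcome,
                schedule_ref = attr(schedule, "schedule_id") %||% NA_character_)
  })
}

#' @noRd
sim_block <- function(params, manifest, phase) {
  n <- nrow(manifest)
  tr <- sim_trials_matrix(params, manifest$difficulty)
  make_records(seq_len(n), manifest$image_id, manifest$label, phase,
               drop(tr$correct), drop(tr$rt))
}

#' @noRd
sim_main_block <- function(params, schedule) {
  tr <- sim_trials_matrix(params, schedule$difficulty)
  make_records(schedule$trial_index, schedule$image_id, schedule$label, "main",
               drop(tr$correct), drop(tr$rt))
}

#' @noRd
make_records <- function(trial_index, image_id, true_label, phase, correct, rt) {
  other <- ifelse(true_label == "animal", "non_animal", "animal")
  tibble::tibble(
    trial_index = trial_index, image_id = image_id, true_label = true_label,
    phase = phase, response = ifelse(correct, true_label, other),
    correct = correct, rt_ms = rt
  )
}

#' Simulate a two-group study cohort
#'
#' Samples demographics, battery subtest scores, disability scores and task
#' parameters for `n_ms` patients and `n_hc` controls under the latent-factor
#' model of [sim_config()]; simulates and scores one full test administration
#' per subject; and attaches a serum NfL value (patients only) linear in the
#' scored composite. Impairment ground truth is obtained by applying
#' [label_impairment()] with [default_norms()] to the generated subtest
#' scores.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `ica_cohort`: `subjects` (one row per subject:
#'   demographics, subtest scores, `edss`, `nfl`, `disease_duration`,
#'   `impaired`, `completed`), `params` (the per-subject generative
#'   parameters), `sessions` (named list of `ica_session`), `results` (scored
#'   first administration, one row per completed session — a subject who
#'   fails both practice gates is aborted and has no score or NfL value),
#'   `stimset`, `pool`.
#' @export
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(sim_config(n_ms = 10, n_hc = 10, seed = 3))
#' dplyr::count(cohort$subjects, group, impaired)
#' }
simulate_cohort <- function(cfg = sim_config()) {
  assert_that(inherits(cfg, "sim_config"), "cfg must be a sim_config()")
  stimset <- generate_stimulus_set(seed = cfg$stim_seed, size_px = 32)
  pool <- generate_mask_pool(64, seed = cfg$pool_seed)

  with_seed(cfg$seed, {
    groups <- c(rep("MS", cfg$n_ms), rep("HC", cfg$n_hc))
    n <- length(groups)
    demo <- cfg$demographics
    ref <- reference_group_stats()

    z_age <- rnorm(n)
    z_edu <- rnorm(n)
    z0 <- rnorm(n)
    resid <- sqrt(1 - cfg$age_loading^2 - cfg$edu_loading^2)
    z_c <- -cfg$age_loading * z_age + cfg$edu_loading * z_edu + resid * z0

    di <- match(groups, demo$group)
    age <- pmin(65, pmax(18, demo$age_mean[di] + demo$age_sd[di] * z_age))
    education <- pmax(5, demo$edu_mean[di] + demo$edu_sd[di] * z_edu)
    gender <- ifelse(runif(n) < demo$pct_female[di], "female", "male")

    subtest <- function(measure) {
      i <- match(paste(measure, groups), paste(ref$measure, ref$group))
      ref$mean[i] + ref$sd[i] * (cfg$bicams_loading * z_c +
                                   sqrt(1 - cfg$bicams_loading^2) * rnorm(n))
    }
    sdmt <- subtest("sdmt")
    bvmtr <- subtest("bvmtr")
    cvlt2 <- subtest("cvlt2")

    ms <- groups == "MS"
    edss <- ifelse(ms,
                   pmin(10, pmax(0, cfg$edss_mean +
                                   cfg$edss_sd * (-0.5 * z_c + sqrt(0.75) * rnorm(n)))),
                   NA_real_)
    disease_duration <- ifelse(ms, pmax(0.2, rnorm(n, 6.8, 4)), NA_real_)

    params <- dplyr::bind_rows(purrr::map(seq_len(n), function(i) {
      dist <- if (ms[i]) cfg$ms_params else cfg$hc_params
      params_from_latent(dist, z_c[i], cfg)
    }))
    params$subject_id <- sprintf("S%03d", seq_len(n))

    session_seeds <- sample.int(.Machine$integer.max - 1, n)
    order_seeds <- sample.int(.Machine$integer.max - 1, n)
    sessions <- purrr::map(seq_len(n), function(i) {
      sched <- build_trial_schedule(stimset, pool, order_seed = order_seeds[i])
      simulate_session(params[i, ], stimset, sched, seed = session_seeds[i],
                       subject_id = params$subject_id[i])
    })
    names(sessions) <- params$subject_id

    completed <- vapply(sessions, function(s) s$practice_outcome != "aborted",
                        logical(1))
    results <- score_sessions(sessions[completed])
    ica_by_subj <- results$ica_score[match(params$subject_id, results$subject_id)]
    nfl <- ifelse(ms & completed,
                  pmax(0.5, cfg$nfl_beta0 + cfg$nfl_beta1 * ica_by_subj +
                         rnorm(n, 0, cfg$nfl_noise_sd)),
                  NA_real_)

    subjects <- tibble::tibble(
      subject_id = params$subject_id, group = groups, age = age,
      gender = gender, education = education,
      sdmt = sdmt, bvmtr = bvmtr, cvlt2 = cvlt2,
      edss = edss, nfl = nfl, disease_duration = disease_duration,
      latent = z_c, completed = completed
    )
    subjects$impaired <- label_impairment(subjects, default_norms())

    structure(list(subjects = subjects, params = params, sessions = sessions,
                   results = results, stimset = stimset, pool = pool,
                   config = cfg),
              class = "ica_cohort")
  })
}

#' @export
print.ica_cohort <- function(x, ...) {
  cat(sprintf("<ica_cohort> %d subjects (%d MS / %d HC), %d sessions, %.0f%% of MS impaired\n",
              nrow(x$subjects), sum(x$subjects$group == "MS"),
              sum(x$subjects$group == "HC"), length(x$sessions),
              100 * mean(x$subjects$impaired[x$subjects$group == "MS"])))
  invisible(x)
}

#' Simulate a repeat administration of the test for an existing cohort
#'
#' Re-tests every subject with the same images and generative parameters but a
#' fresh random presentation order and fresh response noise — the model of a
#' retest visit under a stable underlying state (no learning effect).
#'
#' @param cohort An `ica_cohort`.
#' @param seed Integer seed for the retest administration.
#' @param subject_ids Subjects to re-test (default: all).
#' @return A scored result tibble (as [score_sessions()]) for the retest.
#' @export
simulate_retest <- function(cohort, seed, subject_ids = NULL) {
  assert_that(inherits(cohort, "ica_cohort"), "not an ica_cohort")
  ids <- subject_ids %||% cohort$params$subject_id
  idx <- match(ids, cohort$params$subject_id)
  assert_that(!anyNA(idx), "unknown subject ids")
  with_seed(seed, {
    session_seeds <- sample.int(.Machine$integer.max - 1, length(idx))
    order_seeds <- sample.int(.Machine$integer.max - 1, length(idx))
    sessions <- purrr::map(seq_along(idx), function(j) {
      sched <- build_trial_schedule(cohort$stimset, cohort$pool,
                                    order_seed = order_seeds[j])
      simulate_session(cohort$params[idx[j], ], cohort$stimset, sched,
                       seed = session_seeds[j],
                       subject_id = ids[j])
    })
    completed <- vapply(sessions, function(s) s$practice_outcome != "aborted",
                        logical(1))
    score_sessions(sessions[completed])
  })
}

#' Calibrate a group's parameter distribution to target score moments
#'
#' Iterated moment matching: the group's mean ability and mean log-RT are
#' moved (damped Newton / log-secant updates) until the simulated composite
#' score mean hits `target_mean`, while the latent spread is rescaled until
#' the simulated SD hits `target_sd`. Each iteration simulates `n_sim`
#' synthetic subjects' main tasks under common random numbers and scores them
#' with the production fences and formulas. The split of the mean target
#' between the accuracy and speed components is set by `target_accuracy`
#' (percent).
#'
#' @param target_mean,target_sd Target composite-score moments (mean in
#'   (0, 100)).
#' @param cfg A [sim_config()] providing the fixed model constants.
#' @param target_accuracy Target mean accuracy component (percent).
#' @param n_sim Simulated subjects per iteration (the final verification uses
#'   `3 * n_sim`).
#' @param tol_mean,tol_sd Acceptance tolerances on the achieved moments.
#' @param max_iter Maximum iterations before declaring the target
#'   unattainable.
#' @param seed Base seed; each iteration draws a fresh replicate so the
#'   matched moments are not tied to one Monte Carlo sample.
#' @return A `subject_params_dist` whose `achieved` element holds the final
#'   moments (checked on an independent replicate). Signals
#'   `icatest_calibration_error` with the achieved moments when the target
#'   cannot be met under the parameter bounds.
#' @export
calibrate_group_params <- function(target_mean, target_sd, cfg = sim_config(),
                                   target_accuracy = NULL, n_sim = 3000,
                                   tol_mean = 1.0, tol_sd = 1.5,
                                   max_iter = 50, seed = 42) {
  assert_that(target_mean > 0 && target_mean < 100,
              "target_mean must be in (0, 100)")
  assert_that(target_sd >= 0, "target_sd must be >= 0")
  scfg <- scoring_config()

  # implied component targets
  target_accuracy <- target_accuracy %||% min(96.5, 100 * sqrt(target_mean / 100) * 1.07)
  target_speed <- 100 * target_mean / target_accuracy
  if (target_speed > 99.9 || target_sd < 0.5) {
    rlang::abort(sprintf(
      "calibration target (mean %.2f, sd %.2f) is unattainable: the capped speed scale cannot reach it",
      target_mean, target_sd), class = "icatest_calibration_error")
  }

  difficulty <- with_seed(7, sample(rep(seq(0.05, 0.95, length.out = 50), 2)))

  # analytic initialization
  ability <- stats::uniroot(function(a) {
    mean((1 - 0.02) * plogis(a - cfg$dscale * (difficulty - 0.5)) + 0.01) -
      target_accuracy / 100
  }, c(-5, 12))$root
  mean_rt_target <- scfg$tau_ms * (scfg$offset - log(target_speed / 100))
  rtmu <- log(max(20, mean_rt_target - 200)) - cfg$rt_gamma * 0.5 - 0.25^2 / 2
  spread <- 1

  bounds_ability <- c(-4, 9)
  bounds_rtmu <- c(log(40), log(4000))
  dist <- NULL
  achieved <- NULL
  hits <- 0L  # consecutive in-tolerance iterations (fresh replicate each)

  for (it in seq_len(max_iter)) {
    dist <- new_subject_params_dist(
      ability_mu = ability, ability_spread = 0.62 * spread,
      rtmu_mu = rtmu, rtmu_spread = 0.135 * spread
    )
    sc <- eval_params_dist(dist, cfg, difficulty, n_sim, seed + it)
    achieved <- list(mean = mean(sc$ica_score), sd = sd(sc$ica_score),
                     accuracy = mean(sc$accuracy), speed = mean(sc$speed))

    ok_mean <- abs(achieved$mean - target_mean) <= 0.5 * tol_mean
    ok_sd <- abs(achieved$sd - target_sd) <= 0.5 * tol_sd
    hits <- if (ok_mean && ok_sd) hits + 1L else 0L
    if (hits >= 2L) break

    # accuracy knob: damped Newton with a logistic-slope estimate
    pbar <- min(0.98, max(0.5, achieved$accuracy / 100))
    slope <- max(3, 100 * pbar * (1 - pbar))
    ability <- ability + 0.8 * (target_accuracy - achieved$accuracy) / slope
    # speed knob: log-secant on the shifted-lognormal mean RT
    speed_needed <- min(99.5, max(1, 100 * target_mean / max(achieved$accuracy, 1)))
    rt_needed <- scfg$tau_ms * (scfg$offset - log(speed_needed / 100))
    rt_current <- scfg$tau_ms * (scfg$offset - log(min(achieved$speed, 99.9) / 100))
    rt_needed <- max(rt_needed, dist$rt_shift_ms + 20)
    rt_current <- max(rt_current, dist$rt_shift_ms + 20)
    rtmu <- rtmu + 0.9 * log((rt_needed - dist$rt_shift_ms) /
                               (rt_current - dist$rt_shift_ms))
    # spread knob: ratio update
    spread <- spread * (target_sd / max(achieved$sd, 0.1))^0.7
    spread <- min(max(spread, 0.02), 6)

    saturated_a <- ability <= bounds_ability[1] || ability >= bounds_ability[2]
    saturated_r <- rtmu <= bounds_rtmu[1] || rtmu >= bounds_rtmu[2]
    ability <- min(max(ability, bounds_ability[1]), bounds_ability[2])
    rtmu <- min(max(rtmu, bounds_rtmu[1]), bounds_rtmu[2])
    if (saturated_a && saturated_r) break
  }
  converged <- hits >= 2L

  # verify on a larger independent replicate
  check <- eval_params_dist(dist, cfg, difficulty, 3 * n_sim, seed + max_iter + 1)
  achieved <- list(mean = mean(check$ica_score), sd = sd(check$ica_score),
                   accuracy = mean(check$accuracy), speed = mean(check$speed))
  if (!converged || abs(achieved$mean - target_mean) > tol_mean ||
      abs(achieved$sd - target_sd) > tol_sd) {
    rlang::abort(
      sprintf("calibration to (mean %.2f, sd %.2f) failed: achieved mean %.2f, sd %.2f",
              target_mean, target_sd, achieved$mean, achieved$sd),
      class = "icatest_calibration_error",
      achieved = achieved
    )
  }
  dist$achieved <- achieved
  dist
}
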