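# Cohort configuration and class-conditional effect defaults.

#' Default class-conditional generator effects
#'
#' Distribution parameters for each diagnostic class used by
#' [generate_cohort()]. Defaults encode the marker directions the diagnosis
#' rules rely on: relative to healthy participants, the MCI class has lower
#' daily activity, shorter and rarer excursions from home, lower EMA
#' compliance and mental-sharpness ratings with higher day-to-day variance,
#' a lower n-back starting accuracy and plateau with a steeper learning ramp
#' and noisier daily scores, sparser (possibly empty) journals, and more
#' interview ratings at or below 3.
#'
#' @return Named list with `healthy` and `mci` parameter lists.
#' @export
default_class_effects <- function() {
  list(
    healthy = list(
      activity_meanlog = log(600), activity_meanlog_sd = 0.25,
      activity_sdlog = 0.20,
      excursion_prob = 0.85, excursion_radius_mean = 2000,
      ema_answer_shape1 = 18, ema_answer_shape2 = 2,
      sharp_mean_mu = 4.2, sharp_mean_sd = 0.30, sharp_within_sd = 0.6,
      nback_start_mu = 0.72, nback_start_sd = 0.05,
      nback_plateau_mu = 0.85, nback_plateau_sd = 0.04,
      nback_noise_sd = 0.04,
      journal_pool = "rich", journal_empty_prob = 0,
      journal_entries = c(4L, 10L), journal_sentences = c(2L, 4L),
      rating_probs = c(0.00, 0.02, 0.08, 0.38, 0.52)
    ),
    mci = list(
      activity_meanlog = log(380), activity_meanlog_sd = 0.25,
      activity_sdlog = 0.22,
      excursion_prob = 0.60, excursion_radius_mean = 800,
      ema_answer_shape1 = 6.5, ema_answer_shape2 = 3.5,
      sharp_mean_mu = 3.2, sharp_mean_sd = 0.40, sharp_within_sd = 1.1,
      nback_start_mu = 0.45, nback_start_sd = 0.07,
      nback_plateau_mu = 0.72, nback_plateau_sd = 0.06,
      nback_noise_sd = 0.12,
      journal_pool = "sparse", journal_empty_prob = 0.25,
      journal_entries = c(1L, 3L), journal_sentences = c(1L, 2L),
      rating_probs = c(0.05, 0.18, 0.32, 0.30, 0.15)
    )
  )
}

#' Null (no-signal) class effects
#'
#' Both classes share the healthy parameter set (with journals never forced
#' empty), so labels carry no information. Used for null-calibration checks.
#'
#' @return Named list with identical `healthy` and `mci` parameter lists.
#' @export
null_class_effects <- function() {
  eff <- default_class_effects()
  eff$mci <- eff$healthy
  eff
}

#' Cohort generator configuration
#'
#' Defaults mirror the study population: 124 independent-living older adults
#' (75 healthy, 49 MCI, 89 female), age mean 70.48 (SD 8.72) years with an
#' inclusion floor of 50 years, a minimum of 14 sensor-wear days, a 14%
#' missing-sensor-day rate and 4 EMA prompts/day.
#'
#' The age distribution is a normal truncated at `min_age` whose location is
#' calibrated so the truncated mean equals `age_mean`.
#'
#' @param n_total,n_healthy,n_mci,n_female Cohort composition counts.
#' @param age_mean,age_sd,min_age Age distribution (years).
#' @param min_days Minimum sensor-wear days per participant.
#' @param extra_days_mean Poisson mean of wear days beyond `min_days`.
#' @param missing_day_rate Probability a sensor day is missing.
#' @param ema_per_day Scheduled EMA prompts per day.
#' @param readings_per_day Location readings emitted per non-missing day.
#' @param class_effects Per-class distribution parameters, see
#'   [default_class_effects()].
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_total = 124L, n_healthy = 75L, n_mci = 49L,
                          n_female = 89L,
                          age_mean = 70.48, age_sd = 8.72, min_age = 50,
                          min_days = 14L, extra_days_mean = 7,
                          missing_day_rate = 0.14, ema_per_day = 4L,
                          readings_per_day = 300L,
                          class_effects = default_class_effects(),
                          seed = 1L) {
  cfg <- list(
    n_total = as.integer(n_total), n_healthy = as.integer(n_healthy),
    n_mci = as.integer(n_mci), n_female = as.integer(n_female),
    age_mean = age_mean, age_sd = age_sd, min_age = min_age,
    min_days = as.integer(min_days), extra_days_mean = extra_days_mean,
    missing_day_rate = missing_day_rate, ema_per_day = as.integer(ema_per_day),
    readings_per_day = as.integer(readings_per_day),
    class_effects = class_effects, seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  fail <- function(what) {
    cogdx_stop(paste0("invalid cohort config: ", what), "cogdx_config_error")
  }
  if (cfg$n_healthy + cfg$n_mci != cfg$n_total) {
    fail("n_healthy + n_mci must equal n_total")
  }
  if (cfg$n_female > cfg$n_total) fail("n_female must be <= n_total")
  if (cfg$missing_day_rate < 0 || cfg$missing_day_rate >= 1) {
    fail("missing_day_rate must be in [0, 1)")
  }
  if (cfg$min_days < 14L) fail("min_days must be >= 14")
  if (cfg$n_total < 1L || cfg$n_healthy < 0L || cfg$n_mci < 0L) {
    fail("counts must be non-negative with n_total >= 1")
  }
  if (cfg$ema_per_day < 1L) fail("ema_per_day must be >= 1")
  if (cfg$readings_per_day < 300L) fail("readings_per_day must be >= 300")
  for (cls in class_labels()) {
    if (is.null(cfg$class_effects[[cls]])) {
      fail(paste0("class_effects must define '", cls, "'"))
    }
  }
  invisible(cfg)
}

# Location mu of a normal truncated below at `lower` whose truncated mean is
# `target_mean`. Mean of the truncation is mu + sd * lambda((lower-mu)/sd).
truncnorm_location <- function(target_mean, sd, lower) {
  trunc_mean <- function(mu) {
    a <- (lower - mu) / sd
    mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
  }
  stats::uniroot(function(mu) trunc_mean(mu) - target_mean,
    lower = target_mean - 5 * sd, upper = target_mean + sd,
    tol = 1e-10
  )$root
}

#' Draw participant ages
#'
#' Samples ages from the generator's default age distribution: a normal with
#' the configured mean and SD, truncated below at the inclusion floor
#' (50 years), with the location calibrated so the truncated mean equals
#' `age_mean`. Sampling is by inverse-CDF, so it is deterministic given the
#' seed.
#'
#' @param n Number of ages to draw.
#' @param age_mean,age_sd,min_age Distribution parameters (years).
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` ages, all `>= min_age`.
#' @export
draw_ages <- function(n, age_mean = 70.48, age_sd = 8.72, min_age = 50,
                      seed = NULL) {
  mu <- truncnorm_location(age_mean, age_sd, min_age)
  draw <- function() {
    p0 <- stats::pnorm(min_age, mu, age_sd)
    u <- stats::runif(n, p0, 1)
    stats::qnorm(u, mu, age_sd)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
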