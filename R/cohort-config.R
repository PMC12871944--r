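#' Default per-modality effect sizes
#'
#' Multipliers on the planted trait-to-behaviour loadings, one per data
#' modality. 1 is the calibrated default (association magnitudes chosen to
#' approximate the published Spearman anchors); 0 removes the association
#' entirely (null cohorts). Battery and in-app usage carry somewhat weaker
#' defaults: their links run through nighttime-usage patterns rather than
#' published correlation anchors.
#'
#' @return Named numeric vector.
#' @export
effect_size_defaults <- function() {
  c(active = 1, mobility = 1, steps = 1, app = 1, light = 1, noise = 1,
    brightness = 1, battery = 0.8, inapp = 0.8)
}

#' Default per-sensor opt-in probabilities
#'
#' Conditional on a user enabling at least one sensor. Step count and
#' battery are the most frequently enabled streams, followed by in-app usage
#' and screen brightness, matching the engagement pattern of the study
#' cohort.
#'
#' @return Named numeric vector over the eight sensor categories.
#' @export
sensor_optin_defaults <- function() {
  c(steps = 0.80, battery = 0.75, inapp = 0.65, screen_brightness = 0.60,
    location = 0.50, noise = 0.50, app_usage = 0.50, ambient_light = 0.45)
}

#' Cohort generator configuration
#'
#' Defaults emulate the study cohort: 100 users over 14 days, high-risk
#' prevalences of 30.1% (SDQ), 33% (insomnia), 36.9% (suicidal ideation) and
#' 36.9% (eating disorder), 78/103 iOS users, ~35% of users enabling no
#' passive sensor, and active-data engagement decaying to 14/103 of users by
#' the final day.
#'
#' @param n_users Number of users (>= 2).
#' @param n_days Number of study days (>= 2; triplets need two days).
#' @param prevalence Named fractions, targets for the four binarized
#'   outcomes (`sdq`, `insomnia`, `si`, `ed`).
#' @param effect_sizes Named per-modality multipliers (see
#'   [effect_size_defaults()]), or a single scalar recycled over modalities.
#' @param ios_fraction Fraction of users on iOS.
#' @param sensor_optin_rates Named per-sensor opt-in probabilities,
#'   conditional on enabling at least one sensor.
#' @param zero_sensor_fraction Fraction of users enabling no sensors at all.
#' @param active_retention_final Expected fraction of users still providing
#'   active data on day `n_days`.
#' @param day_noise_scale Multiplier on day-to-day variability of the
#'   active items (day state, item noise and response styles); raise above
#'   1 to emulate noisier daily self-reports.
#' @param site_shift Magnitude of distribution shift applied to an
#'   external-validation cohort (0 = none): translates home locations,
#'   sensor baselines and opt-in rates.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   config including the seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_users = 100, n_days = 14,
                          prevalence = c(sdq = 0.301, insomnia = 0.33,
                                         si = 0.369, ed = 0.369),
                          effect_sizes = effect_size_defaults(),
                          ios_fraction = 78 / 103,
                          sensor_optin_rates = sensor_optin_defaults(),
                          zero_sensor_fraction = 36 / 103,
                          active_retention_final = 14 / 103,
                          day_noise_scale = 1,
                          site_shift = 0,
                          seed = 1L) {
  if (!is.numeric(n_users) || n_users < 2) {
    stop_phenosense("`n_users` must be >= 2.", "phenosense_config_error")
  }
  if (!is.numeric(n_days) || n_days < 2) {
    stop_phenosense("`n_days` must be >= 2.", "phenosense_config_error")
  }
  if (length(effect_sizes) == 1L && is.null(names(effect_sizes))) {
    effect_sizes <- setNames(rep(as.numeric(effect_sizes),
                                 length(effect_size_defaults())),
                             names(effect_size_defaults()))
  } else {
    base <- effect_size_defaults()
    base[names(effect_sizes)] <- effect_sizes
    effect_sizes <- base
  }
  check_fraction(prevalence, "prevalence")
  check_fraction(ios_fraction, "ios_fraction")
  check_fraction(sensor_optin_rates, "sensor_optin_rates")
  check_fraction(zero_sensor_fraction, "zero_sensor_fraction")
  check_fraction(active_retention_final, "active_retention_final")
  if (!all(outcome_names() %in% names(prevalence))) {
    stop_phenosense("`prevalence` must name all four outcomes.",
                    "phenosense_config_error")
  }
  structure(list(
    n_users = as.integer(n_users), n_days = as.integer(n_days),
    prevalence = prevalence, effect_sizes = effect_sizes,
    ios_fraction = ios_fraction, sensor_optin_rates = sensor_optin_rates,
    zero_sensor_fraction = zero_sensor_fraction,
    active_retention_final = active_retention_final,
    day_noise_scale = day_noise_scale,
    site_shift = site_shift, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>", x$n_users, "users x", x$n_days, "days, seed",
      x$seed, "\n")
  invisible(x)
}
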