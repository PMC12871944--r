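test_that("cohort config validates its inputs", {
  expect_error(cohort_config(n_users = 1), class = "phenosense_config_error")
  expect_error(cohort_config(n_days = 1), class = "phenosense_config_error")
  expect_error(cohort_config(ios_fraction = 1.2),
               class = "phenosense_config_error")
  expect_error(cohort_config(prevalence = c(sdq = 0.3)),
               class = "phenosense_config_error")
  # scalar effect size is recycled over modalities
  cfg <- cohort_config(effect_sizes = 0)
  expect_true(all(cfg$effect_sizes == 0))
  cfg2 <- cohort_config(effect_sizes = c(active = 2))
  expect_equal(cfg2$effect_sizes[["active"]], 2)
  expect_equal(cfg2$effect_sizes[["noise"]],
               effect_size_defaults()[["noise"]])
})

test_that("same seed gives identical cohorts, different seeds differ", {
  c1 <- generate_cohort(cohort_config(n_users = 6, seed = 123))
  c2 <- generate_cohort(cohort_config(n_users = 6, seed = 123))
  expect_identical(c1$profiles, c2$profiles)
  expect_identical(c1$outcomes, c2$outcomes)
  expect_identical(c1$active, c2$active)
  expect_identical(c1$sensors, c2$sensors)
  c3 <- generate_cohort(cohort_config(n_users = 6, seed = 124))
  expect_false(identical(c1$outcomes, c3$outcomes))
})

test_that("outcome scores respect their scale ranges", {
  coh <- generate_cohort(cohort_config(n_users = 60, seed = 5))
  oc <- coh$outcomes
  expect_true(all(oc$sdq_total >= 0 & oc$sdq_total <= 40))
  expect_true(all(oc$sci_total >= 0 & oc$sci_total <= 32))
  expect_true(all(oc$ed15_total >= 0 & oc$ed15_total <= 6))
  expect_true(all(oc$si_frequency %in% 0:4))
})

test_that("platform gating holds: no cross-platform sensor rows", {
  coh <- small_cohort()
  prof <- coh$profiles
  ios_users <- prof$user_id[prof$platform == "ios"]
  android_users <- prof$user_id[prof$platform == "android"]
  for (cat in c("ambient_light", "app_usage", "noise")) {
    expect_false(any(coh$sensors[[cat]]$user_id %in% ios_users))
  }
  expect_false(any(coh$sensors$screen_brightness$user_id %in% android_users))
  # enabled_sensors strings never name incompatible sensors
  for (i in seq_len(nrow(prof))) {
    en <- strsplit(prof$enabled_sensors[i], ",")[[1]]
    bad <- if (prof$platform[i] == "ios") {
      c("ambient_light", "app_usage", "noise")
    } else "screen_brightness"
    expect_length(intersect(en, bad), 0)
  }
})

test_that("active responses stay on the 1-7 scale", {
  coh <- small_cohort()
  expect_true(all(coh$active$value %in% 1:7))
})

test_that("zero noise and zero loadings pin items at the scale midpoint", {
  prof <- generate_cohort(cohort_config(n_users = 2, seed = 1))$profiles[1, ]
  resp <- simulate_active_day(prof, 1, seed = 9, effect = 0, noise_scale = 0)
  expect_true(all(resp$value == 4))
  # determinism of the day simulator
  r1 <- simulate_active_day(prof, 2, seed = 77)
  r2 <- simulate_active_day(prof, 2, seed = 77)
  expect_identical(r1, r2)
})

test_that("motivation-productivity day-level coupling is near 0.7", {
  coh <- memo("coupling_cohort", generate_cohort(
    cohort_config(n_users = 150, seed = 31, active_retention_final = 1,
                  zero_sensor_fraction = 1)))
  act <- tidyr::pivot_wider(coh$active, names_from = item,
                            values_from = value)
  r <- cor(act$motivation, act$productivity)
  expect_gt(r, 0.55)
  expect_lt(r, 0.85)
})

test_that("mobility degenerates to pure home dwelling at infinite severity", {
  prof <- generate_cohort(cohort_config(n_users = 2, seed = 2))$profiles[1, ]
  mob <- simulate_mobility_day(prof, 1, severity = Inf, seed = 5)
  expect_true(all(mob$track$lat == prof$home_lat))
  expect_true(all(mob$track$lon == prof$home_lon))
  expect_equal(location_entropy(mob$track), 0)
  expect_equal(radius_of_gyration(mob$track), 0)
  # fixed seed -> identical track
  mob2 <- simulate_mobility_day(prof, 1, severity = Inf, seed = 5)
  expect_identical(mob$track, mob2$track)
})

test_that("mean step count at average severity matches the lognormal median", {
  prof <- generate_cohort(cohort_config(n_users = 2, seed = 3))$profiles[1, ]
  steps <- vapply(1:1000, function(i) {
    simulate_mobility_day(prof, 1, severity = 0, seed = i)$steps
  }, numeric(1))
  # lognormal(log 6000, 0.35) plus a small excursion bonus
  expect_gt(mean(steps), 6000 * 0.8)
  expect_lt(mean(steps), 6000 * 1.2 * exp(0.35^2 / 2) * exp(0.03 * 3))
})

test_that("null cohorts carry no feature-label association", {
  # all-Android full-coverage null cohort: every feature observed for all
  # 100 users, so sampling noise alone cannot push |r| past the bound
  coh <- memo("null_cohort_small", generate_cohort(
    cohort_config(n_users = 100, seed = 17, effect_sizes = 0,
                  zero_sensor_fraction = 0, active_retention_final = 1,
                  ios_fraction = 0,
                  sensor_optin_rates = setNames(
                    rep(1, 8), names(sensor_optin_defaults())))))
  a <- memo("null_features_small",
            assemble_daily_features(coh))
  um <- user_feature_medians(a)
  lab <- binarize_outcomes(coh$outcomes)
  y <- lab$sdq_high[match(um$user_id, lab$user_id)]
  cols <- setdiff(names(um), "user_id")
  rs <- vapply(cols, function(cl) {
    x <- um[[cl]]
    ok <- !is.na(x)
    if (sum(ok) < 10 || length(unique(x[ok])) < 2) return(0)
    abs(cor(x[ok], as.numeric(y[ok])))
  }, numeric(1))
  # point-biserial correlations concentrate near 0 under the null
  expect_gt(mean(rs < 0.25), 0.95)
})

test_that("active dropout is calibrated to the final-day retention", {
  cfg <- cohort_config(n_users = 103, seed = 1,
                       active_retention_final = 14 / 103,
                       zero_sensor_fraction = 1)
  full <- generate_cohort(cfg, missingness = FALSE)
  counts <- vapply(1:50, function(r) {
    dropped <- apply_missingness(full, cfg, seed = r)
    length(unique(dropped$active$user_id[dropped$active$day == 14]))
  }, numeric(1))
  expect_gte(mean(counts), 9)
  expect_lte(mean(counts), 19)
})

test_that("retention 1 drops nothing and empty sensor sets have no rows", {
  coh <- generate_cohort(cohort_config(n_users = 8, seed = 21,
                                       active_retention_final = 1))
  expect_equal(nrow(coh$active), 8 * 14 * 14)
  coh2 <- generate_cohort(cohort_config(n_users = 8, seed = 22,
                                        zero_sensor_fraction = 1))
  for (cat in names(coh2$sensors)) {
    expect_equal(nrow(coh2$sensors[[cat]]), 0)
  }
})
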