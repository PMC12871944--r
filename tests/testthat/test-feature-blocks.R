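test_that("reading stats blocks summarise day and night windows", {
  # constant reading
  b <- reading_stats_block(rep(12, 5), rep(7, 5), "light")
  expect_equal(unname(b[c("light_total_day", "light_mean_day",
                          "light_median_day", "light_sd_day")]),
               c(35, 7, 7, 0))
  # day-only readings leave the night block at the sentinel
  b2 <- reading_stats_block(c(10, 12, 14), c(10, 20, 30), "light")
  expect_true(all(b2[grepl("_night$", names(b2))] == -1))
  # random samples against a direct-summary oracle (population SD)
  withr::with_seed(31, {
    h <- runif(40, 0, 24)
    v <- rnorm(40, 50, 10)
    b3 <- reading_stats_block(h, v, "noise", with_max = TRUE)
    night <- h >= 22 | h < 6
    expect_equal(unname(b3["noise_total_day"]), sum(v))
    expect_equal(unname(b3["noise_max_day"]), max(v))
    expect_equal(unname(b3["noise_sd_day"]),
                 sqrt(mean((v - mean(v))^2)))
    expect_equal(unname(b3["noise_mean_night"]), mean(v[night]))
  })
  expect_true(all(reading_stats_block(numeric(0), numeric(0), "bright") == -1))
})

test_that("app usage block covers counts, categories and fillers", {
  one <- tibble::tibble(hour = 14, app_id = "entertainment_app1",
                        category = "entertainment", duration_s = 60)
  b <- app_usage_block(one)
  expect_equal(unname(b["app_events_day"]), 1)
  expect_equal(unname(b["app_unique_day"]), 1)
  expect_equal(unname(b["app_time_total_day"]), 60)
  expect_equal(unname(b["app_pct_entertainment"]), 100)
  expect_equal(unname(b["app_time_gaming"]), 0)
  expect_equal(unname(b["app_pct_gaming"]), 0)
  expect_equal(unname(b["app_events_night"]), -1)  # no night events
  # mixed toy day against hand-computed shares
  ev <- tibble::tibble(
    hour = c(9, 13, 23, 2),
    app_id = c("a", "b", "a", "c"),
    category = c("social_media", "gaming", "social_media", "communication"),
    duration_s = c(100, 200, 300, 400))
  b2 <- app_usage_block(ev)
  expect_equal(unname(b2["app_pct_social_media"]), 100 * 400 / 1000)
  expect_equal(unname(b2["app_pct_gaming"]), 20)
  expect_equal(unname(b2["app_events_night"]), 2)
  expect_equal(unname(b2["app_time_median_night"]), 350)
  expect_equal(unname(b2["app_first_hour"]), 2)
  expect_equal(unname(b2["app_last_hour"]), 23)
  expect_equal(unname(b2["app_unique_cat_day"]), 3)
  expect_equal(unname(b2["app_unique_cat_night"]), 2)
  # percentage conservation
  pct <- b2[grepl("^app_pct_", names(b2))]
  expect_equal(sum(pct), 100, tolerance = 1e-6)
  expect_true(all(app_usage_block(ev[0, ]) == -1))
})

test_that("battery block counts charges, drain rate and night usage", {
  h <- seq(0, 23.75, by = 0.25)
  # monotone 100 -> 52 over the day: 2 %/h drain, no charges
  lv <- seq(100, 52, length.out = length(h))
  b <- battery_block(h, lv)
  expect_equal(unname(b["batt_charges"]), 0)
  expect_equal(unname(b["batt_drain_per_hour"]), 48 / 23.75, tolerance = 1e-9)
  expect_equal(unname(b["batt_min"]), 52)
  # sawtooth with two charge onsets
  lv2 <- c(seq(80, 40, length.out = 32), seq(45, 90, length.out = 10),
           seq(89, 60, length.out = 40), seq(65, 95, length.out = 14))
  b2 <- battery_block(h, lv2)
  expect_equal(unname(b2["batt_charges"]), 2)
  # event-scan oracle on a random trace
  withr::with_seed(41, {
    lv3 <- pmin(100, pmax(0, 60 + cumsum(rnorm(length(h), 0, 3))))
    b3 <- battery_block(h, lv3)
    d <- diff(lv3)
    rising <- d > 0
    expect_equal(unname(b3["batt_charges"]),
                 sum(rising & !c(FALSE, head(rising, -1))))
    expect_equal(unname(b3["batt_night_use_count"]),
                 sum(d < 0 & (h[-1] >= 22 | h[-1] < 6)))
    expect_equal(unname(b3["batt_hours_below20"]),
                 sum(lv3 < 20) * 23.75 / (length(h) - 1))
  })
  expect_true(all(battery_block(numeric(0), numeric(0)) == -1))
})

test_that("step indicators use strict thresholds", {
  expect_equal(unname(steps_block(7500)), c(7500, 1, 0, 0))
  expect_equal(unname(steps_block(12000)), c(12000, 1, 1, 1))
  expect_equal(unname(steps_block(4000)), c(4000, 0, 0, 0))
  expect_true(all(steps_block(NULL) == -1))
})

test_that("in-app usage block reports first/last hour and night sessions", {
  s <- tibble::tibble(start_hour = c(7.2, 23.5))
  b <- inapp_block(s)
  expect_equal(unname(b), c(7, 23, 1))
  expect_true(all(inapp_block(s[0, ]) == -1))
})

test_that("location block matches per-formula oracles on a synthetic day", {
  home <- list(lat = 51.5, lon = -0.1, cell = "51.5:-0.1")
  # all-day single spot at home
  athome <- toy_track(c(1, 9, 15, 23), rep(51.5, 4), rep(-0.1, 4))
  b <- location_feature_block(athome, home)
  expect_equal(unname(b["loc_total_dist"]), 0)
  expect_equal(unname(b["loc_home_time"]), 1)
  expect_equal(unname(b["loc_entropy"]), 0)
  expect_equal(unname(b[c("loc_max_home_dist", "loc_mean_home_dist",
                          "loc_median_home_dist")]), rep(0, 3))
  # two fixes 1 km apart in daytime: no night movement
  p2 <- toy_track(c(10, 12), c(51.5, 51.5 + 1000 / 111194.9), c(-0.1, -0.1))
  b2 <- location_feature_block(p2, home)
  expect_equal(unname(b2["loc_total_dist"]), 1000, tolerance = 1e-3)
  expect_equal(unname(b2["loc_night_movement"]), 0)
  # 50-fix random day against independent per-formula oracles
  withr::with_seed(51, {
    tr <- toy_track(sort(runif(50, 0, 24)), 51.5 + rnorm(50, 0, 0.01),
                    -0.1 + rnorm(50, 0, 0.01))
    b3 <- location_feature_block(tr, home)
    n <- nrow(tr)
    legs <- haversine_m(tr$lat[-n], tr$lon[-n], tr$lat[-1], tr$lon[-1])
    night_end <- tr$hour[-1] >= 22 | tr$hour[-1] < 6
    dh <- haversine_m(tr$lat, tr$lon, home$lat, home$lon)
    cells <- paste0(round(tr$lat, 3), ":", round(tr$lon, 3))
    pr <- as.numeric(table(cells)) / n
    expect_equal(unname(b3["loc_mean_lat"]), mean(tr$lat))
    expect_equal(unname(b3["loc_sd_lon"]),
                 sqrt(mean((tr$lon - mean(tr$lon))^2)))
    expect_equal(unname(b3["loc_total_dist"]), sum(legs))
    expect_equal(unname(b3["loc_night_movement"]), sum(legs[night_end]))
    expect_equal(unname(b3["loc_count"]), n)
    expect_equal(unname(b3["loc_max_home_dist"]), max(dh))
    expect_equal(unname(b3["loc_median_home_dist"]), median(dh))
    expect_equal(unname(b3["loc_entropy"]), -sum(pr * log(pr)))
    expect_equal(unname(b3["loc_home_time"]), mean(cells == home$cell))
    expect_equal(unname(b3["loc_max_centroid_dist"]),
                 max(haversine_m(tr$lat, tr$lon, mean(tr$lat),
                                 mean(tr$lon))))
    expect_equal(unname(b3["loc_gyration"]),
                 sqrt(mean(haversine_m(tr$lat, tr$lon, mean(tr$lat),
                                       mean(tr$lon))^2)))
  })
  expect_true(all(location_feature_block(athome[0, ], home) == -1))
})

test_that("mobility features are reorder-invariant except path-dependent ones", {
  home <- list(lat = 51.5, lon = -0.1, cell = "51.5:-0.1")
  withr::with_seed(61, {
    tr <- toy_track(sort(runif(25, 6, 20)), 51.5 + rnorm(25, 0, 0.01),
                    -0.1 + rnorm(25, 0, 0.01))
    perm <- sample(25)
    tr2 <- tr[perm, ]
    b1 <- location_feature_block(tr, home)
    b2 <- location_feature_block(tr2, home)
    path_dep <- c("loc_total_dist", "loc_night_movement")
    expect_equal(b1[setdiff(names(b1), path_dep)],
                 b2[setdiff(names(b2), path_dep)])
  })
})
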