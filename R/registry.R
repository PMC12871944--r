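#' Passive-feature registry
#'
#' The canonical, ordered list of the 92 engineered passive features, eight
#' sensor categories in total. Per-category counts are fixed by design:
#' ambient light 8, app usage 36, background noise 10, battery 8, location 15,
#' in-app usage 3, screen brightness 8, step count 4. Ambient light, app usage
#' and background noise are Android-only streams; screen brightness is
#' iOS-only; the rest are available on both platforms.
#'
#' Each feature is computed over the full 24-h day or over the night window
#' (22:00-06:00, half-open). A handful of features are documented fillers
#' (`filler = TRUE`): Table-style category totals under-enumerate the printed
#' per-category counts, and the fillers are semantically adjacent statistics
#' (session-time SDs, first/last app-use hour, unique category counts, max
#' distance from the day centroid, normalized location entropy) that complete
#' the 36 app-usage and 15 location slots.
#'
#' @return A tibble with one row per passive feature: `name`, `category`,
#'   `window` (`"day"` or `"night"`), `kind` (`"continuous"` or `"binary"`),
#'   `units`, `platform` (`"android"`, `"ios"` or `"both"`), `filler`.
#' @examples
#' reg <- feature_registry()
#' nrow(reg) # 92
#' dplyr::count(reg, category)
#' @export
feature_registry <- function() {
  cached <- .phenosense_cache$registry
  if (!is.null(cached)) return(cached)
  spec <- function(name, category, window, kind, units, platform, filler = FALSE) {
    tibble(
      name = name, category = category, window = window, kind = kind,
      units = units, platform = platform, filler = filler
    )
  }
  reading_block <- function(prefix, category, units, platform, with_max = FALSE) {
    stats_day <- c("total", "mean", "median", "sd")
    if (with_max) stats_day <- c("total", "median", "mean", "max", "sd")
    bind_rows(
      spec(paste0(prefix, "_", stats_day, "_day"), category, "day",
           "continuous", units, platform),
      spec(paste0(prefix, "_", stats_day, "_night"), category, "night",
           "continuous", units, platform)
    )
  }

  app_cats <- app_categories()
  reg <- bind_rows(
    # Ambient light (Android only): 8
    reading_block("light", "ambient_light", "lux", "android"),
    # App usage (Android only): 36
    spec(c("app_events_day", "app_unique_day", "app_time_total_day",
           "app_time_mean_day", "app_time_median_day"),
         "app_usage", "day", "continuous", "s", "android"),
    spec(c("app_events_night", "app_unique_night", "app_time_total_night",
           "app_time_mean_night", "app_time_median_night"),
         "app_usage", "night", "continuous", "s", "android"),
    spec(paste0("app_time_", app_cats), "app_usage", "day", "continuous",
         "s", "android"),
    spec(paste0("app_pct_", app_cats), "app_usage", "day", "continuous",
         "%", "android"),
    spec(c("app_time_sd_day", "app_time_sd_night"), "app_usage",
         c("day", "night"), "continuous", "s", "android", filler = TRUE),
    spec(c("app_first_hour", "app_last_hour"), "app_usage", "day",
         "continuous", "h", "android", filler = TRUE),
    spec(c("app_unique_cat_day", "app_unique_cat_night"), "app_usage",
         c("day", "night"), "continuous", "count", "android", filler = TRUE),
    # Background noise (Android only): 10
    reading_block("noise", "noise", "dB", "android", with_max = TRUE),
    # Battery: 8
    spec(c("batt_min", "batt_max", "batt_mean", "batt_median"),
         "battery", "day", "continuous", "%", "both"),
    spec("batt_charges", "battery", "day", "continuous", "count", "both"),
    spec("batt_drain_per_hour", "battery", "day", "continuous", "%/h", "both"),
    spec("batt_hours_below20", "battery", "day", "continuous", "h", "both"),
    spec("batt_night_use_count", "battery", "night", "continuous", "count",
         "both"),
    # Location: 15 (13 enumerated + max distance from day centroid +
    # normalized entropy filler)
    spec(c("loc_mean_lat", "loc_mean_lon"), "location", "day", "continuous",
         "deg", "both"),
    spec("loc_total_dist", "location", "day", "continuous", "m", "both"),
    spec("loc_count", "location", "day", "continuous", "count", "both"),
    spec(c("loc_max_home_dist", "loc_mean_home_dist", "loc_median_home_dist"),
         "location", "day", "continuous", "m", "both"),
    spec("loc_night_movement", "location", "night", "continuous", "m", "both"),
    spec("loc_gyration", "location", "day", "continuous", "m", "both"),
    spec(c("loc_sd_lat", "loc_sd_lon"), "location", "day", "continuous",
         "deg", "both"),
    spec("loc_entropy", "location", "day", "continuous", "nats", "both"),
    spec("loc_home_time", "location", "day", "continuous", "fraction", "both"),
    spec("loc_max_centroid_dist", "location", "day", "continuous", "m",
         "both"),
    spec("loc_entropy_norm", "location", "day", "continuous", "fraction",
         "both", filler = TRUE),
    # In-app usage of the sensing app itself: 3
    spec(c("inapp_first_hour", "inapp_last_hour"), "inapp", "day",
         "continuous", "h", "both"),
    spec("inapp_night_count", "inapp", "night", "continuous", "count",
         "both"),
    # Screen brightness (iOS only): 8
    reading_block("bright", "screen_brightness", "fraction", "ios"),
    # Step count: 4
    spec("steps_count", "steps", "day", "continuous", "steps", "both"),
    spec(c("steps_gt5000", "steps_gt7500", "steps_gt10000"), "steps", "day",
         "binary", "indicator", "both")
  )
  .phenosense_cache$registry <- reg
  reg
}

#' The ten app categories used for app-usage features
#' @return Character vector of category codes.
#' @export
app_categories <- function() {
  c("camera", "communication", "entertainment", "gaming", "physical_health",
    "mental_health", "inapp", "news", "productivity", "social_media")
}

#' Active self-report item registry
#'
#' Daily ecological-momentary-assessment items rated 1-7. The default set of
#' 14 items is configurable; downstream code treats whatever registry it is
#' given as the active feature block.
#'
#' @param items Character vector of item names.
#' @return A tibble with `name` and `kind` columns.
#' @export
active_item_registry <- function(items = c(
  "mood", "sleep_quality", "loneliness", "confidence", "negative_thinking",
  "racing_thoughts", "self_care", "hopefulness", "motivation", "productivity",
  "energy", "irritability", "sociability", "appetite"
)) {
  stopifnot(is.character(items), !anyDuplicated(items))
  tibble(name = items, kind = "active")
}

#' The eight passive sensor categories
#' @return Character vector in registry order.
#' @export
sensor_categories <- function() {
  unique(feature_registry()$category)
}

# Sensors whose raw streams are gated by platform.
android_only_sensors <- function() c("ambient_light", "app_usage", "noise")
ios_only_sensors <- function() "screen_brightness"

sensors_for_platform <- function(platform) {
  all <- sensor_categories()
  if (platform == "ios") setdiff(all, android_only_sensors()) else
    setdiff(all, ios_only_sensors())
}
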