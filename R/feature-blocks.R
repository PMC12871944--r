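# Per-sensor feature blocks. Each block returns a named numeric vector whose
# names and order match feature_registry() for that category; missing input
# yields sentinels. Totals of gridded readings are sums of the 15-minute
# samples, SDs are population SDs.

sentinel_block <- function(names) setNames(rep(SENTINEL, length(names)), names)

registry_names <- function(category) {
  reg <- feature_registry()
  reg$name[reg$category == category]
}

summary_stats <- function(x, with_max = FALSE) {
  if (length(x) == 0L) {
    k <- if (with_max) 5L else 4L
    return(rep(SENTINEL, k))
  }
  if (with_max) {
    c(sum(x), median(x), mean(x), max(x), pop_sd(x))
  } else {
    c(sum(x), mean(x), median(x), pop_sd(x))
  }
}

#' Day/night summary statistics for a gridded sensor reading
#'
#' Total (sum of samples), mean, median and population SD over the full day
#' and over the night window; background noise additionally gets the maximum
#' in both windows. Windows with no readings emit sentinels.
#'
#' @param hours Decimal hours of the readings.
#' @param values Reading values (lux, dB, or 0-1 brightness).
#' @param prefix Registry prefix: `"light"`, `"noise"`, or `"bright"`.
#' @param with_max Include the per-window maximum (noise block).
#' @return Named numeric vector of length 8 (or 10 with `with_max`).
#' @export
reading_stats_block <- function(hours, values, prefix, with_max = FALSE) {
  stat_names <- if (with_max) c("total", "median", "mean", "max", "sd") else
    c("total", "mean", "median", "sd")
  nms <- c(paste0(prefix, "_", stat_names, "_day"),
           paste0(prefix, "_", stat_names, "_night"))
  if (length(values) == 0L) return(sentinel_block(nms))
  night <- is_night_hour(hours)
  setNames(c(summary_stats(values, with_max),
             summary_stats(values[night], with_max)), nms)
}

#' The 15 location features for one user-day
#'
#' Mean/SD latitude and longitude, total distance (sum of consecutive
#' haversine legs), fix count, max/mean/median distance from home, nighttime
#' movement (distance restricted to night-window legs), radius of gyration,
#' location entropy, fraction of fixes in the home cell, maximum distance
#' from the day centroid, and normalized entropy (entropy / log cell count).
#'
#' @param track Jump-filtered GPS fixes for one day: `hour`, `lat`, `lon`,
#'   sorted by time.
#' @param home Output of [infer_home()] (or `NULL`).
#' @param digits Grid resolution for entropy/home cells.
#' @return Named numeric vector of length 15.
#' @export
location_feature_block <- function(track, home, digits = 3) {
  nms <- registry_names("location")
  if (is.null(track) || nrow(track) == 0L) return(sentinel_block(nms))
  n <- nrow(track)
  clat <- mean(track$lat)
  clon <- mean(track$lon)
  legs <- if (n > 1L) {
    haversine_m(track$lat[-n], track$lon[-n], track$lat[-1], track$lon[-1])
  } else numeric(0)
  # A leg counts as nighttime movement if it ends inside the night window.
  night_legs <- if (n > 1L) legs[is_night_hour(track$hour[-1])] else numeric(0)
  if (!is.null(home)) {
    dh <- haversine_m(track$lat, track$lon, home$lat, home$lon)
    home_stats <- c(max(dh), mean(dh), median(dh))
    home_time <- mean(grid_cell(track$lat, track$lon, digits) == home$cell)
  } else {
    home_stats <- rep(SENTINEL, 3)
    home_time <- SENTINEL
  }
  ent <- location_entropy(track, digits)
  n_cells <- length(unique(grid_cell(track$lat, track$lon, digits)))
  ent_norm <- if (n_cells > 1L) ent / log(n_cells) else 0
  setNames(c(
    clat, clon, sum(legs), n, home_stats, sum(night_legs),
    radius_of_gyration(track), pop_sd(track$lat), pop_sd(track$lon),
    ent, home_time,
    max(haversine_m(track$lat, track$lon, clat, clon)),
    ent_norm
  ), nms)
}

#' The 36 app-usage features for one user-day
#'
#' Event count, unique apps, total/mean/median session time for the full day
#' and the night window; per-category total time and percentage of total
#' time across the ten app categories; plus the documented fillers (session
#' time SD day/night, first/last app-use hour, unique categories day/night).
#' Categories with no events get 0 time and 0 share; percentages sum to 100
#' whenever total time is positive. No events at all yields sentinels.
#'
#' @param events Data frame with `hour`, `app_id`, `category`, `duration_s`.
#' @return Named numeric vector of length 36.
#' @export
app_usage_block <- function(events) {
  nms <- registry_names("app_usage")
  if (is.null(events) || nrow(events) == 0L) return(sentinel_block(nms))
  cats <- app_categories()
  win_stats <- function(e) {
    if (nrow(e) == 0L) return(rep(SENTINEL, 5))
    c(nrow(e), length(unique(e$app_id)), sum(e$duration_s),
      mean(e$duration_s), median(e$duration_s))
  }
  night <- is_night_hour(events$hour)
  day_block <- win_stats(events)
  night_block <- win_stats(events[night, , drop = FALSE])
  cat_time <- vapply(cats, function(cc) {
    sum(events$duration_s[events$category == cc])
  }, numeric(1))
  total_time <- sum(events$duration_s)
  cat_pct <- if (total_time > 0) 100 * cat_time / total_time else
    rep(0, length(cats))
  sd_day <- pop_sd(events$duration_s)
  sd_night <- if (any(night)) pop_sd(events$duration_s[night]) else SENTINEL
  uniq_cat_night <- if (any(night)) length(unique(events$category[night])) else
    SENTINEL
  setNames(c(
    day_block, night_block, cat_time, cat_pct,
    sd_day, sd_night,
    floor(min(events$hour)), floor(max(events$hour)),
    length(unique(events$category)), uniq_cat_night
  ), nms)
}

#' The 8 battery features for one user-day
#'
#' Min/max/mean/median level, number of charge onsets (level-increase
#' starts), mean battery use per hour (total level decrease divided by hours
#' observed), hours spent below 20%, and the count of night readings whose
#' level decreased versus the previous reading.
#'
#' @param hours Decimal hours of the (15-minute grid) readings, sorted.
#' @param levels Battery level percentages.
#' @return Named numeric vector of length 8.
#' @export
battery_block <- function(hours, levels) {
  nms <- registry_names("battery")
  if (length(levels) == 0L) return(sentinel_block(nms))
  n <- length(levels)
  diffs <- if (n > 1L) diff(levels) else numeric(0)
  # charge onsets: a rise following a non-rise
  rising <- diffs > 0
  charges <- sum(rising & !c(FALSE, rising[-length(rising)]))
  hours_observed <- if (n > 1L) hours[n] - hours[1] else 0
  drain <- sum(-diffs[diffs < 0])
  drain_per_hour <- if (hours_observed > 0) drain / hours_observed else 0
  # time below 20%: fraction of samples below 20 scaled to observed hours
  step_h <- if (n > 1L) hours_observed / (n - 1) else 0
  below <- sum(levels < 20) * step_h
  night_use <- if (n > 1L) {
    sum(diffs < 0 & is_night_hour(hours[-1]))
  } else 0
  setNames(c(min(levels), max(levels), mean(levels), median(levels),
             charges, drain_per_hour, below, night_use), nms)
}

#' Step-count features for one user-day
#'
#' Daily step count plus binary indicators for strictly exceeding 5000,
#' 7500 and 10,000 steps.
#'
#' @param steps Daily step count (scalar) or `NULL`/`NA` when missing.
#' @return Named numeric vector of length 4.
#' @export
steps_block <- function(steps) {
  nms <- registry_names("steps")
  if (is.null(steps) || length(steps) == 0L || is.na(steps)) {
    return(sentinel_block(nms))
  }
  setNames(c(steps, as.numeric(steps > 5000), as.numeric(steps > 7500),
             as.numeric(steps > 10000)), nms)
}

#' In-app usage features for one user-day
#'
#' First and last hour of use of the sensing app itself (0-23) and the count
#' of night-window sessions.
#'
#' @param sessions Data frame with `start_hour` (decimal).
#' @return Named numeric vector of length 3.
#' @export
inapp_block <- function(sessions) {
  nms <- registry_names("inapp")
  if (is.null(sessions) || nrow(sessions) == 0L) return(sentinel_block(nms))
  setNames(c(floor(min(sessions$start_hour)), floor(max(sessions$start_hour)),
             sum(is_night_hour(sessions$start_hour))), nms)
}
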