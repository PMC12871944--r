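# Synthetic cohort generator.
#
# Users carry a general severity factor plus four outcome-specific factors
# (pairwise trait correlation 0.5). Outcome scale scores are scaled logistic
# transforms of trait + noise, calibrated in closed form so that binarized
# prevalences hit the configured targets. Active items and passive behaviour
# load on the traits with directions matching the published association
# anchors; per-modality effect sizes scale those loadings (0 = null cohort).

TRAIT_COR_SHARED <- 0.5   # variance share of the general factor
OUTCOME_NOISE_SD <- 0.6   # score noise on top of the latent trait
ACTIVE_STYLE_SD <- 0.60   # SD of stable per-user item response styles

#' Active-item trait loadings
#'
#' Loadings of the 14 daily items on the four severity traits (columns sdq,
#' insomnia, si, ed; severity direction positive), plus each item's loading
#' on the shared day state and its day-level noise SD. Signs follow the
#' published association anchors: negative thinking, racing thoughts and
#' loneliness rise with every severity; sleep quality falls most with
#' insomnia severity; self-care and appetite fall most with eating-disorder
#' severity. Motivation and productivity share a strong day-state loading,
#' which induces their strong day-level coupling.
#'
#' @return A tibble with `item`, the four loading columns, `day_state`,
#'   `noise_sd`.
#' @export
active_item_loadings <- function() {
  tibble::tribble(
    ~item,               ~sdq,  ~insomnia, ~si,   ~ed,   ~day_state, ~noise_sd,
    "mood",              -0.35, -0.30,     -0.30, -0.20, 0.30, 0.80,
    "sleep_quality",     -0.30, -0.50,     -0.30, -0.18, 0.15, 0.80,
    "loneliness",         0.35,  0.40,      0.40,  0.25, 0.00, 0.80,
    "confidence",        -0.30, -0.28,     -0.25, -0.30, 0.10, 0.80,
    "negative_thinking",  0.32,  0.36,      0.40,  0.27, 0.00, 0.75,
    "racing_thoughts",    0.38,  0.38,      0.45,  0.42, 0.00, 0.75,
    "self_care",         -0.33, -0.32,     -0.20, -0.33, 0.10, 0.80,
    "hopefulness",       -0.30, -0.28,     -0.30, -0.25, 0.10, 0.80,
    "motivation",        -0.15, -0.10,     -0.10, -0.10, 0.95, 0.50,
    "productivity",      -0.12, -0.10,     -0.10, -0.10, 0.95, 0.50,
    "energy",            -0.20, -0.15,     -0.10, -0.10, 0.50, 0.75,
    "irritability",       0.30,  0.20,      0.20,  0.15, 0.00, 0.85,
    "sociability",       -0.20, -0.10,     -0.15, -0.10, 0.20, 0.85,
    "appetite",          -0.10, -0.10,     -0.10, -0.35, 0.10, 0.85
  )
}

trait_cols <- function() paste0("trait_", outcome_names())

generate_profiles <- function(config) {
  n <- config$n_users
  shift <- config$site_shift
  g <- rnorm(n)
  traits <- vapply(outcome_names(), function(k) {
    sqrt(TRAIT_COR_SHARED) * g + sqrt(1 - TRAIT_COR_SHARED) * rnorm(n)
  }, numeric(n))
  colnames(traits) <- trait_cols()

  platform <- ifelse(runif(n) < config$ios_fraction, "ios", "android")
  sex <- ifelse(runif(n) < 0.71, "female", "male_other")
  # school membership carries a mild severity gradient (catchment-area
  # deprivation): more severe users are likelier to attend school 2
  site <- vapply(seq_len(n), function(i) {
    w <- c(0.4 * exp(-0.25 * g[i]), 0.3 * exp(0.5 * g[i]),
           0.3 * exp(-0.25 * g[i]))
    sample(paste0("school_", 1:3), 1, prob = w / sum(w))
  }, character(1))
  site_lat <- c(school_1 = 51.52, school_2 = 51.46, school_3 = 51.55)
  site_lon <- c(school_1 = -0.18, school_2 = -0.10, school_3 = -0.25)

  e <- config$effect_sizes
  sev_lat <- 0.6 * traits[, "trait_si"] + 0.4 * traits[, "trait_sdq"]
  sev_lon <- traits[, "trait_insomnia"]
  home_lat <- site_lat[site] + shift * 0.5 + rnorm(n, 0, 0.05) +
    e[["mobility"]] * 0.05 * sev_lat
  home_lon <- site_lon[site] + shift * 0.5 + rnorm(n, 0, 0.05) +
    e[["mobility"]] * 0.045 * sev_lon
  home_lat <- round(home_lat, 3)  # home sits on a grid cell centre
  home_lon <- round(home_lon, 3)

  # Per-user excursion anchors, 3-5 points within ~10 km of home.
  anchors <- vapply(seq_len(n), function(i) {
    k <- sample(3:5, 1)
    dlat <- rnorm(k, 0, 0.04)
    dlon <- rnorm(k, 0, 0.04)
    paste(sprintf("%.5f:%.5f", dlat, dlon), collapse = "|")
  }, character(1))

  # Sensor enablement: a configured fraction enables nothing; the rest draw
  # Bernoulli per platform-compatible sensor (opt-in rates shifted under
  # site_shift), with the highest-rate sensor forced on if all draws fail.
  rates <- config$sensor_optin_rates
  if (shift != 0) rates <- plogis(qlogis(pmin(pmax(rates, 1e-6), 1 - 1e-6)) -
                                    0.5 * shift)
  zero_sensor <- runif(n) < config$zero_sensor_fraction
  enabled <- vapply(seq_len(n), function(i) {
    if (zero_sensor[i]) return("")
    cand <- sensors_for_platform(platform[i])
    on <- cand[runif(length(cand)) < rates[cand]]
    if (length(on) == 0L) on <- cand[which.max(rates[cand])]
    paste(sort(on), collapse = ",")
  }, character(1))

  # stable per-user response styles on the 1-7 items (acquiescence-like
  # shifts, independent of severity); dilute item-score correlations the
  # way noisy single-item measures do in real cohorts
  items <- active_item_loadings()$item
  styles <- matrix(rnorm(n * length(items), 0, ACTIVE_STYLE_SD),
                   n, length(items),
                   dimnames = list(NULL, paste0("style_", items)))

  tibble(
    user_id = sprintf("u%03d", seq_len(n)),
    platform = platform, sex = sex, site = site,
    enabled_sensors = enabled,
    trait_g = g
  ) |>
    bind_cols(as_tibble(traits)) |>
    mutate(home_lat = home_lat, home_lon = home_lon, anchors = anchors) |>
    bind_cols(as_tibble(styles))
}

parse_anchors <- function(s) {
  if (is.na(s) || s == "") return(matrix(numeric(0), ncol = 2))
  parts <- strsplit(strsplit(s, "|", fixed = TRUE)[[1]], ":", fixed = TRUE)
  do.call(rbind, lapply(parts, as.numeric))
}

enabled_sensor_list <- function(profile_row) {
  s <- profile_row$enabled_sensors
  if (is.na(s) || s == "") character(0) else strsplit(s, ",", fixed = TRUE)[[1]]
}

# Closed-form prevalence calibration: score = lo + range * plogis(slope * (z
# - z0)) of z = trait + noise ~ N(0, sd_z); solve z0 so that P(score crosses
# the high-risk threshold) equals the target prevalence.
calibrate_z0 <- function(prevalence, p_thr, slope, sd_z) {
  qnorm(1 - prevalence) * sd_z - qlogis(p_thr) / slope
}

generate_outcomes <- function(profiles, config) {
  n <- nrow(profiles)
  sd_z <- sqrt(1 + OUTCOME_NOISE_SD^2)
  prev <- config$prevalence
  z <- function(k) profiles[[paste0("trait_", k)]] + rnorm(n, 0, OUTCOME_NOISE_SD)

  z_sdq <- z("sdq")
  # round(40 p) >= 16  <=>  p >= 15.5/40
  sdq <- pmin(40, pmax(0, round(40 * plogis(
    0.7 * (z_sdq - calibrate_z0(prev[["sdq"]], 15.5 / 40, 0.7, sd_z))))))

  z_ins <- z("insomnia")
  # SCI falls with insomnia severity; round(32 p) <= 16  <=>  p <= 16.5/32
  z0_ins <- qnorm(1 - prev[["insomnia"]]) * sd_z + qlogis(16.5 / 32) / 0.6
  sci <- pmin(32, pmax(0, round(32 * plogis(-0.6 * (z_ins - z0_ins)))))

  z_ed <- z("ed")
  ed <- pmin(6, pmax(0, 6 * plogis(
    0.8 * (z_ed - calibrate_z0(prev[["ed"]], 2.69 / 6, 0.8, sd_z)))))

  z_si <- z("si")
  c1 <- qnorm(1 - prev[["si"]]) * sd_z
  cuts <- c1 + c(0, 0.55, 1.1, 1.65) * sd_z
  si <- findInterval(z_si, cuts)

  tibble(user_id = profiles$user_id, sdq_total = sdq, sci_total = sci,
         ed15_total = ed, si_frequency = si)
}

#' Simulate one day of active self-reports for one user
#'
#' Each item is a clipped, discretized affine function of the user's severity
#' traits, a shared day state (inducing the motivation-productivity
#' coupling) and item noise, mapped onto the 1-7 scale around the midpoint 4.
#'
#' @param profile One row of the cohort profiles table (carries the traits).
#' @param day Day index.
#' @param seed RNG seed for this user-day.
#' @param effect Multiplier on the trait loadings (0 = null).
#' @param noise_scale Multiplier on day state and item noise; 0 with
#'   `effect = 0` makes every item constant at 4.
#' @param loadings Loading table, see [active_item_loadings()].
#' @return Tibble with `user_id`, `day`, `item`, `value` (integers 1-7).
#' @export
simulate_active_day <- function(profile, day, seed, effect = 1,
                                noise_scale = 1,
                                loadings = active_item_loadings()) {
  with_seed(seed, {
    L <- as.matrix(loadings[, c("sdq", "insomnia", "si", "ed")])
    traits <- as.numeric(profile[1, trait_cols()])
    style_cols <- paste0("style_", loadings$item)
    style <- if (all(style_cols %in% names(profile))) {
      as.numeric(profile[1, style_cols])
    } else rep(0, nrow(loadings))
    w <- rnorm(1) * noise_scale
    x <- effect * as.numeric(L %*% traits) +
      loadings$day_state * w + style * noise_scale +
      rnorm(nrow(loadings), 0, loadings$noise_sd * noise_scale)
    value <- pmin(7L, pmax(1L, as.integer(round(4 + 1.45 * x))))
    tibble(user_id = profile$user_id[1], day = as.integer(day),
           item = loadings$item, value = value)
  })
}

#' Simulate one day of mobility for one user
#'
#' A two-state dwell/excursion model: the user dwells at home (fixes exactly
#' at the home coordinates, including at night) and makes a
#' severity-dependent number of excursions to per-user anchor points, each
#' contributing a handful of jittered fixes. The daily step count is
#' lognormal around a 6000-step median, reduced by severity and slightly
#' increased by excursions.
#'
#' @param profile One row of the profiles table (needs `home_lat`,
#'   `home_lon`, `anchors`).
#' @param day Day index.
#' @param severity Scalar severity driving excursion and step suppression;
#'   `Inf` forces pure home dwelling.
#' @param seed RNG seed for this user-day.
#' @param effect Mobility effect multiplier.
#' @param steps_effect Step-count effect multiplier.
#' @return List with `track` (tibble `hour`, `lat`, `lon`, time-sorted) and
#'   `steps` (scalar).
#' @export
simulate_mobility_day <- function(profile, day, severity, seed, effect = 1,
                                  steps_effect = effect) {
  with_seed(seed, {
    home_lat <- profile$home_lat[1]
    home_lon <- profile$home_lon[1]
    anchors <- parse_anchors(profile$anchors[1])
    lambda <- exp(log(2.2) - 0.35 * effect * severity)
    n_exc <- if (!is.finite(lambda) || lambda <= 0) 0L else rpois(1, lambda)
    if (nrow(anchors) == 0L) n_exc <- 0L

    n_home <- sample(8:14, 1)
    hours <- sort(runif(n_home, 0, 24))
    lat <- rep(home_lat, n_home)
    lon <- rep(home_lon, n_home)
    if (n_exc > 0L) {
      for (j in seq_len(n_exc)) {
        a <- anchors[sample(nrow(anchors), 1), ]
        t0 <- runif(1, 8, 20)
        k <- sample(3:6, 1)
        hours <- c(hours, t0 + sort(runif(k, 0, 1.5)))
        lat <- c(lat, home_lat + a[1] + rnorm(k, 0, 4e-4))
        lon <- c(lon, home_lon + a[2] + rnorm(k, 0, 4e-4))
      }
    }
    ord <- order(hours)
    track <- fast_tbl(hour = pmin(hours[ord], 23.999), lat = lat[ord],
                      lon = lon[ord])
    sev_steps <- if (is.finite(severity)) severity else 0
    steps <- round(exp(log(6000) - 0.30 * steps_effect * sev_steps +
                         0.03 * n_exc + rnorm(1, 0, 0.35)))
    list(track = track, steps = max(0, steps))
  })
}

# 15-minute sampling grid (hours).
grid_hours <- function() seq(0, 23.75, by = 0.25)

# Gridded ambient-sensor traces for one user-day. Returns a tibble
# hour/value for the requested stream.
simulate_reading_day <- function(kind, traits, seed, effects) {
  with_seed(seed, {
    h <- grid_hours()
    night <- is_night_hour(h)
    n <- length(h)
    val <- switch(kind,
      ambient_light = {
        e <- effects[["light"]]
        sev <- 0.5 * traits[["trait_insomnia"]] + 0.3 * traits[["trait_ed"]] +
          0.2 * traits[["trait_g"]]
        mu <- ifelse(night, log(3) + 0.5 * e * sev, log(150))
        exp(mu + rnorm(n, 0, 0.8))
      },
      noise = {
        e <- effects[["noise"]]
        sd_day <- 8 * exp(-0.32 * e * (0.6 * traits[["trait_si"]] +
                                         0.4 * traits[["trait_insomnia"]]))
        mu_day <- 45 - 2.5 * e * traits[["trait_sdq"]]
        mu_night <- 32 + 2 * e * traits[["trait_ed"]]
        ifelse(night, rnorm(n, mu_night, 5), rnorm(n, mu_day, sd_day))
      },
      screen_brightness = {
        e <- effects[["brightness"]]
        sev <- 0.5 * traits[["trait_insomnia"]] + 0.5 * traits[["trait_g"]]
        mu <- ifelse(night, -1 + 0.75 * e * sev, 0.2)
        plogis(mu + rnorm(n, 0, 0.7))
      },
      stop("unknown gridded sensor")
    )
    fast_tbl(hour = h, value = val)
  })
}

# Battery trace: piecewise linear drain with 0-2 charge episodes.
simulate_battery_day <- function(traits, seed, effects) {
  with_seed(seed, {
    h <- grid_hours()
    n <- length(h)
    e <- effects[["battery"]]
    sev <- 0.5 * traits[["trait_g"]] + 0.25 * traits[["trait_si"]] +
      0.25 * traits[["trait_ed"]]
    drain <- 0.25 * runif(1, 1.5, 4.0) *
      exp(0.20 * e * sev)  # %/sample; heavier phone use when severe
    # severity raises the chance of active nighttime use (extra drain at
    # night instead of an idle flat trace)
    p_night_use <- plogis(-0.8 + 0.6 * e * sev)
    night <- is_night_hour(h)
    level <- numeric(n)
    level[1] <- runif(1, 55, 100)
    n_charges <- sample(0:2, 1, prob = c(0.3, 0.5, 0.2))
    charge_at <- sort(sample(2:n, n_charges))
    for (i in 2:n) {
      if (i %in% charge_at) {
        level[i] <- min(100, level[i - 1] + runif(1, 15, 45))
      } else {
        use <- if (night[i]) (runif(1) < p_night_use) else TRUE
        dec <- if (use) drain * runif(1, 0.3, 1.7) else 0
        level[i] <- max(0, level[i - 1] - dec)
      }
    }
    fast_tbl(hour = h, level = round(level, 1))
  })
}

# App-usage events for one user-day (Android only).
simulate_app_day <- function(traits, seed, effects) {
  with_seed(seed, {
    e <- effects[["app"]]
    n_events <- rpois(1, 28 * exp(0.12 * e * traits[["trait_si"]]))
    if (n_events == 0L) {
      return(fast_tbl(hour = numeric(0), app_id = character(0),
                      category = character(0), duration_s = numeric(0)))
    }
    cats <- app_categories()
    w <- c(camera = 0.04, communication = 0.22, entertainment = 0.16,
           gaming = 0.10, physical_health = 0.04, mental_health = 0.03,
           inapp = 0.04, news = 0.05, productivity = 0.10,
           social_media = 0.22)
    sev_ent <- 0.35 * traits[["trait_si"]] + 0.25 * traits[["trait_sdq"]] +
      0.25 * traits[["trait_ed"]] + 0.15 * traits[["trait_insomnia"]]
    w[["entertainment"]] <- w[["entertainment"]] * exp(0.6 * e * sev_ent)
    w <- w / sum(w)
    category <- sample(cats, n_events, replace = TRUE, prob = w[cats])
    # each user has a stable-ish pool of apps per category
    app_id <- paste0(category, "_app", sample(1:4, n_events, replace = TRUE))
    p_night <- plogis(-1.8 + 0.45 * e * (0.5 * traits[["trait_ed"]] +
                                           0.5 * traits[["trait_si"]]))
    at_night <- runif(n_events) < p_night
    hour <- ifelse(at_night,
                   (22 + runif(n_events, 0, 8)) %% 24,
                   runif(n_events, 6, 22))
    dur_mu <- log(180) + 0.18 * e * (0.5 * traits[["trait_si"]] +
                                       0.5 * traits[["trait_sdq"]])
    duration_s <- round(exp(dur_mu + rnorm(n_events, 0, 0.9)), 1)
    ord <- order(hour)
    fast_tbl(hour = hour[ord], app_id = app_id[ord], category = category[ord],
             duration_s = duration_s[ord])
  })
}

# Sessions in the sensing app itself.
simulate_inapp_day <- function(traits, seed, effects) {
  with_seed(seed, {
    e <- effects[["inapp"]]
    n_sess <- sample(1:3, 1)
    p_night <- plogis(-2 + 0.6 * e * (0.4 * traits[["trait_g"]] +
                                      0.3 * traits[["trait_si"]] +
                                      0.3 * traits[["trait_ed"]]))
    at_night <- runif(n_sess) < p_night
    start <- ifelse(at_night, (22 + runif(n_sess, 0, 8)) %% 24,
                    runif(n_sess, 7, 22))
    fast_tbl(start_hour = start,
             end_hour = pmin(start + runif(n_sess, 0.05, 0.3), 24))
  })
}

mobility_severity <- function(profile) {
  0.5 * profile$trait_sdq + 0.5 * profile$trait_si
}
steps_severity <- function(profile) {
  0.8 * profile$trait_g + 0.2 * profile$trait_insomnia
}

#' Generate a synthetic smartphone-sensing cohort
#'
#' Produces user profiles (platform, sex, school site, enabled sensors,
#' latent severity traits, home location), outcome scale scores calibrated
#' to the configured prevalences, daily 1-7 active responses, and raw
#' passive sensor event streams for every enabled sensor, then applies
#' engagement decay. Deterministic given the config (including its seed).
#'
#' @param config A [cohort_config()].
#' @param missingness Apply active-engagement decay (default `TRUE`).
#' @return A list of class `phenosense_cohort` with elements `profiles`,
#'   `outcomes`, `active`, `sensors` (named list of per-category tibbles)
#'   and `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_users = 5, seed = 7))
#' coh$profiles
#' @export
generate_cohort <- function(config = cohort_config(), missingness = TRUE) {
  if (!inherits(config, "cohort_config")) {
    stop_phenosense("`config` must be a cohort_config().",
                    "phenosense_config_error")
  }
  e <- config$effect_sizes
  cohort <- with_seed(config$seed, {
    profiles <- generate_profiles(config)
    outcomes <- generate_outcomes(profiles, config)
    base_seed <- config$seed

    active <- purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
      p <- profiles[i, ]
      purrr::map_dfr(seq_len(config$n_days), function(d) {
        simulate_active_day(p, d, child_seed(base_seed, i * 1000L + d),
                            effect = e[["active"]],
                            noise_scale = config$day_noise_scale %||% 1)
      })
    })

    sensors <- setNames(vector("list", length(sensor_categories())),
                        sensor_categories())
    tag <- function(tab, uid, d) {
      tab$user_id <- rep(uid, nrow(tab))
      tab$day <- rep(as.integer(d), nrow(tab))
      tab
    }
    gps_list <- list(); steps_list <- list(); app_list <- list()
    light_list <- list(); noise_list <- list(); bright_list <- list()
    batt_list <- list(); inapp_list <- list()
    for (i in seq_len(nrow(profiles))) {
      p <- profiles[i, ]
      enabled <- enabled_sensor_list(p)
      traits <- as.list(p[1, c("trait_g", trait_cols())])
      for (d in seq_len(config$n_days)) {
        sd_i <- child_seed(base_seed, 7L * i * 10000L + d)
        if (any(c("location", "steps") %in% enabled)) {
          mob <- simulate_mobility_day(p, d, mobility_severity(p), sd_i,
                                       effect = e[["mobility"]],
                                       steps_effect = 0)
          if ("location" %in% enabled) {
            gps_list[[length(gps_list) + 1L]] <-
              tag(mob$track, p$user_id, d)
          }
          if ("steps" %in% enabled) {
            sev <- steps_severity(p)
            stp <- with_seed(child_seed(sd_i, 3L), {
              max(0, round(exp(log(6000) - 0.30 * e[["steps"]] * sev +
                                 rnorm(1, 0, 0.35))))
            })
            steps_list[[length(steps_list) + 1L]] <-
              tibble(user_id = p$user_id, day = d, steps = stp)
          }
        }
        if ("app_usage" %in% enabled) {
          app_list[[length(app_list) + 1L]] <-
            tag(simulate_app_day(traits, child_seed(sd_i, 11L), e),
                p$user_id, d)
        }
        if ("ambient_light" %in% enabled) {
          light_list[[length(light_list) + 1L]] <-
            tag(simulate_reading_day("ambient_light", traits,
                                     child_seed(sd_i, 13L), e), p$user_id, d)
        }
        if ("noise" %in% enabled) {
          noise_list[[length(noise_list) + 1L]] <-
            tag(simulate_reading_day("noise", traits,
                                     child_seed(sd_i, 17L), e), p$user_id, d)
        }
        if ("screen_brightness" %in% enabled) {
          bright_list[[length(bright_list) + 1L]] <-
            tag(simulate_reading_day("screen_brightness", traits,
                                     child_seed(sd_i, 19L), e), p$user_id, d)
        }
        if ("battery" %in% enabled) {
          batt_list[[length(batt_list) + 1L]] <-
            tag(simulate_battery_day(traits, child_seed(sd_i, 23L), e),
                p$user_id, d)
        }
        if ("inapp" %in% enabled) {
          inapp_list[[length(inapp_list) + 1L]] <-
            tag(simulate_inapp_day(traits, child_seed(sd_i, 29L), e),
                p$user_id, d)
        }
      }
    }
    empty <- function(...) tibble(...)
    sensors$location <- if (length(gps_list)) bind_rows(gps_list) else
      empty(hour = numeric(0), lat = numeric(0), lon = numeric(0),
            user_id = character(0), day = integer(0))
    sensors$steps <- if (length(steps_list)) bind_rows(steps_list) else
      empty(user_id = character(0), day = integer(0), steps = numeric(0))
    sensors$app_usage <- if (length(app_list)) bind_rows(app_list) else
      empty(hour = numeric(0), app_id = character(0), category = character(0),
            duration_s = numeric(0), user_id = character(0), day = integer(0))
    sensors$ambient_light <- if (length(light_list)) bind_rows(light_list) else
      empty(hour = numeric(0), value = numeric(0), user_id = character(0),
            day = integer(0))
    sensors$noise <- if (length(noise_list)) bind_rows(noise_list) else
      empty(hour = numeric(0), value = numeric(0), user_id = character(0),
            day = integer(0))
    sensors$screen_brightness <- if (length(bright_list))
      bind_rows(bright_list) else
      empty(hour = numeric(0), value = numeric(0), user_id = character(0),
            day = integer(0))
    sensors$battery <- if (length(batt_list)) bind_rows(batt_list) else
      empty(hour = numeric(0), level = numeric(0), user_id = character(0),
            day = integer(0))
    sensors$inapp <- if (length(inapp_list)) bind_rows(inapp_list) else
      empty(start_hour = numeric(0), end_hour = numeric(0),
            user_id = character(0), day = integer(0))

    structure(list(profiles = profiles, outcomes = outcomes, active = active,
                   sensors = sensors, config = config),
              class = "phenosense_cohort")
  })
  if (missingness) {
    cohort <- apply_missingness(cohort, config,
                                seed = child_seed(config$seed, 999983L))
  }
  cohort
}

#' Apply engagement decay and sensor gating to a cohort
#'
#' Active data follow a geometric dropout: each user has a last active day
#' drawn with a constant per-day hazard calibrated so the expected fraction
#' still responding on the final day equals `active_retention_final`; all
#' users respond on day 1. Sensor logs are restricted to each user's enabled
#' sensors (passive enablement is static over the study).
#'
#' @param cohort A `phenosense_cohort`.
#' @param config The [cohort_config()] (defaults to the cohort's own).
#' @param seed RNG seed for the dropout draws.
#' @return The cohort with dropped records and a `dropout_day` column added
#'   to `profiles`.
#' @export
apply_missingness <- function(cohort, config = cohort$config,
                              seed = child_seed(config$seed, 999983L)) {
  n_days <- config$n_days
  retention <- config$active_retention_final
  hazard <- 1 - retention^(1 / (n_days - 1))
  with_seed(seed, {
    n <- nrow(cohort$profiles)
    # geometric: P(last_day >= d) = (1 - hazard)^(d - 1)
    last_day <- if (hazard <= 0) rep(n_days, n) else
      pmin(1L + stats::rgeom(n, hazard), as.integer(n_days))
    cohort$profiles$dropout_day <- as.integer(last_day)
    keep <- left_join(cohort$active,
                      tibble(user_id = cohort$profiles$user_id,
                             .last = last_day),
                      by = "user_id")
    cohort$active <- cohort$active[keep$day <= keep$.last, , drop = FALSE]
    enabled <- lapply(seq_len(n), function(i)
      enabled_sensor_list(cohort$profiles[i, ]))
    names(enabled) <- cohort$profiles$user_id
    for (cat in names(cohort$sensors)) {
      tab <- cohort$sensors[[cat]]
      if (nrow(tab) == 0L) next
      ok_users <- names(enabled)[vapply(enabled, function(s) cat %in% s,
                                        logical(1))]
      cohort$sensors[[cat]] <- tab[tab$user_id %in% ok_users, , drop = FALSE]
    }
    cohort
  })
}

#' @export
print.phenosense_cohort <- function(x, ...) {
  cat("<phenosense_cohort>", nrow(x$profiles), "users x", x$config$n_days,
      "days;", nrow(x$active), "active responses\n")
  invisible(x)
}
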