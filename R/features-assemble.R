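# Assembly of the per-user-day feature matrix: active items pass through
# unchanged (1-7, sentinel when missed); each enabled sensor contributes its
# registry block; disabled sensors and empty days yield the sentinel.

feature_columns <- function(registry = feature_registry(),
                            active_items = active_item_registry()) {
  c(active_items$name, registry$name)
}

#' Assemble the per-user-day feature matrix
#'
#' One row per user-day over the study window. Active items are passed
#' through unchanged; raw sensor streams are reduced to their registry
#' feature blocks (GPS tracks are jump-filtered and homes inferred from
#' nighttime fixes first); anything unavailable is the sentinel -1.
#'
#' @param cohort A `phenosense_cohort` (generated or read from disk).
#' @param registry Passive-feature registry, see [feature_registry()].
#' @param active_items Active item registry.
#' @param max_speed_kmh GPS jump-filter threshold.
#' @return A tibble: `user_id`, `day`, then one column per active item and
#'   per passive feature.
#' @export
assemble_daily_features <- function(cohort, registry = feature_registry(),
                                    active_items = active_item_registry(),
                                    max_speed_kmh = 200) {
  n_days <- cohort$config$n_days %||%
    max(c(cohort$active$day, 1L,
          unlist(lapply(cohort$sensors, function(s) s$day))))
  users <- cohort$profiles$user_id
  grid <- tidyr::expand_grid(user_id = users, day = seq_len(n_days))
  key <- paste(grid$user_id, grid$day)
  nr <- nrow(grid)

  if (anyDuplicated(cohort$active[, c("user_id", "day", "item")])) {
    stop_phenosense("Duplicate user-day-item rows in active data.",
                    "phenosense_validation_error")
  }

  # Active block
  A <- matrix(SENTINEL, nr, nrow(active_items),
              dimnames = list(NULL, active_items$name))
  if (nrow(cohort$active) > 0L) {
    act <- cohort$active[cohort$active$item %in% active_items$name, ]
    ri <- match(paste(act$user_id, act$day), key)
    ci <- match(act$item, active_items$name)
    ok <- !is.na(ri)
    A[cbind(ri[ok], ci[ok])] <- act$value[ok]
  }

  # Passive block
  P <- matrix(SENTINEL, nr, nrow(registry),
              dimnames = list(NULL, registry$name))
  fill <- function(block_values, user_day_keys) {
    ri <- match(user_day_keys, key)
    ok <- !is.na(ri)
    P[ri[ok], colnames(block_values)] <<- block_values[ok, , drop = FALSE]
  }
  by_user_day <- function(tab) split(seq_len(nrow(tab)),
                                     paste(tab$user_id, tab$day))

  sensors <- cohort$sensors

  gps <- sensors$location
  if (!is.null(gps) && nrow(gps) > 0L) {
    homes <- lapply(split(gps, gps$user_id), infer_home)
    idx <- by_user_day(gps)
    vals <- t(vapply(names(idx), function(k) {
      rows <- gps[idx[[k]], , drop = FALSE]
      rows <- rows[order(rows$hour), , drop = FALSE]
      track <- filter_gps_jumps(rows, max_speed_kmh)
      location_feature_block(track, homes[[rows$user_id[1]]])
    }, numeric(15)))
    fill(vals, names(idx))
  }

  for (cat in c("ambient_light", "noise", "screen_brightness")) {
    tab <- sensors[[cat]]
    if (is.null(tab) || nrow(tab) == 0L) next
    prefix <- c(ambient_light = "light", noise = "noise",
                screen_brightness = "bright")[[cat]]
    with_max <- cat == "noise"
    idx <- by_user_day(tab)
    k_out <- if (with_max) 10L else 8L
    vals <- t(vapply(names(idx), function(k) {
      rows <- tab[idx[[k]], , drop = FALSE]
      reading_stats_block(rows$hour, rows$value, prefix, with_max)
    }, numeric(k_out)))
    fill(vals, names(idx))
  }

  app <- sensors$app_usage
  if (!is.null(app) && nrow(app) > 0L) {
    idx <- by_user_day(app)
    vals <- t(vapply(names(idx), function(k) {
      app_usage_block(app[idx[[k]], , drop = FALSE])
    }, numeric(36)))
    fill(vals, names(idx))
  }

  batt <- sensors$battery
  if (!is.null(batt) && nrow(batt) > 0L) {
    idx <- by_user_day(batt)
    vals <- t(vapply(names(idx), function(k) {
      rows <- batt[idx[[k]], , drop = FALSE]
      rows <- rows[order(rows$hour), , drop = FALSE]
      battery_block(rows$hour, rows$level)
    }, numeric(8)))
    fill(vals, names(idx))
  }

  stp <- sensors$steps
  if (!is.null(stp) && nrow(stp) > 0L) {
    vals <- t(vapply(seq_len(nrow(stp)), function(i) steps_block(stp$steps[i]),
                     numeric(4)))
    colnames(vals) <- registry_names("steps")
    fill(vals, paste(stp$user_id, stp$day))
  }

  inapp <- sensors$inapp
  if (!is.null(inapp) && nrow(inapp) > 0L) {
    idx <- by_user_day(inapp)
    vals <- t(vapply(names(idx), function(k) {
      inapp_block(inapp[idx[[k]], , drop = FALSE])
    }, numeric(3)))
    fill(vals, names(idx))
  }

  bind_cols(grid, as_tibble(A), as_tibble(P))
}

# Running median over the non-sentinel prefix of x; sentinel until the first
# observation.
cummedian_observed <- function(x) {
  out <- rep(SENTINEL, length(x))
  seen <- numeric(0)
  for (t in seq_along(x)) {
    if (!is_sentinel(x[t]) && !is.na(x[t])) seen <- c(seen, x[t])
    if (length(seen) > 0L) out[t] <- median(seen)
  }
  out
}

#' Cumulative-median aggregation of daily features
#'
#' Replaces each user's value of every feature on day t with the median of
#' that user's observed (non-sentinel) values on days 1..t. Smooths isolated
#' single-day anomalies while preserving sustained shifts; a day before the
#' first observation of a feature stays at the sentinel.
#'
#' @param features Output of [assemble_daily_features()].
#' @return Tibble of the same shape.
#' @export
cumulative_median_aggregate <- function(features) {
  stopifnot(all(c("user_id", "day") %in% names(features)))
  ord <- order(features$user_id, features$day)
  features <- features[ord, , drop = FALSE]
  cols <- setdiff(names(features), c("user_id", "day"))
  mat <- as.matrix(features[, cols])
  idx <- split(seq_len(nrow(features)), features$user_id)
  for (rows in idx) {
    mat[rows, ] <- apply(mat[rows, , drop = FALSE], 2, cummedian_observed)
  }
  features[, cols] <- as_tibble(mat)
  features
}

#' Fit a z-score normalizer on training rows
#'
#' Continuous feature columns are centred and scaled by the mean and
#' population SD of their non-sentinel values over the training rows only;
#' binary indicator columns are left untouched. A zero training SD leaves
#' the column centred with a unit divisor (with a warning).
#'
#' @param features Feature tibble.
#' @param train_flags Logical vector flagging training rows.
#' @param registry Passive registry (identifies binary columns).
#' @param active_items Active item registry.
#' @return An object of class `feature_normalizer`.
#' @export
fit_normalizer <- function(features, train_flags,
                           registry = feature_registry(),
                           active_items = active_item_registry()) {
  stopifnot(length(train_flags) == nrow(features))
  binary_cols <- registry$name[registry$kind == "binary"]
  cols <- intersect(feature_columns(registry, active_items), names(features))
  cont <- setdiff(cols, binary_cols)
  train <- features[train_flags, , drop = FALSE]
  stats_tab <- lapply(cont, function(cl) {
    v <- train[[cl]]
    v <- v[!is_sentinel(v) & !is.na(v)]
    if (length(v) == 0L) return(c(mean = 0, sd = 1))
    s <- pop_sd(v)
    if (!is.finite(s) || s == 0) {
      rlang::warn(sprintf("Zero training SD for '%s'; column left centred.",
                          cl))
      s <- 1
    }
    c(mean = mean(v), sd = s)
  })
  names(stats_tab) <- cont
  structure(list(
    continuous = cont, binary = intersect(binary_cols, cols),
    means = vapply(stats_tab, `[[`, numeric(1), "mean"),
    sds = vapply(stats_tab, `[[`, numeric(1), "sd")
  ), class = "feature_normalizer")
}

#' Apply a fitted normalizer
#'
#' Transforms with the training statistics only; sentinel cells are
#' reinserted as -1 after scaling so -1 always means "unavailable".
#'
#' @param normalizer A `feature_normalizer`.
#' @param features Feature tibble (training or test rows).
#' @return The transformed tibble.
#' @export
apply_normalizer <- function(normalizer, features) {
  stopifnot(inherits(normalizer, "feature_normalizer"))
  for (cl in normalizer$continuous) {
    v <- features[[cl]]
    obs <- !is_sentinel(v) & !is.na(v)
    v[obs] <- (v[obs] - normalizer$means[[cl]]) / normalizer$sds[[cl]]
    v[!obs & !is.na(v)] <- SENTINEL
    features[[cl]] <- v
  }
  features
}

#' Fit a normalizer on the training rows and transform the whole matrix
#'
#' @inheritParams fit_normalizer
#' @return List with `features` (transformed) and `normalizer`.
#' @export
fit_apply_normalizer <- function(features, train_flags,
                                 registry = feature_registry(),
                                 active_items = active_item_registry()) {
  nz <- fit_normalizer(features, train_flags, registry, active_items)
  list(features = apply_normalizer(nz, features), normalizer = nz)
}
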