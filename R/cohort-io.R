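#' Write a cohort to a directory of delimited-text tables
#'
#' Layout: `profiles.csv`, `outcomes.csv`, `active.csv`,
#' `sensors/<category>.csv`, plus `manifest.json` carrying the schema
#' version, the generating config and its seed.
#'
#' @param cohort A `phenosense_cohort`.
#' @param dir Target directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "sensors"), recursive = TRUE,
             showWarnings = FALSE)
  readr::write_csv(cohort$profiles, file.path(dir, "profiles.csv"),
                   progress = FALSE)
  readr::write_csv(cohort$outcomes, file.path(dir, "outcomes.csv"),
                   progress = FALSE)
  readr::write_csv(cohort$active, file.path(dir, "active.csv"),
                   progress = FALSE)
  for (cat in names(cohort$sensors)) {
    readr::write_csv(cohort$sensors[[cat]],
                     file.path(dir, "sensors", paste0(cat, ".csv")),
                     progress = FALSE)
  }
  manifest <- list(schema_version = 1L,
                   seed = cohort$config$seed,
                   config = unclass(cohort$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

mandatory_cols <- function() {
  list(profiles = c("user_id", "platform", "enabled_sensors", "home_lat",
                    "home_lon"),
       outcomes = c("user_id", "sdq_total", "sci_total", "ed15_total",
                    "si_frequency"),
       active = c("user_id", "day", "item", "value"))
}

read_cohort_table <- function(path, required) {
  tab <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) {
      stop_phenosense(sprintf("Failed to parse %s: %s", path,
                              conditionMessage(e)),
                      "phenosense_parse_error")
    }
  )
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop_phenosense(
      sprintf("%s: line 1: missing mandatory column(s): %s", path,
              paste(missing, collapse = ", ")),
      "phenosense_parse_error"
    )
  }
  probs <- readr::problems(tab)
  if (nrow(probs) > 0L) {
    stop_phenosense(
      sprintf("%s: line %d: %s", path, probs$row[1] + 1L,
              probs$expected[1]),
      "phenosense_parse_error"
    )
  }
  tab
}

#' Read a cohort written by [write_cohort()]
#'
#' A seed mismatch between the manifest and its embedded config is reported
#' as a warning and the data are still loaded; a missing mandatory column is
#' a parse error naming the file.
#'
#' @param dir Directory produced by [write_cohort()].
#' @return A `phenosense_cohort`.
#' @export
read_cohort <- function(dir) {
  req <- mandatory_cols()
  profiles <- read_cohort_table(file.path(dir, "profiles.csv"),
                                req$profiles)
  # empty sensor sets serialize as empty strings, which read back as NA
  profiles$enabled_sensors[is.na(profiles$enabled_sensors)] <- ""
  outcomes <- read_cohort_table(file.path(dir, "outcomes.csv"),
                                req$outcomes)
  active <- read_cohort_table(file.path(dir, "active.csv"), req$active)
  sensors <- list()
  for (cat in sensor_categories()) {
    path <- file.path(dir, "sensors", paste0(cat, ".csv"))
    if (file.exists(path)) {
      sensors[[cat]] <- read_cohort_table(path, "user_id")
    }
  }
  manifest_path <- file.path(dir, "manifest.json")
  config <- NULL
  if (file.exists(manifest_path)) {
    manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    config <- manifest$config
    if (!is.null(config)) {
      for (f in c("prevalence", "effect_sizes", "sensor_optin_rates")) {
        config[[f]] <- unlist(config[[f]])
      }
      class(config) <- "cohort_config"
    }
    if (!is.null(manifest$seed) && !is.null(config$seed) &&
        manifest$seed != config$seed) {
      rlang::warn(sprintf(
        "manifest seed (%s) does not match config seed (%s); loading anyway",
        manifest$seed, config$seed))
    }
  }
  structure(list(profiles = profiles, outcomes = outcomes, active = active,
                 sensors = sensors, config = config),
            class = "phenosense_cohort")
}
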