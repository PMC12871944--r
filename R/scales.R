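#' Outcome scales and high-risk thresholds
#'
#' Four self-report outcome measures anchor the classification tasks:
#' the Strengths and Difficulties Questionnaire total (SDQ, 0-40), the Sleep
#' Condition Indicator (SCI, 0-32), the ED-15 eating-disorder score (0-6,
#' continuous mean-style score), and a single suicidal-ideation frequency
#' item (0-4). High risk is defined as SDQ >= 16, SCI <= 16 (probable
#' insomnia; equivalent to < 17 on integer scores), ED-15 strictly > 2.69
#' (nonclinical mean + 1 SD), and any nonzero ideation frequency.
#'
#' @param sdq_high_min SDQ total at or above which a user is high risk.
#' @param sci_high_max SCI total at or below which a user is high risk.
#' @param ed15_high_exclusive_min ED-15 score strictly above which a user is
#'   high risk.
#' @param si_high_min Ideation frequency at or above which a user is high
#'   risk.
#' @return A list of class `threshold_config`.
#' @examples
#' threshold_config()
#' @export
threshold_config <- function(sdq_high_min = 16, sci_high_max = 16,
                             ed15_high_exclusive_min = 2.69,
                             si_high_min = 1) {
  cfg <- list(
    sdq_high_min = sdq_high_min, sci_high_max = sci_high_max,
    ed15_high_exclusive_min = ed15_high_exclusive_min,
    si_high_min = si_high_min
  )
  ranges <- scale_ranges()
  bad <- cfg$sdq_high_min < ranges$sdq[1] || cfg$sdq_high_min > ranges$sdq[2] ||
    cfg$sci_high_max < ranges$sci[1] || cfg$sci_high_max > ranges$sci[2] ||
    cfg$ed15_high_exclusive_min < ranges$ed15[1] ||
    cfg$ed15_high_exclusive_min > ranges$ed15[2] ||
    cfg$si_high_min < ranges$si[1] || cfg$si_high_min > ranges$si[2]
  if (bad) {
    stop_phenosense("Thresholds must lie within their scale ranges.",
                    "phenosense_config_error")
  }
  structure(cfg, class = "threshold_config")
}

scale_ranges <- function() {
  list(sdq = c(0, 40), sci = c(0, 32), ed15 = c(0, 6), si = c(0, 4))
}

#' The four outcome identifiers
#' @return `c("sdq", "insomnia", "si", "ed")`.
#' @export
outcome_names <- function() c("sdq", "insomnia", "si", "ed")

#' Binarize outcome scores into high-risk labels
#'
#' @param scores A data frame with columns `user_id`, `sdq_total`,
#'   `sci_total`, `ed15_total`, `si_frequency`.
#' @param thresholds A [threshold_config()].
#' @return A tibble with `user_id` and logical columns `sdq_high`,
#'   `insomnia_high`, `si_high`, `ed_high`.
#' @examples
#' scores <- tibble::tibble(user_id = "u1", sdq_total = 16, sci_total = 17,
#'                          ed15_total = 2.69, si_frequency = 0)
#' binarize_outcomes(scores)
#' @export
binarize_outcomes <- function(scores, thresholds = threshold_config()) {
  stopifnot(inherits(thresholds, "threshold_config"))
  needed <- c("user_id", "sdq_total", "sci_total", "ed15_total",
              "si_frequency")
  if (!all(needed %in% names(scores))) {
    stop_phenosense(
      paste0("`scores` must have columns: ", paste(needed, collapse = ", ")),
      "phenosense_validation_error"
    )
  }
  r <- scale_ranges()
  in_range <- function(x, rg) all(is.finite(x) & x >= rg[1] & x <= rg[2])
  if (!in_range(scores$sdq_total, r$sdq) || !in_range(scores$sci_total, r$sci) ||
      !in_range(scores$ed15_total, r$ed15) ||
      !in_range(scores$si_frequency, r$si)) {
    stop_phenosense("Outcome scores outside their scale ranges.",
                    "phenosense_validation_error")
  }
  tibble(
    user_id = scores$user_id,
    sdq_high = scores$sdq_total >= thresholds$sdq_high_min,
    insomnia_high = scores$sci_total <= thresholds$sci_high_max,
    si_high = scores$si_frequency >= thresholds$si_high_min,
    ed_high = scores$ed15_total > thresholds$ed15_high_exclusive_min
  )
}

#' Per-outcome prevalence summary
#'
#' @param labels Output of [binarize_outcomes()].
#' @return A tibble with `outcome`, `n_high`, `n`, `pct_high` (one-decimal
#'   percentage).
#' @examples
#' labels <- tibble::tibble(user_id = 1:103,
#'                          sdq_high = c(rep(TRUE, 31), rep(FALSE, 72)),
#'                          insomnia_high = FALSE, si_high = FALSE,
#'                          ed_high = FALSE)
#' prevalence_summary(labels) # SDQ: 31 of 103 = 30.1%
#' @export
prevalence_summary <- function(labels) {
  if (is.null(labels) || nrow(labels) == 0L) {
    stop_phenosense("`labels` is empty.", "phenosense_validation_error")
  }
  cols <- c("sdq_high", "insomnia_high", "si_high", "ed_high")
  n <- nrow(labels)
  tibble(
    outcome = outcome_names(),
    n_high = vapply(cols, function(cl) sum(labels[[cl]]), integer(1),
                    USE.NAMES = FALSE),
    n = n
  ) |>
    mutate(pct_high = round(100 * .data$n_high / .data$n, 1))
}

# Map outcome id -> label column of binarize_outcomes() output.
outcome_label_col <- function(outcome) {
  switch(outcome,
    sdq = "sdq_high", insomnia = "insomnia_high", si = "si_high",
    ed = "ed_high",
    stop_phenosense(sprintf("Unknown outcome '%s'.", outcome),
                    "phenosense_validation_error")
  )
}

# Map outcome id -> continuous score column.
outcome_score_col <- function(outcome) {
  switch(outcome,
    sdq = "sdq_total", insomnia = "sci_total", si = "si_frequency",
    ed = "ed15_total",
    stop_phenosense(sprintf("Unknown outcome '%s'.", outcome),
                    "phenosense_validation_error")
  )
}
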