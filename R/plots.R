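#' Plot per-repetition balanced accuracy of LOSO experiments
#'
#' @param object A `loso_result` (or list of them).
#' @param ... Further `loso_result`s to compare.
#' @return A ggplot object: balanced accuracy by experiment with a dashed
#'   chance line at 0.5.
#' @method autoplot loso_result
#' @export
autoplot.loso_result <- function(object, ...) {
  results <- c(list(object), Filter(function(x) inherits(x, "loso_result"),
                                    list(...)))
  dat <- purrr::map_dfr(results, tidy) |>
    filter(.data$metric == "balanced_accuracy") |>
    mutate(experiment = paste(.data$outcome, .data$modality,
                              ifelse(.data$pretraining, "pretrained",
                                     "no-pretrain")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$experiment, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = NULL, y = "Balanced accuracy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Engagement-decay plot for a cohort
#'
#' Users contributing active data and passive data per study day.
#'
#' @param cohort A `phenosense_cohort`.
#' @return A ggplot object.
#' @export
plot_engagement <- function(cohort) {
  n_days <- cohort$config$n_days
  act <- cohort$active |>
    dplyr::distinct(.data$user_id, .data$day) |>
    dplyr::count(.data$day) |>
    mutate(stream = "active")
  pas <- purrr::map_dfr(cohort$sensors, function(s) {
    if (is.null(s) || nrow(s) == 0L || !"day" %in% names(s)) return(NULL)
    dplyr::distinct(s, .data$user_id, .data$day)
  }) |>
    dplyr::distinct(.data$user_id, .data$day) |>
    dplyr::count(.data$day) |>
    mutate(stream = "passive")
  ggplot2::ggplot(bind_rows(act, pas),
                  ggplot2::aes(x = .data$day, y = .data$n,
                               colour = .data$stream)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = seq_len(n_days)) +
    ggplot2::labs(x = "Study day", y = "Users contributing",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Importance bar plot (sensor categories + active items)
#'
#' @param importance Output of [aggregate_importance_by_sensor()].
#' @param top_n Number of terms shown.
#' @return A ggplot object.
#' @export
plot_importance <- function(importance, top_n = 15L) {
  dat <- utils::head(arrange(importance, dplyr::desc(.data$importance)),
                     top_n)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$term, .data$importance),
    y = .data$importance, fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Mean |attribution| (summed by sensor)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Association heat map of an AssociationTable
#'
#' @param assoc Output of [spearman_table()], typically filtered to the
#'   features of interest.
#' @return A ggplot object.
#' @export
plot_associations <- function(assoc) {
  ggplot2::ggplot(assoc, ggplot2::aes(x = .data$outcome, y = .data$feature,
                                      fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
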