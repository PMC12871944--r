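#' Leave-one-subject-out folds
#'
#' @param user_ids Vector of unique user ids (>= 3).
#' @return List of folds, each `list(train = <ids>, test = <id>)`; every
#'   user tests exactly once.
#' @export
loso_folds <- function(user_ids) {
  user_ids <- unique(user_ids)
  if (length(user_ids) < 3L) {
    stop_phenosense("LOSO needs at least 3 users.",
                    "phenosense_validation_error")
  }
  lapply(user_ids, function(u) {
    list(train = setdiff(user_ids, u), test = u)
  })
}

modality_columns <- function(features, modality,
                             registry = feature_registry(),
                             active_items = active_item_registry()) {
  active_cols <- intersect(active_items$name, names(features))
  passive_cols <- intersect(registry$name, names(features))
  switch(modality,
    active = active_cols,
    passive = passive_cols,
    combined = c(active_cols, passive_cols),
    stop_phenosense(sprintf("Unknown modality '%s'.", modality),
                    "phenosense_validation_error")
  )
}

# Users providing a modality: any non-sentinel cell in its columns.
users_with_modality <- function(features, cols) {
  has <- rowSums(!is_sentinel(as.matrix(features[, cols, drop = FALSE]))) > 0
  unique(features$user_id[has])
}

#' Run a repeated LOSO cross-validation experiment
#'
#' For each repetition and each leave-one-subject-out fold: the per-fold
#' normalizer is fitted on training rows only, the encoder is contrastively
#' pretrained on training rows (or the whole network trained end-to-end in
#' the no-pretraining arm), the classification head is fine-tuned with
#' inverse-frequency class weights from the training fold, and the held-out
#' user's day probabilities are averaged into one user-level prediction.
#' Per-repetition seeds are derived deterministically from `seed`.
#'
#' When comparing modalities the cohort is restricted to users providing
#' both active and passive data (`restrict_both = TRUE`, the default).
#'
#' @param features Aggregated (cumulative-median) feature tibble from
#'   [cumulative_median_aggregate()]; unnormalized.
#' @param labels Output of [binarize_outcomes()].
#' @param outcome One of `"sdq"`, `"insomnia"`, `"si"`, `"ed"`.
#' @param modality `"active"`, `"passive"` or `"combined"`.
#' @param pretraining Use contrastive pretraining + frozen encoder (`TRUE`)
#'   or the end-to-end no-pretraining ablation (`FALSE`).
#' @param repetitions Number of repeated runs (model/triplet re-seeding).
#' @param seed Master seed.
#' @param restrict_both Restrict to users providing both modalities.
#' @param pre_cfg,fine_cfg Model configurations.
#' @param registry,active_items Feature registries.
#' @param audit Collect per-fold leakage-audit records.
#' @return Object of class `loso_result`: per-repetition user probabilities
#'   (`predictions`), per-repetition metrics (`rep_metrics`), the mean (SD)
#'   `report`, seeds, skipped-fold count and optional `audit` table.
#' @export
run_loso_experiment <- function(features, labels, outcome,
                                modality = "combined", pretraining = TRUE,
                                repetitions = 10L, seed = 1L,
                                restrict_both = TRUE,
                                pre_cfg = pretrain_config(),
                                fine_cfg = finetune_config(),
                                registry = feature_registry(),
                                active_items = active_item_registry(),
                                audit = FALSE) {
  cols <- modality_columns(features, modality, registry, active_items)
  if (restrict_both) {
    a_users <- users_with_modality(
      features, modality_columns(features, "active", registry, active_items))
    p_users <- users_with_modality(
      features, modality_columns(features, "passive", registry, active_items))
    keep <- intersect(a_users, p_users)
    features <- features[features$user_id %in% keep, , drop = FALSE]
  }
  label_col <- outcome_label_col(outcome)
  user_labels <- labels[[label_col]][match(unique(features$user_id),
                                           labels$user_id)]
  names(user_labels) <- unique(features$user_id)
  folds <- loso_folds(unique(features$user_id))
  row_user <- features$user_id
  row_label <- user_labels[row_user]

  rep_seeds <- vapply(seq_len(repetitions), function(r) child_seed(seed, r),
                      integer(1))
  predictions <- list()
  rep_metrics <- list()
  audit_rows <- list()
  skipped <- 0L
  for (r in seq_len(repetitions)) {
    probs <- rep(NA_real_, length(folds))
    test_users <- vapply(folds, `[[`, character(1), "test")
    for (f in seq_along(folds)) {
      fold <- folds[[f]]
      tr <- row_user %in% fold$train
      te <- row_user == fold$test
      stopifnot(!any(tr & te))  # leakage guard: test rows out of training
      tr_labels <- row_label[tr]
      if (all(tr_labels) || !any(tr_labels)) {
        rlang::warn(sprintf("Fold %d skipped: single-class training fold.",
                            f))
        skipped <- skipped + 1L
        next
      }
      fold_seed <- child_seed(rep_seeds[r], f)
      nz <- fit_normalizer(features[tr, , drop = FALSE], rep(TRUE, sum(tr)),
                           registry, active_items)
      ftr <- apply_normalizer(nz, features[tr, , drop = FALSE])
      fte <- apply_normalizer(nz, features[te, , drop = FALSE])
      cw <- compute_class_weights(tr_labels)
      if (pretraining) {
        enc <- pretrain_encoder(ftr, cols, pre_cfg, seed = fold_seed)
        clf <- finetune_classifier(enc, ftr, tr_labels, fine_cfg,
                                   seed = child_seed(fold_seed, 2L),
                                   class_weights = cw)
      } else {
        clf <- train_end_to_end(ftr, cols, tr_labels, pre_cfg, fine_cfg,
                                seed = fold_seed, class_weights = cw)
      }
      probs[f] <- predict_user(clf, fte)$probability
      if (audit) {
        held_out <- fold$test
        audit_rows[[length(audit_rows) + 1L]] <- tibble(
          rep = r, fold = f, test_user = held_out,
          test_in_train_rows = any(tr & te),
          test_in_triplet_pool = held_out %in% unique(ftr$user_id),
          test_in_weight_pool = held_out %in% row_user[tr],
          normalizer_mean_1 = unname(nz$means[1])
        )
      }
    }
    ok <- !is.na(probs)
    predictions[[r]] <- tibble(rep = r, user_id = test_users[ok],
                               probability = probs[ok],
                               label = unname(user_labels[test_users[ok]]))
    cm <- confusion_and_metrics(user_labels[test_users[ok]], probs[ok])
    rep_metrics[[r]] <- bind_cols(tibble(rep = r), cm$metrics)
  }
  rep_metrics <- bind_rows(rep_metrics)
  structure(list(
    outcome = outcome, modality = modality, pretraining = pretraining,
    predictions = bind_rows(predictions), rep_metrics = rep_metrics,
    report = metrics_report(rep_metrics), seeds = rep_seeds,
    skipped_folds = skipped,
    audit = if (audit) bind_rows(audit_rows) else NULL
  ), class = "loso_result")
}

#' Mean (SD) metric report across repetitions
#'
#' @param rep_metrics Tibble of per-repetition metrics (a `rep` column plus
#'   metric columns).
#' @return Tibble with `metric`, `mean`, `sd` (SD over one repetition is 0).
#' @export
metrics_report <- function(rep_metrics) {
  cols <- setdiff(names(rep_metrics), "rep")
  tibble(
    metric = cols,
    mean = vapply(cols, function(cl) mean(rep_metrics[[cl]]), numeric(1),
                  USE.NAMES = FALSE),
    sd = vapply(cols, function(cl) {
      s <- sd(rep_metrics[[cl]])
      if (is.na(s)) 0 else s
    }, numeric(1), USE.NAMES = FALSE)
  )
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("<loso_result> outcome=%s modality=%s pretraining=%s reps=%d\n",
              x$outcome, x$modality, x$pretraining, nrow(x$rep_metrics)))
  ba <- x$report[x$report$metric == "balanced_accuracy", ]
  cat(sprintf("  balanced accuracy %.3f (SD %.3f)\n", ba$mean, ba$sd))
  invisible(x)
}

#' External validation on a fully held-out cohort
#'
#' The complete pipeline (normalizer, contrastive pretraining, fine-tuning)
#' is fitted on the training cohort only and evaluated once per repetition
#' on the held-out cohort's users; no holdout statistics are used upstream.
#'
#' @param train_cohort,holdout_cohort `phenosense_cohort` objects with
#'   disjoint user sets.
#' @param outcome,modality,pretraining,repetitions,seed As in
#'   [run_loso_experiment()].
#' @param pre_cfg,fine_cfg Model configurations.
#' @return A `loso_result`-shaped object (class `external_result`).
#' @export
external_validation <- function(train_cohort, holdout_cohort, outcome,
                                modality = "combined", pretraining = TRUE,
                                repetitions = 10L, seed = 1L,
                                pre_cfg = pretrain_config(),
                                fine_cfg = finetune_config()) {
  overlap <- intersect(train_cohort$profiles$user_id,
                       holdout_cohort$profiles$user_id)
  if (length(overlap) > 0L) {
    stop_phenosense("Train and holdout cohorts share users.",
                    "phenosense_validation_error")
  }
  f_tr <- cumulative_median_aggregate(assemble_daily_features(train_cohort))
  f_ho <- cumulative_median_aggregate(assemble_daily_features(holdout_cohort))
  lab_tr <- binarize_outcomes(train_cohort$outcomes)
  lab_ho <- binarize_outcomes(holdout_cohort$outcomes)
  label_col <- outcome_label_col(outcome)
  cols <- modality_columns(f_tr, modality)
  tr_labels <- lab_tr[[label_col]][match(f_tr$user_id, lab_tr$user_id)]
  ho_users <- unique(f_ho$user_id)
  ho_labels <- lab_ho[[label_col]][match(ho_users, lab_ho$user_id)]

  rep_seeds <- vapply(seq_len(repetitions), function(r) child_seed(seed, r),
                      integer(1))
  predictions <- list()
  rep_metrics <- list()
  nz <- fit_normalizer(f_tr, rep(TRUE, nrow(f_tr)))
  ftr <- apply_normalizer(nz, f_tr)
  fho <- apply_normalizer(nz, f_ho)
  cw <- compute_class_weights(tr_labels)
  for (r in seq_len(repetitions)) {
    if (pretraining) {
      enc <- pretrain_encoder(ftr, cols, pre_cfg, seed = rep_seeds[r])
      clf <- finetune_classifier(enc, ftr, tr_labels, fine_cfg,
                                 seed = child_seed(rep_seeds[r], 2L),
                                 class_weights = cw)
    } else {
      clf <- train_end_to_end(ftr, cols, tr_labels, pre_cfg, fine_cfg,
                              seed = rep_seeds[r], class_weights = cw)
    }
    probs <- vapply(ho_users, function(u) {
      predict_user(clf, fho[fho$user_id == u, , drop = FALSE])$probability
    }, numeric(1))
    predictions[[r]] <- tibble(rep = r, user_id = ho_users,
                               probability = unname(probs),
                               label = ho_labels)
    cm <- confusion_and_metrics(ho_labels, probs)
    rep_metrics[[r]] <- bind_cols(tibble(rep = r), cm$metrics)
  }
  rep_metrics <- bind_rows(rep_metrics)
  structure(list(
    outcome = outcome, modality = modality, pretraining = pretraining,
    predictions = bind_rows(predictions), rep_metrics = rep_metrics,
    report = metrics_report(rep_metrics), seeds = rep_seeds,
    skipped_folds = 0L, audit = NULL
  ), class = c("external_result", "loso_result"))
}

default_score_bins <- function(outcome) {
  switch(outcome,
    sdq = c(-Inf, 8, 16, 24, Inf),
    insomnia = c(-Inf, 8, 16, 24, Inf),
    si = c(-Inf, 0, 1, 2, 3, Inf),
    ed = c(-Inf, 2, 4, Inf)
  )
}

#' Stratified accuracy report
#'
#' Per-group prediction accuracy across outcome-score bins, or per-subgroup
#' balanced accuracy for sex, school site, or enabled-sensor count (split at
#' <= 3 vs > 3 sensors by default). User-level predictions are the
#' across-repetition mean probabilities thresholded at 0.5. Empty groups are
#' omitted with a warning; balanced accuracy is `NA` for one-class groups.
#'
#' @param result A `loso_result`.
#' @param cohort The evaluated `phenosense_cohort` (profiles + outcomes).
#' @param grouping `"score_bins"`, `"sex"`, `"site"` or `"sensor_count"`.
#' @param bins Score-bin edges (score-bin grouping only).
#' @param sensor_split Sensor-count split point.
#' @return Tibble with group, n, accuracy and (for subgroup groupings)
#'   balanced accuracy.
#' @export
stratified_report <- function(result, cohort,
                              grouping = c("score_bins", "sex", "site",
                                           "sensor_count"),
                              bins = default_score_bins(result$outcome),
                              sensor_split = 3L) {
  grouping <- match.arg(grouping)
  preds <- result$predictions |>
    group_by(.data$user_id) |>
    summarise(probability = mean(.data$probability),
              label = .data$label[1], .groups = "drop") |>
    mutate(pred = .data$probability >= 0.5)
  prof <- cohort$profiles
  group_var <- switch(grouping,
    score_bins = {
      score_col <- outcome_score_col(result$outcome)
      sc <- cohort$outcomes[[score_col]][match(preds$user_id,
                                               cohort$outcomes$user_id)]
      cut(sc, breaks = bins)
    },
    sex = prof$sex[match(preds$user_id, prof$user_id)],
    site = prof$site[match(preds$user_id, prof$user_id)],
    sensor_count = {
      ns <- vapply(match(preds$user_id, prof$user_id), function(i) {
        length(enabled_sensor_list(prof[i, ]))
      }, integer(1))
      ifelse(ns <= sensor_split, paste0("<=", sensor_split, " sensors"),
             paste0(">", sensor_split, " sensors"))
    }
  )
  preds$group <- as.character(group_var)
  if (anyNA(preds$group)) {
    rlang::warn("Users with undefined grouping omitted.")
    preds <- preds[!is.na(preds$group), , drop = FALSE]
  }
  all_levels <- if (grouping == "score_bins") {
    levels(group_var)
  } else unique(preds$group)
  empty <- setdiff(all_levels, unique(preds$group))
  if (length(empty) > 0L) {
    rlang::warn(paste0("Empty group(s) omitted: ",
                       paste(empty, collapse = ", ")))
  }
  preds |>
    group_by(.data$group) |>
    summarise(
      n = dplyr::n(),
      accuracy = mean(.data$pred == .data$label),
      balanced_accuracy = {
        if (any(.data$label) && any(!.data$label)) {
          (mean(.data$pred[.data$label]) +
             mean(!.data$pred[!.data$label])) / 2
        } else NA_real_
      },
      .groups = "drop"
    )
}
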