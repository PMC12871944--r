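# Association screens, group-difference tests and model attributions.

#' Per-user feature medians across days
#'
#' Association analyses correlate features with per-user scale scores, so
#' daily features are reduced to each user's median over observed
#' (non-sentinel) days.
#'
#' @param features Daily feature tibble (raw or aggregated).
#' @param cols Feature columns (default: every non-id column).
#' @return Tibble with `user_id` and one median column per feature; users
#'   with no observation of a feature get `NA` there.
#' @export
user_feature_medians <- function(features,
                                 cols = setdiff(names(features),
                                                c("user_id", "day"))) {
  features |>
    group_by(.data$user_id) |>
    summarise(across(dplyr::all_of(cols), function(v) {
      v <- v[!is_sentinel(v) & !is.na(v)]
      if (length(v) == 0L) NA_real_ else median(v)
    }), .groups = "drop")
}

#' Spearman association table between features and outcome scores
#'
#' Rank correlations (midrank ties) of per-user feature medians with the
#' four continuous outcome scores, with two-sided p-values and
#' Benjamini-Hochberg adjustment across features within each outcome.
#' Constant features are emitted with `NA` rho and a reason.
#'
#' @param user_features Output of [user_feature_medians()].
#' @param outcomes Outcome scores tibble (`user_id`, `sdq_total`,
#'   `sci_total`, `ed15_total`, `si_frequency`).
#' @param min_n Minimum number of complete pairs per feature.
#' @return Tibble: `feature`, `outcome`, `rho`, `p`, `p_adj`, `n`, `note`.
#' @export
spearman_table <- function(user_features, outcomes, min_n = 4L) {
  cols <- setdiff(names(user_features), "user_id")
  score_cols <- setNames(
    c("sdq_total", "sci_total", "si_frequency", "ed15_total"),
    c("sdq", "insomnia", "si", "ed"))
  rows <- purrr::map_dfr(names(score_cols), function(oc) {
    y_all <- outcomes[[score_cols[[oc]]]][match(user_features$user_id,
                                                outcomes$user_id)]
    purrr::map_dfr(cols, function(cl) {
      x <- user_features[[cl]]
      ok <- !is.na(x) & !is.na(y_all)
      x <- x[ok]; y <- y_all[ok]
      if (length(x) < min_n) {
        return(tibble(feature = cl, outcome = oc, rho = NA_real_,
                      p = NA_real_, n = length(x), note = "too few pairs"))
      }
      if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
        return(tibble(feature = cl, outcome = oc, rho = NA_real_,
                      p = NA_real_, n = length(x), note = "constant"))
      }
      ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                      exact = FALSE))
      tibble(feature = cl, outcome = oc, rho = unname(ct$estimate),
             p = ct$p.value, n = length(x), note = NA_character_)
    })
  })
  rows |>
    group_by(.data$outcome) |>
    mutate(p_adj = p.adjust(.data$p, method = "BH")) |>
    ungroup() |>
    select("feature", "outcome", "rho", "p", "p_adj", "n", "note")
}

#' Welch group-difference tests between risk groups
#'
#' Welch two-sample t-tests on standardized per-user feature medians
#' between high- and low-risk users, with Benjamini-Hochberg adjustment
#' across features; reports the direction of the difference and group
#' means/SEs on the standardized scale.
#'
#' @param user_features Output of [user_feature_medians()].
#' @param labels Logical high-risk label per user (aligned with
#'   `user_features$user_id`).
#' @param alternative Sidedness passed to [stats::t.test()].
#' @return Tibble: `feature`, `t`, `p`, `p_adj`, `mean_high`, `mean_low`,
#'   `se_high`, `se_low`, `direction`, `n_high`, `n_low`.
#' @export
group_difference_tests <- function(user_features, labels,
                                   alternative = "two.sided") {
  labels <- as.logical(labels)
  if (sum(labels) < 2L || sum(!labels) < 2L) {
    stop_phenosense("Each risk group needs >= 2 users.",
                    "phenosense_validation_error")
  }
  cols <- setdiff(names(user_features), "user_id")
  rows <- purrr::map_dfr(cols, function(cl) {
    x <- user_features[[cl]]
    ok <- !is.na(x)
    x <- x[ok]; g <- labels[ok]
    if (length(unique(x)) == 1L) {
      # no variance anywhere: no difference by convention
      return(tibble(feature = cl, t = 0, p = 1,
                    mean_high = 0, mean_low = 0, se_high = 0, se_low = 0,
                    direction = "none", n_high = sum(g), n_low = sum(!g)))
    }
    z <- (x - mean(x)) / sd(x)
    hi <- z[g]; lo <- z[!g]
    if (length(hi) < 2L || length(lo) < 2L) {
      return(tibble(feature = cl, t = NA_real_, p = NA_real_,
                    mean_high = NA_real_, mean_low = NA_real_,
                    se_high = NA_real_, se_low = NA_real_,
                    direction = NA_character_, n_high = length(hi),
                    n_low = length(lo)))
    }
    tt <- if (isTRUE(all.equal(var(hi), 0)) && isTRUE(all.equal(var(lo), 0))) {
      list(statistic = c(t = 0), p.value = 1)
    } else {
      t.test(hi, lo, alternative = alternative)
    }
    tibble(feature = cl, t = unname(tt$statistic), p = tt$p.value,
           mean_high = mean(hi), mean_low = mean(lo),
           se_high = sd(hi) / sqrt(length(hi)),
           se_low = sd(lo) / sqrt(length(lo)),
           direction = if (mean(hi) > mean(lo)) "higher_in_high_risk"
                       else if (mean(hi) < mean(lo)) "lower_in_high_risk"
                       else "none",
           n_high = length(hi), n_low = length(lo))
  })
  rows$p_adj <- p.adjust(rows$p, method = "BH")
  select(rows, "feature", "t", "p", "p_adj", "mean_high", "mean_low",
         "se_high", "se_low", "direction", "n_high", "n_low")
}

#' Sampling-Shapley attributions for a fitted classifier
#'
#' Model-agnostic Shapley attributions on the logit scale: for each
#' evaluation row, random feature permutations are walked from a background
#' row towards the evaluation row, attributing each feature its marginal
#' change in model output. Summed attributions equal the model output minus
#' the mean background output (telescoping), satisfying additivity.
#'
#' @param classifier A `phenosense_classifier`, or any function mapping a
#'   numeric feature matrix to a numeric output vector.
#' @param background Numeric matrix (or feature tibble) of background rows
#'   sampled from the training data.
#' @param rows Numeric matrix (or feature tibble) of evaluation rows.
#' @param n_perm Permutations per background row.
#' @param seed RNG seed.
#' @return Matrix (evaluation rows x features) of attributions.
#' @export
shap_attributions <- function(classifier, background, rows, n_perm = 1L,
                              seed = 1L) {
  f <- if (is.function(classifier)) {
    classifier
  } else {
    cols <- classifier$encoder$cols
    function(X) {
      colnames(X) <- cols
      Z <- mlp_forward(classifier$encoder$net, X)
      as.numeric(mlp_forward(classifier$head, Z))
    }
  }
  to_mat <- function(x) {
    if (is.data.frame(x)) {
      x <- x[, setdiff(names(x), c("user_id", "day")), drop = FALSE]
    }
    as.matrix(x)
  }
  B <- to_mat(background)
  X <- to_mat(rows)
  if (nrow(B) == 0L) {
    stop_phenosense("`background` must contain at least one row.",
                    "phenosense_validation_error")
  }
  d <- ncol(X)
  attr_mat <- matrix(0, nrow(X), d, dimnames = list(NULL, colnames(X)))
  with_seed(seed, {
    for (i in seq_len(nrow(X))) {
      x <- X[i, ]
      acc <- numeric(d)
      for (b in seq_len(nrow(B))) {
        for (p in seq_len(n_perm)) {
          perm <- sample.int(d)
          # walk: successively replace background coords by x along perm
          steps <- matrix(rep(B[b, ], d + 1L), d + 1L, d, byrow = TRUE)
          for (k in seq_len(d)) {
            steps[(k + 1L):(d + 1L), perm[k]] <- x[perm[k]]
          }
          out <- f(steps)
          acc[perm] <- acc[perm] + diff(out)
        }
      }
      attr_mat[i, ] <- acc / (nrow(B) * n_perm)
    }
  })
  attr_mat
}

#' Aggregate attribution importances by sensor category
#'
#' Mean absolute attribution per feature over the evaluated rows; passive
#' features are summed within their eight sensor categories while active
#' items are kept individual; sorted descending.
#'
#' @param attributions Matrix from [shap_attributions()] with feature
#'   column names.
#' @param registry Passive registry.
#' @param active_items Active item registry.
#' @return Tibble: `term`, `type` (`"sensor_category"` or `"active_item"`),
#'   `importance`.
#' @export
aggregate_importance_by_sensor <- function(attributions,
                                           registry = feature_registry(),
                                           active_items =
                                             active_item_registry()) {
  imp <- colMeans(abs(attributions))
  known <- c(registry$name, active_items$name)
  unknown <- setdiff(names(imp), known)
  if (length(unknown) > 0L) {
    stop_phenosense(paste0("Unregistered feature column(s): ",
                           paste(unknown, collapse = ", ")),
                    "phenosense_validation_error")
  }
  passive <- imp[names(imp) %in% registry$name]
  cat_of <- registry$category[match(names(passive), registry$name)]
  cat_imp <- tapply(passive, cat_of, sum)
  active <- imp[names(imp) %in% active_items$name]
  bind_rows(
    tibble(term = names(cat_imp), type = "sensor_category",
           importance = as.numeric(cat_imp)),
    tibble(term = names(active), type = "active_item",
           importance = as.numeric(active))
  ) |>
    arrange(dplyr::desc(.data$importance))
}
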