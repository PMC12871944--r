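#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy per-repetition metrics of a LOSO experiment
#'
#' @param x A `loso_result`.
#' @param ... Unused.
#' @return Long tibble: `rep`, `metric`, `value` plus experiment identifiers.
#' @method tidy loso_result
#' @export
tidy.loso_result <- function(x, ...) {
  x$rep_metrics |>
    tidyr::pivot_longer(-"rep", names_to = "metric", values_to = "value") |>
    mutate(outcome = x$outcome, modality = x$modality,
           pretraining = x$pretraining)
}

#' One-row summary of a LOSO experiment
#'
#' @param x A `loso_result`.
#' @param ... Unused.
#' @return One-row tibble with mean metrics, repetition count, skipped
#'   folds.
#' @method glance loso_result
#' @export
glance.loso_result <- function(x, ...) {
  wide <- setNames(as.list(x$report$mean), x$report$metric)
  bind_cols(
    tibble(outcome = x$outcome, modality = x$modality,
           pretraining = x$pretraining,
           n_users = length(unique(x$predictions$user_id)),
           repetitions = nrow(x$rep_metrics),
           skipped_folds = x$skipped_folds),
    as_tibble(wide)
  )
}

#' Tidy an encoder's training trace
#'
#' @param x A `phenosense_encoder`.
#' @param ... Unused.
#' @return Tibble `epoch`, `triplet_loss`.
#' @method tidy phenosense_encoder
#' @export
tidy.phenosense_encoder <- function(x, ...) {
  tibble(epoch = seq_along(x$loss_trace), triplet_loss = x$loss_trace)
}

#' One-row summary of an encoder
#' @param x A `phenosense_encoder`.
#' @param ... Unused.
#' @method glance phenosense_encoder
#' @export
glance.phenosense_encoder <- function(x, ...) {
  tibble(
    input_dim = x$net$widths[1],
    embedding_dim = x$net$widths[length(x$net$widths)],
    epochs = length(x$loss_trace),
    final_loss = if (length(x$loss_trace)) x$loss_trace[length(x$loss_trace)]
                 else NA_real_,
    margin = x$cfg$margin, seed = x$seed
  )
}

#' Tidy a classifier's layer weights
#'
#' @param x A `phenosense_classifier`.
#' @param ... Unused.
#' @return Tibble with one row per layer: size and weight norm.
#' @method tidy phenosense_classifier
#' @export
tidy.phenosense_classifier <- function(x, ...) {
  layers <- c(lapply(x$encoder$net$layers, function(l) c("encoder", l)),
              lapply(x$head$layers, function(l) c("head", l)))
  purrr::map_dfr(seq_along(layers), function(i) {
    l <- layers[[i]]
    tibble(component = l[[1]], layer = i,
           fan_in = nrow(l$W), fan_out = ncol(l$W),
           weight_norm = sqrt(sum(l$W^2)))
  })
}

#' One-row summary of a classifier
#' @param x A `phenosense_classifier`.
#' @param ... Unused.
#' @method glance phenosense_classifier
#' @export
glance.phenosense_classifier <- function(x, ...) {
  tibble(
    embedding_dim = x$encoder$net$widths[length(x$encoder$net$widths)],
    epochs = x$cfg$epochs,
    final_loss = if (length(x$loss_trace)) x$loss_trace[length(x$loss_trace)]
                 else NA_real_,
    weight_pos = x$class_weights[["pos"]],
    weight_neg = x$class_weights[["neg"]],
    seed = x$seed
  )
}
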