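#' Supervised fine-tuning configuration
#'
#' Defaults follow the study protocol: Adam at learning rate 1e-3, 20
#' epochs, batch size 1024, a 2-layer MLP classification head
#' (64 -> 32 -> 1), inverse-frequency class weights.
#'
#' @param lr Learning rate.
#' @param epochs Training epochs (>= 1).
#' @param batch Batch size (>= 1).
#' @param head_widths Hidden widths of the classification head, excluding
#'   its input and the final logit unit.
#' @return A list of class `finetune_config`.
#' @export
finetune_config <- function(lr = 1e-3, epochs = 20L, batch = 1024L,
                            head_widths = 32L) {
  if (epochs < 1L || batch < 1L) {
    stop_phenosense("`epochs` and `batch` must be >= 1.",
                    "phenosense_config_error")
  }
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch = as.integer(batch),
                 head_widths = as.integer(head_widths)),
            class = "finetune_config")
}

#' Inverse-frequency class weights
#'
#' Weight of class c is proportional to 1/count(c), normalized so the two
#' class weights average 1.
#'
#' @param labels Logical (or 0/1) training labels.
#' @return Named numeric vector `c(neg = ..., pos = ...)`.
#' @examples
#' compute_class_weights(c(rep(FALSE, 75), rep(TRUE, 25))) # 0.5, 1.5
#' @export
compute_class_weights <- function(labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop_phenosense("Both classes must be present to compute class weights.",
                    "phenosense_fold_error")
  }
  w <- c(neg = 1 / n_neg, pos = 1 / n_pos)
  w / mean(w)
}

weighted_bce_with_logits <- function(logits, y, w) {
  # log(1 + exp(z)) - y z, numerically stable
  softplus <- ifelse(logits > 0, logits + log1p(exp(-logits)),
                     log1p(exp(logits)))
  mean(w * (softplus - y * logits))
}

#' Fine-tune a classification head on a frozen encoder
#'
#' The pretrained encoder's weights are frozen (its embeddings are computed
#' once); a fresh 2-layer MLP head is trained with class-weighted binary
#' cross-entropy-with-logits by Adam. Rows inherit their user's label.
#'
#' @param encoder A `phenosense_encoder` (pretrained or untrained).
#' @param features Normalized feature tibble of training rows.
#' @param labels Logical vector, one element per row of `features`.
#' @param cfg A [finetune_config()].
#' @param seed RNG seed (head initialisation and batch order).
#' @param class_weights Optional named `c(neg=, pos=)` override.
#' @return Object of class `phenosense_classifier`: `encoder`, `head`,
#'   `cfg`, `loss_trace`, `class_weights`, `seed`.
#' @export
finetune_classifier <- function(encoder, features, labels,
                                cfg = finetune_config(), seed = 1L,
                                class_weights = NULL) {
  stopifnot(inherits(encoder, "phenosense_encoder"))
  y <- as.numeric(as.logical(labels))
  if (length(y) != nrow(features)) {
    stop_phenosense("`labels` must match rows of `features`.",
                    "phenosense_validation_error")
  }
  if (is.null(class_weights)) class_weights <- compute_class_weights(labels)
  Z <- encoder_embed(encoder, features_as_matrix(features, encoder$cols))
  w_row <- ifelse(y == 1, class_weights[["pos"]], class_weights[["neg"]])
  n <- nrow(Z)
  with_seed(seed, {
    head <- mlp_init(c(ncol(Z), cfg$head_widths, 1L))
    st <- adam_init(head)
    n_batches <- max(1L, ceiling(n / cfg$batch))
    loss_trace <- numeric(cfg$epochs)
    t_step <- 0L
    init_loss <- weighted_bce_with_logits(
      as.numeric(mlp_forward(head, Z)), y, w_row)
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      ep_loss <- numeric(n_batches)
      for (b in seq_len(n_batches)) {
        idx <- perm[(((b - 1L) * cfg$batch) + 1L):min(b * cfg$batch, n)]
        fw <- mlp_forward(head, Z[idx, , drop = FALSE], cache = TRUE)
        z <- as.numeric(fw$out)
        ep_loss[b] <- weighted_bce_with_logits(z, y[idx], w_row[idx])
        dz <- matrix(w_row[idx] * (plogis(z) - y[idx]) / length(idx),
                     ncol = 1L)
        g <- mlp_backward(head, fw, dz)$grads
        t_step <- t_step + 1L
        up <- adam_step(head, g, st, t_step, cfg$lr)
        head <- up$net; st <- up$state
      }
      loss_trace[epoch] <- mean(ep_loss)
    }
    structure(list(encoder = encoder, head = head, cfg = cfg,
                   init_loss = init_loss, loss_trace = loss_trace,
                   class_weights = class_weights, seed = as.integer(seed)),
              class = "phenosense_classifier")
  })
}

#' Day-level predicted probabilities
#'
#' @param classifier A `phenosense_classifier`.
#' @param features Normalized feature tibble.
#' @return Numeric vector of per-row probabilities.
#' @export
predict_days <- function(classifier, features) {
  Z <- encoder_embed(classifier$encoder,
                     features_as_matrix(features, classifier$encoder$cols))
  plogis(as.numeric(mlp_forward(classifier$head, Z)))
}

#' User-level prediction by day-probability averaging
#'
#' The user's day-wise prediction probabilities are averaged into a single
#' probability; the label is positive when the average is >= 0.5.
#'
#' @param classifier A `phenosense_classifier`.
#' @param rows Normalized feature rows of one user (>= 1 row).
#' @return List with `probability` and `label`.
#' @export
predict_user <- function(classifier, rows) {
  if (nrow(rows) == 0L) {
    stop_phenosense("`rows` must contain at least one user-day.",
                    "phenosense_validation_error")
  }
  p <- mean(predict_days(classifier, rows))
  list(probability = p, label = p >= 0.5)
}

# End-to-end supervised training of encoder + head (the no-pretraining
# ablation arm): identical architecture, nothing frozen, no triplet phase.
train_end_to_end <- function(features, cols, labels,
                             pre_cfg = pretrain_config(),
                             cfg = finetune_config(), seed = 1L,
                             class_weights = NULL) {
  y <- as.numeric(as.logical(labels))
  if (is.null(class_weights)) class_weights <- compute_class_weights(labels)
  X <- features_as_matrix(features, cols)
  w_row <- ifelse(y == 1, class_weights[["pos"]], class_weights[["neg"]])
  n <- nrow(X)
  with_seed(seed, {
    enc <- mlp_init(c(ncol(X), pre_cfg$encoder_widths))
    head <- mlp_init(c(pre_cfg$encoder_widths[length(pre_cfg$encoder_widths)],
                       cfg$head_widths, 1L))
    st_e <- adam_init(enc)
    st_h <- adam_init(head)
    n_batches <- max(1L, ceiling(n / cfg$batch))
    t_step <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      for (b in seq_len(n_batches)) {
        idx <- perm[(((b - 1L) * cfg$batch) + 1L):min(b * cfg$batch, n)]
        fe <- mlp_forward(enc, X[idx, , drop = FALSE], cache = TRUE)
        fh <- mlp_forward(head, fe$out, cache = TRUE)
        z <- as.numeric(fh$out)
        dz <- matrix(w_row[idx] * (plogis(z) - y[idx]) / length(idx),
                     ncol = 1L)
        bh <- mlp_backward(head, fh, dz)
        be <- mlp_backward(enc, fe, bh$dX)
        t_step <- t_step + 1L
        up_h <- adam_step(head, bh$grads, st_h, t_step, cfg$lr)
        head <- up_h$net; st_h <- up_h$state
        up_e <- adam_step(enc, be$grads, st_e, t_step, cfg$lr)
        enc <- up_e$net; st_e <- up_e$state
      }
    }
    encoder <- structure(list(net = enc, projection = NULL, cols = cols,
                              cfg = pre_cfg, loss_trace = numeric(0),
                              seed = as.integer(seed)),
                         class = "phenosense_encoder")
    structure(list(encoder = encoder, head = head, cfg = cfg,
                   init_loss = NA_real_, loss_trace = numeric(0),
                   class_weights = class_weights, seed = as.integer(seed)),
              class = "phenosense_classifier")
  })
}
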