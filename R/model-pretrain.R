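#' Contrastive pretraining configuration
#'
#' Defaults follow the study protocol: triplet margin 1.0, Adam at learning
#' rate 1e-3, 3 epochs with batches of 256 triplets; a 2-layer MLP encoder
#' (input -> 128 -> 64) and a 2-layer projection head (64 -> 64 -> 32).
#' Hidden widths and the ReLU activation are common-practice defaults.
#'
#' @param margin Triplet margin m (> 0).
#' @param lr Learning rate.
#' @param epochs Pretraining epochs.
#' @param batch Triplets per batch.
#' @param encoder_widths Hidden widths of the encoder, excluding the input.
#' @param head_widths Widths of the projection head, excluding its input.
#' @return A list of class `pretrain_config`.
#' @export
pretrain_config <- function(margin = 1.0, lr = 1e-3, epochs = 3L,
                            batch = 256L, encoder_widths = c(128L, 64L),
                            head_widths = c(64L, 32L)) {
  if (margin <= 0) {
    stop_phenosense("`margin` must be > 0.", "phenosense_config_error")
  }
  if (length(encoder_widths) < 2L || length(head_widths) < 2L) {
    stop_phenosense("Encoder and head need at least 2 layers.",
                    "phenosense_config_error")
  }
  structure(list(margin = margin, lr = lr, epochs = as.integer(epochs),
                 batch = as.integer(batch),
                 encoder_widths = as.integer(encoder_widths),
                 head_widths = as.integer(head_widths)),
            class = "pretrain_config")
}

#' Sample one contrastive triplet of training rows
#'
#' A user with at least two days is drawn uniformly; the anchor is a random
#' day of that user, the positive a different day of the same user, and the
#' negative a random day of a different user. No outcome labels enter the
#' sampling.
#'
#' @param rows Tibble with at least `user_id` and `day` (training rows only).
#' @param seed RNG seed.
#' @return List with rows `anchor`, `positive`, `negative`.
#' @export
sample_triplet <- function(rows, seed = NULL) {
  idx <- sample_triplet_indices(rows$user_id, 1L, seed = seed)
  list(anchor = rows[idx$anchor, ], positive = rows[idx$positive, ],
       negative = rows[idx$negative, ])
}

# Vectorized triplet index sampling over a user-id vector. Anchor users are
# uniform over users with >= 2 rows; positives a different uniform row of
# the same user; negatives a uniform row of a uniform other user.
sample_triplet_indices <- function(user_ids, n_triplets, seed = NULL) {
  run <- function() {
    ord <- order(user_ids)
    sorted_users <- user_ids[ord]
    runs <- rle(as.character(sorted_users))
    all_users <- runs$values
    sizes <- runs$lengths
    starts <- cumsum(c(1L, sizes[-length(sizes)]))
    eligible_idx <- which(sizes >= 2L)
    if (length(all_users) < 2L || length(eligible_idx) < 1L) {
      stop_phenosense(
        "Triplet sampling needs >= 2 users, anchors with >= 2 days.",
        "phenosense_sampling_error"
      )
    }
    B <- n_triplets
    au <- eligible_idx[sample.int(length(eligible_idx), B, replace = TRUE)]
    n_a <- sizes[au]
    i1 <- floor(runif(B) * n_a) + 1L
    i2 <- floor(runif(B) * (n_a - 1L)) + 1L
    i2 <- i2 + (i2 >= i1)
    # negative user: uniform over the other users
    U <- length(all_users)
    nu <- floor(runif(B) * (U - 1L)) + 1L
    nu <- nu + (nu >= au)
    i3 <- floor(runif(B) * sizes[nu]) + 1L
    list(anchor = ord[starts[au] + i1 - 1L],
         positive = ord[starts[au] + i2 - 1L],
         negative = ord[starts[nu] + i3 - 1L])
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Triplet margin loss
#'
#' `mean(max(d(a, p) - d(a, n) + m, 0))` over a batch, with non-squared
#' Euclidean distance d on the embeddings.
#'
#' @param a_emb,p_emb,n_emb Numeric matrices (rows = triplets) or vectors.
#' @param margin Margin m.
#' @return Nonnegative scalar.
#' @examples
#' triplet_margin_loss(c(0, 0), c(0.2, 0), c(1.5, 0), margin = 1) # 0
#' @export
triplet_margin_loss <- function(a_emb, p_emb, n_emb, margin = 1.0) {
  a_emb <- rbind(a_emb); p_emb <- rbind(p_emb); n_emb <- rbind(n_emb)
  if (!all(dim(a_emb) == dim(p_emb)) || !all(dim(a_emb) == dim(n_emb))) {
    stop_phenosense("Embeddings must share dimensions.",
                    "phenosense_validation_error")
  }
  dap <- sqrt(rowSums((a_emb - p_emb)^2))
  dan <- sqrt(rowSums((a_emb - n_emb)^2))
  mean(pmax(dap - dan + margin, 0))
}

encoder_embed <- function(encoder, X) {
  mlp_forward(encoder$net, as.matrix(X))
}

# Extract the feature matrix (columns in `cols`) from a feature tibble.
features_as_matrix <- function(features, cols) {
  as.matrix(features[, cols, drop = FALSE])
}

#' Pretrain the user-day encoder with triplet margin loss
#'
#' Self-supervised: triplets are sampled from training rows without labels,
#' embedded through encoder + projection head, and both are updated by Adam
#' on the batch triplet loss. The projection head is kept for diagnostics
#' but downstream classification uses the encoder output only.
#'
#' @param features Normalized feature tibble of the training rows (must
#'   contain `user_id` and `day`).
#' @param cols Feature columns to encode.
#' @param cfg A [pretrain_config()].
#' @param seed RNG seed (initialisation and triplet sampling).
#' @return Object of class `phenosense_encoder`: `net`, `projection`,
#'   `cols`, `cfg`, `loss_trace` (mean batch loss per epoch), `seed`.
#' @export
pretrain_encoder <- function(features, cols, cfg = pretrain_config(),
                             seed = 1L) {
  X <- features_as_matrix(features, cols)
  user_ids <- features$user_id
  with_seed(seed, {
    enc <- mlp_init(c(ncol(X), cfg$encoder_widths))
    head <- mlp_init(c(cfg$encoder_widths[length(cfg$encoder_widths)],
                       cfg$head_widths))
    st_enc <- adam_init(enc)
    st_head <- adam_init(head)
    n_batches <- max(1L, ceiling(nrow(X) / cfg$batch))
    loss_trace <- numeric(cfg$epochs)
    t_step <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      batch_losses <- numeric(n_batches)
      for (b in seq_len(n_batches)) {
        idx <- sample_triplet_indices(user_ids, cfg$batch)
        B <- cfg$batch
        # forward only the unique sampled rows; triplet roles index into
        # the unique batch (gradients accumulate per unique row)
        all_idx <- c(idx$anchor, idx$positive, idx$negative)
        uniq <- unique(all_idx)
        pos <- match(all_idx, uniq)
        fe <- mlp_forward(enc, X[uniq, , drop = FALSE], cache = TRUE)
        fh <- mlp_forward(head, fe$out, cache = TRUE)
        ia <- seq_len(B); ip <- B + ia; im <- 2L * B + ia
        za <- fh$out[pos[ia], , drop = FALSE]
        zp <- fh$out[pos[ip], , drop = FALSE]
        zn <- fh$out[pos[im], , drop = FALSE]
        eps <- 1e-12
        dap <- sqrt(rowSums((za - zp)^2) + eps)
        dan <- sqrt(rowSums((za - zn)^2) + eps)
        act <- (dap - dan + cfg$margin) > 0
        batch_losses[b] <- mean(pmax(dap - dan + cfg$margin, 0))
        if (!is.finite(batch_losses[b])) {
          stop_phenosense(
            sprintf("Non-finite triplet loss at epoch %d batch %d.",
                    epoch, b),
            "phenosense_training_error"
          )
        }
        scale <- act / B
        uap <- (za - zp) / dap   # unit direction matrices
        uan <- (za - zn) / dan
        dZ <- rbind(scale * (uap - uan), -scale * uap, scale * uan)
        # scatter-add triplet-role gradients onto the unique rows; pos
        # takes every value 1..length(uniq), so rowsum's sorted group
        # order is the unique-row order
        dZu <- rowsum(dZ, pos)
        bh <- mlp_backward(head, fh, dZu)
        be <- mlp_backward(enc, fe, bh$dX)
        t_step <- t_step + 1L
        up_h <- adam_step(head, bh$grads, st_head, t_step, cfg$lr)
        head <- up_h$net; st_head <- up_h$state
        up_e <- adam_step(enc, be$grads, st_enc, t_step, cfg$lr)
        enc <- up_e$net; st_enc <- up_e$state
      }
      loss_trace[epoch] <- mean(batch_losses)
    }
    structure(list(net = enc, projection = head, cols = cols, cfg = cfg,
                   loss_trace = loss_trace, seed = as.integer(seed)),
              class = "phenosense_encoder")
  })
}

#' An untrained (randomly initialised) encoder
#'
#' Reference point for embedding-compactness comparisons.
#' @inheritParams pretrain_encoder
#' @export
untrained_encoder <- function(features, cols, cfg = pretrain_config(),
                              seed = 1L) {
  X <- features_as_matrix(features, cols)
  with_seed(seed, {
    enc <- mlp_init(c(ncol(X), cfg$encoder_widths))
    head <- mlp_init(c(cfg$encoder_widths[length(cfg$encoder_widths)],
                       cfg$head_widths))
    structure(list(net = enc, projection = head, cols = cols, cfg = cfg,
                   loss_trace = numeric(0), seed = as.integer(seed)),
              class = "phenosense_encoder")
  })
}

#' Within/between-user embedding compactness ratio
#'
#' Mean Euclidean distance between embeddings of the same user divided by
#' the mean distance between embeddings of different users. Pretraining that
#' stabilises user identity drives this ratio down.
#'
#' @param encoder A `phenosense_encoder`.
#' @param features Normalized feature tibble with `user_id`.
#' @return Scalar ratio.
#' @export
embedding_compactness <- function(encoder, features) {
  Z <- encoder_embed(encoder, features_as_matrix(features, encoder$cols))
  D <- as.matrix(stats::dist(Z))
  same <- outer(features$user_id, features$user_id, "==")
  diag(same) <- NA
  mean(D[same & upper.tri(D)]) / mean(D[!same & upper.tri(D)])
}
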