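# Minimal dense-network machinery: ReLU MLPs with a linear output layer,
# trained by Adam. Weight matrices are (fan_in x fan_out); forward works on
# row-major batches. Weights and biases are initialised uniform on
# +/- 1/sqrt(fan_in), the convention of the deep-learning framework the
# training protocol was designed around.

mlp_init <- function(widths) {
  n_layers <- length(widths) - 1L
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fan_in <- widths[l]
    fan_out <- widths[l + 1L]
    limit <- 1 / sqrt(fan_in)
    layers[[l]] <- list(
      W = matrix(runif(fan_in * fan_out, -limit, limit), fan_in, fan_out),
      b = runif(fan_out, -limit, limit)
    )
  }
  structure(list(layers = layers, widths = widths), class = "phenosense_mlp")
}

mlp_forward <- function(net, X, cache = FALSE) {
  n_layers <- length(net$layers)
  acts <- vector("list", n_layers + 1L)
  acts[[1L]] <- X
  H <- X
  n <- nrow(X)
  for (l in seq_len(n_layers)) {
    Z <- H %*% net$layers[[l]]$W
    Z <- Z + rep(net$layers[[l]]$b, each = n)  # column-major bias add
    if (l < n_layers) Z[Z < 0] <- 0
    H <- Z
    acts[[l + 1L]] <- H
  }
  if (cache) list(out = H, acts = acts) else H
}

# Backprop dL/d(output) through the net. Returns per-layer grads and the
# gradient w.r.t. the input batch (for chaining through a frozen-free stack).
mlp_backward <- function(net, fw, dOut) {
  n_layers <- length(net$layers)
  grads <- vector("list", n_layers)
  delta <- dOut
  for (l in rev(seq_len(n_layers))) {
    if (l < n_layers) {
      # ReLU derivative via the cached post-activation
      delta[fw$acts[[l + 1L]] <= 0] <- 0
    }
    H_prev <- fw$acts[[l]]
    grads[[l]] <- list(W = crossprod(H_prev, delta), b = colSums(delta))
    delta <- tcrossprod(delta, net$layers[[l]]$W)
  }
  list(grads = grads, dX = delta)
}

adam_init <- function(net) {
  lapply(net$layers, function(ly) list(
    mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0
  ))
}

adam_step <- function(net, grads, state, t, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (l in seq_along(net$layers)) {
    g <- grads[[l]]
    st <- state[[l]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$W
    st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
    net$layers[[l]]$W <- net$layers[[l]]$W -
      lr * (st$mW / bc1) / (sqrt(st$vW / bc2) + eps)
    net$layers[[l]]$b <- net$layers[[l]]$b -
      lr * (st$mb / bc1) / (sqrt(st$vb / bc2) + eps)
    state[[l]] <- st
  }
  list(net = net, state = state)
}

add_grads <- function(a, b) {
  for (l in seq_along(a)) {
    a[[l]]$W <- a[[l]]$W + b[[l]]$W
    a[[l]]$b <- a[[l]]$b + b[[l]]$b
  }
  a
}
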