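# Minimal fully-connected network toolkit (base R matrices, samples as
# columns). Backs the adversarial autoencoder, the VAE/GAN baselines and the
# MLP classifier. ReLU hidden units, inverted dropout, plain SGD.

# Weights and biases drawn from U(-1/sqrt(fan_in), 1/sqrt(fan_in)), the
# standard dense-layer default. The modest gain matters for the generative
# models: with few training samples the decoder's sensitivity to untrained
# latent directions stays at its initialization scale, so prior draws decode
# to the learned class shape rather than amplified noise.
nn_init <- function(widths, out_activation = c("linear", "sigmoid",
                                               "softmax")) {
  out_activation <- match.arg(out_activation)
  L <- length(widths) - 1
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    bnd <- 1 / sqrt(widths[l])
    layers[[l]] <- list(
      W = matrix(stats::runif(widths[l + 1] * widths[l], -bnd, bnd),
                 widths[l + 1], widths[l]),
      b = stats::runif(widths[l + 1], -bnd, bnd))
  }
  list(layers = layers, widths = widths, out_activation = out_activation)
}

# Forward pass. X: in_dim x batch. Returns output plus caches for backward.
# Dropout (inverted) is applied to hidden activations when training.
nn_forward <- function(net, X, dropout = 0, training = FALSE) {
  L <- length(net$layers)
  a <- list(X)
  z <- vector("list", L)
  masks <- vector("list", L)
  for (l in seq_len(L)) {
    z[[l]] <- net$layers[[l]]$W %*% a[[l]] + net$layers[[l]]$b
    if (l < L) {
      h <- pmax(z[[l]], 0)
      if (training && dropout > 0) {
        m <- matrix(stats::rbinom(length(h), 1, 1 - dropout) / (1 - dropout),
                    nrow(h), ncol(h))
        h <- h * m
        masks[[l]] <- m
      }
      a[[l + 1]] <- h
    } else {
      a[[l + 1]] <- switch(net$out_activation,
                           linear = z[[l]],
                           sigmoid = 1 / (1 + exp(-z[[l]])),
                           softmax = {
                             e <- exp(sweep(z[[l]], 2, apply(z[[l]], 2, max)))
                             sweep(e, 2, colSums(e), "/")
                           })
    }
  }
  list(out = a[[L + 1]], a = a, z = z, masks = masks)
}

# Backward pass from the gradient w.r.t. the LAST layer's pre-activation
# (dZ_L). For linear output that equals dLoss/dOut; for sigmoid/softmax with
# the matching cross-entropy loss it is (out - target) times any scaling.
# Returns per-layer gradients and the gradient w.r.t. the input.
nn_backward <- function(net, cache, dZ_L) {
  L <- length(net$layers)
  grads <- vector("list", L)
  dZ <- dZ_L
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = dZ %*% t(cache$a[[l]]), b = rowSums(dZ))
    if (l > 1) {
      dA <- t(net$layers[[l]]$W) %*% dZ
      dZ <- dA * (cache$z[[l - 1]] > 0)
      if (!is.null(cache$masks[[l - 1]])) dZ <- dZ * cache$masks[[l - 1]]
    } else {
      dA <- t(net$layers[[l]]$W) %*% dZ
    }
  }
  list(layers = grads, dX = dA)
}

nn_sgd_step <- function(net, grads, lr) {
  for (l in seq_along(net$layers)) {
    net$layers[[l]]$W <- net$layers[[l]]$W - lr * grads$layers[[l]]$W
    net$layers[[l]]$b <- net$layers[[l]]$b - lr * grads$layers[[l]]$b
  }
  net
}
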