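#' Configuration for the adversarial autoencoder
#'
#' Defaults follow the fully-connected architecture used for SWP
#' augmentation: a 5-layer encoder 411-200-100-100-50, a mirror-image 5-layer
#' decoder, and a 5-layer discriminator from the 50-dimensional latent code
#' to a single sigmoid output. The latent prior is standard Gaussian. The
#' discriminator's interior widths are an architectural assumption (only its
#' input and output sizes are fixed by the design); they are configurable.
#'
#' @param encoder_widths Layer widths, input first (default
#'   `c(411, 200, 100, 100, 50)`).
#' @param decoder_widths Mirror of the encoder (default
#'   `c(50, 100, 100, 200, 411)`).
#' @param discriminator_widths Default `c(50, 100, 100, 50, 25, 1)`.
#' @param dropout Dropout probability on hidden layers during training (0.2).
#' @param recon_lr Reconstruction-phase SGD learning rate (1e-4).
#' @param gen_lr Regularization-phase learning rate, used for both the
#'   discriminator and the encoder-as-generator updates (5e-4).
#' @param epochs Training epochs (200).
#' @param batch_size Samples per SGD update (1: per-sample stochastic
#'   updates; groups are small so an epoch is `n` updates).
#' @param seed Training seed (10); controls initialization, dropout masks,
#'   prior draws and sample order.
#' @return A `swp_aae_config` list.
#' @export
swp_aae_config <- function(encoder_widths = c(411, 200, 100, 100, 50),
                           decoder_widths = rev(encoder_widths),
                           discriminator_widths = c(50, 100, 100, 50, 25, 1),
                           dropout = 0.2, recon_lr = 1e-4, gen_lr = 5e-4,
                           epochs = 200, batch_size = 1, seed = 10) {
  latent <- encoder_widths[length(encoder_widths)]
  if (decoder_widths[1] != latent || discriminator_widths[1] != latent)
    swp_abort("latent dimension mismatch: encoder output, decoder input and discriminator input must agree",
              "swp_config_error")
  if (encoder_widths[1] != decoder_widths[length(decoder_widths)])
    swp_abort("encoder input width must equal decoder output width",
              "swp_config_error")
  if (discriminator_widths[length(discriminator_widths)] != 1)
    swp_abort("discriminator must end in a single output unit",
              "swp_config_error")
  structure(list(encoder_widths = encoder_widths,
                 decoder_widths = decoder_widths,
                 discriminator_widths = discriminator_widths,
                 dropout = dropout, recon_lr = recon_lr, gen_lr = gen_lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "swp_aae_config")
}

check_group_traces <- function(traces, input_width, min_n = 2) {
  if (length(traces) < min_n)
    swp_abort(sprintf("need at least %d traces in the group, got %d", min_n,
                      length(traces)), "swp_data_error")
  X <- traces_to_matrix(traces)
  if (ncol(X$matrix) != input_width)
    swp_abort(sprintf("trace length %d does not match network input width %d",
                      ncol(X$matrix), input_width), "swp_shape_error")
  if (length(unique(X$labels)) > 1 ||
      length(unique(X$leaf[!is.na(X$leaf)])) > 1)
    swp_abort("all traces in a training group must share one (leaf, condition)",
              "swp_shape_error")
  X
}

group_key <- function(X) {
  list(leaf = X$leaf[1], condition = X$labels[1],
       max_real_length = max(X$real_lengths))
}

minibatches <- function(n, batch_size) {
  ord <- sample.int(n)
  split(ord, ceiling(seq_along(ord) / batch_size))
}

#' Train an adversarial autoencoder on one trace group
#'
#' Trains on the normalized traces of a single (leaf, condition) group.
#' Each epoch alternates, per minibatch, (1) a reconstruction step updating
#' encoder and decoder by SGD on the L1 loss (sum over the 411 dimensions,
#' mean over the batch) at `recon_lr`; (2) a regularization step updating the
#' discriminator to separate standard-Gaussian prior draws (real) from
#' encoder codes (fake) at `gen_lr`; and (3) a generator step updating the
#' encoder so its codes score as real, using the non-saturating objective, at
#' `gen_lr`. All randomness derives from `cfg$seed`; training is
#' bit-reproducible.
#'
#' @param traces List of `swp_trace` from one (leaf, condition) group.
#' @param cfg A [swp_aae_config()].
#' @return An object of class `swp_aae`: trained `encoder`, `decoder`,
#'   `discriminator`, the `config`, the group key, and a per-epoch `history`
#'   data frame (`l1_recon`, `d_loss`, `g_loss`).
#' @export
train_aae <- function(traces, cfg = swp_aae_config()) {
  X <- check_group_traces(traces, cfg$encoder_widths[1])
  xs <- t(X$matrix)                      # dims x samples
  n <- ncol(xs)
  latent <- cfg$encoder_widths[length(cfg$encoder_widths)]
  with_seed(cfg$seed, {
    enc <- nn_init(cfg$encoder_widths, "linear")
    dec <- nn_init(cfg$decoder_widths, "linear")
    disc <- nn_init(cfg$discriminator_widths, "sigmoid")
    hist <- matrix(NA_real_, cfg$epochs, 3,
                   dimnames = list(NULL, c("l1_recon", "d_loss", "g_loss")))
    for (ep in seq_len(cfg$epochs)) {
      ep_l1 <- ep_d <- ep_g <- 0
      batches <- minibatches(n, cfg$batch_size)
      for (idx in batches) {
        xb <- xs[, idx, drop = FALSE]
        B <- length(idx)

        # (1) reconstruction: L1, sum over dims, mean over batch
        ce <- nn_forward(enc, xb, cfg$dropout, training = TRUE)
        cd <- nn_forward(dec, ce$out, cfg$dropout, training = TRUE)
        resid <- cd$out - xb
        ep_l1 <- ep_l1 + sum(abs(resid))
        gdec <- nn_backward(dec, cd, sign(resid) / B)
        genc <- nn_backward(enc, ce, gdec$dX)
        enc <- nn_sgd_step(enc, genc, cfg$recon_lr)
        dec <- nn_sgd_step(dec, gdec, cfg$recon_lr)

        # (2) discriminator: prior draws real (1), encoder codes fake (0)
        z_real <- matrix(stats::rnorm(latent * B), latent, B)
        z_fake <- nn_forward(enc, xb, cfg$dropout, training = TRUE)$out
        zb <- cbind(z_real, z_fake)
        lab <- c(rep(1, B), rep(0, B))
        cdi <- nn_forward(disc, zb, cfg$dropout, training = TRUE)
        p <- pmin(pmax(cdi$out, 1e-12), 1 - 1e-12)
        ep_d <- ep_d + sum(-(lab * log(p) + (1 - lab) * log(1 - p))) / 2
        gd <- nn_backward(disc, cdi, (cdi$out - rbind(lab)) / (2 * B))
        disc <- nn_sgd_step(disc, gd, cfg$gen_lr)

        # (3) encoder as generator: make codes score real (non-saturating)
        ce2 <- nn_forward(enc, xb, cfg$dropout, training = TRUE)
        cdi2 <- nn_forward(disc, ce2$out, cfg$dropout, training = TRUE)
        p2 <- pmin(pmax(cdi2$out, 1e-12), 1 - 1e-12)
        ep_g <- ep_g + sum(-log(p2))
        gd2 <- nn_backward(disc, cdi2, (cdi2$out - 1) / B)
        genc2 <- nn_backward(enc, ce2, gd2$dX)
        enc <- nn_sgd_step(enc, genc2, cfg$gen_lr)
      }
      hist[ep, ] <- c(ep_l1 / n, ep_d / n, ep_g / n)
    }
    structure(list(encoder = enc, decoder = dec, discriminator = disc,
                   config = cfg, group = group_key(X),
                   history = as.data.frame(hist)),
              class = c("swp_aae", "swp_generative_model"))
  })
}

#' @export
print.swp_generative_model <- function(x, ...) {
  cat(sprintf("<%s> leaf %s / %s: %d epochs", class(x)[1], x$group$leaf,
              x$group$condition, nrow(x$history)))
  if ("l1_recon" %in% names(x$history))
    cat(sprintf(", final mean L1 %.3f (first %.3f)",
                x$history$l1_recon[nrow(x$history)], x$history$l1_recon[1]))
  cat("\n")
  invisible(x)
}

#' Train a variational autoencoder baseline
#'
#' Same encoder/decoder widths as the AAE; the encoder trunk feeds two linear
#' heads producing the mean and log-variance of a diagonal-Gaussian latent.
#' Objective: L1 reconstruction (sum over dims, mean over batch) plus the
#' analytic KL divergence to the standard-Gaussian prior, minimized jointly
#' by SGD at `recon_lr`.
#'
#' @inheritParams train_aae
#' @return An object of class `swp_vae` with `history` columns `l1_recon`
#'   and `kl`.
#' @export
train_vae <- function(traces, cfg = swp_aae_config()) {
  X <- check_group_traces(traces, cfg$encoder_widths[1])
  xs <- t(X$matrix)
  n <- ncol(xs)
  ew <- cfg$encoder_widths
  latent <- ew[length(ew)]
  trunk_w <- ew[-length(ew)]             # e.g. 411,200,100,100
  with_seed(cfg$seed, {
    trunk <- nn_init(trunk_w, "linear")  # last trunk layer kept linear; ReLU
    head_mu <- nn_init(c(trunk_w[length(trunk_w)], latent), "linear")
    head_lv <- nn_init(c(trunk_w[length(trunk_w)], latent), "linear")
    dec <- nn_init(cfg$decoder_widths, "linear")
    hist <- matrix(NA_real_, cfg$epochs, 2,
                   dimnames = list(NULL, c("l1_recon", "kl")))
    for (ep in seq_len(cfg$epochs)) {
      ep_l1 <- ep_kl <- 0
      for (idx in minibatches(n, cfg$batch_size)) {
        xb <- xs[, idx, drop = FALSE]
        B <- length(idx)
        ct <- nn_forward(trunk, xb, cfg$dropout, training = TRUE)
        h <- pmax(ct$out, 0)             # ReLU into the two heads
        cmu <- nn_forward(head_mu, h)
        clv <- nn_forward(head_lv, h)
        mu <- cmu$out
        lv <- pmin(pmax(clv$out, -10), 10)
        eps <- matrix(stats::rnorm(latent * B), latent, B)
        z <- mu + exp(lv / 2) * eps
        cd <- nn_forward(dec, z, cfg$dropout, training = TRUE)
        resid <- cd$out - xb
        ep_l1 <- ep_l1 + sum(abs(resid))
        ep_kl <- ep_kl + 0.5 * sum(exp(lv) + mu^2 - 1 - lv)
        gdec <- nn_backward(dec, cd, sign(resid) / B)
        dz <- gdec$dX
        dmu <- dz + mu / B
        dlv <- dz * eps * exp(lv / 2) / 2 + 0.5 * (exp(lv) - 1) / B
        gmu <- nn_backward(head_mu, cmu, dmu)
        glv <- nn_backward(head_lv, clv, dlv)
        dh <- (gmu$dX + glv$dX) * (ct$out > 0)
        gtr <- nn_backward(trunk, ct, dh)
        dec <- nn_sgd_step(dec, gdec, cfg$recon_lr)
        head_mu <- nn_sgd_step(head_mu, gmu, cfg$recon_lr)
        head_lv <- nn_sgd_step(head_lv, glv, cfg$recon_lr)
        trunk <- nn_sgd_step(trunk, gtr, cfg$recon_lr)
      }
      hist[ep, ] <- c(ep_l1 / n, ep_kl / n)
    }
    structure(list(trunk = trunk, head_mu = head_mu, head_lv = head_lv,
                   decoder = dec, config = cfg, group = group_key(X),
                   history = as.data.frame(hist)),
              class = c("swp_vae", "swp_generative_model"))
  })
}

#' Train a GAN baseline
#'
#' Fully connected generator (latent 50 to 411 outputs, same widths as the
#' AAE decoder) against a fully connected discriminator on the 411-point
#' traces. Alternating SGD: discriminator on real traces vs generated ones,
#' then the generator with the non-saturating objective, both at `gen_lr`.
#'
#' @inheritParams train_aae
#' @param disc_widths Discriminator widths from trace to a single sigmoid
#'   unit.
#' @return An object of class `swp_gan` with `history` columns `d_loss` and
#'   `g_loss`.
#' @export
train_gan <- function(traces, cfg = swp_aae_config(),
                      disc_widths = c(411, 200, 100, 50, 25, 1)) {
  X <- check_group_traces(traces, cfg$decoder_widths[length(cfg$decoder_widths)])
  xs <- t(X$matrix)
  n <- ncol(xs)
  latent <- cfg$decoder_widths[1]
  with_seed(cfg$seed, {
    gen <- nn_init(cfg$decoder_widths, "linear")
    disc <- nn_init(disc_widths, "sigmoid")
    hist <- matrix(NA_real_, cfg$epochs, 2,
                   dimnames = list(NULL, c("d_loss", "g_loss")))
    for (ep in seq_len(cfg$epochs)) {
      ep_d <- ep_g <- 0
      for (idx in minibatches(n, cfg$batch_size)) {
        xb <- xs[, idx, drop = FALSE]
        B <- length(idx)
        z <- matrix(stats::rnorm(latent * B), latent, B)
        fake <- nn_forward(gen, z, cfg$dropout, training = TRUE)$out
        db <- cbind(xb, fake)
        lab <- c(rep(1, B), rep(0, B))
        cd <- nn_forward(disc, db, cfg$dropout, training = TRUE)
        p <- pmin(pmax(cd$out, 1e-12), 1 - 1e-12)
        ep_d <- ep_d + sum(-(lab * log(p) + (1 - lab) * log(1 - p))) / 2
        gd <- nn_backward(disc, cd, (cd$out - rbind(lab)) / (2 * B))
        disc <- nn_sgd_step(disc, gd, cfg$gen_lr)

        z2 <- matrix(stats::rnorm(latent * B), latent, B)
        cg <- nn_forward(gen, z2, cfg$dropout, training = TRUE)
        cd2 <- nn_forward(disc, cg$out, cfg$dropout, training = TRUE)
        p2 <- pmin(pmax(cd2$out, 1e-12), 1 - 1e-12)
        ep_g <- ep_g + sum(-log(p2))
        gd2 <- nn_backward(disc, cd2, (cd2$out - 1) / B)
        ggen <- nn_backward(gen, cg, gd2$dX)
        gen <- nn_sgd_step(gen, ggen, cfg$gen_lr)
      }
      hist[ep, ] <- c(ep_d / n, ep_g / n)
    }
    structure(list(generator = gen, discriminator = disc, config = cfg,
                   group = group_key(X), history = as.data.frame(hist)),
              class = c("swp_gan", "swp_generative_model"))
  })
}

decode_latent <- function(model, z) {
  if (inherits(model, "swp_gan")) {
    nn_forward(model$generator, z)$out
  } else {
    nn_forward(model$decoder, z)$out
  }
}

model_latent_dim <- function(model) {
  if (inherits(model, "swp_gan")) model$config$decoder_widths[1]
  else model$config$decoder_widths[1]
}

#' Generate augmented traces from a trained model
#'
#' Draws `n` latent vectors from the standard-Gaussian prior, decodes each in
#' inference mode (no dropout), and clips the outputs to \[-1, 1\]. Sample
#' ids get an `aug_` prefix and the traces carry the model's (leaf,
#' condition) group key so downstream splitting can keep them out of test
#' sets. The padded tail is not re-zeroed by default (the model learns the
#' zero tail); `rezero_tail = TRUE` zeroes everything past the group's
#' longest real length.
#'
#' @param model A trained `swp_aae`, `swp_vae` or `swp_gan`.
#' @param n Number of virtual traces (>= 1).
#' @param seed Integer seed for the prior draws.
#' @param rezero_tail Zero the fill region of each generated trace.
#' @return List of `swp_trace` with `provenance` attribute `"augmented"`.
#' @export
generate_augmented <- function(model, n = 50, seed = 10,
                               rezero_tail = FALSE) {
  stopifnot(inherits(model, "swp_generative_model"))
  if (n < 1) swp_abort("n must be >= 1", "swp_config_error")
  latent <- model_latent_dim(model)
  out <- with_seed(derive_seed(seed, "generate", model$group$leaf,
                               model$group$condition), {
    z <- matrix(stats::rnorm(latent * n), latent, n)
    decode_latent(model, z)
  })
  out <- pmin(pmax(out, -1), 1)
  rl <- model$group$max_real_length
  lapply(seq_len(n), function(k) {
    v <- out[, k]
    if (rezero_tail && rl < length(v)) v[(rl + 1):length(v)] <- 0
    tr <- structure(list(values = v,
                         real_length = if (rezero_tail) rl else length(v),
                         sample_id = sprintf("aug_leaf%s_%s_%03d",
                                             model$group$leaf,
                                             model$group$condition, k),
                         leaf = model$group$leaf,
                         condition = model$group$condition),
                    class = "swp_trace")
    attr(tr, "provenance") <- "augmented"
    tr
  })
}

#' Augment every (leaf, condition) group of a trace set
#'
#' Splits the traces by group, trains one generative model per group (six at
#' the default dataset scale), and generates `n_per_group` virtual traces per
#' group. Originals are never modified.
#'
#' @param traces List of `swp_trace` covering one or more groups.
#' @param method `"aae"`, `"vae"` or `"gan"`.
#' @param n_per_group Virtual traces per group (>= 1).
#' @param cfg A [swp_aae_config()] shared across groups; each group trains
#'   with a seed derived from `cfg$seed` and its group key.
#' @return List with `augmented` (flat list of generated `swp_trace`) and
#'   `models` (named by `leaf<k>_<condition>`).
#' @export
augment_dataset <- function(traces, method = c("aae", "vae", "gan"),
                            n_per_group = 50, cfg = swp_aae_config()) {
  method <- match.arg(method)
  if (n_per_group < 1)
    swp_abort("n_per_group must be >= 1", "swp_config_error")
  keys <- vapply(traces, function(t)
    sprintf("leaf%s_%s", t$leaf, t$condition), character(1))
  groups <- split(traces, keys)
  trainer <- switch(method, aae = train_aae, vae = train_vae,
                    gan = train_gan)
  models <- list()
  augmented <- list()
  for (key in names(groups)) {
    gcfg <- cfg
    gcfg$seed <- derive_seed(cfg$seed, "train", key)
    models[[key]] <- trainer(groups[[key]], gcfg)
    augmented <- c(augmented,
                   generate_augmented(models[[key]], n_per_group,
                                      seed = derive_seed(cfg$seed, "gen",
                                                         key)))
  }
  list(augmented = augmented, models = models)
}
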