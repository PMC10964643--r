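#' Classifier specification
#'
#' Defaults: SVM with C = 1, radial-basis
#' kernel and gamma = 1/n_features; KNN with k = 5, Euclidean distance and
#' majority vote (ties broken by the single nearest neighbour); random forest
#' with 100 trees and seed 0; MLP with one hidden layer of 10 rectifier
#' units, softmax output, learning rate 0.01 and 500 full-batch epochs.
#'
#' @param kind One of `"svm"`, `"knn"`, `"random_forest"`, `"mlp"`.
#' @param ... Overrides for the per-classifier defaults: `cost` and `gamma`
#'   (svm; `gamma = NULL` means 1/n_features), `k` (knn), `ntree` and
#'   `rf_seed` (random_forest), `hidden`, `lr`, `epochs`, `mlp_seed` (mlp),
#'   `scale_features` (z-score columns before fitting, default `FALSE`).
#' @return A `swp_classifier_spec` list.
#' @export
swp_classifier_spec <- function(kind = c("svm", "knn", "random_forest",
                                         "mlp"), ...) {
  kind <- match.arg(kind)
  defaults <- list(cost = 1, gamma = NULL, k = 5L, ntree = 100L,
                   rf_seed = 0L, hidden = 10L, lr = 0.01, epochs = 500L,
                   mlp_seed = 0L, scale_features = FALSE)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown))
    swp_abort(sprintf("unknown classifier option(s): %s",
                      paste(unknown, collapse = ", ")), "swp_config_error")
  defaults[names(dots)] <- dots
  structure(c(list(kind = kind), defaults), class = "swp_classifier_spec")
}

#' Split protocol
#'
#' @param kind `"loocv"` (each original sample is the test set once) or
#'   `"kfold"`.
#' @param folds Number of folds when `kind = "kfold"` (default 5).
#' @param augment_training_only Keep augmented samples out of every test set
#'   (default `TRUE`); when `FALSE` augmented samples are pooled into the
#'   cross-validation splits alongside originals.
#' @return A `swp_split_protocol` list.
#' @export
swp_split_protocol <- function(kind = c("loocv", "kfold"), folds = 5L,
                               augment_training_only = TRUE) {
  kind <- match.arg(kind)
  if (kind == "kfold" && folds < 2)
    swp_abort("kfold needs at least 2 folds", "swp_config_error")
  structure(list(kind = kind, folds = as.integer(folds),
                 augment_training_only = augment_training_only),
            class = "swp_split_protocol")
}

knn_predict <- function(train_x, train_y, test_x, k) {
  if (k > nrow(train_x)) {
    swp_warn(sprintf("k = %d exceeds %d training samples; clamped", k,
                     nrow(train_x)), "swp_knn_clamp")
    k <- nrow(train_x)
  }
  apply(test_x, 1, function(q) {
    d <- sqrt(colSums((t(train_x) - q)^2))
    ord <- order(d)
    nb <- train_y[ord[seq_len(k)]]
    tab <- table(nb)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) top else {
      # tie: the class of the single nearest neighbour among tied classes
      nb[match(TRUE, nb %in% top)]
    }
  })
}

fit_predict <- function(spec, train_x, train_y, test_x, seed) {
  if (spec$scale_features) {
    mu <- colMeans(train_x)
    sdv <- apply(train_x, 2, stats::sd)
    sdv[sdv == 0] <- 1
    train_x <- scale(train_x, mu, sdv)
    test_x <- scale(test_x, mu, sdv)
  }
  classes <- sort(unique(train_y))
  if (length(classes) == 1) return(rep(classes, nrow(test_x)))
  switch(spec$kind,
    svm = {
      gamma <- if (is.null(spec$gamma)) 1 / ncol(train_x) else spec$gamma
      fit <- e1071::svm(train_x, factor(train_y, levels = classes),
                        kernel = "radial", cost = spec$cost, gamma = gamma,
                        scale = FALSE)
      as.character(stats::predict(fit, test_x))
    },
    knn = knn_predict(train_x, train_y, test_x, spec$k),
    random_forest = with_seed(spec$rf_seed, {
      fit <- randomForest::randomForest(train_x,
                                        factor(train_y, levels = classes),
                                        ntree = spec$ntree)
      as.character(stats::predict(fit, test_x))
    }),
    mlp = mlp_fit_predict(spec, train_x, train_y, test_x, classes, seed))
}

# One-hidden-layer softmax classifier trained by full-batch gradient descent
# on the cross-entropy loss; ReLU hidden units, seeded initialization.
mlp_fit_predict <- function(spec, train_x, train_y, test_x, classes, seed) {
  K <- length(classes)
  Y <- matrix(0, K, nrow(train_x))
  Y[cbind(match(train_y, classes), seq_len(nrow(train_x)))] <- 1
  X <- t(train_x)
  net <- with_seed(derive_seed(spec$mlp_seed, seed), {
    net <- nn_init(c(ncol(train_x), spec$hidden, K), "softmax")
    for (ep in seq_len(spec$epochs)) {
      cc <- nn_forward(net, X)
      g <- nn_backward(net, cc, (cc$out - Y) / ncol(X))
      net <- nn_sgd_step(net, g, spec$lr)
    }
    net
  })
  probs <- nn_forward(net, t(test_x))$out
  classes[apply(probs, 2, which.max)]
}

#' Cross-validated classification with optional training-set augmentation
#'
#' Runs the requested split protocol over the original samples; when
#' augmented features are supplied and the protocol keeps augmentation
#' training-only (the default), every training fold is extended with all
#' augmented rows while test folds contain originals only. Pooled held-out
#' predictions feed [confusion_and_metrics()].
#'
#' @param x Numeric feature matrix (rows = original samples).
#' @param y Condition label per row.
#' @param spec A [swp_classifier_spec()].
#' @param protocol A [swp_split_protocol()].
#' @param augmented_x,augmented_y Optional augmented feature block and
#'   labels.
#' @param seed Master seed for fold assignment and seeded learners.
#' @return An `swp_classification_report` (with a `predictions` attribute:
#'   data frame of sample index, truth, prediction).
#' @export
run_classification <- function(x, y, spec = swp_classifier_spec("random_forest"),
                               protocol = swp_split_protocol("loocv"),
                               augmented_x = NULL, augmented_y = NULL,
                               seed = 10) {
  x <- as.matrix(x)
  if (nrow(x) != length(y))
    swp_abort("feature rows and labels disagree", "swp_shape_error")
  if (!is.null(augmented_x)) {
    augmented_x <- as.matrix(augmented_x)
    if (ncol(augmented_x) != ncol(x))
      swp_abort("augmented feature dimensionality differs from originals",
                "swp_shape_error")
    if (nrow(augmented_x) != length(augmented_y))
      swp_abort("augmented rows and labels disagree", "swp_shape_error")
  }
  pool_aug <- !is.null(augmented_x) && !protocol$augment_training_only
  if (pool_aug) {
    x <- rbind(x, augmented_x)
    y <- c(y, augmented_y)
    augmented_x <- NULL
  }
  n <- nrow(x)
  folds <- if (protocol$kind == "loocv") as.list(seq_len(n)) else
    with_seed(derive_seed(seed, "folds"), {
      split(sample.int(n), rep_len(seq_len(protocol$folds), n))
    })
  truth <- character(0); pred <- character(0); idx_all <- integer(0)
  for (f in folds) {
    tr_x <- x[-f, , drop = FALSE]; tr_y <- y[-f]
    if (!is.null(augmented_x)) {
      tr_x <- rbind(tr_x, augmented_x)
      tr_y <- c(tr_y, augmented_y)
    }
    if (length(unique(y[-f])) < length(unique(y)))
      swp_warn("a class is absent from this training fold", "swp_fold_gap")
    p <- fit_predict(spec, tr_x, tr_y, x[f, , drop = FALSE],
                     derive_seed(seed, "fold", f[1]))
    truth <- c(truth, y[f]); pred <- c(pred, p); idx_all <- c(idx_all, f)
  }
  rep <- confusion_and_metrics(truth, pred,
                               classes = intersect(swp_conditions(),
                                                   unique(y)))
  attr(rep, "predictions") <- data.frame(index = idx_all, truth = truth,
                                         predicted = pred)
  rep
}

#' Feature-by-classifier-by-method evaluation grid
#'
#' Evaluates every combination of feature kind, classifier and augmentation
#' method on one leaf's traces, mirroring the tabular comparisons of
#' augmented vs original training.
#'
#' @param traces List of `swp_trace` for one leaf (originals).
#' @param feature_kinds Subset of `c("time_domain","deriv_1st","integral")`.
#' @param classifier_kinds Subset of
#'   `c("svm","knn","random_forest","mlp")`.
#' @param methods Augmentation methods; `"none"` plus any of
#'   `c("aae","vae","gan")`.
#' @param protocol A [swp_split_protocol()].
#' @param n_per_group Augmented traces per group.
#' @param cfg A [swp_aae_config()] for the generative models.
#' @param seed Master seed.
#' @return Data frame with one row per cell: `feature`, `classifier`,
#'   `method`, `accuracy`, `macro_precision`, `macro_recall`, `macro_f1`.
#' @export
run_grid <- function(traces,
                     feature_kinds = c("time_domain", "deriv_1st",
                                       "integral"),
                     classifier_kinds = c("svm", "knn", "random_forest",
                                          "mlp"),
                     methods = "none",
                     protocol = swp_split_protocol("loocv"),
                     n_per_group = 50, cfg = swp_aae_config(), seed = 10) {
  if (!length(feature_kinds) || !length(classifier_kinds))
    swp_abort("feature_kinds and classifier_kinds must be nonempty",
              "swp_config_error")
  aug_traces <- list()
  for (m in setdiff(methods, "none")) {
    aug_traces[[m]] <- augment_dataset(traces, method = m,
                                       n_per_group = n_per_group,
                                       cfg = cfg)$augmented
  }
  rows <- list()
  for (fk in feature_kinds) {
    fm <- build_feature_matrix(traces, fk)
    aug_fm <- lapply(aug_traces, function(at) build_feature_matrix(at, fk))
    for (ck in classifier_kinds) {
      spec <- swp_classifier_spec(ck)
      for (m in methods) {
        res <- tryCatch({
          if (m == "none") {
            run_classification(fm$matrix, fm$labels, spec, protocol,
                               seed = seed)
          } else {
            run_classification(fm$matrix, fm$labels, spec, protocol,
                               augmented_x = aug_fm[[m]]$matrix,
                               augmented_y = aug_fm[[m]]$labels, seed = seed)
          }
        }, error = function(e) e)
        rows[[length(rows) + 1]] <- if (inherits(res, "error")) {
          data.frame(feature = fk, classifier = ck, method = m,
                     accuracy = NA_real_, macro_precision = NA_real_,
                     macro_recall = NA_real_, macro_f1 = NA_real_,
                     error = conditionMessage(res))
        } else {
          data.frame(feature = fk, classifier = ck, method = m,
                     accuracy = res$accuracy,
                     macro_precision = res$macro_precision,
                     macro_recall = res$macro_recall,
                     macro_f1 = res$macro_f1, error = NA_character_)
        }
      }
    }
  }
  do.call(rbind, rows)
}
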