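#' Per-class template trace
#'
#' The template of a group is the element-wise mean over that group's traces
#' (the per-dimension mean across samples).
#'
#' @param traces Nonempty list of `swp_trace` (equal lengths).
#' @return Numeric vector of the common trace length, with attributes `leaf`
#'   and `condition` when the traces agree on them.
#' @export
class_template <- function(traces) {
  if (!length(traces)) swp_abort("empty group", "swp_data_error")
  X <- traces_to_matrix(traces)
  tmpl <- colMeans(X$matrix)
  if (length(unique(X$labels)) == 1) attr(tmpl, "condition") <- X$labels[1]
  if (length(unique(X$leaf[!is.na(X$leaf)])) == 1)
    attr(tmpl, "leaf") <- X$leaf[1]
  tmpl
}

#' Template-similarity metrics
#'
#' Quantifies how close a set of traces sits to a class template using three
#' indicators, each computed per sample against the template and then
#' averaged over the `m` samples:
#' Euclidean distance `ED = (1/m) * sum_h ||x_h - y||_2`,
#' Pearson correlation `PCC = (1/m) * sum_h cor(x_h, y)` and
#' cosine similarity `CS = (1/m) * sum_h <x_h, y> / (||x_h|| ||y||)`.
#' Samples with zero variance are skipped for PCC (with a warning, reducing
#' `m` for that metric); zero-norm samples likewise for CS.
#'
#' @param samples List of `swp_trace` or numeric vectors.
#' @param template Numeric template vector (e.g. from [class_template()]).
#' @return Named numeric vector `c(ED=, PCC=, CS=)`.
#' @export
similarity_metrics <- function(samples, template) {
  if (!length(samples)) swp_abort("no samples", "swp_data_error")
  vecs <- lapply(samples, function(s) if (is.numeric(s)) s else s$values)
  if (any(vapply(vecs, length, integer(1)) != length(template)))
    swp_abort("sample length does not match template length",
              "swp_shape_error")
  y <- as.numeric(template)
  ed <- vapply(vecs, function(x) sqrt(sum((x - y)^2)), numeric(1))
  sdy <- stats::sd(y)
  if (sdy == 0)
    swp_abort("template has zero variance: PCC undefined", "swp_metric_error")
  ny <- sqrt(sum(y^2))
  if (ny == 0)
    swp_abort("template has zero norm: CS undefined", "swp_metric_error")
  pcc <- vapply(vecs, function(x) {
    if (stats::sd(x) == 0) NA_real_ else stats::cor(x, y)
  }, numeric(1))
  if (anyNA(pcc)) {
    swp_warn(sprintf("%d zero-variance sample(s) skipped for PCC",
                     sum(is.na(pcc))), "swp_metric_skip")
    if (all(is.na(pcc)))
      swp_abort("all samples degenerate for PCC", "swp_metric_error")
  }
  cs <- vapply(vecs, function(x) {
    nx <- sqrt(sum(x^2))
    if (nx == 0) NA_real_ else sum(x * y) / (nx * ny)
  }, numeric(1))
  if (anyNA(cs)) {
    swp_warn(sprintf("%d zero-norm sample(s) skipped for CS",
                     sum(is.na(cs))), "swp_metric_skip")
    if (all(is.na(cs)))
      swp_abort("all samples degenerate for CS", "swp_metric_error")
  }
  c(ED = mean(ed), PCC = mean(pcc, na.rm = TRUE), CS = mean(cs, na.rm = TRUE))
}

#' Augmentation-fidelity report for all groups
#'
#' For each (leaf, condition) group: builds the template from the original
#' traces and reports ED/PCC/CS of the augmented traces vs the template next
#' to the same metrics for the original traces themselves. An augmented set
#' whose similarities are close to the originals' is considered reliable.
#'
#' @param original,augmented Lists of `swp_trace`.
#' @return Data frame with columns `leaf`, `condition`, `metric`,
#'   `augmented`, `original`, `gap` (absolute difference).
#' @export
augmentation_fidelity <- function(original, augmented) {
  key <- function(t) sprintf("leaf%s_%s", t$leaf, t$condition)
  og <- split(original, vapply(original, key, character(1)))
  ag <- split(augmented, vapply(augmented, key, character(1)))
  rows <- list()
  for (k in names(og)) {
    if (is.null(ag[[k]])) next
    tmpl <- class_template(og[[k]])
    sa <- similarity_metrics(ag[[k]], tmpl)
    so <- similarity_metrics(og[[k]], tmpl)
    rows[[k]] <- data.frame(leaf = og[[k]][[1]]$leaf,
                            condition = og[[k]][[1]]$condition,
                            metric = names(sa), augmented = unname(sa),
                            original = unname(so),
                            gap = abs(unname(sa) - unname(so)),
                            row.names = NULL)
  }
  if (!length(rows)) swp_abort("no overlapping groups", "swp_data_error")
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Confusion matrix and macro-averaged metrics
#'
#' Builds the K-by-K confusion matrix (rows = true label, columns =
#' predicted) and derives accuracy plus one-vs-rest precision, recall and F1
#' per class, macro-averaged with equal class weight. A class never predicted
#' (TP + FP = 0) contributes precision 0; a class absent from the truth
#' (TP + FN = 0) contributes recall 0; F1 is 0 when precision + recall = 0.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param classes Class order for the matrix (default: the light-regime
#'   conditions present).
#' @return Object of class `swp_classification_report`: `confusion`,
#'   `per_class` data frame, `accuracy`, `macro_precision`, `macro_recall`,
#'   `macro_f1`, `n`.
#' @export
confusion_and_metrics <- function(truth, predicted, classes = NULL) {
  if (!length(truth) || length(truth) != length(predicted))
    swp_abort("truth and predicted must be nonempty and equal length",
              "swp_data_error")
  if (is.null(classes))
    classes <- intersect(swp_conditions(), unique(c(truth, predicted)))
  if (!all(c(truth, predicted) %in% classes))
    swp_abort("labels outside the declared class set", "swp_schema_error")
  tf <- factor(truth, levels = classes)
  pf <- factor(predicted, levels = classes)
  cm <- table(true = tf, predicted = pf)
  n <- length(truth)
  per <- lapply(classes, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    tn <- n - tp - fp - fn
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(class = cl, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = prec, recall = rec, f1 = f1)
  })
  per <- do.call(rbind, per)
  structure(list(confusion = cm, per_class = per,
                 accuracy = sum(diag(cm)) / n,
                 macro_precision = mean(per$precision),
                 macro_recall = mean(per$recall),
                 macro_f1 = mean(per$f1), n = n),
            class = "swp_classification_report")
}

#' @export
print.swp_classification_report <- function(x, ...) {
  cat(sprintf("<swp_classification_report> n = %d\n", x$n))
  print(x$confusion)
  cat(sprintf("accuracy %.3f | macro precision %.3f recall %.3f F1 %.3f\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  invisible(x)
}

#' Serialize a classification report to JSON
#' @param report An `swp_classification_report`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- list(classes = rownames(report$confusion),
              confusion = unclass(unname(as.matrix(report$confusion))),
              per_class = report$per_class,
              accuracy = report$accuracy,
              macro_precision = report$macro_precision,
              macro_recall = report$macro_recall,
              macro_f1 = report$macro_f1, n = report$n)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Rebuild a classification report from JSON
#' @param json JSON string or path produced by [report_to_json()].
#' @return An `swp_classification_report`.
#' @export
report_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  cm <- as.table(matrix(obj$confusion, length(obj$classes),
                        dimnames = list(true = obj$classes,
                                        predicted = obj$classes)))
  structure(list(confusion = cm, per_class = obj$per_class,
                 accuracy = obj$accuracy,
                 macro_precision = obj$macro_precision,
                 macro_recall = obj$macro_recall,
                 macro_f1 = obj$macro_f1, n = obj$n),
            class = "swp_classification_report")
}
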