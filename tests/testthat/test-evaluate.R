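# Loop-based similarity oracle, independent of the vectorized implementation.
oracle_similarity <- function(samples, template) {
  m <- length(samples)
  ed <- pcc <- cs <- numeric(m)
  n <- length(template)
  for (h in 1:m) {
    x <- samples[[h]]; y <- template
    s2 <- 0; for (i in 1:n) s2 <- s2 + (x[i] - y[i])^2
    ed[h] <- sqrt(s2)
    xb <- sum(x) / n; yb <- sum(y) / n
    num <- 0; dx <- 0; dy <- 0; dot <- 0; nx <- 0; ny <- 0
    for (i in 1:n) {
      num <- num + (x[i] - xb) * (y[i] - yb)
      dx <- dx + (x[i] - xb)^2; dy <- dy + (y[i] - yb)^2
      dot <- dot + x[i] * y[i]; nx <- nx + x[i]^2; ny <- ny + y[i]^2
    }
    pcc[h] <- num / (sqrt(dx) * sqrt(dy))
    cs[h] <- dot / (sqrt(nx) * sqrt(ny))
  }
  c(ED = mean(ed), PCC = mean(pcc), CS = mean(cs))
}

test_that("class templates are element-wise means", {
  t1 <- make_trace(c(1, 2, 3, 4))
  expect_equal(as.numeric(class_template(list(t1))), c(1, 2, 3, 4))
  t2 <- make_trace(-c(1, 2, 3, 4))
  expect_equal(as.numeric(class_template(list(t1, t2))), rep(0, 4))
  a <- c(1, 0, 2, -1); b <- c(0, 3, 1, 1); c3 <- c(2, 0, 0, 3)
  expect_equal(as.numeric(class_template(list(make_trace(a), make_trace(b),
                                              make_trace(c3)))),
               (a + b + c3) / 3)
  expect_error(class_template(list()), class = "swp_data_error")
})

test_that("similarity metrics satisfy their scaling identities", {
  tmpl <- c(0.5, -1, 2, 0.25, -0.5)
  s <- similarity_metrics(list(tmpl), tmpl)
  expect_equal(unname(s), c(0, 1, 1))

  d <- similarity_metrics(list(2 * tmpl), tmpl)
  expect_equal(d[["PCC"]], 1)
  expect_equal(d[["CS"]], 1)
  expect_equal(d[["ED"]], sqrt(sum(tmpl^2)))

  orth <- c(1, 0, 0, 0, 0); t2 <- c(0, 1, 0, 0, 0)
  expect_equal(similarity_metrics(list(orth), t2)[["CS"]], 0)
})

test_that("similarity metrics match the loop oracle on random sets", {
  set.seed(21)
  for (k in 1:50) {
    n <- sample(5:60, 1)
    m <- sample(1:8, 1)
    samples <- replicate(m, rnorm(n), simplify = FALSE)
    tmpl <- rnorm(n)
    expect_equal(similarity_metrics(samples, tmpl),
                 oracle_similarity(samples, tmpl), tolerance = 1e-12)
  }
})

test_that("degenerate samples are skipped with a warning for PCC", {
  tmpl <- c(1, 2, 3, 4)
  expect_warning(
    s <- similarity_metrics(list(c(1, 1, 1, 1), c(1, 2, 3, 5)), tmpl),
    class = "swp_warning")
  expect_equal(s[["PCC"]], stats::cor(c(1, 2, 3, 5), tmpl))
  expect_error(suppressWarnings(
    similarity_metrics(list(rep(2, 4)), tmpl)), class = "swp_metric_error")
  expect_error(similarity_metrics(list(c(1, 2, 3)), tmpl),
               class = "swp_shape_error")
})

test_that("confusion matrices and macro metrics evaluate worked examples", {
  truth <- rep(c("Normal", "SED", "LED"), each = 5)
  rep1 <- confusion_and_metrics(truth, truth)
  expect_equal(rep1$accuracy, 1)
  expect_equal(rep1$macro_f1, 1)
  expect_equal(rep1$macro_precision, 1)
  expect_equal(rep1$macro_recall, 1)

  # 2-class counts [[2,1],[1,2]]
  t2 <- c("Normal", "Normal", "Normal", "SED", "SED", "SED")
  p2 <- c("Normal", "Normal", "SED", "Normal", "SED", "SED")
  rep2 <- confusion_and_metrics(t2, p2, classes = c("Normal", "SED"))
  expect_equal(rep2$accuracy, 4 / 6)
  expect_equal(rep2$per_class$precision, c(2 / 3, 2 / 3))
  expect_equal(rep2$per_class$recall, c(2 / 3, 2 / 3))
  expect_equal(rep2$macro_f1, 2 / 3)

  all_wrong <- confusion_and_metrics(c("SED", "LED"), c("LED", "SED"))
  expect_equal(all_wrong$accuracy, 0)

  # a never-predicted class contributes precision 0
  rep3 <- confusion_and_metrics(c("Normal", "SED"), c("Normal", "Normal"))
  expect_equal(rep3$per_class$precision[rep3$per_class$class == "SED"], 0)

  expect_error(confusion_and_metrics(character(), character()),
               class = "swp_data_error")
  expect_error(confusion_and_metrics("Normal", "DARK"),
               class = "swp_schema_error")
})

test_that("macro metrics match a brute-force per-class loop on random labels", {
  set.seed(31)
  classes <- swp_conditions()
  for (k in 1:1000) {
    n <- sample(3:40, 1)
    truth <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    rep <- confusion_and_metrics(truth, pred, classes)
    prec <- rec <- f1 <- numeric(3)
    acc <- sum(truth == pred) / n
    for (j in 1:3) {
      cl <- classes[j]
      tp <- sum(truth == cl & pred == cl)
      fp <- sum(truth != cl & pred == cl)
      fn <- sum(truth == cl & pred != cl)
      prec[j] <- if (tp + fp == 0) 0 else tp / (tp + fp)
      rec[j] <- if (tp + fn == 0) 0 else tp / (tp + fn)
      f1[j] <- if (prec[j] + rec[j] == 0) 0 else
        2 * prec[j] * rec[j] / (prec[j] + rec[j])
    }
    expect_equal(rep$accuracy, acc)
    expect_equal(rep$macro_precision, mean(prec))
    expect_equal(rep$macro_recall, mean(rec))
    expect_equal(rep$macro_f1, mean(f1))
  }
})

test_that("classification reports round-trip through JSON", {
  rep <- confusion_and_metrics(c("Normal", "SED", "LED", "SED"),
                               c("Normal", "SED", "SED", "SED"))
  js <- report_to_json(rep)
  back <- report_from_json(js)
  expect_equal(back$accuracy, rep$accuracy)
  expect_equal(back$macro_f1, rep$macro_f1)
  expect_equal(as.matrix(back$confusion), as.matrix(rep$confusion),
               ignore_attr = TRUE)
  expect_identical(as.character(report_to_json(back)), as.character(js))
})

test_that("augmentation fidelity tables pair augmented and original metrics", {
  grp <- tiny_traces(8)
  aug <- augment_dataset(grp, "aae", n_per_group = 3,
                         cfg = fast_aae_cfg(epochs = 8))
  fid <- augmentation_fidelity(grp, aug$augmented)
  expect_equal(sort(unique(fid$metric)), c("CS", "ED", "PCC"))
  expect_equal(nrow(fid), 9)               # 3 conditions x 3 metrics
  expect_true(all(fid$gap >= 0))
  expect_true(all(fid$original[fid$metric == "CS"] <= 1))
})
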