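test_that("confusion metrics match hand arithmetic and degenerate rules", {
  perfect <- confusion_and_scores(rep(c(0, 1), 25), rep(c(0, 1), 25))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$f1, 1)
  y_true <- c(rep(1, 90), rep(0, 20), rep(0, 80), rep(1, 10))
  y_pred <- c(rep(1, 90), rep(1, 20), rep(0, 80), rep(0, 10))
  cs <- confusion_and_scores(y_true, y_pred)
  expect_equal(unname(cs$confusion), c(90, 20, 80, 10))
  expect_equal(cs$precision, 0.8182, tolerance = 1e-4)
  expect_equal(cs$recall, 0.9)
  expect_equal(cs$f1, 0.8571, tolerance = 1e-4)
  expect_warning(expect_warning(
    all0 <- confusion_and_scores(c(1, 1, 0), c(0, 0, 0)), "undefined"))
  expect_equal(all0$precision, 0)
  expect_equal(all0$f1, 0)
  expect_error(confusion_and_scores(c(1, 0), c(1, 0, 1)), "lengths differ")
})

test_that("MCC hits the worked value and the zero-factor convention", {
  expect_equal(mcc(c(TP = 50, FP = 0, TN = 50, FN = 0)), 1)
  expect_equal(mcc(c(TP = 0, FP = 50, TN = 0, FN = 50)), -1)
  expect_equal(mcc(c(TP = 90, FP = 20, TN = 80, FN = 10)), 0.7035,
               tolerance = 1e-4)
  expect_equal(mcc(c(TP = 10, FP = 5, TN = 0, FN = 0)), 0)
})

test_that("MCC is class-swap invariant while F1 is not", {
  cm <- c(TP = 70, FP = 15, TN = 40, FN = 25)
  swapped <- c(TP = cm[["TN"]], FP = cm[["FN"]], TN = cm[["TP"]], FN = cm[["FP"]])
  expect_equal(mcc(cm), mcc(swapped))
  y_true <- c(rep(1, 95), rep(0, 40), rep(0, 55), rep(1, 10))
  y_pred <- c(rep(1, 95), rep(1, 40), rep(0, 55), rep(0, 10))
  f1_pos <- confusion_and_scores(y_true, y_pred)$f1
  f1_neg <- confusion_and_scores(1 - y_true, 1 - y_pred)$f1
  expect_false(isTRUE(all.equal(f1_pos, f1_neg)))
})

test_that("ROC sweep matches the worked set, endpoints and rank statistic", {
  roc <- roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
  expect_equal(roc$auc, 0.75)
  expect_equal(unlist(roc$points[1, 1:2]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc$points[nrow(roc$points), 1:2]), c(fpr = 1, tpr = 1))
  perfect <- roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(perfect$auc, 1)
  expect_error(roc_auc(c(1, 1), c(0.1, 0.2)), "both classes")
  # trapezoid AUC equals the Mann-Whitney statistic on tie-free scores
  set.seed(51)
  for (i in 1:5) {
    y <- rbinom(150, 1, 0.4)
    s <- rnorm(150) + y
    u <- sum(outer(s[y == 1], s[y == 0], ">"))
    expect_equal(roc_auc(y, s)$auc, u / (sum(y == 1) * sum(y == 0)),
                 tolerance = 1e-12)
  }
  # and agrees with an established implementation
  y <- rbinom(200, 1, 0.5); s <- rnorm(200) + 0.8 * y
  expect_equal(roc_auc(y, s)$auc,
               as.numeric(suppressMessages(pROC::auc(y, s))),
               tolerance = 1e-10)
})

test_that("label-independent scores give chance AUC", {
  set.seed(60)
  y <- rbinom(2000, 1, 0.5)
  s <- rnorm(2000)
  expect_lt(abs(roc_auc(y, s)$auc - 0.5), 0.03)
})

test_that("average precision uses step interpolation", {
  perfect <- pr_ap(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(perfect$average_precision, 1)
  # hand-enumerated 4-point sweep: s desc = .8(y1), .4(y0), .35(y1), .1(y0)
  ap <- pr_ap(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
  expect_equal(ap$average_precision, 0.5 * 1 + 0.5 * (2 / 3))
  expect_error(pr_ap(c(1, 1), c(0.3, 0.4)), "both classes")
})

test_that("cross-validation partitions rows, stratifies and scores separable data", {
  set.seed(70)
  tab <- data.frame(x1 = rep(c(4, 0), each = 60), x2 = rnorm(120),
                    label = rep(c(1, 0), each = 60))
  cv <- cross_validate(tab, list(n_estimators = 30), k = 5, seed = 70)
  expect_equal(cv[["mean"]], 100)
  expect_equal(cv[["sd"]], 0)
  folds <- geneconf:::stratified_folds(tab$label, 5, seed = 70)
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(length(folds), 120)
  for (f in 1:5) {
    expect_equal(sum(folds == f), 24)
    expect_lte(abs(sum(tab$label[folds == f] == 1) - 12), 1)
  }
  expect_error(cross_validate(tab, k = 100), "at least k")
})

test_that("pearson correlation matches direct computation", {
  expect_equal(pearson_correlation(1:10, 1:10)$r, 1)
  expect_equal(pearson_correlation(1:10, -(1:10))$r, -1)
  res <- pearson_correlation(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 7))
  expect_equal(res$r, 12 / sqrt(10 * 21.2), tolerance = 1e-9)  # 0.8242
  # p-value via the t transform
  r <- res$r; n <- 5
  t <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(res$p, 2 * stats::pt(-abs(t), n - 2), tolerance = 1e-12)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})

test_that("evaluate_classifier bundles the suite consistently", {
  set.seed(80)
  tab <- data.frame(gene_id = paste0("g", 1:400),
                    x1 = rnorm(400), x2 = rnorm(400),
                    label = rep(c(1, 0), each = 200))
  tab$x1 <- tab$x1 + 2.5 * tab$label
  sp <- split_dataset(tab, 0.8, seed = 80)
  m <- train_classifier(sp$train, list(n_estimators = 40), seed = 80)
  rep_ <- evaluate_classifier(m, sp$test)
  expect_s3_class(rep_, "evaluation_report")
  expect_equal(sum(rep_$confusion), nrow(sp$test))
  expect_gte(rep_$auroc, 0.9)
  expect_equal(rep_$mcc, mcc(rep_$confusion))
  expect_output(print(rep_), "accuracy")
})
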