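separable_table <- function(n = 200, seed = 1, gap = 4) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  data.frame(gene_id = paste0("g", seq_len(n)),
             x1 = rnorm(n, mean = gap * y, sd = 0.4),
             x2 = rnorm(n),
             label = y)
}

test_that("split sizes, determinism and the partition identity hold", {
  tab <- separable_table(1000, seed = 3)
  sp <- split_dataset(tab, 0.8, seed = 5)
  expect_equal(nrow(sp$train), 800)
  expect_equal(nrow(sp$test), 200)
  expect_length(intersect(sp$train$gene_id, sp$test$gene_id), 0)
  expect_setequal(c(sp$train$gene_id, sp$test$gene_id), tab$gene_id)
  sp2 <- split_dataset(tab, 0.8, seed = 5)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_dataset(tab, 0.8, seed = 6)))
})

test_that("stratified split preserves class proportions within one row", {
  set.seed(9)
  tab <- separable_table(1000, seed = 9)
  tab$label <- rbinom(1000, 1, 0.75)
  sp <- split_dataset(tab, 0.8, seed = 1, stratified = TRUE)
  for (cl in 0:1) {
    expect_lte(abs(sum(sp$train$label == cl) - 0.8 * sum(tab$label == cl)), 1)
  }
  one_class <- tab[tab$label == 1, ]
  expect_error(split_dataset(one_class, 0.8, 1, stratified = TRUE),
               "both classes")
})

test_that("training fits separable data perfectly and deterministically", {
  tab <- separable_table(200, seed = 2)
  m <- train_classifier(tab, list(n_estimators = 50), seed = 11)
  pred <- predict(m, tab)
  expect_equal(mean(pred$label == tab$label), 1.0)
  m2 <- train_classifier(tab, list(n_estimators = 50), seed = 11)
  expect_identical(predict(m2, tab)$probability, pred$probability)
  # degenerate inputs
  expect_error(train_classifier(tab[tab$label == 1, ]), "single class")
  bad <- tab; bad$x1 <- as.character(bad$x1)
  expect_error(train_classifier(bad), "non-numeric")
})

test_that("shuffled labels give chance-level cross-validated accuracy", {
  set.seed(13)
  tab <- separable_table(300, seed = 13)
  tab$label <- sample(tab$label)
  cv <- cross_validate(tab, list(n_estimators = 40), k = 10, seed = 13)
  expect_gt(cv[["mean"]], 43)
  expect_lt(cv[["mean"]], 57)
})

test_that("prediction enforces column order and the 0.5 tie rule", {
  tab <- separable_table(100, seed = 4)
  m <- train_classifier(tab, list(n_estimators = 20), seed = 4)
  swapped <- tab[, c("gene_id", "x2", "x1", "label")]
  expect_error(predict(m, swapped), "x1")
  renamed <- tab
  names(renamed)[names(renamed) == "x2"] <- "z9"
  expect_error(predict(m, renamed), "z9")
  # permuting rows permutes outputs identically
  perm <- sample(nrow(tab))
  p1 <- predict(m, tab)
  p2 <- predict(m, tab[perm, ])
  expect_equal(p2$probability, p1$probability[perm])
  # threshold semantics: label 1 iff probability >= 0.5
  expect_equal(p1$label, as.integer(p1$probability >= 0.5))
})

test_that("Bayesian search respects bounds, maximizes history, reruns identically", {
  tab <- separable_table(120, seed = 6, gap = 2)
  space <- default_hyperparameter_space()
  res <- tune_hyperparameters(tab, space, n_iter = 8, inner_cv_folds = 3,
                              seed = 21, n_initial = 4, pool_size = 100)
  expect_equal(nrow(res$history), 8)
  for (nm in names(space)) {
    vals <- res$history[[nm]]
    expect_true(all(vals >= space[[nm]]$lower - 1e-12))
    expect_true(all(vals <= space[[nm]]$upper + 1e-12))
    if (space[[nm]]$integer) expect_true(all(vals == round(vals)))
  }
  expect_equal(res$best_score, max(res$history$mean_score))
  expect_gte(res$best_score, res$history$mean_score[1])
  res2 <- tune_hyperparameters(tab, space, n_iter = 8, inner_cv_folds = 3,
                               seed = 21, n_initial = 4, pool_size = 100)
  expect_identical(res$history, res2$history)
  empty <- space
  empty$gamma$upper <- empty$gamma$lower
  expect_error(tune_hyperparameters(tab, empty, n_iter = 5, seed = 1),
               "empty search-space")
})

test_that("scale_pos_weight shifts minority-class recall as expected", {
  set.seed(30)
  n <- 600
  y <- rbinom(n, 1, 0.15)  # positives are the minority
  tab <- data.frame(x1 = rnorm(n, 1.2 * y, 1), x2 = rnorm(n), label = y)
  sp <- split_dataset(tab, 0.8, seed = 30)
  fit <- function(spw) {
    m <- train_classifier(sp$train, list(n_estimators = 60,
                                         scale_pos_weight = spw), seed = 30)
    p <- predict(m, sp$test)
    sum(p$label == 1 & sp$test$label == 1) / sum(sp$test$label == 1)
  }
  # upweighting the minority positive class raises its recall
  expect_gt(fit(sum(y == 0) / sum(y == 1)), fit(1))
})
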