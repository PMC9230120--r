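# Gradient-boosted tree classifier: splitting, training, prediction, and
# Bayesian hyperparameter search. Positive class = 1 = high confidence.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Extract the numeric feature matrix from a labelled feature table
#'
#' Every column except `gene_id` and `label` is treated as a feature and
#' must be numeric.
#'
#' @param table Feature data.frame.
#' @return Numeric matrix with feature column names.
#' @export
feature_matrix <- function(table) {
  feats <- setdiff(names(table), c("gene_id", "label"))
  bad <- feats[!vapply(table[feats], is.numeric, logical(1))]
  if (length(bad)) stop("non-numeric feature column(s): ",
                        paste(bad, collapse = ", "))
  as.matrix(table[feats])
}

#' Split a labelled table into training and test partitions
#'
#' Row sets are disjoint, their union is the input, and
#' `nrow(train) = round(train_fraction * n)`. The stratified split (the
#' default, appropriate for the ~3:1 class imbalance typical of
#' conserved/non-conserved gene sets) keeps per-class proportions within
#' one row via largest-remainder allocation; a plain random split is
#' available with `stratified = FALSE`. Deterministic for a fixed seed.
#'
#' @param table Data.frame with a `label` column.
#' @param train_fraction Fraction of rows in the training partition.
#' @param seed Integer seed.
#' @param stratified Stratify by label?
#' @return List with elements `train` and `test` (data.frames).
#' @export
split_dataset <- function(table, train_fraction = 0.8, seed = 42L,
                          stratified = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1, "label" %in% names(table))
  n <- nrow(table)
  n_train <- round(train_fraction * n)
  idx <- with_seed(seed, {
    if (stratified) {
      classes <- sort(unique(table$label))
      if (length(classes) < 2L)
        stop("stratified split requires both classes present")
      quota <- vapply(classes, function(cl) train_fraction * sum(table$label == cl),
                      numeric(1))
      base <- floor(quota)
      extra <- n_train - sum(base)
      take <- base
      if (extra > 0) {
        ord <- order(quota - base, decreasing = TRUE)
        take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1L
      }
      unlist(lapply(seq_along(classes), function(i) {
        rows <- which(table$label == classes[i])
        sample(rows, take[i])
      }))
    } else {
      sample.int(n, n_train)
    }
  })
  list(train = table[sort(idx), , drop = FALSE],
       test = table[setdiff(seq_len(n), idx), , drop = FALSE])
}

map_xgb_params <- function(params) {
  defaults <- list(learning_rate = 0.3, min_child_weight = 1, max_depth = 6,
                   max_delta_step = 0, subsample = 1, colsample_bytree = 1,
                   colsample_bylevel = 1, reg_lambda = 1, reg_alpha = 0,
                   gamma = 0, n_estimators = 100, scale_pos_weight = 1)
  p <- utils::modifyList(defaults, params[names(params) %in% names(defaults)])
  list(nrounds = as.integer(p$n_estimators),
       xgb = list(objective = "binary:logistic",
                  eta = p$learning_rate,
                  min_child_weight = p$min_child_weight,
                  max_depth = as.integer(p$max_depth),
                  max_delta_step = p$max_delta_step,
                  subsample = p$subsample,
                  colsample_bytree = p$colsample_bytree,
                  colsample_bylevel = p$colsample_bylevel,
                  lambda = p$reg_lambda,
                  alpha = p$reg_alpha,
                  gamma = p$gamma,
                  scale_pos_weight = p$scale_pos_weight,
                  base_score = 0.5,
                  tree_method = "hist",
                  nthread = 1))
}

#' Train the boosted-tree classifier
#'
#' Fits a binary XGBoost ensemble on a labelled feature table.
#' Hyperparameters use the search-space names (`learning_rate`,
#' `n_estimators`, `reg_lambda`, ...); unspecified ones fall back to the
#' library defaults. Training is single-threaded with histogram tree
#' construction and an explicit seed, so refits are bit-identical.
#'
#' @param train Labelled feature table (must contain both classes).
#' @param params Named list of hyperparameters (possibly empty).
#' @param seed Integer seed.
#' @return An object of class `gene_classifier`.
#' @export
train_classifier <- function(train, params = list(), seed = 42L) {
  x <- feature_matrix(train)
  y <- train$label
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  mp <- map_xgb_params(params)
  mp$xgb$seed <- as.integer(seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  booster <- xgboost::xgb.train(params = mp$xgb, data = dtrain,
                                nrounds = mp$nrounds, verbose = 0)
  structure(list(booster = booster,
                 params = params,
                 feature_names = colnames(x),
                 positive_class = 1L,
                 n_train = nrow(x),
                 seed = as.integer(seed)),
            class = "gene_classifier")
}

check_feature_columns <- function(model, features) {
  got <- colnames(features)
  want <- model$feature_names
  if (length(got) != length(want) || any(got != want)) {
    m <- min(length(got), length(want))
    first_bad <- which(got[seq_len(m)] != want[seq_len(m)])[1L]
    if (is.na(first_bad)) first_bad <- m + 1L
    stop("feature columns do not match training order; first mismatch: ",
         "expected '",
         if (first_bad <= length(want)) want[first_bad] else "<none>",
         "', got '",
         if (first_bad <= length(got)) got[first_bad] else "<missing>", "'")
  }
}

#' Predict gene-model confidence
#'
#' @param object A `gene_classifier`.
#' @param newdata Feature table whose feature columns match the training
#'   order exactly.
#' @param ... Unused.
#' @return Data.frame with `gene_id` (if present in `newdata`),
#'   `probability` (of the high-confidence class) and `label`
#'   (1 iff probability >= 0.5; the 0.5 tie goes to class 1).
#' @export
predict.gene_classifier <- function(object, newdata, ...) {
  x <- feature_matrix(newdata)
  check_feature_columns(object, x)
  prob <- predict(object$booster, xgboost::xgb.DMatrix(x))
  out <- data.frame(probability = prob, label = as.integer(prob >= 0.5))
  if ("gene_id" %in% names(newdata)) out <- cbind(gene_id = newdata$gene_id, out)
  out
}

#' Default hyperparameter search space
#'
#' Closed intervals for each tunable dimension of the boosted-tree model.
#' Regularization strengths and `scale_pos_weight` span orders of
#' magnitude and are sampled log-uniformly; `max_depth`, `max_delta_step`
#' and `n_estimators` are integers.
#'
#' @return Named list of dimensions, each with `lower`, `upper`, `log`,
#'   `integer`.
#' @export
default_hyperparameter_space <- function() {
  dim <- function(lower, upper, log = FALSE, integer = FALSE)
    list(lower = lower, upper = upper, log = log, integer = integer)
  list(learning_rate = dim(0.01, 1.0, log = TRUE),
       min_child_weight = dim(0, 10),
       max_depth = dim(0, 50, integer = TRUE),
       max_delta_step = dim(0, 20, integer = TRUE),
       subsample = dim(0.01, 1.0),
       colsample_bytree = dim(0.01, 1.0),
       colsample_bylevel = dim(0.01, 1.0),
       reg_lambda = dim(1e-9, 1000, log = TRUE),
       reg_alpha = dim(1e-9, 1.0, log = TRUE),
       gamma = dim(1e-9, 0.5, log = TRUE),
       n_estimators = dim(50, 200, integer = TRUE),
       scale_pos_weight = dim(1e-6, 500, log = TRUE))
}

space_decode <- function(u, space) {
  stats::setNames(lapply(seq_along(space), function(j) {
    d <- space[[j]]
    v <- if (d$log) exp(log(d$lower) + u[j] * (log(d$upper) - log(d$lower)))
         else d$lower + u[j] * (d$upper - d$lower)
    if (d$integer) round(v) else v
  }), names(space))
}

stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      rows <- which(labels == cl)
      fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
    }
    fold
  })
}

cv_accuracy <- function(table, params, folds, seed) {
  acc <- vapply(sort(unique(folds)), function(f) {
    fit <- train_classifier(table[folds != f, , drop = FALSE], params, seed)
    pred <- predict(fit, table[folds == f, , drop = FALSE])
    mean(pred$label == table$label[folds == f])
  }, numeric(1))
  c(mean = mean(acc), sd = stats::sd(acc))
}

# Lengthscale scales with sqrt(d): pairwise distances in a d-dimensional
# unit cube concentrate around sqrt(d/6), so a fixed small lengthscale
# would zero out all correlations and reduce the surrogate to noise.
gp_fit <- function(X, y, lengthscale = 0.5 * sqrt(ncol(X)), noise = 1e-4) {
  mu <- mean(y); sdv <- stats::sd(y)
  if (!is.finite(sdv) || sdv < 1e-12) sdv <- 1
  ys <- (y - mu) / sdv
  K <- exp(-0.5 * as.matrix(stats::dist(X))^2 / lengthscale^2)
  L <- chol(K + diag(noise + 1e-8, nrow(X)))
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  list(X = X, L = L, alpha = alpha, mu = mu, sdv = sdv,
       lengthscale = lengthscale)
}

gp_predict <- function(gp, Xnew) {
  d2 <- outer(rowSums(Xnew^2), rowSums(gp$X^2), "+") - 2 * Xnew %*% t(gp$X)
  Ks <- exp(-0.5 * pmax(d2, 0) / gp$lengthscale^2)
  mean_s <- as.vector(Ks %*% gp$alpha)
  v <- forwardsolve(t(gp$L), t(Ks))
  var_s <- pmax(1 - colSums(v^2), 1e-12)
  list(mean = gp$mu + gp$sdv * mean_s, sd = gp$sdv * sqrt(var_s))
}

#' Bayesian hyperparameter search
#'
#' Sequential model-based optimization of mean inner-CV accuracy over the
#' hyperparameter space: an initial seeded random design, then a Gaussian
#' process surrogate (squared-exponential kernel on the unit-scaled
#' space) whose expected-improvement acquisition picks each next
#' configuration from a random candidate pool. Every evaluated
#' configuration lies inside its stated interval; the returned best
#' configuration maximizes the observed mean inner-CV accuracy.
#'
#' @param train Labelled feature table.
#' @param space Search space from [default_hyperparameter_space()].
#' @param n_iter Total configurations to evaluate (>= 5).
#' @param inner_cv_folds Folds of the inner cross-validation (>= 2).
#' @param seed Integer seed; fixes the design, the folds and the model
#'   fits, so reruns reproduce the history exactly.
#' @param n_initial Size of the space-filling (Latin hypercube) initial
#'   design evaluated before the surrogate starts.
#' @param pool_size Candidate-pool size for the acquisition step.
#' @return List with `best_params`, `best_score`, and `history` (one row
#'   per iteration: the configuration, mean and sd of inner-CV accuracy).
#' @export
tune_hyperparameters <- function(train, space = default_hyperparameter_space(),
                                 n_iter = 50L, inner_cv_folds = 5L, seed = 42L,
                                 n_initial = 10L, pool_size = 500L) {
  stopifnot(n_iter >= 5, inner_cv_folds >= 2)
  if (any(!vapply(space, function(d) d$upper > d$lower, logical(1))))
    stop("empty search-space dimension")
  d <- length(space)
  folds <- stratified_folds(train$label, inner_cv_folds, seed)
  U <- matrix(NA_real_, n_iter, d)
  scores <- matrix(NA_real_, n_iter, 2L)
  history <- vector("list", n_iter)
  n_initial <- max(min(n_initial, n_iter), 2L)
  with_seed(seed, {
    design <- lhs::randomLHS(n_initial, d)
    for (i in seq_len(n_iter)) {
      u <- if (i <= n_initial) {
        design[i, ]
      } else {
        gp <- gp_fit(U[seq_len(i - 1L), , drop = FALSE], scores[seq_len(i - 1L), 1L])
        cand <- matrix(stats::runif(pool_size * d), pool_size, d)
        pr <- gp_predict(gp, cand)
        best <- max(scores[seq_len(i - 1L), 1L])
        z <- (pr$mean - best - 0.01) / pr$sd
        ei <- (pr$mean - best - 0.01) * stats::pnorm(z) + pr$sd * stats::dnorm(z)
        cand[which.max(ei), ]
      }
      U[i, ] <- u
      params <- space_decode(u, space)
      scores[i, ] <- cv_accuracy(train, params, folds, seed)
      history[[i]] <- data.frame(iteration = i, as.data.frame(params),
                                 mean_score = scores[i, 1L],
                                 sd_score = scores[i, 2L])
    }
  })
  history <- do.call(rbind, history)
  best <- which.max(history$mean_score)
  list(best_params = space_decode(U[best, ], space),
       best_score = history$mean_score[best],
       history = history)
}
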