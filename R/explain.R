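# Model explanation: split-gain/weight importances and exact tree Shapley
# attributions, with a plot-ready long-format export for beeswarm summaries.

#' Split-based feature importances
#'
#' `gain` is the total loss reduction attributed to splits on each
#' feature; `weight` (the "F-score" of the usual importance plot) is the
#' number of splits using it. Both are aggregated directly from the tree
#' dump, so features never used by the ensemble appear with gain 0 and
#' weight 0. Rows are sorted by the chosen metric, descending.
#'
#' @param model A fitted `gene_classifier`.
#' @param metric `"gain"` or `"weight"` (sort order only; both are
#'   returned).
#' @return Data.frame `feature`, `gain`, `weight`, `rank_gain`,
#'   `rank_weight`.
#' @export
feature_importance <- function(model, metric = c("gain", "weight")) {
  metric <- match.arg(metric)
  if (!inherits(model, "gene_classifier")) stop("expected a gene_classifier")
  dump <- xgboost::xgb.model.dt.tree(model = model$booster)
  splits <- dump[dump$Feature != "Leaf", ]
  gain <- tapply(splits$Gain, splits$Feature, sum)
  weight <- tapply(rep(1L, nrow(splits)), splits$Feature, sum)
  out <- data.frame(feature = model$feature_names,
                    gain = as.numeric(gain[model$feature_names]),
                    weight = as.integer(weight[model$feature_names]),
                    stringsAsFactors = FALSE)
  out$gain[is.na(out$gain)] <- 0
  out$weight[is.na(out$weight)] <- 0L
  out$rank_gain <- rank(-out$gain, ties.method = "min")
  out$rank_weight <- rank(-out$weight, ties.method = "min")
  out[order(-out[[metric]]), , drop = FALSE]
}

#' Exact tree Shapley attributions
#'
#' Per-sample, per-feature Shapley values in margin (log-odds) space via
#' the polynomial tree-traversal algorithm, so local accuracy is exact:
#' for every sample, `base + sum(attributions)` equals the model's margin
#' output. Margin space is used deliberately — the identity does not hold
#' after the logistic link.
#'
#' @param model A fitted `gene_classifier`.
#' @param features Feature table with columns matching the training
#'   order.
#' @return List of class `shap_matrix`: `values` (n x p matrix), `base`
#'   (scalar expected margin), `gene_id` (or row indices).
#' @export
shap_attributions <- function(model, features) {
  x <- feature_matrix(features)
  check_feature_columns(model, x)
  contrib <- predict(model$booster, xgboost::xgb.DMatrix(x),
                     predcontrib = TRUE)
  p <- length(model$feature_names)
  values <- contrib[, seq_len(p), drop = FALSE]
  colnames(values) <- model$feature_names
  ids <- if ("gene_id" %in% names(features)) features$gene_id
         else as.character(seq_len(nrow(x)))
  structure(list(values = values, base = unname(contrib[1L, p + 1L]),
                 gene_id = ids),
            class = "shap_matrix")
}

#' Plot-ready beeswarm export
#'
#' Ranks features by mean absolute attribution and emits a long-format
#' table (one row per sample and top feature) carrying the attribution,
#' the raw feature value and its within-feature percentile — everything a
#' beeswarm summary plot needs.
#'
#' @param shap A `shap_matrix` from [shap_attributions()].
#' @param features The feature table the attributions were computed on.
#' @param top_n Number of top features to export.
#' @return Data.frame `feature`, `rank`, `sample_id`, `attribution`,
#'   `feature_value`, `value_percentile`.
#' @export
beeswarm_export <- function(shap, features, top_n = 20L) {
  if (top_n < 1) stop("top_n must be >= 1")
  stopifnot(inherits(shap, "shap_matrix"))
  vals <- shap$values
  if (nrow(vals) != nrow(features)) stop("shap and features are not aligned")
  imp <- colMeans(abs(vals))
  ord <- order(imp, decreasing = TRUE)
  top <- colnames(vals)[ord][seq_len(min(top_n, ncol(vals)))]
  out <- lapply(seq_along(top), function(r) {
    f <- top[r]
    v <- features[[f]]
    data.frame(feature = f, rank = r, sample_id = shap$gene_id,
               attribution = vals[, f], feature_value = v,
               value_percentile = 100 * (rank(v, ties.method = "average") - 0.5) /
                 length(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
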