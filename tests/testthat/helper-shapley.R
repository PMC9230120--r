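# Brute-force Shapley oracle for small tree ensembles: enumerates every
# feature coalition, with the conditional expectation of a tree for a
# coalition computed by cover-weighted traversal (features outside the
# coalition average over both children). Feasible for <= 3 features.

tree_tables <- function(booster) {
  dump <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  split(dump, dump$Tree)
}

tree_cond_expect <- function(tree, x, coalition) {
  rownames(tree) <- tree$ID
  rec <- function(id) {
    node <- tree[id, ]
    if (node$Feature == "Leaf") return(node$Gain)
    if (node$Feature %in% coalition) {
      branch <- if (x[[node$Feature]] < node$Split) node$Yes else node$No
      return(rec(branch))
    }
    wy <- tree[node$Yes, "Cover"]
    wn <- tree[node$No, "Cover"]
    (wy * rec(node$Yes) + wn * rec(node$No)) / (wy + wn)
  }
  rec(tree$ID[tree$Node == 0])
}

shapley_oracle <- function(booster, x, feature_names) {
  trees <- tree_tables(booster)
  v <- function(coalition) {
    sum(vapply(trees, tree_cond_expect, numeric(1), x = x,
               coalition = coalition))
  }
  p <- length(feature_names)
  phi <- setNames(numeric(p), feature_names)
  for (j in feature_names) {
    others <- setdiff(feature_names, j)
    for (size in 0:length(others)) {
      subsets <- if (size == 0) list(character(0)) else
        utils::combn(others, size, simplify = FALSE)
      w <- factorial(size) * factorial(p - size - 1) / factorial(p)
      for (S in subsets) phi[j] <- phi[j] + w * (v(c(S, j)) - v(S))
    }
  }
  list(phi = phi, base = v(character(0)))
}
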