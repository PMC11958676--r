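# Generic tree-ensemble representation used by the explainability engine.
#
# A tree is a numeric matrix with one row per node and columns
#   feature   1-based split feature index, 0 for leaves
#   threshold split point; x[feature] <= threshold goes to `yes`
#   yes, no   1-based child node indices (0 for leaves)
#   value     leaf value (here: training fraction of +BATS in the leaf,
#             via the forest's own leaf estimates)
#   cover     training rows passing through the node
# Node 1 is the root; children always have larger indices than parents.

tree_cols <- c("feature", "threshold", "yes", "no", "value", "cover")

#' Construct a tree ensemble
#'
#' @param trees list of node matrices (see package internals for the
#'   column layout); most users obtain one via [as_tree_ensemble()].
#' @param feature_names names of the feature space the trees split on.
#' @return object of class `tree_ensemble` with a `base_value`: the
#'   cover-weighted mean leaf value averaged over trees (the model's mean
#'   prediction).
#' @export
tree_ensemble <- function(trees, feature_names) {
  trees <- lapply(trees, function(tm) {
    tm <- as.matrix(tm)
    colnames(tm) <- tree_cols
    storage.mode(tm) <- "double"
    tm
  })
  base <- mean(vapply(trees, function(tm) {
    leaves <- tm[, "feature"] == 0
    sum(tm[leaves, "value"] * tm[leaves, "cover"]) / sum(tm[leaves, "cover"])
  }, numeric(1)))
  structure(list(trees = trees, feature_names = feature_names,
                 base_value = base),
            class = "tree_ensemble")
}

#' @export
print.tree_ensemble <- function(x, ...) {
  cat("Tree ensemble: ", length(x$trees), " trees over ",
      length(x$feature_names), " features; base value ",
      signif(x$base_value, 4), "\n", sep = "")
  invisible(x)
}

# route rows of X through one tree; returns list of row-index vectors per
# node (children carry larger indices than parents, so one forward pass)
route_rows <- function(tm, X) {
  idx <- vector("list", nrow(tm))
  idx[[1]] <- seq_len(nrow(X))
  for (j in seq_len(nrow(tm))) {
    rows <- idx[[j]]
    if (tm[j, "feature"] == 0 || length(rows) == 0) next
    left <- X[rows, tm[j, "feature"]] <= tm[j, "threshold"]
    yi <- tm[j, "yes"]; ni <- tm[j, "no"]
    idx[[yi]] <- c(idx[[yi]], rows[left])
    idx[[ni]] <- c(idx[[ni]], rows[!left])
  }
  idx
}

#' Extract the tree structures of a fitted random forest
#'
#' Converts a `ranger` probability forest into the package's generic
#' tree-ensemble form. Leaf values are the forest's own terminal-node
#' +BATS probabilities; node covers are recomputed by routing the supplied
#' (training) data through each tree, so the ensemble's predictions equal
#' the forest's and the cover fractions define the marginalization used by
#' [signed_contributions()].
#'
#' @param fit a `ranger` model fitted with `probability = TRUE`.
#' @param X the training feature matrix (same columns, same order).
#' @param positive_class column of the terminal-node probabilities to use
#'   as the leaf value.
#' @return a [tree_ensemble()].
#' @export
as_tree_ensemble <- function(fit, X, positive_class = "pos") {
  stopifnot(inherits(fit, "ranger"))
  if (fit$treetype != "Probability estimation") {
    stop("fit the forest with probability = TRUE")
  }
  X <- as.matrix(X)
  trees <- vector("list", fit$num.trees)
  pred_col <- paste0("pred.", positive_class)
  for (t in seq_len(fit$num.trees)) {
    ti <- ranger::treeInfo(fit, t)
    tm <- cbind(feature = ifelse(ti$terminal, 0, ti$splitvarID + 1),
                threshold = ifelse(ti$terminal, 0, ti$splitval),
                yes = ifelse(ti$terminal, 0, ti$leftChild + 1),
                no = ifelse(ti$terminal, 0, ti$rightChild + 1),
                value = ifelse(ti$terminal, ti[[pred_col]], 0),
                cover = 0)
    idx <- route_rows(tm, X)
    tm[, "cover"] <- lengths(idx)
    if (any(tm[, "cover"] == 0)) {
      stop("tree ", t, " has nodes no supplied row reaches; pass the ",
           "training data used to fit the forest")
    }
    trees[[t]] <- tm
  }
  tree_ensemble(trees, colnames(X))
}

#' Predict with a generic tree ensemble
#'
#' Mean leaf value over trees — for ensembles extracted from a probability
#' forest, the predicted +BATS probability.
#'
#' @param object a [tree_ensemble()].
#' @param newdata numeric matrix with the ensemble's feature columns.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.tree_ensemble <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == length(object$feature_names))
  .tree_predict_cpp(object$trees, newdata)
}

# cover-weighted conditional expectation of one tree given the features in
# S (logical vector): in-coalition features follow x, the rest are
# marginalized by cover fractions
tree_expectation <- function(tm, x, S) {
  rec <- function(j) {
    if (tm[j, "feature"] == 0) return(tm[j, "value"])
    f <- tm[j, "feature"]
    yi <- tm[j, "yes"]; ni <- tm[j, "no"]
    if (S[f]) {
      if (x[f] <= tm[j, "threshold"]) rec(yi) else rec(ni)
    } else {
      (tm[yi, "cover"] * rec(yi) + tm[ni, "cover"] * rec(ni)) /
        tm[j, "cover"]
    }
  }
  rec(1)
}

#' Exhaustive Shapley values for a small tree ensemble
#'
#' Brute-force Shapley attribution by enumeration of all 2^p coalitions,
#' with the coalition value defined as the cover-weighted tree-conditional
#' expectation — the same value function the fast path algorithm in
#' [signed_contributions()] attributes. Exponential in the number of
#' features; intended as the reference oracle on small instances.
#'
#' @param ens a [tree_ensemble()].
#' @param x a single feature row (numeric vector).
#' @param max_features refuse larger problems (2^p blow-up).
#' @return list with `phi` (named per-feature values) and `base`
#'   (`v(empty set)` = the ensemble base value).
#' @export
exhaustive_shapley <- function(ens, x, max_features = 12) {
  p <- length(ens$feature_names)
  if (p > max_features) {
    stop("exhaustive enumeration over 2^", p, " coalitions refused; ",
         "this oracle is for small instances")
  }
  v_of <- function(S) {
    mean(vapply(ens$trees, tree_expectation, numeric(1), x = x, S = S))
  }
  n_sets <- 2^p
  v <- numeric(n_sets)
  sets <- matrix(FALSE, n_sets, p)
  for (m in seq_len(n_sets) - 1L) {
    S <- as.logical(bitwAnd(m, 2^(seq_len(p) - 1L)))
    sets[m + 1L, ] <- S
    v[m + 1L] <- v_of(S)
  }
  sizes <- rowSums(sets)
  phi <- numeric(p)
  for (j in seq_len(p)) {
    without <- which(!sets[, j])
    for (m in without) {
      s <- sizes[m]
      w <- factorial(s) * factorial(p - s - 1) / factorial(p)
      m_with <- m + 2^(j - 1L)
      phi[j] <- phi[j] + w * (v[m_with] - v[m])
    }
  }
  list(phi = setNames(phi, ens$feature_names), base = v[1])
}
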