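#' Impurity (Gini) feature importance with per-tree dispersion
#'
#' For every tree of a fitted random forest, sums the impurity decrease
#' (binary Gini, weighted by the fraction of training rows reaching the
#' node) over all nodes splitting on each feature; reports the mean and
#' standard deviation of these per-tree totals across trees, scaled so the
#' mean importances sum to 1.
#'
#' @param fit a `ranger` probability forest (non-tree models are rejected).
#' @param X,y the training features and labels (factor with levels
#'   `neg`/`pos`) used to fit the forest; node impurities are recomputed
#'   by routing them through the trees.
#' @return data.frame: `feature`, `gini_mean` (sums to 1), `gini_std`.
#' @export
gini_importance <- function(fit, X, y) {
  if (!inherits(fit, "ranger")) {
    stop("impurity importance is defined for tree ensembles; got ",
         paste(class(fit), collapse = "/"))
  }
  X <- as.matrix(X)
  y <- factor(y, levels = c("neg", "pos"))
  p <- ncol(X)
  n_total <- nrow(X)
  ypos <- y == "pos"
  per_tree <- matrix(0, fit$num.trees, p)
  for (t in seq_len(fit$num.trees)) {
    ti <- ranger::treeInfo(fit, t)
    tm <- cbind(feature = ifelse(ti$terminal, 0, ti$splitvarID + 1),
                threshold = ifelse(ti$terminal, 0, ti$splitval),
                yes = ifelse(ti$terminal, 0, ti$leftChild + 1),
                no = ifelse(ti$terminal, 0, ti$rightChild + 1),
                value = 0, cover = 0)
    idx <- route_rows(tm, X)
    n <- lengths(idx)
    npos <- vapply(idx, function(i) sum(ypos[i]), numeric(1))
    pr <- ifelse(n > 0, npos / pmax(n, 1), 0)
    imp <- 2 * pr * (1 - pr)
    internal <- which(tm[, "feature"] != 0 & n > 0)
    for (j in internal) {
      yi <- tm[j, "yes"]; ni <- tm[j, "no"]
      dec <- (n[j] / n_total) *
        (imp[j] - (n[yi] / n[j]) * imp[yi] - (n[ni] / n[j]) * imp[ni])
      f <- tm[j, "feature"]
      per_tree[t, f] <- per_tree[t, f] + dec
    }
  }
  gm <- colMeans(per_tree)
  gs <- apply(per_tree, 2, stats::sd)
  total <- sum(gm)
  if (total > 0) {
    gm <- gm / total
    gs <- gs / total
  }
  data.frame(feature = colnames(X), gini_mean = gm, gini_std = gs,
             stringsAsFactors = FALSE)
}

#' Signed per-epoch feature contributions (Shapley-style)
#'
#' Additive attribution of every prediction of a tree ensemble to its
#' features, using the polynomial-time path algorithm over the trees with
#' cover-fraction marginalization. Satisfies local accuracy: for every
#' epoch, `base_value + sum(contributions)` equals the ensemble's
#' predicted +BATS probability (to numerical tolerance). Positive values
#' push the prediction toward +BATS.
#'
#' @param model a [tree_ensemble()] (see [as_tree_ensemble()] to extract
#'   one from a fitted forest).
#' @param feature_rows numeric matrix of epochs to explain; column names,
#'   when present, must match the ensemble's feature space.
#' @return list of class `signed_contributions`: `contributions`
#'   (epochs x features), `base_value`, `prediction` (per-epoch model
#'   output).
#' @export
signed_contributions <- function(model, feature_rows) {
  stopifnot(inherits(model, "tree_ensemble"))
  feature_rows <- as.matrix(feature_rows)
  if (!is.null(colnames(feature_rows)) &&
      !identical(colnames(feature_rows), model$feature_names)) {
    stop("feature columns do not match the model's feature space")
  }
  if (ncol(feature_rows) != length(model$feature_names)) {
    stop("expected ", length(model$feature_names), " feature columns, got ",
         ncol(feature_rows))
  }
  phi <- .tree_shap_cpp(model$trees, feature_rows)
  colnames(phi) <- model$feature_names
  structure(list(contributions = phi,
                 base_value = model$base_value,
                 prediction = predict(model, feature_rows)),
            class = "signed_contributions")
}

#' @export
print.signed_contributions <- function(x, ...) {
  cat("Signed contributions: ", nrow(x$contributions), " epochs x ",
      ncol(x$contributions), " features; base value ",
      signif(x$base_value, 4), "\n", sep = "")
  invisible(x)
}

# class key per feature: family for aperiodic features, family x band else
feature_class <- function(meta) {
  ifelse(is.na(meta$band), meta$family, paste(meta$band, meta$family))
}

#' Aggregate contributions by feature class
#'
#' Sums the mean absolute contribution of all features in each class
#' (band x family, e.g. "alpha band_power"), overall and per predicted
#' group, ordered by decreasing overall importance.
#'
#' @param sc a [signed_contributions()] result.
#' @param feature_meta the feature metadata (`fm$meta`) covering every
#'   contribution column; unmapped features are rejected.
#' @param predicted optional factor of predicted groups per epoch
#'   (levels `neg`/`pos`); adds per-group aggregate columns.
#' @return data.frame: `class`, `importance` (summed mean |contribution|),
#'   `mean_signed` (summed mean signed contribution), and with
#'   `predicted`: `importance_pos`, `importance_neg`.
#' @export
class_aggregate <- function(sc, feature_meta, predicted = NULL) {
  stopifnot(inherits(sc, "signed_contributions"))
  feats <- colnames(sc$contributions)
  idx <- match(feats, feature_meta$feature)
  if (anyNA(idx)) {
    stop("features missing from metadata: ",
         paste(feats[is.na(idx)], collapse = ", "))
  }
  cls <- feature_class(feature_meta[idx, , drop = FALSE])
  absmean <- colMeans(abs(sc$contributions))
  sgnmean <- colMeans(sc$contributions)
  out <- aggregate(cbind(importance = absmean, mean_signed = sgnmean),
                   by = list(class = cls), FUN = sum)
  if (!is.null(predicted)) {
    predicted <- factor(predicted, levels = c("neg", "pos"))
    for (g in levels(predicted)) {
      rows <- predicted == g
      v <- if (any(rows)) colMeans(abs(sc$contributions[rows, , drop = FALSE]))
           else rep(0, length(feats))
      agg <- aggregate(v, by = list(class = cls), FUN = sum)
      out[[paste0("importance_", g)]] <- agg$x[match(out$class, agg$class)]
    }
  }
  out[order(-out$importance), , drop = FALSE]
}

#' Two-feature partial dependence surface
#'
#' Average model prediction with two features clamped to each point of a
#' grid — e.g. the joint effect of the aperiodic offset and slope on the
#' predicted +BATS probability.
#'
#' @param model a [tree_ensemble()].
#' @param feature_rows background feature matrix (typically the training
#'   epochs).
#' @param feature_x,feature_y names of the two features.
#' @param grid_x,grid_y grid values; default: 11 quantile-spaced points of
#'   the background distribution.
#' @return list of class `partial_dependence_2d`: `x`, `y`,
#'   `surface` (length(x) x length(y) matrix of mean predictions).
#' @export
partial_dependence_2d <- function(model, feature_rows, feature_x, feature_y,
                                  grid_x = NULL, grid_y = NULL) {
  stopifnot(inherits(model, "tree_ensemble"))
  feature_rows <- as.matrix(feature_rows)
  ix <- match(feature_x, model$feature_names)
  iy <- match(feature_y, model$feature_names)
  if (is.na(ix) || is.na(iy)) {
    stop("both features must be in the model's feature space")
  }
  if (is.null(grid_x)) {
    grid_x <- unname(quantile(feature_rows[, ix], probs = seq(0, 1, 0.1)))
  }
  if (is.null(grid_y)) {
    grid_y <- unname(quantile(feature_rows[, iy], probs = seq(0, 1, 0.1)))
  }
  if (length(grid_x) == 0 || length(grid_y) == 0) {
    stop("empty partial-dependence grid")
  }
  surface <- matrix(NA_real_, length(grid_x), length(grid_y))
  work <- feature_rows
  for (a in seq_along(grid_x)) {
    work[, ix] <- grid_x[a]
    for (b in seq_along(grid_y)) {
      work[, iy] <- grid_y[b]
      surface[a, b] <- mean(predict(model, work))
    }
  }
  structure(list(x = grid_x, y = grid_y, surface = surface,
                 feature_x = feature_x, feature_y = feature_y),
            class = "partial_dependence_2d")
}

#' @export
print.partial_dependence_2d <- function(x, ...) {
  cat("Partial dependence of prediction on ", x$feature_x, " x ",
      x$feature_y, ": ", length(x$x), " x ", length(x$y), " grid, range [",
      signif(min(x$surface), 3), ", ", signif(max(x$surface), 3), "]\n",
      sep = "")
  invisible(x)
}
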