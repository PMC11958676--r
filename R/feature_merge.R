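#' Merge highly correlated features
#'
#' Removes multicollinearity while keeping features interpretable: builds a
#' graph with an edge between every pair of features whose absolute Pearson
#' correlation exceeds `threshold`, takes connected components, and keeps
#' only the lowest-column-index feature of each component (a deterministic,
#' interpretable representative) — no linear combinations are formed.
#' Constant columns (zero variance) are dropped first with a warning, as
#' their correlation is undefined.
#'
#' Correlation is computed on all supplied rows. By default that is the
#' full epoch set (merging before the train/test split); pass the training
#' rows only via `rows` for a leakage-safe variant.
#'
#' @param fm a [feature_matrix()].
#' @param threshold absolute-correlation threshold above which features are
#'   considered redundant.
#' @param rows optional row indices on which to compute correlations
#'   (the returned matrix still contains all rows).
#' @return list with `fm` (the reduced [feature_matrix()]) and `report`, a
#'   `merge_report`: `threshold`, `kept` (feature names), `dropped` (named
#'   character vector, dropped feature -> representative), `groups` (list of
#'   connected components with >1 member), `constant` (dropped constant
#'   columns).
#' @examples
#' m <- matrix(rnorm(300), 100, 3)
#' m <- cbind(m, m[, 1]) # exact duplicate of column 1
#' fm <- feature_matrix(m, data.frame(feature = paste0("f", 1:4),
#'   family = "band_power", band = "alpha", unit = "Cz", hemisphere = "mid"))
#' merge_correlated(fm)$report
#' @export
merge_correlated <- function(fm, threshold = 0.9, rows = NULL) {
  stopifnot(inherits(fm, "feature_matrix"), threshold > 0, threshold <= 1)
  X <- fm$values
  if (!is.null(rows)) X <- X[rows, , drop = FALSE]
  if (nrow(X) < 2) {
    stop("correlation is undefined on fewer than 2 rows")
  }
  nm <- fm$meta$feature
  sds <- apply(X, 2, stats::sd)
  constant <- nm[sds == 0]
  if (length(constant)) {
    warning(length(constant), " constant column(s) dropped before merging: ",
            paste(utils::head(constant, 5), collapse = ", "),
            if (length(constant) > 5) ", ...")
  }
  keep0 <- which(sds > 0)
  C <- abs(stats::cor(X[, keep0, drop = FALSE]))
  adj <- C > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  kept_idx <- integer(0)
  dropped <- character(0)
  groups <- list()
  for (cid in seq_len(max(comp))) {
    mem <- keep0[comp == cid] # original column indices, ascending
    rep_i <- mem[1] # lowest canonical column index is the representative
    kept_idx <- c(kept_idx, rep_i)
    if (length(mem) > 1) {
      d <- setNames(rep(nm[rep_i], length(mem) - 1), nm[mem[-1]])
      dropped <- c(dropped, d)
      groups[[length(groups) + 1]] <- nm[mem]
    }
  }
  kept_idx <- sort(kept_idx)
  report <- structure(list(threshold = threshold,
                           kept = nm[kept_idx],
                           dropped = dropped,
                           groups = groups,
                           constant = constant),
                      class = "merge_report")
  list(fm = select_features(fm, kept_idx), report = report)
}

#' @export
print.merge_report <- function(x, ...) {
  cat("Feature merge (|r| > ", x$threshold, "): kept ", length(x$kept),
      ", dropped ", length(x$dropped), " into ", length(x$groups),
      " correlated group(s)",
      if (length(x$constant)) paste0("; ", length(x$constant),
                                     " constant column(s) removed"),
      "\n", sep = "")
  invisible(x)
}
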