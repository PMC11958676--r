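#' Feature matrix container
#'
#' The tabular interchange object of the pipeline: an epochs x features
#' numeric matrix plus per-column metadata (feature family, band, spatial
#' unit, hemisphere) and per-row metadata (subject, epoch index, group).
#'
#' @param values numeric matrix, epochs x features.
#' @param meta data.frame with one row per column of `values`; must contain
#'   columns `feature` (unique names), `family` (one of `band_power`,
#'   `entropy`, `aperiodic_offset`, `aperiodic_slope`, `source_power`,
#'   `coherence`), `band` (band name or `NA`), `unit` (channel, label or
#'   pair identifier) and `hemisphere`.
#' @param rows data.frame with one row per row of `values` (e.g.
#'   `subject_id`, `epoch`, `group`); defaults to epoch indices.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, meta,
                           rows = data.frame(epoch = seq_len(nrow(values)))) {
  values <- as.matrix(values)
  stopifnot(is.data.frame(meta),
            all(c("feature", "family", "band", "unit", "hemisphere")
                %in% names(meta)),
            nrow(meta) == ncol(values),
            nrow(rows) == nrow(values))
  if (anyDuplicated(meta$feature)) {
    stop("duplicate feature names: ",
         paste(unique(meta$feature[duplicated(meta$feature)]), collapse = ", "))
  }
  colnames(values) <- meta$feature
  structure(list(values = values, meta = meta, rows = rows),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  fam <- table(x$meta$family)
  cat("Feature matrix: ", nrow(x$values), " epochs x ", ncol(x$values),
      " features (", paste(names(fam), fam, sep = ":", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Select a subset of features
#'
#' @param fm a [feature_matrix()].
#' @param which feature names, column indices, or a logical vector.
#' @return a `feature_matrix` with the selected columns.
#' @export
select_features <- function(fm, which) {
  if (is.character(which)) which <- match(which, fm$meta$feature)
  if (anyNA(which)) stop("unknown feature names requested")
  feature_matrix(fm$values[, which, drop = FALSE],
                 fm$meta[which, , drop = FALSE], fm$rows)
}

#' Stack feature matrices from several subjects (same columns)
#'
#' @param ... `feature_matrix` objects with identical feature metadata.
#' @return the row-bound `feature_matrix`.
#' @export
stack_features <- function(...) {
  fms <- list(...)
  if (length(fms) == 1 && is.list(fms[[1]]) &&
      !inherits(fms[[1]], "feature_matrix")) {
    fms <- fms[[1]]
  }
  ref <- fms[[1]]
  for (fm in fms[-1]) {
    if (!identical(fm$meta$feature, ref$meta$feature)) {
      stop("feature matrices have different columns and cannot be stacked")
    }
  }
  feature_matrix(do.call(rbind, lapply(fms, `[[`, "values")), ref$meta,
                 do.call(rbind, lapply(fms, `[[`, "rows")))
}

#' Bind feature families computed on the same epochs (same rows)
#'
#' @param ... `feature_matrix` objects with identical row metadata.
#' @return the column-bound `feature_matrix`.
#' @export
bind_features <- function(...) {
  fms <- list(...)
  ref <- fms[[1]]
  for (fm in fms[-1]) {
    if (nrow(fm$values) != nrow(ref$values)) {
      stop("feature matrices have different numbers of epochs")
    }
  }
  meta_cols <- Reduce(intersect, lapply(fms, function(f) names(f$meta)))
  feature_matrix(do.call(cbind, lapply(fms, `[[`, "values")),
                 do.call(rbind, lapply(fms, function(f) f$meta[meta_cols])),
                 ref$rows)
}

# drop rows containing non-finite features, with a log message;
# returns fm with attribute "dropped_rows" recording what was removed
drop_bad_rows <- function(fm) {
  bad <- !apply(is.finite(fm$values), 1L, all)
  if (any(bad)) {
    message(sum(bad), " epoch(s) contained non-finite features and were ",
            "excluded")
    dropped <- fm$rows[bad, , drop = FALSE]
    fm <- feature_matrix(fm$values[!bad, , drop = FALSE], fm$meta,
                         fm$rows[!bad, , drop = FALSE])
    attr(fm, "dropped_rows") <- dropped
  }
  fm
}

#' Write a feature matrix as CSV plus a JSON metadata sidecar
#'
#' @param fm a [feature_matrix()].
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- cbind(fm$rows, as.data.frame(fm$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(features = fm$meta,
                            row_columns = names(fm$rows)),
                       paste0(path, ".meta.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path with an adjacent `<path>.meta.json` sidecar.
#' @return a [feature_matrix()].
#' @export
read_feature_matrix <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- as.data.frame(side$features)
  feature_matrix(as.matrix(df[, meta$feature, drop = FALSE]), meta,
                 df[, side$row_columns, drop = FALSE])
}
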