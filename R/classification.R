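#' Train/test split specification
#'
#' @param train_fraction fraction of epochs (or subjects) in the training
#'   set.
#' @param mode `"epoch_level"` splits 2-s epochs at random, so one subject
#'   can contribute epochs to both sides (replicates the original design
#'   but leaks subject identity into the test set — flagged in every
#'   report); `"subject_level"` keeps each subject's epochs together.
#' @param cv_folds folds for cross-validation on the training set.
#' @param seed seed controlling shuffling, the split, fold assignment and
#'   stochastic classifiers.
#' @return list of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.7,
                       mode = c("epoch_level", "subject_level"),
                       cv_folds = 10L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(train_fraction > 0, train_fraction < 1, cv_folds >= 2)
  structure(list(train_fraction = train_fraction, mode = mode,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "split_spec")
}

#' Binarize BATS outcome scores
#'
#' On the Regensburg scale (post-stimulation loudness 0-100%) a subject is
#' +BATS iff score <= threshold; on the Zurich scale (0 ... -5) iff
#' score <= threshold (default -1). The threshold itself counts as +BATS
#' (boundary inclusive on the suppression side). When `rows` is supplied,
#' every epoch inherits its subject's label.
#'
#' @param outcomes a `subject_outcomes` data.frame (see
#'   [assign_outcomes()]): columns `subject_id`, `scale`, `score`.
#' @param threshold binarization threshold; default 90 (Regensburg) or -1
#'   (Zurich).
#' @param rows optional data.frame with a `subject_id` column (e.g.
#'   `fm$rows`); labels are then expanded to one per row.
#' @return factor with levels `neg`, `pos` — per subject (named), or per
#'   row of `rows`.
#' @export
binarize_outcome <- function(outcomes, threshold = NULL, rows = NULL) {
  scales <- unique(outcomes$scale)
  if (length(scales) != 1) {
    stop("outcomes mix scales (", paste(scales, collapse = ", "),
         "); binarization needs a single scale")
  }
  if (is.null(threshold)) {
    threshold <- if (scales == "regensburg_0_100") 90 else -1
  }
  lab <- factor(ifelse(outcomes$score <= threshold, "pos", "neg"),
                levels = c("neg", "pos"))
  names(lab) <- outcomes$subject_id
  if (is.null(rows)) return(lab)
  idx <- match(rows$subject_id, outcomes$subject_id)
  if (anyNA(idx)) {
    stop("rows reference subjects absent from outcomes: ",
         paste(unique(rows$subject_id[is.na(idx)]), collapse = ", "))
  }
  lab[idx]
}

#' Confusion counts with +BATS as the positive class
#'
#' @param truth,pred factors with levels `neg`, `pos`.
#' @return list of class `confusion_counts`: `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_counts <- function(truth, pred) {
  structure(list(tp = sum(truth == "pos" & pred == "pos"),
                 fn = sum(truth == "pos" & pred == "neg"),
                 fp = sum(truth == "neg" & pred == "pos"),
                 tn = sum(truth == "neg" & pred == "neg")),
            class = "confusion_counts")
}

#' Threat-score accuracy (TP / (TP + FN + FP))
#'
#' The study's accuracy statistic: the count of correctly classified +BATS
#' epochs divided by everything except the true negatives. This is the
#' Jaccard index (threat score) of the +BATS class, not standard accuracy;
#' it is never larger than standard accuracy when true negatives exist, and
#' both are reported side by side throughout the pipeline.
#'
#' @param counts a [confusion_counts()] object.
#' @return value in `[0, 1]`, or `NA` (with a warning) when
#'   `tp + fn + fp = 0`.
#' @examples
#' eq1_accuracy(structure(list(tp = 3, fn = 1, fp = 1, tn = 0),
#'                        class = "confusion_counts")) # 0.6
#' @export
eq1_accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  den <- counts$tp + counts$fn + counts$fp
  if (den == 0) {
    warning("tp + fn + fp = 0; threat-score accuracy undefined")
    return(NA_real_)
  }
  counts$tp / den
}

#' Standard accuracy ((TP + TN) / all)
#'
#' @param counts a [confusion_counts()] object.
#' @return value in `[0, 1]`.
#' @export
standard_accuracy <- function(counts) {
  with(counts, (tp + tn) / (tp + fn + fp + tn))
}

# deterministic train/test split of row indices
make_split <- function(rows, labels, split) {
  n <- nrow(rows)
  set.seed(split$seed)
  if (split$mode == "epoch_level") {
    perm <- sample.int(n)
    n_train <- floor(split$train_fraction * n)
    list(train = sort(perm[seq_len(n_train)]),
         test = sort(perm[-seq_len(n_train)]))
  } else {
    subs <- unique(rows$subject_id)
    perm <- sample(subs)
    n_train <- max(1, floor(split$train_fraction * length(subs)))
    tr_subs <- perm[seq_len(n_train)]
    list(train = which(rows$subject_id %in% tr_subs),
         test = which(!rows$subject_id %in% tr_subs))
  }
}

# stratified fold assignment for the training rows
make_folds <- function(y, k, seed) {
  set.seed(seed + 1L)
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fit_predict_one <- function(def, X_tr, y_tr, X_te, seed) {
  if (isTRUE(def$standardize)) {
    st <- std_fit(X_tr)
    X_tr <- std_apply(st, X_tr)
    X_te <- std_apply(st, X_te)
  }
  model <- def$fit(X_tr, y_tr, seed)
  list(model = model, pred = def$predict(model, X_te))
}

#' Benchmark the classifier suite on a feature matrix
#'
#' Shuffles the epochs with the split seed, performs the 70/30 train/test
#' split, runs stratified k-fold cross-validation on the training set only,
#' then fits each classifier on the full training set and evaluates it on
#' the held-out test set, reporting the threat-score accuracy
#' ([eq1_accuracy()]) alongside standard accuracy. Classifiers that error
#' on the given data (e.g. QDA on rank-deficient features) are reported as
#' failed rather than aborting the run. Folds missing a class are skipped
#' with a message.
#'
#' @param fm a [feature_matrix()].
#' @param labels factor (levels `neg`, `pos`), one per row of `fm` — see
#'   [binarize_outcome()].
#' @param split a [split_spec()].
#' @param suite classifier ids to run (see [classifier_suite()]).
#' @param threshold optional annotation: the outcome threshold behind
#'   `labels`, echoed into each result.
#' @param cv run the cross-validation stage; `FALSE` skips it (test-set
#'   evaluation only), useful in repeated-simulation studies.
#' @return object of class `classification_suite`: list of per-classifier
#'   results (`classifier`, `eq1_accuracy`, `standard_accuracy`,
#'   `cv_scores`, `confusion`, `n_features`, `error`), plus the split
#'   bookkeeping.
#' @export
run_suite <- function(fm, labels, split = split_spec(),
                      suite = names(classifier_defs()), threshold = NA,
                      cv = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"))
  labels <- factor(labels, levels = c("neg", "pos"))
  stopifnot(length(labels) == nrow(fm$values))
  defs <- classifier_defs()
  unknown <- setdiff(suite, names(defs))
  if (length(unknown)) stop("unknown classifier id(s): ",
                            paste(unknown, collapse = ", "))
  sp <- make_split(fm$rows, labels, split)
  y_tr <- labels[sp$train]; y_te <- labels[sp$test]
  if (nlevels(droplevels(y_tr)) < 2 || nlevels(droplevels(y_te)) < 2) {
    stop("train or test set contains a single class; adjust the split or ",
         "threshold")
  }
  X_tr <- fm$values[sp$train, , drop = FALSE]
  X_te <- fm$values[sp$test, , drop = FALSE]
  fold <- make_folds(y_tr, split$cv_folds, split$seed)
  results <- list()
  for (id in suite) {
    def <- defs[[id]]
    res <- tryCatch({
      cv_scores <- rep(NA_real_, split$cv_folds)
      for (k in if (cv) seq_len(split$cv_folds) else integer(0)) {
        tr <- fold != k; va <- fold == k
        if (nlevels(droplevels(y_tr[tr])) < 2 || !any(va)) {
          message("fold ", k, " skipped for ", id,
                  " (missing class or empty fold)")
          next
        }
        fp <- fit_predict_one(def, X_tr[tr, , drop = FALSE], y_tr[tr],
                              X_tr[va, , drop = FALSE],
                              seed = split$seed + k)
        cv_scores[k] <- mean(fp$pred == y_tr[va])
      }
      fp <- fit_predict_one(def, X_tr, y_tr, X_te, seed = split$seed)
      cc <- confusion_counts(y_te, fp$pred)
      list(classifier = id, label = def$label, threshold = threshold,
           eq1_accuracy = eq1_accuracy(cc),
           standard_accuracy = standard_accuracy(cc),
           cv_scores = cv_scores, confusion = cc,
           n_features = ncol(fm$values), error = NA_character_)
    }, error = function(e) {
      list(classifier = id, label = def$label, threshold = threshold,
           eq1_accuracy = NA_real_, standard_accuracy = NA_real_,
           cv_scores = rep(NA_real_, split$cv_folds), confusion = NULL,
           n_features = ncol(fm$values), error = conditionMessage(e))
    })
    results[[id]] <- res
  }
  structure(list(results = results, split = split,
                 train_idx = sp$train, test_idx = sp$test,
                 n_train = length(sp$train), n_test = length(sp$test),
                 leakage_note = if (split$mode == "epoch_level")
                   paste("epoch-level split: epochs from one subject can",
                         "appear in both train and test")
                 else "subject-level split"),
            class = "classification_suite")
}

#' @export
print.classification_suite <- function(x, ...) {
  cat("Classifier suite (", x$n_train, " train / ", x$n_test,
      " test epochs; ", x$leakage_note, ")\n", sep = "")
  df <- summary(x)
  print(df, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.classification_suite <- function(object, ...) {
  do.call(rbind, lapply(object$results, function(r) {
    data.frame(classifier = r$classifier,
               eq1_accuracy = r$eq1_accuracy,
               standard_accuracy = r$standard_accuracy,
               cv_mean = mean(r$cv_scores, na.rm = TRUE),
               failed = !is.na(r$error))
  }))
}

#' Sweep the outcome binarization threshold
#'
#' Re-binarizes the outcomes at each threshold and re-runs the classifier
#' suite, producing one result per (threshold, classifier) — the data
#' behind a radial accuracy summary. Thresholds yielding a single class
#' are marked degenerate instead of erroring.
#'
#' @param fm a [feature_matrix()].
#' @param outcomes a `subject_outcomes` data.frame.
#' @param thresholds outcome thresholds to sweep (Regensburg scale).
#' @param split a [split_spec()].
#' @param suite classifier ids.
#' @return data.frame: `threshold`, `classifier`, `eq1_accuracy`,
#'   `standard_accuracy`, `degenerate`.
#' @export
threshold_sweep <- function(fm, outcomes, thresholds = c(90, 80, 70, 60, 50),
                            split = split_spec(),
                            suite = names(classifier_defs())) {
  out <- list()
  for (thr in thresholds) {
    labels <- binarize_outcome(outcomes, thr, rows = fm$rows)
    if (nlevels(droplevels(labels)) < 2) {
      out[[length(out) + 1]] <- data.frame(
        threshold = thr, classifier = suite, eq1_accuracy = NA_real_,
        standard_accuracy = NA_real_, degenerate = TRUE)
      next
    }
    rs <- run_suite(fm, labels, split, suite, threshold = thr)
    out[[length(out) + 1]] <- cbind(summary(rs)[
      c("classifier", "eq1_accuracy", "standard_accuracy")],
      threshold = thr, degenerate = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df[c("threshold", "classifier", "eq1_accuracy", "standard_accuracy",
       "degenerate")]
}

#' Shuffled-label control run
#'
#' Permutes the epoch labels (so each class is an even mixture of true and
#' false labels), then re-runs the full pipeline on the permuted labels.
#' Test accuracy near chance validates that the unshuffled accuracy
#' reflects real label structure rather than pipeline leakage.
#'
#' @param fm a [feature_matrix()].
#' @param labels true epoch labels.
#' @param split a [split_spec()].
#' @param perm_seed seed for the permutation.
#' @param permutation optional explicit permutation of `seq_along(labels)`
#'   (the identity permutation reproduces the unshuffled run).
#' @param suite classifier ids (default random forest only).
#' @param cv run the cross-validation stage (see [run_suite()]).
#' @return a `classification_suite`.
#' @export
shuffled_label_control <- function(fm, labels, split = split_spec(),
                                   perm_seed = split$seed,
                                   permutation = NULL, suite = "rf",
                                   cv = TRUE) {
  labels <- factor(labels, levels = c("neg", "pos"))
  if (is.null(permutation)) {
    set.seed(perm_seed + 2L)
    permutation <- sample.int(length(labels))
  }
  stopifnot(length(permutation) == length(labels))
  run_suite(fm, labels[permutation], split, suite, cv = cv)
}

#' Retrain on the top-k most important features
#'
#' Fits a random forest on the training split, ranks all features by its
#' impurity (Gini) importance, restricts the feature matrix to the top `k`,
#' refits and re-evaluates on the identical split.
#'
#' @param fm a [feature_matrix()].
#' @param labels epoch labels.
#' @param split a [split_spec()].
#' @param k number of features to keep (clamped to the number of columns,
#'   with a warning).
#' @param suite classifier ids for the retrained model.
#' @return list: `suite` (a `classification_suite` on the reduced
#'   features), `selected` (feature names in rank order), `importance`
#'   (named numeric, full ranking).
#' @export
top_k_retrain <- function(fm, labels, split = split_spec(), k = 100,
                          suite = "rf") {
  labels <- factor(labels, levels = c("neg", "pos"))
  if (k > ncol(fm$values)) {
    warning("k = ", k, " exceeds ", ncol(fm$values),
            " features; clamping")
    k <- ncol(fm$values)
  }
  sp <- make_split(fm$rows, labels, split)
  rf <- ranger::ranger(x = fm$values[sp$train, , drop = FALSE],
                       y = labels[sp$train], num.trees = 200,
                       probability = TRUE, importance = "impurity",
                       seed = split$seed, num.threads = 1)
  imp <- sort(rf$variable.importance, decreasing = TRUE)
  selected <- names(imp)[seq_len(k)]
  reduced <- select_features(fm, selected)
  list(suite = run_suite(reduced, labels, split, suite),
       selected = selected, importance = imp)
}
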