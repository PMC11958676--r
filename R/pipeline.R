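#' Extract all feature families from a synthetic cohort
#'
#' Simulates each subject in turn (independent per-subject random streams)
#' and immediately reduces the signals to per-epoch features, so large
#' cohorts never hold raw signals for more than one subject at a time.
#'
#' @param config a [cohort_config()].
#' @param families subset of `c("sensor", "source", "connectivity")`.
#' @param map network map for connectivity features; defaults to
#'   [default_network_map()] for the 68-label atlas, otherwise a toy map
#'   splitting the labels between an auditory and a default-mode set.
#' @param scheme a [band_scheme()].
#' @param psd a [psd_settings()] object.
#' @param coh_bands bands for connectivity features.
#' @return list: `sensor`, `source`, `connectivity` (stacked
#'   [feature_matrix()] objects, those requested), `outcomes`, `config`.
#' @export
cohort_features <- function(config,
                            families = c("sensor", "source"),
                            map = NULL, scheme = band_scheme(),
                            psd = psd_settings(),
                            coh_bands = c("alpha", "gamma")) {
  families <- match.arg(families,
                        c("sensor", "source", "connectivity"),
                        several.ok = TRUE)
  if ("connectivity" %in% families && is.null(map)) {
    map <- if (config$n_labels == 68) default_network_map()
           else toy_network_map(config$label_names)
  }
  mixing <- default_mixing(config$n_channels, config$n_labels,
                           seed = config$seed)
  groups <- rep(c("pos", "neg"), times = config$n_subjects_per_group)
  ids <- sprintf("S%03d", seq_along(groups))
  set.seed(subject_seed(config$seed, 0L))
  outcomes <- assign_outcomes(config, groups, ids)
  sens <- src <- coh <- list()
  for (i in seq_along(groups)) {
    lts <- simulate_label_signals(config, groups[i], ids[i],
                                  subject_index = i)
    if ("sensor" %in% families) {
      es <- project_to_sensors(lts, mixing,
                               channel_names = config$channel_names,
                               sensor_noise_sd = config$sensor_noise_sd)
      sens[[ids[i]]] <- assemble_sensor_features(es, scheme, psd)
    }
    if ("source" %in% families) {
      src[[ids[i]]] <- label_band_power(lts, scheme, psd)
    }
    if ("connectivity" %in% families) {
      coh[[ids[i]]] <- network_coherence(lts, map, bands = coh_bands,
                                         scheme = scheme, settings = psd)
    }
  }
  list(sensor = if (length(sens)) stack_features(sens),
       source = if (length(src)) stack_features(src),
       connectivity = if (length(coh)) stack_features(coh),
       outcomes = outcomes, config = config)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages in their canonical order — simulate, extract
#' features, merge correlated features, split/cross-validate/test the
#' classifier suite, run the shuffled-label control, retrain on the top-k
#' features, and explain the forest — and collects a structured run
#' manifest (config echo, seeds, feature counts before/after merging,
#' split sizes, per-stage runtimes, package version). The manifest is
#' returned, and persisted when `out_dir` is given, even if a stage fails;
#' completed stages keep their outputs.
#'
#' @param config a [cohort_config()].
#' @param families feature families to compute (see [cohort_features()]).
#' @param suite classifier ids for the benchmark stage.
#' @param split a [split_spec()]; defaults to the config's master seed.
#' @param top_k features kept in the retraining stage.
#' @param out_dir optional directory for artifacts (feature CSVs, merge
#'   report, manifest JSON).
#' @return list of class `bats_run`: `manifest`, `features` (post-merge),
#'   `merge_reports`, `labels`, `suite_result`, `shuffled_result`,
#'   `top_k_result`, `importance`, `contributions`, `class_importance`.
#' @export
run_pipeline <- function(config, families = c("sensor", "source"),
                         suite = "rf",
                         split = split_spec(seed = config$seed),
                         top_k = 100, out_dir = NULL) {
  manifest <- list(package_version =
                     as.character(utils::packageVersion("batseeg")),
                   seed = config$seed,
                   config = config[c("n_subjects_per_group",
                                     "n_epochs_per_subject",
                                     "epoch_duration", "sampling_rate",
                                     "n_channels", "n_labels",
                                     "outcome_scale", "outcome_threshold",
                                     "seed")],
                   split = unclass(split),
                   stages = list(), feature_counts = list(),
                   failed_stage = NULL)
  out <- list()
  t_all <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- expr()
    manifest$stages[[name]] <<-
      round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  finish <- function() {
    manifest$total_seconds <<- round(proc.time()[["elapsed"]] - t_all, 3)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    }
  }
  result <- tryCatch({
    feats <- stage("features", function()
      cohort_features(config, families = families))
    labels_by_fam <- list()
    merged <- list()
    reports <- list()
    for (fam in families) {
      fm <- feats[[fam]]
      manifest$feature_counts[[fam]] <-
        list(pre_merge = ncol(fm$values))
      mg <- stage(paste0("merge_", fam), function()
        merge_correlated(fm, threshold = 0.9))
      merged[[fam]] <- mg$fm
      reports[[fam]] <- mg$report
      manifest$feature_counts[[fam]]$post_merge <- ncol(mg$fm$values)
      labels_by_fam[[fam]] <-
        binarize_outcome(feats$outcomes, config$outcome_threshold,
                         rows = mg$fm$rows)
    }
    primary <- families[1]
    fm <- merged[[primary]]
    labels <- labels_by_fam[[primary]]
    suite_result <- stage("classify", function()
      run_suite(fm, labels, split, suite,
                threshold = config$outcome_threshold))
    manifest$split_sizes <- list(train = suite_result$n_train,
                                 test = suite_result$n_test)
    shuffled_result <- stage("shuffled_control", function()
      shuffled_label_control(fm, labels, split))
    top_k_result <- stage("top_k_retrain", function()
      top_k_retrain(fm, labels, split, k = min(top_k, ncol(fm$values))))
    expl <- stage("explain", function() {
      sp <- make_split(fm$rows, labels, split)
      X_tr <- fm$values[sp$train, , drop = FALSE]
      rf <- ranger::ranger(x = X_tr, y = labels[sp$train], num.trees = 200,
                           probability = TRUE, seed = split$seed,
                           num.threads = 1)
      ens <- as_tree_ensemble(rf, X_tr)
      sc <- signed_contributions(ens, fm$values[sp$test, , drop = FALSE])
      gi <- gini_importance(rf, X_tr, labels[sp$train])
      pred <- factor(ifelse(sc$prediction >= 0.5, "pos", "neg"),
                     levels = c("neg", "pos"))
      list(importance = gi,
           contributions = sc,
           class_importance = class_aggregate(
             sc, fm$meta, predicted = pred))
    })
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (fam in families) {
        write_feature_matrix(merged[[fam]],
                             file.path(out_dir, paste0(fam, "_features.csv")))
      }
      jsonlite::write_json(
        lapply(reports, function(r) list(threshold = r$threshold,
                                         kept = r$kept,
                                         dropped = as.list(r$dropped))),
        file.path(out_dir, "merge_reports.json"),
        auto_unbox = TRUE, digits = NA)
      manifest$artifacts <- list.files(out_dir)
    }
    list(features = merged, merge_reports = reports, labels = labels,
         outcomes = feats$outcomes,
         suite_result = suite_result, shuffled_result = shuffled_result,
         top_k_result = top_k_result, importance = expl$importance,
         contributions = expl$contributions,
         class_importance = expl$class_importance)
  }, error = function(e) {
    manifest$failed_stage <<- conditionMessage(e)
    list(error = conditionMessage(e))
  })
  finish()
  structure(c(list(manifest = manifest), result), class = "bats_run")
}

#' @export
print.bats_run <- function(x, ...) {
  cat("BATS pipeline run (seed ", x$manifest$seed, ")\n", sep = "")
  for (fam in names(x$manifest$feature_counts)) {
    fc <- x$manifest$feature_counts[[fam]]
    cat("  ", fam, " features: ", fc$pre_merge, " -> ", fc$post_merge,
        " after merging\n", sep = "")
  }
  if (!is.null(x$manifest$failed_stage)) {
    cat("  FAILED: ", x$manifest$failed_stage, "\n", sep = "")
  } else if (!is.null(x$suite_result)) {
    print(x$suite_result)
  }
  invisible(x)
}

# per-band label importance from a source feature matrix:
# merge, fit a forest, sum impurity importance per (band, label)
top_band_labels <- function(fm, labels, bands, k = 10, threshold = 0.9,
                            seed = 1L) {
  mg <- merge_correlated(fm, threshold = threshold)
  rf <- ranger::ranger(x = mg$fm$values, y = labels, num.trees = 300,
                       probability = TRUE, importance = "impurity",
                       seed = seed, num.threads = 1)
  imp <- rf$variable.importance
  meta <- mg$fm$meta
  out <- list(merge = mg$report)
  for (b in bands) {
    sel <- which(meta$band == b)
    lab_imp <- tapply(imp[sel], meta$unit[sel], sum)
    out[[b]] <- names(sort(lab_imp, decreasing = TRUE))[
      seq_len(min(k, length(lab_imp)))]
  }
  out
}

#' Cross-cohort validation of important source labels
#'
#' Processes a main and a validation source-feature cohort identically
#' (merge at the same threshold, fit a forest, rank labels by summed
#' impurity importance per band) and reports, per band, how many of the
#' main cohort's top-k labels reappear in the validation cohort's top-k.
#' A label that the validation cohort dropped during feature merging
#' counts as present when its recorded merge representative's label is in
#' the validation top-k (dropped-by-collinearity is agreement, not
#' disagreement).
#'
#' @param fm_main,fm_valid source-band-power [feature_matrix()] objects
#'   from the two cohorts; must share an identical label set (atlas
#'   mismatch is rejected).
#' @param labels_main,labels_valid epoch labels per cohort.
#' @param bands bands to compare.
#' @param k size of the top-label list.
#' @param threshold merge threshold applied to both cohorts.
#' @param seed forest seed.
#' @return list of class `label_overlap_report`: per band `overlap`
#'   (count), `top_main`, `top_valid`, plus `k`.
#' @export
validate_external_cohort <- function(fm_main, labels_main,
                                     fm_valid, labels_valid,
                                     bands = c("alpha", "gamma"), k = 10,
                                     threshold = 0.9, seed = 1L) {
  units_main <- sort(unique(fm_main$meta$unit))
  units_valid <- sort(unique(fm_valid$meta$unit))
  if (!identical(units_main, units_valid)) {
    stop("label atlases differ between cohorts; top-label overlap is ",
         "undefined")
  }
  tm <- top_band_labels(fm_main, labels_main, bands, k, threshold, seed)
  tv <- top_band_labels(fm_valid, labels_valid, bands, k, threshold, seed)
  # representative label of features dropped in the validation merge
  rep_of <- tv$merge$dropped
  feat_label <- setNames(fm_valid$meta$unit, fm_valid$meta$feature)
  feat_band <- setNames(fm_valid$meta$band, fm_valid$meta$feature)
  out <- list(k = k)
  for (b in bands) {
    present <- tm[[b]] %in% tv[[b]]
    # dropped-label accounting: find the validation features of this band
    # whose label is the candidate, follow the merge mapping
    for (i in which(!present)) {
      cand <- tm[[b]][i]
      dropped_feats <- names(rep_of)[feat_label[names(rep_of)] == cand &
                                     feat_band[names(rep_of)] == b]
      reps <- unique(feat_label[unname(rep_of[dropped_feats])])
      if (length(reps) && any(reps %in% tv[[b]])) present[i] <- TRUE
    }
    out[[b]] <- list(overlap = sum(present), top_main = tm[[b]],
                     top_valid = tv[[b]])
  }
  structure(out, class = "label_overlap_report")
}

#' @export
print.label_overlap_report <- function(x, ...) {
  bands <- setdiff(names(x), "k")
  cat("Top-", x$k, " important-label overlap per band:\n", sep = "")
  for (b in bands) {
    cat("  ", b, ": ", x[[b]]$overlap, "/", x$k, "\n", sep = "")
  }
  invisible(x)
}

#' Write a cohort to a plain-text fixture directory
#'
#' One CSV per subject and signal level (label time courses flattened to
#' `(epochs * samples) x labels`, sensors likewise) plus a JSON manifest
#' with dimensions, outcomes and a config echo.
#'
#' @param cohort an `eeg_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config
  manifest <- list(
    subjects = cohort$outcomes$subject_id,
    outcomes = cohort$outcomes,
    config = cfg[c("n_subjects_per_group", "n_epochs_per_subject",
                   "epoch_duration", "sampling_rate", "n_channels",
                   "n_labels", "outcome_scale", "outcome_threshold",
                   "seed")],
    label_names = cfg$label_names,
    channel_names = cfg$channel_names)
  flatten <- function(arr) {
    d <- dim(arr) # epochs x units x samples
    matrix(aperm(arr, c(3, 1, 2)), nrow = d[1] * d[3], ncol = d[2])
  }
  for (sid in cohort$outcomes$subject_id) {
    if (!is.null(cohort$label_ts[[sid]])) {
      m <- flatten(cohort$label_ts[[sid]]$data)
      colnames(m) <- cfg$label_names
      utils::write.csv(m, file.path(dir, paste0(sid, "_labels.csv")),
                       row.names = FALSE)
    }
    if (!is.null(cohort$sensor[[sid]])) {
      m <- flatten(cohort$sensor[[sid]]$data)
      colnames(m) <- cfg$channel_names
      utils::write.csv(m, file.path(dir, paste0(sid, "_sensors.csv")),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Read a cohort fixture directory written by [write_cohort()]
#'
#' @param dir fixture directory.
#' @return an `eeg_cohort` (without a mixing matrix).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "cohort.json"),
                                  simplifyVector = TRUE)
  cfg <- manifest$config
  E <- cfg$n_epochs_per_subject
  n <- as.integer(round(cfg$epoch_duration * cfg$sampling_rate))
  unflatten <- function(m) {
    aperm(array(as.matrix(m), dim = c(n, E, ncol(m))), c(2, 3, 1))
  }
  outcomes <- manifest$outcomes
  class(outcomes) <- c("subject_outcomes", "data.frame")
  label_ts <- list()
  sensor <- list()
  for (i in seq_along(manifest$subjects)) {
    sid <- manifest$subjects[i]
    grp <- outcomes$true_group[i]
    lf <- file.path(dir, paste0(sid, "_labels.csv"))
    sf <- file.path(dir, paste0(sid, "_sensors.csv"))
    if (file.exists(lf)) {
      label_ts[[sid]] <- structure(
        list(subject_id = sid, data = unflatten(utils::read.csv(lf)),
             label_names = manifest$label_names,
             sampling_rate = cfg$sampling_rate, group = grp),
        class = "label_time_series")
    }
    if (file.exists(sf)) {
      sensor[[sid]] <- structure(
        list(subject_id = sid, data = unflatten(utils::read.csv(sf)),
             channel_names = manifest$channel_names,
             sampling_rate = cfg$sampling_rate, group = grp),
        class = "epoch_set")
    }
  }
  structure(list(config = manifest$config, outcomes = outcomes,
                 mixing = NULL,
                 label_ts = if (length(label_ts)) label_ts,
                 sensor = if (length(sensor)) sensor),
            class = "eeg_cohort")
}
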