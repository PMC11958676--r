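# Classifier registry: ten widely used model families behind one uniform
# fit/predict contract. Each entry has
#   fit(X, y, seed) -> model      (X numeric matrix, y factor neg/pos)
#   predict(model, X) -> factor with the same levels
# All hyperparameters are the frozen defaults listed here, so runs are
# reproducible across library versions; no tuning is performed anywhere.

# standardize by train statistics (for scale-sensitive models)
std_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}
std_apply <- function(st, X) sweep(sweep(X, 2, st$mu, "-"), 2, st$sd, "/")

classifier_defs <- function() {
  lv <- c("neg", "pos")
  as_class <- function(p) factor(ifelse(p >= 0.5, "pos", "neg"), levels = lv)
  list(
    rf = list(
      label = "Random Forest",
      fit = function(X, y, seed) {
        ranger::ranger(x = X, y = y, num.trees = 200, probability = TRUE,
                       seed = seed, num.threads = 1)
      },
      predict = function(m, X) {
        as_class(stats::predict(m, X, num.threads = 1)$predictions[, "pos"])
      }),
    gboost = list(
      label = "Gradient Boosting",
      fit = function(X, y, seed) {
        set.seed(seed)
        dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y == "pos"))
        xgboost::xgb.train(params = list(objective = "binary:logistic",
                                         max_depth = 3, eta = 0.1,
                                         nthread = 1),
                           data = dtrain, nrounds = 100, verbose = 0)
      },
      predict = function(m, X) {
        as_class(stats::predict(m, xgboost::xgb.DMatrix(X)))
      }),
    qda = list(
      label = "Quadratic Discriminant Analysis",
      fit = function(X, y, seed) MASS::qda(X, grouping = y),
      predict = function(m, X) {
        factor(as.character(stats::predict(m, X)$class), levels = lv)
      }),
    nbayes = list(
      label = "Gaussian Naive Bayes",
      fit = function(X, y, seed) e1071::naiveBayes(X, y),
      predict = function(m, X) {
        factor(as.character(stats::predict(m, X)), levels = lv)
      }),
    dtree = list(
      label = "Decision Tree",
      fit = function(X, y, seed) {
        set.seed(seed)
        df <- data.frame(X, check.names = FALSE)
        df$.y <- y
        rpart::rpart(.y ~ ., df, method = "class")
      },
      predict = function(m, X) {
        p <- stats::predict(m, data.frame(X, check.names = FALSE),
                            type = "class")
        factor(as.character(p), levels = lv)
      }),
    svm_rbf = list(
      label = "RBF-kernel SVM",
      fit = function(X, y, seed) e1071::svm(X, y, kernel = "radial",
                                            scale = FALSE),
      predict = function(m, X) {
        factor(as.character(stats::predict(m, X)), levels = lv)
      },
      standardize = TRUE),
    svm_linear = list(
      label = "Linear SVM",
      fit = function(X, y, seed) e1071::svm(X, y, kernel = "linear",
                                            scale = FALSE),
      predict = function(m, X) {
        factor(as.character(stats::predict(m, X)), levels = lv)
      },
      standardize = TRUE),
    gproc = list(
      label = "Gaussian Process",
      fit = function(X, y, seed) {
        set.seed(seed)
        kernlab::gausspr(x = X, y = y, kernel = "rbfdot")
      },
      predict = function(m, X) {
        factor(as.character(kernlab::predict(m, X)), levels = lv)
      },
      standardize = TRUE),
    knn = list(
      label = "k-Nearest Neighbours",
      fit = function(X, y, seed) list(X = X, y = y, k = 5L), # lazy learner
      predict = function(m, X) {
        factor(as.character(class::knn(m$X, X, m$y, k = m$k)), levels = lv)
      },
      standardize = TRUE),
    net = list(
      label = "Feed-forward Net",
      fit = function(X, y, seed) {
        set.seed(seed)
        nnet::nnet(X, cbind(neg = y == "neg", pos = y == "pos"),
                   size = 8, decay = 1e-3, maxit = 200, trace = FALSE,
                   MaxNWts = 200000, softmax = TRUE)
      },
      predict = function(m, X) as_class(stats::predict(m, X)[, "pos"]),
      standardize = TRUE)
  )
}

#' The classifier suite
#'
#' Identifiers of the ten model families benchmarked by [run_suite()]:
#' random forest (`rf`), gradient boosting (`gboost`), quadratic
#' discriminant analysis (`qda`), Gaussian naive Bayes (`nbayes`),
#' decision tree (`dtree`), RBF-kernel and linear SVM (`svm_rbf`,
#' `svm_linear`), Gaussian process (`gproc`), k-nearest neighbours
#' (`knn`) and a small fixed-architecture feed-forward net (`net`).
#' All are run with frozen default parameters; there is no tuning.
#'
#' @return named character vector, id -> human-readable label.
#' @export
classifier_suite <- function() {
  defs <- classifier_defs()
  vapply(defs, `[[`, character(1), "label")
}
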