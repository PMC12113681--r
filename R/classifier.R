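#' Train a potency classifier on binary fingerprints
#'
#' Wraps four interchangeable backends behind one interface: gradient-boosted
#' trees (`"gbt"`, xgboost), random forest (`"rf"`), a radial-kernel support
#' vector machine (`"svm"`) and k-nearest neighbours (`"knn"`). The default
#' gradient-boosting hyperparameters are the grid optimum used for the
#' screening model (`max_depth = 9`, 100 boosting rounds, log-loss objective).
#' Training is reproducible: the same data, backend and seed give identical
#' predictions.
#'
#' @param x Binary feature matrix (rows = compounds, columns = fingerprint
#'   bits).
#' @param y Binary labels (0/1, logical, or two-level factor; the second
#'   level / 1 is the positive class).
#' @param backend One of `"gbt"`, `"rf"`, `"svm"`, `"knn"`.
#' @param hyperparams Named list overriding the backend defaults
#'   (gbt: `max_depth`, `nrounds`, `eta`; rf: `ntree`, `mtry`;
#'   svm: `cost`, `gamma`; knn: `k`).
#' @param seed Integer seed controlling every stochastic element of training.
#' @return An object of class `activity_classifier` exposing
#'   [predict_probability()].
#' @export
train_activity_classifier <- function(x, y,
                                      backend = c("gbt", "rf", "svm", "knn"),
                                      hyperparams = list(), seed = 1) {
  backend <- match.arg(backend)
  x <- as.matrix(x)
  y <- as_binary_labels(y)
  if (nrow(x) != length(y)) abort("`x` rows and `y` length must agree.")
  if (length(unique(y)) < 2) {
    abort("Training labels contain a single class; two classes are required.")
  }

  fit <- switch(
    backend,
    gbt = {
      hp <- modifyList(list(max_depth = 9, nrounds = 100, eta = 0.3), hyperparams)
      with_seed(seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic", eval_metric = "logloss",
                      max_depth = hp$max_depth, eta = hp$eta, nthread = 1),
        data = xgboost::xgb.DMatrix(x, label = y),
        nrounds = hp$nrounds, verbose = 0
      ))
    },
    rf = {
      hp <- modifyList(list(ntree = 500, mtry = max(1, floor(sqrt(ncol(x))))),
                       hyperparams)
      with_seed(seed, randomForest::randomForest(
        x = x, y = factor(y, levels = c(0, 1)),
        ntree = hp$ntree, mtry = hp$mtry
      ))
    },
    svm = {
      hp <- modifyList(list(cost = 1, gamma = 1 / ncol(x)), hyperparams)
      with_seed(seed, e1071::svm(
        x = x, y = factor(y, levels = c(0, 1)),
        kernel = "radial", cost = hp$cost, gamma = hp$gamma,
        probability = TRUE
      ))
    },
    knn = {
      hp <- modifyList(list(k = 5), hyperparams)
      list(train_x = x, train_y = y, k = hp$k)
    }
  )

  structure(
    list(backend = backend, fit = fit, seed = seed, n_features = ncol(x),
         n_train = nrow(x)),
    class = "activity_classifier"
  )
}

#' Predicted probability of the positive class
#'
#' @param model An `activity_classifier`.
#' @param x Feature matrix with the same number of columns as at training.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict_probability <- function(model, x) {
  stopifnot(inherits(model, "activity_classifier"))
  x <- as.matrix(x)
  if (ncol(x) != model$n_features) {
    abort("Feature count differs from the training matrix.")
  }
  switch(
    model$backend,
    gbt = as.numeric(predict(model$fit, xgboost::xgb.DMatrix(x))),
    rf = as.numeric(predict(model$fit, x, type = "prob")[, "1"]),
    svm = {
      pr <- predict(model$fit, x, probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "1"])
    },
    knn = with_seed(model$seed, {
      pred <- class::knn(model$fit$train_x, x,
                         cl = factor(model$fit$train_y, levels = c(0, 1)),
                         k = model$fit$k, prob = TRUE)
      vote <- attr(pred, "prob")
      ifelse(pred == "1", vote, 1 - vote)
    })
  )
}

#' @export
predict.activity_classifier <- function(object, newdata,
                                        type = c("prob", "class"),
                                        threshold = 0.5, ...) {
  type <- match.arg(type)
  p <- predict_probability(object, newdata)
  if (type == "prob") p else as.integer(p > threshold)
}

#' @export
print.activity_classifier <- function(x, ...) {
  cat(sprintf(
    "Activity classifier (backend = %s): %d training compounds, %d features\n",
    x$backend, x$n_train, x$n_features
  ))
  invisible(x)
}

#' @exportS3Method
glance.activity_classifier <- function(x, ...) {
  tibble::tibble(backend = x$backend, n_train = x$n_train,
                 n_features = x$n_features, seed = x$seed)
}

# Stratified fold assignment: each class is shuffled and dealt round-robin.
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Stratified k-fold cross-validation of a fingerprint classifier
#'
#' @inheritParams train_activity_classifier
#' @param k Number of folds (>= 2); every class must have at least `k`
#'   members.
#' @param threshold Probability threshold used to form per-fold confusion
#'   counts.
#' @return An object of class `cv_result` with per-fold metrics (`folds`),
#'   and summary fields `mean_accuracy`, `sd_accuracy`, `mean_auc`.
#' @export
cross_validate <- function(x, y, k = 5, seed = 1,
                           backend = c("gbt", "rf", "svm", "knn"),
                           hyperparams = list(), threshold = 0.5) {
  backend <- match.arg(backend)
  x <- as.matrix(x)
  y <- as_binary_labels(y)
  if (k < 2) abort("`k` must be at least 2.")
  if (min(table(y)) < k) {
    abort("Each class needs at least `k` members for stratified folds.")
  }
  fold <- stratified_folds(y, k, seed)
  folds <- purrr::map_dfr(seq_len(k), function(j) {
    test <- fold == j
    model <- train_activity_classifier(x[!test, , drop = FALSE], y[!test],
                                       backend = backend,
                                       hyperparams = hyperparams,
                                       seed = seed + j)
    p <- predict_probability(model, x[test, , drop = FALSE])
    m <- classification_metrics(confusion_from_probs(y[test], p, threshold))
    dplyr::mutate(m, fold = j, auc = roc_auc(y[test], p), .before = 1)
  })
  structure(
    list(
      folds = folds, k = k, backend = backend, seed = seed,
      mean_accuracy = mean(folds$accuracy), sd_accuracy = sd(folds$accuracy),
      mean_auc = mean(folds$auc)
    ),
    class = "cv_result"
  )
}

#' @exportS3Method
tidy.cv_result <- function(x, ...) x$folds

#' @exportS3Method
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    k = x$k, backend = x$backend,
    mean_accuracy = x$mean_accuracy, sd_accuracy = x$sd_accuracy,
    mean_auc = x$mean_auc
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV (%s): accuracy %.4f +/- %.4f, AUC %.4f\n",
    x$k, x$backend, x$mean_accuracy, x$sd_accuracy, x$mean_auc
  ))
  invisible(x)
}
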