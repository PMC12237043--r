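# Classifier registry. Every backend is wrapped so that it (a) fits on a
# numeric matrix X and 0/1 labels y, (b) supports inverse-frequency
# ("balanced") class weighting where the backend admits it, and (c) exposes
# positive-class probabilities through predict_prob(). The wrappers carry
# no acquisition logic; they are ordinary supervised fits.

classifier_names <- function() {
  c("logistic", "svm_linear", "svm_rbf", "decision_tree", "random_forest",
    "gradient_boosting", "naive_bayes", "mlp")
}

balanced_case_weights <- function(y) {
  tab <- table(factor(y, levels = c(0, 1)))
  w <- length(y) / (2 * pmax(as.numeric(tab), 1))
  names(w) <- c("0", "1")
  w[as.character(y)]
}

#' Train a probabilistic classifier from the backend registry
#'
#' Fits one of the registered classifiers on a numeric feature matrix with
#' 0/1 labels. Available backends: `"logistic"` (binomial GLM),
#' `"svm_linear"` / `"svm_rbf"` (probability-calibrated SVM),
#' `"decision_tree"` (CART), `"random_forest"`, `"gradient_boosting"`
#' (xgboost), `"naive_bayes"`, `"mlp"` (single-hidden-layer network).
#' With `class_weight = "balanced"` classes are weighted inversely to their
#' frequency, which matters at the low prevalences this package targets.
#'
#' @param classifier Backend name (see above).
#' @param X Numeric matrix, rows = samples.
#' @param y 0/1 label vector; both classes must be present.
#' @param class_weight `"balanced"` (default) or `"none"`.
#' @param params Named list of backend hyperparameters (e.g. `cost` for
#'   SVM, `max_depth`/`nrounds` for gradient boosting, `size`/`decay` for
#'   the MLP, `ntree` for the random forest, `cp` for the tree).
#' @param seed Integer seed (stochastic backends).
#' @return Object of class `"fal_classifier"`; use [predict_prob()] for
#'   positive-class probabilities.
#' @export
train_classifier <- function(classifier, X, y,
                             class_weight = c("balanced", "none"),
                             params = list(), seed = 1L) {
  class_weight <- match.arg(class_weight)
  if (!classifier %in% classifier_names()) {
    stop("train_classifier: unknown classifier '", classifier,
         "'; available: ", paste(classifier_names(), collapse = ", "))
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    stop("train_classifier: only class ", unique(y),
         " present; need both classes (imbalance too extreme for a fit)")
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  w <- if (class_weight == "balanced") balanced_case_weights(y) else
    rep(1, length(y))
  cls_w <- if (class_weight == "balanced") {
    tab <- table(factor(y, levels = c(0, 1)))
    stats::setNames(length(y) / (2 * pmax(as.numeric(tab), 1)), c("0", "1"))
  } else {
    c("0" = 1, "1" = 1)
  }
  df <- data.frame(X)
  df$.y <- factor(y, levels = c(0, 1))
  fit <- switch(classifier,
    logistic = {
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial(),
                 weights = w))
    },
    svm_linear = e1071::svm(.y ~ ., data = df, kernel = "linear",
                            cost = params$cost %||% 1,
                            probability = TRUE, class.weights = cls_w),
    svm_rbf = e1071::svm(.y ~ ., data = df, kernel = "radial",
                         cost = params$cost %||% 1,
                         gamma = params$gamma %||% (1 / ncol(X)),
                         probability = TRUE, class.weights = cls_w),
    decision_tree = rpart::rpart(.y ~ ., data = df, weights = w,
                                 method = "class",
                                 control = rpart::rpart.control(
                                   cp = params$cp %||% 0.01,
                                   maxdepth = params$max_depth %||% 30,
                                   minsplit = params$minsplit %||% 20)),
    random_forest = randomForest::randomForest(
      x = X, y = df$.y,
      ntree = params$ntree %||% 200,
      mtry = params$mtry %||% max(1, floor(sqrt(ncol(X)))),
      classwt = if (class_weight == "balanced") cls_w else NULL),
    gradient_boosting = {
      spw <- if (class_weight == "balanced") sum(y == 0) / max(sum(y == 1), 1)
             else 1
      xgboost::xgboost(
        x = X, y = factor(y, levels = c(0, 1)),
        objective = "binary:logistic",
        nrounds = params$nrounds %||% 50,
        max_depth = params$max_depth %||% 4,
        learning_rate = params$eta %||% 0.3,
        scale_pos_weight = spw,
        nthreads = 1, seed = seed %% 2147483647)
    },
    naive_bayes = e1071::naiveBayes(.y ~ ., data = df),
    mlp = {
      utils::capture.output(
        m <- nnet::nnet(.y ~ ., data = df, weights = w,
                        size = params$size %||% 8,
                        decay = params$decay %||% 1e-3,
                        maxit = params$maxit %||% 200, trace = FALSE))
      m
    })
  structure(list(classifier = classifier, fit = fit,
                 feature_names = colnames(df)[seq_len(ncol(X))],
                 class_weight = class_weight, params = params),
            class = "fal_classifier")
}

#' Positive-class probabilities from a fitted classifier
#'
#' @param model A `"fal_classifier"` from [train_classifier()].
#' @param X Numeric matrix of rows to score.
#' @return Numeric vector of P(y = 1 | x), one per row.
#' @export
predict_prob <- function(model, X) {
  stopifnot(inherits(model, "fal_classifier"))
  X <- as.matrix(X)
  colnames(X) <- model$feature_names
  if (model$classifier == "logistic") {
    # direct linear-predictor evaluation: predict.glm's data-frame path is
    # orders of magnitude slower, and the Shapley value function calls this
    # once per feature subset
    beta <- stats::coef(model$fit)
    beta[is.na(beta)] <- 0  # collinear columns dropped by the fit
    eta <- drop(X %*% beta[-1]) + beta[1]
    return(unname(stats::plogis(eta)))
  }
  df <- data.frame(X)
  p <- switch(model$classifier,
    svm_linear = ,
    svm_rbf = {
      pr <- stats::predict(model$fit, newdata = df, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    decision_tree = stats::predict(model$fit, newdata = df)[, "1"],
    random_forest = stats::predict(model$fit, newdata = X,
                                   type = "prob")[, "1"],
    gradient_boosting = as.numeric(stats::predict(model$fit, newdata = X)),
    naive_bayes = stats::predict(model$fit, newdata = df,
                                 type = "raw")[, "1"],
    mlp = as.numeric(stats::predict(model$fit, newdata = df)))
  unname(pmin(pmax(p, 0), 1))
}

#' Predicted class labels at a 0.5 probability threshold
#'
#' @inheritParams predict_prob
#' @return Integer vector of 0/1 predictions.
#' @export
predict_class <- function(model, X) {
  as.integer(predict_prob(model, X) >= 0.5)
}

#' Exhaustive grid search with stratified cross-validated F1
#'
#' Scores every point of a hyperparameter grid by mean F1 over stratified
#' k-fold cross-validation and returns the best point; ties break toward
#' the earlier grid point in declaration order, and the search is
#' deterministic under the seed.
#'
#' @param classifier Backend name, as in [train_classifier()].
#' @param X,y Training matrix and 0/1 labels.
#' @param grid List of named hyperparameter lists (the grid points), e.g.
#'   `list(list(cost = 1), list(cost = 10))`.
#' @param folds Number of CV folds, default 5. Must not exceed the minority
#'   class count.
#' @param class_weight Passed to [train_classifier()].
#' @param seed Integer seed.
#' @return List with `best_params`, `best_score` (mean CV F1), and `scores`
#'   per grid point.
#' @export
tune_hyperparameters <- function(classifier, X, y, grid, folds = 5,
                                 class_weight = "balanced", seed = 1L) {
  if (length(grid) == 0) stop("tune_hyperparameters: empty grid")
  scores <- vapply(seq_along(grid), function(g) {
    cv <- cross_validate(classifier, X, y, folds = folds,
                         class_weight = class_weight,
                         params = grid[[g]], seed = seed)
    cv$mean["f1"]
  }, numeric(1))
  best <- which.max(scores)  # which.max returns the first maximum: tie-break
  list(best_params = grid[[best]], best_score = unname(scores[best]),
       scores = unname(scores))
}
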