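#' Label oracle over a hidden label vector
#'
#' Simulation stand-in for a human annotator: answers label queries by
#' index, counts queries, and refuses to answer the same index twice (so a
#' run's query count always equals its labeled-set size).
#'
#' @param labels Full 0/1 label vector (hidden from the sampler).
#' @return Object of class `"label_oracle"` with functions `answer(idx)`
#'   (vectorized) and `query_count()`.
#' @export
label_oracle <- function(labels) {
  asked <- logical(length(labels))
  count <- 0L
  answer <- function(idx) {
    if (any(asked[idx])) {
      stop("label_oracle: index queried twice: ",
           idx[asked[idx]][1])
    }
    asked[idx] <<- TRUE
    count <<- count + length(idx)
    labels[idx]
  }
  structure(list(answer = answer,
                 query_count = function() count),
            class = "label_oracle")
}

#' Loop configuration for focal active learning
#'
#' Bundles the tunable parameters of the acquisition loop.
#'
#' @param k_foci Number of foci (clusters); `NULL` means
#'   [default_k()] of the pool size.
#' @param batch_size Samples added per iteration; default `2 * k_foci`.
#' @param target_fraction Stop once the labeled sub-pool reaches this
#'   fraction of the initial unlabeled pool; default 0.20.
#' @param weights [score_weights()] for the combined acquisition score.
#' @param classifier Backend name (see [train_classifier()]), default
#'   `"logistic"`.
#' @param params Classifier hyperparameters.
#' @param class_weight `"balanced"` (default) or `"none"`.
#' @param acquisition `"fal"` (default) or `"random"` (uniform sampling at
#'   the same budget, as a baseline).
#' @param disable_shap_weighting Ablation: skip Shapley importance
#'   computation (importances stay all-ones).
#' @param disable_attention Ablation: compute importances but do not
#'   re-weight the feature matrices.
#' @param minority_mode `"predicted"` (default; the sampler sees only
#'   model-predicted classes for unlabeled rows) or `"oracle"` (true
#'   labels, for simulation studies only).
#' @param shap_eval_rows Cap on labeled rows receiving Shapley evaluation
#'   per iteration (default 200).
#' @param shap_background Background sample size for the interventional
#'   value function (default 100).
#' @param max_iter,tol Clustering controls passed to [kmeans_cosine()].
#' @param seed Root seed; every stage derives its own stream from it.
#' @return Object of class `"fal_config"`.
#' @export
fal_config <- function(k_foci = NULL, batch_size = NULL,
                       target_fraction = 0.20,
                       weights = score_weights(),
                       classifier = "logistic", params = list(),
                       class_weight = "balanced",
                       acquisition = c("fal", "random"),
                       disable_shap_weighting = FALSE,
                       disable_attention = FALSE,
                       minority_mode = c("predicted", "oracle"),
                       shap_eval_rows = 200, shap_background = 100,
                       max_iter = 300, tol = 1e-6, seed = 1L) {
  acquisition <- match.arg(acquisition)
  minority_mode <- match.arg(minority_mode)
  stopifnot(target_fraction > 0, target_fraction <= 1)
  if (is.numeric(weights)) weights <- score_weights(weights[1], weights[2],
                                                    weights[3])
  structure(list(k_foci = k_foci, batch_size = batch_size,
                 target_fraction = target_fraction, weights = weights,
                 classifier = classifier, params = params,
                 class_weight = class_weight, acquisition = acquisition,
                 disable_shap_weighting = disable_shap_weighting,
                 disable_attention = disable_attention,
                 minority_mode = minority_mode,
                 shap_eval_rows = shap_eval_rows,
                 shap_background = shap_background,
                 max_iter = max_iter, tol = tol, seed = as.integer(seed)),
            class = "fal_config")
}

#' Run the focal active-learning loop on an unlabeled pool
#'
#' The engine behind [fal()]. Starting from an unlabeled pool: (1) foci are
#' selected by cosine k-means and labeled through the oracle; (2) each
#' iteration trains the classifier on the attention-weighted labeled set,
#' scores every unlabeled candidate by the combined acquisition score
#' (nearest-focus similarity + prediction uncertainty + minority priority),
#' labels the top batch, moves it into the labeled sub-pool, and recomputes
#' Shapley importances from the enlarged labeled set; (3) the loop stops
#' once the labeled sub-pool reaches `target_fraction` of the initial pool
#' (the final batch may be partial), and the returned model is retrained on
#' the full labeled sub-pool.
#'
#' At iteration 0 the uncertainty model is trained on the foci alone; if
#' the foci happen to be single-class, the uncertainty weight is zeroed for
#' that iteration (class probabilities are undefined for an unseen class)
#' and restored once both classes appear.
#'
#' @param X Numeric feature matrix of the pool (preprocessed).
#' @param oracle A [label_oracle()] defined on all rows of `X`.
#' @param config A [fal_config()].
#' @return List with `model` (final `"fal_classifier"`), `labeled` /
#'   `unlabeled` index vectors, `importance` (final importance vector),
#'   `focus_set`, `history` (per-iteration data frame: iteration, n_labeled,
#'   batch size, minority fraction of the labeled set) and
#'   `importance_history` (iteration x feature matrix).
#' @export
run_focal_active_learning <- function(X, oracle, config = fal_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  k <- config$k_foci %||% default_k(n)
  batch <- config$batch_size %||% (2L * k)
  budget <- ceiling(config$target_fraction * n)
  if (budget < k) {
    stop("run_focal_active_learning: label budget (", budget,
         ") smaller than number of foci (", k, ")")
  }
  labeled <- integer(0)
  y_lab <- numeric(0)
  importance <- rep(1, p)
  if (config$acquisition == "fal") {
    fs <- kmeans_cosine(X, k, max_iter = config$max_iter, tol = config$tol,
                        seed = derive_seed(config$seed, "kmeans"))
    foci_idx <- fs$foci
    labeled <- foci_idx
    y_lab <- oracle$answer(foci_idx)
  } else {
    fs <- NULL
    old <- local_seed(derive_seed(config$seed, "loop"))
    first <- sample(seq_len(n), min(k, budget))
    restore_seed(old)
    labeled <- first
    y_lab <- oracle$answer(first)
  }
  unlabeled <- setdiff(seq_len(n), labeled)
  history <- list()
  imp_history <- list()
  record <- function(iter, batch_n) {
    history[[length(history) + 1]] <<- data.frame(
      iteration = iter, n_labeled = length(labeled), batch = batch_n,
      minority_fraction = mean(y_lab == find_minority_overall(y_lab)))
    imp_history[[length(imp_history) + 1]] <<- importance
  }
  find_minority_overall <- function(y) {
    if (length(unique(y)) < 2) return(1)  # positives are the scarce class
    find_minority_class(y)
  }
  update_importance <- function(model) {
    if (config$disable_shap_weighting) return(rep(1, p))
    old <- local_seed(derive_seed(config$seed, "shap"))
    on.exit(restore_seed(old), add = TRUE)
    eval_idx <- labeled
    if (length(eval_idx) > config$shap_eval_rows) {
      eval_idx <- sample(eval_idx, config$shap_eval_rows)
    }
    bg_idx <- labeled
    if (length(bg_idx) > config$shap_background) {
      bg_idx <- sample(bg_idx, config$shap_background)
    }
    Xw <- weight_matrix(X)
    phi <- shapley_matrix(function(Z) predict_prob(model, Z),
                          Xw[eval_idx, , drop = FALSE],
                          Xw[bg_idx, , drop = FALSE])
    feature_importance(phi)
  }
  weight_matrix <- function(M) {
    if (config$disable_attention) return(M)
    apply_attention_weights(M, importance)
  }
  iter <- 0L
  record(iter, length(labeled))
  model <- NULL
  while (length(labeled) < budget && length(unlabeled) > 0) {
    iter <- iter + 1L
    take <- min(batch, budget - length(labeled), length(unlabeled))
    if (config$acquisition == "random") {
      old <- local_seed(derive_seed(config$seed, "loop") + iter)
      sel <- sample(seq_along(unlabeled), take)
      restore_seed(old)
    } else {
      both <- length(unique(y_lab)) >= 2
      w <- config$weights
      if (both) {
        model <- train_classifier(config$classifier,
                                  weight_matrix(X[labeled, , drop = FALSE]),
                                  y_lab, class_weight = config$class_weight,
                                  params = config$params,
                                  seed = derive_seed(config$seed, "model") + iter)
        probs <- predict_prob(model, weight_matrix(X[unlabeled, , drop = FALSE]))
        unc <- -pmax(probs, 1 - probs)
        minority <- find_minority_class(y_lab)
        delta <- if (config$minority_mode == "oracle") {
          as.numeric(oracle_peek(oracle, unlabeled) == minority)
        } else {
          as.numeric(as.integer(probs >= 0.5) == minority)
        }
      } else {
        # single-class foci: probabilities undefined for the unseen class
        w <- score_weights(w$alpha, 0, w$gamma)
        unc <- rep(0, length(unlabeled))
        delta <- rep(0, length(unlabeled))
      }
      sims <- similarity_to_foci(weight_matrix(X[unlabeled, , drop = FALSE]),
                                 weight_matrix(fs$centroids))
      sc <- combined_scores(sims, unc, delta, w)
      sel <- select_batch(sc, take)
    }
    new_idx <- unlabeled[sel]
    y_new <- oracle$answer(new_idx)
    labeled <- c(labeled, new_idx)
    y_lab <- c(y_lab, y_new)
    unlabeled <- setdiff(unlabeled, new_idx)
    if (config$acquisition == "fal" && length(unique(y_lab)) >= 2) {
      model <- train_classifier(config$classifier,
                                weight_matrix(X[labeled, , drop = FALSE]),
                                y_lab, class_weight = config$class_weight,
                                params = config$params,
                                seed = derive_seed(config$seed, "model") + 1000L + iter)
      importance <- update_importance(model)
    }
    record(iter, length(new_idx))
  }
  final <- train_classifier(config$classifier,
                            weight_matrix(X[labeled, , drop = FALSE]),
                            y_lab, class_weight = config$class_weight,
                            params = config$params,
                            seed = derive_seed(config$seed, "model"))
  hist_df <- do.call(rbind, history)
  imp_mat <- do.call(rbind, imp_history)
  colnames(imp_mat) <- colnames(X) %||% paste0("x", seq_len(p))
  list(model = final, labeled = labeled, y_labeled = y_lab,
       unlabeled = unlabeled, importance = importance, focus_set = fs,
       history = hist_df, importance_history = imp_mat)
}

# Internal: oracle mode for simulation studies reads hidden labels without
# consuming queries. Only defined for label_oracle closures.
oracle_peek <- function(oracle, idx) {
  environment(oracle$answer)$labels[idx]
}

#' Fit a classifier by focal active learning
#'
#' The main fitting function. Given a (preprocessed, numeric) table with a
#' 0/1 response, it treats the response as a hidden annotation source,
#' selects representative foci by cosine k-means, then iteratively grows a
#' labeled sub-pool by combined-score acquisition (similarity +
#' uncertainty + minority priority) with Shapley-based attention
#' re-weighting of features between iterations, and returns the classifier
#' trained on the final sub-pool. Only the queried labels are ever revealed
#' to the learner, so the fit simulates an annotation budget of
#' `target_fraction` of the pool.
#'
#' @param formula Model formula, e.g. `diabetes ~ .`. The response must be
#'   0/1.
#' @param data Data frame of numeric (encoded, standardized) features.
#' @param x,y Alternatively, a numeric matrix and 0/1 label vector
#'   (default method).
#' @param ... Arguments forwarded to [fal_config()] (`k_foci`,
#'   `batch_size`, `target_fraction`, `weights`, `classifier`,
#'   `acquisition`, ablation flags, `seed`, ...).
#' @param config A ready-made [fal_config()]; overrides `...`.
#' @return Object of class `"fal"`: the fitted classifier plus the pool
#'   state (`labeled`, `unlabeled`), acquisition `history`, final
#'   `importance` vector, `importance_history`, `focus_set`, `config`,
#'   `oracle_queries` and the matched `call`. Supports `print()`,
#'   `summary()`, `predict()`, `coef()` and `plot()`.
#' @export
#' @examples
#' spec <- synthetic_spec(n_rows = 400, seed = 7)
#' d <- generate_synthetic(spec)
#' d[c("age", "bmi", "HbA1c_level", "blood_glucose_level")] <-
#'   scale(d[c("age", "bmi", "HbA1c_level", "blood_glucose_level")])
#' fit <- fal(diabetes ~ ., data = d, k_foci = 10, seed = 7)
#' fit
fal <- function(...) UseMethod("fal", ..1)

#' @rdname fal
#' @export
fal.formula <- function(formula, data, ..., config = NULL) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- as.matrix(mf[, -1, drop = FALSE])
  fit <- fal.default(X, y, ..., config = config)
  fit$call <- match.call()
  fit$terms <- stats::terms(mf)
  fit
}

#' @rdname fal
#' @export
fal.default <- function(x, y, ..., config = NULL) {
  X <- as.matrix(x)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("fal: response must be 0/1")
  if (is.null(config)) config <- fal_config(...)
  oracle <- label_oracle(y)
  res <- run_focal_active_learning(X, oracle, config)
  structure(list(model = res$model, labeled = res$labeled,
                 y_labeled = res$y_labeled, unlabeled = res$unlabeled,
                 importance = res$importance,
                 importance_history = res$importance_history,
                 focus_set = res$focus_set, history = res$history,
                 config = config, n_pool = nrow(X),
                 feature_names = colnames(X),
                 oracle_queries = oracle$query_count(),
                 call = match.call()),
            class = "fal")
}

#' @export
print.fal <- function(x, ...) {
  cat("Focal active learning fit\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  pool %d, labeled %d (%.1f%%), %d acquisition iterations\n",
              x$n_pool, length(x$labeled),
              100 * length(x$labeled) / x$n_pool,
              max(x$history$iteration)))
  cat(sprintf("  classifier: %s (%s), minority fraction of sub-pool: %.3f\n",
              x$config$classifier, x$config$acquisition,
              utils::tail(x$history$minority_fraction, 1)))
  invisible(x)
}

#' @export
summary.fal <- function(object, ...) {
  structure(list(fit = object), class = "summary.fal")
}

#' @export
print.summary.fal <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nAcquisition history:\n")
  print(f$history, row.names = FALSE)
  if (!is.null(f$feature_names)) {
    cat("\nFinal feature importances (mean-|Shapley|, mean-one scaled):\n")
    imp <- stats::setNames(f$importance, f$feature_names)
    print(round(sort(imp, decreasing = TRUE), 4))
  }
  invisible(x)
}

#' Predict from a focal active-learning fit
#'
#' Applies the fit's attention weighting to `newdata` and scores it with
#' the final classifier.
#'
#' @param object A `"fal"` fit.
#' @param newdata Data frame or matrix with the training feature columns.
#' @param type `"prob"` for positive-class probabilities (default) or
#'   `"class"` for 0/1 labels at the 0.5 threshold.
#' @param ... Unused.
#' @export
predict.fal <- function(object, newdata,
                        type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (!is.null(object$terms) && is.data.frame(newdata)) {
    tt <- stats::delete.response(object$terms)
    newdata <- as.matrix(stats::model.frame(tt, newdata))
  }
  X <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(X))) {
    X <- X[, object$feature_names, drop = FALSE]
  }
  if (!object$config$disable_attention) {
    X <- apply_attention_weights(X, object$importance)
  }
  p <- predict_prob(object$model, X)
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' @export
coef.fal <- function(object, ...) {
  stats::setNames(object$importance,
                  object$feature_names %||%
                    paste0("x", seq_along(object$importance)))
}

#' Plot acquisition history of a focal active-learning fit
#'
#' Two base-graphics panels: labeled sub-pool growth and the minority
#' fraction of the labeled set across iterations (the latter is the
#' quantity the minority-priority term is meant to push above the pool
#' prevalence).
#'
#' @param x A `"fal"` fit.
#' @param ... Passed to `plot()`.
#' @export
plot.fal <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(h$iteration, h$n_labeled, type = "b", pch = 16,
       xlab = "iteration", ylab = "labeled samples",
       main = "Sub-pool growth", ...)
  plot(h$iteration, h$minority_fraction, type = "b", pch = 16,
       xlab = "iteration", ylab = "minority fraction",
       main = "Labeled-set balance", ...)
  invisible(x)
}
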