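#' Exact Shapley feature attributions for a black-box scorer
#'
#' Computes, for one evaluation row `x`, the exact Shapley value of every
#' feature:
#' \deqn{\phi_i = \sum_{S \subseteq N \setminus \{i\}}
#'   \frac{|S|!\,(|N|-|S|-1)!}{|N|!} \left[ v(S \cup \{i\}) - v(S) \right]}
#' where the value of a coalition `S` is the interventional expectation of
#' the model output: features in `S` take their values from `x`, features
#' outside `S` are replaced by rows of a `background` sample, and the model
#' output is averaged over the background rows. The full \eqn{2^{|N|}}
#' subset lattice is enumerated, so the method is exact but limited to
#' `<= 12` features (tabular clinical panels are typically well below
#' this); wider tables must use the Monte-Carlo permutation approximation
#' (`method = "sampling"`).
#'
#' Efficiency holds by construction:
#' \eqn{\sum_i \phi_i = v(N) - v(\emptyset)}.
#'
#' @param predict_fn Function taking a numeric matrix (rows = samples) and
#'   returning one numeric score per row, e.g. the positive-class
#'   probability of a fitted classifier.
#' @param x Numeric vector: the row to explain.
#' @param background Numeric matrix of reference rows used to marginalize
#'   absent features.
#' @param method `"exact"` (subset enumeration, default) or `"sampling"`
#'   (random permutation averaging, for > 12 features).
#' @param n_perm Number of permutations for `method = "sampling"`.
#' @param seed Seed for `method = "sampling"`.
#' @return Numeric vector of Shapley values, one per feature.
#' @export
exact_shapley <- function(predict_fn, x, background,
                          method = c("exact", "sampling"),
                          n_perm = 200, seed = 1L) {
  method <- match.arg(method)
  background <- as.matrix(background)
  p <- length(x)
  stopifnot(ncol(background) == p)
  if (method == "sampling") {
    return(shapley_sampling(predict_fn, x, background, n_perm, seed))
  }
  if (p > 12) {
    stop("exact_shapley: exact enumeration limited to 12 features; ",
         "use method = \"sampling\" for wider tables")
  }
  v <- coalition_values(predict_fn, matrix(x, nrow = 1), background)[1, ]
  phi_from_values(v, p)
}

# Value v(S) for every subset S of the feature set, for each evaluation row.
# Subsets are indexed by bitmask + 1 (mask 0 = empty set). Returns an
# n_eval x 2^p matrix. One predict_fn call per subset, each over
# n_eval * n_background hybrid rows.
coalition_values <- function(predict_fn, X_eval, background) {
  X_eval <- as.matrix(X_eval)
  p <- ncol(X_eval)
  nb <- nrow(background)
  ne <- nrow(X_eval)
  n_sub <- 2^p
  base <- background[rep(seq_len(nb), times = ne), , drop = FALSE]
  eval_rep <- rep(seq_len(ne), each = nb)
  v <- matrix(0, nrow = ne, ncol = n_sub)
  for (mask in 0:(n_sub - 1)) {
    in_S <- bitwAnd(mask, bitwShiftL(1L, 0:(p - 1))) != 0
    Z <- base
    if (any(in_S)) {
      Z[, in_S] <- X_eval[eval_rep, in_S, drop = FALSE]
    }
    preds <- predict_fn(Z)
    v[, mask + 1] <- colMeans(matrix(preds, nrow = nb, ncol = ne))
  }
  v
}

# Recover phi from the 2^p coalition values of one evaluation row.
phi_from_values <- function(v, p) {
  masks <- 0:(2^p - 1)
  sizes <- vapply(masks, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) != 0),
                  numeric(1))
  w <- numeric(length(masks))  # weight of S as the coalition without i
  proper <- sizes < p
  w[proper] <- factorial(sizes[proper]) * factorial(p - sizes[proper] - 1) /
    factorial(p)
  phi <- numeric(p)
  for (i in seq_len(p)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- masks[bitwAnd(masks, bit) == 0]
    phi[i] <- sum(w[without + 1] * (v[without + bit + 1] - v[without + 1]))
  }
  phi
}

# Monte-Carlo permutation estimate of Shapley values: average marginal
# contribution over random feature orderings.
shapley_sampling <- function(predict_fn, x, background, n_perm, seed) {
  p <- length(x)
  nb <- nrow(background)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  phi <- numeric(p)
  for (r in seq_len(n_perm)) {
    ord <- sample.int(p)
    Z <- background
    prev <- mean(predict_fn(Z))
    for (i in ord) {
      Z[, i] <- x[i]
      cur <- mean(predict_fn(Z))
      phi[i] <- phi[i] + (cur - prev)
      prev <- cur
    }
  }
  phi / n_perm
}

#' Shapley values for a set of evaluation rows
#'
#' Vectorized wrapper around the exact computation: returns the matrix of
#' per-row Shapley values used to form feature importances. Shares the
#' coalition-value evaluation across rows, so the model is called once per
#' feature subset.
#'
#' @inheritParams exact_shapley
#' @param X_eval Numeric matrix of rows to explain.
#' @return n_eval x p matrix of Shapley values.
#' @export
shapley_matrix <- function(predict_fn, X_eval, background) {
  X_eval <- as.matrix(X_eval)
  p <- ncol(X_eval)
  if (p > 12) {
    stop("shapley_matrix: exact enumeration limited to 12 features")
  }
  v <- coalition_values(predict_fn, X_eval, background)
  t(apply(v, 1, phi_from_values, p = p))
}

#' Mean-absolute-Shapley feature importances
#'
#' Importance of feature j is the mean over evaluation rows of
#' \eqn{|\phi_{ij}|}, rescaled to have mean 1 so that attention weighting
#' preserves the overall feature scale. If all Shapley values are zero the
#' rescaling is undefined; the importances are then defined as all ones
#' (weighting becomes a no-op).
#'
#' @param shap_rows Matrix of Shapley values, rows = samples, cols =
#'   features.
#' @return Numeric importance vector with mean 1.
#' @export
feature_importance <- function(shap_rows) {
  shap_rows <- as.matrix(shap_rows)
  if (nrow(shap_rows) < 1) stop("feature_importance: need at least 1 row")
  imp <- colMeans(abs(shap_rows))
  m <- mean(imp)
  if (m == 0) return(rep(1, ncol(shap_rows)))
  imp / m
}

#' Attention-weight feature columns by importance
#'
#' Multiplies each feature column elementwise by its importance:
#' `weighted[i, j] = X[i, j] * importance[j]`. With mean-one importances
#' this leaves the average column scale unchanged while amplifying the
#' features the model currently relies on.
#'
#' @param X Numeric matrix.
#' @param importance Numeric vector, one weight per column.
#' @return The weighted matrix.
#' @export
apply_attention_weights <- function(X, importance) {
  X <- as.matrix(X)
  if (length(importance) != ncol(X)) {
    stop("apply_attention_weights: importance length (", length(importance),
         ") != number of columns (", ncol(X), ")")
  }
  sweep(X, 2, importance, `*`)
}
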