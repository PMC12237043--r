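#' Prediction uncertainty of a class-probability vector
#'
#' \eqn{u(x) = -\max_c P(y = c \mid x)}: the negative of the most confident
#' class probability. Higher values mean less confidence; for C classes the
#' range is \[-1, -1/C\], maximized at the uniform distribution.
#'
#' @param probs Nonnegative probability vector summing to 1 (within 1e-6).
#' @return Scalar uncertainty.
#' @export
#' @examples
#' prediction_uncertainty(c(0.5, 0.5))  # -0.5, maximally uncertain
prediction_uncertainty <- function(probs) {
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-6) {
    stop("prediction_uncertainty: not a probability distribution")
  }
  -max(probs)
}

#' Identify the minority class
#'
#' Returns the class label with the fewest observations; ties break toward
#' the numerically smallest label.
#'
#' @param labels Non-empty vector of class labels.
#' @return The minority class label.
#' @export
find_minority_class <- function(labels) {
  if (length(labels) == 0) stop("find_minority_class: empty input")
  classes <- sort(unique(labels))
  counts <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  classes[which.min(counts)]
}

#' Cosine similarity of a sample to its nearest focus
#'
#' The similarity term of the acquisition score: the maximum cosine
#' similarity between `x` and any focus vector (nearest-focus
#' aggregation). `aggregate = "assigned"` instead uses the single focus of
#' the cluster the sample is assigned to.
#'
#' @param x Numeric vector, or matrix of rows.
#' @param foci Matrix whose rows are the focus vectors (or a `"focus_set"`,
#'   in which case its centroids are used).
#' @param aggregate `"max"` (default) or `"assigned"`.
#' @return Scalar (or vector, for matrix input) similarity.
#' @export
similarity_to_foci <- function(x, foci, aggregate = c("max", "assigned")) {
  aggregate <- match.arg(aggregate)
  fs <- NULL
  if (inherits(foci, "focus_set")) {
    fs <- foci
    foci <- fs$centroids
  }
  foci <- as.matrix(foci)
  if (nrow(foci) == 0) stop("similarity_to_foci: empty focus set")
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  sims <- cosine_sim_matrix(X, foci)
  out <- if (aggregate == "max") {
    apply(sims, 1, max)
  } else {
    if (is.null(fs)) stop("similarity_to_foci: 'assigned' needs a focus_set")
    assign_idx <- assign_clusters(X, foci)
    sims[cbind(seq_len(nrow(X)), assign_idx)]
  }
  if (is.matrix(x)) out else out[1]
}

# Min-max rescale to [0, 1]; a constant vector maps to 0 so it cannot
# dominate the combined score.
minmax01 <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Combined acquisition scores for labeling candidates
#'
#' Scores each unlabeled candidate as
#' \deqn{score_i = \alpha \, \tilde{s}_i + \beta \, \tilde{u}_i +
#'   \gamma \, \delta_i}
#' where \eqn{\tilde{s}} and \eqn{\tilde{u}} are the similarity and
#' uncertainty terms min-max normalized to \[0, 1\] over the current
#' candidate set (the raw terms live on incompatible scales), and
#' \eqn{\delta_i \in \{0,1\}} flags membership in the minority class.
#'
#' @param similarity Numeric vector: nearest-focus cosine similarity per
#'   candidate.
#' @param uncertainty Numeric vector: [prediction_uncertainty()] per
#'   candidate.
#' @param minority_flag 0/1 vector: candidate (predicted) minority-class
#'   membership.
#' @param weights Object from [score_weights()], or numeric length-3
#'   vector `c(alpha, beta, gamma)`.
#' @return Data frame with columns `similarity`, `uncertainty`,
#'   `minority_flag` (the normalized terms actually combined) and
#'   `combined_score`.
#' @export
combined_scores <- function(similarity, uncertainty, minority_flag,
                            weights = score_weights()) {
  if (is.numeric(weights)) weights <- score_weights(weights[1], weights[2],
                                                    weights[3])
  n <- length(similarity)
  stopifnot(length(uncertainty) == n, length(minority_flag) == n,
            all(minority_flag %in% c(0, 1)))
  s <- minmax01(similarity)
  u <- minmax01(uncertainty)
  score <- weights$alpha * s + weights$beta * u +
    weights$gamma * minority_flag
  data.frame(similarity = s, uncertainty = u,
             minority_flag = minority_flag, combined_score = score)
}

#' Acquisition score weights
#'
#' The mixing weights (alpha: similarity, beta: uncertainty, gamma:
#' minority priority) of the combined acquisition score. All three default
#' to 1/3; at least one must be positive.
#'
#' @param alpha,beta,gamma Nonnegative weights.
#' @return Object of class `"score_weights"`.
#' @export
score_weights <- function(alpha = 1 / 3, beta = 1 / 3, gamma = 1 / 3) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0)
  if (alpha + beta + gamma <= 0) {
    stop("score_weights: all weights zero")
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "score_weights")
}

#' Select the top-scoring batch of candidates
#'
#' Returns the positions of the `batch_size` highest combined scores; ties
#' break toward the lower row index, and if fewer candidates remain than
#' requested, all are returned.
#'
#' @param scores Numeric vector of combined scores (or the data frame from
#'   [combined_scores()]).
#' @param batch_size Number of candidates to select, >= 1.
#' @return Integer vector of selected positions (into `scores`).
#' @export
select_batch <- function(scores, batch_size) {
  if (is.data.frame(scores)) scores <- scores$combined_score
  stopifnot(batch_size >= 1)
  n <- length(scores)
  k <- min(batch_size, n)
  ord <- order(-scores, seq_len(n))  # descending score, then lower index
  sort(ord[seq_len(k)])
}
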