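#' Cosine similarity between two vectors
#'
#' \eqn{\cos(u, v) = u \cdot v / (\|u\| \|v\|)}, in \[-1, 1\]. If either
#' vector has zero norm the similarity is defined as 0 (such vectors can
#' arise when a constant feature is standardized); this keeps downstream
#' argmax assignments well defined.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Scalar similarity.
#' @export
#' @examples
#' cosine_similarity(c(1, 1), c(1, 0))  # 1/sqrt(2)
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    stop("cosine_similarity: vectors differ in length")
  }
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

# Row-normalize to unit L2 norm; zero rows stay zero.
unit_rows <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  nz <- nrm > 0
  X[nz, ] <- X[nz, , drop = FALSE] / nrm[nz]
  X
}

# n x k matrix of cosine similarities between rows of X and rows of C.
cosine_sim_matrix <- function(X, C) {
  unit_rows(as.matrix(X)) %*% t(unit_rows(as.matrix(C)))
}

#' Assign samples to their most similar centroid
#'
#' Each row of `X` goes to the centroid with the highest cosine similarity;
#' ties break toward the lower centroid index. Zero-norm rows (similarity 0
#' to everything) fall into cluster 1.
#'
#' @param X Numeric matrix (rows = samples).
#' @param centroids Numeric matrix (rows = centroids).
#' @return Integer vector of cluster indices in `1:nrow(centroids)`.
#' @export
assign_clusters <- function(X, centroids) {
  X <- as.matrix(X)
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 1) stop("assign_clusters: need at least 1 centroid")
  sims <- cosine_sim_matrix(X, centroids)
  max.col(sims, ties.method = "first")
}

#' Update centroids as within-cluster means
#'
#' \eqn{\mu_j = |c_j|^{-1} \sum_{x_i \in c_j} x_i}. An empty cluster is
#' repaired by re-seeding its centroid at the sample that fits the current
#' clustering worst (lowest similarity to its nearest non-empty centroid).
#'
#' @param X Numeric matrix.
#' @param assignments Integer cluster indices in `1:k`.
#' @param k Number of clusters.
#' @return k x ncol(X) centroid matrix.
#' @export
update_centroids <- function(X, assignments, k) {
  X <- as.matrix(X)
  stopifnot(all(assignments >= 1), all(assignments <= k))
  p <- ncol(X)
  centroids <- matrix(0, nrow = k, ncol = p)
  counts <- tabulate(assignments, nbins = k)
  for (j in which(counts > 0)) {
    centroids[j, ] <- colMeans(X[assignments == j, , drop = FALSE])
  }
  empty <- which(counts == 0)
  if (length(empty) > 0) {
    sims <- cosine_sim_matrix(X, centroids[counts > 0, , drop = FALSE])
    fit <- apply(sims, 1, max)
    worst <- order(fit)  # least-well-represented samples first
    for (i in seq_along(empty)) {
      centroids[empty[i], ] <- X[worst[i], ]
    }
  }
  colnames(centroids) <- colnames(X)
  centroids
}

# k-means++-style seeding on cosine distance (1 - similarity).
seed_centroids <- function(Xn, k) {
  n <- nrow(Xn)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  if (k > 1) {
    best_sim <- drop(Xn %*% Xn[centers[1], ])
    for (j in 2:k) {
      d <- pmax(1 - best_sim, 0)
      if (sum(d) == 0) {
        centers[j] <- sample.int(n, 1)
      } else {
        centers[j] <- sample.int(n, 1, prob = d)
      }
      best_sim <- pmax(best_sim, drop(Xn %*% Xn[centers[j], ]))
    }
  }
  Xn[centers, , drop = FALSE]
}

#' K-means clustering under cosine similarity (spherical k-means)
#'
#' Alternates [assign_clusters()] and [update_centroids()] until the
#' assignment is stable, the total within-cluster similarity improves by
#' less than `tol`, or `max_iter` is reached. By default samples are
#' unit-normalized internally and centroids re-normalized after the mean
#' update (the spherical variant), which makes the within-cluster cosine
#' objective monotone non-decreasing; `normalize = FALSE` runs the raw
#' cosine-assignment / arithmetic-mean variant, which keeps the mean update
#' literal but loses the monotonicity guarantee.
#'
#' Initial centroids are drawn by k-means++-style seeding on cosine
#' distance, so the result is deterministic under a fixed seed.
#'
#' @param X Numeric matrix, rows = samples.
#' @param k Number of clusters, `1 <= k <= nrow(X)`.
#' @param max_iter Iteration cap, default 300.
#' @param tol Convergence tolerance on the objective change, default 1e-6.
#' @param seed Integer seed.
#' @param normalize Unit-normalize samples (spherical mode)? Default TRUE.
#' @return An object of class `"focus_set"`: list with `centroids` (k x p),
#'   `assignments`, `foci` (one representative sample index per cluster,
#'   from [select_foci()]), `k`, `objective` (per-iteration total
#'   within-cluster similarity) and `iterations`.
#' @export
kmeans_cosine <- function(X, k, max_iter = 300, tol = 1e-6, seed = 1L,
                          normalize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1) stop("kmeans_cosine: k must be >= 1")
  if (k > n) stop("kmeans_cosine: k exceeds number of samples")
  Xw <- if (normalize) unit_rows(X) else X
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  Xn <- unit_rows(X)
  centroids <- seed_centroids(Xn, k)
  assignments <- assign_clusters(Xw, centroids)
  objective <- numeric(0)
  iter <- 0
  repeat {
    iter <- iter + 1
    centroids <- update_centroids(Xw, assignments, k)
    if (normalize) centroids <- unit_rows(centroids)
    sims <- cosine_sim_matrix(Xw, centroids)
    new_assign <- max.col(sims, ties.method = "first")
    obj <- sum(sims[cbind(seq_len(n), new_assign)])
    objective <- c(objective, obj)
    stable <- identical(new_assign, assignments)
    assignments <- new_assign
    if (stable) break
    if (iter >= 2 && abs(objective[iter] - objective[iter - 1]) < tol) break
    if (iter >= max_iter) break
  }
  fs <- structure(list(centroids = centroids, assignments = assignments,
                       k = k, objective = objective, iterations = iter,
                       normalize = normalize),
                  class = "focus_set")
  fs$foci <- select_foci(X, fs)
  fs
}

#' Select one representative sample (focus) per cluster
#'
#' For each cluster, returns the index of the member sample with the
#' highest cosine similarity to the cluster centroid; ties break toward the
#' lower row index.
#'
#' @param X The sample matrix the clustering was run on.
#' @param focus_set A `"focus_set"` (the `foci` field may be absent).
#' @return Integer vector of length k: one sample index per cluster.
#' @export
select_foci <- function(X, focus_set) {
  X <- as.matrix(X)
  sims <- cosine_sim_matrix(X, focus_set$centroids)
  vapply(seq_len(focus_set$k), function(j) {
    members <- which(focus_set$assignments == j)
    if (length(members) == 0) return(NA_integer_)
    members[which.max(sims[members, j])]
  }, integer(1))
}

#' Default number of foci
#'
#' The common rule of thumb \eqn{k = \mathrm{round}(\sqrt{n/2})}, floored
#' at 1: at n = 100{,}000 it gives k = 224, i.e. foci on the order of a few
#' hundred for pools of this size. An explicit `k` always takes precedence.
#'
#' @param n Number of pool samples, `n >= 1`.
#' @return Integer k.
#' @export
default_k <- function(n) {
  stopifnot(n >= 1)
  max(1L, as.integer(round(sqrt(n / 2))))
}

#' @export
print.focus_set <- function(x, ...) {
  cat("Cosine k-means focus set\n")
  cat("  clusters:   ", x$k, "\n", sep = "")
  cat("  iterations: ", x$iterations, "\n", sep = "")
  cat("  objective:  ", format(utils::tail(x$objective, 1), digits = 6),
      " (total within-cluster similarity)\n", sep = "")
  invisible(x)
}
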