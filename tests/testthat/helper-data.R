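# Shared fixture builders. All fixtures are generated in code, seeded.

# Two well-separated Gaussian blobs with labels; linearly separable for
# sep >= ~6.
make_separable_data <- function(n = 100, p = 3, sep = 8, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  X[y == 1, 1] <- X[y == 1, 1] + sep
  colnames(X) <- paste0("x", seq_len(p))
  list(X = X, y = y)
}

# Standardize the four continuous columns of a generated synthetic table.
standardize_synth <- function(d) {
  cc <- c("age", "bmi", "HbA1c_level", "blood_glucose_level")
  d[cc] <- scale(d[cc])
  d
}

# Independent brute-force oracle for classification metrics: elementwise
# comparisons only, no shared code with the package implementation.
oracle_metrics <- function(y_true, y_pred) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_along(y_true)) {
    if (y_true[i] == 1 && y_pred[i] == 1) tp <- tp + 1
    if (y_true[i] == 0 && y_pred[i] == 0) tn <- tn + 1
    if (y_true[i] == 0 && y_pred[i] == 1) fp <- fp + 1
    if (y_true[i] == 1 && y_pred[i] == 0) fn <- fn + 1
  }
  acc <- (tp + tn) / length(y_true)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(TP = tp, TN = tn, FP = fp, FN = fn, accuracy = acc,
       precision = prec, recall = rec, f1 = f1)
}

# Independent coalition-value function for Shapley oracles: features in S
# come from x, the rest from each background row; model output averaged
# over background rows. Deliberately written as plain loops.
oracle_value <- function(f, x, background, S) {
  total <- 0
  for (b in seq_len(nrow(background))) {
    z <- background[b, ]
    for (j in S) z[j] <- x[j]
    total <- total + f(matrix(z, nrow = 1))
  }
  total / nrow(background)
}

# Permutation-average Shapley oracle: phi_i = average over all |N|!
# orderings of the marginal contribution of i when added in that order.
oracle_shapley_perm <- function(f, x, background) {
  p <- length(x)
  perms <- all_permutations(p)
  phi <- numeric(p)
  for (r in seq_len(nrow(perms))) {
    S <- integer(0)
    v_prev <- oracle_value(f, x, background, S)
    for (i in perms[r, ]) {
      S <- c(S, i)
      v_cur <- oracle_value(f, x, background, S)
      phi[i] <- phi[i] + (v_cur - v_prev)
      v_prev <- v_cur
    }
  }
  phi / nrow(perms)
}

all_permutations <- function(p) {
  if (p == 1) return(matrix(1L))
  sub <- all_permutations(p - 1)
  out <- matrix(0L, nrow = nrow(sub) * p, ncol = p)
  row <- 0
  for (r in seq_len(nrow(sub))) {
    for (pos in seq_len(p)) {
      row <- row + 1
      out[row, ] <- append(sub[r, ], p, after = pos - 1)
    }
  }
  out
}

# Brute-force best 2-partition under the spherical k-means objective: for
# unit vectors the total within-cluster cosine similarity of a cluster
# equals the norm of its vector sum, so maximize ||s_A|| + ||s_B|| over
# all bipartitions.
oracle_best_2partition <- function(X) {
  Xn <- X / sqrt(rowSums(X^2))
  n <- nrow(Xn)
  best <- -Inf
  best_assign <- NULL
  for (mask in 1:(2^(n - 1) - 1)) {  # fix sample 1 in group A; skip empty B
    inA <- c(TRUE, bitwAnd(mask, 2^(seq_len(n - 1) - 1)) == 0)
    sA <- colSums(Xn[inA, , drop = FALSE])
    sB <- colSums(Xn[!inA, , drop = FALSE])
    obj <- sqrt(sum(sA^2)) + sqrt(sum(sB^2))
    if (obj > best) {
      best <- obj
      best_assign <- inA
    }
  }
  list(objective = best, assign = best_assign)
}
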