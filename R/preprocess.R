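#' Remove exact duplicate rows
#'
#' Drops rows that are exact duplicates (all columns, including any label
#' column, equal), keeping the first occurrence and preserving the original
#' row order otherwise.
#'
#' @param table A data frame.
#' @return The deduplicated data frame, with attribute `"n_removed"` giving
#'   the number of rows dropped.
#' @export
#' @examples
#' df <- data.frame(a = c(1, 1, 2), b = c("x", "x", "y"))
#' drop_duplicates(df)
drop_duplicates <- function(table) {
  stopifnot(is.data.frame(table))
  keep <- !duplicated(table)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Remove outliers by interquartile-range fences
#'
#' Computes per-column quartiles (type-7 linear interpolation) on the input
#' table and removes every row with a value outside
#' \eqn{[Q_1 - m \cdot IQR,\; Q_3 + m \cdot IQR]} in any of the named
#' columns. Fences are computed once, on the data as given; they are not
#' re-estimated after rows are removed.
#'
#' @param table A data frame.
#' @param columns Character vector of continuous column names to screen.
#' @param multiplier Fence width `m` in IQR units; default 1.5.
#' @return A list with `table` (filtered data frame), `removed` (integer
#'   indices of removed rows, relative to the input) and `bounds` (a
#'   2 x length(columns) matrix of lower/upper fences).
#' @export
iqr_filter <- function(table, columns, multiplier = 1.5) {
  stopifnot(is.data.frame(table), multiplier > 0)
  missing_cols <- setdiff(columns, names(table))
  if (length(missing_cols) > 0) {
    stop("iqr_filter: unknown column(s): ", paste(missing_cols, collapse = ", "))
  }
  bounds <- sapply(columns, function(cn) {
    x <- table[[cn]]
    q <- stats::quantile(x, probs = c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    c(lower = q[1] - multiplier * iqr, upper = q[2] + multiplier * iqr)
  })
  bounds <- matrix(bounds, nrow = 2,
                   dimnames = list(c("lower", "upper"), columns))
  out_of_fence <- rep(FALSE, nrow(table))
  for (cn in columns) {
    x <- table[[cn]]
    out_of_fence <- out_of_fence | x < bounds["lower", cn] | x > bounds["upper", cn]
  }
  removed <- which(out_of_fence)
  kept <- table[!out_of_fence, , drop = FALSE]
  rownames(kept) <- NULL
  list(table = kept, removed = removed, bounds = bounds)
}

#' Fit z-score standardization parameters
#'
#' Estimates a per-column location \eqn{\gamma} (mean) and scale
#' \eqn{\sigma} (standard deviation) so that columns can be transformed to
#' \eqn{x = (x' - \gamma)/\sigma}. The scale uses the population
#' (n-denominator) convention by default; set `sd_type = "sample"` for the
#' n-1 convention. Fit on the training split only and apply everywhere.
#'
#' Columns with zero spread get `sigma = 0` and are flagged; they pass
#' through [apply_standardizer()] unchanged.
#'
#' @param table Data frame holding the training rows.
#' @param columns Character vector of numeric columns to standardize.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return An object of class `"standardizer"`: a list with `columns`,
#'   `mean`, `sd`, `constant` (logical flag per column) and `sd_type`.
#' @export
fit_standardizer <- function(table, columns,
                             sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0) stop("fit_standardizer: empty table")
  missing_cols <- setdiff(columns, names(table))
  if (length(missing_cols) > 0) {
    stop("fit_standardizer: unknown column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(table)
  mu <- vapply(columns, function(cn) mean(table[[cn]]), numeric(1))
  sigma <- vapply(columns, function(cn) {
    s2 <- stats::var(table[[cn]])
    if (is.na(s2)) s2 <- 0
    if (sd_type == "population") s2 <- s2 * (n - 1) / n
    sqrt(s2)
  }, numeric(1))
  structure(list(columns = columns, mean = mu, sd = sigma,
                 constant = sigma == 0, sd_type = sd_type),
            class = "standardizer")
}

#' Apply fitted standardization parameters
#'
#' Transforms each fitted column to \eqn{(x' - \gamma)/\sigma}. Columns the
#' standardizer was not fitted on are untouched; zero-variance (flagged)
#' columns pass through unchanged.
#'
#' @param table Data frame to transform.
#' @param params A `"standardizer"` from [fit_standardizer()].
#' @return The transformed data frame.
#' @export
apply_standardizer <- function(table, params) {
  stopifnot(inherits(params, "standardizer"))
  missing_cols <- setdiff(params$columns, names(table))
  if (length(missing_cols) > 0) {
    stop("apply_standardizer: table lacks fitted column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (cn in params$columns) {
    if (params$constant[[cn]]) next
    table[[cn]] <- (table[[cn]] - params$mean[[cn]]) / params$sd[[cn]]
  }
  table
}

#' Label-encode categorical columns
#'
#' Maps each category to an integer by lexicographic order of the category
#' strings (first category -> 0). The category maps are stored on the result
#' (attribute `"category_maps"`) so encodings are reproducible and can be
#' re-applied to new data; an unseen category at re-apply time is an error.
#'
#' @param table Data frame.
#' @param columns Columns to encode. Defaults to all character/factor
#'   columns.
#' @param maps Optional previously fitted category maps (named list of
#'   named integer vectors) to re-apply.
#' @return Data frame with encoded integer columns and a `"category_maps"`
#'   attribute.
#' @export
encode_categoricals <- function(table, columns = NULL, maps = NULL) {
  stopifnot(is.data.frame(table))
  if (is.null(columns)) {
    columns <- names(table)[vapply(table, function(x)
      is.character(x) || is.factor(x), logical(1))]
  }
  if (is.null(maps)) {
    maps <- lapply(columns, function(cn) {
      cats <- sort(unique(as.character(table[[cn]])), method = "radix")
      stats::setNames(seq_along(cats) - 1L, cats)
    })
    names(maps) <- columns
  }
  for (cn in columns) {
    vals <- as.character(table[[cn]])
    unseen <- setdiff(unique(vals), names(maps[[cn]]))
    if (length(unseen) > 0) {
      stop("encode_categoricals: unseen category '", unseen[1],
           "' in column '", cn, "'")
    }
    table[[cn]] <- unname(maps[[cn]][vals])
  }
  attr(table, "category_maps") <- maps
  table
}

#' Split rows into train / validation / test index sets
#'
#' Draws disjoint, covering index sets with the requested fractions.
#' With `stratify = TRUE` (the default) the split is drawn within each label
#' class, so each split's positive fraction matches the global prevalence to
#' within one sample per split — important at low prevalence, where an
#' unstratified 15% split can end up with very few positives.
#'
#' @param n Number of rows, or a data frame (its `nrow` is used).
#' @param fractions Numeric length-3 vector (train, validation, test)
#'   summing to 1.
#' @param labels Optional 0/1 label vector, required when `stratify = TRUE`.
#' @param stratify Stratify on `labels`? Default `TRUE` when labels given.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with integer index vectors `train`, `validation`, `test`.
#' @export
split_dataset <- function(n, fractions = c(0.70, 0.15, 0.15), labels = NULL,
                          stratify = !is.null(labels), seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  stopifnot(length(fractions) == 3, all(fractions > 0))
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("split_dataset: fractions must sum to 1")
  }
  if (stratify && is.null(labels)) {
    stop("split_dataset: stratify = TRUE requires labels")
  }
  allocate <- function(idx, rng_perm) {
    m <- length(idx)
    perm <- idx[rng_perm]
    n_train <- round(fractions[1] * m)
    n_val <- round(fractions[2] * m)
    n_val <- min(n_val, m - n_train)
    list(train = perm[seq_len(n_train)],
         validation = perm[n_train + seq_len(n_val)],
         test = perm[n_train + n_val + seq_len(m - n_train - n_val)])
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  if (stratify) {
    classes <- sort(unique(labels))
    parts <- lapply(classes, function(cl) {
      idx <- which(labels == cl)
      allocate(idx, sample.int(length(idx)))
    })
    out <- list(
      train = sort(unlist(lapply(parts, `[[`, "train"))),
      validation = sort(unlist(lapply(parts, `[[`, "validation"))),
      test = sort(unlist(lapply(parts, `[[`, "test"))))
  } else {
    out <- allocate(seq_len(n), sample.int(n))
    out <- lapply(out, sort)
  }
  out
}

#' Pearson correlation matrix with zero-variance guard
#'
#' Standard pairwise Pearson correlations over the numeric columns. A
#' zero-variance column would make r undefined; its correlations are
#' reported as 0 (diagonal stays 1) and a warning names the column, so
#' degenerate columns are visible rather than silently dropped.
#'
#' @param table Data frame (numeric columns used).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(table) {
  stopifnot(is.data.frame(table) || is.matrix(table))
  if (is.data.frame(table)) {
    table <- table[vapply(table, is.numeric, logical(1))]
    table <- as.matrix(table)
  }
  if (nrow(table) < 2) stop("pearson_matrix: need at least 2 rows")
  sds <- apply(table, 2, stats::sd)
  const <- sds == 0
  r <- suppressWarnings(stats::cor(table))
  if (any(const)) {
    warning("pearson_matrix: zero-variance column(s): ",
            paste(colnames(table)[const], collapse = ", "),
            "; correlations reported as 0")
    r[const, ] <- 0
    r[, const] <- 0
  }
  diag(r) <- 1
  r
}

#' Downsample the majority class to a fixed ratio
#'
#' Keeps all positive (label 1) rows and draws negatives without
#' replacement until the negative:positive ratio reaches
#' `ratio_negative_to_positive` (all negatives are kept if there are fewer
#' than that). Intended as an optional rebalancing step applied after
#' splitting.
#'
#' @param labels 0/1 label vector.
#' @param ratio_negative_to_positive Target ratio; default 4 (i.e. 4
#'   negatives per positive).
#' @param seed Integer seed.
#' @return Sorted integer vector of kept row indices.
#' @export
downsample_ratio <- function(labels, ratio_negative_to_positive = 4,
                             seed = 1L) {
  stopifnot(all(labels %in% c(0, 1)))
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  if (length(pos) == 0) stop("downsample_ratio: no positive samples")
  n_keep <- min(length(neg),
                floor(ratio_negative_to_positive * length(pos)))
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  keep_neg <- if (n_keep < length(neg)) sample(neg, n_keep) else neg
  sort(c(pos, keep_neg))
}

#' Run the full preprocessing pipeline
#'
#' Applies, in order: duplicate removal, IQR outlier fencing on the named
#' continuous columns, label encoding of categorical columns, a stratified
#' train/validation/test split, and z-score standardization with parameters
#' fitted on the training split only. Outlier fencing runs on the full
#' table, before splitting.
#'
#' @param table Raw data frame including the label column.
#' @param label_column Name of the 0/1 label column.
#' @param continuous_columns Columns screened by the IQR filter and
#'   standardized.
#' @param categorical_columns Columns to label-encode (default: character /
#'   factor columns).
#' @param fractions Split fractions, default `c(0.70, 0.15, 0.15)`.
#' @param iqr_multiplier IQR fence width, default 1.5.
#' @param stratify Stratify the split on the label? Default TRUE.
#' @param seed Integer seed for the split.
#' @return List with `train`, `validation`, `test` (standardized data
#'   frames), `standardizer`, `category_maps`, `split` (index sets relative
#'   to the cleaned table), `n_duplicates_removed`, `iqr_removed`,
#'   `clean` (the cleaned, encoded, unstandardized table).
#' @export
preprocess_pipeline <- function(table, label_column,
                                continuous_columns,
                                categorical_columns = NULL,
                                fractions = c(0.70, 0.15, 0.15),
                                iqr_multiplier = 1.5,
                                stratify = TRUE,
                                seed = 1L) {
  if (!label_column %in% names(table)) {
    stop("preprocess_pipeline: missing label column '", label_column, "'")
  }
  if (anyNA(table)) stop("preprocess_pipeline: missing values in input")
  dedup <- drop_duplicates(table)
  n_dup <- attr(dedup, "n_removed")
  filt <- iqr_filter(dedup, continuous_columns, iqr_multiplier)
  enc <- encode_categoricals(filt$table, categorical_columns)
  labels <- enc[[label_column]]
  if (!all(labels %in% c(0, 1))) {
    stop("preprocess_pipeline: label column must be 0/1")
  }
  split <- split_dataset(nrow(enc), fractions, labels = labels,
                         stratify = stratify, seed = seed)
  std <- fit_standardizer(enc[split$train, , drop = FALSE],
                          continuous_columns)
  out_split <- lapply(split, function(idx) {
    apply_standardizer(enc[idx, , drop = FALSE], std)
  })
  list(train = out_split$train, validation = out_split$validation,
       test = out_split$test, standardizer = std,
       category_maps = attr(enc, "category_maps"), split = split,
       n_duplicates_removed = n_dup, iqr_removed = filt$removed,
       clean = enc)
}
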