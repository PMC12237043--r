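# Synthetic imbalanced clinical tables. Continuous features are truncated
# normals whose underlying parameters are calibrated so the POST-truncation
# mean/SD hit the requested targets; labels come from a logistic model on
# the features with the intercept calibrated to the target prevalence.

# Closed-form mean/SD of a normal(mu, sigma) truncated to [a, b].
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  Z <- stats::pnorm(be) - stats::pnorm(al)
  d <- (stats::dnorm(al) - stats::dnorm(be)) / Z
  m <- mu + sigma * d
  v <- sigma^2 * (1 + (al * stats::dnorm(al) - be * stats::dnorm(be)) / Z - d^2)
  c(mean = unname(m), sd = unname(sqrt(v)))
}

# Find underlying (mu, sigma) whose truncated moments match the targets.
calibrate_truncnorm <- function(target_mean, target_sd, a, b) {
  obj <- function(par) {
    m <- suppressWarnings(truncnorm_moments(par[1], exp(par[2]), a, b))
    if (any(!is.finite(m))) return(1e6)
    (m["mean"] - target_mean)^2 / target_sd^2 +
      (m["sd"] - target_sd)^2 / target_sd^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

rtruncnorm_n <- function(n, mu, sigma, a, b) {
  lo <- stats::pnorm(a, mu, sigma)
  hi <- stats::pnorm(b, mu, sigma)
  stats::qnorm(stats::runif(n, lo, hi), mu, sigma)
}

#' Default synthetic-data specification
#'
#' A specification emulating a large diabetes-screening table: four
#' continuous features (age, bmi, HbA1c_level, blood_glucose_level) with
#' the stated means and SDs, truncated to plausible clinical ranges; four
#' encoded categorical features (gender 0/1 balanced, rare hypertension and
#' heart_disease flags, smoking_history coded 0-4 and skewed toward 0 =
#' never smoked); and a logistic label model in which HbA1c and blood
#' glucose carry most of the signal, with the intercept calibrated at
#' generation time to the target prevalence (default 8.5% positive).
#'
#' @param n_rows Number of rows to generate, default 10000.
#' @param prevalence Target positive fraction in (0, 1), default 0.085.
#' @param effect_size Multiplier on the label-model coefficients; 0 gives a
#'   null model (labels independent of features), larger values give a more
#'   separable task. Default 1.
#' @param seed Integer seed stored on the spec.
#' @return Object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_rows = 10000, prevalence = 0.085,
                           effect_size = 1, seed = 1L) {
  stopifnot(prevalence > 0, prevalence < 1, effect_size >= 0, n_rows >= 1)
  continuous <- data.frame(
    name = c("age", "bmi", "HbA1c_level", "blood_glucose_level"),
    mean = c(46.5441, 28.4241, 5.5643, 139.6282),
    sd = c(19.5403, 6.5162, 1.0955, 42.1659),
    lower = c(18, 12, 3.5, 70),
    upper = c(90, 60, 9.0, 300),
    stringsAsFactors = FALSE)
  categorical <- list(
    gender = c("0" = 0.5, "1" = 0.5),
    hypertension = c("0" = 0.92, "1" = 0.08),
    heart_disease = c("0" = 0.96, "1" = 0.04),
    smoking_history = c("0" = 0.60, "1" = 0.10, "2" = 0.15, "3" = 0.10,
                        "4" = 0.05))
  # Coefficients act on standardized continuous features and raw category
  # codes; glycemic markers dominate, demographics contribute weakly.
  coefficients <- c(age = 0.30, bmi = 0.30, HbA1c_level = 1.20,
                    blood_glucose_level = 1.00, gender = 0.10,
                    hypertension = 0.40, heart_disease = 0.40,
                    smoking_history = 0.15) * effect_size
  structure(list(n_rows = as.integer(n_rows), prevalence = prevalence,
                 continuous = continuous, categorical = categorical,
                 coefficients = coefficients, effect_size = effect_size,
                 label_column = "diabetes", seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Rescale a specification's label-model signal strength
#'
#' Multiplies the label-model coefficients by `effect_size` relative to the
#' unit-effect baseline, so Bayes-optimal discriminability grows
#' monotonically with `effect_size`; 0 removes all signal (null model).
#'
#' @param spec A `"synthetic_spec"`.
#' @param effect_size Nonnegative multiplier.
#' @return The modified spec.
#' @export
plant_separability <- function(spec, effect_size) {
  stopifnot(inherits(spec, "synthetic_spec"), effect_size >= 0)
  base <- if (spec$effect_size > 0) {
    spec$coefficients / spec$effect_size
  } else {
    synthetic_spec(effect_size = 1)$coefficients
  }
  spec$coefficients <- base * effect_size
  spec$effect_size <- effect_size
  spec
}

#' Generate a synthetic imbalanced table from a specification
#'
#' Features are drawn independently (matching the near-zero pairwise
#' correlations typical of screening tables): truncated normals for the
#' continuous features, with underlying parameters calibrated so the
#' post-truncation mean/SD match the spec, and categorical draws for the
#' rest. Labels are Bernoulli under a logistic model; the intercept is
#' found by bisection against the realized draws so the empirical
#' prevalence lands within half a percentage point of target (exact to
#' 1/n). With all-zero coefficients the labels are independent coin flips
#' at the target prevalence.
#'
#' @param spec A `"synthetic_spec"`.
#' @param seed Optional seed overriding the one stored on the spec.
#' @return Data frame with the 8 feature columns and the 0/1 label column
#'   (named by `spec$label_column`). The calibrated intercept is attached
#'   as attribute `"intercept"`.
#' @export
generate_synthetic <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seed <- seed %||% spec$seed
  n <- spec$n_rows
  old <- local_seed(derive_seed(seed, "generate"))
  on.exit(restore_seed(old), add = TRUE)
  cols <- list()
  for (i in seq_len(nrow(spec$continuous))) {
    cc <- spec$continuous[i, ]
    par <- calibrate_truncnorm(cc$mean, cc$sd, cc$lower, cc$upper)
    cols[[cc$name]] <- rtruncnorm_n(n, par["mu"], par["sigma"],
                                    cc$lower, cc$upper)
  }
  for (nm in names(spec$categorical)) {
    probs <- spec$categorical[[nm]]
    cols[[nm]] <- as.numeric(names(probs))[
      sample.int(length(probs), n, replace = TRUE, prob = probs)]
  }
  df <- as.data.frame(cols)
  df <- df[, c("gender", "age", "hypertension", "heart_disease",
               "smoking_history", "bmi", "HbA1c_level",
               "blood_glucose_level")]
  # Linear predictor on standardized continuous / raw categorical scale.
  eta <- rep(0, n)
  for (nm in names(spec$coefficients)) {
    b <- spec$coefficients[[nm]]
    if (b == 0) next
    x <- df[[nm]]
    row <- match(nm, spec$continuous$name)
    if (!is.na(row)) {
      x <- (x - spec$continuous$mean[row]) / spec$continuous$sd[row]
    }
    eta <- eta + b * x
  }
  u <- stats::runif(n)
  # Row i turns positive once b0 exceeds qlogis(u_i) - eta_i, so the
  # intercept that yields exactly k = round(n * prevalence) positives sits
  # between the k-th and (k+1)-th order statistics of those thresholds.
  thresh <- sort(stats::qlogis(u) - eta)
  if (any(!is.finite(thresh))) {
    stop("generate_synthetic: prevalence not reachable; degenerate coefficients")
  }
  k <- max(1L, round(n * spec$prevalence))
  b0 <- if (k < n) (thresh[k] + thresh[k + 1]) / 2 else thresh[n] + 1
  df[[spec$label_column]] <- as.integer(u < stats::plogis(b0 + eta))
  attr(df, "intercept") <- b0
  df
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic imbalanced-table spec\n")
  cat("  rows:        ", x$n_rows, "\n", sep = "")
  cat("  prevalence:  ", x$prevalence, "\n", sep = "")
  cat("  effect size: ", x$effect_size, "\n", sep = "")
  cat("  features:    ", paste(c(x$continuous$name,
                                 names(x$categorical)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Serialize / restore a synthetic specification as JSON
#'
#' @param spec A `"synthetic_spec"`.
#' @param path File path to write to / read from.
#' @return `spec_to_json` invisibly returns the path; `spec_from_json`
#'   returns the restored spec.
#' @export
spec_to_json <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  obj <- unclass(spec)
  # atomic-vector names do not survive JSON serialization; use objects
  obj$coefficients <- as.list(obj$coefficients)
  obj$categorical <- lapply(obj$categorical, as.list)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname spec_to_json
#' @export
spec_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$categorical <- lapply(raw$categorical, unlist)
  raw$coefficients <- unlist(raw$coefficients)
  raw$n_rows <- as.integer(raw$n_rows)
  raw$seed <- as.integer(raw$seed)
  structure(raw, class = "synthetic_spec")
}
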