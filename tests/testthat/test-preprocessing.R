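test_that("duplicate rows reduce to first occurrence, preserving order", {
  df <- data.frame(a = c(1, 1, 2), b = c("x", "x", "y"))
  out <- drop_duplicates(df)
  expect_equal(out$a, c(1, 2))
  expect_equal(attr(out, "n_removed"), 1L)

  distinct <- data.frame(a = 1:3, b = c("p", "q", "r"))
  expect_equal(drop_duplicates(distinct)$a, 1:3)

  interleaved <- data.frame(a = c(1, 2, 1, 2, 1), b = c("A", "B", "A", "B", "A"))
  out2 <- drop_duplicates(interleaved)
  expect_equal(out2$a, c(1, 2))
  expect_equal(attr(out2, "n_removed"), 3L)

  # idempotence
  expect_equal(drop_duplicates(out2)$a, out2$a)
})

test_that("IQR fences remove a planted outlier and nothing else", {
  x <- c(1:100, 1000)
  df <- data.frame(v = x)
  res <- iqr_filter(df, "v")
  # independent fence computation: type-7 interpolated quartiles by hand
  h <- function(p) {
    k <- (length(x) - 1) * p + 1
    lo <- floor(k)
    sort(x)[lo] + (k - lo) * (sort(x)[lo + 1 - (k == lo)] - sort(x)[lo])
  }
  q1 <- h(0.25); q3 <- h(0.75); iqr <- q3 - q1
  expect_true(1000 > q3 + 1.5 * iqr)
  expect_true(all(1:100 >= q1 - 1.5 * iqr & 1:100 <= q3 + 1.5 * iqr))
  expect_equal(res$removed, 101L)
  expect_equal(nrow(res$table), 100)

  # constant column: fences collapse onto the constant, nothing removed
  cst <- data.frame(v = rep(5, 10))
  expect_length(iqr_filter(cst, "v")$removed, 0)

  # everything inside: identity
  inside <- data.frame(v = c(10, 11, 12, 13))
  expect_length(iqr_filter(inside, "v")$removed, 0)

  expect_error(iqr_filter(df, "nope"), "nope")
})

test_that("filtered output respects the fences computed on its input", {
  set.seed(42)
  for (r in 1:5) {
    df <- data.frame(a = rt(200, df = 2), b = rnorm(200))
    res <- iqr_filter(df, c("a", "b"))
    for (cn in c("a", "b")) {
      expect_true(all(res$table[[cn]] >= res$bounds["lower", cn]))
      expect_true(all(res$table[[cn]] <= res$bounds["upper", cn]))
    }
  }
})

test_that("standardizer uses the population SD convention and flags constants", {
  df <- data.frame(a = c(2, 4), b = c(7, 7))
  s <- fit_standardizer(df, c("a", "b"))
  expect_equal(unname(s$mean["a"]), 3)
  expect_equal(unname(s$sd["a"]), 1)  # n-denominator: sqrt(((2-3)^2+(4-3)^2)/2)
  expect_true(s$constant[["b"]])
  out <- apply_standardizer(df, s)
  expect_equal(out$a, c(-1, 1))
  expect_equal(out$b, c(7, 7))  # constant column passes through

  s2 <- fit_standardizer(df, c("a", "b"), sd_type = "sample")
  expect_equal(unname(s2$sd["a"]), sqrt(2))

  expect_error(fit_standardizer(df[0, ], "a"), "empty")
})

test_that("z-scoring maps the mean to 0, mean+sd to 1, and a clinical age case to 1", {
  s <- structure(list(columns = "age", mean = c(age = 46.5441),
                      sd = c(age = 19.5403), constant = c(age = FALSE),
                      sd_type = "population"), class = "standardizer")
  df <- data.frame(age = c(46.5441, 46.5441 + 19.5403, 66.0844))
  out <- apply_standardizer(df, s)
  expect_equal(out$age[1], 0)
  expect_equal(out$age[2], 1)
  expect_equal(out$age[3], 1.0, tolerance = 1e-6)
  expect_error(apply_standardizer(data.frame(x = 1), s), "age")
})

test_that("standardized training columns have mean 0 and unit SD within 1e-9", {
  set.seed(7)
  df <- data.frame(a = rnorm(50, 10, 3), b = runif(50, 0, 100))
  s <- fit_standardizer(df, c("a", "b"))
  out <- apply_standardizer(df, s)
  n <- nrow(df)
  for (cn in c("a", "b")) {
    expect_lt(abs(mean(out[[cn]])), 1e-9)
    expect_lt(abs(sqrt(mean((out[[cn]] - mean(out[[cn]]))^2)) - 1), 1e-9)
  }
})

test_that("label encoding is lexicographic and rejects unseen categories", {
  df <- data.frame(gender = c("Female", "Male", "Female"),
                   smoking = c("c", "a", "b"))
  out <- encode_categoricals(df)
  expect_equal(out$gender, c(0, 1, 0))
  expect_equal(out$smoking, c(2, 0, 1))
  maps <- attr(out, "category_maps")
  expect_equal(maps$smoking, c(a = 0L, b = 1L, c = 2L))

  # already-integer columns untouched
  df2 <- data.frame(k = c(3L, 1L))
  expect_equal(encode_categoricals(df2)$k, c(3L, 1L))

  expect_error(
    encode_categoricals(data.frame(gender = "Other"), "gender",
                        maps = maps["gender"]),
    "Other")
})

test_that("splits have the requested sizes and partition the rows", {
  sp <- split_dataset(1000, seed = 3, stratify = FALSE)
  expect_length(sp$train, 700)
  expect_length(sp$validation, 150)
  expect_length(sp$test, 150)
  expect_setequal(c(sp$train, sp$validation, sp$test), 1:1000)

  sp2 <- split_dataset(1000, seed = 3, stratify = FALSE)
  expect_identical(sp, sp2)  # determinism

  for (seed in 1:5) {
    n <- 97
    sp3 <- split_dataset(n, seed = seed, stratify = FALSE)
    all_idx <- unlist(sp3)
    expect_length(all_idx, n)
    expect_setequal(all_idx, seq_len(n))
  }
  expect_error(split_dataset(10, fractions = c(0.5, 0.3, 0.3)), "sum to 1")
})

test_that("stratified splits hold the class fraction within one sample", {
  y <- rep(c(1, 0), times = c(10, 90))
  sp <- split_dataset(100, labels = y, seed = 11)
  expect_setequal(unlist(sp), 1:100)
  for (part in sp) {
    expected <- 0.10 * length(part)
    expect_lte(abs(sum(y[part]) - expected), 1)
  }
})

test_that("Pearson matrix matches hand-computed r and guards zero variance", {
  df <- data.frame(x = c(1, 2, 3), y = c(1, 2, 4), z = c(3, 2, 1))
  r <- pearson_matrix(df)
  expect_equal(diag(r), c(x = 1, y = 1, z = 1))
  expect_equal(r["x", "z"], -1)
  # hand: cov = 1.5, sd_x = 1, sd_y = sqrt(7/3) => r = 1.5/sqrt(7/3)
  expect_equal(r["x", "y"], 1.5 / (1 * sqrt(7 / 3)), tolerance = 1e-12)
  expect_equal(round(r["x", "y"], 4), 0.9820)
  expect_equal(r, t(r))

  dfc <- data.frame(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(rc <- pearson_matrix(dfc), "zero-variance")
  expect_equal(rc["a", "b"], 0)
  expect_equal(rc["b", "b"], 1)
})

test_that("ratio downsampling keeps all positives and is seeded", {
  y <- rep(c(0, 1), times = c(100, 10))
  keep <- downsample_ratio(y, 4, seed = 2)
  expect_equal(sum(y[keep] == 1), 10)
  expect_equal(sum(y[keep] == 0), 40)
  expect_identical(keep, downsample_ratio(y, 4, seed = 2))

  # fewer negatives than the ratio allows: all kept
  y2 <- rep(c(0, 1), times = c(3, 10))
  expect_length(downsample_ratio(y2, 4, seed = 1), 13)
  expect_error(downsample_ratio(rep(0, 5)), "positive")
})

test_that("pipeline orders dedup, fences, encoding, split and standardization", {
  set.seed(5)
  n <- 300
  df <- data.frame(
    gender = sample(c("F", "M"), n, replace = TRUE),
    age = rnorm(n, 50, 10),
    marker = rnorm(n, 5, 1),
    diabetes = rbinom(n, 1, 0.3))
  df$age[1] <- 1e4  # planted outlier
  df <- rbind(df, df[2, ])  # planted duplicate
  pp <- preprocess_pipeline(df, "diabetes", c("age", "marker"), seed = 9)
  expect_equal(pp$n_duplicates_removed, 1L)
  expect_true(1 %in% pp$iqr_removed)
  expect_lt(abs(mean(pp$train$age)), 1e-9)
  expect_true(all(pp$train$gender %in% c(0, 1)))
  expect_setequal(unlist(pp$split), seq_len(nrow(pp$clean)))
  expect_error(preprocess_pipeline(df, "missing_label", "age"), "label")
})
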