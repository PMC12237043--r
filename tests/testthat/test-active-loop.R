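test_that("classifier registry fits, predicts probabilities, and validates input", {
  d <- make_separable_data(n = 80, seed = 3)
  m <- train_classifier("logistic", d$X, d$y)
  expect_equal(predict_class(m, d$X), d$y)  # separable: perfect training fit
  p <- predict_prob(m, d$X)
  expect_true(all(p >= 0 & p <= 1))

  expect_error(train_classifier("oracle_of_delphi", d$X, d$y), "unknown")
  expect_error(train_classifier("logistic", d$X, rep(1, 80)), "class")
})

test_that("every backend returns calibrated-range probabilities", {
  d <- make_separable_data(n = 60, p = 3, sep = 4, seed = 5)
  for (clf in c("logistic", "svm_linear", "svm_rbf", "decision_tree",
                "random_forest", "gradient_boosting", "naive_bayes",
                "mlp")) {
    m <- train_classifier(clf, d$X, d$y, seed = 1,
                          params = list(ntree = 50, nrounds = 20, size = 3,
                                        maxit = 50))
    p <- predict_prob(m, d$X)
    expect_length(p, 60)
    expect_true(all(p >= 0 & p <= 1), label = clf)
    acc <- mean(as.integer(p >= 0.5) == d$y)
    expect_gt(acc, 0.8)
  }
})

test_that("balanced class weights raise minority recall on imbalanced data", {
  set.seed(17)
  n <- 600
  y <- rbinom(n, 1, 0.1)
  X <- matrix(rnorm(n * 3), n, 3)
  X[y == 1, 1] <- X[y == 1, 1] + 1.5  # weak signal: errors inevitable
  bal <- train_classifier("logistic", X, y, class_weight = "balanced",
                          seed = 1)
  unw <- train_classifier("logistic", X, y, class_weight = "none", seed = 1)
  rec <- function(m) metrics(confusion_counts(y, predict_class(m, X)))$recall
  expect_gt(rec(bal), rec(unw))
})

test_that("grid search scores by CV F1 with first-point tie-breaking", {
  d <- make_separable_data(n = 60, sep = 5, seed = 8)
  single <- tune_hyperparameters("decision_tree", d$X, d$y,
                                 grid = list(list(cp = 0.01)), seed = 2)
  expect_equal(single$best_params, list(cp = 0.01))

  # cp = 1 forbids any split -> constant tree -> F1 = 0; cp = 0.01 dominates
  two <- tune_hyperparameters("decision_tree", d$X, d$y,
                              grid = list(list(cp = 1), list(cp = 0.01)),
                              seed = 2)
  expect_equal(two$best_params, list(cp = 0.01))
  expect_gt(two$best_score, two$scores[1])

  again <- tune_hyperparameters("decision_tree", d$X, d$y,
                                grid = list(list(cp = 1), list(cp = 0.01)),
                                seed = 2)
  expect_identical(two$scores, again$scores)
  expect_error(tune_hyperparameters("logistic", d$X, d$y, grid = list()),
               "empty")
})

test_that("the label oracle counts queries and refuses repeats", {
  o <- label_oracle(c(1, 0, 1, 0))
  expect_equal(o$answer(c(2, 3)), c(0, 1))
  expect_equal(o$query_count(), 2L)
  expect_error(o$answer(2), "twice")
  expect_equal(o$query_count(), 2L)
})

test_that("the loop stops at the stated budget with 2 x foci batches", {
  set.seed(1)
  d <- standardize_synth(generate_synthetic(synthetic_spec(n_rows = 1000,
                                                           seed = 6)))
  X <- as.matrix(d[setdiff(names(d), "diabetes")])
  res <- run_focal_active_learning(X, label_oracle(d$diabetes),
                                   fal_config(k_foci = 40, batch_size = 80,
                                              target_fraction = 0.20,
                                              seed = 2))
  expect_equal(length(res$labeled), 200)  # 20% of 1000
  expect_equal(max(res$history$iteration), 2)  # ceil((200 - 40)/80)
  expect_equal(res$history$batch, c(40, 80, 80))
})

test_that("a budget equal to the focus count runs zero batch iterations", {
  d <- make_separable_data(n = 100, seed = 12)
  res <- run_focal_active_learning(d$X, label_oracle(d$y),
                                   fal_config(k_foci = 20,
                                              target_fraction = 0.20,
                                              seed = 3))
  expect_equal(max(res$history$iteration), 0)
  expect_length(res$labeled, 20)
  expect_setequal(res$labeled, res$focus_set$foci)
})

test_that("pool state stays a partition and queries equal the labeled size", {
  d <- standardize_synth(generate_synthetic(synthetic_spec(n_rows = 600,
                                                           seed = 13)))
  X <- as.matrix(d[setdiff(names(d), "diabetes")])
  oracle <- label_oracle(d$diabetes)
  res <- run_focal_active_learning(X, oracle,
                                   fal_config(k_foci = 15, seed = 4))
  expect_length(intersect(res$labeled, res$unlabeled), 0)
  expect_setequal(c(res$labeled, res$unlabeled), seq_len(600))
  expect_equal(oracle$query_count(), length(res$labeled))
  expect_true(all(diff(res$history$n_labeled) > 0))
  expect_equal(anyDuplicated(res$labeled), 0)
})

test_that("ablation flags disable importance weighting but keep the budget", {
  d <- standardize_synth(generate_synthetic(synthetic_spec(n_rows = 500,
                                                           seed = 19)))
  X <- as.matrix(d[setdiff(names(d), "diabetes")])
  res <- run_focal_active_learning(
    X, label_oracle(d$diabetes),
    fal_config(k_foci = 12, seed = 5, disable_shap_weighting = TRUE,
               disable_attention = TRUE))
  expect_true(all(res$importance_history == 1))
  expect_equal(length(res$labeled), ceiling(0.2 * 500))
})

test_that("fitting is deterministic under the seed, via formula or matrix", {
  d <- standardize_synth(generate_synthetic(synthetic_spec(n_rows = 400,
                                                           seed = 23)))
  f1 <- fal(diabetes ~ ., data = d, k_foci = 10, seed = 7)
  f2 <- fal(diabetes ~ ., data = d, k_foci = 10, seed = 7)
  expect_identical(f1$labeled, f2$labeled)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$importance, f2$importance)

  X <- as.matrix(d[setdiff(names(d), "diabetes")])
  f3 <- fal(X, d$diabetes, k_foci = 10, seed = 7)
  expect_identical(sort(f1$labeled), sort(f3$labeled))
  expect_equal(unname(coef(f1)), unname(f3$importance))

  p <- predict(f1, d[1:5, ])
  expect_length(p, 5)
  expect_true(all(p >= 0 & p <= 1))
  cls <- predict(f1, d[1:5, ], type = "class")
  expect_true(all(cls %in% c(0, 1)))
})

test_that("random acquisition runs at the same budget for baseline comparisons", {
  d <- standardize_synth(generate_synthetic(synthetic_spec(n_rows = 400,
                                                           seed = 29)))
  X <- as.matrix(d[setdiff(names(d), "diabetes")])
  res <- run_focal_active_learning(X, label_oracle(d$diabetes),
                                   fal_config(k_foci = 10,
                                              acquisition = "random",
                                              seed = 8))
  expect_length(res$labeled, ceiling(0.2 * 400))
  expect_null(res$focus_set)
})

test_that("print and summary surface the fit without error", {
  d <- make_separable_data(n = 100, seed = 31)
  colnames(d$X) <- c("f1", "f2", "f3")
  fit <- fal(d$X, d$y, k_foci = 10, target_fraction = 0.3, seed = 9)
  expect_output(print(fit), "Focal active learning")
  expect_output(print(summary(fit)), "importances")
})
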