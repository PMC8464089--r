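# tiny separable two-class feature matrix: class means 10 SDs apart
separable_matrix <- function(n_per_class = 20, seed = 1) {
  set.seed(seed)
  labels <- rep(c("p", "q"), each = n_per_class)
  x <- data.frame(f1 = rnorm(2 * n_per_class) +
                    ifelse(labels == "q", 10, 0),
                  f2 = rnorm(2 * n_per_class),
                  check.names = FALSE)
  list(x = x, labels = labels)
}

small_spec <- function(kind) {
  grid <- switch(kind, mlp = data.frame(hidden = c(2, 5)),
                 svm_linear = data.frame(cost = c(0.1, 1)),
                 svm_rbf = expand.grid(gamma = c(0.01, 0.1),
                                       cost = c(1, 10)))
  classifier_spec(kind, grid)
}

test_that("fully separated classes reach 100% for all three classifiers", {
  d <- separable_matrix()
  for (kind in c("mlp", "svm_linear", "svm_rbf")) {
    acc <- nested_cv_accuracy(d$x, d$labels, small_spec(kind), seed = 2)
    expect_equal(as.numeric(acc), 100, info = kind)
  }
})

test_that("nested CV is reproducible and respects its preconditions", {
  d <- separable_matrix()
  a1 <- nested_cv_accuracy(d$x, d$labels, small_spec("svm_linear"), seed = 7)
  a2 <- nested_cv_accuracy(d$x, d$labels, small_spec("svm_linear"), seed = 7)
  expect_identical(a1, a2)
  expect_error(nested_cv_accuracy(d$x[1:25, ], d$labels[1:25],
                                  small_spec("svm_linear")),
               "at least 10")
  expect_error(nested_cv_accuracy(d$x, d$labels, "svm_linear",
                                  feature_subset = "nope"), "unknown feature")
})

test_that("stratified folds keep class proportions within one instance", {
  labels <- factor(rep(c("a", "b", "c"), times = c(40, 25, 12)))
  folds <- eegrhythms:::stratified_folds(labels, 10, seed = 3)
  expect_length(unlist(folds), length(labels))
  expect_false(anyDuplicated(unlist(folds)) > 0)
  for (cl in levels(labels)) {
    per_fold <- vapply(folds, function(f) sum(labels[f] == cl), integer(1))
    expect_lte(max(per_fold) - min(per_fold), 1L)
  }
})

test_that("the tanh MLP fits a nonlinear (XOR) boundary", {
  set.seed(11)
  x <- cbind(a = c(rnorm(30, 0, 0.5), rnorm(30, 3, 0.5),
                   rnorm(30, 0, 0.5), rnorm(30, 3, 0.5)),
             b = c(rnorm(30, 0, 0.5), rnorm(30, 3, 0.5),
                   rnorm(30, 3, 0.5), rnorm(30, 0, 0.5)))
  y <- rep(c("u", "u", "v", "v"), each = 30)   # XOR layout, not separable
  model <- eegrhythms:::mlp_fit(x, y, hidden = 8, seed = 5)
  expect_gt(mean(predict(model, x) == y), 0.95)
  expect_setequal(levels(predict(model, x)), c("u", "v"))
})

test_that("the MLP is a single tanh hidden layer with softmax output", {
  set.seed(3)
  x <- matrix(rnorm(40), 20, 2)
  y <- rep(c("u", "v"), 10)
  model <- eegrhythms:::mlp_fit(x, y, hidden = 4, seed = 1)
  p <- model$par
  expect_equal(dim(p$w1), c(2, 4))     # one hidden layer of 4 units
  expect_equal(dim(p$w2), c(4, 2))
  # manual tanh forward pass reproduces the model's decisions exactly
  scores <- sweep(tanh(sweep(x %*% p$w1, 2, p$b1, "+")) %*% p$w2, 2,
                  p$b2, "+")
  manual <- model$levels[max.col(scores, ties.method = "first")]
  expect_identical(as.character(predict(model, x)), manual)
})

test_that("sequential curve finds the optimal point contract", {
  d <- separable_matrix()
  # make f2 weakly informative so the curve is non-trivial
  r <- relieff_rank(d$x, d$labels, k_neighbors = 5)
  cv <- sequential_curve(d$x, d$labels, small_spec("svm_linear"),
                         ranking = r, seed = 3)
  expect_length(cv$accuracy, 2)
  expect_equal(cv$optimal_accuracy, max(cv$accuracy))
  expect_identical(cv$optimal_n,
                   which(cv$accuracy == max(cv$accuracy))[1])
  expect_equal(cv$all_features_accuracy, cv$accuracy[2])
  # a perfectly informative top feature already classifies at n = 1
  expect_equal(cv$accuracy[1], 100)
})

test_that("foldwise ranking never sees the held-out fold (canary)", {
  set.seed(23)
  n <- 60
  labels <- rep(c("p", "q"), each = n / 2)
  seed <- 17
  folds <- eegrhythms:::stratified_folds(
    labels, 5, eegrhythms:::derive_seed(seed, 1))
  canary <- as.numeric(seq_len(n) %in% folds[[1]])
  x <- data.frame(sig = as.numeric(labels == "q") + rnorm(n, sd = 0.3),
                  canary = canary, check.names = FALSE)
  cv <- sequential_curve(x, labels, small_spec("svm_linear"), seed = seed,
                         ranking_mode = "foldwise", outer_folds = 5,
                         inner_folds = 5, k_neighbors = 3)
  # on fold 1's training part the canary is constant -> zero ReliefF weight
  expect_identical(unname(cv$fold_rankings[[1]]$weights["canary"]), 0)
  expect_identical(cv$fold_rankings[[1]]$order[1], "sig")
})

test_that("problem definitions map Bonn classes onto groups", {
  probs <- problem_definitions()
  expect_length(probs, 5)
  p <- problem_definitions("ABCD/E")[[1]]
  expect_identical(unname(p$map[c("A", "D", "E")]),
                   c("ABCD", "ABCD", "E"))
  y <- eegrhythms:::apply_problem(c("A", "C", "E", "B"), p)
  expect_identical(as.character(y), c("ABCD", "ABCD", "E", "ABCD"))
  pd <- problem_definitions("A/E")[[1]]
  expect_true(is.na(eegrhythms:::apply_problem("C", pd)))
  expect_error(problem_definitions("AE"), "two groups")
  expect_error(problem_definitions("A/AE"), "more than one group")
})

test_that("the problem suite reports curves, top features and both modes", {
  spec <- synthetic_corpus_spec(segments_per_class = 12, n_samples = 256,
                                seed = 31)
  fm <- extract_feature_matrix(generate_bonn_mimic(spec))
  rep <- run_problem_suite(fm, problems = problem_definitions(c("A/E", "D/E")),
                           classifiers = list(small_spec("svm_linear")),
                           seed = 3, k_neighbors = 5, n_max = 2,
                           outer_folds = 4, inner_folds = 3)
  expect_s3_class(rep, "suite_report")
  expect_length(rep$curves, 2)
  expect_length(rep$top5[["A/E"]], 5)
  expect_equal(nrow(rep$summary), 2)
  expect_true(all(rep$summary$accuracy_with_selection >= 0 &
                    rep$summary$accuracy_with_selection <= 100))
})
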