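# small, well-separated three-class blobs for protocol tests
make_blobs <- function(n_per = 20, shift = 6, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(shift, 0), c(0, shift))
  x <- do.call(rbind, lapply(1:3, function(i)
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))))
  list(x = x, y = rep(c("dog", "fox", "wolf"), each = n_per))
}

test_that("stratified bootstrap draws only input rows, preserving proportions", {
  b <- make_blobs(seed = 71)
  out <- stratified_bootstrap(b$x, b$y, n_out = 60, seed = 1)
  expect_equal(nrow(out$x), 60L)
  # closure: every output row is one of the input rows
  key <- apply(b$x, 1, paste, collapse = "|")
  expect_true(all(apply(out$x, 1, paste, collapse = "|") %in% key))
  # stratification within one sample of the target
  expect_true(all(abs(table(out$y) - 20) <= 1))
  # origin bookkeeping is consistent
  expect_equal(out$x, b$x[out$origin, ], ignore_attr = TRUE)
  expect_identical(out$y, b$y[out$origin])

  # determinism
  out2 <- stratified_bootstrap(b$x, b$y, n_out = 60, seed = 1)
  expect_identical(out, out2)

  expect_error(stratified_bootstrap(b$x[0, ], character(0)), "non-empty")
})

test_that("the 70:30 split is stratified, disjoint and exhaustive", {
  b <- make_blobs(n_per = 34, seed = 72)
  b$x <- b$x[1:100, ]; b$y <- b$y[1:100]  # n = 100, classes 34/34/32
  sp <- train_test_split(b$x, b$y, 0.70, seed = 2)
  expect_equal(length(sp$train$y), 70L)
  expect_equal(length(sp$test$y), 30L)
  expect_length(intersect(sp$train$idx, sp$test$idx), 0)
  expect_setequal(c(sp$train$idx, sp$test$idx), 1:100)
  for (cl in unique(b$y)) {
    n_cl <- sum(b$y == cl)
    expect_lte(abs(sum(sp$train$y == cl) - 0.7 * n_cl), 1)
  }
  expect_error(train_test_split(b$x[1:3, ], c("a", "a", "b")),
               "at least 2")
})

test_that("the RBF kernel matches its closed form", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), 3), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 1), 0.5), exp(-1), tolerance = 1e-12)
  expect_equal(rbf_kernel(c(0, 3), c(4, 0), 1e-9), 1, tolerance = 1e-6)
  expect_error(rbf_kernel(1:3, 1:2, 1), "equal length")
  expect_error(rbf_kernel(1:2, 2:3, 0), "positive")
})

test_that("random search is deterministic and degenerates gracefully", {
  b <- make_blobs(seed = 73)
  c1 <- random_search_svm(b$x, b$y, n_iter = 5, k = 3, seed = 4)
  c2 <- random_search_svm(b$x, b$y, n_iter = 5, k = 3, seed = 4)
  expect_identical(c1[c("cost", "gamma")], c2[c("cost", "gamma")])

  single <- random_search_svm(b$x, b$y, n_iter = 1, k = 3, seed = 5)
  expect_true(single$cost > 0 && single$gamma > 0)

  expect_error(random_search_svm(b$x, b$y, n_iter = 0, k = 3), "at least 1")
  expect_error(random_search_svm(b$x, b$y, n_iter = 2, k = 25, seed = 1),
               "exceeds")
})

test_that("grouped folds keep bootstrap duplicates together", {
  b <- make_blobs(n_per = 12, seed = 74)
  boot <- stratified_bootstrap(b$x, b$y, n_out = 120, seed = 6)
  cfg <- random_search_svm(boot$x, boot$y, n_iter = 3, k = 4, seed = 7,
                           groups = boot$origin)
  expect_s3_class(cfg, "svm_config")
  # with only 2 distinct specimens per class, k = 4 must be refused
  tiny <- list(x = b$x[c(1:2, 13:14, 25:26), ], y = b$y[c(1:2, 13:14, 25:26)])
  boot2 <- stratified_bootstrap(tiny$x, tiny$y, n_out = 60, seed = 8)
  expect_error(random_search_svm(boot2$x, boot2$y, n_iter = 2, k = 4,
                                 seed = 9, groups = boot2$origin),
               "distinct")
})

test_that("the SVM separates blobs, ignores duplication, and solves XOR", {
  b <- make_blobs(seed = 75)
  cfg <- list(cost = 100, gamma = 0.1)
  fit <- train_svm(b$x, b$y, cfg)
  expect_equal(mean(as.character(predict(fit, b$x)) == b$y), 1)

  # duplicating every training row leaves predictions unchanged
  fit_dup <- train_svm(rbind(b$x, b$x), c(b$y, b$y), cfg)
  grid <- as.matrix(expand.grid(seq(-2, 8, 1), seq(-2, 8, 1)))
  expect_identical(as.character(predict(fit, grid)),
                   as.character(predict(fit_dup, grid)))

  # XOR arrangement needs the non-linear boundary
  xor_x <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  xor_x <- xor_x[rep(1:4, each = 5), ] + matrix(rnorm(40, 0, 0.05), 20, 2)
  xor_y <- rep(c("a", "a", "b", "b"), each = 5)
  fit_xor <- train_svm(xor_x, xor_y, list(cost = 1000, gamma = 2),
                       scale_features = FALSE)
  expect_equal(mean(as.character(predict(fit_xor, xor_x)) == xor_y), 1)

  expect_error(train_svm(b$x[1:20, ], b$y[1:20], cfg), "single class")
})

test_that("evaluation metrics match hand-computed oracle values", {
  # perfect prediction
  perfect <- classification_metrics(c("dog", "fox", "wolf"),
                                    c("dog", "fox", "wolf"))
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$balanced_accuracy, 1)
  expect_equal(perfect$mse, 0)

  # binary confusion [[45, 5], [10, 40]]: p_o = 0.85, p_e = 0.50, kappa = 0.70
  y_true <- rep(c("a", "b"), c(50, 50))
  y_pred <- c(rep("a", 45), rep("b", 5), rep("a", 10), rep("b", 40))
  r <- classification_metrics(y_true, y_pred)
  expect_equal(unclass(r$confusion), matrix(c(45, 10, 5, 40), 2),
               ignore_attr = TRUE)
  expect_equal(r$kappa, 0.70, tolerance = 1e-12)

  # squared-error loss on integer codes: true (0,1,2), predicted (0,1,0)
  r2 <- classification_metrics(c("dog", "fox", "wolf"),
                               c("dog", "fox", "dog"))
  expect_equal(r2$mse, 4 / 3, tolerance = 1e-12)

  # Clopper-Pearson interval matches binom.test
  ci <- stats::binom.test(85, 100)$conf.int
  expect_equal(c(r$ci_low, r$ci_high), as.numeric(ci), tolerance = 1e-12)
})

test_that("evaluation refuses labels never seen in training", {
  b <- make_blobs(seed = 76)
  fit <- train_svm(b$x, b$y, list(cost = 10, gamma = 0.5))
  expect_error(evaluate_classifier(fit, b$x[1:2, ], c("dog", "bear")),
               "not seen")
  expect_error(evaluate_classifier(fit, b$x[0, ], character(0)), "empty")
})

test_that("training-time benchmarking reports coherent summaries", {
  b <- make_blobs(n_per = 10, seed = 77)
  cfg <- list(cost = 10, gamma = 0.5)
  one <- benchmark_training(b$x, b$y, cfg, n_rep = 1)
  expect_length(attr(one, "times_ms"), 1L)
  many <- benchmark_training(b$x, b$y, cfg, n_rep = 10)
  expect_lte(as.numeric(many), max(attr(many, "times_ms")))
  expect_gte(as.numeric(many), 0)
})
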