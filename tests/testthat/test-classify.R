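test_that("separable classes train error-free and predict deterministically", {
  d <- toy_classes(n_per_class = 15, k = 2, sep = 10, seed = 1)
  m <- ova_svm(d$x, d$y, svm_spec("linear"))
  p1 <- predict(m, d$x)
  p2 <- predict(m, d$x)
  expect_identical(p1, p2)
  expect_equal(mean(p1 != d$y), 0)
  dec <- predict(m, d$x, type = "decision")
  expect_equal(dim(dec), c(nrow(d$x), 2))
})

test_that("XOR geometry defeats the linear kernel but not the Gaussian", {
  set.seed(2)
  centers <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  lab <- c("a", "a", "b", "b")
  x <- NULL; y <- NULL
  for (i in 1:4) {
    x <- rbind(x, sweep(matrix(rnorm(30, sd = 0.05), ncol = 2), 2,
                        centers[i, ], "+"))
    y <- c(y, rep(lab[i], 15))
  }
  lin_err <- mean(predict(ova_svm(x, y, svm_spec("linear")), x) != y)
  expect_gte(lin_err, 0.25)
  gau_err <- mean(predict(ova_svm(x, y, svm_spec("gaussian", C = 100)), x)
                  != y)
  expect_equal(gau_err, 0)
})

test_that("degenerate training inputs are rejected", {
  d <- toy_classes(k = 2)
  expect_error(ova_svm(d$x, rep("one", nrow(d$x))), "2 classes")
  expect_error(predict(ova_svm(d$x, d$y), d$x[, 1:2]), "columns")
  expect_error(svm_spec(C = -1), "C")
  expect_error(cv_mean_error(d$x, d$y, k = 1), "k")
})

test_that("stratified folds partition every class into k balanced parts", {
  set.seed(3)
  for (i in 1:10) {
    k <- sample(2:6, 1)
    y <- sample(rep(letters[1:3], times = k * sample(2:5, 3, replace = TRUE)))
    f <- stratified_folds(y, k, seed = i)
    expect_setequal(unique(f), seq_len(k))       # exhaustive
    expect_length(f, length(y))                  # disjoint by construction
    per_class <- table(y, f)
    # balanced within each class: fold sizes differ by at most one
    expect_lte(max(apply(per_class, 1, function(r) max(r) - min(r))), 1)
  }
  expect_error(stratified_folds(c("a", "a", "b"), k = 2), "smaller than k")
})

test_that("cross-validated error is near zero when separable, near chance when shuffled", {
  d <- toy_classes(n_per_class = 30, k = 3, sep = 8, seed = 4)
  cv <- cv_mean_error(d$x, d$y, svm_spec("linear"), k = 5, seed = 1)
  expect_lt(cv$mean_error, 0.05)
  expect_true(all(cv$fold_errors >= 0 & cv$fold_errors <= 1))

  set.seed(5)
  n <- 250
  x <- matrix(rnorm(n * 6), ncol = 6)
  y <- sample(rep(paste0("c", 1:5), length.out = n))
  cv0 <- cv_mean_error(x, y, svm_spec("linear"), k = 5, seed = 2)
  expect_lt(abs(cv0$mean_error - 0.8), 0.1)
})

test_that("CV is reproducible for a fixed seed and seed-sensitive otherwise", {
  d <- toy_classes(n_per_class = 20, k = 3, sep = 1.5, seed = 6)
  a <- cv_mean_error(d$x, d$y, svm_spec("gaussian"), k = 4, seed = 9)
  b <- cv_mean_error(d$x, d$y, svm_spec("gaussian"), k = 4, seed = 9)
  expect_identical(a$mean_error, b$mean_error)
  expect_identical(a$folds, b$folds)
})

test_that("a duplicated standardized column barely moves linear-kernel CV error", {
  d <- toy_classes(n_per_class = 25, k = 3, sep = 2, seed = 7)
  base <- cv_mean_error(d$x, d$y, svm_spec("linear"), k = 5, seed = 3)
  dup <- cbind(d$x, dup = d$x[, 1])
  with_dup <- cv_mean_error(dup, d$y, svm_spec("linear"), k = 5, seed = 3)
  expect_lt(abs(with_dup$mean_error - base$mean_error), 0.05)
})

test_that("one-vs-all predictions agree with an independent SVM on clear data", {
  d <- toy_classes(n_per_class = 20, k = 3, sep = 8, seed = 8)
  test <- toy_classes(n_per_class = 10, k = 3, sep = 8, seed = 9)
  ours <- predict(ova_svm(d$x, d$y, svm_spec("gaussian")), test$x)
  ref <- kernlab::ksvm(x = d$x, y = factor(d$y), kernel = "rbfdot",
                       C = 1, scaled = TRUE)
  theirs <- kernlab::predict(ref, test$x)
  expect_equal(mean(as.character(ours) != test$y), 0)
  expect_equal(mean(as.character(theirs) != test$y), 0)
})
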