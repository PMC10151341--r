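test_that("folds are disjoint, cover all samples and balance sizes", {
  f <- make_folds(rep(1:3, length.out = 10), eval_config(k = 5, seed = 1))
  expect_identical(sort(unlist(f)), 1:10)
  expect_true(all(lengths(f) == 2L))

  f11 <- make_folds(rep(1:3, length.out = 11),
                    eval_config(k = 5, stratified = FALSE, seed = 2))
  expect_identical(sort(lengths(f11)), c(2L, 2L, 2L, 2L, 3L))
  expect_identical(sort(unlist(f11)), 1:11)
})

test_that("stratified folds split 60/25/15 of 100 into 12/5/3 per fold", {
  labels <- rep(1:3, c(60, 25, 15))
  f <- make_folds(labels, eval_config(k = 5, seed = 3))
  for (fold in f) {
    expect_identical(as.integer(table(factor(labels[fold], levels = 1:3))),
                     c(12L, 5L, 3L))
  }
})

test_that("fold properties hold over random sizes and are seed-reproducible", {
  set.seed(44)
  for (trial in 1:20) {
    n <- sample(10:80, 1)
    k <- sample(2:min(8, n %/% 3), 1)
    labels <- sample(1:3, n, replace = TRUE)
    cfg <- eval_config(k = k, seed = trial)
    f <- make_folds(labels, cfg)
    expect_identical(sort(unlist(f)), seq_len(n))
    expect_lte(diff(range(lengths(f))), 1L)
    for (cls in 1:3) {
      per <- vapply(f, function(ix) sum(labels[ix] == cls), 0L)
      expect_lte(diff(range(per)), 1L)
    }
    expect_identical(f, make_folds(labels, cfg))
  }
  expect_error(make_folds(c(1, 2, 3), eval_config(k = 5)),
               class = "mammoqc_config_error")
})

test_that("metrics match hand-computed values on a known confusion matrix", {
  perfect <- compute_metrics(diag(c(10, 10, 10)))
  expect_equal(unlist(perfect$macro), c(accuracy = 1, recall = 1, precision = 1, f1 = 1))

  cm <- matrix(c(8, 2, 0, 1, 6, 0, 1, 2, 10), 3, 3) # rows truth, cols predicted
  rep <- compute_metrics(cm)
  expect_equal(rep$macro$accuracy, 0.8)
  expect_equal(rep$macro$recall, (0.8 + 0.6 + 1.0) / 3)
  expect_equal(rep$macro$precision, (8 / 10 + 6 / 7 + 10 / 13) / 3)
  f1 <- c(0.8, 2 * (6 / 7) * 0.6 / (6 / 7 + 0.6), 2 * (10 / 13) / (10 / 13 + 1))
  expect_equal(rep$macro$f1, mean(f1))
})

test_that("zero-denominator classes contribute zero to the macro means", {
  rep <- compute_metrics(diag(c(10, 0, 0)))
  expect_equal(rep$macro$accuracy, 1)
  expect_equal(rep$macro$recall, 1 / 3)
  expect_equal(rep$macro$precision, 1 / 3)
  expect_error(compute_metrics(matrix(0, 3, 3)), class = "mammoqc_input_error")
})

test_that("metric computation agrees with the brute-force oracle", {
  set.seed(55)
  for (i in 1:100) {
    cm <- matrix(rpois(9, 4), 3, 3)
    if (i %% 5 == 0) cm[sample(1:3, 1), ] <- 0  # empty truth rows
    if (sum(cm) == 0) next
    rep <- compute_metrics(cm)
    expect_equal(unlist(rep$macro), oracle_metrics(cm))
  }
})

test_that("a perfect oracle classifier yields a diagonal summed matrix", {
  labels <- rep(1:3, c(9, 6, 5))
  patches <- lapply(labels, function(l) matrix(l * 10, 8, 8))
  perfect_trainer <- function(patches, labels, cfg)
    structure(list(), class = "mean_rule_clf")
  cv <- cross_validate(tibble::tibble(patch = patches, label = labels),
                       eval_config(k = 5, seed = 6), training_config(),
                       trainer = perfect_trainer)
  expect_equal(unclass(cv$confusion), diag(c(9, 6, 5)),
               ignore_attr = TRUE)
  expect_equal(glance(cv)$accuracy, 1)
  expect_identical(sum(cv$confusion), 20L)
})

test_that("a constant classifier fills a single predicted column", {
  labels <- rep(1:3, c(6, 5, 4))
  patches <- lapply(labels, function(l) matrix(l, 8, 8))
  constant_trainer <- function(patches, labels, cfg)
    structure(list(), class = "always_average_clf")
  cv <- cross_validate(tibble::tibble(patch = patches, label = labels),
                       eval_config(k = 5, seed = 7), training_config(),
                       trainer = constant_trainer)
  cm <- unclass(cv$confusion)
  expect_true(all(cm[, c(1, 3)] == 0))
  expect_equal(unname(cm[, 2]), c(6, 5, 4))
})

test_that("tidy and glance expose per-class and macro views", {
  cm <- matrix(c(8, 2, 0, 1, 6, 0, 1, 2, 10), 3, 3)
  rep <- compute_metrics(cm)
  expect_identical(tidy(rep)$class, c("poor", "average", "excellent"))
  expect_identical(names(glance(rep)), c("accuracy", "recall", "precision", "f1"))
})
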