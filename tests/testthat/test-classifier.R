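test_that("softmax matches its closed form and is shift invariant", {
  expect_equal(unname(softmax3(c(0, 0, 0))), rep(1 / 3, 3))
  expect_equal(unname(softmax3(log(c(1, 2, 7)))), c(0.1, 0.2, 0.7))
  set.seed(17)
  for (i in 1:200) {
    z <- rnorm(3, sd = 10)
    p <- softmax3(z)
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_equal(unname(softmax3(z + rnorm(1, sd = 50))), unname(p),
                 tolerance = 1e-9)
  }
  expect_error(softmax3(c(1, Inf, 0)), class = "mammoqc_numeric_error")
  expect_error(softmax3(c(1, 2)), class = "mammoqc_numeric_error")
})

test_that("predicted class probabilities sum to one for any weights", {
  m <- positioning_model(training_config(seed = 23))
  set.seed(23)
  pr <- predict(m, replicate(5, matrix(runif(64 * 64, 0, 255), 64, 64),
                             simplify = FALSE))
  expect_identical(nrow(pr), 5L)
  expect_true(all(abs(pr$p_poor + pr$p_average + pr$p_excellent - 1) < 1e-6))
  expect_true(all(pr$p_poor >= 0 & pr$p_poor <= 1))
})

test_that("probability ties resolve to the lower (more conservative) class code", {
  m <- positioning_model(training_config(seed = 1))
  m$weights$W[] <- 0; m$weights$b[] <- 0
  m$weights$V[] <- 0; m$weights$c[] <- 0
  pr <- predict(m, matrix(100, 64, 64))
  expect_equal(unlist(pr[1, 1:3], use.names = FALSE), rep(1 / 3, 3))
  expect_identical(pr$label, 1L)
  expect_identical(pr$label_name, "poor")
})

test_that("prediction is deterministic at fixed weights", {
  m <- positioning_model(training_config(seed = 2))
  patch <- matrix(seq(0, 255, length.out = 64 * 64), 64, 64)
  expect_identical(predict(m, patch), predict(m, patch))
})

test_that("training requires every class and consistent patch shapes", {
  patches <- replicate(6, matrix(runif(64 * 64, 0, 255), 64, 64), simplify = FALSE)
  expect_error(train_classifier(patches, rep(1L, 6), training_config(max_epochs = 1)),
               class = "mammoqc_training_error")
  bad <- patches; bad[[3]] <- matrix(0, 32, 32)
  expect_error(train_classifier(bad, c(1, 1, 2, 2, 3, 3), training_config(max_epochs = 1)),
               class = "mammoqc_input_error")
})

test_that("batch size 16 on 64 samples gives 4 gradient updates per epoch", {
  set.seed(5)
  patches <- replicate(64, matrix(runif(64 * 64, 0, 255), 64, 64), simplify = FALSE)
  labels <- rep(1:3, length.out = 64)
  fit <- train_classifier(patches, labels,
                          training_config(max_epochs = 1L, batch_size = 16L, seed = 3))
  expect_identical(fit$updates_per_epoch, 4L)
  expect_identical(glance(fit)$updates_per_epoch, 4L)
})

test_that("the tiny CNN overfits cleanly separable classes", {
  set.seed(7)
  labels <- rep(1:3, each = 20)
  patches <- lapply(labels, function(l)
    matrix(l * 70 + rnorm(64 * 64, 0, 8), 64, 64))
  fit <- train_classifier(patches, labels,
                          training_config(max_epochs = 30L, seed = 11))
  expect_gte(fit$train_accuracy, 0.95)
  pr <- predict(fit, patches[labels == 2])
  expect_true(all(pr$p_average > 0.5))
})

test_that("training is reproducible from the seed", {
  set.seed(8)
  labels <- rep(1:3, each = 6)
  patches <- lapply(labels, function(l) matrix(l * 60 + rnorm(64 * 64, 0, 5), 64, 64))
  f1 <- train_classifier(patches, labels, training_config(max_epochs = 3L, seed = 4))
  f2 <- train_classifier(patches, labels, training_config(max_epochs = 3L, seed = 4))
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)
})

test_that("unavailable pretrained backbones are refused", {
  expect_error(positioning_model(training_config(backbone = "vgg16")),
               class = "mammoqc_config_error")
})
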