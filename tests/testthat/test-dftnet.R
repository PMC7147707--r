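# Unit tests use a reduced input size so the pooling cascade and training
# mechanics are exercised quickly; the full-size regime is covered by the
# pipeline acceptance tests.

test_that("layer stack and shape arithmetic follow the architecture", {
  m <- dftnet_build(dftnet_spec(c(64, 64, 3), n_classes = 5), seed = 1)
  st <- dftnet_structure(m)
  expect_equal(nrow(st), 9)
  expect_equal(st$type, c("Conv.", "Max-Pool", "Conv.", "Conv.", "Max-Pool",
                          "Conv.", "Max-Pool", "Conv.", "Full Conn."))
  expect_equal(st$kernel, c("7x7", "3x3", "1x1", "3x3", "3x3", "3x3", "2x2",
                            "3x3", "-"))
  expect_equal(st$stride, c("1x1", "2x2", "1x1", "1x1", "2x2", "1x1", "2x2",
                            "1x1", "-"))
  expect_equal(st$filters, c(32L, NA, 64L, 64L, NA, 32L, NA, 32L, NA))
  expect_equal(st$fc_units[9], 5L)
  # same-padded convs preserve H x W; valid pools shrink it
  expect_equal(st$out_shape,
               c("64x64x32", "31x31x32", "31x31x64", "31x31x64", "15x15x64",
                 "15x15x32", "7x7x32", "7x7x32", "1x1x5"))
})

test_that("parameter count equals the closed-form layer sum", {
  m <- dftnet_build(dftnet_spec(c(64, 64, 3), n_classes = 2), seed = 1)
  expected <- (7 * 7 * 3) * 32 + 32 +
    (1 * 1 * 32) * 64 + 64 +
    (3 * 3 * 64) * 64 + 64 +
    (3 * 3 * 64) * 32 + 32 +
    (3 * 3 * 32) * 32 + 32 +
    (7 * 7 * 32) * 2 + 2
  expect_equal(dftnet_n_params(m), expected)
})

test_that("builds are seeded and inputs too small for the pools error", {
  a <- dftnet_build(dftnet_spec(c(32, 32, 1), 2), seed = 5)
  b <- dftnet_build(dftnet_spec(c(32, 32, 1), 2), seed = 5)
  expect_identical(a$layers[[1]]$W_mat, b$layers[[1]]$W_mat)
  c3 <- dftnet_build(dftnet_spec(c(32, 32, 1), 2), seed = 6)
  expect_false(identical(a$layers[[1]]$W_mat, c3$layers[[1]]$W_mat))

  expect_error(dftnet_build(dftnet_spec(c(8, 8, 1), 2)), "layer 7")
  expect_error(dftnet_spec(c(16, 16, 1), n_classes = 1), "n_classes")
})

test_that("predictions are normalized probabilities with deterministic argmax", {
  m <- dftnet_build(dftnet_spec(c(18, 18, 1), 3), seed = 2)
  set.seed(1)
  imgs <- lapply(1:4, function(i) matrix(runif(18 * 18), 18, 18))
  pr <- dftnet_predict(m, imgs)
  expect_equal(dim(pr$probs), c(4L, 3L))
  expect_equal(rowSums(pr$probs), rep(1, 4), tolerance = 1e-6)
  expect_true(all(pr$probs >= 0 & pr$probs <= 1))
  expect_identical(pr$labels, dftnet_predict(m, imgs)$labels)
  # zero-initialized output layer ties all classes; argmax breaks low
  expect_true(all(pr$labels == 1L))
  expect_error(dftnet_predict(m, list(matrix(0, 5, 5))), "does not match")
})

test_that("zero learning rate leaves weights untouched and loss flat", {
  m <- dftnet_build(dftnet_spec(c(18, 18, 1), 2), seed = 3)
  w0 <- m$layers[[1]]$W_mat
  set.seed(2)
  imgs <- lapply(1:8, function(i) matrix(runif(18 * 18), 18, 18))
  labs <- rep(1:2, 4)
  dftnet_train(m, imgs, labs,
               dftnet_train_config(max_epochs = 2, learning_rate = 0, seed = 1))
  expect_identical(m$layers[[1]]$W_mat, w0)
  expect_equal(m$history$loss[1], m$history$loss[2])
})

test_that("initial loss on balanced classes equals log(n_classes)", {
  m <- dftnet_build(dftnet_spec(c(18, 18, 1), 4), seed = 4)
  set.seed(3)
  imgs <- lapply(1:8, function(i) matrix(runif(18 * 18), 18, 18))
  dftnet_train(m, imgs, rep(1:4, 2),
               dftnet_train_config(max_epochs = 1, learning_rate = 0, seed = 1))
  expect_equal(m$history$loss[1], log(4), tolerance = 1e-9)
})

test_that("training separates a small separable problem deterministically", {
  d <- separable_patches(15, size = 18, seed = 6)
  m1 <- dftnet_build(dftnet_spec(c(18, 18, 1), 2), seed = 7)
  dftnet_train(m1, d$images, d$labels,
               dftnet_train_config(max_epochs = 12, batch_size = 10, seed = 7,
                                   early_stop = list(metric = "train_accuracy",
                                                     threshold = 1)))
  expect_gte(tail(m1$history$train_accuracy, 1), 0.95)

  m2 <- dftnet_build(dftnet_spec(c(18, 18, 1), 2), seed = 7)
  dftnet_train(m2, d$images, d$labels,
               dftnet_train_config(max_epochs = nrow(m1$history),
                                   batch_size = 10, seed = 7))
  expect_equal(m1$history$loss, m2$history$loss, tolerance = 1e-12)

  pr <- dftnet_predict(m1, d$images)
  expect_gte(mean(pr$labels == d$labels), 0.95)
})

test_that("training rejects degenerate datasets", {
  m <- dftnet_build(dftnet_spec(c(18, 18, 1), 2), seed = 1)
  img <- matrix(0.5, 18, 18)
  expect_error(dftnet_train(m, list(), integer()), "empty")
  expect_error(dftnet_train(m, list(img, img), c(1L, 1L)), "single class")
  expect_error(dftnet_train(m, list(img, img), c(1L, 3L)), "labels")
})
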