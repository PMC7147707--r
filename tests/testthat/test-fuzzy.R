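test_that("histograms count pixels correctly", {
  g <- gray_image(matrix(c(0L, 0L, 1L, 1L), 2, 2), 2)
  expect_equal(compute_histogram(g)$probs, c(0.5, 0.5))

  one <- gray_image(matrix(3L, 2, 2), 8)
  expect_equal(compute_histogram(one)$probs, c(0, 0, 0, 1, 0, 0, 0, 0))

  mask <- matrix(c(1, 0, 0, 1), 2, 2)
  gm <- compute_histogram(g, restrict_to = mask)
  expect_equal(sum(gm$probs), 1)
  expect_error(compute_histogram(g, restrict_to = matrix(0, 2, 2)), "empty")
})

test_that("membership functions form a partition of unity", {
  p <- fuzzy_partition(c(100, 200), 256)
  expect_equal(drop(membership(p, 150)), c(0.5, 0.5))
  expect_equal(drop(membership(p, 50)), c(1, 0))
  expect_equal(drop(membership(p, 250)), c(0, 1))

  # property: random partitions, all gray levels, rows sum to 1
  for (s in 1:20) {
    set.seed(s)
    n <- sample(2:5, 1)
    bp <- sort(runif(2 * (n - 1), 0, 31))
    p <- fuzzy_partition(bp, 32)
    mu <- membership(p, 0:31)
    expect_true(all(mu >= 0 & mu <= 1))
    expect_lt(max(abs(rowSums(mu) - 1)), 1e-9)
  }
  expect_error(fuzzy_partition(c(200, 100), 256), "non-decreasing")
})

test_that("crisp breakpoints (a == c) reduce to a step", {
  p <- fuzzy_partition(c(10, 10), 32)
  mu <- membership(p, c(9, 10, 11))
  expect_equal(mu[, 1], c(1, 1, 0))
  expect_equal(mu[, 2], c(0, 0, 1))
})

test_that("total fuzzy entropy matches a hand-computed value", {
  # uniform histogram on L = 4, crisp split at gray 1 (segments {0,1}, {2,3}):
  # each segment has P = 1/2 and two terms of 1/2, so H_i = ln 2 and the
  # normalized total is 2 ln 2 / (2 ln 4)
  h <- hist_from_counts(c(1, 1, 1, 1))
  p <- fuzzy_partition(c(1, 1), 4)
  expect_equal(total_fuzzy_entropy(h, p), 2 * log(2) / (2 * log(4)))
  expect_equal(total_fuzzy_entropy(h, p, normalize = FALSE), 2 * log(2))

  # one-hot histogram has no uncertainty under any partition
  oh <- hist_from_counts(c(0, 5, 0, 0))
  expect_equal(total_fuzzy_entropy(oh, p), 0)
})

test_that("entropy stays finite with sparse histograms and zero-mass segments", {
  h <- hist_from_counts(c(3, 0, 0, 2, 0, 1, 0, 0))
  p <- fuzzy_partition(c(2, 5), 8)
  expect_true(is.finite(total_fuzzy_entropy(h, p)))
  # a segment with no mass contributes nothing
  empty_top <- hist_from_counts(c(4, 1, 0, 0, 0, 0, 0, 0))
  p_far <- fuzzy_partition(c(6, 7), 8)
  expect_equal(total_fuzzy_entropy(empty_top, p_far, normalize = FALSE),
               -sum(c(0.8, 0.2) * log(c(0.8, 0.2))))
})

test_that("DE finds the exhaustive-search optimum on a bimodal histogram", {
  h <- two_mode_histogram(seed = 3)
  de <- optimize_partition(h, 2, de_config(seed = 3))
  expect_equal(attr(de, "entropy"), exhaustive_best_entropy(h),
               tolerance = 1e-12)
  thr <- extract_thresholds(de)
  expect_gt(thr[1], 8)   # threshold strictly between the modes
  expect_lt(thr[1], 24)
})

test_that("DE is deterministic and beats random search", {
  h <- random_histogram(32, seed = 5)
  a <- optimize_partition(h, 3, de_config(seed = 11, generations = 40))
  b <- optimize_partition(h, 3, de_config(seed = 11, generations = 40))
  expect_identical(a$breakpoints, b$breakpoints)

  set.seed(99)
  rand_best <- max(replicate(1000, {
    bp <- sort(pmin(pmax(round(runif(4, 0, 31)), 0), 31))
    total_fuzzy_entropy(h, fuzzy_partition(bp, 32))
  }))
  expect_gte(attr(a, "entropy"), rand_best)
})

test_that("optimized partitions respect the partition of unity", {
  h <- random_histogram(32, seed = 8)
  for (n in 2:4) {
    p <- optimize_partition(h, n, de_config(seed = n, generations = 30))
    mu <- membership(p, 0:31)
    expect_lt(max(abs(rowSums(mu) - 1)), 1e-9)
  }
  expect_error(optimize_partition(h, 20), "too many segments")
})

test_that("threshold extraction takes overlap midpoints and repairs ties", {
  p <- fuzzy_partition(c(100, 200), 256)
  expect_equal(as.integer(extract_thresholds(p)), 150L)

  p4 <- fuzzy_partition(c(10, 20, 30, 40, 50, 60), 256)
  thr <- extract_thresholds(p4)
  expect_length(thr, 3)
  expect_true(all(diff(thr) > 0))

  # coincident overlaps force the +1 repair
  tie <- fuzzy_partition(c(10, 10, 10, 10), 32)
  expect_equal(as.integer(extract_thresholds(tie)), c(10L, 11L))
})

test_that("segmentation labels count thresholds strictly below the gray", {
  g <- gray_image(matrix(c(0L, 0L, 1L, 2L), 2, 2), 4)
  res <- segment_image(g, 1L)
  expect_equal(res$labels, matrix(c(0L, 0L, 0L, 1L), 2, 2))

  res0 <- segment_image(g, integer())
  expect_true(all(res0$labels == 0L))
  expect_true(all(res0$roi_mask == 1L))  # single segment is the top segment

  # monotone labeling: higher gray never gets a lower label
  set.seed(2)
  px <- matrix(sample(0:31, 100, TRUE), 10, 10)
  r <- segment_image(gray_image(px, 32), c(5L, 17L))
  ord <- order(as.vector(px))
  expect_true(all(diff(as.vector(r$labels)[ord]) >= 0))
})

test_that("top-segment mass matches the histogram mass above the last threshold", {
  set.seed(6)
  px <- matrix(sample(0:31, 400, TRUE), 20, 20)
  g <- gray_image(px, 32)
  res <- segment_image(g, c(7L, 20L))
  h <- compute_histogram(g)
  expect_equal(sum(res$roi_mask), round(sum(h$probs[22:32]) * 400))
})

test_that("ROI is restricted to the foot mask", {
  px <- matrix(31L, 4, 4)
  mask <- matrix(c(1, 1, 0, 0), 4, 4)
  res <- segment_image(gray_image(px, 32), 10L, mask = mask)
  expect_true(all(res$roi_mask[mask == 0] == 0))
})

test_that("segmentation level selection reports per-n entropies and picks sanely", {
  tg <- generate_synthetic(synthetic_spec(pattern = "butterfly", seed = 4))
  g <- to_gray(tg, 32)
  sel <- select_segmentation_level(g, candidates = 2:4,
                                   cfg = de_config(seed = 1, generations = 30),
                                   mask = tg$mask)
  tab <- attr(sel, "entropy_table")
  expect_equal(tab$n_segments, 2:4)
  expect_true(all(is.finite(tab$entropy)))
  expect_false(attr(sel, "fallback"))

  one <- suppressWarnings(select_segmentation_level(g, candidates = 3,
                                   cfg = de_config(seed = 1, generations = 30),
                                   mask = tg$mask))
  expect_equal(length(one$thresholds), 2)  # the single candidate was chosen
})
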