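test_that("angiosome partition is exhaustive, exclusive and side-aware", {
  mask <- block_mask(100, 40)
  a <- partition_angiosomes(mask, side = "left")
  regs <- unclass(a)
  counts <- table(factor(regs[mask == 1L],
                         levels = c("MPA", "LPA", "MCA", "LCA")))
  expect_true(all(counts > 0))
  expect_equal(sum(counts), sum(mask))                 # exhaustive on mask
  expect_true(all(regs[mask == 0L] == "background"))   # exclusive off mask

  # mirroring the mask and flipping the side mirrors the medial labels
  b <- partition_angiosomes(mask[, ncol(mask):1], side = "right")
  expect_equal(unclass(b)[, ncol(mask):1], regs, ignore_attr = TRUE)
})

test_that("heel fraction controls the calcaneal band rows", {
  mask <- block_mask(100, 40, frame = c(100L, 40L))  # mask fills the frame
  a <- partition_angiosomes(mask, side = "left", heel_fraction = 0.27)
  heel_rows <- which(apply(unclass(a), 1, function(r) any(r %in% c("MCA", "LCA"))))
  expect_equal(length(heel_rows), 27)
  expect_equal(range(heel_rows), c(74, 100))           # proximal 27% of 100 rows
})

test_that("disconnected masks are rejected", {
  m <- matrix(0L, 10, 10)
  m[1:2, 1:2] <- 1L; m[8:9, 8:9] <- 1L
  expect_error(partition_angiosomes(m), "disconnected")
  expect_error(partition_angiosomes(matrix(0L, 5, 5)), "empty")
})

test_that("angiosome means average the right pixels", {
  mask <- block_mask(100, 40)
  a <- partition_angiosomes(mask, side = "left")
  temps <- matrix(30, nrow(mask), ncol(mask))
  tg <- thermogram(temps, mask = mask, side = "left")
  m <- angiosome_means(tg, a)
  expect_equal(unlist(m[c("mpa", "lpa", "mca", "lca")], use.names = FALSE),
               rep(30, 4))

  temps[unclass(a) == "MPA"] <- 32
  tg2 <- thermogram(temps, mask = mask, side = "left")
  m2 <- angiosome_means(tg2, a)
  expect_equal(m2$mpa, 32)
  expect_equal(c(m2$lpa, m2$mca, m2$lca), rep(30, 3))

  # background temperature is irrelevant
  temps[mask == 0L] <- -100
  m3 <- angiosome_means(thermogram(temps, mask = mask, side = "left"), a)
  expect_equal(unlist(m3), unlist(m2))
})

test_that("TCI follows the signed control-minus-subject mean", {
  ref <- angiosome_temps(30, 30, 30, 30)
  expect_equal(compute_tci(angiosome_temps(28, 28, 28, 28), ref), 2)
  expect_equal(compute_tci(ref, ref), 0)
  # signed differences cancel
  expect_equal(compute_tci(angiosome_temps(31, 29, 30, 30), ref), 0)
  # absolute mode does not cancel
  expect_equal(compute_tci(angiosome_temps(31, 29, 30, 30), ref,
                           absolute = TRUE), 0.5)
})

test_that("TCI is linear under uniform subject shifts", {
  set.seed(12)
  for (i in 1:25) {
    ref <- do.call(angiosome_temps, as.list(runif(4, 25, 35)))
    sub <- do.call(angiosome_temps, as.list(runif(4, 25, 35)))
    delta <- runif(1, -3, 3)
    shifted <- do.call(angiosome_temps, lapply(sub, `+`, delta))
    expect_equal(compute_tci(shifted, ref), compute_tci(sub, ref) - delta)
  }
})

test_that("level assignment bins |TCI| against the boundaries", {
  b <- c(1, 2, 3, 4)
  expect_equal(assign_level(0.5, b), 1L)
  expect_equal(assign_level(2.5, b), 3L)
  expect_equal(assign_level(-2.5, b), 3L)   # magnitude-based by default
  expect_equal(assign_level(9, b), 5L)
  expect_equal(assign_level(-2.5, b, signed = TRUE), 1L)
  expect_error(assign_level(1, c(2, 1, 3, 4)), "increasing")

  # level is non-decreasing in |tci|
  lv <- vapply(seq(0, 6, by = 0.1), assign_level, integer(1), boundaries = b)
  expect_true(all(diff(lv) >= 0))
})
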