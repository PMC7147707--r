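# Shared fixtures and independent oracles for the test suite.

# Exhaustive search over all integer (a, c) pairs for the best 2-segment
# fuzzy-entropy partition of a histogram -- the independent optimizer oracle.
exhaustive_best_entropy <- function(h) {
  best <- -Inf
  for (a in 0:(h$levels - 1L)) for (cc in a:(h$levels - 1L)) {
    e <- total_fuzzy_entropy(h, fuzzy_partition(c(a, cc), h$levels))
    if (e > best) best <- e
  }
  best
}

# Mann-Whitney pair-counting AUC (ties count 1/2) -- the ranking oracle.
pair_counting_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Histogram from counts.
hist_from_counts <- function(counts) {
  gray_histogram(counts / sum(counts), length(counts))
}

# Random normalized histogram.
random_histogram <- function(levels, seed) {
  set.seed(seed)
  p <- stats::runif(levels)
  gray_histogram(p / sum(p), levels)
}

# Two-mode histogram: discretized Gaussian mixture over the gray axis.
two_mode_histogram <- function(levels = 32L, modes = c(8, 24), sd = 2,
                               n_draws = 2000L, seed = 1L) {
  set.seed(seed)
  draws <- c(round(stats::rnorm(n_draws / 2, modes[1], sd)),
             round(stats::rnorm(n_draws / 2, modes[2], sd)))
  draws <- pmin(pmax(draws, 0), levels - 1L)
  hist_from_counts(tabulate(draws + 1L, nbins = levels))
}

# Separable two-class gray patches: dark vs bright uniform noise.
separable_patches <- function(n_per_class, size = 64L, seed = 1L) {
  set.seed(seed)
  imgs <- c(lapply(seq_len(n_per_class), function(i)
              matrix(stats::runif(size^2, 0.0, 0.45), size, size)),
            lapply(seq_len(n_per_class), function(i)
              matrix(stats::runif(size^2, 0.55, 1.0), size, size)))
  list(images = imgs, labels = rep(1:2, each = n_per_class))
}

# Small rectangular foot-like mask embedded in a frame.
block_mask <- function(nr = 100L, nc = 40L, frame = c(120L, 60L)) {
  m <- matrix(0L, frame[1], frame[2])
  r0 <- (frame[1] - nr) %/% 2L; c0 <- (frame[2] - nc) %/% 2L
  m[r0 + seq_len(nr), c0 + seq_len(nc)] <- 1L
  m
}
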