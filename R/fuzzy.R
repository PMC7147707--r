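#' Normalized gray-level histogram
#'
#' @param img a [gray_image].
#' @param restrict_to optional binary mask; only pixels under the mask are
#'   counted.
#' @return A `gray_histogram`: list with `probs` (length-L vector summing to
#'   1) and `levels`.
#' @export
compute_histogram <- function(img, restrict_to = NULL) {
  stopifnot(inherits(img, "gray_image"))
  px <- img$pixels
  if (!is.null(restrict_to)) {
    restrict_to <- as.matrix(restrict_to)
    if (!identical(dim(restrict_to), dim(px)))
      stop_validation("mask dimensions do not match image")
    px <- px[restrict_to != 0]
    if (!length(px)) stop_validation("empty mask: no pixels to count")
  }
  counts <- tabulate(as.vector(px) + 1L, nbins = img$levels)
  gray_histogram(counts / sum(counts), img$levels)
}

#' @rdname compute_histogram
#' @param probs normalized frequencies (length L, non-negative, sum 1).
#' @param levels number of gray levels L.
#' @export
gray_histogram <- function(probs, levels) {
  levels <- as.integer(levels)
  if (length(probs) != levels) stop_validation("probs must have length L")
  if (any(probs < 0)) stop_validation("negative probabilities")
  if (abs(sum(probs) - 1) > 1e-9) stop_validation("probs must sum to 1")
  structure(list(probs = as.numeric(probs), levels = levels),
            class = "gray_histogram")
}

#' Fuzzy partition of the gray axis
#'
#' `n` overlapping trapezoidal membership functions over gray levels
#' `0 ... L-1`, parameterized by `2(n-1)` sorted breakpoints
#' `(a1, c1, a2, c2, ...)`. The first set is 1 up to `a1` and descends
#' linearly to 0 at `c1`; each next set rises over the same ramp (so the
#' functions sum to 1 at every gray level), plateaus, and descends over its
#' own `(a, c)` ramp; the last set mirrors the first. `a == c` gives a crisp
#' step between the two sets.
#'
#' @param breakpoints numeric vector of length `2(n-1)`, non-decreasing,
#'   within `[0, L-1]`.
#' @param levels number of gray levels L.
#' @return A `fuzzy_partition` with `n_segments`, `breakpoints`, `levels`.
#' @export
fuzzy_partition <- function(breakpoints, levels) {
  breakpoints <- as.numeric(breakpoints)
  if (length(breakpoints) %% 2L != 0L || !length(breakpoints))
    stop_validation("breakpoints must have even positive length 2(n-1)")
  if (is.unsorted(breakpoints))
    stop_validation("breakpoints must be non-decreasing")
  levels <- as.integer(levels)
  if (any(breakpoints < 0 | breakpoints > levels - 1L))
    stop_validation("breakpoints outside [0, L-1]")
  structure(list(n_segments = length(breakpoints) / 2L + 1L,
                 breakpoints = breakpoints, levels = levels),
            class = "fuzzy_partition")
}

# Ascending ramp through (a, c): 0 below a, 1 above c, linear between;
# a == c degenerates to a step that is 0 at a and 1 above.
ramp_up <- function(k, a, c) {
  if (c > a) pmin(1, pmax(0, (k - a) / (c - a))) else as.numeric(k > a)
}

#' Membership degrees at a gray level
#'
#' @param p a [fuzzy_partition].
#' @param k gray level(s) in `[0, L-1]` (vectorized).
#' @return Matrix with one row per value of `k` and `n_segments` columns;
#'   rows sum to 1 (partition of unity).
#' @export
membership <- function(p, k) {
  stopifnot(inherits(p, "fuzzy_partition"))
  if (any(k < 0 | k > p$levels - 1L))
    stop_validation("gray level outside [0, L-1]")
  n <- p$n_segments
  a <- p$breakpoints[seq(1L, by = 2L, length.out = n - 1L)]
  cc <- p$breakpoints[seq(2L, by = 2L, length.out = n - 1L)]
  up <- vapply(seq_len(n - 1L), function(i) ramp_up(k, a[i], cc[i]),
               numeric(length(k)))
  up <- matrix(up, nrow = length(k))
  mu <- matrix(0, length(k), n)
  mu[, 1L] <- 1 - up[, 1L]
  if (n > 2L)
    for (i in 2L:(n - 1L)) mu[, i] <- up[, i - 1L] - up[, i]
  mu[, n] <- up[, n - 1L]
  mu
}

#' Total fuzzy entropy of a histogram under a fuzzy partition
#'
#' For each fuzzy segment i with membership \eqn{\mu_i}, the segment mass is
#' \eqn{P_i = \sum_k p_k \mu_i(k)} and its entropy
#' \eqn{H_i = -\sum_k (p_k \mu_i(k)/P_i) \ln(p_k \mu_i(k)/P_i)} over terms
#' with positive mass. The total is \eqn{\sum_i H_i}, by default normalized
#' by \eqn{n \ln L} so values are comparable across segment counts.
#'
#' @param h a `gray_histogram`.
#' @param p a [fuzzy_partition] over the same L.
#' @param normalize divide by `n * log(L)` (default `TRUE`).
#' @return Non-negative finite entropy value.
#' @export
total_fuzzy_entropy <- function(h, p, normalize = TRUE) {
  stopifnot(inherits(h, "gray_histogram"), inherits(p, "fuzzy_partition"))
  if (h$levels != p$levels)
    stop_validation("histogram and partition use different L")
  mu <- membership(p, 0:(h$levels - 1L))
  w <- h$probs * mu                       # L x n masses
  P <- colSums(w)
  if (all(P <= 0)) stop_validation("empty histogram")
  H <- 0
  for (i in seq_along(P)) {
    if (P[i] <= 0) next                   # zero-mass segment contributes 0
    q <- w[, i][w[, i] > 0] / P[i]
    H <- H - sum(q * log(q))
  }
  if (normalize) H / (p$n_segments * log(h$levels)) else H
}

#' Differential Evolution configuration
#'
#' @param population_size number of candidate vectors (>= 4).
#' @param F mutation factor in (0, 2].
#' @param CR crossover rate in \[0, 1\].
#' @param generations number of DE generations.
#' @param seed RNG seed; runs are reproducible.
#' @param strategy only `"rand1bin"` (DE/rand/1/bin) is implemented.
#' @return A `de_config` object.
#' @export
de_config <- function(population_size = 30L, F = 0.5, CR = 0.9,
                      generations = 150L, seed = 1L, strategy = "rand1bin") {
  strategy <- match.arg(strategy)
  if (population_size < 4L) stop_validation("population_size must be >= 4")
  if (F <= 0 || F > 2) stop_validation("F must be in (0, 2]")
  if (CR < 0 || CR > 1) stop_validation("CR must be in [0, 1]")
  structure(list(population_size = as.integer(population_size), F = F,
                 CR = CR, generations = as.integer(generations),
                 seed = as.integer(seed), strategy = strategy),
            class = "de_config")
}

# Repair a raw candidate into valid integer-valued breakpoints: round to the
# gray grid, sort, clip. Thresholds are gray levels, so the search is over
# the integer lattice while DE mutates in the continuous box.
repair_candidate <- function(x, levels) {
  sort(pmin(pmax(round(x), 0), levels - 1L))
}

#' Maximize total fuzzy entropy with DE/rand/1/bin
#'
#' Searches the `2(n-1)`-dimensional space of sorted gray-level breakpoints
#' for the fuzzy partition maximizing [total_fuzzy_entropy()]. Candidates
#' are repaired by rounding to integer gray levels, sorting and clipping.
#'
#' @param h a `gray_histogram`.
#' @param n_segments number of fuzzy segments (>= 2).
#' @param cfg a [de_config()].
#' @param normalize passed to [total_fuzzy_entropy()].
#' @return The best [fuzzy_partition] found, with attributes `entropy` (its
#'   objective value) and `trace` (best objective per generation).
#' @export
optimize_partition <- function(h, n_segments = 3L, cfg = de_config(),
                               normalize = TRUE) {
  stopifnot(inherits(h, "gray_histogram"))
  n_segments <- as.integer(n_segments)
  if (n_segments < 2L) stop_validation("n_segments must be >= 2")
  d <- 2L * (n_segments - 1L)
  if (d > h$levels)
    stop_validation("too many segments (", n_segments, ") for L = ", h$levels)
  L <- h$levels
  obj <- function(x) {
    total_fuzzy_entropy(h, fuzzy_partition(repair_candidate(x, L), L),
                        normalize = normalize)
  }
  with_seed(cfg$seed, {
    np <- cfg$population_size
    pop <- matrix(stats::runif(np * d, 0, L - 1), np, d)
    fit <- apply(pop, 1L, obj)
    trace <- numeric(cfg$generations)
    for (g in seq_len(cfg$generations)) {
      for (i in seq_len(np)) {
        idx <- sample(setdiff(seq_len(np), i), 3L)
        v <- pop[idx[1], ] + cfg$F * (pop[idx[2], ] - pop[idx[3], ])
        jr <- sample.int(d, 1L)
        cross <- stats::runif(d) < cfg$CR
        cross[jr] <- TRUE
        u <- ifelse(cross, v, pop[i, ])
        fu <- obj(u)
        if (fu >= fit[i]) { pop[i, ] <- u; fit[i] <- fu }
      }
      trace[g] <- max(fit)
    }
    best <- pop[which.max(fit), ]
    p <- fuzzy_partition(repair_candidate(best, L), L)
    attr(p, "entropy") <- max(fit)
    attr(p, "trace") <- trace
    p
  })
}

#' Extract thresholds from a fuzzy partition
#'
#' Each threshold sits at the middle of the overlap of two consecutive fuzzy
#' sets: `T_i = round((a_i + c_i) / 2)`. Rounding ties are repaired by
#' incrementing duplicates upward so the thresholds stay strictly increasing.
#'
#' @param p a [fuzzy_partition].
#' @return A `threshold_set`: sorted integer vector of length `n - 1`.
#' @export
extract_thresholds <- function(p) {
  stopifnot(inherits(p, "fuzzy_partition"))
  n <- p$n_segments
  a <- p$breakpoints[seq(1L, by = 2L, length.out = n - 1L)]
  cc <- p$breakpoints[seq(2L, by = 2L, length.out = n - 1L)]
  t <- as.integer(round((a + cc) / 2))
  if (length(t) > 1L)
    for (i in 2L:length(t)) if (t[i] <= t[i - 1L]) t[i] <- t[i - 1L] + 1L
  t <- pmin(t, p$levels - 1L)
  structure(t, class = "threshold_set", levels = p$levels)
}

#' Segment an image by thresholds
#'
#' A pixel's label is the number of thresholds strictly below its gray
#' level (labels `0 ... n-1`). The region of interest is the hottest (top)
#' segment, intersected with the foot mask when one is given.
#'
#' @param img a [gray_image].
#' @param thresholds integer thresholds (a `threshold_set` or plain vector);
#'   may be empty, in which case all labels are 0.
#' @param mask optional binary foot mask.
#' @param entropy optional entropy of the partition the thresholds came
#'   from, stored in the result.
#' @return A `segmentation_result`: `labels`, `thresholds`, `entropy`,
#'   `roi_mask`.
#' @export
segment_image <- function(img, thresholds, mask = NULL, entropy = NA_real_) {
  stopifnot(inherits(img, "gray_image"))
  t <- sort(as.integer(thresholds))
  if (any(t < 0 | t > img$levels - 1L))
    stop_validation("thresholds outside [0, L-1]")
  labels <- matrix(0L, nrow(img$pixels), ncol(img$pixels))
  for (ti in t) labels <- labels + (img$pixels > ti)
  roi <- (labels == length(t)) * 1L
  if (!is.null(mask)) {
    mask <- (as.matrix(mask) != 0) * 1L
    roi <- roi * mask
  }
  structure(list(labels = labels, thresholds = t, entropy = entropy,
                 roi_mask = roi),
            class = "segmentation_result")
}

#' Entropy-optimal multilevel segmentation
#'
#' Runs [optimize_partition()], extracts thresholds at the fuzzy-set overlap
#' midpoints and labels the image.
#'
#' @inheritParams segment_image
#' @param n_segments number of segments.
#' @param cfg a [de_config()].
#' @return A `segmentation_result` with attribute `partition`.
#' @export
segment_fuzzy <- function(img, n_segments = 3L, cfg = de_config(),
                          mask = NULL) {
  h <- compute_histogram(img, restrict_to = NULL)
  p <- optimize_partition(h, n_segments, cfg)
  res <- segment_image(img, extract_thresholds(p), mask = mask,
                       entropy = attr(p, "entropy"))
  attr(res, "partition") <- p
  res
}

#' Choose the number of segmentation levels
#'
#' Balances a high total fuzzy entropy against a usable hottest-region ROI:
#' for each candidate segment count the entropy-optimal segmentation is
#' computed, and by default the largest `n` whose ROI forms a defined
#' region — covering at least `min_roi_fraction` of the foot mask, with its
#' largest connected component holding at least `min_component_share` of
#' the ROI pixels (stray speckle from sensor noise is tolerated) — is
#' selected; if no candidate qualifies, the maximum-entropy segmentation is
#' returned with a warning flag.
#'
#' @param img a [gray_image].
#' @param candidates candidate segment counts (e.g. `2:5`).
#' @param cfg a [de_config()]; candidate `n` is added to the seed so runs
#'   are independent but reproducible.
#' @param mask optional binary foot mask used for the ROI rule.
#' @param min_roi_fraction minimum ROI size as a fraction of the foot mask
#'   (or image when no mask), default 0.02.
#' @param min_component_share minimum fraction of ROI pixels in its largest
#'   connected component, default 0.9 (1 demands a single component).
#' @return The chosen `segmentation_result`, with attributes
#'   `entropy_table` (data.frame: n_segments, entropy, thresholds, roi_ok)
#'   and `fallback` (TRUE when no candidate met the ROI rule).
#' @export
select_segmentation_level <- function(img, candidates = 2:5,
                                      cfg = de_config(), mask = NULL,
                                      min_roi_fraction = 0.02,
                                      min_component_share = 0.9) {
  if (!length(candidates)) stop_validation("no candidate segment counts")
  h <- compute_histogram(img)
  denom <- if (is.null(mask)) length(img$pixels) else sum(mask != 0)
  results <- list()
  tab <- data.frame(n_segments = integer(), entropy = numeric(),
                    thresholds = character(), roi_ok = logical())
  for (n in sort(as.integer(candidates))) {
    cfg_n <- de_config(cfg$population_size, cfg$F, cfg$CR, cfg$generations,
                       seed = cfg$seed + n, strategy = cfg$strategy)
    p <- optimize_partition(h, n, cfg_n)
    res <- segment_image(img, extract_thresholds(p), mask = mask,
                         entropy = attr(p, "entropy"))
    attr(res, "partition") <- p
    npx <- sum(res$roi_mask)
    main_share <- if (npx > 0) {
      comp <- EBImage::bwlabel(res$roi_mask)
      max(tabulate(comp[comp > 0])) / npx
    } else 0
    ok <- npx >= min_roi_fraction * denom && main_share >= min_component_share
    results[[as.character(n)]] <- res
    tab <- rbind(tab, data.frame(
      n_segments = n, entropy = attr(p, "entropy"),
      thresholds = paste(res$thresholds, collapse = ","), roi_ok = ok))
  }
  chosen_n <- if (any(tab$roi_ok)) max(tab$n_segments[tab$roi_ok]) else
    tab$n_segments[which.max(tab$entropy)]
  fallback <- !any(tab$roi_ok)
  if (fallback)
    warning("no candidate produced a usable ROI; returning max-entropy segmentation")
  out <- results[[as.character(chosen_n)]]
  attr(out, "entropy_table") <- tab
  attr(out, "fallback") <- fallback
  out
}
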