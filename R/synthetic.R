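#' Specification for a synthetic plantar thermogram
#'
#' Encodes the controlled thermal structure of a generated thermogram:
#' either the control-group "butterfly" pattern (warmest along the medial
#' arch, cooling toward the periphery) or a graded hot-region pattern whose
#' blob amplitudes are calibrated so the thermal change index against the
#' generator's own control reference lands in a requested class.
#'
#' @param image_shape `c(rows, cols)` of the image; toes at the top, heel at
#'   the bottom.
#' @param pattern `"butterfly"` (control) or `"hot_region"` (DM-like).
#' @param target_class requested thermal change level 1..5 (hot_region only).
#' @param background_temp background temperature (degC), must be below
#'   `base_foot_temp`.
#' @param base_foot_temp baseline plantar temperature (degC).
#' @param hot_region_count number of Gaussian hot blobs (hot_region only).
#' @param noise_sd standard deviation of additive Gaussian sensor noise (degC).
#' @param seed RNG seed; equal specs generate bit-identical thermograms.
#' @param side which foot the mask represents.
#' @param arch_amplitude peak elevation of the butterfly arch over the
#'   baseline (degC).
#' @param boundaries TCI class cut points used for class targeting.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(image_shape = c(120L, 64L),
                           pattern = c("butterfly", "hot_region"),
                           target_class = 1L,
                           background_temp = 22,
                           base_foot_temp = 30,
                           hot_region_count = 2L,
                           noise_sd = 0.3,
                           seed = 1L,
                           side = c("left", "right"),
                           arch_amplitude = 4,
                           boundaries = default_tci_boundaries()) {
  pattern <- match.arg(pattern)
  side <- match.arg(side)
  if (!(target_class %in% 1:5)) stop_validation("target_class must be in 1..5")
  if (noise_sd < 0) stop_validation("noise_sd must be >= 0")
  if (background_temp >= base_foot_temp)
    stop_validation("background_temp must be below base_foot_temp")
  structure(list(image_shape = as.integer(image_shape), pattern = pattern,
                 target_class = as.integer(target_class),
                 background_temp = background_temp,
                 base_foot_temp = base_foot_temp,
                 hot_region_count = as.integer(hot_region_count),
                 noise_sd = noise_sd, seed = as.integer(seed), side = side,
                 arch_amplitude = arch_amplitude, boundaries = boundaries),
            class = "synthetic_spec")
}

# Elliptical foot mask covering roughly half the frame, slightly narrower at
# the heel. Returns a 0/1 integer matrix.
synthetic_foot_mask <- function(shape) {
  R <- shape[1]; C <- shape[2]
  r <- matrix(seq_len(R), R, C)
  cc <- matrix(seq_len(C), R, C, byrow = TRUE)
  cy <- (R + 1) / 2; cx <- (C + 1) / 2
  ry <- 0.46 * R
  # taper: forefoot (top) wider than heel (bottom)
  taper <- 1 - 0.25 * pmax(0, (r - cy) / ry)
  rx <- 0.38 * C * taper
  m <- ((r - cy) / ry)^2 + ((cc - cx) / rx)^2 <= 1
  m * 1L
}

# Noise-free butterfly field and the planted arch band (elevation >= half
# the arch amplitude). The arch sits on the medial half at mid-foot height.
butterfly_field <- function(spec, mask) {
  R <- spec$image_shape[1]; C <- spec$image_shape[2]
  r <- matrix(seq_len(R), R, C)
  cc <- matrix(seq_len(C), R, C, byrow = TRUE)
  medial_sign <- if (spec$side == "left") 1 else -1
  arch_r <- 0.48 * R
  arch_c <- (C + 1) / 2 + medial_sign * 0.14 * C
  sr <- 0.16 * R; sc <- 0.14 * C
  elev <- spec$arch_amplitude *
    exp(-0.5 * (((r - arch_r) / sr)^2 + ((cc - arch_c) / sc)^2))
  temps <- matrix(spec$background_temp, R, C)
  temps[mask == 1L] <- spec$base_foot_temp + elev[mask == 1L]
  band <- (elev >= spec$arch_amplitude / 2) & (mask == 1L)
  list(temps = temps, arch_band = band * 1L)
}

# Hot blobs with unit total amplitude scale; centers/sizes drawn from the
# spec seed so calibration and final rendering see the same geometry.
# Blob width grows with the target class: higher change grades correspond
# to hot regions covering progressively more of the sole, up to almost the
# whole plantar region at level 5.
hot_blob_field <- function(spec, mask) {
  R <- spec$image_shape[1]; C <- spec$image_shape[2]
  n <- spec$hot_region_count
  field <- matrix(0, R, C)
  if (n == 0L) return(field)
  idx <- which(mask == 1L)
  widen <- 1 + 0.35 * (spec$target_class - 1L)
  with_seed(spec$seed + 7919L, {
    centers <- sample(idx, n)
    rel_amp <- stats::runif(n, 0.5, 1)
    sig <- stats::runif(n, 0.10, 0.18) * min(R, C) * widen
    r <- matrix(seq_len(R), R, C)
    cc <- matrix(seq_len(C), R, C, byrow = TRUE)
    for (i in seq_len(n)) {
      cr <- ((centers[i] - 1) %% R) + 1
      ccol <- ((centers[i] - 1) %/% R) + 1
      field <- field + rel_amp[i] *
        exp(-0.5 * (((r - cr) / sig[i])^2 + ((cc - ccol) / sig[i])^2))
    }
  })
  field
}

#' Control reference angiosome temperatures for a synthetic geometry
#'
#' Mean angiosome temperatures of the noise-free butterfly pattern on the
#' same frame, against which generated hot-region subjects are graded.
#'
#' @param spec a [synthetic_spec()].
#' @return An `angiosome_temps` object.
#' @export
synthetic_reference <- function(spec) {
  mask <- synthetic_foot_mask(spec$image_shape)
  bf <- butterfly_field(spec, mask)
  tg <- thermogram(bf$temps, mask = mask, subject_id = "synthetic-control",
                   group = "control", side = spec$side)
  amap <- partition_angiosomes(mask, side = spec$side)
  angiosome_means(tg, amap)
}

#' Generate a synthetic plantar thermogram
#'
#' `butterfly` places the temperature maximum along the medial arch, decaying
#' outward, over a cold uniform background. `hot_region` starts from a flat
#' plantar field (the butterfly pattern is lost in DM feet) and adds
#' `hot_region_count` Gaussian hot blobs whose common amplitude scale is
#' calibrated by bisection, on the noise-free field, so that the TCI against
#' [synthetic_reference()] falls inside the `target_class` interval.
#' Gaussian noise of sd `noise_sd` is added last. Equal specs produce
#' bit-identical output.
#'
#' @param spec a [synthetic_spec()].
#' @return A [thermogram] with attributes: `arch_band` (binary matrix of the
#'   planted arch, butterfly only), `reference` (control `angiosome_temps`),
#'   `achieved_tci` and `achieved_level` (hot_region only).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  mask <- synthetic_foot_mask(spec$image_shape)
  amap <- partition_angiosomes(mask, side = spec$side)
  ref <- {
    bf <- butterfly_field(spec, mask)
    tg0 <- thermogram(bf$temps, mask = mask, group = "control", side = spec$side)
    angiosome_means(tg0, amap)
  }

  if (spec$pattern == "butterfly") {
    bf <- butterfly_field(spec, mask)
    temps <- bf$temps
    attr_extra <- list(arch_band = bf$arch_band)
  } else {
    blobs <- hot_blob_field(spec, mask)
    tci_at <- function(beta) {
      temps <- matrix(spec$background_temp, spec$image_shape[1], spec$image_shape[2])
      temps[mask == 1L] <- spec$base_foot_temp + beta * blobs[mask == 1L]
      subj <- angiosome_means(thermogram(temps, mask = mask, side = spec$side), amap)
      compute_tci(subj, ref)
    }
    b <- spec$boundaries
    # signed target: blobs warm the subject, so TCI decreases monotonically
    # with the amplitude scale; class k >= 2 targets the midpoint of
    # (-b[k], -b[k-1]), class 5 one unit beyond the last cut, class 1 zero.
    target <- if (spec$target_class == 1L) 0 else
      if (spec$target_class == 5L) -(b[4] + 1) else
        -(b[spec$target_class - 1L] + b[spec$target_class]) / 2
    beta_hi <- 40
    if (tci_at(0) < target || tci_at(beta_hi) > target)
      stop_validation("target_class ", spec$target_class,
                      " unreachable: TCI range [", round(tci_at(beta_hi), 3),
                      ", ", round(tci_at(0), 3), "] cannot reach ", target)
    lo <- 0; hi <- beta_hi
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (tci_at(mid) > target) lo <- mid else hi <- mid
    }
    beta <- (lo + hi) / 2
    temps <- matrix(spec$background_temp, spec$image_shape[1], spec$image_shape[2])
    temps[mask == 1L] <- spec$base_foot_temp + beta * blobs[mask == 1L]
    achieved <- tci_at(beta)
    if (assign_level(achieved, b) != spec$target_class)
      stop_validation("calibrated TCI ", round(achieved, 4),
                      " misses class ", spec$target_class, " interval")
    attr_extra <- list(achieved_tci = achieved,
                       achieved_level = assign_level(achieved, b))
  }

  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
      matrix(stats::rnorm(prod(spec$image_shape), 0, spec$noise_sd),
             spec$image_shape[1], spec$image_shape[2]))
    temps <- temps + noise
  }
  tg <- thermogram(temps, mask = mask,
                   subject_id = sprintf("synthetic-%s-%d", spec$pattern, spec$seed),
                   group = if (spec$pattern == "butterfly") "control" else "dm",
                   side = spec$side)
  attr(tg, "reference") <- ref
  for (nm in names(attr_extra)) attr(tg, nm) <- attr_extra[[nm]]
  tg
}
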