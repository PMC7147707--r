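#' Partition a foot mask into four plantar angiosomes
#'
#' The plantar surface is divided into the territories of the medial plantar
#' artery (MPA), lateral plantar artery (LPA), medial calcaneal artery (MCA)
#' and lateral calcaneal artery (LCA). The heel band (the proximal
#' `heel_fraction` of the mask's bounding-box height, at the bottom of the
#' image) is split at the per-row mask midline into MCA (medial) and LCA
#' (lateral); the remaining distal region is split the same way into MPA and
#' LPA. In plantar view the medial border of a left foot appears on the
#' right of the image, and vice versa.
#'
#' @param mask binary matrix, 1 = plantar pixel; must be a single connected
#'   region.
#' @param side `"left"` or `"right"` foot.
#' @param heel_fraction proportion of the mask's bounding-box height assigned
#'   to the calcaneal (heel) band; default 0.27.
#' @return An `angiosome_map`: a character matrix over the image with values
#'   `"MPA"`, `"LPA"`, `"MCA"`, `"LCA"` or `"background"`.
#' @export
partition_angiosomes <- function(mask, side = c("left", "right"),
                                 heel_fraction = 0.27) {
  side <- match.arg(side)
  mask <- (as.matrix(mask) != 0) * 1L
  if (sum(mask) == 0L) stop_validation("empty foot mask")
  lab <- EBImage::bwlabel(mask)
  if (max(lab) > 1L) stop_validation("foot mask is disconnected (",
                                     max(lab), " components)")
  rows <- which(rowSums(mask) > 0)
  r0 <- min(rows); r1 <- max(rows)
  height <- r1 - r0 + 1L
  heel_rows <- max(1L, ceiling(heel_fraction * height))
  heel_start <- r1 - heel_rows + 1L

  out <- matrix("background", nrow(mask), ncol(mask))
  medial_is_right <- (side == "left")
  for (r in rows) {
    cols <- which(mask[r, ] == 1L)
    if (!length(cols)) next
    mid <- (min(cols) + max(cols)) / 2
    medial <- if (medial_is_right) cols[cols > mid] else cols[cols <= mid]
    lateral <- setdiff(cols, medial)
    if (r >= heel_start) {
      out[r, medial] <- "MCA"; out[r, lateral] <- "LCA"
    } else {
      out[r, medial] <- "MPA"; out[r, lateral] <- "LPA"
    }
  }
  structure(out, class = "angiosome_map", side = side,
            heel_rows = c(heel_start, r1))
}

#' Mean temperature per angiosome
#'
#' @param t a [thermogram] (its mask must agree with `a`'s foot region).
#' @param a an `angiosome_map` from [partition_angiosomes()].
#' @return An `angiosome_temps` object: named list with `mpa`, `lpa`, `mca`,
#'   `lca` mean temperatures (degC).
#' @export
angiosome_means <- function(t, a) {
  stopifnot(inherits(t, "thermogram"), inherits(a, "angiosome_map"))
  if (!identical(dim(t$temps), dim(unclass(a))))
    stop_validation("thermogram and angiosome map dimensions differ")
  regs <- c(mpa = "MPA", lpa = "LPA", mca = "MCA", lca = "LCA")
  vals <- lapply(regs, function(r) {
    sel <- unclass(a) == r
    if (!any(sel)) stop_validation("angiosome region ", r, " is empty")
    mean(t$temps[sel])
  })
  structure(vals, class = "angiosome_temps")
}

#' Build angiosome temperatures from four values
#'
#' @param mpa,lpa,mca,lca mean temperatures in degrees Celsius.
#' @return An `angiosome_temps` object.
#' @export
angiosome_temps <- function(mpa, lpa, mca, lca) {
  v <- c(mpa, lpa, mca, lca)
  if (any(!is.finite(v))) stop_validation("angiosome temperatures must be finite")
  structure(list(mpa = mpa, lpa = lpa, mca = mca, lca = lca),
            class = "angiosome_temps")
}

#' Thermal change index (TCI)
#'
#' The signed mean, over the four angiosomes, of the control-reference
#' temperature minus the subject temperature:
#' \deqn{TCI = \frac{1}{4}\sum_{ang} (C_{ang} - DM_{ang})}
#' A subject warmer than the reference therefore yields a negative TCI.
#' With `absolute = TRUE` the per-angiosome differences enter as absolute
#' values instead.
#'
#' @param subject `angiosome_temps` of the subject (DM) foot.
#' @param reference `angiosome_temps` of the control reference.
#' @param absolute use per-angiosome absolute differences (default `FALSE`,
#'   the signed convention).
#' @return TCI in degrees Celsius.
#' @export
compute_tci <- function(subject, reference, absolute = FALSE) {
  stopifnot(inherits(subject, "angiosome_temps"),
            inherits(reference, "angiosome_temps"))
  d <- unlist(reference[c("mpa", "lpa", "mca", "lca")]) -
       unlist(subject[c("mpa", "lpa", "mca", "lca")])
  if (absolute) d <- abs(d)
  unname(mean(d))
}

#' Default TCI class boundaries
#'
#' Equally spaced cut points (1, 2, 3, 4 degC) separating the five thermal
#' change levels. These are configuration defaults; population-derived cut
#' points should be supplied where available.
#' @export
default_tci_boundaries <- function() c(1, 2, 3, 4)

#' Assign a five-level thermal change class
#'
#' The magnitude of the TCI is binned against four strictly increasing
#' boundaries: level = 1 + number of boundaries strictly below `|tci|`
#' (or below the signed value with `signed = TRUE`).
#'
#' @param tci thermal change index (degC).
#' @param boundaries strictly increasing vector of 4 cut points.
#' @param signed bin the signed TCI rather than its magnitude.
#' @return Integer level in 1..5.
#' @export
assign_level <- function(tci, boundaries = default_tci_boundaries(),
                         signed = FALSE) {
  boundaries <- as.numeric(boundaries)
  if (is.unsorted(boundaries, strictly = TRUE))
    stop_validation("boundaries must be strictly increasing")
  x <- if (signed) tci else abs(tci)
  1L + sum(boundaries < x)
}

#' Full TCI grading of a subject thermogram
#'
#' Convenience wrapper: partitions the subject's mask into angiosomes,
#' computes its mean angiosome temperatures and the TCI against a control
#' reference, and assigns the change level.
#'
#' @param t subject [thermogram] (must carry a mask).
#' @param reference control `angiosome_temps`.
#' @param boundaries class cut points, see [assign_level()].
#' @param heel_fraction see [partition_angiosomes()].
#' @return A `tci_result`: list with `tci`, `level`, `boundaries_used`,
#'   `subject_temps`.
#' @export
grade_thermogram <- function(t, reference,
                             boundaries = default_tci_boundaries(),
                             heel_fraction = 0.27) {
  stopifnot(inherits(t, "thermogram"))
  if (is.null(t$mask)) stop_validation("thermogram has no foot mask")
  amap <- partition_angiosomes(t$mask, side = t$side,
                               heel_fraction = heel_fraction)
  subj <- angiosome_means(t, amap)
  tci <- compute_tci(subj, reference)
  structure(list(tci = tci, level = assign_level(tci, boundaries),
                 boundaries_used = boundaries, subject_temps = subj),
            class = "tci_result")
}

#' @export
print.tci_result <- function(x, ...) {
  cat(sprintf("<tci_result> TCI = %.3f degC, level %d (boundaries: %s)\n",
              x$tci, x$level, paste(x$boundaries_used, collapse = ", ")))
  invisible(x)
}
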