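#' Five-element ROI feature vector
#'
#' Features of the hottest-region ROI used by the classical classifiers:
#' number of ROI pixels, mean and population variance of the ROI gray
#' values, the maximum total fuzzy entropy of the segmentation that produced
#' the ROI, and the index value — by default the modal gray level inside the
#' ROI (ties broken toward the lowest level); alternatively the ROI's
#' segment index.
#'
#' @param seg a `segmentation_result` with a non-empty `roi_mask`.
#' @param img the [gray_image] the segmentation was computed on.
#' @param index_mode `"modal_gray"` (default) or `"segment_index"`.
#' @return Named numeric vector `c(n_pixels, mean_value, variance,
#'   max_entropy, index_value)` with attribute `index_mode`.
#' @export
extract_features <- function(seg, img, index_mode = c("modal_gray", "segment_index")) {
  index_mode <- match.arg(index_mode)
  stopifnot(inherits(seg, "segmentation_result"), inherits(img, "gray_image"))
  sel <- seg$roi_mask != 0
  if (!any(sel)) stop_validation("empty ROI: no features to extract")
  v <- as.numeric(img$pixels[sel])
  idx <- if (index_mode == "modal_gray") {
    counts <- tabulate(v + 1L, nbins = img$levels)
    which.max(counts) - 1L          # lowest level wins ties
  } else {
    length(seg$thresholds)          # label of the top segment
  }
  out <- c(n_pixels = length(v), mean_value = mean(v),
           variance = mean((v - mean(v))^2),   # population variance
           max_entropy = seg$entropy, index_value = as.numeric(idx))
  attr(out, "index_mode") <- index_mode
  out
}

#' Extract square patches on a regular grid
#'
#' Tiles the image row-major with the given size and stride and keeps tiles
#' whose foot-mask coverage is at least `min_mask_fraction`.
#'
#' @param img a [gray_image] or numeric matrix (e.g. a temperature field).
#' @param mask optional binary mask; `NULL` means full coverage everywhere.
#' @param patch_size side length of the square tiles.
#' @param stride grid step (default `patch_size`, non-overlapping).
#' @param min_mask_fraction minimum fraction of mask pixels per kept tile.
#' @param label class label 1..5 attached to every patch.
#' @param source_id identifier of the source image.
#' @return A `patch_set`: list with `patches` (list of matrices), `origins`
#'   (matrix of top-left row/col), `source_id`, `label`, `transforms`.
#'   Empty (with a warning) when no tile qualifies.
#' @export
extract_patches <- function(img, mask = NULL, patch_size = 32L,
                            stride = patch_size, min_mask_fraction = 0.5,
                            label = 1L, source_id = "unknown") {
  m <- if (inherits(img, "gray_image")) img$pixels else as.matrix(img)
  patch_size <- as.integer(patch_size); stride <- as.integer(stride)
  if (patch_size > nrow(m) || patch_size > ncol(m))
    stop_validation("patch_size exceeds image dimensions")
  if (stride < 1L) stop_validation("stride must be positive")
  if (!is.null(mask)) mask <- (as.matrix(mask) != 0) * 1L
  rs <- seq(1L, nrow(m) - patch_size + 1L, by = stride)
  cs <- seq(1L, ncol(m) - patch_size + 1L, by = stride)
  patches <- list(); origins <- NULL
  for (r in rs) for (cc in cs) {            # row-major order
    cov <- if (is.null(mask)) 1 else
      mean(mask[r:(r + patch_size - 1L), cc:(cc + patch_size - 1L)])
    if (cov >= min_mask_fraction) {
      patches[[length(patches) + 1L]] <-
        m[r:(r + patch_size - 1L), cc:(cc + patch_size - 1L)]
      origins <- rbind(origins, c(r, cc))
    }
  }
  if (!length(patches)) {
    warning("no patch met the mask-coverage requirement")
    origins <- matrix(integer(), 0L, 2L)
  }
  colnames(origins) <- c("row", "col")
  structure(list(patches = patches, origins = origins,
                 source_id = source_id, label = as.integer(label),
                 transforms = rep("orig", length(patches))),
            class = "patch_set")
}

# 90-degree counter-clockwise rotation of a matrix.
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
flip_h <- function(m) m[, ncol(m):1, drop = FALSE]   # mirror columns
flip_v <- function(m) m[nrow(m):1, , drop = FALSE]   # mirror rows

#' Rotation/flip augmentation of a patch set
#'
#' Each square input patch yields seven variants in a fixed order: the
#' original, rotations by 90, 180 and 270 degrees, horizontal flip,
#' vertical flip, and horizontal+vertical flip. Labels and origins are
#' inherited.
#'
#' @param p a `patch_set` of square patches.
#' @return A `patch_set` with 7x as many patches; `transforms` records the
#'   variant (`orig`, `r90`, `r180`, `r270`, `fh`, `fv`, `fhv`).
#' @export
augment_patches <- function(p) {
  stopifnot(inherits(p, "patch_set"))
  if (any(vapply(p$patches, function(m) nrow(m) != ncol(m), logical(1))))
    stop_validation("augmentation requires square patches")
  ops <- list(orig = identity, r90 = rot90,
              r180 = function(m) rot90(rot90(m)),
              r270 = function(m) rot90(rot90(rot90(m))),
              fh = flip_h, fv = flip_v,
              fhv = function(m) flip_h(flip_v(m)))
  out <- vector("list", 7L * length(p$patches))
  transforms <- character(length(out))
  origins <- matrix(0L, length(out), 2L, dimnames = list(NULL, c("row", "col")))
  k <- 0L
  for (i in seq_along(p$patches)) {
    for (nm in names(ops)) {
      k <- k + 1L
      out[[k]] <- ops[[nm]](p$patches[[i]])
      transforms[k] <- nm
      origins[k, ] <- p$origins[i, ]
    }
  }
  structure(list(patches = out, origins = origins, source_id = p$source_id,
                 label = p$label, transforms = transforms),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  sz <- if (length(x$patches)) paste(dim(x$patches[[1]]), collapse = "x") else "-"
  cat(sprintf("<patch_set> %d patches (%s) from %s, class %d\n",
              length(x$patches), sz, x$source_id, x$label))
  invisible(x)
}
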