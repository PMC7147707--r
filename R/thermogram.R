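#' Construct a plantar thermogram
#'
#' A thermogram stores a per-pixel temperature field (degrees Celsius) of the
#' plantar region, an optional binary foot mask (1 = plantar pixel), and
#' subject metadata.
#'
#' @param temps numeric matrix of temperatures in degrees Celsius.
#' @param mask optional binary matrix (0/1 or logical) of the same dimensions;
#'   1 marks plantar pixels.
#' @param subject_id character identifier.
#' @param group subject group, `"control"` or `"dm"`.
#' @param side imaged foot, `"left"` or `"right"`.
#' @return An object of class `thermogram`.
#' @export
thermogram <- function(temps, mask = NULL, subject_id = "unknown",
                       group = c("dm", "control"), side = c("left", "right")) {
  group <- match.arg(group)
  side <- match.arg(side)
  temps <- as.matrix(temps)
  storage.mode(temps) <- "double"
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(temps)))
      stop_validation("mask dimensions ", paste(dim(mask), collapse = "x"),
                      " do not match temps ", paste(dim(temps), collapse = "x"))
    mask <- (mask != 0) * 1L
    if (sum(mask) == 0L)
      stop_validation("mask has no plantar pixels")
    if (any(!is.finite(temps[mask == 1L])))
      stop_validation("non-finite temperatures under the mask")
  } else if (any(!is.finite(temps))) {
    stop_validation("non-finite temperatures and no mask to exclude them")
  }
  structure(list(temps = temps, mask = mask, subject_id = subject_id,
                 group = group, side = side),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  d <- dim(x$temps)
  rng <- range(if (is.null(x$mask)) x$temps else x$temps[x$mask == 1L])
  cat(sprintf("<thermogram> %s (%s, %s foot): %dx%d px, %.1f-%.1f degC%s\n",
              x$subject_id, x$group, x$side, d[1], d[2], rng[1], rng[2],
              if (is.null(x$mask)) "" else sprintf(", mask %d px", sum(x$mask))))
  invisible(x)
}

#' Construct a gray-level image
#'
#' @param pixels integer matrix of gray levels in `[0, levels - 1]`.
#' @param levels number of gray levels L (>= 2).
#' @return An object of class `gray_image` with fields `pixels` and `levels`.
#' @export
gray_image <- function(pixels, levels) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  levels <- as.integer(levels)
  if (levels < 2L) stop_validation("levels must be >= 2")
  if (any(pixels < 0L | pixels > levels - 1L))
    stop_validation("pixel values outside [0, ", levels - 1L, "]")
  structure(list(pixels = pixels, levels = levels), class = "gray_image")
}

#' Quantize a thermogram to gray levels
#'
#' Linear min-max quantization of the temperature field onto
#' `0 ... levels - 1`. By default the range is taken per image (the coldest
#' pixel maps to 0, the hottest to `levels - 1`); an absolute range can be
#' supplied for cross-image comparability.
#'
#' @param t a [thermogram].
#' @param levels number of gray levels (default 256).
#' @param range optional `c(min, max)` absolute temperature range; when `NULL`
#'   (default) the image's own range is used.
#' @param restrict_to_mask if `TRUE` and a mask is present, the quantization
#'   range is computed over mask pixels only.
#' @return A [gray_image]. A constant input maps every pixel to 0 and sets
#'   attribute `constant_input = TRUE` with a warning.
#' @export
to_gray <- function(t, levels = 256L, range = NULL, restrict_to_mask = FALSE) {
  stopifnot(inherits(t, "thermogram"))
  levels <- as.integer(levels)
  if (levels < 2L) stop_validation("levels must be >= 2")
  v <- t$temps
  src <- if (restrict_to_mask && !is.null(t$mask)) v[t$mask == 1L] else v
  rng <- if (is.null(range)) base::range(src, finite = TRUE) else as.numeric(range)
  constant <- FALSE
  if (diff(rng) <= 0) {
    warning("constant temperature field: all pixels map to gray 0")
    px <- matrix(0L, nrow(v), ncol(v))
    constant <- TRUE
  } else {
    # scale to [0, levels-1]; floor with a top-edge clamp so the maximum
    # lands on levels-1 rather than overflowing
    scaled <- (v - rng[1]) / (rng[2] - rng[1]) * levels
    px <- pmin(pmax(floor(scaled), 0), levels - 1L)
    storage.mode(px) <- "integer"
  }
  g <- gray_image(px, levels)
  attr(g, "constant_input") <- constant
  attr(g, "temp_range") <- rng
  g
}

mask_sibling_path <- function(path) {
  sub("\\.[A-Za-z0-9]+$", "_mask.png", path)
}

#' Read a thermogram from disk
#'
#' Supported encodings: `csv` (comma-separated temperature matrix, row-major,
#' no header, degrees Celsius), `tiff16` (16-bit grayscale TIFF holding
#' temperatures linearly mapped over `temp_range`), and `png8` (8-bit
#' grayscale PNG, likewise mapped over `temp_range`). A binary mask is loaded
#' automatically from the sibling file `<stem>_mask.png` when present.
#'
#' @param path input file path.
#' @param format one of `"csv"`, `"tiff16"`, `"png8"`.
#' @param temp_range temperature range `c(min, max)` encoded by the raster
#'   formats (default `c(18, 38)` degC, a typical plantar window).
#' @param ... metadata passed to [thermogram()] (`subject_id`, `group`, `side`).
#' @return A [thermogram].
#' @export
read_thermogram <- function(path, format = c("csv", "tiff16", "png8"),
                            temp_range = c(18, 38), ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format("file not found: ", path)
  temps <- switch(format,
    csv = {
      rows <- tryCatch(utils::read.csv(path, header = FALSE),
                       error = function(e) stop_format("cannot parse CSV ", path, ": ",
                                                       conditionMessage(e)))
      as.matrix(rows)
    },
    tiff16 = {
      img <- tryCatch(tiff::readTIFF(path),
                      error = function(e) stop_format("cannot read TIFF ", path, ": ",
                                                      conditionMessage(e)))
      if (length(dim(img)) == 3L) img <- img[, , 1L]
      temp_range[1] + img * diff(temp_range)
    },
    png8 = {
      img <- tryCatch(png::readPNG(path),
                      error = function(e) stop_format("cannot read PNG ", path, ": ",
                                                      conditionMessage(e)))
      if (length(dim(img)) == 3L) img <- img[, , 1L]
      temp_range[1] + img * diff(temp_range)
    })
  dimnames(temps) <- NULL
  mask <- NULL
  mp <- mask_sibling_path(path)
  if (mp != path && file.exists(mp)) {
    m <- png::readPNG(mp)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    mask <- (m > 0.5) * 1L
  }
  thermogram(temps, mask = mask, ...)
}

#' Write a thermogram to disk
#'
#' Inverse of [read_thermogram()]; the mask (if any) is written to the
#' sibling file `<stem>_mask.png` as a 0/255 PNG.
#'
#' @inheritParams read_thermogram
#' @param t a [thermogram].
#' @return `path`, invisibly.
#' @export
write_thermogram <- function(t, path, format = c("csv", "tiff16", "png8"),
                             temp_range = c(18, 38)) {
  stopifnot(inherits(t, "thermogram"))
  format <- match.arg(format)
  switch(format,
    csv = utils::write.table(t$temps, path, sep = ",", row.names = FALSE,
                             col.names = FALSE),
    tiff16 = {
      z <- (t$temps - temp_range[1]) / diff(temp_range)
      tiff::writeTIFF(pmin(pmax(z, 0), 1), path, bits.per.sample = 16L)
    },
    png8 = {
      z <- (t$temps - temp_range[1]) / diff(temp_range)
      png::writePNG(pmin(pmax(z, 0), 1), path)
    })
  if (!is.null(t$mask))
    png::writePNG(matrix(as.numeric(t$mask), nrow(t$mask)),
                  mask_sibling_path(path))
  invisible(path)
}
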