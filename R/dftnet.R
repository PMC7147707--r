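#' DFTNet architecture specification
#'
#' The fixed nine-layer stack of the thermogram patch classifier:
#' conv 7x7/32, maxpool 3x3 s2, conv 1x1/64, conv 3x3/64, maxpool 3x3 s2,
#' conv 3x3/32, maxpool 2x2 s2, conv 3x3/32, fully-connected with one unit
#' per class. Convolutions are stride 1 with same-padding and ReLU
#' activations; pools use valid padding; the output layer feeds a softmax.
#'
#' @param input_shape `c(H, W, C)` of the input patches (default
#'   `c(64, 64, 3)`; grayscale patches are replicated across channels by
#'   [dftnet_train()]).
#' @param n_classes number of output classes (>= 2).
#' @return A `dftnet_spec` object with the immutable `layers` list.
#' @export
dftnet_spec <- function(input_shape = c(64L, 64L, 3L), n_classes = 2L) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop_validation("n_classes must be >= 2")
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3L || any(input_shape < 1L))
    stop_validation("input_shape must be c(H, W, C)")
  layers <- list(
    list(type = "conv",    kernel = c(7L, 7L), stride = 1L, filters = 32L),
    list(type = "maxpool", kernel = c(3L, 3L), stride = 2L),
    list(type = "conv",    kernel = c(1L, 1L), stride = 1L, filters = 64L),
    list(type = "conv",    kernel = c(3L, 3L), stride = 1L, filters = 64L),
    list(type = "maxpool", kernel = c(3L, 3L), stride = 2L),
    list(type = "conv",    kernel = c(3L, 3L), stride = 1L, filters = 32L),
    list(type = "maxpool", kernel = c(2L, 2L), stride = 2L),
    list(type = "conv",    kernel = c(3L, 3L), stride = 1L, filters = 32L),
    list(type = "fc",      units = n_classes))
  structure(list(layers = layers, input_shape = input_shape,
                 n_classes = n_classes),
            class = "dftnet_spec")
}

#' Training configuration for DFTNet
#'
#' Defaults follow the reference regime: Adam with learning rate 0.001,
#' minibatch size 64, at most 100 epochs.
#'
#' @param max_epochs maximum number of epochs.
#' @param batch_size minibatch size.
#' @param optimizer only `"adam"` is implemented.
#' @param learning_rate Adam step size (0 disables learning).
#' @param seed RNG seed for initialization and epoch shuffling.
#' @param early_stop optional list `list(metric = "train_accuracy",
#'   threshold = x)` (or `metric = "val_accuracy"` when validation data are
#'   given): training stops once the epoch metric reaches the threshold.
#' @return A `dftnet_train_config` object.
#' @export
dftnet_train_config <- function(max_epochs = 100L, batch_size = 64L,
                                optimizer = "adam", learning_rate = 0.001,
                                seed = 1L, early_stop = NULL) {
  optimizer <- match.arg(optimizer)
  if (max_epochs < 1L || batch_size < 1L || learning_rate < 0)
    stop_validation("epochs and batch size must be positive, learning_rate >= 0")
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 learning_rate = learning_rate, seed = as.integer(seed),
                 early_stop = early_stop),
            class = "dftnet_train_config")
}

# --- geometry --------------------------------------------------------------
# Activations are stored as [H*W, C] matrices with column-major plane
# vectors (index r + (c-1)*H), so convolutions reduce to one indexing pass
# (im2col) plus a BLAS matrix product.

# im2col index map for a same-padded stride-1 convolution on an H x W plane:
# padded plane size, indices of real positions inside the padded plane, and
# an [H*W, kh*kw] matrix of padded-plane indices per output position.
conv_geometry <- function(H, W, kh, kw) {
  pt <- (kh - 1L) %/% 2L; pl <- (kw - 1L) %/% 2L
  Hp <- H + kh - 1L; Wp <- W + kw - 1L
  inner <- as.vector(outer((pt + 1L):(pt + H), (pl + 1L):(pl + W),
                           function(r, c) r + (c - 1L) * Hp))
  out_r <- rep(seq_len(H), W); out_c <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, kh * kw)
  j <- 0L
  for (dw in 0L:(kw - 1L)) for (dh in 0L:(kh - 1L)) {
    j <- j + 1L
    idx[, j] <- (out_r + dh) + (out_c + dw - 1L) * Hp
  }
  list(Hp = Hp, Wp = Wp, inner = inner, idx = idx)
}

# Valid-padded pool: output size and an [Ho*Wo, k*k] matrix of input-plane
# indices. Errors when the window does not fit.
pool_geometry <- function(H, W, k, s, layer_no) {
  if (k > H || k > W)
    stop_validation("input ", H, "x", W, " too small for the ", k, "x", k,
                    " pool at layer ", layer_no)
  Ho <- (H - k) %/% s + 1L; Wo <- (W - k) %/% s + 1L
  out_r <- rep(seq_len(Ho), Wo); out_c <- rep(seq_len(Wo), each = Ho)
  in_r0 <- (out_r - 1L) * s; in_c0 <- (out_c - 1L) * s
  idx <- matrix(0L, Ho * Wo, k * k)
  j <- 0L
  for (dw in 1L:k) for (dh in 1L:k) {
    j <- j + 1L
    idx[, j] <- (in_r0 + dh) + (in_c0 + dw - 1L) * H
  }
  list(Ho = Ho, Wo = Wo, idx = idx)
}

he_uniform <- function(nr, nc, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build a DFTNet model
#'
#' Precomputes the layer geometry for the spec's input shape and draws
#' seeded initial weights: He-uniform for the convolution kernels, zeros
#' for the output layer, so an untrained network predicts the uniform
#' distribution and the initial cross-entropy equals `log(n_classes)`.
#'
#' @param spec a [dftnet_spec()].
#' @param seed RNG seed for weight initialization.
#' @return A `dftnet_model` (an environment) with fields `spec`, `layers`
#'   (geometry + parameters) and `shapes` (per-layer output `c(H, W, C)`).
#' @export
dftnet_build <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "dftnet_spec"))
  H <- spec$input_shape[1]; W <- spec$input_shape[2]; C <- spec$input_shape[3]
  layers <- vector("list", length(spec$layers))
  shapes <- vector("list", length(spec$layers) + 1L)
  shapes[[1L]] <- c(H, W, C)
  with_seed(seed, {
    for (li in seq_along(spec$layers)) {
      ly <- spec$layers[[li]]
      if (ly$type == "conv") {
        geo <- conv_geometry(H, W, ly$kernel[1], ly$kernel[2])
        k2 <- prod(ly$kernel)
        layers[[li]] <- list(
          type = "conv", kernel = ly$kernel, stride = ly$stride,
          filters = ly$filters, in_channels = C, geo = geo, H = H, W = W,
          W_mat = he_uniform(k2 * C, ly$filters, fan_in = k2 * C),
          b = numeric(ly$filters))
        C <- ly$filters
      } else if (ly$type == "maxpool") {
        geo <- pool_geometry(H, W, ly$kernel[1], ly$stride, li)
        layers[[li]] <- list(type = "maxpool", kernel = ly$kernel,
                             stride = ly$stride, geo = geo, H = H, W = W,
                             channels = C)
        H <- geo$Ho; W <- geo$Wo
      } else {                               # fc
        fan_in <- H * W * C
        layers[[li]] <- list(type = "fc", units = ly$units, fan_in = fan_in,
                             W_mat = matrix(0, fan_in, ly$units),
                             b = numeric(ly$units))
        H <- 1L; W <- 1L; C <- ly$units
      }
      shapes[[li + 1L]] <- c(H, W, C)
    }
  })
  model <- new.env(parent = emptyenv())
  model$spec <- spec
  model$layers <- layers
  model$shapes <- shapes
  model$seed <- as.integer(seed)
  class(model) <- "dftnet_model"
  model
}

#' Structural dump of a built model
#'
#' One row per layer: type, kernel, stride, filter count or FC units, and
#' the output shape — for auditing the built network layer by layer.
#'
#' @param model a `dftnet_model`.
#' @return A data.frame with one row per layer.
#' @export
dftnet_structure <- function(model) {
  stopifnot(inherits(model, "dftnet_model"))
  do.call(rbind, lapply(seq_along(model$layers), function(i) {
    ly <- model$layers[[i]]
    data.frame(
      layer = i,
      type = switch(ly$type, conv = "Conv.", maxpool = "Max-Pool",
                    fc = "Full Conn."),
      kernel = if (ly$type == "fc") "-" else
        paste0(ly$kernel[1], "x", ly$kernel[2]),
      stride = if (ly$type == "fc") "-" else paste0(ly$stride, "x", ly$stride),
      filters = if (ly$type == "conv") ly$filters else NA_integer_,
      fc_units = if (ly$type == "fc") ly$units else NA_integer_,
      out_shape = paste(model$shapes[[i + 1L]], collapse = "x"),
      stringsAsFactors = FALSE)
  }))
}

#' Number of trainable parameters
#' @param model a `dftnet_model`.
#' @return Total count of weights and biases.
#' @export
dftnet_n_params <- function(model) {
  sum(vapply(model$layers, function(ly) {
    if (ly$type == "maxpool") 0 else length(ly$W_mat) + length(ly$b)
  }, numeric(1)))
}

# --- forward / backward ----------------------------------------------------

# Forward pass for one image given as an [H*W, C] matrix. Returns class
# probabilities and, when keep = TRUE, per-layer caches for backprop.
dftnet_forward_one <- function(model, A, keep = FALSE) {
  cache <- if (keep) vector("list", length(model$layers)) else NULL
  for (li in seq_along(model$layers)) {
    ly <- model$layers[[li]]
    if (ly$type == "conv") {
      geo <- ly$geo
      HW <- nrow(geo$idx); k2 <- ncol(geo$idx)
      P <- matrix(0, geo$Hp * geo$Wp, ly$in_channels)
      P[geo$inner, ] <- A
      Xcol <- matrix(P[as.vector(geo$idx), ], HW, k2 * ly$in_channels)
      Z <- Xcol %*% ly$W_mat
      Z <- sweep(Z, 2L, ly$b, "+")
      mask <- Z > 0
      A <- Z * mask
      if (keep) cache[[li]] <- list(Xcol = Xcol, relu = mask)
    } else if (ly$type == "maxpool") {
      geo <- ly$geo
      HWo <- nrow(geo$idx); k2 <- ncol(geo$idx)
      out <- matrix(0, HWo, ly$channels)
      amax <- matrix(0L, HWo, ly$channels)
      for (ch in seq_len(ly$channels)) {
        V <- matrix(A[geo$idx, ch], HWo, k2)
        m <- max.col(V, ties.method = "first")
        out[, ch] <- V[cbind(seq_len(HWo), m)]
        amax[, ch] <- m
      }
      if (keep) cache[[li]] <- list(amax = amax, in_HW = nrow(A))
      A <- out
    } else {                                 # fc + softmax
      a <- as.vector(A)
      z <- drop(crossprod(ly$W_mat, a)) + ly$b
      z <- z - max(z)
      p <- exp(z); p <- p / sum(p)
      if (keep) cache[[li]] <- list(a = a)
      A <- matrix(p, 1L)
    }
  }
  list(probs = drop(A), cache = cache)
}

# Backward pass for one image. `dlogit` is (p - onehot) at the FC output;
# gradients are accumulated into the `grads` list of environments.
dftnet_backward_one <- function(model, cache, dlogit, grads) {
  d <- dlogit                               # gradient w.r.t. current output
  for (li in rev(seq_along(model$layers))) {
    ly <- model$layers[[li]]
    if (ly$type == "fc") {
      cc <- cache[[li]]
      grads[[li]]$dW <- grads[[li]]$dW + cc$a %o% d
      grads[[li]]$db <- grads[[li]]$db + d
      prev <- model$shapes[[li]]            # input shape of this layer
      d <- matrix(drop(ly$W_mat %*% d), prev[1] * prev[2], prev[3])
    } else if (ly$type == "maxpool") {
      cc <- cache[[li]]
      geo <- ly$geo
      dprev <- matrix(0, cc$in_HW, ly$channels)
      for (j in seq_len(ncol(geo$idx))) {
        sel <- which(cc$amax == j, arr.ind = TRUE)
        if (!nrow(sel)) next
        tgt <- geo$idx[sel[, 1L], j] + (sel[, 2L] - 1L) * cc$in_HW
        dprev[tgt] <- dprev[tgt] + d[sel]
      }
      d <- dprev
    } else {                                 # conv
      cc <- cache[[li]]
      dZ <- d * cc$relu
      grads[[li]]$dW <- grads[[li]]$dW + crossprod(cc$Xcol, dZ)
      grads[[li]]$db <- grads[[li]]$db + colSums(dZ)
      geo <- ly$geo
      k2 <- ncol(geo$idx)
      dXcol <- dZ %*% t(ly$W_mat)            # [HW, k2*C]
      dP <- matrix(0, geo$Hp * geo$Wp, ly$in_channels)
      for (j in seq_len(k2)) {
        cols <- j + k2 * (seq_len(ly$in_channels) - 1L)
        dP[geo$idx[, j], ] <- dP[geo$idx[, j], ] + dXcol[, cols, drop = FALSE]
      }
      d <- dP[geo$inner, , drop = FALSE]
    }
  }
  invisible(NULL)
}

# Coerce input images (list of H x W matrices or H x W x C arrays, or an
# H x W x C x N array) to a list of [H*W, C] matrices matching the spec.
as_input_list <- function(images, input_shape) {
  H <- input_shape[1]; W <- input_shape[2]; C <- input_shape[3]
  if (is.array(images) && length(dim(images)) == 4L)
    images <- lapply(seq_len(dim(images)[4]), function(i) images[, , , i])
  if (!is.list(images)) images <- list(images)
  lapply(images, function(im) {
    dm <- dim(im)
    if (length(dm) == 2L) {
      if (dm[1] != H || dm[2] != W)
        stop_validation("image ", dm[1], "x", dm[2], " does not match input ",
                        H, "x", W)
      matrix(rep(as.vector(im), C), H * W, C)   # replicate gray channel
    } else if (length(dm) == 3L) {
      if (dm[1] != H || dm[2] != W || dm[3] != C)
        stop_validation("image ", paste(dm, collapse = "x"),
                        " does not match input ", H, "x", W, "x", C)
      matrix(as.vector(im), H * W, C)
    } else stop_validation("images must be 2-D or 3-D")
  })
}

#' Train a DFTNet model
#'
#' Minimizes the softmax cross-entropy with minibatch Adam. The loss
#' trajectory is reproducible under a fixed seed.
#'
#' @param model a `dftnet_model` from [dftnet_build()]; updated in place
#'   and also returned.
#' @param images training images: list of `H x W` matrices (grayscale,
#'   replicated across channels) or `H x W x C` arrays, or an
#'   `H x W x C x N` array. Pixel values are expected in roughly `[0, 1]`.
#' @param labels integer class labels in `1..n_classes`.
#' @param cfg a [dftnet_train_config()].
#' @param val_images,val_labels optional held-out set evaluated once per
#'   epoch.
#' @return The model, with `model$history`: data.frame of per-epoch `loss`,
#'   `train_accuracy` and (when validation data are given) `val_accuracy`.
#' @export
dftnet_train <- function(model, images, labels, cfg = dftnet_train_config(),
                         val_images = NULL, val_labels = NULL) {
  stopifnot(inherits(model, "dftnet_model"))
  xs <- as_input_list(images, model$spec$input_shape)
  labels <- as.integer(labels)
  K <- model$spec$n_classes
  if (!length(xs)) stop_validation("empty training set")
  if (length(labels) != length(xs)) stop_validation("labels/images length mismatch")
  if (any(labels < 1L | labels > K))
    stop_validation("labels must be in 1..", K)
  if (length(unique(labels)) < 2L)
    stop_validation("training set contains a single class")
  vxs <- if (!is.null(val_images)) as_input_list(val_images, model$spec$input_shape)

  grads <- lapply(model$layers, function(ly) {
    g <- new.env(parent = emptyenv())
    if (ly$type != "maxpool") { g$dW <- ly$W_mat * 0; g$db <- ly$b * 0 }
    g
  })
  adam <- lapply(model$layers, function(ly) {
    if (ly$type == "maxpool") return(NULL)
    list(mW = ly$W_mat * 0, vW = ly$W_mat * 0,
         mb = ly$b * 0, vb = ly$b * 0)
  })
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  history <- NULL
  n <- length(xs)

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0; correct <- 0L
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        batch <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        B <- length(batch)
        for (li in seq_along(grads)) {
          if (model$layers[[li]]$type == "maxpool") next
          grads[[li]]$dW[] <- 0; grads[[li]]$db[] <- 0
        }
        for (i in batch) {
          fw <- dftnet_forward_one(model, xs[[i]], keep = TRUE)
          p <- fw$probs
          y <- labels[i]
          epoch_loss <- epoch_loss - log(max(p[y], 1e-12))
          if (which.max(p) == y) correct <- correct + 1L
          dlogit <- p; dlogit[y] <- dlogit[y] - 1
          dftnet_backward_one(model, fw$cache, dlogit, grads)
        }
        step <- step + 1L
        for (li in seq_along(model$layers)) {
          ly <- model$layers[[li]]
          if (ly$type == "maxpool") next
          gW <- grads[[li]]$dW / B; gb <- grads[[li]]$db / B
          st <- adam[[li]]
          st$mW <- b1 * st$mW + (1 - b1) * gW
          st$vW <- b2 * st$vW + (1 - b2) * gW^2
          st$mb <- b1 * st$mb + (1 - b1) * gb
          st$vb <- b2 * st$vb + (1 - b2) * gb^2
          adam[[li]] <- st
          corr1 <- 1 - b1^step; corr2 <- 1 - b2^step
          ly$W_mat <- ly$W_mat - cfg$learning_rate * (st$mW / corr1) /
            (sqrt(st$vW / corr2) + eps)
          ly$b <- ly$b - cfg$learning_rate * (st$mb / corr1) /
            (sqrt(st$vb / corr2) + eps)
          model$layers[[li]] <- ly
        }
      }
      row <- data.frame(epoch = epoch, loss = epoch_loss / n,
                        train_accuracy = correct / n)
      if (!is.null(val_images)) {
        vp <- vapply(vxs, function(x)
          which.max(dftnet_forward_one(model, x)$probs), integer(1))
        row$val_accuracy <- mean(vp == as.integer(val_labels))
      }
      history <- rbind(history, row)
      es <- cfg$early_stop
      if (!is.null(es)) {
        metric <- switch(es$metric, train_accuracy = row$train_accuracy,
                         val_accuracy = row$val_accuracy,
                         stop_validation("unknown early_stop metric"))
        if (isTRUE(metric >= es$threshold)) break
      }
    }
  })
  model$history <- history
  invisible(model)
}

#' Predict class probabilities with a DFTNet model
#'
#' Inference is deterministic given fixed weights; argmax ties break toward
#' the lowest class index.
#'
#' @param model a trained `dftnet_model`.
#' @param images as in [dftnet_train()].
#' @return List with `probs` (`N x n_classes` matrix, rows summing to 1)
#'   and `labels` (integer argmax per row).
#' @export
dftnet_predict <- function(model, images) {
  stopifnot(inherits(model, "dftnet_model"))
  xs <- as_input_list(images, model$spec$input_shape)
  probs <- t(vapply(xs, function(x) dftnet_forward_one(model, x)$probs,
                    numeric(model$spec$n_classes)))
  list(probs = probs, labels = apply(probs, 1L, which.max))
}

#' @export
print.dftnet_model <- function(x, ...) {
  cat(sprintf("<dftnet_model> input %s, %d classes, %d parameters%s\n",
              paste(x$spec$input_shape, collapse = "x"), x$spec$n_classes,
              dftnet_n_params(x),
              if (is.null(x$history)) " (untrained)" else
                sprintf(", trained %d epochs", nrow(x$history))))
  invisible(x)
}
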