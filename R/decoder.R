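# Waveform -> image decoding: preprocessing to the 4096-sample network
# input, three inverse models (five-layer fully connected net, small U-Net
# on the 64x64 reshape, ridge-regularized linear pseudoinverse), image
# metrics (pixelwise Pearson fidelity, SSIM), and direct waveform
# classification.

#' Decoder configuration
#'
#' @param arch `"fc5"` (five fully connected layers,
#'   4096-2048-1024-2048-4096 with sigmoid output), `"unet"` (convolutional
#'   encoder-decoder on the 64x64 reshape) or `"linear"` (ridge-regularized
#'   least squares, the linear pseudoinverse oracle).
#' @param input_len Waveform samples fed to the network (default 4096; must
#'   be a perfect square for `unet`).
#' @param output_shape Image output shape (default 64x64).
#' @param epochs,batch_size,learning_rate,seed Training hyperparameters.
#' @param lr_decay Learning-rate step factor applied at one third and two
#'   thirds of the epochs.
#' @param loss Training loss (`"mse"`).
#' @param ridge_lambda Ridge penalty for the linear architecture.
#' @param unet_base Channel width of the first U-Net level.
#' @return An object of class `decoder_config`.
#' @export
decoder_config <- function(arch = c("fc5", "unet", "linear"),
                           input_len = 4096, output_shape = c(64, 64),
                           epochs = 50, batch_size = 128,
                           learning_rate = 1e-3, lr_decay = 0.3, seed = 1,
                           loss = "mse", ridge_lambda = 1e-4,
                           unet_base = 8) {
  arch <- match.arg(arch)
  if (arch == "unet") {
    side <- sqrt(input_len)
    if (side != round(side)) {
      stop("input_len must be a perfect square for the unet architecture")
    }
  }
  if (loss != "mse") stop("only the mse loss is implemented")
  structure(list(arch = arch, input_len = input_len,
                 output_shape = output_shape, epochs = epochs,
                 batch_size = batch_size, learning_rate = learning_rate,
                 lr_decay = lr_decay, seed = seed, loss = loss,
                 ridge_lambda = ridge_lambda, unet_base = unet_base),
            class = "decoder_config")
}

# Crop / zero-pad a sample matrix (rows = frames) to `target_len` columns
# starting at column `start` (1-based; may be negative for padding).
crop_at <- function(samples, target_len, start) {
  n <- ncol(samples)
  idx <- start + seq_len(target_len) - 1
  out <- matrix(0, nrow(samples), target_len)
  keep <- idx >= 1 & idx <= n
  out[, keep] <- samples[, idx[keep], drop = FALSE]
  out
}

# Crop start centred on the support centroid of the mean absolute trace.
# Computed once on the training set and reused for held-out data, mimicking
# a fixed oscilloscope trigger.
centre_crop_start <- function(samples, target_len) {
  n <- ncol(samples)
  prof <- colMeans(abs(samples))
  centroid <- if (sum(prof) > 0) sum(prof * seq_len(n)) / sum(prof) else
    (n + 1) / 2
  round(centroid - target_len / 2)
}

#' Preprocess waveforms for the decoder
#'
#' Crops or zero-pads symmetrically about the support centroid to
#' `target_len` samples, then normalizes to zero mean and unit max-abs. When
#' `stats` is omitted the normalization statistics are computed from the
#' input (training-set role) and returned as an attribute; pass a training
#' set's statistics to transform held-out data consistently.
#'
#' @param w A `waveform`, a `waveform_set`, or a samples matrix.
#' @param target_len Output length (default 4096).
#' @param stats Optional list `(offset, scale)` from a previous call.
#' @return A matrix (rows = frames) with attribute `norm_stats`.
#' @export
preprocess_waveform <- function(w, target_len = 4096, stats = NULL) {
  samples <- if (inherits(w, "waveform")) matrix(w$samples, nrow = 1)
  else if (inherits(w, "waveform_set")) w$samples
  else as.matrix(w)
  if (ncol(samples) == 0) stop("waveform has zero length")
  if (all(samples == 0)) {
    warning("all-zero waveform; returning zeros")
    out <- matrix(0, nrow(samples), target_len)
    attr(out, "norm_stats") <- stats %||%
      list(offset = 0, scale = 1, crop_start = 1)
    return(out)
  }
  if (is.null(stats)) {
    start <- centre_crop_start(samples, target_len)
    x <- crop_at(samples, target_len, start)
    offset <- mean(x)
    scale <- max(abs(x - offset))
    if (scale == 0) scale <- 1
    stats <- list(offset = offset, scale = scale, crop_start = start)
  } else {
    x <- crop_at(samples, target_len,
                 stats$crop_start %||% centre_crop_start(samples, target_len))
  }
  out <- (x - stats$offset) / stats$scale
  attr(out, "norm_stats") <- stats
  out
}

# 64x64 training targets from a pattern tibble (bilinear, row-per-image,
# pixels flattened in the image's column-major storage order). The bilinear
# interpolation is a fixed linear map for a given shape pair, so it is
# applied to the whole set as one matrix product.
decoder_targets <- function(patterns, output_shape = c(64, 64)) {
  in_shape <- dim(patterns$image[[1]])
  w <- bilinear_weight_matrix(in_shape, output_shape)
  pattern_matrix(patterns) %*% w
}

# Sparse-in-structure (at most 4 nonzeros per column) weight matrix mapping
# a flattened in_shape image to its flattened bilinear resize.
bilinear_weight_matrix <- function(in_shape, out_shape) {
  key <- paste(c(in_shape, out_shape), collapse = "x")
  cache <- .bilinear_cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  rows <- in_shape[1]; cols <- in_shape[2]
  or <- out_shape[1]; oc <- out_shape[2]
  ys <- pmin(pmax((seq_len(or) - 0.5) * rows / or + 0.5, 1), rows)
  xs <- pmin(pmax((seq_len(oc) - 0.5) * cols / oc + 0.5, 1), cols)
  xm <- rep(xs, each = or)
  ym <- rep(ys, oc)
  x0 <- pmin(pmax(floor(xm), 1), cols); x1 <- pmin(x0 + 1, cols)
  y0 <- pmin(pmax(floor(ym), 1), rows); y1 <- pmin(y0 + 1, rows)
  fx <- pmin(pmax(xm - x0, 0), 1); fy <- pmin(pmax(ym - y0, 0), 1)
  w <- matrix(0, rows * cols, or * oc)
  out_idx <- seq_len(or * oc)
  add <- function(xx, yy, wt) {
    idx <- cbind((xx - 1) * rows + yy, out_idx)
    w[idx] <<- w[idx] + wt
  }
  add(x0, y0, (1 - fx) * (1 - fy))
  add(x1, y0, fx * (1 - fy))
  add(x0, y1, (1 - fx) * fy)
  add(x1, y1, fx * fy)
  cache[[key]] <- w
  w
}

.bilinear_cache <- new.env(parent = emptyenv())

#' Train a waveform-to-image decoder
#'
#' Fits the architecture chosen in `config` to preprocessed waveform /
#' image-target pairs with the MSE loss and Adam updates (linear: closed-form
#' ridge solve). Ground-truth images are interpolated to the 64x64 output
#' resolution. Deterministic for a fixed `config$seed`.
#'
#' @param waveforms A `waveform_set` (or raw samples matrix).
#' @param patterns The matching pattern tibble (same row order).
#' @param config A [decoder_config()].
#' @param verbose Print per-epoch losses.
#' @return An object of class `trained_decoder` with elements `config`,
#'   `fit` (architecture-specific parameters), `normalization`, and
#'   `provenance` (training-set size and seed).
#' @export
train_decoder <- function(waveforms, patterns, config = decoder_config(),
                          verbose = FALSE) {
  x <- preprocess_waveform(waveforms, config$input_len)
  stats <- attr(x, "norm_stats")
  if (nrow(x) < 100) stop("at least 100 training pairs are required")
  y <- decoder_targets(patterns, config$output_shape)
  if (nrow(y) != nrow(x)) stop("waveform and pattern counts differ")
  fit <- switch(config$arch,
    linear = ridge_fit(x, y, config$ridge_lambda),
    fc5 = {
      widths <- c(config$input_len, 2048, 1024, 2048,
                  prod(config$output_shape))
      mlp_fit(x, y, widths, c("relu", "relu", "relu", "sigmoid"),
              loss = "mse", epochs = config$epochs,
              batch_size = config$batch_size, lr = config$learning_rate,
              lr_decay = config$lr_decay %||% 0.3, seed = config$seed,
              verbose = verbose)
    },
    unet = {
      side <- as.integer(sqrt(config$input_len))
      # row-major waveform reshape, stored column-major: a transpose
      # permutation of the flat sample index
      unet_fit(x[, row_major_perm(side), drop = FALSE], y,
               epochs = config$epochs,
               batch_size = min(config$batch_size, 32),
               lr = config$learning_rate,
               lr_decay = config$lr_decay %||% 0.3, seed = config$seed,
               base = config$unet_base, verbose = verbose)
    })
  structure(list(config = config, fit = fit, normalization = stats,
                 provenance = list(n_train = nrow(x), seed = config$seed)),
            class = "trained_decoder")
}

ridge_fit <- function(x, y, lambda) {
  xm <- colMeans(x)
  ym <- colMeans(y)
  xc <- sweep(x, 2, xm)
  yc <- sweep(y, 2, ym)
  n <- nrow(x); p <- ncol(x)
  if (n >= p) {
    xtx <- crossprod(xc)
    # penalty scaled by the mean feature variance so lambda is dimensionless
    scale <- mean(diag(xtx)) + .Machine$double.eps
    w <- solve(xtx + diag(lambda * scale, p), crossprod(xc, yc))
  } else {
    # dual (kernel) form, numerically exact in the underdetermined regime
    k <- tcrossprod(xc)
    scale <- mean(diag(k)) + .Machine$double.eps
    alpha <- solve(k + diag(lambda * scale, n), yc)
    w <- crossprod(xc, alpha)
  }
  list(w = w, x_mean = xm, intercept = ym)
}

ridge_predict <- function(fit, x) {
  sweep(sweep(x, 2, fit$x_mean) %*% fit$w, 2, fit$intercept, "+")
}

#' @export
print.trained_decoder <- function(x, ...) {
  cat(sprintf("<trained_decoder> arch %s, trained on %d pairs (seed %d)\n",
              x$config$arch, x$provenance$n_train, x$provenance$seed))
  if (!is.null(x$fit$history)) {
    cat(sprintf("  final training loss %.6g after %d epochs\n",
                utils::tail(x$fit$history, 1), length(x$fit$history)))
  }
  invisible(x)
}

#' Reconstruct images from waveforms
#'
#' @param model A [train_decoder()] result.
#' @param w A `waveform`, `waveform_set` or samples matrix.
#' @return For a single waveform, an `image_pattern` (64x64, clipped to
#'   `[0, 1]`); for a set, a list of `image_pattern`s.
#' @export
reconstruct <- function(model, w) {
  stopifnot(inherits(model, "trained_decoder"))
  x <- preprocess_waveform(w, model$config$input_len,
                           stats = model$normalization)
  preds <- decoder_predict(model, x)
  shp <- model$config$output_shape
  out <- lapply(seq_len(nrow(preds)), function(i) {
    image_pattern(matrix(pmin(pmax(preds[i, ], 0), 1), shp[1], shp[2]),
                  kind = "glyph")
  })
  if (inherits(w, "waveform") ||
      (!inherits(w, "waveform_set") && is.null(dim(w)))) {
    out[[1]]
  } else out
}

# flat index permutation turning a row-major-reshaped side x side image
# into the package's column-major pixel layout
row_major_perm <- function(side) {
  as.vector(matrix(seq_len(side^2), side, side, byrow = TRUE))
}

decoder_predict <- function(model, x) {
  switch(model$config$arch,
    linear = ridge_predict(model$fit, x),
    fc5 = {
      net <- model$fit
      act_code <- match(vapply(net$layers, `[[`, "", "act"),
                        c("linear", "relu", "sigmoid")) - 1L
      fc_predict_core(x, lapply(net$layers, `[[`, "w"),
                      lapply(net$layers, `[[`, "b"), act_code)
    },
    unet = {
      side <- as.integer(sqrt(model$config$input_len))
      unet_predict_core(x[, row_major_perm(side), drop = FALSE],
                        lapply(model$fit$layers, `[[`, "w"),
                        lapply(model$fit$layers, `[[`, "b"),
                        as.integer(model$fit$base), side)
    })
}

# Matrix of clipped reconstructions (row per frame), avoiding per-image
# object overhead in bulk evaluation.
reconstruct_matrix <- function(model, w) {
  x <- preprocess_waveform(w, model$config$input_len,
                           stats = model$normalization)
  pmin(pmax(decoder_predict(model, x), 0), 1)
}

#' Pixelwise Pearson fidelity between two images
#'
#' The 2D correlation used to score reconstructions: subtract each image's
#' mean, normalize by the standard deviations, average the product. If
#' either image is constant the correlation is undefined and reported as 0.
#'
#' @param a,b `image_pattern`s or matrices of identical shape.
#' @return A scalar in `[-1, 1]`.
#' @examples
#' fidelity(matrix(c(1, 0, 0, 0), 2), matrix(c(1, 0, 0, 1), 2)) # 0.577
#' @export
fidelity <- function(a, b) {
  am <- as_intensity_matrix(a)
  bm <- as_intensity_matrix(b)
  if (!all(dim(am) == dim(bm))) stop("images must have identical shape")
  av <- as.vector(am); bv <- as.vector(bm)
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(0)
  stats::cor(av, bv)
}

#' Structural similarity index (SSIM)
#'
#' Standard SSIM with an 11x11 Gaussian window (sigma 1.5), K1 = 0.01,
#' K2 = 0.03, dynamic range 1, averaged over the valid (fully windowed)
#' region. Images smaller than the window fall back to a single global
#' window.
#'
#' @param a,b `image_pattern`s or matrices of identical shape, values in
#'   `[0, 1]`.
#' @return A scalar SSIM value.
#' @export
ssim_metric <- function(a, b) {
  x <- as_intensity_matrix(a)
  y <- as_intensity_matrix(b)
  if (!all(dim(x) == dim(y))) stop("images must have identical shape")
  k1 <- 0.01; k2 <- 0.03; drange <- 1
  c1 <- (k1 * drange)^2; c2 <- (k2 * drange)^2
  if (any(dim(x) < 11)) {
    mx <- mean(x); my <- mean(y)
    vx <- stats::var(as.vector(x)); vy <- stats::var(as.vector(y))
    cxy <- stats::cov(as.vector(x), as.vector(y))
    return(((2 * mx * my + c1) * (2 * cxy + c2)) /
             ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  g <- stats::dnorm(seq(-5, 5), 0, 1.5)
  g <- g / sum(g)
  f <- function(m) gauss_filter_valid(m, g)
  mx <- f(x); my <- f(y)
  vx <- f(x * x) - mx^2
  vy <- f(y * y) - my^2
  cxy <- f(x * y) - mx * my
  ssim_map <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mean(ssim_map)
}

# Separable valid-mode Gaussian filtering via banded matrix products.
gauss_filter_valid <- function(m, g) {
  k <- length(g)
  conv_rows <- function(mm) {
    n <- nrow(mm)
    out <- matrix(0, n - k + 1, ncol(mm))
    for (i in seq_len(k)) {
      out <- out + g[i] * mm[i:(n - k + i), , drop = FALSE]
    }
    out
  }
  t(conv_rows(t(conv_rows(m))))
}

#' Classify waveforms directly
#'
#' Trains a compact fully connected classifier (input_len - 512 - classes,
#' relu hidden layer, softmax cross-entropy) on preprocessed waveforms and
#' reports held-out accuracy.
#'
#' @param train_waveforms,train_labels Training `waveform_set` (or samples
#'   matrix) and integer class labels.
#' @param test_waveforms,test_labels Held-out set.
#' @param seed Integer seed.
#' @param epochs,batch_size,learning_rate Training hyperparameters.
#' @param input_len Network input length.
#' @return A list with `accuracy` (fraction in `[0, 1]`), `predicted`
#'   (labels for the test set) and `classes`.
#' @export
classify_waveforms <- function(train_waveforms, train_labels,
                               test_waveforms, test_labels, seed = 1,
                               epochs = 30, batch_size = 64,
                               learning_rate = 1e-3, input_len = 4096) {
  classes <- sort(unique(train_labels))
  if (length(classes) < 2) stop("at least two classes are required")
  x <- preprocess_waveform(train_waveforms, input_len)
  stats <- attr(x, "norm_stats")
  xt <- preprocess_waveform(test_waveforms, input_len, stats = stats)
  y <- matrix(0, length(train_labels), length(classes))
  y[cbind(seq_along(train_labels), match(train_labels, classes))] <- 1
  net <- mlp_fit(x, y, c(input_len, 512, length(classes)),
                 c("relu", "linear"), loss = "softmax_ce", epochs = epochs,
                 batch_size = batch_size, lr = learning_rate, seed = seed)
  logits <- mlp_forward(net, xt)
  pred <- classes[max.col(logits, ties.method = "first")]
  list(accuracy = mean(pred == test_labels), predicted = pred,
       classes = classes)
}

# ---- broom-style accessors -------------------------------------------------

#' Tidy a trained decoder's training history
#'
#' @param x A `trained_decoder`.
#' @param ... Unused.
#' @return A tibble with `epoch` and `loss` (empty for the linear
#'   architecture, which has no iterative history).
#' @export
tidy.trained_decoder <- function(x, ...) {
  h <- x$fit$history
  if (is.null(h)) return(tibble::tibble(epoch = integer(0), loss = numeric(0)))
  tibble::tibble(epoch = seq_along(h), loss = h)
}

#' Glance at a trained decoder
#'
#' @param x A `trained_decoder`.
#' @param ... Unused.
#' @return A one-row tibble: architecture, training size, epochs, final
#'   loss, seed.
#' @export
glance.trained_decoder <- function(x, ...) {
  tibble::tibble(
    arch = x$config$arch,
    n_train = x$provenance$n_train,
    epochs = if (is.null(x$fit$history)) 0L else length(x$fit$history),
    final_loss = if (is.null(x$fit$history)) NA_real_ else
      utils::tail(x$fit$history, 1),
    seed = x$provenance$seed)
}

#' Evaluate reconstruction metrics over a test set
#'
#' @param model A `trained_decoder`.
#' @param waveforms Held-out `waveform_set`.
#' @param patterns Matching pattern tibble (ground truth).
#' @return A list of class `recon_metrics`: `per_image` tibble
#'   (`id`, `fidelity`, `ssim`), plus `fidelity_mean` and `ssim_mean`.
#' @export
evaluate_reconstruction <- function(model, waveforms, patterns) {
  preds <- reconstruct_matrix(model, waveforms)
  targets <- decoder_targets(patterns, model$config$output_shape)
  shp <- model$config$output_shape
  per <- purrr::map_dfr(seq_len(nrow(preds)), function(i) {
    pm <- matrix(preds[i, ], shp[1], shp[2])
    tm <- matrix(targets[i, ], shp[1], shp[2])
    tibble::tibble(id = patterns$id[i], fidelity = fidelity(pm, tm),
                   ssim = ssim_metric(pm, tm))
  })
  structure(list(per_image = per,
                 fidelity_mean = mean(per$fidelity),
                 ssim_mean = mean(per$ssim)),
            class = "recon_metrics")
}

#' @export
print.recon_metrics <- function(x, ...) {
  cat(sprintf("<recon_metrics> n = %d, mean fidelity %.3f, mean SSIM %.3f\n",
              nrow(x$per_image), x$fidelity_mean, x$ssim_mean))
  invisible(x)
}

#' @rdname evaluate_reconstruction
#' @param x A `recon_metrics` object.
#' @param ... Unused.
#' @export
tidy.recon_metrics <- function(x, ...) x$per_image

#' @rdname evaluate_reconstruction
#' @export
glance.recon_metrics <- function(x, ...) {
  tibble::tibble(n = nrow(x$per_image), fidelity_mean = x$fidelity_mean,
                 ssim_mean = x$ssim_mean)
}
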