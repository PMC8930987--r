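# Seeded synthetic pattern generators: stroke glyphs (a download-free
# stand-in for handwritten-digit corpora), complex random-stroke patterns
# with affine augmentation, USAF-style resolution bar targets, and smooth
# grayscale blobs. Every generator is deterministic given its seed.

#' Construct a single image pattern
#'
#' @param intensities Matrix with values in `[0, 1]` (rows = image rows).
#' @param pixel_pitch_um Physical pixel pitch in micrometres.
#' @param label Optional class id.
#' @param kind One of `"glyph"`, `"strokes"`, `"bars"`, `"grayscale"`.
#' @return An object of class `image_pattern`.
#' @export
image_pattern <- function(intensities, pixel_pitch_um = 7.56, label = NA,
                          kind = "glyph") {
  intensities <- as.matrix(intensities)
  if (any(!is.finite(intensities)) || any(intensities < 0) ||
      any(intensities > 1)) {
    stop("intensities must be finite and within [0, 1]")
  }
  structure(list(intensities = intensities, pixel_pitch_um = pixel_pitch_um,
                 label = label, kind = kind),
            class = "image_pattern")
}

#' @export
print.image_pattern <- function(x, ...) {
  cat(sprintf("<image_pattern> %dx%d %s, pitch %g um, label %s\n",
              nrow(x$intensities), ncol(x$intensities), x$kind,
              x$pixel_pitch_um, format(x$label)))
  invisible(x)
}

pattern_tbl <- function(images, labels, kind, pixel_pitch_um) {
  tibble::tibble(
    id = seq_along(images),
    label = labels,
    kind = kind,
    pixel_pitch_um = pixel_pitch_um,
    image = images)
}

# ---- rasterization ---------------------------------------------------------

# Distance-based polyline rasterizer: ink where the distance from the pixel
# centre to any segment is below half the stroke width. `pts` is an n x 2
# matrix of (col, row) vertices in pixel units; NA rows split sub-strokes.
rasterize_polyline <- function(pts, shape, width_px = 1.5) {
  rows <- shape[1]; cols <- shape[2]
  px <- matrix(rep(seq_len(cols), each = rows), rows, cols) # x = column
  py <- matrix(rep(seq_len(rows), cols), rows, cols)        # y = row
  dmin <- matrix(Inf, rows, cols)
  n <- nrow(pts)
  for (i in seq_len(max(n - 1, 0))) {
    p1 <- pts[i, ]; p2 <- pts[i + 1, ]
    if (any(is.na(p1)) || any(is.na(p2))) next
    vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
    len2 <- vx^2 + vy^2
    if (len2 < 1e-12) {
      d <- sqrt((px - p1[1])^2 + (py - p1[2])^2)
    } else {
      t <- ((px - p1[1]) * vx + (py - p1[2]) * vy) / len2
      t <- pmin(pmax(t, 0), 1)
      d <- sqrt((px - (p1[1] + t * vx))^2 + (py - (p1[2] + t * vy))^2)
    }
    dmin <- pmin(dmin, d)
  }
  cov <- pmin(pmax(1 - (dmin - width_px / 2), 0), 1) # soft 1-px edge
  (cov >= 0.5) * 1
}

# 36 stroke-skeleton class templates (digit shapes 0-9, then letter-like
# strokes), each a list of polylines in the unit square (x right, y up).
arc_pts <- function(cx, cy, r, a0, a1, n = 16, rx = r, ry = r) {
  a <- seq(a0, a1, length.out = n)
  cbind(cx + rx * cos(a), cy + ry * sin(a))
}
seg <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  m
}

glyph_templates <- function() {
  tpl <- list(
    # 0-9
    list(arc_pts(0.5, 0.5, 0.35, 0, 2 * pi, 24, rx = 0.28, ry = 0.4)),
    list(seg(0.35, 0.75, 0.5, 0.9, 0.5, 0.1), seg(0.3, 0.1, 0.7, 0.1)),
    list(arc_pts(0.5, 0.65, 0.25, pi, -0.25 * pi, 14),
         seg(0.68, 0.48, 0.25, 0.1, 0.78, 0.1)),
    list(arc_pts(0.48, 0.7, 0.2, pi, -pi / 2, 12),
         arc_pts(0.48, 0.3, 0.2, pi / 2, -pi, 12)),
    list(seg(0.65, 0.1, 0.65, 0.9, 0.25, 0.35, 0.8, 0.35)),
    list(seg(0.72, 0.9, 0.3, 0.9, 0.3, 0.55),
         arc_pts(0.45, 0.33, 0.25, pi / 2, -0.8 * pi, 14)),
    list(arc_pts(0.5, 0.32, 0.22, 0, 2 * pi, 18),
         arc_pts(0.62, 0.62, 0.45, 0.55 * pi, 0.85 * pi, 8)),
    list(seg(0.25, 0.9, 0.75, 0.9, 0.4, 0.1)),
    list(arc_pts(0.5, 0.68, 0.18, 0, 2 * pi, 16),
         arc_pts(0.5, 0.28, 0.22, 0, 2 * pi, 18)),
    list(arc_pts(0.5, 0.68, 0.22, 0, 2 * pi, 18),
         arc_pts(0.38, 0.38, 0.45, -0.15 * pi, -0.45 * pi, 8)),
    # A-Z style strokes
    list(seg(0.2, 0.1, 0.5, 0.9, 0.8, 0.1), seg(0.32, 0.42, 0.68, 0.42)),
    list(seg(0.3, 0.1, 0.3, 0.9), arc_pts(0.3, 0.7, 0.2, pi / 2, -pi / 2, 10),
         arc_pts(0.3, 0.3, 0.2, pi / 2, -pi / 2, 10)),
    list(arc_pts(0.55, 0.5, 0.35, 0.3 * pi, 1.7 * pi, 18)),
    list(seg(0.3, 0.1, 0.3, 0.9), arc_pts(0.3, 0.5, 0.4, pi / 2, -pi / 2, 14)),
    list(seg(0.7, 0.9, 0.3, 0.9, 0.3, 0.1, 0.7, 0.1), seg(0.3, 0.5, 0.6, 0.5)),
    list(seg(0.7, 0.9, 0.3, 0.9, 0.3, 0.1), seg(0.3, 0.5, 0.6, 0.5)),
    list(arc_pts(0.55, 0.5, 0.35, 0.3 * pi, 1.6 * pi, 16),
         seg(0.66, 0.38, 0.66, 0.18, 0.5, 0.38)),
    list(seg(0.3, 0.1, 0.3, 0.9), seg(0.7, 0.1, 0.7, 0.9), seg(0.3, 0.5, 0.7, 0.5)),
    list(seg(0.4, 0.1, 0.6, 0.1), seg(0.5, 0.1, 0.5, 0.9), seg(0.4, 0.9, 0.6, 0.9)),
    list(seg(0.6, 0.9, 0.6, 0.25), arc_pts(0.45, 0.25, 0.15, 0, -pi, 8)),
    list(seg(0.3, 0.1, 0.3, 0.9), seg(0.3, 0.45, 0.7, 0.9), seg(0.42, 0.55, 0.7, 0.1)),
    list(seg(0.3, 0.9, 0.3, 0.1, 0.7, 0.1)),
    list(seg(0.25, 0.1, 0.25, 0.9, 0.5, 0.45, 0.75, 0.9, 0.75, 0.1)),
    list(seg(0.3, 0.1, 0.3, 0.9, 0.7, 0.1, 0.7, 0.9)),
    list(arc_pts(0.5, 0.5, 0.35, 0, 2 * pi, 22, rx = 0.3, ry = 0.4)),
    list(seg(0.3, 0.1, 0.3, 0.9), arc_pts(0.3, 0.68, 0.22, pi / 2, -pi / 2, 10)),
    list(arc_pts(0.5, 0.55, 0.3, 0, 2 * pi, 20), seg(0.55, 0.35, 0.75, 0.12)),
    list(seg(0.3, 0.1, 0.3, 0.9), arc_pts(0.3, 0.7, 0.2, pi / 2, -pi / 2, 10),
         seg(0.35, 0.5, 0.7, 0.1)),
    list(arc_pts(0.5, 0.7, 0.18, 0.1 * pi, pi, 10),
         seg(0.33, 0.6, 0.67, 0.4), arc_pts(0.5, 0.3, 0.18, -pi, -0.1 * pi, 10)),
    list(seg(0.2, 0.9, 0.8, 0.9), seg(0.5, 0.9, 0.5, 0.1)),
    list(seg(0.3, 0.9, 0.3, 0.3), arc_pts(0.5, 0.3, 0.2, -pi, 0, 10),
         seg(0.7, 0.3, 0.7, 0.9)),
    list(seg(0.22, 0.9, 0.5, 0.1, 0.78, 0.9)),
    list(seg(0.2, 0.9, 0.35, 0.1, 0.5, 0.6, 0.65, 0.1, 0.8, 0.9)),
    list(seg(0.25, 0.1, 0.75, 0.9), seg(0.25, 0.9, 0.75, 0.1)),
    list(seg(0.25, 0.9, 0.5, 0.5, 0.75, 0.9), seg(0.5, 0.5, 0.5, 0.1)),
    list(seg(0.25, 0.9, 0.75, 0.9, 0.25, 0.1, 0.75, 0.1))
  )
  tpl
}

# Map unit-square template points to pixel coordinates with a random affine
# jitter: +/-10% scale, +/-10 deg rotation, +/-2 px shift.
jitter_points <- function(pts, shape, scale_jit = 0.1, rot_deg = 10,
                          shift_px = 2) {
  rows <- shape[1]; cols <- shape[2]
  s <- (1 + stats::runif(1, -scale_jit, scale_jit)) * 0.8 * min(rows, cols)
  th <- stats::runif(1, -rot_deg, rot_deg) * pi / 180
  dx <- stats::runif(1, -shift_px, shift_px)
  dy <- stats::runif(1, -shift_px, shift_px)
  x <- (pts[, 1] - 0.5) * s
  y <- (pts[, 2] - 0.5) * s
  xr <- x * cos(th) - y * sin(th)
  yr <- x * sin(th) + y * cos(th)
  # y up in template coords -> row index grows downward
  cbind(cols / 2 + 0.5 + xr + dx, rows / 2 + 0.5 - yr + dy)
}

#' Generate labeled synthetic stroke glyphs
#'
#' Each class has a fixed stroke-skeleton template (polylines and arcs);
#' samples are drawn by applying a random affine jitter (scale within 10%,
#' rotation within 10 degrees, shift within 2 px) and rasterizing at a
#' stroke width of ~9% of the image side (2.5 px at 28x28, matching the
#' stroke thickness and ~13% ink fraction of handwritten-digit corpora),
#' then binarizing at 0.5. Class labels are sampled uniformly.
#'
#' @param n Number of images.
#' @param shape Image shape `(rows, cols)`, at least 16x16; default 28x28.
#' @param n_classes Number of classes (at most 36).
#' @param seed Integer seed; the output is a pure function of the arguments.
#' @param pixel_pitch_um Physical pixel pitch (default 7.56 um).
#' @return A tibble with columns `id`, `label` (0-based class), `kind`,
#'   `pixel_pitch_um` and list-column `image` of 0/1 matrices.
#' @examples
#' glyphs <- make_glyphs(12, seed = 1)
#' table(glyphs$label)
#' @export
make_glyphs <- function(n, shape = c(28, 28), n_classes = 10, seed = 1,
                        pixel_pitch_um = 7.56) {
  if (n_classes > 36) stop("n_classes must be at most 36")
  if (any(shape < 16)) stop("shape must be at least 16x16")
  tpl <- glyph_templates()[seq_len(n_classes)]
  width <- max(2, 0.09 * min(shape))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  labels <- sample.int(n_classes, n, replace = TRUE) - 1L
  images <- vector("list", n)
  for (i in seq_len(n)) {
    strokes <- tpl[[labels[i] + 1L]]
    pts <- do.call(rbind, lapply(strokes, function(s) rbind(s, c(NA, NA))))
    img <- rasterize_polyline(jitter_points(pts, shape), shape, width)
    images[[i]] <- img
  }
  pattern_tbl(images, labels, "glyph", pixel_pitch_um)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# One random multi-stroke pattern: a few quadratic Bezier curves.
random_stroke_points <- function(shape, n_strokes) {
  rows <- shape[1]; cols <- shape[2]
  out <- list()
  for (s in seq_len(n_strokes)) {
    p <- matrix(stats::runif(6), 3, 2)
    p[, 1] <- 1 + p[, 1] * (cols - 2)
    p[, 2] <- 1 + p[, 2] * (rows - 2)
    t <- seq(0, 1, length.out = 14)
    bez <- outer((1 - t)^2, p[1, ]) + 2 * outer(t * (1 - t), p[2, ]) +
      outer(t^2, p[3, ])
    out[[s]] <- rbind(bez, c(NA, NA))
  }
  do.call(rbind, out)
}

affine_remap <- function(img, scale, theta, dx, dy) {
  rows <- nrow(img); cols <- ncol(img)
  cx <- (cols + 1) / 2; cy <- (rows + 1) / 2
  xo <- matrix(rep(seq_len(cols), each = rows), rows, cols) - cx
  yo <- matrix(rep(seq_len(rows), cols), rows, cols) - cy
  # inverse map of rotate(theta) + scale + shift
  xs <- (cos(theta) * (xo - dx) + sin(theta) * (yo - dy)) / scale + cx
  ys <- (-sin(theta) * (xo - dx) + cos(theta) * (yo - dy)) / scale + cy
  bilinear_sample(img, xs, ys)
}

# Bilinear sample of matrix `img` at (x = col, y = row) positions; outside
# the image the value is 0.
bilinear_sample <- function(img, xs, ys) {
  rows <- nrow(img); cols <- ncol(img)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  val <- function(xx, yy) {
    ok <- xx >= 1 & xx <= cols & yy >= 1 & yy <= rows
    v <- numeric(length(xx))
    v[ok] <- img[cbind(yy[ok], xx[ok])]
    v
  }
  dim_out <- dim(xs)
  x0v <- as.vector(x0); y0v <- as.vector(y0)
  fxv <- as.vector(fx); fyv <- as.vector(fy)
  v <- (1 - fxv) * (1 - fyv) * val(x0v, y0v) +
    fxv * (1 - fyv) * val(x0v + 1, y0v) +
    (1 - fxv) * fyv * val(x0v, y0v + 1) +
    fxv * fyv * val(x0v + 1, y0v + 1)
  matrix(v, dim_out[1], dim_out[2])
}

#' Generate complex random-stroke patterns
#'
#' Draws `n` base patterns of random quadratic Bezier strokes, binarized at
#' 0.5. With `augment = TRUE`, each base pattern is additionally emitted under
#' `n_variants` random shift/rotation/scale transforms, mirroring the
#' train-set augmentation used to increase pattern complexity.
#'
#' @param n Number of base patterns.
#' @param shape Image shape `(rows, cols)`; default 40x40.
#' @param strokes_per_image Integer range `c(lo, hi)` of strokes per pattern.
#' @param augment Emit augmented variants as extra rows.
#' @param n_variants Augmented copies per base pattern.
#' @param seed Integer seed.
#' @param pixel_pitch_um Physical pixel pitch.
#' @return A pattern tibble (see [make_glyphs()]); `label` is the base-pattern
#'   index so augmented copies share their parent's label.
#' @export
make_random_strokes <- function(n, shape = c(40, 40),
                                strokes_per_image = c(3, 6), augment = FALSE,
                                n_variants = 3, seed = 1,
                                pixel_pitch_um = 7.56) {
  stopifnot(n >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  width <- max(1.5, 0.045 * min(shape))
  images <- list(); labels <- integer(0)
  for (i in seq_len(n)) {
    k <- sample(seq(strokes_per_image[1], strokes_per_image[2]), 1)
    base <- rasterize_polyline(random_stroke_points(shape, k), shape, width)
    images[[length(images) + 1]] <- base
    labels <- c(labels, i)
    if (augment) {
      for (v in seq_len(n_variants)) {
        aug <- affine_remap(base,
                            scale = stats::runif(1, 0.8, 1.2),
                            theta = stats::runif(1, -pi / 6, pi / 6),
                            dx = stats::runif(1, -3, 3),
                            dy = stats::runif(1, -3, 3))
        images[[length(images) + 1]] <- (aug >= 0.5) * 1
        labels <- c(labels, i)
      }
    }
  }
  pattern_tbl(images, labels, "strokes", pixel_pitch_um)
}

#' Generate a USAF-style resolution bar target
#'
#' Groups of three bars per pitch, one horizontal and one vertical set per
#' group, laid out left to right in descending pitch. Bars are exactly 0/1
#' valued; at the default 7.56 um pitch the smallest permissible group
#' (2 px pitch) corresponds to 15.12 um.
#'
#' @param shape Image shape `(rows, cols)`; default 40x40.
#' @param pitches_px Bar pitches in pixels, each at least 2.
#' @param pixel_pitch_um Physical pixel pitch.
#' @return An `image_pattern` of kind `"bars"` with attribute `groups`, a
#'   tibble describing each bar group (pitch, orientation, bounding box) for
#'   later profile extraction.
#' @export
make_resolution_target <- function(shape = c(40, 40), pitches_px = c(6, 4, 2),
                                   pixel_pitch_um = 7.56) {
  if (any(pitches_px < 2)) stop("every pitch must be at least 2 px")
  pitches_px <- sort(as.integer(pitches_px), decreasing = TRUE)
  rows <- shape[1]; cols <- shape[2]
  img <- matrix(0, rows, cols)
  groups <- list()
  x <- 2L
  for (p in pitches_px) {
    bar <- max(1L, p %/% 2L)       # bar width; pitch = bar + gap
    gw <- 3L * p                    # column budget per group (bar length)
    gh <- 3L * p                    # bar length
    yb <- rows - (2L * p + bar)     # bottom (horizontal) group start row
    if (x + gw - 1L > cols - 1L || 2L + gh - 1L >= yb) {
      stop("resolution target layout overflows the requested shape")
    }
    # vertical bars (top half): 3 bars of width `bar` at pitch p
    y0 <- 2L
    for (b in 0:2) {
      xs <- x + b * p
      img[y0:(y0 + gh - 1), xs:(xs + bar - 1)] <- 1
    }
    groups[[length(groups) + 1]] <- tibble::tibble(
      pitch_px = p, orientation = "vertical",
      row0 = y0, row1 = y0 + gh - 1, col0 = x, col1 = x + 2L * p + bar - 1L)
    # horizontal bars (bottom half)
    for (b in 0:2) {
      ys <- yb + b * p
      img[ys:(ys + bar - 1), x:(x + gh - 1)] <- 1
    }
    groups[[length(groups) + 1]] <- tibble::tibble(
      pitch_px = p, orientation = "horizontal",
      row0 = yb, row1 = yb + 2L * p + bar - 1L, col0 = x, col1 = x + gh - 1L)
    x <- x + gw + 1L
  }
  pat <- image_pattern(img, pixel_pitch_um, label = NA, kind = "bars")
  attr(pat, "groups") <- dplyr::bind_rows(groups)
  pat
}

#' Generate smooth grayscale blob patterns
#'
#' Each image is a sum of 2-5 random Gaussian blobs, normalized to max 1;
#' values are continuous in `[0, 1]` (not binarized).
#'
#' @param n Number of images.
#' @param shape Image shape; default 28x28.
#' @param seed Integer seed.
#' @param pixel_pitch_um Physical pixel pitch.
#' @return A pattern tibble of kind `"grayscale"`.
#' @export
make_grayscale <- function(n, shape = c(28, 28), seed = 1,
                           pixel_pitch_um = 7.56) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- shape[1]; cols <- shape[2]
  gx <- matrix(rep(seq_len(cols), each = rows), rows, cols)
  gy <- matrix(rep(seq_len(rows), cols), rows, cols)
  images <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sample(2:5, 1)
    img <- matrix(0, rows, cols)
    for (b in seq_len(k)) {
      cx <- stats::runif(1, 1, cols); cy <- stats::runif(1, 1, rows)
      sg <- stats::runif(1, 0.08, 0.25) * min(shape)
      amp <- stats::runif(1, 0.4, 1)
      img <- img + amp * exp(-((gx - cx)^2 + (gy - cy)^2) / (2 * sg^2))
    }
    images[[i]] <- img / max(img)
  }
  pattern_tbl(images, rep(NA_integer_, n), "grayscale", pixel_pitch_um)
}

#' Stack a pattern tibble's images into a matrix
#'
#' @param patterns A pattern tibble.
#' @return A numeric matrix, one row per image, pixels in column-major order
#'   of the image matrix.
#' @export
pattern_matrix <- function(patterns) {
  do.call(rbind, lapply(patterns$image, as.vector))
}

#' Resize an image by bilinear interpolation
#'
#' Used to interpolate ground-truth patterns to the decoder's 64x64 target
#' resolution. Output pixel centres are mapped linearly onto input pixel
#' centres (edge-clamped).
#'
#' @param img Numeric matrix.
#' @param out_shape Target `(rows, cols)`.
#' @return A matrix of the target shape.
#' @export
resize_bilinear <- function(img, out_shape = c(64, 64)) {
  rows <- nrow(img); cols <- ncol(img)
  or <- out_shape[1]; oc <- out_shape[2]
  ys <- (seq_len(or) - 0.5) * rows / or + 0.5
  xs <- (seq_len(oc) - 0.5) * cols / oc + 0.5
  ys <- pmin(pmax(ys, 1), rows)
  xs <- pmin(pmax(xs, 1), cols)
  xm <- matrix(rep(xs, each = or), or, oc)
  ym <- matrix(rep(ys, oc), or, oc)
  bilinear_sample_clamped(img, xm, ym)
}

bilinear_sample_clamped <- function(img, xs, ys) {
  rows <- nrow(img); cols <- ncol(img)
  x0 <- pmin(pmax(floor(xs), 1), cols); x1 <- pmin(x0 + 1, cols)
  y0 <- pmin(pmax(floor(ys), 1), rows); y1 <- pmin(y0 + 1, rows)
  fx <- pmin(pmax(xs - x0, 0), 1); fy <- pmin(pmax(ys - y0, 0), 1)
  v <- (1 - fx) * (1 - fy) * img[cbind(as.vector(y0), as.vector(x0))] +
    fx * (1 - fy) * img[cbind(as.vector(y0), as.vector(x1))] +
    (1 - fx) * fy * img[cbind(as.vector(y1), as.vector(x0))] +
    fx * fy * img[cbind(as.vector(y1), as.vector(x1))]
  matrix(v, nrow(xs), ncol(xs))
}
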