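# Forward encoder: image -> modal coupling -> per-mode delayed sub-pulses ->
# detector impulse response -> sampling -> additive noise. Coupling is
# coherent by default (the scene is illuminated by a coherent laser);
# detection sums per-mode powers incoherently, which is exact for a
# spatially integrating photodiode receiving orthogonal modes.

#' Describe the illumination pulse train
#'
#' @param fwhm_ps Pulse duration FWHM in ps (default 45.1, the width after
#'   transit through the probe).
#' @param period_ns Repetition period in ns (default 65, i.e. 15.4 MHz).
#' @param energy Pulse energy in arbitrary units.
#' @return An object of class `optical_pulse`.
#' @export
optical_pulse <- function(fwhm_ps = 45.1, period_ns = 65, energy = 1) {
  if (fwhm_ps <= 0) stop("fwhm_ps must be positive")
  if (period_ns <= fwhm_ps / 1000) stop("period_ns must exceed the pulse width")
  structure(list(fwhm_ps = fwhm_ps, period_ns = period_ns, energy = energy),
            class = "optical_pulse")
}

#' Describe the photodetector and digitizer
#'
#' @param bandwidth_ghz -3 dB bandwidth in GHz (default 30).
#' @param sample_rate_gsps Sampling rate in GS/s (default 100).
#' @param noise_snr_db Additive white Gaussian noise SNR in dB (default 30).
#' @param impulse_fwhm_ps Impulse-response FWHM in ps (default 15).
#' @return An object of class `detector_spec`. Warns when the sampling rate
#'   is below twice the bandwidth.
#' @export
detector_spec <- function(bandwidth_ghz = 30, sample_rate_gsps = 100,
                          noise_snr_db = 30, impulse_fwhm_ps = 15) {
  stopifnot(bandwidth_ghz > 0, sample_rate_gsps > 0, impulse_fwhm_ps > 0)
  if (sample_rate_gsps <= 2 * bandwidth_ghz) {
    warning("sample_rate_gsps below twice the detector bandwidth")
  }
  structure(list(bandwidth_ghz = bandwidth_ghz,
                 sample_rate_gsps = sample_rate_gsps,
                 noise_snr_db = noise_snr_db,
                 impulse_fwhm_ps = impulse_fwhm_ps),
            class = "detector_spec")
}

#' Describe the object-to-facet imaging geometry
#'
#' @param pixel_pitch_um Object pixel size in um (default 7.56).
#' @param image_shape Image shape `(rows, cols)`.
#' @param magnification Object-plane to fiber-facet scale. `NULL` (default)
#'   auto-fits the image footprint to `fill_fraction` of the core diameter.
#' @param offset_um Lateral offset of the image centre from the fiber axis
#'   (um, length-2). The default (2, 1.5) reflects a realistic alignment
#'   tolerance (~10% of the reference core radius); an exactly centred
#'   scene makes the coherent measurement blind to 180-degree rotations of
#'   the image (every mode field is either symmetric or antisymmetric
#'   under point reflection), an idealization real instruments do not
#'   have.
#' @param fill_fraction Fraction of the core diameter the footprint fills
#'   when `magnification` is auto-fitted.
#' @return An object of class `scene_geometry`.
#' @export
scene_geometry <- function(pixel_pitch_um = 7.56, image_shape = c(28, 28),
                           magnification = NULL, offset_um = c(2, 1.5),
                           fill_fraction = 0.9) {
  if (pixel_pitch_um <= 0) stop("pixel_pitch_um must be positive")
  structure(list(pixel_pitch_um = pixel_pitch_um,
                 image_shape = as.integer(image_shape),
                 magnification = magnification,
                 offset_um = offset_um, fill_fraction = fill_fraction),
            class = "scene_geometry")
}

geometry_magnification <- function(geometry, basis) {
  if (!is.null(geometry$magnification)) return(geometry$magnification)
  footprint <- max(geometry$image_shape) * geometry$pixel_pitch_um
  geometry$fill_fraction * 2 * basis$fiber$core_radius_um / footprint
}

# Linear operator mapping an image (pixel vector, column-major) to its
# bilinear resampling on the facet field grid, plus in-core bookkeeping.
# Cached pieces: `b` (grid^2 x n_px, dense for simplicity at these sizes),
# `m_inc` (n_modes x n_px: per-mode power response), `incore_px`
# (per-pixel weight giving in-core intensity), `illum_incore` (in-core
# intensity of a uniform unit image, the illumination normalizer).
coupling_operator <- function(basis, geometry) {
  mag <- geometry_magnification(geometry, basis)
  shp <- geometry$image_shape
  rows <- shp[1]; cols <- shp[2]
  gx <- basis$grid_x_um
  gs <- basis$grid_size
  # facet grid point coords
  fx <- matrix(gx, gs, gs)                   # x along first index
  fy <- matrix(gx, gs, gs, byrow = TRUE)
  # inverse map: facet -> object-plane pixel indices (x = col, y = row up)
  ox <- (fx - geometry$offset_um[1]) / mag
  oy <- (fy - geometry$offset_um[2]) / mag
  cc <- ox / geometry$pixel_pitch_um + (cols + 1) / 2
  rr <- (rows + 1) / 2 - oy / geometry$pixel_pitch_um
  n_g <- gs^2
  n_px <- rows * cols
  b <- matrix(0, n_g, n_px)
  x0 <- floor(cc); y0 <- floor(rr)
  fxw <- cc - x0; fyw <- rr - y0
  add_w <- function(xx, yy, wgt) {
    ok <- which(xx >= 1 & xx <= cols & yy >= 1 & yy <= rows & wgt > 0)
    if (length(ok)) {
      px <- (xx[ok] - 1) * rows + yy[ok] # column-major pixel index
      idx <- cbind(ok, px)
      b[idx] <<- b[idx] + wgt[ok]
    }
  }
  add_w(as.vector(x0), as.vector(y0), as.vector((1 - fxw) * (1 - fyw)))
  add_w(as.vector(x0 + 1), as.vector(y0), as.vector(fxw * (1 - fyw)))
  add_w(as.vector(x0), as.vector(y0 + 1), as.vector((1 - fxw) * fyw))
  add_w(as.vector(x0 + 1), as.vector(y0 + 1), as.vector(fxw * fyw))

  r_g <- sqrt(as.vector(fx)^2 + as.vector(fy)^2)
  incore <- as.numeric(r_g <= basis$fiber$core_radius_um)
  m_inc <- (basis$fields^2) %*% b
  overlap <- sum(incore %*% b) / max(sum(b), .Machine$double.eps)
  if (overlap < 0.1) {
    warning("less than 10% of the image footprint overlaps the fiber core")
  }
  list(b = b, m_inc = m_inc, incore_px = as.vector(incore %*% b),
       illum_incore = sum(incore %*% b) / n_px * n_px, # = sum over pixels
       incore_mask = incore, magnification = mag)
}

#' Couple an image into the fiber's mode basis
#'
#' The image is resampled onto the facet grid through the scene geometry.
#' Under the coherent model (the default: the instrument illuminates the
#' scene with a coherent laser) `c_m = sum_px sqrt(I_px) exp(i phi_px)
#' psi_m(px)` with plane-wave phases (`phi = 0`) or uniform random speckle
#' phases, and `P_m = |c_m|^2`; under the incoherent model
#' `P_m = sum_px I_px |psi_m(px)|^2` (linear in intensity, but blind to
#' odd azimuthal image harmonics). Powers are reported as fractions of the input intensity:
#' with `normalize = "image"` the reference is the image's own in-core
#' intensity (so a pure-mode field couples with `P = 1`); with
#' `normalize = "illumination"` the reference is a fixed uniform unit
#' illumination, which keeps the incoherent map exactly linear in the image
#' and is what the waveform-simulation pipeline uses.
#'
#' @param image An `image_pattern`, a pattern-tibble row, or a matrix.
#' @param basis A [find_lp_modes()] result.
#' @param geometry A [scene_geometry()]; defaults to one matching the image
#'   shape.
#' @param model `"coherent"` (default) or `"incoherent"`.
#' @param speckle_seed Optional seed for random speckle phases (coherent
#'   model only); `NULL` means plane-wave phases.
#' @param normalize `"image"` or `"illumination"` (see above).
#' @param operator Optional precomputed internal coupling operator (for
#'   repeated calls with identical geometry).
#' @return A list of class `coupling_result` with `mode_powers`,
#'   `mode_amplitudes` (complex, coherent model only) and `model`.
#' @export
couple_image <- function(image, basis, geometry = NULL,
                         model = c("coherent", "incoherent"),
                         speckle_seed = NULL,
                         normalize = c("image", "illumination"),
                         operator = NULL) {
  model <- match.arg(model)
  normalize <- match.arg(normalize)
  img <- as_intensity_matrix(image)
  if (any(img < 0)) stop("image intensities must be nonnegative")
  if (is.null(geometry)) geometry <- scene_geometry(image_shape = dim(img))
  if (!all(dim(img) == geometry$image_shape)) {
    stop("image shape does not match geometry$image_shape")
  }
  if (is.null(operator)) operator <- coupling_operator(basis, geometry)
  iv <- as.vector(img)
  norm_ref <- switch(normalize,
    image = sum(operator$incore_px * iv),
    illumination = sum(operator$incore_px))
  if (model == "incoherent") {
    p <- as.vector(operator$m_inc %*% iv)
    amps <- NULL
  } else {
    amp_grid <- sqrt(pmax(as.vector(operator$b %*% iv), 0))
    if (!is.null(speckle_seed)) {
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
      set.seed(speckle_seed)
      phases <- stats::runif(length(amp_grid), 0, 2 * pi)
      field <- amp_grid * exp(1i * phases)
    } else {
      field <- amp_grid + 0i
    }
    amps <- as.vector(basis$fields %*% field)
    p <- Mod(amps)^2
  }
  if (norm_ref > 0) {
    p <- p / norm_ref
    if (!is.null(amps)) amps <- amps / sqrt(norm_ref)
  } else {
    p[] <- 0
    if (!is.null(amps)) amps[] <- 0
  }
  structure(list(mode_powers = p, mode_amplitudes = amps, model = model),
            class = "coupling_result")
}

as_intensity_matrix <- function(image) {
  if (inherits(image, "image_pattern")) return(image$intensities)
  if (is.matrix(image)) return(image)
  if (is.list(image) && !is.null(image$image)) {
    img <- image$image
    if (is.list(img)) img <- img[[1]]
    return(img)
  }
  stop("cannot interpret `image` as an intensity matrix")
}

#' Perturb a coupling result (modal crosstalk + delay jitter)
#'
#' Emulates slow environmental drift (temperature, bending) as (i) random
#' orthogonal mixing of mode amplitudes within blocks of modes whose
#' unperturbed delays differ by less than one pulse FWHM, interpolated
#' between the identity at `strength = 0` and a fully random rotation at
#' `strength = 1` (matrix exponential of a scaled random skew-symmetric
#' generator), and (ii) zero-mean Gaussian jitter of scale
#' `delay_jitter_ps * strength` added to each mode's delay. Total power is
#' conserved exactly; the output is deterministic given `seed`.
#'
#' @param result A [couple_image()] result (or a matrix of per-image mode
#'   powers, one row per image).
#' @param basis A [find_lp_modes()] result.
#' @param strength Perturbation strength in `[0, 1]`.
#' @param delay_jitter_ps Delay-jitter scale in ps at `strength = 1`.
#' @param seed Integer seed.
#' @param pulse_fwhm_ps Pulse FWHM used to define near-degenerate blocks.
#' @return A list with `result` (powers perturbed in place) and `delays_ps`
#'   (jittered delays over the basis fiber length).
#' @export
perturb_coupling <- function(result, basis, strength, delay_jitter_ps = 20,
                             seed = 1, pulse_fwhm_ps = 45.1) {
  if (strength < 0 || strength > 1) stop("strength must lie in [0, 1]")
  delays <- basis$modes$delay_ps_per_m * basis$fiber$length_m
  p_mat <- if (inherits(result, "coupling_result")) {
    matrix(result$mode_powers, nrow = 1)
  } else {
    as.matrix(result)
  }
  if (strength == 0) {
    out <- if (inherits(result, "coupling_result")) result else p_mat
    return(list(result = out, delays_ps = delays))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # near-degenerate blocks by consecutive-gap clustering of sorted delays
  ord <- order(delays)
  gaps <- diff(delays[ord])
  block_id <- cumsum(c(1, as.numeric(gaps >= pulse_fwhm_ps)))
  amps <- sqrt(t(p_mat)) # modes x images
  for (bid in unique(block_id)) {
    idx <- ord[block_id == bid]
    k <- length(idx)
    if (k < 2) next
    a <- matrix(stats::rnorm(k * k), k, k)
    skew <- (a - t(a)) / 2
    q <- expm_series(strength * skew)
    amps[idx, ] <- q %*% amps[idx, ]
  }
  p_new <- t(amps^2)
  delays_new <- delays + stats::rnorm(length(delays)) * delay_jitter_ps * strength
  out <- if (inherits(result, "coupling_result")) {
    structure(list(mode_powers = as.vector(p_new),
                   mode_amplitudes = NULL, model = result$model),
              class = "coupling_result")
  } else {
    p_new
  }
  list(result = out, delays_ps = delays_new)
}

# Matrix exponential by scaling-and-squaring of a truncated Taylor series;
# adequate for the small skew-symmetric generators used in perturbations.
expm_series <- function(a) {
  nrm <- max(abs(a))
  s <- max(0, ceiling(log2(max(nrm, 1e-300)) + 1))
  a <- a / 2^s
  res <- diag(nrow(a))
  term <- diag(nrow(a))
  for (k in 1:14) {
    term <- term %*% a / k
    res <- res + term
  }
  for (i in seq_len(s)) res <- res %*% res
  res
}

effective_sigma_ps <- function(pulse, det) {
  sqrt(pulse$fwhm_ps^2 + det$impulse_fwhm_ps^2) / (2 * sqrt(2 * log(2)))
}

default_window_ps <- function(delays_ps, pulse, det) {
  c(min(delays_ps) - 5 * pulse$fwhm_ps,
    max(delays_ps) + 5 * pulse$fwhm_ps + 5 * det$impulse_fwhm_ps)
}

#' Synthesize the detector-sampled waveform of one frame
#'
#' The ideal intensity trace is `P(t) = sum_m P_m g(t - tau_m)` with `g` a
#' unit-area Gaussian of the pulse FWHM; convolution with the Gaussian
#' detector impulse response is applied analytically (the two Gaussians
#' combine in quadrature), the trace is sampled at the digitizer rate, and
#' white Gaussian noise at the detector SNR is added when `noise_seed` is
#' given.
#'
#' @param result A [couple_image()] result (or a bare power vector).
#' @param delays_ps Per-mode delays in ps (same length as the powers).
#' @param pulse An [optical_pulse()].
#' @param det A [detector_spec()].
#' @param noise_seed Optional integer; `NULL` skips noise.
#' @param window_ps Optional `c(start, end)` time window in ps; defaults to
#'   `[min tau - 5 FWHM, max tau + 5 FWHM + 5 impulse]`. Pass the window of
#'   the unperturbed configuration to mimic a fixed oscilloscope trigger.
#' @return An object of class `waveform`: `samples`, `dt_ps`, `t0_ps` (time
#'   of the first sample relative to the earliest mode arrival) and `meta`.
#' @export
synthesize_waveform <- function(result, delays_ps, pulse, det,
                                noise_seed = NULL, window_ps = NULL) {
  p <- if (inherits(result, "coupling_result")) result$mode_powers else
    as.vector(result)
  if (length(p) == 0) stop("empty mode set")
  if (length(p) != length(delays_ps)) {
    stop("powers and delays must have the same length")
  }
  if (is.null(window_ps)) window_ps <- default_window_ps(delays_ps, pulse, det)
  dt <- 1000 / det$sample_rate_gsps
  t <- seq(window_ps[1], window_ps[2], by = dt)
  sig <- effective_sigma_ps(pulse, det)
  g <- gauss_kernel_matrix(delays_ps, t, sig)
  s <- as.vector(matrix(p, nrow = 1) %*% g) * pulse$energy
  if (!is.null(noise_seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(noise_seed)
    sd_n <- sqrt(mean(s^2)) / 10^(det$noise_snr_db / 20)
    s <- s + stats::rnorm(length(s), 0, sd_n)
  }
  structure(list(samples = s, dt_ps = dt,
                 t0_ps = window_ps[1] - min(delays_ps),
                 meta = list(noise_seed = noise_seed,
                             window_ps = window_ps)),
            class = "waveform")
}

gauss_kernel_matrix <- function(delays_ps, t, sigma_ps) {
  # rows: modes, cols: time samples; each row a unit-area Gaussian (per ps).
  # Tails below 1e-30 of the peak are flushed to exact zero: they are
  # physically meaningless and subnormal values would poison the downstream
  # matrix products.
  dt_m <- outer(delays_ps, t, function(d, tt) tt - d)
  g <- exp(-dt_m^2 / (2 * sigma_ps^2))
  g[g < 1e-30] <- 0
  g / (sigma_ps * sqrt(2 * pi))
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g ps (%.2f ns), t0 = %g ps\n",
              length(x$samples), x$dt_ps,
              length(x$samples) * x$dt_ps / 1000, x$t0_ps))
  invisible(x)
}

#' Simulate waveforms for a whole pattern set
#'
#' End-to-end batch forward model: modal coupling of every image (coherent
#' plane-wave by default; normalization against the fixed uniform
#' illumination), sub-pulse synthesis over a window shared by all frames of
#' the configuration, detector sampling, and seeded per-dataset noise.
#'
#' @param patterns A pattern tibble (from the `make_*` generators).
#' @param basis A [find_lp_modes()] result.
#' @param geometry A [scene_geometry()]; defaults to the pattern shape.
#' @param pulse An [optical_pulse()].
#' @param det A [detector_spec()].
#' @param model Coupling model (coherent default).
#' @param noise_seed Optional integer; `NULL` skips noise.
#' @param perturbation Optional list `(strength, delay_jitter_ps, seed)`
#'   applied to all frames (one environmental state for the whole set).
#' @return An object of class `waveform_set`: `samples` (matrix, one row per
#'   image), `dt_ps`, `t0_ps`, `window_ps` and `meta` (the pattern tibble
#'   minus images).
#' @export
simulate_waveforms <- function(patterns, basis, geometry = NULL,
                               pulse = optical_pulse(), det = detector_spec(),
                               model = c("coherent", "incoherent"),
                               noise_seed = NULL, perturbation = NULL) {
  model <- match.arg(model)
  shp <- dim(patterns$image[[1]])
  if (is.null(geometry)) {
    geometry <- scene_geometry(pixel_pitch_um = patterns$pixel_pitch_um[1],
                               image_shape = shp)
  }
  op <- coupling_operator(basis, geometry)
  imgs <- pattern_matrix(patterns)
  norm_ref <- sum(op$incore_px)
  if (model == "incoherent") {
    p <- imgs %*% t(op$m_inc) / norm_ref
  } else {
    amp <- sqrt(pmax(imgs %*% t(op$b), 0))
    c_m <- amp %*% t(basis$fields)
    p <- c_m^2 / norm_ref
  }
  delays <- basis$modes$delay_ps_per_m * basis$fiber$length_m
  window <- default_window_ps(delays, pulse, det)
  if (!is.null(perturbation)) {
    pert <- perturb_coupling(p, basis, perturbation$strength,
                             perturbation$delay_jitter_ps %||% 20,
                             perturbation$seed %||% 1,
                             pulse$fwhm_ps)
    p <- pert$result
    delays <- pert$delays_ps
  }
  dt <- 1000 / det$sample_rate_gsps
  t <- seq(window[1], window[2], by = dt)
  g <- gauss_kernel_matrix(delays, t, effective_sigma_ps(pulse, det))
  s <- p %*% g * pulse$energy
  if (!is.null(noise_seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(noise_seed)
    rms <- sqrt(rowMeans(s^2))
    sd_n <- rms / 10^(det$noise_snr_db / 20)
    s <- s + matrix(stats::rnorm(length(s)), nrow(s)) * sd_n
  }
  structure(list(samples = s, dt_ps = dt,
                 t0_ps = window[1] - min(basis$modes$delay_ps_per_m) *
                   basis$fiber$length_m,
                 window_ps = window,
                 meta = dplyr::select(patterns, -"image")),
            class = "waveform_set")
}

#' @export
print.waveform_set <- function(x, ...) {
  cat(sprintf("<waveform_set> %d frames x %d samples @ %g ps\n",
              nrow(x$samples), ncol(x$samples), x$dt_ps))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Single-frame temporal span
#'
#' Duration over which one frame's waveform is above 1% of its possible
#' peak: the intermodal delay spread plus Gaussian tails of the effective
#' (pulse + detector) response.
#'
#' @param basis A [find_lp_modes()] result.
#' @param pulse An [optical_pulse()].
#' @param det A [detector_spec()].
#' @param length_m Optional fiber length override (m).
#' @return Span in ns.
#' @export
frame_span_ns <- function(basis, pulse = optical_pulse(),
                          det = detector_spec(), length_m = NULL) {
  spread <- delay_spread_ns(basis, length_m)
  tail_ps <- sqrt(2 * log(100)) * effective_sigma_ps(pulse, det)
  spread + 2 * tail_ps / 1000
}

#' Concatenate frames into a pulse-train stream
#'
#' Frames are placed at multiples of the pulse period. The overlap flag is
#' true iff the single-frame span strictly exceeds the period (a frame span
#' exactly equal to the period does not overlap).
#'
#' @param patterns A pattern tibble (at least one row).
#' @param basis,geometry,pulse,det,model,noise_seed As in
#'   [simulate_waveforms()].
#' @return A list with `stream` (a `waveform` holding the concatenated
#'   trace), `frame_span_ns`, `period_ns` and `overlap`.
#' @export
waveform_train <- function(patterns, basis, geometry = NULL,
                           pulse = optical_pulse(), det = detector_spec(),
                           model = "incoherent", noise_seed = NULL) {
  stopifnot(nrow(patterns) >= 1)
  ws <- simulate_waveforms(patterns, basis, geometry, pulse, det, model,
                           noise_seed = NULL)
  span <- frame_span_ns(basis, pulse, det)
  period_ps <- pulse$period_ns * 1000
  n <- nrow(ws$samples)
  dt <- ws$dt_ps
  total <- ceiling(period_ps * n / dt)
  stream <- numeric(total)
  n_s <- ncol(ws$samples)
  for (i in seq_len(n)) {
    k0 <- round((i - 1) * period_ps / dt)
    idx <- (k0 + 1):(k0 + n_s)
    keep <- idx <= total
    stream[idx[keep]] <- stream[idx[keep]] + ws$samples[i, keep]
  }
  if (!is.null(noise_seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(noise_seed)
    sd_n <- sqrt(mean(stream^2)) / 10^(det$noise_snr_db / 20)
    stream <- stream + stats::rnorm(total, 0, sd_n)
  }
  wf <- structure(list(samples = stream, dt_ps = dt, t0_ps = ws$t0_ps,
                       meta = list(n_frames = n, period_ns = pulse$period_ns)),
                  class = "waveform")
  list(stream = wf, frame_span_ns = span, period_ns = pulse$period_ns,
       overlap = span > pulse$period_ns)
}

#' Maximum non-overlapping frame rate
#'
#' The reciprocal of the single-frame span, displayed to 3 significant
#' figures: a 65 ns period gives 15.4 MHz; an 18.7 ns span allows 53.5 MHz.
#'
#' @param single_frame_span_ns Span of one frame in ns.
#' @return Rate in MHz (3 significant figures).
#' @examples
#' max_frame_rate(65)   # 15.4
#' max_frame_rate(18.7) # 53.5
#' @export
max_frame_rate <- function(single_frame_span_ns) {
  if (any(single_frame_span_ns <= 0)) stop("span must be positive")
  signif(1000 / single_frame_span_ns, 3)
}

#' Record duration of a digitizer acquisition
#'
#' @param n_samples Record length in samples (default 62.5e6).
#' @param sample_rate_gsps Sampling rate in GS/s (default 100).
#' @return Duration in microseconds (62.5 Msamples at 100 GS/s = 625 us).
#' @export
record_duration_us <- function(n_samples = 62.5e6, sample_rate_gsps = 100) {
  n_samples / (sample_rate_gsps * 1e9) * 1e6
}

#' Frame depth of a single acquisition
#'
#' Number of whole frame periods fitting in one digitizer record.
#'
#' @param record_us Record duration in microseconds.
#' @param period_ns Frame period in ns.
#' @return Integer frame count.
#' @export
frame_depth <- function(record_us = 625, period_ns = 65) {
  floor(record_us * 1000 / period_ns)
}
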