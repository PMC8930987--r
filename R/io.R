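# Configuration, file formats and optional external-data readers: a
# validated nested run configuration (YAML) with hardware defaults, a CSV +
# binary trace container with bit-exact round-trip, 8-bit grayscale PNG
# pattern i/o, dataset directories with JSON manifests, and an IDX
# (MNIST-compatible) image reader for user-supplied digit files.

#' Default run configuration
#'
#' Nested blocks `fiber`, `pulse`, `detector`, `geometry`, `decoder` and
#' `study`, populated with the reference hardware: 50 um core / NA 0.22 /
#' 1 km fiber at 1064 nm (0.14 nm source bandwidth), 45.1 ps pulses with a
#' 65 ns period, a 30 GHz detector with 15 ps impulse response sampled at
#' 100 GS/s at 30 dB SNR, and 7.56 um object pixels on a 28x28 scene.
#'
#' @param seed Global seed recorded in the config.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    version = "1",
    seed = seed,
    fiber = list(core_radius_um = 25, na = 0.22, n_clad = 1.4496,
                 length_m = 1000, wavelength_nm = 1064,
                 bandwidth_nm = 0.14),
    pulse = list(fwhm_ps = 45.1, period_ns = 65, energy = 1),
    detector = list(bandwidth_ghz = 30, sample_rate_gsps = 100,
                    noise_snr_db = 30, impulse_fwhm_ps = 15),
    geometry = list(pixel_pitch_um = 7.56, image_shape = c(28L, 28L),
                    magnification = NULL, offset_um = c(2, 1.5),
                    fill_fraction = 0.9),
    decoder = list(arch = "fc5", input_len = 4096L,
                   output_shape = c(64L, 64L), epochs = 50L,
                   batch_size = 128L, learning_rate = 1e-3,
                   lr_decay = 0.3, seed = 1L, loss = "mse",
                   ridge_lambda = 1e-4),
    study = list(n_train = 2000L, n_test = 500L,
                 lengths_m = c(100, 150, 250, 400, 700, 1000),
                 strengths = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                 contrast_threshold = 0.2, dominance_factor = 100)),
    class = "run_config")
}

merge_validate <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- paste0(path, key)
    if (!key %in% names(defaults)) {
      stop("unknown configuration key: ", full)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        stop("configuration block expected at key: ", full)
      }
      defaults[[key]] <- merge_validate(defaults[[key]], user[[key]],
                                        paste0(full, "$"))
    } else {
      defaults[key] <- user[key] # keeps explicit NULLs
    }
  }
  defaults
}

#' Load, save and fingerprint run configurations
#'
#' `load_config()` reads a YAML file, validates it against the default
#' schema (unknown keys are an error) and fills unspecified values with the
#' hardware defaults; an empty file yields the full default configuration.
#' `save_config()` writes YAML; `config_digest()` returns a stable short
#' hash of the canonical (key-sorted) JSON form, invariant to key order.
#'
#' @param path File path.
#' @return `load_config`: a `run_config`; `config_digest`: a character
#'   scalar.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_validate(unclass(default_config()), user)
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @param config A `run_config` (or any nested list).
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname load_config
#' @export
config_digest <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  rlang::hash(jsonlite::toJSON(canon(unclass(config)), auto_unbox = TRUE,
                               digits = NA, null = "null"))
}

#' Build the forward-model objects described by a config
#'
#' @param config A `run_config`.
#' @return A list with `fiber`, `pulse`, `det` and `geometry` objects.
#' @export
config_objects <- function(config) {
  f <- config$fiber
  g <- config$geometry
  list(
    fiber = fiber_spec(f$core_radius_um, f$na, f$length_m, f$wavelength_nm,
                       f$n_clad),
    pulse = optical_pulse(config$pulse$fwhm_ps, config$pulse$period_ns,
                          config$pulse$energy),
    det = detector_spec(config$detector$bandwidth_ghz,
                        config$detector$sample_rate_gsps,
                        config$detector$noise_snr_db,
                        config$detector$impulse_fwhm_ps),
    geometry = scene_geometry(g$pixel_pitch_um, g$image_shape,
                              g$magnification, g$offset_um,
                              g$fill_fraction))
}

# ---- traces ----------------------------------------------------------------

#' Write and read waveform traces
#'
#' The binary container is a little-endian file with a JSON header
#' (preceded by its byte length as a 32-bit integer) holding `dt_ps`,
#' `t0_ps`, `length`, `version` and free-form `meta`, followed by the raw
#' doubles; write/read round-trips are bit-exact. The CSV form has columns
#' `t_ps, value` and round-trips to 1e-9.
#'
#' @param w A `waveform`.
#' @param path Output path.
#' @return The path (writers, invisibly) or a `waveform` (readers).
#' @export
write_trace <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  header <- jsonlite::toJSON(
    list(dt_ps = w$dt_ps, t0_ps = w$t0_ps, length = length(w$samples),
         version = "1", meta = w$meta),
    auto_unbox = TRUE, digits = NA, null = "null")
  hraw <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(length(hraw), con, size = 4, endian = "little")
  writeBin(hraw, con)
  writeBin(w$samples, con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hlen <- readBin(con, integer(), 1, size = 4, endian = "little")
  if (length(hlen) == 0 || hlen <= 0) stop("corrupt trace header")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, raw(), hlen)))
  samples <- readBin(con, numeric(), header$length + 1, size = 8,
                     endian = "little")
  if (length(samples) != header$length) {
    stop("trace payload length mismatch: header says ", header$length,
         ", file holds ", length(samples))
  }
  structure(list(samples = samples, dt_ps = as.numeric(header$dt_ps),
                 t0_ps = as.numeric(header$t0_ps), meta = header$meta),
            class = "waveform")
}

#' @rdname write_trace
#' @export
write_trace_csv <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  t_ps <- w$t0_ps + (seq_along(w$samples) - 1) * w$dt_ps
  utils::write.csv(data.frame(t_ps = t_ps, value = w$samples), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  dt <- if (nrow(df) > 1) df$t_ps[2] - df$t_ps[1] else 1
  structure(list(samples = df$value, dt_ps = dt, t0_ps = df$t_ps[1],
                 meta = list()),
            class = "waveform")
}

# ---- images ----------------------------------------------------------------

#' Write / read an image pattern as 8-bit grayscale PNG
#'
#' @param pattern An `image_pattern` or matrix in `[0, 1]`.
#' @param path File path.
#' @return The path (writer, invisibly) or an `image_pattern` (reader).
#' @export
write_pattern_png <- function(pattern, path) {
  img <- as_intensity_matrix(pattern)
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname write_pattern_png
#' @param pixel_pitch_um Pitch recorded on the read pattern.
#' @export
read_pattern_png <- function(path, pixel_pitch_um = 7.56) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  image_pattern(img, pixel_pitch_um, kind = "grayscale")
}

#' Write a simulated dataset directory
#'
#' One directory holding PNG images, binary traces and a JSON manifest
#' mapping image/trace pairs and recording seeds and the configuration
#' digest.
#'
#' @param patterns Pattern tibble.
#' @param waveforms Matching `waveform_set`.
#' @param dir Output directory (created).
#' @param config Optional configuration stored by digest in the manifest.
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(patterns, waveforms, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  dir.create(file.path(dir, "traces"), showWarnings = FALSE)
  entries <- vector("list", nrow(patterns))
  for (i in seq_len(nrow(patterns))) {
    img_file <- sprintf("images/%05d.png", patterns$id[i])
    trc_file <- sprintf("traces/%05d.bin", patterns$id[i])
    write_pattern_png(patterns$image[[i]], file.path(dir, img_file))
    wf <- structure(list(samples = waveforms$samples[i, ],
                         dt_ps = waveforms$dt_ps, t0_ps = waveforms$t0_ps,
                         meta = list(id = patterns$id[i])),
                    class = "waveform")
    write_trace(wf, file.path(dir, trc_file))
    entries[[i]] <- list(id = patterns$id[i], label = patterns$label[i],
                         image = img_file, trace = trc_file)
  }
  manifest <- list(
    n = nrow(patterns), kind = patterns$kind[1],
    pixel_pitch_um = patterns$pixel_pitch_um[1],
    config_digest = if (is.null(config)) NULL else config_digest(config),
    entries = entries)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(mpath)
}

# ---- IDX -------------------------------------------------------------------

#' Read images from an IDX file
#'
#' Accepts the big-endian IDX format used by handwritten-digit corpora
#' (magic `0x00000803`, unsigned bytes); pixel values are scaled to
#' `[0, 1]`.
#'
#' @param path IDX file path.
#' @param pixel_pitch_um Pitch recorded on the patterns.
#' @return A pattern tibble (possibly empty, with a warning, when the
#'   header declares zero images).
#' @export
read_idx_images <- function(path, pixel_pitch_um = 7.56) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, integer(), 1, size = 4, endian = "big")
  if (length(magic) == 0 || magic != 2051L) {
    stop("not an IDX image file (bad magic number)")
  }
  dims <- readBin(con, integer(), 3, size = 4, endian = "big")
  if (length(dims) < 3) stop("truncated IDX header")
  n <- dims[1]; rows <- dims[2]; cols <- dims[3]
  if (n == 0) {
    warning("IDX header declares zero images")
    return(pattern_tbl(list(), integer(0), "glyph", pixel_pitch_um))
  }
  payload <- readBin(con, integer(), n * rows * cols, size = 1,
                     signed = FALSE)
  if (length(payload) != n * rows * cols) {
    stop("truncated IDX payload: expected ", n * rows * cols, " bytes, got ",
         length(payload))
  }
  images <- lapply(seq_len(n), function(i) {
    off <- (i - 1) * rows * cols
    # IDX stores row-major
    matrix(payload[off + seq_len(rows * cols)] / 255, rows, cols,
           byrow = TRUE)
  })
  pattern_tbl(images, rep(NA_integer_, n), "glyph", pixel_pitch_um)
}
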