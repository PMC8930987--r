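# Scripted desk-scale studies: fiber-length ablation, frame-rate analysis,
# perturbation robustness with joint training, bar-target resolution, and
# waveform classification. Every study returns a `study_result` whose table
# is fully determined by its seed and configuration.

study_result <- function(study, table, config, extra = list()) {
  structure(c(list(study = study, table = table,
                   config_hash = config_digest(config), config = config),
              extra),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result: %s> (config %s)\n", x$study, x$config_hash))
  print(x$table)
  invisible(x)
}

#' @rdname run_length_ablation
#' @param x A `study_result`.
#' @param ... Unused.
#' @export
tidy.study_result <- function(x, ...) x$table

# Shared helper: glyph dataset -> waveforms -> decoder -> mean test fidelity
# for one fiber length. Delays scale exactly linearly with length, so the
# mode basis is solved once and re-scaled.
ablation_fidelity <- function(basis, length_m, n_train, n_test, seed,
                              config, pulse, det, shape = c(28, 28)) {
  basis$fiber$length_m <- length_m
  n <- n_train + n_test
  patterns <- make_glyphs(n, shape = shape, seed = seed)
  ws <- simulate_waveforms(patterns, basis, pulse = pulse, det = det,
                           noise_seed = seed + 1)
  tr <- seq_len(n_train)
  ws_tr <- subset_waveforms(ws, tr)
  ws_te <- subset_waveforms(ws, n_train + seq_len(n_test))
  model <- train_decoder(ws_tr, patterns[tr, ], config)
  ev <- evaluate_reconstruction(model, ws_te, patterns[n_train + seq_len(n_test), ])
  list(fidelity = ev$fidelity_mean, ssim = ev$ssim_mean)
}

subset_waveforms <- function(ws, idx) {
  structure(list(samples = ws$samples[idx, , drop = FALSE], dt_ps = ws$dt_ps,
                 t0_ps = ws$t0_ps, window_ps = ws$window_ps,
                 meta = ws$meta[idx, ]),
            class = "waveform_set")
}

#' Fiber-length ablation of reconstruction fidelity
#'
#' For each fiber length the mode delays are re-scaled, a glyph dataset is
#' simulated, a decoder is trained and mean held-out fidelity recorded. The
#' expected shape mirrors the imaging physics: a plateau for lengths of
#' 400 m and above (sub-pulses fully resolved) and a clear decline at around
#' 100 m, where the intermodal delay gaps drop below the pulse width and the
#' modal information overlaps irrecoverably.
#'
#' @param lengths_m Fiber lengths in metres (default
#'   `c(100, 150, 250, 400, 700, 1000)`).
#' @param n_train,n_test Dataset sizes per length (defaults 2000 / 500).
#' @param seed Integer seed.
#' @param basis Optional precomputed [find_lp_modes()] basis.
#' @param config [decoder_config()] used at every length (default linear:
#'   the ablation needs ordering, not peak quality).
#' @param pulse,det Pulse and detector specifications.
#' @return A `study_result` whose table has one row per length with
#'   `fidelity_mean` and `ssim_mean`.
#' @export
run_length_ablation <- function(lengths_m = c(100, 150, 250, 400, 700, 1000),
                                n_train = 2000, n_test = 500, seed = 1,
                                basis = NULL,
                                config = decoder_config("linear"),
                                pulse = optical_pulse(),
                                det = detector_spec()) {
  stopifnot(all(lengths_m > 0))
  if (is.null(basis)) {
    basis <- find_lp_modes(fiber_spec(25, 0.22, max(lengths_m), 1064))
  }
  rows <- purrr::map_dfr(lengths_m, function(L) {
    r <- ablation_fidelity(basis, L, n_train, n_test, seed, config, pulse, det)
    tibble::tibble(length_m = L, fidelity_mean = r$fidelity,
                   ssim_mean = r$ssim, seed = seed)
  })
  study_result("length_ablation", rows,
               list(lengths_m = lengths_m, n_train = n_train,
                    n_test = n_test, seed = seed, arch = config$arch))
}

#' Frame-rate analysis across fiber lengths
#'
#' Computes the single-frame temporal span and the maximum non-overlapping
#' frame rate per fiber length, and flags whether frames overlap at the
#' given pulse period.
#'
#' @param lengths_m Fiber lengths in metres.
#' @param period_ns Pulse repetition period (default 65 ns).
#' @param basis Optional precomputed basis.
#' @param pulse,det Pulse and detector specifications.
#' @return A `study_result` with per-length `frame_span_ns`,
#'   `max_frame_rate_mhz` and `overlap_at_period`.
#' @export
run_frame_rate_analysis <- function(lengths_m = c(400, 1000), period_ns = 65,
                                    basis = NULL, pulse = optical_pulse(),
                                    det = detector_spec()) {
  if (is.null(basis)) {
    basis <- find_lp_modes(fiber_spec(25, 0.22, max(lengths_m), 1064),
                           grid_size = 32)
  }
  rows <- purrr::map_dfr(lengths_m, function(L) {
    span <- frame_span_ns(basis, pulse, det, length_m = L)
    tibble::tibble(length_m = L, frame_span_ns = span,
                   max_frame_rate_mhz = max_frame_rate(span),
                   overlap_at_period = span > period_ns)
  })
  study_result("frame_rate", rows,
               list(lengths_m = lengths_m, period_ns = period_ns))
}

#' Robustness to modal crosstalk and delay jitter
#'
#' Trains a decoder on the unperturbed configuration (and, when
#' `joint_training`, a second decoder on data pooled across perturbation
#' strengths) and evaluates both against test waveforms synthesized under
#' each perturbation strength. The tolerated range of a decoder is the
#' largest strength up to which fidelity stays at or above
#' `fidelity_floor` contiguously from zero; pooled training should tolerate
#' at least as wide a range as single-condition training.
#'
#' @param strengths Perturbation strengths in `[0, 1]` (include 0).
#' @param delay_jitter_ps Delay-jitter scale at strength 1.
#' @param joint_training Also train on data pooled across `strengths`.
#' @param n_train,n_test Training / test sizes.
#' @param seed Integer seed.
#' @param basis Optional precomputed basis.
#' @param config Decoder configuration (default linear).
#' @param pulse,det Pulse and detector specifications.
#' @param fidelity_floor Fidelity threshold defining the tolerated range.
#' @return A `study_result`; the table has one row per (training scheme,
#'   strength), and `tolerated` holds each scheme's tolerated range.
#' @export
run_robustness <- function(strengths = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                           delay_jitter_ps = 20, joint_training = TRUE,
                           n_train = 1500, n_test = 300, seed = 1,
                           basis = NULL, config = decoder_config("linear"),
                           pulse = optical_pulse(), det = detector_spec(),
                           fidelity_floor = 0.70) {
  if (is.null(basis)) {
    basis <- find_lp_modes(fiber_spec(25, 0.22, 1000, 1064))
  }
  n <- n_train + n_test
  patterns <- make_glyphs(n, seed = seed)
  tr_idx <- seq_len(n_train)
  te_idx <- n_train + seq_len(n_test)
  sim <- function(strength, noise_seed, pert_seed) {
    pert <- if (strength > 0) {
      list(strength = strength, delay_jitter_ps = delay_jitter_ps,
           seed = pert_seed)
    } else NULL
    simulate_waveforms(patterns, basis, pulse = pulse, det = det,
                       noise_seed = noise_seed, perturbation = pert)
  }
  # training data: the unperturbed condition, plus (joint) each strength
  ws0 <- sim(0, seed + 1, seed)
  model_single <- train_decoder(subset_waveforms(ws0, tr_idx),
                                patterns[tr_idx, ], config)
  model_joint <- NULL
  if (joint_training) {
    pools <- lapply(seq_along(strengths), function(i) {
      subset_waveforms(sim(strengths[i], seed + 1, seed + 100 + i), tr_idx)
    })
    pooled <- structure(
      list(samples = do.call(rbind, lapply(pools, function(w) w$samples)),
           dt_ps = ws0$dt_ps, t0_ps = ws0$t0_ps, window_ps = ws0$window_ps,
           meta = dplyr::bind_rows(lapply(pools, function(w) w$meta))),
      class = "waveform_set")
    pooled_patterns <- dplyr::bind_rows(
      replicate(length(strengths), patterns[tr_idx, ], simplify = FALSE))
    model_joint <- train_decoder(pooled, pooled_patterns, config)
  }
  # evaluation: fresh perturbation realizations per strength
  rows <- purrr::map_dfr(seq_along(strengths), function(i) {
    s <- strengths[i]
    ws_te <- subset_waveforms(sim(s, seed + 2, seed + 200 + i), te_idx)
    out <- tibble::tibble(
      scheme = "single", strength = s,
      fidelity_mean = evaluate_reconstruction(model_single, ws_te,
                                              patterns[te_idx, ])$fidelity_mean)
    if (!is.null(model_joint)) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        scheme = "joint", strength = s,
        fidelity_mean = evaluate_reconstruction(model_joint, ws_te,
                                                patterns[te_idx, ])$fidelity_mean))
    }
    out
  })
  tolerated <- dplyr::summarize(
    dplyr::group_by(rows, .data$scheme),
    tolerated_strength = tolerated_range(.data$strength,
                                         .data$fidelity_mean,
                                         fidelity_floor))
  study_result("robustness", rows,
               list(strengths = strengths, delay_jitter_ps = delay_jitter_ps,
                    joint_training = joint_training, n_train = n_train,
                    n_test = n_test, seed = seed, arch = config$arch,
                    fidelity_floor = fidelity_floor),
               extra = list(tolerated = tolerated))
}

# Largest strength reachable from 0 with fidelity >= floor at every
# intermediate tested strength.
tolerated_range <- function(strength, fid, floor_) {
  ord <- order(strength)
  s <- strength[ord]; f <- fid[ord]
  ok <- f >= floor_
  if (!ok[1]) return(0)
  last <- which(!ok)[1]
  if (is.na(last)) s[length(s)] else s[last - 1]
}

#' Bar-target resolution test
#'
#' Reconstructs a resolution bar target with a decoder trained on random
#' stroke patterns and reports the Michelson contrast of the intensity
#' profile across each bar group; a pitch counts as resolved when its
#' contrast exceeds `contrast_threshold` (default 0.2).
#'
#' @param model A `trained_decoder` (trained on stroke patterns of the same
#'   scene geometry).
#' @param target A [make_resolution_target()] pattern.
#' @param basis The mode basis used for the forward model.
#' @param geometry Optional [scene_geometry()] (defaults to the target
#'   shape).
#' @param pulse,det Pulse and detector specifications.
#' @param noise_seed Optional noise seed for the probe waveform.
#' @param model_coupling Coupling model for the probe waveform (match the
#'   model the decoder was trained with).
#' @param contrast_threshold Resolution criterion.
#' @return A `study_result` with per-group `pitch_px`, `pitch_um`,
#'   `orientation`, `contrast` and `resolved`; the reconstruction is
#'   attached as `recon`.
#' @export
run_resolution_test <- function(model, target, basis, geometry = NULL,
                                pulse = optical_pulse(),
                                det = detector_spec(), noise_seed = NULL,
                                model_coupling = c("coherent", "incoherent"),
                                contrast_threshold = 0.2) {
  model_coupling <- match.arg(model_coupling)
  groups <- attr(target, "groups")
  if (is.null(groups)) stop("target must come from make_resolution_target()")
  patterns <- pattern_tbl(list(target$intensities), NA_integer_, "bars",
                          target$pixel_pitch_um)
  ws <- simulate_waveforms(patterns, basis, geometry, pulse, det,
                           model = model_coupling, noise_seed = noise_seed)
  recon <- reconstruct(model, ws)[[1]]
  rows <- purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    contrast <- bar_group_contrast(recon$intensities, g,
                                   dim(target$intensities))
    tibble::tibble(pitch_px = g$pitch_px,
                   pitch_um = g$pitch_px * target$pixel_pitch_um,
                   orientation = g$orientation, contrast = contrast,
                   resolved = contrast > contrast_threshold)
  })
  study_result("resolution", rows,
               list(contrast_threshold = contrast_threshold,
                    pitches_px = unique(groups$pitch_px)),
               extra = list(recon = recon))
}

# Michelson contrast of the mean profile across a bar group, comparing bar
# centres with gap centres. `shape_in` is the original target shape; the
# reconstruction may live on a different (e.g. 64x64) grid and is sampled at
# scaled coordinates.
bar_group_contrast <- function(recon, group, shape_in) {
  sr <- nrow(recon) / shape_in[1]
  sc <- ncol(recon) / shape_in[2]
  p <- group$pitch_px
  bar <- max(1L, p %/% 2L)
  if (group$orientation == "vertical") {
    # bars repeat along columns; average profile over rows of the group
    rows <- round((group$row0:group$row1) * sr)
    prof_at <- function(col) {
      cols <- pmin(pmax(round(col * sc), 1), ncol(recon))
      mean(recon[pmin(pmax(rows, 1), nrow(recon)), cols])
    }
    bar_pos <- group$col0 + (0:2) * p + (bar - 1) / 2
    gap_pos <- group$col0 + (0:1) * p + bar + (p - bar - 1) / 2
  } else {
    cols <- round((group$col0:group$col1) * sc)
    prof_at <- function(row) {
      rws <- pmin(pmax(round(row * sr), 1), nrow(recon))
      mean(recon[rws, pmin(pmax(cols, 1), ncol(recon))])
    }
    bar_pos <- group$row0 + (0:2) * p + (bar - 1) / 2
    gap_pos <- group$row0 + (0:1) * p + bar + (p - bar - 1) / 2
  }
  i_max <- mean(vapply(bar_pos, prof_at, numeric(1)))
  i_min <- mean(vapply(gap_pos, prof_at, numeric(1)))
  if (i_max + i_min == 0) return(0)
  (i_max - i_min) / (i_max + i_min)
}

#' Waveform classification study
#'
#' Simulates a labeled glyph dataset, trains the waveform classifier and
#' reports held-out accuracy together with a shuffled-label chance baseline.
#'
#' @param n_classes Number of glyph classes (default 10).
#' @param n_train,n_test Training / test sizes.
#' @param seed Integer seed.
#' @param basis Optional precomputed basis.
#' @param pulse,det Pulse and detector specifications.
#' @param epochs Classifier training epochs.
#' @param chance_baseline Also evaluate with shuffled training labels.
#' @return A `study_result` with rows `accuracy` and (optionally)
#'   `chance_accuracy`.
#' @export
run_classification <- function(n_classes = 10, n_train = 10000,
                               n_test = 1000, seed = 1, basis = NULL,
                               pulse = optical_pulse(),
                               det = detector_spec(), epochs = 30,
                               chance_baseline = FALSE) {
  if (is.null(basis)) {
    basis <- find_lp_modes(fiber_spec(25, 0.22, 1000, 1064))
  }
  n <- n_train + n_test
  patterns <- make_glyphs(n, n_classes = n_classes, seed = seed)
  ws <- simulate_waveforms(patterns, basis, noise_seed = seed + 1,
                           pulse = pulse, det = det)
  tr <- seq_len(n_train); te <- n_train + seq_len(n_test)
  res <- classify_waveforms(subset_waveforms(ws, tr), patterns$label[tr],
                            subset_waveforms(ws, te), patterns$label[te],
                            seed = seed, epochs = epochs)
  rows <- tibble::tibble(metric = "accuracy", value = res$accuracy,
                         seed = seed)
  if (chance_baseline) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed + 7)
    shuffled <- sample(patterns$label[tr])
    chance <- classify_waveforms(subset_waveforms(ws, tr), shuffled,
                                 subset_waveforms(ws, te),
                                 patterns$label[te], seed = seed,
                                 epochs = epochs)
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      metric = "chance_accuracy", value = chance$accuracy, seed = seed))
  }
  study_result("classification", rows,
               list(n_classes = n_classes, n_train = n_train,
                    n_test = n_test, seed = seed, epochs = epochs))
}

#' Synthetic frame-stream demo
#'
#' Builds a short pulse-train stream in which one glyph morphs into another
#' in three stages (first glyph, overlap region only, second glyph),
#' mimicking a display refresh observed frame by frame. A demonstration of
#' the stream machinery, not an analysis surface.
#'
#' @param basis Optional precomputed basis.
#' @param n_frames Frames per stage.
#' @param seed Integer seed.
#' @param pulse,det Pulse and detector specifications.
#' @return A list with the `waveform_train()` output and the frame patterns.
#' @export
demo_frame_stream <- function(basis = NULL, n_frames = 3, seed = 1,
                              pulse = optical_pulse(),
                              det = detector_spec()) {
  if (is.null(basis)) {
    basis <- find_lp_modes(fiber_spec(25, 0.22, 1000, 1064), grid_size = 64)
  }
  g <- make_glyphs(2, n_classes = 10, seed = seed)
  a <- g$image[[1]]; b <- g$image[[2]]
  stages <- c(replicate(n_frames, a, simplify = FALSE),
              replicate(n_frames, a * b, simplify = FALSE),
              replicate(n_frames, b, simplify = FALSE))
  patterns <- pattern_tbl(stages, rep(1:3, each = n_frames), "glyph",
                          g$pixel_pitch_um[1])
  stream <- waveform_train(patterns, basis, pulse = pulse, det = det)
  list(stream = stream, patterns = patterns)
}
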