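# Forward encoder: modal coupling, perturbation, waveform synthesis,
# pulse-train assembly and frame-rate arithmetic.

test_that("a dark scene couples no power", {
  basis <- tiny_basis()
  cr <- couple_image(matrix(0, 28, 28), basis)
  expect_true(all(cr$mode_powers == 0))
})

test_that("injecting a pure mode field couples into that mode only", {
  basis <- paper_basis() # fine grid keeps the quadrature error below 1e-3
  gs <- basis$grid_size
  i01 <- which(basis$modes$l == 0 & basis$modes$m == 1)
  psi <- matrix(basis$fields[i01, ], gs, gs)
  img <- psi^2 / max(psi^2) # fundamental mode is sign-definite
  geom <- scene_geometry(pixel_pitch_um = diff(basis$grid_x_um)[1],
                         image_shape = c(gs, gs), magnification = 1,
                         offset_um = c(0, 0)) # facet-native injection
  cr <- couple_image(img, basis, geom, model = "coherent")
  expect_equal(cr$mode_powers[i01], 1, tolerance = 1e-3)
  expect_lt(max(cr$mode_powers[-i01]), 1e-6)
})

test_that("a centred uniform disc couples only into l = 0 modes", {
  basis <- tiny_basis()
  gs <- basis$grid_size
  r <- sqrt(outer(basis$grid_x_um^2, basis$grid_y_um^2, "+"))
  img <- (r <= basis$fiber$core_radius_um) * 1
  geom <- scene_geometry(pixel_pitch_um = diff(basis$grid_x_um)[1],
                         image_shape = c(gs, gs), magnification = 1,
                         offset_um = c(0, 0)) # centred disc on axis
  cr <- couple_image(img, basis, geom, model = "coherent")
  p0 <- sum(cr$mode_powers[basis$modes$l == 0])
  p_other <- sum(cr$mode_powers[basis$modes$l != 0])
  expect_lt(p_other / p0, 1e-4)
})

test_that("incoherent coupling is linear under illumination normalization", {
  basis <- tiny_basis()
  set.seed(42)
  i1 <- matrix(runif(28 * 28), 28, 28)
  i2 <- matrix(runif(28 * 28), 28, 28)
  geom <- scene_geometry(image_shape = c(28, 28))
  cp <- function(img) couple_image(img, basis, geom, model = "incoherent",
                                   normalize = "illumination")$mode_powers
  mix <- cp(0.3 * i1 + 0.6 * i2)
  expect_equal(mix, 0.3 * cp(i1) + 0.6 * cp(i2), tolerance = 1e-9)
})

test_that("coupled power never exceeds the in-core intensity (Bessel bound)", {
  basis <- tiny_basis()
  set.seed(1)
  geom <- scene_geometry(image_shape = c(28, 28))
  # the bound applies to scenes inside the core footprint: mask the image
  # to the disc of pixels whose facet positions stay within the core
  rr <- sqrt(outer((1:28 - 14.5)^2, (1:28 - 14.5)^2, "+"))
  mask <- rr <= 12
  for (k in 1:5) {
    img <- matrix(runif(28 * 28), 28, 28) * mask
    cr <- couple_image(img, basis, geom, normalize = "image")
    expect_lte(sum(cr$mode_powers), 1 + 1e-6)
  }
})

test_that("coupling perturbation conserves power, is seeded, and is the identity at zero strength", {
  basis <- tiny_basis()
  img <- make_glyphs(1, seed = 3)$image[[1]]
  cr <- couple_image(img, basis, scene_geometry(image_shape = c(28, 28)))
  p0 <- perturb_coupling(cr, basis, strength = 0, seed = 5)
  expect_identical(p0$result$mode_powers, cr$mode_powers)
  expect_identical(p0$delays_ps,
                   basis$modes$delay_ps_per_m * basis$fiber$length_m)
  p1 <- perturb_coupling(cr, basis, strength = 1, delay_jitter_ps = 15,
                         seed = 5)
  expect_equal(sum(p1$result$mode_powers), sum(cr$mode_powers),
               tolerance = 1e-9)
  p1b <- perturb_coupling(cr, basis, strength = 1, delay_jitter_ps = 15,
                          seed = 5)
  expect_identical(p1$result$mode_powers, p1b$result$mode_powers)
  expect_identical(p1$delays_ps, p1b$delays_ps)
  expect_false(identical(p1$delays_ps, p0$delays_ps))
  expect_error(perturb_coupling(cr, basis, strength = 2), "strength")
})

test_that("a single sub-pulse carries unit energy through the detector", {
  pulse <- optical_pulse(fwhm_ps = 45.1)
  det <- detector_spec()
  w <- synthesize_waveform(c(1), delays_ps = 0, pulse = pulse, det = det)
  expect_equal(sum(w$samples) * w$dt_ps, 1, tolerance = 1e-3)
  expect_error(synthesize_waveform(numeric(0), numeric(0), pulse, det),
               "empty")
})

test_that("two equal sub-pulses appear at the right separation", {
  pulse <- optical_pulse(fwhm_ps = 45.1)
  det <- detector_spec()
  w <- synthesize_waveform(c(0.5, 0.5), delays_ps = c(0, 1000), pulse, det)
  s <- w$samples
  # two local maxima of equal height, 1000 ps apart (within one sample)
  peaks <- which(diff(sign(diff(s))) == -2) + 1
  top2 <- peaks[order(s[peaks], decreasing = TRUE)][1:2]
  expect_equal(abs(diff(sort(top2))) * w$dt_ps, 1000,
               tolerance = w$dt_ps + 1e-9)
  expect_equal(s[top2[1]], s[top2[2]], tolerance = 1e-6)
  expect_equal(sum(s) * w$dt_ps, 1, tolerance = 1e-3)
})

test_that("waveform support stays inside the delay-spread window", {
  basis <- tiny_basis()
  g <- make_glyphs(1, seed = 6)
  ws <- simulate_waveforms(g, basis)
  spread_ps <- delay_spread_ns(basis) * 1000
  t_rel <- ws$t0_ps + (seq_len(ncol(ws$samples)) - 1) * ws$dt_ps
  nz <- which(ws$samples[1, ] > 1e-9 * max(ws$samples[1, ]))
  expect_gte(min(t_rel[nz]), -500)
  expect_lte(max(t_rel[nz]), spread_ps + 500)
})

test_that("pre-noise waveform energy equals coupled power", {
  basis <- tiny_basis()
  g <- make_glyphs(3, seed = 2)
  ws <- simulate_waveforms(g, basis) # no noise, coherent default
  geom <- scene_geometry(image_shape = c(28, 28))
  for (i in 1:3) {
    cr <- couple_image(g$image[[i]], basis, geom,
                       normalize = "illumination")
    expect_equal(sum(ws$samples[i, ]) * ws$dt_ps, sum(cr$mode_powers),
                 tolerance = 1e-3)
  }
})

test_that("the incoherent forward map is linear pre-noise", {
  basis <- tiny_basis()
  set.seed(11)
  imgs <- list(matrix(runif(784), 28, 28), matrix(runif(784), 28, 28))
  mixed <- 0.25 * imgs[[1]] + 0.5 * imgs[[2]]
  pats <- tibble::tibble(id = 1:3, label = NA, kind = "glyph",
                         pixel_pitch_um = 7.56,
                         image = c(imgs, list(mixed)))
  ws <- simulate_waveforms(pats, basis, model = "incoherent")
  expect_equal(ws$samples[3, ],
               0.25 * ws$samples[1, ] + 0.5 * ws$samples[2, ],
               tolerance = 1e-9)
})

test_that("detector noise is seeded and reproducible", {
  basis <- tiny_basis()
  g <- make_glyphs(2, seed = 4)
  w1 <- simulate_waveforms(g, basis, noise_seed = 99)
  w2 <- simulate_waveforms(g, basis, noise_seed = 99)
  w3 <- simulate_waveforms(g, basis, noise_seed = 100)
  expect_identical(w1$samples, w2$samples)
  expect_false(identical(w1$samples, w3$samples))
})

test_that("frame span scales linearly with fiber length", {
  basis <- tiny_basis()
  pulse <- optical_pulse(); det <- detector_spec()
  spans <- vapply(c(150, 400, 1000), function(L) {
    frame_span_ns(basis, pulse, det, length_m = L)
  }, numeric(1))
  spreads <- vapply(c(150, 400, 1000), delay_spread_ns, numeric(1),
                    basis = basis)
  tail_ns <- spans - spreads
  expect_equal(tail_ns[1], tail_ns[2], tolerance = 1e-12)
  expect_equal(tail_ns[2], tail_ns[3], tolerance = 1e-12)
  expect_equal(spreads[3] / spreads[2], 2.5, tolerance = 1e-12)
})

test_that("pulse trains flag overlap against the repetition period", {
  basis <- paper_basis()
  g <- make_glyphs(2, seed = 5)
  # reference configuration: ~50 ns frames at a 65 ns period fit cleanly
  tr65 <- waveform_train(g, basis, pulse = optical_pulse(period_ns = 65))
  expect_false(tr65$overlap)
  expect_gt(tr65$frame_span_ns, 45)
  # a 40 ns period is too short for the same frames
  tr40 <- waveform_train(g, basis, pulse = optical_pulse(period_ns = 40))
  expect_true(tr40$overlap)
  # exact equality of span and period does not overlap (closed-open)
  span <- frame_span_ns(basis, optical_pulse(period_ns = 65),
                        detector_spec())
  tr_eq <- waveform_train(g, basis,
                          pulse = optical_pulse(period_ns = span))
  expect_false(tr_eq$overlap)
})

test_that("frame-rate arithmetic reproduces the instrument numbers", {
  expect_equal(max_frame_rate(65), 15.4, tolerance = 1e-9)
  expect_equal(max_frame_rate(18.7), 53.5, tolerance = 1e-9)
  expect_equal(max_frame_rate(1000), 1, tolerance = 1e-9)
  expect_error(max_frame_rate(0), "positive")
})

test_that("digitizer record duration and frame depth follow from the sample rate", {
  expect_equal(record_duration_us(62.5e6, 100), 625, tolerance = 1e-12)
  expect_identical(frame_depth(625, 65), 9615)
  expect_warning(detector_spec(bandwidth_ghz = 60, sample_rate_gsps = 100),
                 "twice")
})
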