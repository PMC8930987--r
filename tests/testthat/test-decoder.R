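# Decoder stack: preprocessing, metrics (against hand-computed and
# independently computed references), the linear pseudoinverse oracle, the
# trained networks' contracts, and waveform classification.

test_that("preprocessing crops to the network length and is idempotent on stats", {
  set.seed(3)
  w <- matrix(0, 2, 4500)
  w[, 2000:2600] <- abs(matrix(rnorm(2 * 601), 2))
  x <- preprocess_waveform(w, 4096)
  expect_identical(dim(x), c(2L, 4096L))
  st <- attr(x, "norm_stats")
  x2 <- preprocess_waveform(w, 4096, stats = st)
  expect_equal(unclass(x), unclass(x2), ignore_attr = TRUE)
  # identical waveforms map to identical vectors
  expect_identical(x[1, ], preprocess_waveform(w[1, , drop = FALSE], 4096,
                                               stats = st)[1, ])
  expect_warning(preprocess_waveform(matrix(0, 1, 100), 64), "all-zero")
})

test_that("row-major reshape of a 4096 vector is invertible", {
  v <- rnorm(4096)
  m <- matrix(v, 64, 64, byrow = TRUE)
  expect_identical(as.vector(t(m)), v)
})

test_that("fidelity is the pixelwise Pearson correlation", {
  a <- matrix(c(1, 0, 0, 0), 2)
  b <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(fidelity(a, b), 0.5 / sqrt(0.75), tolerance = 1e-12)
  set.seed(9)
  x <- matrix(runif(64), 8)
  expect_equal(fidelity(x, x), 1, tolerance = 1e-12)
  xb <- (x > 0.5) * 1
  expect_equal(fidelity(xb, 1 - xb), -1, tolerance = 1e-12)
  expect_identical(fidelity(matrix(0.5, 8, 8), x), 0)
  expect_error(fidelity(x, matrix(0, 4, 4)), "shape")
})

test_that("ssim matches an independently computed reference", {
  # construction mirrored from a scikit-image session (gaussian_weights,
  # sigma = 1.5, use_sample_covariance = FALSE, data_range = 1):
  # x = (sin(0.3 i) cos(0.2 j) + 1)/2, y = clip(x + 0.15 sin(0.7 (i+2j))),
  # 32x32, 0-based indices -> ssim = 0.7005198587405814
  i <- matrix(0:31, 32, 32)
  j <- t(i)
  x <- (sin(0.3 * i) * cos(0.2 * j) + 1) / 2
  y <- pmin(pmax(x + 0.15 * sin(0.7 * (i + 2 * j)), 0), 1)
  expect_equal(ssim_metric(x, y), 0.7005198587405814, tolerance = 1e-10)
})

test_that("ssim behaves like a similarity index", {
  set.seed(4)
  x <- matrix(runif(64 * 64), 64)
  expect_equal(ssim_metric(x, x), 1, tolerance = 1e-12)
  noisy <- pmin(pmax(x + 0.2 * rnorm(length(x)), 0), 1)
  expect_lt(ssim_metric(x, noisy), 1)
  expect_lt(ssim_metric(x, matrix(0.5, 64, 64)), ssim_metric(x, noisy))
  expect_equal(ssim_metric(x, noisy), ssim_metric(noisy, x),
               tolerance = 1e-12)
  # shuffling destroys structure under both metrics
  shuffled <- matrix(sample(x), 64)
  expect_lt(ssim_metric(x, shuffled), 0.5)
  expect_lt(abs(fidelity(x, shuffled)), 0.2)
  # images smaller than the window fall back to a global window
  small <- matrix(runif(36), 6)
  expect_equal(ssim_metric(small, small), 1, tolerance = 1e-9)
})

test_that("the ridge pseudoinverse recovers noiseless low-dimensional scenes", {
  basis <- medium_basis()
  # the incoherent (intensity-linear) map is exactly invertible on pattern
  # families whose dimension stays below the map's rank: build a
  # 12-dimensional nonnegative family
  set.seed(21)
  basis_imgs <- replicate(12, matrix(runif(64), 8, 8), simplify = FALSE)
  images <- replicate(140, {
    w <- runif(12)
    img <- Reduce(`+`, Map(`*`, basis_imgs, w))
    img / max(img)
  }, simplify = FALSE)
  pats <- tibble::tibble(id = seq_along(images), label = NA, kind = "glyph",
                         pixel_pitch_um = 7.56, image = images)
  ws <- simulate_waveforms(pats, basis, model = "incoherent") # noiseless
  model <- train_decoder(ws, pats,
                         decoder_config("linear", output_shape = c(8, 8),
                                        ridge_lambda = 1e-10))
  ev <- evaluate_reconstruction(model, ws, pats)
  expect_gt(ev$fidelity_mean, 0.99)
})

test_that("reconstruction honours the output contracts", {
  basis <- medium_basis()
  pats <- make_random_strokes(120, shape = c(8, 8), seed = 22)
  ws <- simulate_waveforms(pats, basis, noise_seed = 1)
  model <- train_decoder(ws, pats,
                         decoder_config("linear", output_shape = c(8, 8)))
  out <- reconstruct(model, ws)
  expect_length(out, 120)
  expect_identical(dim(out[[1]]$intensities), c(8L, 8L))
  rng <- range(vapply(out, function(p) range(p$intensities), numeric(2)))
  expect_gte(rng[1], 0)
  expect_lte(rng[2], 1)
  # an all-zero waveform yields the model intercept image
  zero_w <- ws
  zero_w$samples <- matrix(0, 1, ncol(ws$samples))
  suppressWarnings(pred <- reconstruct(model, zero_w))
  expect_equal(as.vector(pred[[1]]$intensities),
               pmin(pmax(model$fit$intercept -
                           as.vector(model$fit$x_mean %*% model$fit$w), 0), 1),
               tolerance = 1e-9)
})

test_that("fc5 training is seeded, reproducible, and reduces the loss", {
  set.seed(10)
  n <- 150
  x <- matrix(rnorm(n * 256), n)
  truth <- matrix(rnorm(256 * 64), 256)
  y <- 1 / (1 + exp(-(x %*% truth)))
  fit <- function(seed) {
    fibertwin:::mlp_fit(x, y, c(256, 64, 64), c("relu", "sigmoid"),
                        epochs = 8, batch_size = 32, seed = seed)
  }
  a <- fit(5); b <- fit(5); c <- fit(6)
  expect_identical(a$history, b$history)
  expect_identical(a$layers[[1]]$w, b$layers[[1]]$w)
  expect_false(identical(a$history, c$history))
  expect_lt(utils::tail(a$history, 1), a$history[1])
})

test_that("the unet architecture learns waveform-to-image recovery", {
  basis <- tiny_basis()
  pats <- make_glyphs(450, seed = 13)
  ws <- simulate_waveforms(pats, basis, noise_seed = 3)
  tr <- 1:400; te <- 401:450
  model <- train_decoder(fibertwin:::subset_waveforms(ws, tr), pats[tr, ],
                         decoder_config("unet", epochs = 25,
                                        batch_size = 16,
                                        learning_rate = 1e-3,
                                        unet_base = 8, seed = 1))
  h <- model$fit$history
  expect_lt(utils::tail(h, 1), h[1])
  # well below the constant-image optimum (the glyph target variance)
  expect_lt(utils::tail(h, 1), 0.10)
  out <- reconstruct(model, fibertwin:::subset_waveforms(ws, te))
  expect_identical(dim(out[[1]]$intensities), c(64L, 64L))
  rng <- range(vapply(out, function(p) range(p$intensities), numeric(2)))
  expect_gte(rng[1], 0); expect_lte(rng[2], 1)
  ev <- evaluate_reconstruction(model, fibertwin:::subset_waveforms(ws, te),
                                pats[te, ])
  expect_gt(ev$fidelity_mean, 0.4)
})

test_that("waveform classification separates orthogonal mode excitations", {
  basis <- tiny_basis()
  n_modes <- nrow(basis$modes)
  delays <- basis$modes$delay_ps_per_m * basis$fiber$length_m
  pulse <- optical_pulse(); det <- detector_spec()
  # two classes excite disjoint mode groups: linearly separable waveforms
  p_a <- c(rep(1, 3), rep(0, n_modes - 3)) / 3
  p_b <- c(rep(0, n_modes - 3), rep(1, 3)) / 3
  mk <- function(p, n) {
    t(vapply(seq_len(n), function(i) {
      synthesize_waveform(p * runif(1, 0.5, 1), delays, pulse, det)$samples
    }, numeric(length(synthesize_waveform(p, delays, pulse, det)$samples))))
  }
  set.seed(31)
  xa <- mk(p_a, 30); xb <- mk(p_b, 30)
  x <- rbind(xa, xb)
  labels <- rep(c(0, 1), each = 30)
  res <- classify_waveforms(x, labels, x, labels, seed = 1, epochs = 15,
                            input_len = 4096)
  expect_equal(res$accuracy, 1.0)
  expect_error(classify_waveforms(x, rep(0, 60), x, labels), "two classes")
})

test_that("shuffled labels yield chance-level accuracy", {
  set.seed(17)
  n <- 1200
  x <- matrix(rnorm(n * 512), n)
  labels <- sample(0:3, n, replace = TRUE)
  res <- classify_waveforms(x[1:600, ], labels[1:600],
                            x[601:1200, ], labels[601:1200],
                            seed = 2, epochs = 5, input_len = 512)
  expect_gt(res$accuracy, 0.25 - 0.05)
  expect_lt(res$accuracy, 0.25 + 0.05)
})

test_that("tidy and glance summarize trained decoders", {
  basis <- medium_basis()
  pats <- make_random_strokes(110, shape = c(8, 8), seed = 23)
  ws <- simulate_waveforms(pats, basis, noise_seed = 3)
  model <- train_decoder(ws, pats,
                         decoder_config("linear", output_shape = c(8, 8)))
  g <- glance(model)
  expect_identical(g$arch, "linear")
  expect_identical(g$n_train, 110L)
  expect_identical(nrow(tidy(model)), 0L)
  ev <- evaluate_reconstruction(model, ws, pats)
  expect_identical(nrow(tidy(ev)), 110L)
  expect_named(glance(ev), c("n", "fidelity_mean", "ssim_mean"))
})
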