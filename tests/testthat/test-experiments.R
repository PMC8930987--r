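# Scripted studies at reduced sizes: fiber-length ablation ordering,
# frame-rate analysis, robustness with joint training, bar-target
# resolution, classification, and study reproducibility.

test_that("fidelity plateaus at long fiber lengths and drops at 100 m", {
  res <- length_ablation_small()
  tb <- res$table
  f <- function(L) tb$fidelity_mean[tb$length_m == L]
  expect_lte(f(1000) - f(400), 0.05)
  expect_lt(f(100), f(400))
})

test_that("length-ablation tables reproduce exactly under a fixed seed", {
  res <- length_ablation_small()
  res2 <- run_length_ablation(lengths_m = c(100, 400, 1000), n_train = 500,
                              n_test = 120, seed = 3, basis = paper_basis(),
                              config = decoder_config("linear",
                                                      ridge_lambda = 0.1))
  expect_identical(res$table$fidelity_mean, res2$table$fidelity_mean)
  expect_identical(res$config_hash, res2$config_hash)
})

test_that("frame-rate analysis reports spans, rates and overlap", {
  res <- run_frame_rate_analysis(lengths_m = c(500, 1000), period_ns = 65,
                                 basis = paper_basis())
  tb <- res$table
  expect_identical(nrow(tb), 2L)
  # the 1 km configuration fits in the 65 ns period
  expect_false(tb$overlap_at_period[tb$length_m == 1000])
  # doubling the length halves the maximum frame rate (within 1%)
  r500 <- tb$max_frame_rate_mhz[tb$length_m == 500]
  r1000 <- tb$max_frame_rate_mhz[tb$length_m == 1000]
  expect_equal(r500 / r1000, 2, tolerance = 0.01)
  expect_equal(tb$max_frame_rate_mhz,
               max_frame_rate(tb$frame_span_ns), tolerance = 1e-9)
})

test_that("perturbation degrades fidelity and joint training widens tolerance", {
  res <- robustness_small()
  tb <- res$table
  single <- tb[tb$scheme == "single", ]
  single <- single[order(single$strength), ]
  # degradation is monotone up to one small inversion
  dips <- diff(single$fidelity_mean)
  expect_lte(sum(dips > 0.01), 1)
  expect_lt(single$fidelity_mean[3], single$fidelity_mean[1])
  tol <- res$tolerated
  expect_gte(tol$tolerated_strength[tol$scheme == "joint"],
             tol$tolerated_strength[tol$scheme == "single"])
})

test_that("an unperturbed test set reproduces the baseline fidelity", {
  res <- robustness_small()
  tb <- res$table
  s0 <- tb$fidelity_mean[tb$scheme == "single" & tb$strength == 0]
  # strength 0 evaluates the decoder on its own training condition
  expect_gt(s0, 0.5)
})

test_that("the noiseless linear oracle resolves the 15 um (2 px) bar group", {
  # the oracle precondition is a pattern family whose dimension stays below
  # the forward map's rank: train on the 12 bar-lane primitives whose exact
  # sum is the resolution target, then reconstruct the target itself
  basis <- paper_basis()
  geom <- scene_geometry(image_shape = c(24, 24))
  tgt <- make_resolution_target(shape = c(24, 24), pitches_px = c(4, 2))
  g <- attr(tgt, "groups")
  prims <- list()
  for (i in seq_len(nrow(g))) {
    p <- g$pitch_px[i]; bar <- max(1L, p %/% 2L)
    for (b in 0:2) {
      m <- matrix(0, 24, 24)
      if (g$orientation[i] == "vertical") {
        xs <- g$col0[i] + b * p
        m[g$row0[i]:g$row1[i], xs:(xs + bar - 1)] <- 1
      } else {
        ys <- g$row0[i] + b * p
        m[ys:(ys + bar - 1), g$col0[i]:g$col1[i]] <- 1
      }
      prims[[length(prims) + 1]] <- m
    }
  }
  expect_true(all(Reduce(`+`, prims) == tgt$intensities))
  set.seed(9)
  images <- replicate(150, {
    w <- runif(length(prims))
    img <- Reduce(`+`, Map(`*`, prims, w))
    img / max(img)
  }, simplify = FALSE)
  pats <- tibble::tibble(id = seq_along(images), label = NA, kind = "bars",
                         pixel_pitch_um = 7.56, image = images)
  ws <- simulate_waveforms(pats, basis, geom, model = "incoherent")
  model <- train_decoder(ws, pats,
                         decoder_config("linear", output_shape = c(24, 24),
                                        ridge_lambda = 1e-10))
  res <- run_resolution_test(model, tgt, basis, geom,
                             model_coupling = "incoherent")
  tb <- res$table
  # 2 px at the 7.56 um pitch is the 15.12 um feature
  expect_equal(unique(tb$pitch_um[tb$pitch_px == 2]), 15.12,
               tolerance = 1e-9)
  expect_true(all(tb$resolved[tb$pitch_px == 2]))
  coarse <- mean(tb$contrast[tb$pitch_px == 4])
  fine <- mean(tb$contrast[tb$pitch_px == 2])
  expect_gte(coarse, fine - 0.05)
  # profile extraction on the un-reconstructed target gives full contrast
  perfect <- fibertwin:::bar_group_contrast(
    tgt$intensities, attr(tgt, "groups")[1, ], dim(tgt$intensities))
  expect_equal(perfect, 1.0, tolerance = 1e-12)
})

test_that("the classification study reports seeded accuracy above chance", {
  res <- run_classification(n_classes = 4, n_train = 400, n_test = 100,
                            seed = 5, basis = paper_basis(), epochs = 10,
                            chance_baseline = TRUE)
  tb <- res$table
  acc <- tb$value[tb$metric == "accuracy"]
  chance <- tb$value[tb$metric == "chance_accuracy"]
  expect_gt(acc, 0.8)
  expect_lt(chance, 0.45)
  res2 <- run_classification(n_classes = 4, n_train = 400, n_test = 100,
                             seed = 5, basis = paper_basis(), epochs = 10)
  expect_identical(acc, res2$table$value[res2$table$metric == "accuracy"])
})

test_that("the frame-stream demo assembles a non-overlapping pulse train", {
  demo <- demo_frame_stream(basis = paper_basis(), n_frames = 2, seed = 7)
  expect_false(demo$stream$overlap)
  expect_identical(nrow(demo$patterns), 6L)
  expect_gt(length(demo$stream$stream$samples), 0)
})

test_that("study results print and plot", {
  res <- length_ablation_small()
  expect_output(print(res), "length_ablation")
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  expect_s3_class(autoplot(robustness_small()), "ggplot")
  expect_identical(tidy(res), res$table)
})
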