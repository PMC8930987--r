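# Synthetic pattern generators: determinism, binarization, class balance,
# augmentation counting, and the resolution-target construction.

test_that("glyph generation is deterministic and binary", {
  a <- make_glyphs(10, seed = 7)
  b <- make_glyphs(10, seed = 7)
  expect_identical(a$image, b$image)
  expect_identical(a$label, b$label)
  vals <- unique(unlist(lapply(a$image, unique)))
  expect_true(all(vals %in% c(0, 1)))
  c <- make_glyphs(10, seed = 8)
  expect_false(identical(a$image, c$image))
})

test_that("glyph class labels are roughly balanced", {
  g <- make_glyphs(1000, n_classes = 10, seed = 1)
  counts <- table(factor(g$label, levels = 0:9))
  expect_true(all(counts >= 80))
  expect_true(all(counts <= 120))
})

test_that("glyph generation validates its arguments", {
  expect_error(make_glyphs(5, shape = c(10, 10)), "16x16")
  expect_error(make_glyphs(5, n_classes = 37), "36")
})

test_that("stroke patterns count correctly with and without augmentation", {
  base <- make_random_strokes(100, seed = 3, augment = FALSE)
  expect_identical(nrow(base), 100L)
  aug <- make_random_strokes(100, seed = 3, augment = TRUE, n_variants = 3)
  expect_identical(nrow(aug), 400L)
  # augmented copies inherit the base pattern's label
  expect_identical(length(unique(aug$label)), 100L)
  expect_identical(make_random_strokes(20, seed = 5)$image,
                   make_random_strokes(20, seed = 5)$image)
})

test_that("stroke patterns have a moderate ink fraction", {
  s <- make_random_strokes(200, seed = 2)
  ink <- mean(vapply(s$image, mean, numeric(1)))
  expect_gt(ink, 0.05)
  expect_lt(ink, 0.35)
})

test_that("resolution target bars are square waves with known pitch", {
  tgt <- make_resolution_target(shape = c(40, 40), pitches_px = c(6, 4, 2),
                                pixel_pitch_um = 7.56)
  img <- tgt$intensities
  expect_true(all(img %in% c(0, 1)))
  groups <- attr(tgt, "groups")
  expect_identical(nrow(groups), 6L) # 3 pitches x 2 orientations
  # 2 px pitch at the 7.56 um micromirror pitch is a 15.12 um feature
  expect_equal(min(groups$pitch_px) * 7.56, 15.12, tolerance = 1e-12)
  # a horizontal profile across a vertical 3-bar group crosses 0.5 six times
  g <- groups[groups$orientation == "vertical" & groups$pitch_px == 4, ]
  row <- round((g$row0 + g$row1) / 2)
  prof <- img[row, (g$col0 - 1):(g$col1 + 1)]
  crossings <- sum(abs(diff(prof > 0.5)))
  expect_identical(crossings, 6L)
  expect_error(make_resolution_target(shape = c(40, 40),
                                      pitches_px = c(12, 10, 8, 6, 4)),
               "overflow")
  expect_error(make_resolution_target(pitches_px = c(1)), "2 px")
})

test_that("grayscale patterns are continuous, normalized and deterministic", {
  g <- make_grayscale(5, seed = 9)
  for (im in g$image) {
    expect_gte(min(im), 0)
    expect_equal(max(im), 1, tolerance = 1e-12)
    expect_gte(length(unique(as.vector(im))), 10)
  }
  expect_identical(g$image, make_grayscale(5, seed = 9)$image)
})

test_that("bilinear resize preserves constants and overall mass roughly", {
  im <- matrix(runif(28 * 28), 28, 28)
  up <- resize_bilinear(im, c(64, 64))
  expect_identical(dim(up), c(64L, 64L))
  expect_equal(mean(up), mean(im), tolerance = 0.02)
  expect_equal(resize_bilinear(matrix(0.37, 5, 5), c(16, 16)),
               matrix(0.37, 16, 16), tolerance = 1e-12)
})
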