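# LP-mode solver: V-number arithmetic, root finding against an independent
# scan oracle, waveguide invariants, and group-delay physics.

test_that("v_number matches closed-form evaluation", {
  expect_equal(v_number(paper_fiber()), 2 * pi * 25 * 0.22 / 1.064,
               tolerance = 1e-12)
  expect_equal(v_number(paper_fiber()), 32.48, tolerance = 1e-4)
  # long-wavelength limit
  expect_lt(v_number(fiber_spec(25, 0.22, 1000, 1e9)), 1e-3)
  # small-core, low-NA fiber sits below the single-mode cutoff 2.405
  v_sm <- v_number(fiber_spec(2.5, 0.10, 1000, 1064))
  expect_equal(v_sm, 1.476, tolerance = 1e-3)
  expect_lt(v_sm, 2.405)
})

test_that("fiber_spec rejects unphysical parameters", {
  expect_error(fiber_spec(-1, 0.22, 1000, 1064), "core_radius_um")
  expect_error(fiber_spec(25, 0, 1000, 1064), "na")
  expect_error(fiber_spec(25, 1.6, 1000, 1064), "na")
  expect_error(fiber_spec(25, 0.22, 0, 1064), "length_m")
  expect_gt(fiber_spec(25, 0.22, 1, 1064)$n_core, 1.4496)
})

test_that("a fiber below the first LP(1,1) cutoff guides exactly one mode", {
  # choose the wavelength so that V = 2.0 < 2.405
  lam <- 2 * pi * 25 * 0.22 / 2.0 * 1000
  basis <- find_lp_modes(fiber_spec(25, 0.22, 1000, lam), grid_size = 32)
  expect_identical(nrow(basis$modes), 1L)
  expect_identical(basis$modes$l, 0L)
  expect_identical(basis$modes$m, 1L)
})

test_that("mode counts agree with the independent sign-change oracle", {
  for (V in c(2, 5, 10, 32.48)) {
    lam <- 2 * pi * 25 * 0.22 / V * 1000
    basis <- find_lp_modes(fiber_spec(25, 0.22, 1000, lam), grid_size = 32)
    n_lm <- nrow(unique(basis$modes[, c("l", "m")]))
    expect_identical(n_lm, as.integer(oracle_mode_count(v_number(
      fiber_spec(25, 0.22, 1000, lam)))))
  }
})

test_that("spatial mode count of the reference fiber is near V^2/4", {
  basis <- paper_basis()
  v <- basis$v_number
  expect_gt(nrow(basis$modes), 0.8 * v^2 / 4)
  expect_lt(nrow(basis$modes), 1.2 * v^2 / 4)
  expect_true(any(basis$modes$l == 0 & basis$modes$m == 1))
})

test_that("solved modes satisfy the waveguide invariants", {
  for (basis in list(tiny_basis(), paper_basis())) {
    v <- basis$v_number
    expect_lt(max(abs(basis$modes$u^2 + basis$modes$w^2 - v^2)) / v^2, 1e-9)
    k <- 2 * pi / (basis$fiber$wavelength_nm * 1e-9)
    expect_true(all(basis$modes$beta_rad_per_m > k * basis$fiber$n_clad))
    expect_true(all(basis$modes$beta_rad_per_m < k * basis$fiber$n_core))
    # per-metre group delays within the slab bounds
    c0 <- 299792458
    delta <- (basis$fiber$n_core - basis$fiber$n_clad) / basis$fiber$n_core
    expect_true(all(basis$modes$delay_ps_per_m >=
                      basis$fiber$n_clad / c0 * 1e12))
    expect_true(all(basis$modes$delay_ps_per_m <=
                      basis$fiber$n_core * (1 + delta) / c0 * 1e12))
  }
})

test_that("mode fields are orthonormal on the grid", {
  basis <- tiny_basis()
  gram <- tcrossprod(basis$fields)
  expect_lt(max(abs(gram - diag(nrow(gram)))), 1e-3)
})

test_that("fundamental-mode transit time matches n_core L / c", {
  basis <- paper_basis()
  gd <- group_delays(basis)
  lp01 <- gd[gd$l == 0 & gd$m == 1, ]
  # 1.4662 / c * 1 km = 4.891 us under the constant-index assumption
  expect_equal(lp01$delay_ps / 1e6, 4.891, tolerance = 0.01)
})

test_that("intermodal delay spread lies between the observed span and the ray bound", {
  basis <- paper_basis()
  spread_km <- delay_spread_ns(basis, 1000)
  c0 <- 299792458
  ray_bound_ns <- 1000 * basis$fiber$na^2 /
    (2 * basis$fiber$n_core * c0) * 1e9
  expect_gt(spread_km, 40)
  expect_gte(spread_km, 45)      # covers the observed 45 ns waveform span
  expect_lte(spread_km, ray_bound_ns)
  expect_lt(spread_km, 56)
})

test_that("delay spread is exactly linear in fiber length", {
  basis <- tiny_basis()
  expect_equal(delay_spread_ns(basis, 400), 0.4 * delay_spread_ns(basis, 1000),
               tolerance = 1e-12)
})

test_that("delay spread grows with numerical aperture and respects the ray bound", {
  c0 <- 299792458
  spreads <- vapply(c(0.12, 0.22, 0.30), function(na) {
    fib <- fiber_spec(25, na, 1000, 1064)
    basis <- find_lp_modes(fib, grid_size = 32)
    s <- delay_spread_ns(basis)
    bound <- 1000 * na^2 / (2 * fib$n_core * c0) * 1e9
    expect_lte(s, bound)
    s
  }, numeric(1))
  expect_true(all(diff(spreads) > 0))
})

test_that("intermodal dispersion dominates chromatic dispersion for the instrument", {
  basis <- paper_basis()
  rep <- dispersion_dominance_check(basis$fiber, pulse_fwhm_ps = 45.1,
                                    bandwidth_nm = 0.14,
                                    chrom_disp_ps_nm_km = -25,
                                    basis = basis)
  expect_equal(rep$chromatic_broadening_ps, 25 * 0.14 * 1, tolerance = 1e-12)
  expect_true(rep$dominant)
  expect_gt(rep$intermodal_spread_ns * 1000, 100 * rep$chromatic_broadening_ps)
  # zero source bandwidth: no chromatic broadening, still dominant
  rep0 <- dispersion_dominance_check(basis$fiber, 45.1, 0, -25, basis = basis)
  expect_identical(rep0$chromatic_broadening_ps, 0)
  expect_true(rep0$dominant)
})

test_that("mode table round-trips through CSV", {
  basis <- tiny_basis()
  path <- withr::local_tempfile(fileext = ".csv")
  write_mode_table(basis, path)
  tab <- read_mode_table(path)
  expect_identical(nrow(tab), nrow(basis$modes))
  expect_equal(tab$u, basis$modes$u, tolerance = 1e-12)
  expect_equal(tab$delay_ps_per_m, basis$modes$delay_ps_per_m,
               tolerance = 1e-12)
})

test_that("an excitation cap keeps the fastest modes only", {
  basis <- find_lp_modes(tiny_fiber(), grid_size = 32, max_modes = 5)
  expect_identical(nrow(basis$modes), 5L)
  expect_identical(nrow(basis$fields), 5L)
})
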