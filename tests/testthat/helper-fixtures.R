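# Shared fixtures, built once per test run and cached. The "tiny" fiber
# (V ~ 7) keeps most tests fast; the reference fiber (V ~ 32.5) is solved
# once and shared by the physics and acceptance tests.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

tiny_fiber <- function(length_m = 1000) {
  fiber_spec(core_radius_um = 8, na = 0.15, length_m = length_m,
             wavelength_nm = 1064)
}

tiny_basis <- function() {
  cached("tiny_basis", find_lp_modes(tiny_fiber(), grid_size = 64))
}

# reference fiber of the simulated instrument: 50 um core, NA 0.22, 1 km,
# 1064 nm
paper_fiber <- function(length_m = 1000) {
  fiber_spec(core_radius_um = 25, na = 0.22, length_m = length_m,
             wavelength_nm = 1064)
}

paper_basis <- function() {
  cached("paper_basis", find_lp_modes(paper_fiber(), grid_size = 128))
}

# medium-V fiber with more distinct-delay mode groups (the waveform's
# information content) than an 8x8 pattern has pixels; used by the
# pseudoinverse-recovery oracle tests
medium_basis <- function() {
  cached("medium_basis",
         find_lp_modes(fiber_spec(18, 0.22, 1000, 1064), grid_size = 64))
}

# Independent root-count oracle: sign-change scan of the ratio form of the
# characteristic equation u J_{l-1}(u)/J_l(u) + w K_{l-1}(w)/K_l(w) on a
# fine uniform grid, discarding sign changes across poles (zeros of J_l).
# Counts (l, m) pairs; orientation degeneracy is not counted.
oracle_mode_count <- function(V, n_grid = 20000) {
  count <- 0
  l <- 0
  repeat {
    us <- seq(V * 1e-6, V * (1 - 1e-9), length.out = n_grid)
    w <- sqrt(pmax(V^2 - us^2, 0))
    jl <- besselJ(us, l)
    f <- us * besselJ(us, l - 1) / jl +
      w * besselK(w, abs(l - 1), expon.scaled = TRUE) /
        besselK(w, l, expon.scaled = TRUE)
    sgn <- sign(f)
    flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    # a sign change bracketing a zero of J_l is a pole, not a root
    pole <- vapply(flips, function(i) {
      sign(jl[i]) * sign(jl[i + 1]) < 0
    }, logical(1))
    n_l <- sum(!pole)
    if (n_l == 0 && l > 0) break
    count <- count + n_l
    l <- l + 1
  }
  count
}

expect_deterministic <- function(expr1, expr2) {
  expect_identical(force(expr1), force(expr2))
}
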