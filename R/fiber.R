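# LP-mode solver for a step-index multimode fiber under the weakly-guiding
# (scalar) approximation. One polarization is modeled; degenerate cos/sin
# orientations of l > 0 modes carry identical propagation constants and delays.

SPEED_OF_LIGHT <- 299792458 # m/s

#' Describe a step-index multimode fiber
#'
#' The fiber is specified the way datasheets specify it: core radius,
#' numerical aperture, length and operating wavelength. The cladding index
#' must be supplied (datasheets rarely give it); the core index follows from
#' `n_core = sqrt(n_clad^2 + NA^2)`.
#'
#' @param core_radius_um Core radius in micrometres.
#' @param na Numerical aperture (dimensionless, `0 < na < n_clad`).
#' @param length_m Fiber length in metres.
#' @param wavelength_nm Vacuum wavelength in nanometres.
#' @param n_clad Cladding refractive index. Defaults to 1.4496, fused silica
#'   near 1064 nm; both indices are held constant across wavelength
#'   perturbations (no material dispersion).
#'
#' @return An object of class `fiber_spec`.
#' @examples
#' fib <- fiber_spec(core_radius_um = 25, na = 0.22,
#'                   length_m = 1000, wavelength_nm = 1064)
#' v_number(fib)
#' @export
fiber_spec <- function(core_radius_um, na, length_m, wavelength_nm,
                       n_clad = 1.4496) {
  stopifnot(is.numeric(core_radius_um), is.numeric(na), is.numeric(length_m),
            is.numeric(wavelength_nm), is.numeric(n_clad))
  if (core_radius_um <= 0) stop("core_radius_um must be positive")
  if (length_m <= 0) stop("length_m must be positive")
  if (wavelength_nm <= 0) stop("wavelength_nm must be positive")
  if (na <= 0 || na >= n_clad) stop("na must satisfy 0 < na < n_clad")
  structure(
    list(core_radius_um = core_radius_um, na = na, length_m = length_m,
         wavelength_nm = wavelength_nm, n_clad = n_clad,
         n_core = sqrt(n_clad^2 + na^2)),
    class = "fiber_spec")
}

#' @export
print.fiber_spec <- function(x, ...) {
  cat(sprintf(
    "<fiber_spec> a = %g um, NA = %g, L = %g m, lambda = %g nm\n",
    x$core_radius_um, x$na, x$length_m, x$wavelength_nm))
  cat(sprintf("  n_core = %.5f, n_clad = %.5f, V = %.3f\n",
              x$n_core, x$n_clad, v_number(x)))
  invisible(x)
}

#' Normalized frequency (V-number) of a step-index fiber
#'
#' `V = 2 pi a NA / lambda`. A step-index fiber guides a single spatial mode
#' when `V < 2.405` (the first zero of the order-0 Bessel function) and of
#' order `V^2 / 4` spatial modes per polarization when `V` is large.
#'
#' @param fiber A [fiber_spec()].
#' @return The dimensionless V-number.
#' @export
v_number <- function(fiber) {
  stopifnot(inherits(fiber, "fiber_spec"))
  2 * pi * fiber$core_radius_um * fiber$na / (fiber$wavelength_nm * 1e-3)
}

# Pole-free form of the weakly-guiding characteristic equation
#   u J_{l-1}(u) / J_l(u) = -w K_{l-1}(w) / K_l(w),  w = sqrt(V^2 - u^2),
# rewritten as g(u) = u J_{l-1}(u) K_l(w) + w K_{l-1}(w) J_l(u) = 0.
# Exponentially scaled K avoids overflow; the common factor exp(w) > 0 does
# not move the roots.
lp_char_fun <- function(u, l, V) {
  w <- sqrt(pmax(V^2 - u^2, 0))
  jm1 <- besselJ(u, l - 1)
  jl <- besselJ(u, l)
  km1 <- besselK(w, abs(l - 1), expon.scaled = TRUE)
  kl <- besselK(w, l, expon.scaled = TRUE)
  u * jm1 * kl + w * km1 * jl
}

# Bracket sign changes of g on a uniform u grid and refine by bisection.
lp_roots_for_l <- function(l, V, n_grid = 4000, tol = 1e-12) {
  if (V <= 0) return(numeric(0))
  us <- seq(V / n_grid * 1e-3, V * (1 - 1e-9), length.out = n_grid)
  g <- lp_char_fun(us, l, V)
  bad <- !is.finite(g)
  if (any(bad)) g[bad] <- 0 # treated as no sign information
  idx <- which(g[-1] * g[-length(g)] < 0)
  vapply(idx, function(i) {
    lo <- us[i]; hi <- us[i + 1]
    glo <- lp_char_fun(lo, l, V)
    for (it in seq_len(200)) {
      mid <- (lo + hi) / 2
      gm <- lp_char_fun(mid, l, V)
      if (!is.finite(gm)) {
        stop(sprintf(
          "LP root refinement failed for l = %d in bracket [%g, %g]",
          l, lo, hi))
      }
      if (gm * glo <= 0) hi <- mid else { lo <- mid; glo <- gm }
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }, numeric(1))
}

# All guided (l, m) roots at normalized frequency V: list keyed by l of
# ascending u values (m = index within the vector). LP(l,1) cutoffs grow
# monotonically with l, so the scan stops at the first empty azimuthal order.
lp_all_roots <- function(V, n_grid = 4000) {
  out <- list()
  l <- 0
  repeat {
    r <- lp_roots_for_l(l, V, n_grid)
    if (length(r) == 0 && l > 0) break
    if (length(r) > 0) out[[as.character(l)]] <- r
    l <- l + 1
  }
  out
}

beta_from_u <- function(u, fiber, wavelength_nm = fiber$wavelength_nm) {
  k <- 2 * pi / (wavelength_nm * 1e-9)
  a <- fiber$core_radius_um * 1e-6
  sqrt((k * fiber$n_core)^2 - (u / a)^2)
}

# Group delay per metre (ps/m) of each root of one azimuthal order, by a
# centred finite difference of beta over wavelength (relative step `rel_step`),
# re-solving the characteristic equation at each perturbed wavelength with the
# indices held constant. Near-cutoff modes that vanish at the shorter
# perturbed wavelength fall back to a one-sided difference.
lp_group_delay_l <- function(l, u0, fiber, rel_step = 1e-4, n_grid = 4000) {
  lam <- fiber$wavelength_nm
  lam_p <- lam * (1 + rel_step)
  lam_m <- lam * (1 - rel_step)
  v_of <- function(w_nm) 2 * pi * fiber$core_radius_um * fiber$na / (w_nm * 1e-3)
  up <- lp_roots_for_l(l, v_of(lam_p), n_grid) # V larger: all modes persist
  um <- lp_roots_for_l(l, v_of(lam_m), n_grid) # V smaller: cutoffs may drop
  om <- function(w_nm) 2 * pi * SPEED_OF_LIGHT / (w_nm * 1e-9)
  vapply(seq_along(u0), function(m) {
    b0 <- beta_from_u(u0[m], fiber, lam)
    bp <- if (m <= length(up)) beta_from_u(up[m], fiber, lam_p) else NA_real_
    bm <- if (m <= length(um)) beta_from_u(um[m], fiber, lam_m) else NA_real_
    tau <- if (!is.na(bp) && !is.na(bm)) {
      (bp - bm) / (om(lam_p) - om(lam_m))
    } else if (!is.na(bp)) {
      warning(sprintf(
        "LP(%d,%d) lost at perturbed wavelength; one-sided difference used",
        l, m))
      (bp - b0) / (om(lam_p) - om(lam))
    } else {
      stop(sprintf("LP(%d,%d): root not recovered at perturbed wavelengths",
                   l, m))
    }
    tau * 1e12 # s/m -> ps/m
  }, numeric(1))
}

# Sample the analytic transverse field of LP(l, m) on grid points given in
# polar coordinates (r in um, phi in rad). Continuity at r = a is built in.
lp_field_samples <- function(l, u, w, orientation, r_um, phi, a_um) {
  rr <- r_um / a_um
  inside <- rr <= 1
  rad <- numeric(length(rr))
  rad[inside] <- besselJ(u * rr[inside], l) / besselJ(u, l)
  rad[!inside] <- besselK(w * rr[!inside], l) / besselK(w, l)
  az <- if (l == 0) 1 else if (orientation == "even") cos(l * phi) else sin(l * phi)
  rad * az
}

#' Solve the guided LP modes of a step-index fiber
#'
#' Finds every guided `LP(l, m)` solution of the weakly-guiding characteristic
#' equation `u J_(l-1)(u)/J_l(u) = -w K_(l-1)(w)/K_l(w)` with
#' `w = sqrt(V^2 - u^2)`, enumerating both cos/sin orientations for `l > 0`.
#' Roots are bracketed by a sign-change scan of the pole-free form of the
#' equation on a uniform grid of `n_grid` points per azimuthal order and
#' refined by bisection to 1e-12. Per-mode group delays (ps/m) come from a
#' centred finite difference of the propagation constant over wavelength
#' (relative step 1e-4, indices held constant). Transverse fields are sampled
#' as analytic `J_l`/`K_l` profiles on a square grid spanning
#' `grid_span_factor` times the core diameter and then discretely
#' orthonormalized (symmetric orthogonalization), so the discrete inner
#' product of a mode with itself is exactly 1 and cross-products vanish.
#'
#' @param fiber A [fiber_spec()].
#' @param grid_size Side length of the square field grid (default 128,
#'   minimum 32).
#' @param grid_span_factor Grid span as a multiple of the core diameter.
#' @param n_grid Number of scan points per azimuthal order for root
#'   bracketing.
#' @param max_modes Optional cap on the number of spatial modes retained
#'   (ascending group delay); emulates an experiment that excites only a
#'   subset of the guided modes. `Inf` keeps all.
#' @param orientation_split_ps_km Standard deviation (ps per km) of the
#'   seeded zero-mean Gaussian group-delay splitting between the cos/sin
#'   orientations of each `l > 0` mode pair. Ideally degenerate orientations
#'   share one arrival time, which makes an intensity detector blind to the
#'   azimuthal content of the scene (their powers only ever appear summed,
#'   and `cos^2 + sin^2 = 1`); in real kilometre-scale fibers core
#'   noncircularity and stress split the pair by tens of ps/km, which is
#'   what lets the waveform carry 2D information. Default 40; set 0 for the
#'   ideal fully degenerate fiber.
#' @param split_seed Seed for the orientation splitting draws.
#'
#' @return An object of class `mode_basis`: a list with `fiber`, `v_number`,
#'   `modes` (a tibble with columns `l`, `m`, `orientation`, `u`, `w`,
#'   `beta_rad_per_m`, `delay_ps_per_m`, sorted by ascending group delay),
#'   `fields` (matrix, one row per mode, orthonormal on the grid), and the
#'   grid coordinates `grid_x_um`, `grid_y_um`.
#' @examples
#' fib <- fiber_spec(25, 0.22, 1000, 1064)
#' basis <- find_lp_modes(fib, grid_size = 64)
#' nrow(basis$modes)
#' @export
find_lp_modes <- function(fiber, grid_size = 128, grid_span_factor = 1.5,
                          n_grid = 4000, max_modes = Inf,
                          orientation_split_ps_km = 40, split_seed = 1) {
  stopifnot(inherits(fiber, "fiber_spec"))
  if (grid_size < 32) stop("grid_size must be at least 32")
  V <- v_number(fiber)
  roots <- lp_all_roots(V, n_grid)
  if (length(roots) == 0) {
    stop("no guided modes found; V may be degenerate (V = ", format(V), ")")
  }

  rows <- list()
  for (lch in names(roots)) {
    l <- as.integer(lch)
    u0 <- roots[[lch]]
    tau <- lp_group_delay_l(l, u0, fiber, n_grid = n_grid)
    for (m in seq_along(u0)) {
      ors <- if (l == 0) "even" else c("even", "odd")
      for (orient in ors) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          l = l, m = m, orientation = orient,
          u = u0[m], w = sqrt(max(V^2 - u0[m]^2, 0)),
          beta_rad_per_m = beta_from_u(u0[m], fiber),
          delay_ps_per_m = tau[m])
      }
    }
  }
  modes <- dplyr::bind_rows(rows)
  if (orientation_split_ps_km > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(split_seed)
    pairs <- unique(modes[modes$l > 0, c("l", "m")])
    if (nrow(pairs) > 0) {
      split <- stats::rnorm(nrow(pairs), 0, orientation_split_ps_km / 1000)
      for (i in seq_len(nrow(pairs))) {
        sel <- modes$l == pairs$l[i] & modes$m == pairs$m[i]
        sgn <- ifelse(modes$orientation[sel] == "even", 0.5, -0.5)
        modes$delay_ps_per_m[sel] <- modes$delay_ps_per_m[sel] +
          sgn * split[i]
      }
    }
  }
  modes <- dplyr::arrange(modes, .data$delay_ps_per_m,
                          .data$l, .data$m, .data$orientation)
  if (is.finite(max_modes) && nrow(modes) > max_modes) {
    modes <- modes[seq_len(max_modes), ]
  }

  a <- fiber$core_radius_um
  half <- grid_span_factor * a
  xs <- seq(-half, half, length.out = grid_size)
  gx <- matrix(xs, grid_size, grid_size)        # x varies along rows index
  gy <- matrix(xs, grid_size, grid_size, byrow = TRUE)
  r <- sqrt(gx^2 + gy^2)
  phi <- atan2(gy, gx)

  fields <- matrix(0, nrow(modes), grid_size^2)
  for (i in seq_len(nrow(modes))) {
    f <- lp_field_samples(modes$l[i], modes$u[i], modes$w[i],
                          modes$orientation[i], r, phi, a)
    fields[i, ] <- as.vector(f)
  }
  fields <- fields / sqrt(rowSums(fields^2))
  # symmetric (S^{-1/2}) orthonormalization of the sampled analytic fields
  s <- tcrossprod(fields)
  es <- eigen(s, symmetric = TRUE)
  s_inv_sqrt <- es$vectors %*% (t(es$vectors) / sqrt(pmax(es$values, 1e-12)))
  fields <- s_inv_sqrt %*% fields

  structure(
    list(fiber = fiber, v_number = V, modes = modes, fields = fields,
         grid_x_um = xs, grid_y_um = xs, grid_size = grid_size),
    class = "mode_basis")
}

#' @export
print.mode_basis <- function(x, ...) {
  cat(sprintf(
    "<mode_basis> V = %.3f, %d spatial modes (max l = %d), grid %dx%d\n",
    x$v_number, nrow(x$modes), max(x$modes$l), x$grid_size, x$grid_size))
  cat(sprintf("  delay spread: %.3f ns over %g m\n",
              diff(range(x$modes$delay_ps_per_m)) * x$fiber$length_m / 1000,
              x$fiber$length_m))
  invisible(x)
}

#' Per-mode group delays over the fiber length
#'
#' Multiplies each mode's group delay per metre by the fiber length, so delays
#' are exactly linear in length by construction.
#'
#' @param basis A [find_lp_modes()] result.
#' @param length_m Fiber length in metres; defaults to the basis fiber length.
#' @return A tibble with the mode identity columns plus `delay_ps`, sorted
#'   ascending by delay.
#' @examples
#' fib <- fiber_spec(25, 0.22, 1000, 1064)
#' basis <- find_lp_modes(fib, grid_size = 64)
#' rng <- range(group_delays(basis)$delay_ps)
#' (rng[2] - rng[1]) / 1000 # intermodal spread in ns
#' @export
group_delays <- function(basis, length_m = NULL) {
  stopifnot(inherits(basis, "mode_basis"))
  if (is.null(length_m)) length_m <- basis$fiber$length_m
  stopifnot(length_m > 0)
  dplyr::arrange(
    dplyr::mutate(basis$modes, delay_ps = .data$delay_ps_per_m * length_m),
    .data$delay_ps)
}

#' Intermodal delay spread in nanoseconds
#'
#' @param basis A [find_lp_modes()] result.
#' @param length_m Fiber length in metres; defaults to the basis fiber length.
#' @return Max minus min group delay, in ns.
#' @export
delay_spread_ns <- function(basis, length_m = NULL) {
  d <- group_delays(basis, length_m)$delay_ps
  diff(range(d)) / 1000
}

#' Check that intermodal dispersion dominates chromatic dispersion
#'
#' Temporal encoding relies on the pulse splitting into per-mode sub-pulses,
#' which requires the intermodal delay spread to dwarf chromatic broadening.
#' Chromatic broadening is `|D| * delta_lambda * L`; the system is declared
#' intermodal-dominated when the intermodal spread exceeds
#' `dominance_factor` times the chromatic broadening (and is itself nonzero).
#'
#' @param fiber A [fiber_spec()].
#' @param pulse_fwhm_ps Pulse duration FWHM in ps.
#' @param bandwidth_nm Source spectral width in nm.
#' @param chrom_disp_ps_nm_km Chromatic dispersion parameter D in ps/(nm km).
#' @param basis Optional precomputed [find_lp_modes()] basis (saves re-solving).
#' @param dominance_factor Required ratio of intermodal spread to chromatic
#'   broadening (default 100).
#' @return A tibble with one row: `intermodal_spread_ns`,
#'   `chromatic_broadening_ps`, `dominant`.
#' @export
dispersion_dominance_check <- function(fiber, pulse_fwhm_ps, bandwidth_nm,
                                       chrom_disp_ps_nm_km, basis = NULL,
                                       dominance_factor = 100) {
  stopifnot(inherits(fiber, "fiber_spec"))
  if (pulse_fwhm_ps <= 0) stop("pulse_fwhm_ps must be positive")
  if (bandwidth_nm < 0) stop("bandwidth_nm must be nonnegative")
  if (is.null(basis)) basis <- find_lp_modes(fiber, grid_size = 32)
  spread_ns <- delay_spread_ns(basis, fiber$length_m)
  chrom_ps <- abs(chrom_disp_ps_nm_km) * bandwidth_nm * fiber$length_m / 1000
  dominant <- spread_ns > 0 &&
    (spread_ns * 1000) > dominance_factor * chrom_ps
  tibble::tibble(intermodal_spread_ns = spread_ns,
                 chromatic_broadening_ps = chrom_ps,
                 dominant = dominant)
}

#' Export / import the mode table as CSV
#'
#' Columns: `l, m, orientation, u, w, beta_rad_per_m, delay_ps_per_m`.
#'
#' @param basis A [find_lp_modes()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); a tibble (reader).
#' @export
write_mode_table <- function(basis, path) {
  stopifnot(inherits(basis, "mode_basis"))
  utils::write.csv(basis$modes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mode_table
#' @export
read_mode_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
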