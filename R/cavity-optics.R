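# Closed-form optics of the low-finesse elastic microcavity.
#
# All thicknesses and wavelengths are in nanometres; intensities are in
# arbitrary camera units; reflectances are fractions of incident intensity.

#' Describe an elastic optical microcavity
#'
#' A microcavity chip is a thin elastomer layer (refractive index `n`, rest
#' thickness `d0`) between two semi-transparent mirrors. Cells cultured on the
#' top mirror deform it, which shifts the cavity resonances and modulates the
#' reflected intensity. The reflected signal is modelled as an offset cosine
#' with background `B` and amplitude `A` (two-beam limit), or with the full
#' two-mirror resonator lineshape using the mirror reflectances `R1` (bottom)
#' and `R2` (top).
#'
#' `A` and `B` may be scalars or per-pixel matrices (to model illumination
#' inhomogeneity); they are taken as wavelength-independent within one
#' wavelength pair, which holds to good approximation within one free
#' spectral range of the cavity.
#'
#' The default mirror reflectances are assumptions: the thin chromium/gold
#' mirrors of real chips are not characterised by a single number here, and
#' only the low-finesse behaviour matters for the method.
#'
#' @param n Refractive index of the cavity medium (dimensionless, > 1).
#' @param d0 Rest cavity thickness in nm.
#' @param R1,R2 Bottom and top mirror intensity reflectances, each in `[0, 1)`.
#' @param A Fringe amplitude (a.u.), scalar or matrix; `A >= 0`.
#' @param B Background offset (a.u.), scalar or matrix; `B >= A` everywhere so
#'   that the modelled intensity is never negative.
#' @return An object of class `cavity_spec`.
#' @examples
#' cav <- cavity_spec()
#' reflectance_two_beam(cav, d = 8000, lambda = 633)
#' @export
cavity_spec <- function(n = 1.40, d0 = 8000, R1 = 0.30, R2 = 0.25,
                        A = 40, B = 100) {
  stopifnot(is.numeric(n), length(n) == 1L, n > 1,
            is.numeric(d0), length(d0) == 1L, d0 > 0)
  if (!is.numeric(R1) || length(R1) != 1L || R1 < 0 || R1 >= 1)
    stop("'R1' must be a single reflectance in [0, 1)")
  if (!is.numeric(R2) || length(R2) != 1L || R2 < 0 || R2 >= 1)
    stop("'R2' must be a single reflectance in [0, 1)")
  if (any(A < 0)) stop("'A' must be non-negative everywhere")
  if (is.matrix(A) || is.matrix(B)) {
    if (is.matrix(A) && is.matrix(B) && !identical(dim(A), dim(B)))
      stop("matrix 'A' and 'B' must share dimensions")
  }
  if (any(B - A < 0)) stop("'B' must be >= 'A' everywhere (intensity >= 0)")
  structure(list(n = n, d0 = d0, R1 = R1, R2 = R2, A = A, B = B),
            class = "cavity_spec")
}

#' @export
print.cavity_spec <- function(x, ...) {
  cat("Elastic microcavity\n")
  cat(sprintf("  n = %.3f, rest thickness d0 = %g nm\n", x$n, x$d0))
  cat(sprintf("  mirror reflectances R1 = %.3f, R2 = %.3f\n", x$R1, x$R2))
  fmt <- function(v) if (is.matrix(v))
    sprintf("%dx%d field (mean %.3g)", nrow(v), ncol(v), mean(v))
  else sprintf("%g", v)
  cat(sprintf("  fringe amplitude A = %s, background B = %s (a.u.)\n",
              fmt(x$A), fmt(x$B)))
  invisible(x)
}

#' Define a dual-wavelength illumination pair
#'
#' The two illumination wavelengths must lie within one free spectral range of
#' the cavity so that the interference patterns they produce stay in register
#' (no mode ambiguity between them).
#'
#' @param lambda1,lambda2 Illumination wavelengths in nm, `lambda1 < lambda2`.
#' @return An object of class `wavelength_pair`.
#' @examples
#' wavelength_pair(628, 633)
#' @export
wavelength_pair <- function(lambda1, lambda2) {
  stopifnot(is.numeric(lambda1), is.numeric(lambda2),
            length(lambda1) == 1L, length(lambda2) == 1L,
            lambda1 > 0, lambda2 > 0)
  if (lambda1 >= lambda2) stop("'lambda1' must be smaller than 'lambda2'")
  structure(list(lambda1 = lambda1, lambda2 = lambda2),
            class = "wavelength_pair")
}

#' @export
print.wavelength_pair <- function(x, ...) {
  cat(sprintf("Wavelength pair: %g / %g nm\n", x$lambda1, x$lambda2))
  cat(sprintf("  mode spacing at n = 1.40: %.1f nm\n",
              fringe_mode_spacing(x, 1.40)))
  invisible(x)
}

# round-trip / half-round-trip phase helpers
phi_fast <- function(d, pair, n) {
  2 * pi * n * (pair$lambda1 + pair$lambda2) * d / (pair$lambda1 * pair$lambda2)
}
phi_slow <- function(d, pair, n) {
  2 * pi * n * (pair$lambda2 - pair$lambda1) * d / (pair$lambda1 * pair$lambda2)
}

#' Two-beam reflected intensity of the cavity
#'
#' Low-finesse (two-beam) approximation of the reflected intensity:
#' `I = B + A * cos(4 * pi * n * d / lambda)`. Periodic in thickness `d` with
#' period `lambda / (2 n)`.
#'
#' @param cavity A [cavity_spec()].
#' @param d Cavity thickness in nm (vector or matrix; matrices must match any
#'   per-pixel `A`/`B` fields of the cavity).
#' @param lambda Illumination wavelength in nm (scalar).
#' @return Reflected intensity in the same shape as `d` (a.u.).
#' @export
reflectance_two_beam <- function(cavity, d, lambda) {
  stopifnot(inherits(cavity, "cavity_spec"))
  if (any(d <= 0)) stop("'d' must be positive")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("'lambda' must be a single positive wavelength")
  cavity$B + cavity$A * cos(4 * pi * cavity$n * d / lambda)
}

#' Fabry-Perot reflected intensity fraction
#'
#' Reflected-intensity fraction of a lossless two-mirror resonator with
#' amplitude reflectances `sqrt(R1)`, `sqrt(R2)` and round-trip phase
#' `delta = 4 pi n d / lambda`:
#' \deqn{R(\delta) = \frac{R_1 + R_2 - 2\sqrt{R_1 R_2}\cos\delta}
#'                        {1 + R_1 R_2 - 2\sqrt{R_1 R_2}\cos\delta}.}
#' Minima (cavity resonances) occur where `2 n d = m lambda` for integer
#' mode order `m`; as `R1 * R2 -> 0` the lineshape tends to an offset cosine
#' (the two-beam limit). Mirror absorption is not modelled; absorbing metal
#' mirrors are represented by effective `R1`, `R2`.
#'
#' @inheritParams reflectance_two_beam
#' @return Reflected fraction of incident intensity, same shape as `d`.
#' @export
reflectance_fabry_perot <- function(cavity, d, lambda) {
  stopifnot(inherits(cavity, "cavity_spec"))
  if (any(d <= 0)) stop("'d' must be positive")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("'lambda' must be a single positive wavelength")
  r12 <- sqrt(cavity$R1 * cavity$R2)
  cd <- cos(4 * pi * cavity$n * d / lambda)
  (cavity$R1 + cavity$R2 - 2 * r12 * cd) / (1 + cavity$R1 * cavity$R2 - 2 * r12 * cd)
}

#' Thickness change between adjacent fringes
#'
#' The difference of the two monochromatic images vanishes whenever the fast
#' interference phase is a multiple of pi; consecutive zeros are separated by
#' a thickness change
#' `d_mode = lambda1 * lambda2 / (2 n (lambda1 + lambda2))` -- about 113 nm
#' for 628/633 nm and about 125 nm for 695/700 nm at `n = 1.40`. Fringe
#' counting resolves displacement to within one such mode; the lookup table
#' supplies the fine displacement inside it.
#'
#' @param pair A [wavelength_pair()].
#' @param n Refractive index of the cavity medium.
#' @return Mode spacing in nm.
#' @examples
#' fringe_mode_spacing(wavelength_pair(628, 633), 1.40)
#' @export
fringe_mode_spacing <- function(pair, n) {
  stopifnot(inherits(pair, "wavelength_pair"), is.numeric(n), n > 0)
  pair$lambda1 * pair$lambda2 / (2 * n * (pair$lambda1 + pair$lambda2))
}

#' Free spectral range of the cavity
#'
#' Wavelength spacing between adjacent cavity resonances,
#' `lambda^2 / (2 n d)`; about 18 nm for `lambda = 630` nm, `n = 1.40`,
#' `d = 8` um. The two illumination wavelengths of a pair must be closer than
#' this.
#'
#' @param lambda Wavelength in nm.
#' @param n Refractive index.
#' @param d Cavity thickness in nm.
#' @return Free spectral range in nm.
#' @export
free_spectral_range <- function(lambda, n, d) {
  stopifnot(all(lambda > 0), all(n > 0), all(d > 0))
  lambda^2 / (2 * n * d)
}

#' Airy radius of the imaging objective
#'
#' First-zero radius of the diffraction pattern, `0.61 * lambda / NA`. Feature
#' footprints comparable to this radius (about 640 nm at 630 nm with NA 0.6)
#' appear enlarged by diffraction, which matters for podosome area estimates.
#'
#' @param lambda Wavelength in nm.
#' @param numerical_aperture Objective numerical aperture (0 < NA <= 1.5).
#' @return Airy radius in nm.
#' @export
airy_radius <- function(lambda, numerical_aperture) {
  stopifnot(all(lambda > 0))
  if (any(numerical_aperture <= 0) || any(numerical_aperture > 1.5))
    stop("'numerical_aperture' must be in (0, 1.5]")
  0.61 * lambda / numerical_aperture
}

#' Ideal division-image value at a given thickness
#'
#' Closed-form value of the division image for the two-beam model,
#' `-cot(phi_fast) * cot(phi_slow)` with
#' `phi_fast = 2 pi n (lambda1 + lambda2) d / (lambda1 lambda2)` and
#' `phi_slow = 2 pi n (lambda2 - lambda1) d / (lambda1 lambda2)`.
#' Unlike the raw cosine images, this quantity is asymmetric in `d` and so
#' encodes the direction of thickness changes. It is strictly monotone in `d`
#' between consecutive poles; at fringe zeros (poles of the cotangent) the
#' value is undefined and `NaN` is returned.
#'
#' @param d Thickness in nm (vectorised).
#' @param pair A [wavelength_pair()].
#' @param n Refractive index.
#' @param tol Pole tolerance: values with `|sin(phi_fast) * sin(phi_slow)|`
#'   below `tol` are flagged as `NaN`.
#' @return Dimensionless division value, `NaN` at poles.
#' @export
division_ideal <- function(d, pair, n, tol = 1e-12) {
  stopifnot(inherits(pair, "wavelength_pair"), is.numeric(n), n > 0)
  pf <- phi_fast(d, pair, n)
  ps <- phi_slow(d, pair, n)
  s <- sin(pf) * sin(ps)
  out <- -(cos(pf) * cos(ps)) / s
  out[abs(s) < tol] <- NaN
  out
}
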