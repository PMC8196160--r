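# Mechanics: displacement maps -> stresses and forces.
#
# Stress/force estimation uses the flat cylindrical punch on an elastic
# half-space, F = 2 E / (1 - nu^2) * a * delta, in place of finite-element
# stress computation; for podosome-scale indenters the two agree closely.
# Unit bookkeeping: E in Pa, contact radius a in um, depth delta in nm,
# force in pN (1 pN / um^2 = 1 Pa, so stress = force / area directly).

#' Describe the elastic substrate
#'
#' The apparent stiffness is the effective Young's modulus of the composite
#' elastomer-plus-top-mirror surface as measured by indentation (about
#' 5--14 kPa for typical chips). The default Poisson ratio 0.5 treats the
#' silicone elastomer as incompressible; this is an assumption (the ratio
#' of real chips is not characterised here) and enters only through the
#' factor `1 / (1 - nu^2)`.
#'
#' @param E Apparent Young's modulus in Pa.
#' @param nu Poisson ratio in `[0, 0.5]`.
#' @return An object of class `elastic_substrate`.
#' @export
elastic_substrate <- function(E = 5000, nu = 0.5) {
  stopifnot(is.numeric(E), E > 0, is.numeric(nu), nu >= 0, nu <= 0.5)
  structure(list(E = E, nu = nu), class = "elastic_substrate")
}

#' @export
print.elastic_substrate <- function(x, ...) {
  cat(sprintf("Elastic substrate: E = %g Pa, nu = %.2f\n", x$E, x$nu))
  invisible(x)
}

#' Spatial band-pass filter of a displacement map
#'
#' Frequency-domain band-pass retaining lateral wavelengths between
#' `low_cut` and `high_cut` (um): used to emphasise podosome-scale
#' protrusions against broad cell-wide indentation. The DC component is
#' always removed, so the output is mean-free.
#'
#' @param map A [displacement_map()] or numeric matrix.
#' @param low_cut Shortest retained wavelength (um); must exceed two pixels.
#' @param high_cut Longest retained wavelength (um).
#' @param pixel_size Pixel pitch in um (taken from the map if available).
#' @return Same type as `map`, filtered.
#' @export
bandpass_spatial <- function(map, low_cut, high_cut,
                             pixel_size = NULL) {
  is_map <- inherits(map, "displacement_map")
  v <- if (is_map) map$values else map
  if (is.null(pixel_size)) {
    if (!is_map) stop("'pixel_size' is required for a bare matrix")
    pixel_size <- map$pixel_size
  }
  stopifnot(is.matrix(v))
  if (!(high_cut > low_cut)) stop("'high_cut' must exceed 'low_cut'")
  if (low_cut <= 2 * pixel_size)
    stop("'low_cut' must exceed two pixels (", 2 * pixel_size, " um)")
  ny <- nrow(v); nx <- ncol(v)
  fy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1))[seq_len(ny)] / (ny * pixel_size)
  fx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1))[seq_len(nx)] / (nx * pixel_size)
  f <- sqrt(outer(fy^2, fx^2, `+`))
  keep <- f >= 1 / high_cut & f <= 1 / low_cut
  if (!any(keep)) stop("band retains no resolvable spatial frequency")
  V <- stats::fft(v - mean(v)) * keep
  out <- Re(stats::fft(V, inverse = TRUE)) / length(v)
  if (is_map) displacement_map(out, pixel_size, flags = map$flags) else out
}

# one step of 8-connected dilation of a logical mask
dilate8 <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  out <- mask
  out[-1, ] <- out[-1, ] | mask[-ny, ]
  out[-ny, ] <- out[-ny, ] | mask[-1, ]
  v <- out
  out[, -1] <- out[, -1] | v[, -nx]
  out[, -nx] <- out[, -nx] | v[, -1]
  out
}

# 8-connected labelling of a logical mask by iterative minimum propagation
label_components8 <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  lab[mask] <- seq_len(sum(mask))
  big <- ny * nx + 1L
  L <- matrix(big, ny, nx)
  L[mask] <- lab[mask]
  shift <- function(m, dr, dc) {
    out <- matrix(big, ny, nx)
    rs <- seq_len(ny) - dr; cs <- seq_len(nx) - dc
    ok_r <- rs >= 1 & rs <= ny; ok_c <- cs >= 1 & cs <= nx
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  repeat {
    Lnew <- L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      Lnew <- pmin(Lnew, shift(L, dr, dc))
    }
    Lnew[!mask] <- big
    if (identical(Lnew, L)) break
    L <- Lnew
  }
  L[!mask] <- 0L
  L[mask] <- as.integer(factor(L[mask]))
  L
}

#' Segment podosome-scale indentations
#'
#' Thresholds indentations deeper than `depth_threshold` on a (typically
#' band-passed) map, labels 8-connected components, discards components
#' smaller than `min_area`, and records each component's geometry. Two
#' protrusions closer than the optical resolution merge into one component;
#' areas are pixel counts times pixel area, with no sub-pixel boundary
#' refinement, so footprints approaching the Airy disc are overestimated.
#'
#' @param map A [displacement_map()] (usually after [bandpass_spatial()]).
#' @param depth_threshold Indentation threshold in nm (positive number;
#'   pixels with values below `-depth_threshold` are segmented).
#' @param min_area Minimum component area in um^2.
#' @param depth_map Optional unfiltered [displacement_map()] from which the
#'   per-component maximum depth is read (the band-passed map attenuates
#'   depths); defaults to `map` itself. Depths are measured relative to the
#'   local baseline -- the median of a ring of pixels around the component
#'   -- so a broad cell-wide indentation underneath does not inflate them.
#' @return A data frame with one row per component: `label`, centroid
#'   `x`/`y` (um), `area_um2`, `depth_nm` (maximum indentation depth,
#'   positive), and placeholders `force_pN`, `stress_Pa` filled by
#'   [podosome_forces()].
#' @export
segment_podosomes <- function(map, depth_threshold, min_area = 0.1,
                              depth_map = NULL) {
  stopifnot(inherits(map, "displacement_map"), depth_threshold > 0)
  v <- map$values
  ref <- if (is.null(depth_map)) v else {
    stopifnot(inherits(depth_map, "displacement_map"),
              identical(dim(depth_map$values), dim(v)))
    depth_map$values
  }
  px <- map$pixel_size
  mask <- !is.na(v) & v < -depth_threshold
  empty <- data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      area_um2 = numeric(0), depth_nm = numeric(0),
                      force_pN = numeric(0), stress_Pa = numeric(0))
  if (!any(mask)) return(empty)
  L <- label_components8(mask)
  ids <- seq_len(max(L))
  rows <- lapply(ids, function(id) {
    comp <- L == id
    idx <- which(comp, arr.ind = TRUE)
    area <- nrow(idx) * px^2
    if (area < min_area) return(NULL)
    ring <- dilate8(dilate8(dilate8(comp))) & !comp & L == 0L
    base <- if (any(ring)) stats::median(ref[ring], na.rm = TRUE) else 0
    data.frame(label = id,
               x = mean((idx[, 2] - 0.5) * px),
               y = mean((idx[, 1] - 0.5) * px),
               area_um2 = area,
               depth_nm = max(0, base - min(ref[comp], na.rm = TRUE)),
               force_pN = NA_real_, stress_Pa = NA_real_)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out$label <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Flat-punch force for a cylindrical indenter
#'
#' Force of a rigid flat-ended cylinder of radius `a` indenting an elastic
#' half-space by `delta`: `F = 2 E / (1 - nu^2) * a * delta`. The half-space
#' assumption ignores the finite elastomer thickness; for podosome-scale
#' contacts (a << layer thickness) this is a small correction.
#'
#' @param substrate An [elastic_substrate()].
#' @param a Contact radius in um (vectorised).
#' @param delta Indentation depth in nm (vectorised, >= 0).
#' @return Force in pN.
#' @examples
#' punch_force(elastic_substrate(5000, 0.5), a = 0.5, delta = 1)
#' @export
punch_force <- function(substrate, a, delta) {
  stopifnot(inherits(substrate, "elastic_substrate"))
  if (any(a <= 0)) stop("'a' must be positive")
  if (any(delta < 0)) stop("'delta' must be non-negative")
  # E [Pa] * a [um -> 1e-6 m] * delta [nm -> 1e-9 m] -> N; * 1e12 -> pN
  2 * substrate$E / (1 - substrate$nu^2) * a * delta * 1e-3
}

#' Fill in punch-model forces and stresses for podosome records
#'
#' Each record's contact radius is taken from its indentation area
#' (`a = sqrt(area / pi)`), the depth is the component's maximum depth, and
#' the force follows [punch_force()]; the mean stress is force over area
#' (pN/um^2 = Pa).
#'
#' @param records Data frame from [segment_podosomes()].
#' @param substrate An [elastic_substrate()].
#' @return `records` with `force_pN` and `stress_Pa` set.
#' @export
podosome_forces <- function(records, substrate) {
  stopifnot(is.data.frame(records))
  if (!nrow(records)) return(records)
  a <- sqrt(records$area_um2 / pi)
  records$force_pN <- punch_force(substrate, a, records$depth_nm)
  records$stress_Pa <- records$force_pN / records$area_um2
  records
}

#' Linear force--area fit for podosome populations
#'
#' Ordinary least squares of punch-model force against indentation area,
#' restricted to areas above `min_area` (footprints below it are broadened
#' by diffraction and deviate from the linear trend).
#'
#' @param records Data frame with `force_pN` and `area_um2`.
#' @param min_area Area cut in um^2 (default 0.7).
#' @return List with `slope` (pN/um^2), `intercept` (pN), `r_squared`, `n`.
#' @export
force_area_fit <- function(records, min_area = 0.7) {
  stopifnot(is.data.frame(records))
  sub <- records[records$area_um2 > min_area, , drop = FALSE]
  if (nrow(sub) < 3L)
    stop("undefined fit: fewer than 3 records above the area cut")
  if (stats::sd(sub$area_um2) == 0)
    stop("undefined fit: all areas above the cut are equal")
  fit <- stats::lm(force_pN ~ area_um2, data = sub)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       n = nrow(sub))
}

#' Indented volume of a region
#'
#' Volume by which the surface is pushed into the cavity over a region:
#' the sum of indentation depths (only negative displacements count) times
#' the pixel area, in um^3. Used as a frame-by-frame proxy for the total
#' contractile force of a cell.
#'
#' @param map A [displacement_map()].
#' @param region Optional `list(rows =, cols =)`; default whole map.
#' @return Indented volume in um^3.
#' @export
indented_volume <- function(map, region = NULL) {
  stopifnot(inherits(map, "displacement_map"))
  v <- map$values
  if (!is.null(region)) v <- v[region$rows, region$cols, drop = FALSE]
  sum(pmax(0, -v), na.rm = TRUE) * map$pixel_size^2 * 1e-3
}
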