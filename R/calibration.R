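# Lookup-table calibration and the wavelength-scanning thickness oracle.
#
# The lookup table maps division-image values to fine displacement within
# one fringe mode; it is built from a cavity region of gradually varying
# thickness (a wedge) whose absolute thickness is known either analytically
# (synthetic truth) or from a wavelength-scanning measurement. The
# wavelength-scan analysis (per-pixel resonance minima -> absolute
# thickness) is the independent oracle WARP maps are validated against; it
# never consumes WARP intermediate products.

#' Build a lookup table from a calibration ramp
#'
#' Pairs division-image values with the fine displacement modulo the mode
#' spacing, separately for the two mode classes. The absolute thickness
#' reference may be the synthetic ground-truth displacement field, a
#' wavelength-scan derived thickness map, or a [spectral_scan()] (analysed
#' per pixel first). Samples are binned in fine displacement, cleaned up by
#' isotonic regression so each class is strictly monotone in the division
#' value, and stored as an invertible piecewise-linear table.
#'
#' The slowly varying envelope cotangent changes a little from one fringe
#' mode to the next, so raw division values from different modes of the
#' ramp disagree slightly at the same fine displacement. Because the
#' calibration knows the reference thickness of every sample, each value is
#' rescaled to a common reference thickness (the mean calibration
#' thickness) before binning, which removes that bias from the stored
#' table. Applying the table to thicknesses far from the reference retains
#' a small residual drift, inherent to the two-wavelength method.
#'
#' @param div A [division_image()] of the calibration region.
#' @param reference Reference for the same pixels: a matrix or
#'   [displacement_map()] (kind `"displacement"`, nm relative to `d0`;
#'   kind `"thickness"`, absolute nm), or a [spectral_scan()].
#' @param pair The [wavelength_pair()] in use.
#' @param n Refractive index.
#' @param d0 Rest thickness (nm); needed when `reference` is a displacement.
#' @param reference_kind `"displacement"` or `"thickness"`.
#' @param region Optional `list(rows =, cols =)` restricting the ramp
#'   region; default all pixels.
#' @param samples Number of fine-displacement bins per mode class.
#' @return An object of class `warp_lut`: per-class tables of
#'   `(value, d_lookup)`, the mode spacing `d_mode`, the calibrated
#'   `orientation` (+1 when division values increase with thickness within
#'   a mode) and build metadata.
#' @export
build_lookup_from_ramp <- function(div, reference, pair, n, d0 = NULL,
                                   reference_kind = c("displacement",
                                                      "thickness"),
                                   region = NULL, samples = 256L) {
  stopifnot(inherits(div, "warp_division"), inherits(pair, "wavelength_pair"))
  reference_kind <- match.arg(reference_kind)
  if (inherits(reference, "spectral_scan")) {
    reference <- erism_thickness_matrix(reference, n)
    reference_kind <- "thickness"
  }
  if (inherits(reference, "displacement_map")) reference <- reference$values
  stopifnot(is.matrix(reference), identical(dim(reference), dim(div$values)))
  dabs <- if (reference_kind == "displacement") {
    if (is.null(d0)) stop("'d0' is required for a displacement reference")
    d0 + reference
  } else reference
  if (is.null(region))
    region <- list(rows = seq_len(nrow(dabs)), cols = seq_len(ncol(dabs)))
  sel <- matrix(FALSE, nrow(dabs), ncol(dabs))
  sel[region$rows, region$cols] <- TRUE
  sel <- sel & !div$mask & is.finite(dabs)
  if (!any(sel)) stop("insufficient coverage: no usable calibration pixels")
  d_mode <- fringe_mode_spacing(pair, n)
  span <- diff(range(dabs[sel]))
  if (span < d_mode)
    stop(sprintf(paste0("insufficient coverage: calibration ramp spans ",
                        "%.0f nm < one mode (%.0f nm)"), span, d_mode))
  if (span < 2 * d_mode)
    warning("calibration ramp spans less than two full modes; ",
            "lookup endpoints may be poorly constrained")

  vals <- div$values[sel]
  modes <- div$mode[sel]
  dl <- (dabs[sel] / d_mode) %% 1 * d_mode
  # rescale the slow envelope cotangent to the reference thickness
  d_ref <- mean(dabs[sel])
  cot_slow <- function(d) 1 / tan(phi_slow(d, pair, n))
  corr <- cot_slow(d_ref) / cot_slow(dabs[sel])
  corr[!is.finite(corr)] <- 1
  vals <- vals * corr
  classes <- list()
  orient <- integer(0)
  for (cls in c(1L, 2L)) {
    i <- which(modes == cls)
    if (length(i) < 8L) next
    bins <- pmin(floor(dl[i] / d_mode * samples), samples - 1L)
    med <- tapply(vals[i], bins, stats::median)
    bx <- as.numeric(tapply(dl[i], bins, mean))
    o <- sign(stats::cor(bx, med, method = "spearman"))
    if (!is.finite(o) || o == 0) next
    iso <- stats::isoreg(bx, o * med)
    v <- o * iso$yf
    keep <- c(TRUE, diff(o * v) > 0)      # strictly monotone in value
    tab <- data.frame(value = v[keep], d_lookup = bx[keep])
    tab <- tab[order(tab$value), , drop = FALSE]
    if (nrow(tab) < 2L) next
    classes[[as.character(cls)]] <- tab
    orient <- c(orient, o)
  }
  if (!length(classes))
    stop("insufficient coverage: no mode class yielded a monotone table")
  orientation <- sign(sum(orient))
  if (orientation == 0) orientation <- orient[1]
  structure(list(classes = classes, d_mode = d_mode,
                 orientation = orientation,
                 meta = list(lambda1 = pair$lambda1, lambda2 = pair$lambda2,
                             refractive_index = n, d0 = d0,
                             samples = samples,
                             built = format(Sys.time(), "%Y-%m-%d"))),
            class = "warp_lut")
}

#' @export
print.warp_lut <- function(x, ...) {
  cat(sprintf("WARP lookup table: d_mode = %.2f nm, orientation %+d\n",
              x$d_mode, x$orientation))
  for (cls in names(x$classes))
    cat(sprintf("  mode %s: %d samples, values %.2f .. %.2f\n", cls,
                nrow(x$classes[[cls]]), min(x$classes[[cls]]$value),
                max(x$classes[[cls]]$value)))
  invisible(x)
}

#' Convert division values to fine displacements
#'
#' Monotone piecewise-linear interpolation of the calibrated table for the
#' given mode class. Values outside the calibrated range clamp to the
#' nearest endpoint and are flagged in the `clamped` attribute.
#'
#' @param lut A [build_lookup_from_ramp()] table.
#' @param values Division-image values (vector; `NA` passes through).
#' @param mode_class Mode class per value (1 or 2; scalar or vector).
#' @return Fine displacements `d_lookup` in `[0, d_mode)` nm, with logical
#'   attribute `clamped`.
#' @export
lookup_apply <- function(lut, values, mode_class) {
  stopifnot(inherits(lut, "warp_lut"))
  if (length(mode_class) == 1L) mode_class <- rep(mode_class, length(values))
  stopifnot(length(mode_class) == length(values))
  known <- names(lut$classes)
  bad <- !is.na(mode_class) & !(as.character(mode_class) %in% known)
  if (any(bad))
    stop("unknown mode class: ", paste(unique(mode_class[bad]), collapse = ", "))
  out <- rep(NA_real_, length(values))
  clamped <- rep(FALSE, length(values))
  for (cls in known) {
    tab <- lut$classes[[cls]]
    i <- which(as.character(mode_class) == cls & !is.na(values))
    if (!length(i)) next
    out[i] <- stats::approx(tab$value, tab$d_lookup, xout = values[i],
                            rule = 2, ties = "ordered")$y
    clamped[i] <- values[i] < min(tab$value) | values[i] > max(tab$value)
  }
  attr(out, "clamped") <- clamped
  out
}

#' Serialise a lookup table to a plain-text file
#'
#' Versioned two-column-per-class text format with a metadata header; the
#' inverse of [read_lut()].
#'
#' @param lut A `warp_lut`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lut <- function(lut, path) {
  stopifnot(inherits(lut, "warp_lut"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# warpmic lookup table v1",
               sprintf("# d_mode: %.10g", lut$d_mode),
               sprintf("# orientation: %d", lut$orientation)), con)
  for (key in names(lut$meta))
    writeLines(sprintf("# %s: %s", key, lut$meta[[key]]), con)
  writeLines("mode\tvalue\td_lookup", con)
  for (cls in names(lut$classes)) {
    tab <- lut$classes[[cls]]
    writeLines(sprintf("%s\t%.10g\t%.10g", cls, tab$value, tab$d_lookup), con)
  }
  invisible(path)
}

#' Read a lookup table written by [write_lut()]
#'
#' @param path File path.
#' @return A `warp_lut`.
#' @export
read_lut <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^# *", "", hdr[-1])
  keys <- sub(":.*$", "", kv)
  vals <- sub("^[^:]*: *", "", kv)
  meta <- as.list(vals)
  names(meta) <- keys
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.table(text = paste(body, collapse = "\n"), header = TRUE,
                           sep = "\t", colClasses = c("character", "numeric",
                                                      "numeric"))
  classes <- lapply(split(tab[c("value", "d_lookup")], tab$mode),
                    function(x) x[order(x$value), , drop = FALSE])
  structure(list(classes = classes,
                 d_mode = as.numeric(meta[["d_mode"]]),
                 orientation = as.integer(meta[["orientation"]]),
                 meta = meta[setdiff(names(meta), c("d_mode", "orientation"))]),
            class = "warp_lut")
}

#' Construct a spectral scan
#'
#' Per-pixel reflectance as a function of illumination wavelength, the raw
#' material of the wavelength-scanning thickness measurement (typically 201
#' wavelengths in 1 nm steps from 550 to 750 nm).
#'
#' @param refl 3-D array `c(rows, cols, wavelengths)` of reflectance.
#' @param wavelengths Strictly increasing wavelength grid (nm).
#' @param pixel_size Pixel pitch in um.
#' @return An object of class `spectral_scan`.
#' @export
spectral_scan <- function(refl, wavelengths, pixel_size) {
  stopifnot(length(dim(refl)) == 3L, dim(refl)[3] == length(wavelengths),
            all(diff(wavelengths) > 0), pixel_size > 0)
  structure(list(refl = refl, wavelengths = wavelengths,
                 pixel_size = pixel_size),
            class = "spectral_scan")
}

#' @export
print.spectral_scan <- function(x, ...) {
  d <- dim(x$refl)
  cat(sprintf("Spectral scan: %d x %d px, %d wavelengths (%g .. %g nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Simulate a wavelength-scanning acquisition
#'
#' Renders the cavity reflectance over a wavelength grid with the full
#' two-mirror resonator lineshape (whose minima sit at the cavity
#' resonances `2 n d = m lambda`), scaled by the cavity amplitude field,
#' with optional camera noise.
#'
#' @param cavity A [cavity_spec()].
#' @param truth Displacement field in nm.
#' @param pixel_size Pixel pitch in um.
#' @param wavelengths Wavelength grid in nm (default 550:750).
#' @param noise_sd Additive noise s.d. (a.u.).
#' @param seed Seed for the noise draw.
#' @return A [spectral_scan()].
#' @export
simulate_spectral_scan <- function(cavity, truth, pixel_size,
                                   wavelengths = 550:750, noise_sd = 0,
                                   seed = 1L) {
  stopifnot(inherits(cavity, "cavity_spec"), is.matrix(truth))
  d <- cavity$d0 + truth
  refl <- array(0, c(nrow(truth), ncol(truth), length(wavelengths)))
  rs <- if (noise_sd > 0) local_rng(seed)
  for (j in seq_along(wavelengths)) {
    img <- cavity$A * reflectance_fabry_perot(cavity, d, wavelengths[j])
    if (noise_sd > 0)
      img <- img + matrix(rs$rnorm(length(img), 0, noise_sd), nrow(img))
    refl[, , j] <- img
  }
  spectral_scan(refl, wavelengths, pixel_size)
}

# adjacent-minima pairs -> mean thickness; lams: increasing minima positions
pairs_to_thickness <- function(lams, n, max_order_residual = 0.2) {
  if (length(lams) < 2L) return(c(d = NA_real_, npairs = 0))
  lb <- lams[-length(lams)]
  la <- lams[-1]
  m_exact <- lb / (la - lb)
  m <- round(m_exact)
  ok <- is.finite(m_exact) & abs(m_exact - m) <= max_order_residual & m > 0
  if (!any(ok)) return(c(d = NA_real_, npairs = 0))
  c(d = mean(m[ok] * la[ok] / (2 * n)), npairs = sum(ok))
}

# refine minima positions of one spectrum by parabolic interpolation
spectrum_minima <- function(refl, wavelengths) {
  nl <- length(wavelengths)
  i <- which(refl[2:(nl - 1)] < refl[1:(nl - 2)] &
             refl[2:(nl - 1)] <= refl[3:nl]) + 1L
  if (!length(i)) return(numeric(0))
  y1 <- refl[i - 1L]; y2 <- refl[i]; y3 <- refl[i + 1L]
  denom <- y1 - 2 * y2 + y3
  delta <- ifelse(denom > 0, 0.5 * (y1 - y3) / denom, 0)
  wavelengths[i] + delta * (wavelengths[i + 1L] - wavelengths[i - 1L]) / 2
}

#' Absolute cavity thickness from a reflectance spectrum
#'
#' Locates the resonance minima of one reflectance spectrum (sub-sample, by
#' parabolic interpolation around each sampled minimum), assigns each
#' adjacent pair of minima `lambda_b < lambda_a` the integer resonance order
#' `m = round(lambda_b / (lambda_a - lambda_b))` -- pairs whose order
#' residual exceeds 0.2 are rejected as localisation noise -- and returns
#' the thickness `d = m * lambda_a / (2 n)` averaged over accepted pairs.
#'
#' @param reflectance Reflectance values over the wavelength grid.
#' @param wavelengths Strictly increasing wavelength grid (nm).
#' @param n Refractive index.
#' @return Absolute thickness in nm.
#' @export
erism_thickness <- function(reflectance, wavelengths, n) {
  stopifnot(length(reflectance) == length(wavelengths),
            all(diff(wavelengths) > 0), n > 0)
  lams <- spectrum_minima(reflectance, wavelengths)
  if (length(lams) < 2L)
    stop("insufficient resonances: need at least 2 reflectance minima")
  res <- pairs_to_thickness(lams, n)
  if (res[["npairs"]] == 0)
    stop("insufficient resonances: no adjacent minima pair has a ",
         "consistent resonance order")
  res[["d"]]
}

# vectorised per-pixel absolute thickness over a whole scan
erism_thickness_matrix <- function(scan, n) {
  stopifnot(inherits(scan, "spectral_scan"))
  d3 <- dim(scan$refl)
  npix <- d3[1] * d3[2]
  nl <- d3[3]
  M <- matrix(scan$refl, npix, nl)
  wl <- scan$wavelengths
  lmin <- M[, 2:(nl - 1), drop = FALSE] < M[, 1:(nl - 2), drop = FALSE] &
          M[, 2:(nl - 1), drop = FALSE] <= M[, 3:nl, drop = FALSE]
  idx <- which(lmin, arr.ind = TRUE)
  out <- rep(NA_real_, npix)
  if (!nrow(idx)) return(matrix(out, d3[1], d3[2]))
  pix <- idx[, 1]
  j <- idx[, 2] + 1L
  y1 <- M[cbind(pix, j - 1L)]; y2 <- M[cbind(pix, j)]; y3 <- M[cbind(pix, j + 1L)]
  denom <- y1 - 2 * y2 + y3
  delta <- ifelse(denom > 0, 0.5 * (y1 - y3) / denom, 0)
  lam <- wl[j] + delta * (wl[j + 1L] - wl[j - 1L]) / 2
  ord <- order(pix, lam)
  pix <- pix[ord]; lam <- lam[ord]
  adj <- which(pix[-length(pix)] == pix[-1])
  if (!length(adj)) return(matrix(out, d3[1], d3[2]))
  lb <- lam[adj]; la <- lam[adj + 1L]; pp <- pix[adj]
  m_exact <- lb / (la - lb)
  m <- round(m_exact)
  ok <- is.finite(m_exact) & abs(m_exact - m) <= 0.2 & m > 0
  if (!any(ok)) return(matrix(out, d3[1], d3[2]))
  dvals <- m[ok] * la[ok] / (2 * n)
  pp <- pp[ok]
  sums <- rowsum(dvals, pp)
  cnts <- rowsum(rep(1, length(pp)), pp)
  out[as.integer(rownames(sums))] <- sums / cnts
  matrix(out, d3[1], d3[2])
}

#' Displacement map from a wavelength scan
#'
#' Per-pixel absolute thickness via [erism_thickness()] (vectorised), minus
#' the mean over the flat reference region: the ground-truth oracle that
#' WARP maps are compared against. Pixels whose spectrum yields no
#' consistent resonance pair are `NA` and flagged.
#'
#' @param scan A [spectral_scan()].
#' @param n Refractive index.
#' @param flat_region `list(rows =, cols =)` of uniform cavity thickness;
#'   defaults to the whole image.
#' @return A [displacement_map()] (relative displacement, nm).
#' @export
erism_map <- function(scan, n, flat_region = NULL) {
  thick <- erism_thickness_matrix(scan, n)
  if (is.null(flat_region))
    flat_region <- list(rows = seq_len(nrow(thick)),
                        cols = seq_len(ncol(thick)))
  base <- mean(thick[flat_region$rows, flat_region$cols], na.rm = TRUE)
  flags <- matrix(0L, nrow(thick), ncol(thick))
  flags[!is.finite(thick)] <- 1L
  displacement_map(thick - base, scan$pixel_size, flags = flags,
                   flat_region = flat_region)
}
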