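# Displacement maps: reconstructed relative top-mirror displacement.

#' Construct a displacement map
#'
#' Reconstructed relative displacement of the cavity top mirror, in nm per
#' pixel; negative values indent into the cavity (cells pushing in). The
#' map carries per-pixel quality flags (0 = ok, 1 = interpolated across a
#' pole-masked run, 2 = lookup value clamped at the calibrated range) and
#' the flat reference region its baseline was taken from.
#'
#' @param values Numeric matrix of displacements (nm).
#' @param pixel_size Pixel pitch in um.
#' @param flags Integer matrix of per-pixel quality flags (0/1/2).
#' @param flat_region Baseline region, `list(rows =, cols =)`.
#' @param d_mode Mode spacing used in the reconstruction (nm), if any.
#' @return An object of class `displacement_map`.
#' @export
displacement_map <- function(values, pixel_size, flags = NULL,
                             flat_region = NULL, d_mode = NULL) {
  stopifnot(is.matrix(values), pixel_size > 0)
  if (is.null(flags)) flags <- matrix(0L, nrow(values), ncol(values))
  stopifnot(identical(dim(flags), dim(values)))
  structure(list(values = values, pixel_size = pixel_size, flags = flags,
                 flat_region = flat_region, d_mode = d_mode),
            class = "displacement_map")
}

#' @export
print.displacement_map <- function(x, ...) {
  v <- x$values
  cat(sprintf("Displacement map: %d x %d px (%.2f um/px)\n",
              nrow(v), ncol(v), x$pixel_size))
  cat(sprintf("  range %.1f .. %.1f nm; %.1f%% flagged\n",
              min(v, na.rm = TRUE), max(v, na.rm = TRUE),
              100 * mean(x$flags != 0L)))
  invisible(x)
}

#' @export
plot.displacement_map <- function(x, ..., main = "displacement (nm)") {
  v <- x$values
  xs <- (seq_len(ncol(v)) - 0.5) * x$pixel_size
  ys <- (seq_len(nrow(v)) - 0.5) * x$pixel_size
  graphics::image(xs, ys, t(v)[, rev(seq_len(nrow(v)))],
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  xlab = "x (um)", ylab = "y (um)", main = main,
                  useRaster = TRUE, asp = 1, ...)
  invisible(x)
}

#' Full width at half maximum of a residual distribution
#'
#' Summarises the agreement between two displacement maps the way a residual
#' histogram is summarised: kernel density of the residuals, width of the
#' region above half the density peak.
#'
#' @param residuals Numeric vector of residuals (nm).
#' @return FWHM in the units of `residuals`.
#' @export
residual_fwhm <- function(residuals) {
  residuals <- residuals[is.finite(residuals)]
  stopifnot(length(residuals) > 10L)
  dens <- stats::density(residuals, n = 2048)
  half <- max(dens$y) / 2
  above <- which(dens$y >= half)
  dens$x[max(above)] - dens$x[min(above)]
}
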