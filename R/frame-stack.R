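# Time-ordered, wavelength-labelled stacks of monochromatic intensity frames.

#' Construct a labelled frame stack
#'
#' A frame stack holds the time-ordered monochromatic intensity rasters of a
#' dual-wavelength acquisition. Wavelength labels must strictly alternate
#' between the two values and timestamps must strictly increase; both are
#' validated here and again when stacks are read from disk.
#'
#' @param frames List of numeric matrices, all the same size.
#' @param wavelengths Numeric vector, one wavelength label (nm) per frame.
#' @param timestamps Numeric vector of acquisition times (s).
#' @param pixel_size Pixel pitch in um.
#' @param meta Named list of acquisition metadata (wavelength pair,
#'   refractive index, frame rate, ...).
#' @return An object of class `warp_frame_stack`.
#' @export
frame_stack <- function(frames, wavelengths, timestamps, pixel_size,
                        meta = list()) {
  if (!is.list(frames) || !length(frames) ||
      !all(vapply(frames, is.matrix, TRUE)))
    stop("'frames' must be a non-empty list of matrices")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share dimensions")
  n <- length(frames)
  stopifnot(length(wavelengths) == n, length(timestamps) == n, pixel_size > 0)
  if (any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  check_alternation(wavelengths)
  structure(list(frames = frames, wavelengths = wavelengths,
                 timestamps = timestamps, pixel_size = pixel_size,
                 meta = meta),
            class = "warp_frame_stack")
}

check_alternation <- function(wavelengths) {
  labs <- unique(wavelengths)
  if (length(labs) > 2L)
    stop("frame stack carries more than two wavelength labels")
  if (length(wavelengths) >= 2L) {
    same <- which(diff(wavelengths) == 0)
    if (length(same))
      stop(sprintf(
        "wavelength labels do not alternate: frames %d and %d are both %g nm",
        same[1], same[1] + 1L, wavelengths[same[1]]))
  }
  invisible(TRUE)
}

#' @export
print.warp_frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("WARP frame stack: %d frames of %d x %d px (%.2f um/px)\n",
              length(x$frames), d[1], d[2], x$pixel_size))
  cat(sprintf("  wavelengths: %s nm; t = %.4g .. %.4g s\n",
              paste(unique(x$wavelengths), collapse = " / "),
              min(x$timestamps), max(x$timestamps)))
  invisible(x)
}

#' @export
length.warp_frame_stack <- function(x) length(x$frames)
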