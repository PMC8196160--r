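# Temporal analysis of displacement and force traces: filtering,
# contraction detection, beat statistics, and micro-contraction tracking.

#' Construct a uniformly sampled time trace
#'
#' @param values Numeric vector (e.g. indented volume in um^3 or force in
#'   pN).
#' @param rate Sampling rate in Hz.
#' @param t0 Time of the first sample (s).
#' @param unit Unit tag for the values.
#' @return An object of class `time_trace` with fields `t`, `values`,
#'   `rate`, `unit`.
#' @export
time_trace <- function(values, rate, t0 = 0, unit = "") {
  stopifnot(is.numeric(values), length(values) >= 2L, rate > 0)
  structure(list(t = t0 + (seq_along(values) - 1) / rate,
                 values = as.numeric(values), rate = rate, unit = unit),
            class = "time_trace")
}

#' @export
print.time_trace <- function(x, ...) {
  cat(sprintf("Time trace: %d samples at %g Hz (%.3g .. %.3g %s)\n",
              length(x$values), x$rate, min(x$values), max(x$values),
              x$unit))
  invisible(x)
}

#' @export
plot.time_trace <- function(x, ...,
                            ylab = if (nzchar(x$unit)) x$unit else "value") {
  graphics::plot(x$t, x$values, type = "l", xlab = "time (s)", ylab = ylab,
                 ...)
  invisible(x)
}

#' Centred moving average of a trace
#'
#' Boxcar mean over a window of `window` seconds; at the trace edges the
#' window shrinks so that the length is preserved.
#'
#' @param trace A [time_trace()].
#' @param window Window length in seconds (at least 2 samples).
#' @return The filtered [time_trace()].
#' @export
moving_average <- function(trace, window) {
  stopifnot(inherits(trace, "time_trace"))
  n <- length(trace$values)
  w <- round(window * trace$rate)
  if (w < 2L) stop("'window' must cover at least 2 samples")
  if (w > n) stop("'window' is longer than the trace")
  half_l <- (w - 1L) %/% 2L
  half_r <- w - 1L - half_l
  cs <- cumsum(c(0, trace$values))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_l)
  hi <- pmin(n, i + half_r)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  time_trace(out, trace$rate, t0 = trace$t[1], unit = trace$unit)
}

#' Temporal Fourier high-pass filter
#'
#' Hard spectral mask: the trace mean is removed, frequency components
#' strictly below `cutoff` are zeroed, and everything at or above the
#' cutoff is preserved. Used to separate fast force fluctuations from slow
#' baseline drift (e.g. a 0.2 Hz cutoff on podosome force traces).
#'
#' @param trace A [time_trace()].
#' @param cutoff Cutoff frequency in Hz, below the Nyquist frequency.
#' @return The filtered [time_trace()] (mean-free).
#' @export
highpass <- function(trace, cutoff) {
  stopifnot(inherits(trace, "time_trace"))
  if (cutoff >= trace$rate / 2) stop("'cutoff' must be below Nyquist")
  v <- trace$values - mean(trace$values)
  n <- length(v)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * trace$rate / n
  V <- stats::fft(v)
  V[f < cutoff] <- 0
  out <- Re(stats::fft(V, inverse = TRUE)) / n
  time_trace(out, trace$rate, t0 = trace$t[1], unit = trace$unit)
}

#' Detect contraction events in a trace
#'
#' Local maxima whose amplitude above the preceding local minimum exceeds
#' `prominence` times the trace's robust range (1st--99th percentile),
#' separated by at least `min_separation` seconds (of nearby candidates the
#' larger peak wins). Each event records its peak time and value, its
#' amplitude above the local baseline, and the instantaneous frequency from
#' the interval to the previous accepted peak (the first event has none).
#'
#' @param trace A [time_trace()] with at least 3 samples.
#' @param prominence Amplitude threshold as a fraction of the robust range.
#' @param min_separation Minimum peak separation in seconds.
#' @return Data frame with columns `time`, `value`, `amplitude`,
#'   `frequency` (Hz, `NA` for the first event).
#' @export
detect_contractions <- function(trace, prominence = 0.2, min_separation = 0) {
  stopifnot(inherits(trace, "time_trace"), length(trace$values) >= 3L)
  v <- trace$values
  n <- length(v)
  rng <- diff(stats::quantile(v, c(0.01, 0.99), names = FALSE))
  empty <- data.frame(time = numeric(0), value = numeric(0),
                      amplitude = numeric(0), frequency = numeric(0))
  if (rng <= 0) return(empty)
  i <- 2:(n - 1)
  peaks <- i[v[i] >= v[i - 1] & v[i] > v[i + 1]]
  if (!length(peaks)) return(empty)
  amp <- vapply(seq_along(peaks), function(j) {
    lo <- if (j == 1L) 1L else peaks[j - 1L]
    v[peaks[j]] - min(v[lo:peaks[j]])
  }, numeric(1))
  keep <- amp >= prominence * rng
  peaks <- peaks[keep]; amp <- amp[keep]
  if (!length(peaks)) return(empty)
  if (min_separation > 0 && length(peaks) > 1L) {
    ord <- order(v[peaks], -peaks, decreasing = TRUE)
    acc <- integer(0)
    for (p in peaks[ord]) {
      if (!length(acc) ||
          all(abs(trace$t[p] - trace$t[acc]) >= min_separation))
        acc <- c(acc, p)
    }
    sel <- peaks %in% acc
    peaks <- peaks[sel]; amp <- amp[sel]
  }
  tt <- trace$t[peaks]
  freq <- c(NA_real_, 1 / diff(tt))
  data.frame(time = tt, value = v[peaks], amplitude = amp, frequency = freq)
}

#' Summary statistics of contraction events
#'
#' Sample mean, standard deviation (n - 1 normalisation) and coefficient of
#' variation (CV = s.d. / mean) of the event amplitudes and instantaneous
#' frequencies, optionally restricted to a time window (e.g. successive
#' 20 s intervals of a drug-challenge recording).
#'
#' @param events Data frame from [detect_contractions()].
#' @param window Optional time window `c(t0, t1)` in seconds.
#' @return List with `amplitude` and `frequency`, each holding `mean`,
#'   `sd`, `cv`, and `n_events`.
#' @export
contraction_stats <- function(events, window = NULL) {
  stopifnot(is.data.frame(events))
  if (!is.null(window))
    events <- events[events$time >= window[1] & events$time <= window[2], ,
                     drop = FALSE]
  if (nrow(events) < 2L)
    stop("undefined stats: fewer than 2 events in the window")
  one <- function(x) {
    x <- x[is.finite(x)]
    m <- mean(x); s <- stats::sd(x)
    list(mean = m, sd = s, cv = s / m)
  }
  c(list(amplitude = one(events$amplitude),
         frequency = one(events$frequency)),
    n_events = nrow(events))
}

#' Correlation of peak force with contraction frequency
#'
#' Least-squares fit of the per-contraction peak value (e.g. peak indented
#' volume) against the instantaneous contraction frequency, restricted to
#' frequencies below `cap` (the correlation breaks down for the fastest
#' beats; the default cap is 8 Hz).
#'
#' @param peaks Per-contraction peak values.
#' @param frequencies Matching instantaneous frequencies in Hz.
#' @param cap Frequency cap in Hz.
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
force_frequency_correlation <- function(peaks, frequencies, cap = 8) {
  stopifnot(length(peaks) == length(frequencies))
  ok <- is.finite(peaks) & is.finite(frequencies) & frequencies < cap
  if (sum(ok) < 3L)
    stop("undefined fit: fewer than 3 contraction pairs below the cap")
  fit <- stats::lm(peaks[ok] ~ frequencies[ok])
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       n = sum(ok))
}

#' Detect micro-contraction events in a map stack
#'
#' Transient, shallow, localised contractions (tens of milliseconds, tens
#' of nanometres) between main contraction cycles. Each frame is spatially
#' band-passed, indentations deeper than `detect_floor` are segmented, and
#' blobs are linked across frames into tracks by nearest-centroid
#' association within `link_radius`. Tracks whose maximum depth stays at or
#' below `depth_ceiling` and whose duration stays at or below
#' `duration_ceiling` are reported as micro-contraction events (deeper or
#' longer tracks belong to main contractions). Depths are measured on the
#' unfiltered maps within the detected footprint. Events shorter than the
#' frame interval cannot be timed; sampling at 50 fps or more is needed for
#' sub-100 ms events.
#'
#' @param maps List of [displacement_map()]s or a 3-D array
#'   `c(rows, cols, frames)`.
#' @param times Frame times in seconds.
#' @param pixel_size Pixel pitch in um (required for an array input).
#' @param band Retained lateral wavelength band `c(low, high)` in um; the
#'   lower edge is raised to just above two pixels if needed.
#' @param depth_ceiling Maximum event depth in nm.
#' @param duration_ceiling Maximum event duration in seconds.
#' @param detect_floor Segmentation threshold in nm.
#' @param link_radius Maximum centroid displacement between frames in um.
#' @return Data frame with one row per event (`depth_nm`, `duration_s`,
#'   `t_start`, `t_end`, `n_frames`) and the per-frame centroid trajectory
#'   in the `trajectory` attribute (list of data frames).
#' @export
micro_contraction_detect <- function(maps, times, pixel_size = NULL,
                                     band = c(1, 10), depth_ceiling = 30,
                                     duration_ceiling = 0.1,
                                     detect_floor = 8, link_radius = 2) {
  if (is.array(maps) && length(dim(maps)) == 3L) {
    if (is.null(pixel_size)) stop("'pixel_size' is required for array input")
    maps <- lapply(seq_len(dim(maps)[3]),
                   function(i) displacement_map(maps[, , i], pixel_size))
  }
  stopifnot(is.list(maps), length(maps) == length(times),
            all(diff(times) > 0))
  dt <- stats::median(diff(times))
  band[1] <- max(band[1], 2.05 * maps[[1]]$pixel_size)
  tracks <- list()      # each: list(last, centroid, frames, depths, times)
  finished <- list()
  for (i in seq_along(maps)) {
    bp <- bandpass_spatial(maps[[i]], band[1], band[2])
    blobs <- segment_podosomes(bp, depth_threshold = detect_floor,
                               min_area = 0, depth_map = maps[[i]])
    used <- rep(FALSE, nrow(blobs))
    for (k in seq_along(tracks)) {
      tr <- tracks[[k]]
      if (tr$last < i - 1L) next
      if (nrow(blobs)) {
        dist <- sqrt((blobs$x - tr$cx)^2 + (blobs$y - tr$cy)^2)
        j <- which(!used & dist <= link_radius)
        if (length(j)) {
          j <- j[which.min(dist[j])]
          used[j] <- TRUE
          tr$last <- i
          tr$cx <- blobs$x[j]; tr$cy <- blobs$y[j]
          tr$frames <- c(tr$frames, i)
          tr$depths <- c(tr$depths, blobs$depth_nm[j])
          tr$xs <- c(tr$xs, blobs$x[j]); tr$ys <- c(tr$ys, blobs$y[j])
          tracks[[k]] <- tr
        }
      }
    }
    alive <- vapply(tracks, function(tr) tr$last >= i - 1L, TRUE)
    finished <- c(finished, tracks[!alive])
    tracks <- tracks[alive]
    if (nrow(blobs)) {
      for (j in which(!used)) {
        tracks[[length(tracks) + 1L]] <-
          list(last = i, cx = blobs$x[j], cy = blobs$y[j], frames = i,
               depths = blobs$depth_nm[j], xs = blobs$x[j], ys = blobs$y[j])
      }
    }
  }
  finished <- c(finished, tracks)
  if (!length(finished))
    return(structure(data.frame(depth_nm = numeric(0),
                                duration_s = numeric(0),
                                t_start = numeric(0), t_end = numeric(0),
                                n_frames = integer(0)),
                     trajectory = list()))
  rows <- list(); trajs <- list()
  for (tr in finished) {
    depth <- max(tr$depths)
    dur <- length(tr$frames) * dt
    if (depth > depth_ceiling || dur > duration_ceiling) next
    rows[[length(rows) + 1L]] <-
      data.frame(depth_nm = depth, duration_s = dur,
                 t_start = times[min(tr$frames)],
                 t_end = times[max(tr$frames)],
                 n_frames = length(tr$frames))
    trajs[[length(trajs) + 1L]] <-
      data.frame(t = times[tr$frames], x = tr$xs, y = tr$ys,
                 depth_nm = tr$depths)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(depth_nm = numeric(0), duration_s = numeric(0),
                         t_start = numeric(0), t_end = numeric(0),
                         n_frames = integer(0))
  rownames(out) <- NULL
  structure(out, trajectory = trajs)
}
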