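# WARP reconstruction: from an alternating dual-wavelength frame stack to a
# displacement map.
#
# Pipeline: pair frames (motion-artefact averaging) -> sum & difference
# images -> background 2B from difference zero-crossings -> division image
# (sum - 2B) / difference with pole masking and mode classes -> sub-pixel
# fringe-transition detection -> per-row scans combining mode counting with
# the lookup-table fine displacement -> rebaselining on a flat region.

#' Pair frames for motion-artefact mitigation
#'
#' Consecutive frames of an alternating acquisition are offset in time by one
#' exposure, so a moving scene breaks the assumption that the two wavelengths
#' see the same deformation. Each interior frame of one wavelength is
#' therefore compared against the mean of its two neighbours at the other
#' wavelength (method `"neighbours"`), which cancels the temporal offset to
#' first order; `"previous"` (naive pairing with the preceding frame only) is
#' provided for comparison. Unpaired frames at the stack ends are dropped.
#'
#' @param stack A [frame_stack()] with at least 3 frames.
#' @param single Which wavelength keeps single frames while the other is
#'   neighbour-averaged: `"auto"` (the label of the second frame, so every
#'   interior frame of that label is paired), `"lambda1"` or `"lambda2"`.
#' @param method `"neighbours"` (mean of preceding and following frame) or
#'   `"previous"` (preceding frame only).
#' @return A list of class `warp_paired_list`; each element has the rasters
#'   `I1` (at the smaller wavelength), `I2`, and mid-timestamp `t`.
#' @export
pair_frames <- function(stack, single = c("auto", "lambda1", "lambda2"),
                        method = c("neighbours", "previous")) {
  stopifnot(inherits(stack, "warp_frame_stack"))
  single <- match.arg(single)
  method <- match.arg(method)
  n <- length(stack$frames)
  if (n < 3L) stop("need at least 3 frames to pair")
  check_alternation(stack$wavelengths)
  wls <- sort(unique(stack$wavelengths))
  if (length(wls) != 2L) stop("stack must carry exactly two wavelengths")
  l1 <- wls[1]; l2 <- wls[2]
  single_wl <- switch(single,
    auto = stack$wavelengths[2],
    lambda1 = l1,
    lambda2 = l2)
  idx <- which(stack$wavelengths == single_wl)
  idx <- idx[idx > 1L & idx < n]
  if (!length(idx)) stop("no interior frames of the chosen wavelength")
  out <- lapply(idx, function(i) {
    partner <- if (method == "neighbours")
      (stack$frames[[i - 1L]] + stack$frames[[i + 1L]]) / 2
    else stack$frames[[i - 1L]]
    if (single_wl == l1)
      list(I1 = stack$frames[[i]], I2 = partner, t = stack$timestamps[i])
    else
      list(I1 = partner, I2 = stack$frames[[i]], t = stack$timestamps[i])
  })
  structure(out, class = "warp_paired_list",
            pixel_size = stack$pixel_size, meta = stack$meta)
}

#' Sum and difference images of a frame pair
#'
#' The pixelwise difference `I(lambda1) - I(lambda2)` cancels the background
#' term and equals `-2 A sin(phi_fast) sin(phi_slow)`; the sum retains the
#' background, `2B + 2 A cos(phi_fast) cos(phi_slow)`.
#'
#' @param paired One element of [pair_frames()] output (a list with rasters
#'   `I1` and `I2`), or any list with those two fields.
#' @return A list with matrices `sum` and `diff`.
#' @export
sum_diff <- function(paired) {
  stopifnot(is.matrix(paired$I1), is.matrix(paired$I2),
            identical(dim(paired$I1), dim(paired$I2)))
  list(sum = paired$I1 + paired$I2, diff = paired$I1 - paired$I2)
}

# sub-pixel zero crossings of a vector; exact-zero samples are assigned to
# the interval on their left. Returns fractional positions (1-based index
# units; a crossing at position p lies between pixels floor(p) and
# floor(p) + 1).
zero_crossings <- function(v) {
  n <- length(v)
  if (n < 2L) return(numeric(0))
  pos <- numeric(0)
  z <- which(v == 0)
  z <- z[z > 1L]              # a leading zero has no left interval
  if (length(z)) pos <- z - 0.5
  s <- sign(v)
  i <- which(s[-n] != 0 & s[-1] != 0 & s[-n] != s[-1])
  if (length(i)) pos <- c(pos, i + v[i] / (v[i] - v[i + 1L]))
  sort(pos)
}

# smooth a vector with a centred 3-point mean (ends untouched); preserves the
# zero positions of locally linear signals while suppressing single-pixel
# noise crossings
smooth3 <- function(v) {
  n <- length(v)
  if (n < 3L) return(v)
  out <- v
  out[2:(n - 1L)] <- (v[1:(n - 2L)] + v[2:(n - 1L)] + v[3:n]) / 3
  out
}

# Detect fringe transitions along one line.
#   diffv: difference-image values; divv: division values (NA at poles);
#   maskv: pole mask. Crossings with no unmasked pixel between them are
#   clustered; each cluster contributes at most one net transition whose
#   direction comes from the division-image sign on either side. A cluster
#   whose flanking division signs agree carries no net mode change and is
#   dropped (the smoothness prior of the scan).
detect_transitions_line <- function(diffv, divv, maskv, presmooth = TRUE) {
  n <- length(diffv)
  dv <- if (presmooth) smooth3(diffv) else diffv
  pos <- zero_crossings(dv)
  if (!length(pos))
    return(data.frame(position = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  unm <- which(!maskv)
  cl <- integer(length(pos)); cl[1] <- 1L
  if (length(pos) > 1L) {
    for (k in 2:length(pos)) {
      between <- any(unm > pos[k - 1L] & unm < pos[k])
      cl[k] <- if (between) cl[k - 1L] + 1L else cl[k - 1L]
    }
  }
  res_pos <- numeric(0); res_dir <- character(0)
  for (g in unique(cl)) {
    p <- pos[cl == g]
    left <- unm[unm < min(p)]
    right <- unm[unm > max(p)]
    if (!length(left) || !length(right)) next  # no anchor on one side
    vl <- divv[max(left)]; vr <- divv[min(right)]
    if (is.na(vl) || is.na(vr) || sign(vl) == sign(vr)) next
    res_pos <- c(res_pos, mean(range(p)))
    res_dir <- c(res_dir, if (vl > 0) "pn" else "np")
  }
  data.frame(position = res_pos, direction = res_dir,
             stringsAsFactors = FALSE)
}

#' Detect fringe transitions along a scan line
#'
#' Zero crossings of the difference image mark transitions between adjacent
#' fringe modes. Crossings are located to sub-pixel precision by linear
#' interpolation between the bracketing samples (a crossing landing exactly
#' on a sample is assigned to the interval on its left); the transition
#' direction -- positive-to-negative (`"pn"`) or negative-to-positive
#' (`"np"`) -- is read from the sign of the division image on either side of
#' the crossing. Crossings inside a single pole-masked run are merged into
#' one net transition, which makes the count robust to noise wiggles around
#' a fringe zero.
#'
#' @param div A [division_image()] result.
#' @param row Row index of the scan line.
#' @return A data frame with columns `position` (sub-pixel column index) and
#'   `direction` (`"np"` or `"pn"`).
#' @export
detect_fringe_transitions <- function(div, row) {
  stopifnot(inherits(div, "warp_division"),
            row >= 1L, row <= nrow(div$diff))
  detect_transitions_line(div$diff[row, ], div$values[row, ], div$mask[row, ])
}

#' Estimate the background term 2B
#'
#' At every zero crossing of the difference image the fast cosine term of the
#' sum image is at an extremum, so the sum alternates between `2B + 2A|cos
#' phi_slow|` and `2B - 2A|cos phi_slow|` there. Sampling the sum at the
#' crossings (sub-pixel, linearly interpolated) and averaging midpoints of
#' consecutive samples therefore recovers `2B` without knowing `A`. Where
#' the thickness is non-monotone along a row, consecutive crossings can sit
#' at the same extremum, so only sample pairs that straddle a provisional
#' midrange estimate contribute midpoints. With `field = TRUE` a smooth
#' low-order polynomial surface is fitted to the per-crossing midpoints
#' instead, tracking slow illumination inhomogeneity.
#'
#' @param s Sum raster.
#' @param d Difference raster.
#' @param field Return a fitted per-pixel background surface instead of a
#'   scalar.
#' @param degree Polynomial degree of the background surface.
#' @return Scalar `2B`, or a matrix the size of `s` when `field = TRUE`.
#' @export
estimate_background <- function(s, d, field = FALSE, degree = 2L) {
  stopifnot(is.matrix(s), is.matrix(d), identical(dim(s), dim(d)))
  samp_x <- numeric(0); samp_y <- numeric(0); samp_v <- numeric(0)
  for (r in seq_len(nrow(d))) {
    pos <- zero_crossings(smooth3(d[r, ]))
    if (length(pos) < 2L) next
    sv <- stats::approx(seq_len(ncol(s)), s[r, ], xout = pos)$y
    samp_x <- c(samp_x, pos); samp_y <- c(samp_y, rep(r, length(pos)))
    samp_v <- c(samp_v, sv)
  }
  if (length(samp_v) < 2L)
    stop("insufficient fringes: too few difference zero-crossings ",
         "to estimate the background (try refine_background_by_steps)")
  # provisional midrange, then midpoints of straddling consecutive pairs only
  b0 <- mean(stats::quantile(samp_v, c(0.05, 0.95), names = FALSE))
  xs <- numeric(0); ys <- numeric(0); bs <- numeric(0)
  for (r in unique(samp_y)) {
    i <- which(samp_y == r)
    sv <- samp_v[i]; pos <- samp_x[i]
    if (length(sv) < 2L) next
    straddle <- (sv[-1] - b0) * (sv[-length(sv)] - b0) <= 0
    if (!any(straddle)) next
    mid <- ((sv[-1] + sv[-length(sv)]) / 2)[straddle]
    xm <- ((pos[-1] + pos[-length(pos)]) / 2)[straddle]
    xs <- c(xs, xm); ys <- c(ys, rep(r, length(mid))); bs <- c(bs, mid)
  }
  if (length(bs) < 1L) return(b0)
  if (!field) return(mean(bs))
  if (length(bs) < (degree + 1)^2)
    stop("too few crossings for a degree-", degree, " background surface")
  dat <- data.frame(b = bs, x = xs, y = ys)
  fit <- stats::lm(b ~ stats::poly(x, y, degree = degree, raw = TRUE),
                   data = dat)
  grid <- expand.grid(x = seq_len(ncol(s)), y = seq_len(nrow(s)))
  pred <- stats::predict(fit, newdata = grid)
  matrix(pred, nrow(s), ncol(s), byrow = TRUE)
}

#' Refine the background by minimising spurious thickness steps
#'
#' A mis-set background shifts the division image and makes the scan
#' misplace fringe assignments, which shows up as abrupt steps in the
#' reconstructed thickness. This refinement scans candidate `2B` values over
#' a span, reconstructs a probe region for each candidate, and scores the
#' number of pixel-to-pixel jumps larger than half a mode spacing; ties
#' (smooth scenes rarely produce whole-mode miscounts) are broken by the
#' total pixel-to-pixel roughness of the probe reconstruction, which a
#' mis-set background inflates through lookup distortion near the fringe
#' poles. If no candidate removes all spurious steps the best one is
#' returned with a warning.
#'
#' @param paired A frame pair (list with `I1`, `I2`).
#' @param lut A [build_lookup_from_ramp()] table.
#' @param initial Initial `2B` estimate.
#' @param span Relative search span; candidates cover
#'   `initial * (1 +/- span)`.
#' @param n_candidates Number of candidates across the span.
#' @param probe_rows Rows of the probe region (default: up to 8 rows spread
#'   over the image).
#' @return The refined scalar `2B`, with attribute `score` (residual step
#'   count).
#' @export
refine_background_by_steps <- function(paired, lut, initial, span = 0.15,
                                       n_candidates = 31L, probe_rows = NULL) {
  sd_ <- sum_diff(paired)
  ny <- nrow(sd_$sum)
  if (is.null(probe_rows))
    probe_rows <- unique(round(seq(1, ny, length.out = min(8L, ny))))
  cand <- initial * seq(1 - span, 1 + span, length.out = n_candidates)
  n_trans <- 0L
  score_one <- function(b2) {
    div <- division_image(sd_$sum, sd_$diff, b2)
    steps <- 0L
    rough <- 0
    for (r in probe_rows) {
      tr <- detect_fringe_transitions(div, r)
      n_trans <<- n_trans + nrow(tr)
      rec <- reconstruct_line(div$values[r, ], div$mode[r, ], div$mask[r, ],
                              tr, lut)
      jumps <- abs(diff(rec$values))
      steps <- steps + sum(jumps > lut$d_mode / 2, na.rm = TRUE)
      rough <- rough + sum(jumps, na.rm = TRUE)
    }
    c(steps, rough)
  }
  scores <- vapply(cand, score_one, numeric(2))
  if (n_trans == 0L) {
    warning("no fringe transitions in the probe region; ",
            "returning the initial background estimate")
    return(structure(initial, score = 0L))
  }
  best <- which(scores[1, ] == min(scores[1, ]))
  pick <- best[which.min(scores[2, best])]
  if (min(scores[1, ]) > 0)
    warning("no background candidate removes all spurious steps; ",
            "returning the best candidate")
  structure(cand[pick], score = scores[1, pick])
}

#' Build the division image
#'
#' Pixelwise `(sum - 2B) / difference`: the quantity whose cotangent-like
#' asymmetry encodes the direction of thickness change. Pixels where the
#' difference magnitude falls below `pole_frac` of its row-wise robust
#' maximum lie near a fringe zero; they are masked (`NA`) rather than
#' divided. Each unmasked pixel is assigned a mode class from the sign of
#' the difference image (positive = Mode 1, negative = Mode 2); the class is
#' constant between consecutive fringe transitions along a scan line.
#'
#' @param s Sum raster.
#' @param d Difference raster.
#' @param b2 Background `2B` (scalar or matrix).
#' @param pole_frac Pole-masking threshold as a fraction of the row-wise
#'   robust (98th percentile) difference magnitude.
#' @return An object of class `warp_division` with fields `values` (masked
#'   division raster), `mask`, `mode` (1/2/NA), `diff`, `sum`, `b2`.
#' @export
division_image <- function(s, d, b2, pole_frac = 0.05) {
  stopifnot(is.matrix(s), is.matrix(d), identical(dim(s), dim(d)),
            pole_frac > 0, pole_frac < 1)
  rmax <- apply(abs(d), 1L, stats::quantile, probs = 0.98, names = FALSE)
  if (max(rmax) <= 0) {                 # degenerate: no fringe signal at all
    mask <- matrix(TRUE, nrow(d), ncol(d))
  } else {
    rmax[rmax <= 0] <- max(rmax)        # fully flat rows: defer to global
    thresh <- matrix(pole_frac * rmax, nrow(d), ncol(d))
    mask <- abs(d) < thresh
  }
  vals <- (s - b2) / d
  vals[mask] <- NA_real_
  mode <- matrix(NA_integer_, nrow(d), ncol(d))
  mode[!mask & d > 0] <- 1L
  mode[!mask & d < 0] <- 2L
  structure(list(values = vals, mask = mask, mode = mode,
                 diff = d, sum = s, b2 = b2),
            class = "warp_division")
}

#' @export
print.warp_division <- function(x, ...) {
  cat(sprintf("Division image: %d x %d px, %.1f%% pole-masked\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$mask)))
  invisible(x)
}

# Core 1-D scan: fringe counting plus lookup fine displacement.
# Returns raw thickness-change values relative to an arbitrary per-line
# constant (one whole-mode counter anchored at the line start). Masked
# pixels are filled by linear interpolation and flagged.
reconstruct_line <- function(divv, modev, maskv, transitions, lut) {
  n <- length(divv)
  fine <- rep(NA_real_, n)
  unm <- which(!maskv)
  flags <- integer(n)                    # 0 ok, 1 interpolated, 2 clamped
  if (length(unm)) {
    fl <- lookup_apply(lut, divv[unm], modev[unm])
    fine[unm] <- fl
    cl <- attr(fl, "clamped")
    if (!is.null(cl)) flags[unm[cl]] <- 2L
  }
  k <- numeric(n)
  if (nrow(transitions)) {
    stp <- ifelse(transitions$direction == "pn", 1, -1) * lut$orientation
    for (j in seq_len(nrow(transitions))) {
      after <- seq_len(n) > transitions$position[j]
      k[after] <- k[after] + stp[j]
    }
  }
  vals <- k * lut$d_mode + fine
  if (anyNA(vals)) {
    ok <- which(!is.na(vals))
    if (length(ok) >= 2L) {
      nas <- which(is.na(vals))
      vals[nas] <- stats::approx(ok, vals[ok], xout = nas, rule = 2)$y
      flags[nas] <- 1L
    } else if (length(ok) == 1L) {
      vals[is.na(vals)] <- vals[ok]
      flags[is.na(fine)] <- 1L
    }
  }
  list(values = vals, flags = flags, k = k)
}

#' Reconstruct one row of a displacement map
#'
#' Scans a row left to right: the whole-mode displacement is tracked by
#' incrementing one counter at positive-to-negative division-sign
#' transitions and another at negative-to-positive ones (their signed sum,
#' times the mode spacing, is the coarse displacement; which direction
#' increments which counter follows the lookup table's calibrated
#' orientation), and the lookup table supplies the fine displacement within
#' the current mode. The row is reported relative to `d_offset`, the value
#' assigned to its seed pixel.
#'
#' @param div A [division_image()].
#' @param row Row index.
#' @param lut Lookup table from [build_lookup_from_ramp()].
#' @param d_offset Baseline displacement of the row's seed pixel (nm).
#' @param seed_col Column whose pixel carries `d_offset` (default 1).
#' @return List with `values` (nm) and integer `flags` (0 ok,
#'   1 interpolated, 2 lookup clamped).
#' @export
reconstruct_row <- function(div, row, lut, d_offset = 0, seed_col = 1L) {
  stopifnot(inherits(div, "warp_division"))
  tr <- detect_fringe_transitions(div, row)
  rec <- reconstruct_line(div$values[row, ], div$mode[row, ],
                          div$mask[row, ], tr, lut)
  list(values = rec$values - rec$values[seed_col] + d_offset,
       flags = rec$flags)
}

#' Reconstruct a displacement map from a frame pair
#'
#' Full WARP reconstruction: sum/difference images, background estimation
#' (unless `background` is supplied), division image, a single vertical scan
#' down the seed column to establish each row's baseline offset, a
#' horizontal scan per row, and finally rebaselining by subtracting the mean
#' over a declared flat reference region (an area of uniform cavity
#' thickness). Pole-masked pixels are filled by interpolation along their
#' row and flagged; their lookup values never seed an offset.
#'
#' @param paired One frame pair (element of [pair_frames()], or a list with
#'   `I1`, `I2`).
#' @param lut Lookup table built for the same cavity and wavelength pair.
#' @param pixel_size Pixel pitch in um.
#' @param flat_region Flat reference region `list(rows =, cols =)` (index
#'   vectors). When `NULL`, the lowest-variance block of a coarse grid is
#'   used if it is flat enough; otherwise an error asks for an explicit
#'   region.
#' @param background Optional known `2B`; estimated from the data when
#'   `NULL`.
#' @param refine Also run [refine_background_by_steps()] on the estimate.
#' @param field Estimate the background as a smooth surface rather than a
#'   scalar.
#' @param seed_col Column used for the vertical baseline scan.
#' @param pole_frac Pole-masking threshold, see [division_image()].
#' @return A [displacement_map()] (values in nm, negative = indentation).
#' @export
reconstruct_map <- function(paired, lut, pixel_size = attr(paired, "pixel_size"),
                            flat_region = NULL, background = NULL,
                            refine = FALSE, field = FALSE, seed_col = 1L,
                            pole_frac = 0.05) {
  if (inherits(paired, "warp_paired_list")) {
    if (is.null(pixel_size)) pixel_size <- attr(paired, "pixel_size")
    paired <- paired[[1L]]
  }
  stopifnot(is.matrix(paired$I1))
  if (is.null(pixel_size)) stop("'pixel_size' is required")
  sd_ <- sum_diff(paired)
  b2 <- background
  if (is.null(b2)) b2 <- estimate_background(sd_$sum, sd_$diff, field = field)
  if (refine && !is.matrix(b2))
    b2 <- as.numeric(refine_background_by_steps(paired, lut, b2))
  div <- division_image(sd_$sum, sd_$diff, b2, pole_frac = pole_frac)
  if (all(div$mask))
    stop("division image is fully pole-masked; cannot reconstruct")
  ny <- nrow(div$values); nx <- ncol(div$values)

  # vertical scan down the seed column -> per-row baseline offsets
  ctr <- detect_transitions_line(div$diff[, seed_col], div$values[, seed_col],
                                 div$mask[, seed_col])
  crec <- reconstruct_line(div$values[, seed_col], div$mode[, seed_col],
                           div$mask[, seed_col], ctr, lut)

  values <- matrix(NA_real_, ny, nx)
  flags <- matrix(0L, ny, nx)
  for (r in seq_len(ny)) {
    tr <- detect_fringe_transitions(div, r)
    rec <- reconstruct_line(div$values[r, ], div$mode[r, ], div$mask[r, ],
                            tr, lut)
    values[r, ] <- rec$values - rec$values[seed_col] + crec$values[r]
    flags[r, ] <- rec$flags
  }
  flags[crec$flags > 0, seed_col] <- pmax(flags[crec$flags > 0, seed_col], 1L)

  if (is.null(flat_region)) {
    flat_region <- auto_flat_region(values)
    if (is.null(flat_region))
      stop("no sufficiently flat reference area found; pass 'flat_region' ",
           "(list(rows =, cols =)) covering uniform cavity thickness")
  }
  base <- mean(values[flat_region$rows, flat_region$cols], na.rm = TRUE)
  values <- values - base
  displacement_map(values, pixel_size, flags = flags,
                   flat_region = flat_region, d_mode = lut$d_mode)
}

# pick the flattest block of a coarse grid; NULL if nothing is flat
auto_flat_region <- function(values, nblocks = 4L, max_sd = 5) {
  ny <- nrow(values); nx <- ncol(values)
  rb <- split(seq_len(ny), cut(seq_len(ny), nblocks, labels = FALSE))
  cb <- split(seq_len(nx), cut(seq_len(nx), nblocks, labels = FALSE))
  best <- NULL; best_sd <- Inf
  for (rr in rb) for (cc in cb) {
    s <- stats::sd(values[rr, cc], na.rm = TRUE)
    if (is.finite(s) && s < best_sd) {
      best_sd <- s
      best <- list(rows = rr, cols = cc)
    }
  }
  if (best_sd <= max_sd) best else NULL
}

#' 2x2 pixel binning
#'
#' Non-overlapping 2x2 block means, used to trade lateral resolution for
#' field of view and frame rate. Odd dimensions are padded by edge
#' replication (recorded in the `padded` attribute); the pixel size of any
#' derived map doubles.
#'
#' @param raster A numeric matrix.
#' @return The binned matrix (half dimensions, rounded up), with attribute
#'   `padded`.
#' @export
bin2x2 <- function(raster) {
  stopifnot(is.matrix(raster))
  ny <- nrow(raster); nx <- ncol(raster)
  padded <- (ny %% 2L != 0L) || (nx %% 2L != 0L)
  if (ny %% 2L) raster <- rbind(raster, raster[ny, , drop = FALSE])
  if (nx %% 2L) raster <- cbind(raster, raster[, ncol(raster), drop = FALSE])
  ny <- nrow(raster); nx <- ncol(raster)
  out <- (raster[seq(1, ny, 2), seq(1, nx, 2)] +
          raster[seq(2, ny, 2), seq(1, nx, 2)] +
          raster[seq(1, ny, 2), seq(2, nx, 2)] +
          raster[seq(2, ny, 2), seq(2, nx, 2)]) / 4
  attr(out, "padded") <- padded
  out
}
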