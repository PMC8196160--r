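# Synthetic scene generation: ground-truth displacement fields and their
# rendering into dual-wavelength interference frame stacks.
#
# Displacement sign convention: negative values indent into the cavity
# (cells pushing in); units nm. Lateral coordinates are in micrometres with
# the origin at the image corner; pixel (row r, col c) has centre
# ((c - 0.5) * pixel_size, (r - 0.5) * pixel_size).

#' Scene features
#'
#' Building blocks of a synthetic deformation scene. Depths are given as
#' positive indentation depths in nm for the indenting kinds
#' (`gaussian_indent`, `cylindrical_dimple`, `plateau`); the rendered field is
#' negative where the cavity is compressed. `ramp` interpolates the thickness
#' change linearly along one axis between two values (nm, signed), staying
#' constant outside the given range -- a wedge, as used for lookup-table
#' calibration.
#'
#' Each feature may move with a constant lateral `velocity` (um/s) and may be
#' gated to a time window `[t_on, t_off)`, which is how transient
#' micro-contraction events are seeded.
#'
#' @param centre Feature centre `c(x, y)` in um.
#' @param sigma Gaussian lateral scale in um.
#' @param depth Indentation depth in nm (positive indents).
#' @param radius Dimple (flat-punch) radius in um.
#' @param edge Edge softness of the dimple/plateau profile in um.
#' @param axis `"x"` or `"y"` for ramps.
#' @param from,to Axis positions (um) between which the ramp interpolates.
#' @param value_from,value_to Thickness change (nm, signed) at `from` / `to`.
#' @param rect Plateau rectangle `c(x0, y0, x1, y1)` in um.
#' @param velocity Lateral drift of the feature centre, `c(vx, vy)` um/s.
#' @param t_on,t_off Time window (s) in which the feature exists.
#' @param temporal_scaling Whether the scene's temporal model modulates this
#'   feature (`TRUE`) or it stays static (`FALSE`).
#' @return A list of class `warp_feature`.
#' @name scene_features
NULL

warp_feature <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "warp_feature")
}

#' @rdname scene_features
#' @export
feat_gaussian <- function(centre, sigma, depth, velocity = c(0, 0),
                          t_on = -Inf, t_off = Inf, temporal_scaling = TRUE) {
  stopifnot(length(centre) == 2L, sigma > 0)
  warp_feature("gaussian_indent", centre = centre, sigma = sigma,
               depth = depth, velocity = velocity, t_on = t_on, t_off = t_off,
               temporal_scaling = temporal_scaling)
}

#' @rdname scene_features
#' @export
feat_dimple <- function(centre, radius, depth, edge = 0.15, velocity = c(0, 0),
                        t_on = -Inf, t_off = Inf, temporal_scaling = TRUE) {
  stopifnot(length(centre) == 2L, radius > 0, edge > 0)
  warp_feature("cylindrical_dimple", centre = centre, radius = radius,
               depth = depth, edge = edge, velocity = velocity,
               t_on = t_on, t_off = t_off, temporal_scaling = temporal_scaling)
}

#' @rdname scene_features
#' @export
feat_ramp <- function(axis = c("x", "y"), from, to, value_from, value_to,
                      temporal_scaling = FALSE) {
  axis <- match.arg(axis)
  stopifnot(from < to)
  warp_feature("ramp", axis = axis, from = from, to = to,
               value_from = value_from, value_to = value_to,
               velocity = c(0, 0), t_on = -Inf, t_off = Inf,
               temporal_scaling = temporal_scaling)
}

#' @rdname scene_features
#' @export
feat_plateau <- function(rect, depth, edge = 0.3, velocity = c(0, 0),
                         t_on = -Inf, t_off = Inf, temporal_scaling = TRUE) {
  stopifnot(length(rect) == 4L, rect[1] < rect[3], rect[2] < rect[4])
  warp_feature("plateau", rect = rect, depth = depth, edge = edge,
               velocity = velocity, t_on = t_on, t_off = t_off,
               temporal_scaling = temporal_scaling)
}

#' Temporal models for a scene
#'
#' `temporal_static()` keeps all features constant. `temporal_periodic()`
#' modulates the temporally scaled features with a periodic contraction
#' waveform: `"sine"` gives `(1 - cos(2 pi f t)) / 2` (smooth contraction and
#' relaxation), `"pulse"` a raised-cosine pulse occupying the first `duty`
#' fraction of every period. `temporal_fluctuation()` modulates features with
#' a band-limited stochastic signal (a fixed sum of random-phase tones below
#' `bandwidth`), deterministic given the scene seed.
#'
#' @param frequency Contraction frequency in Hz.
#' @param waveform `"sine"` or `"pulse"`.
#' @param duty Fraction of the period occupied by a pulse.
#' @param amplitude Peak modulation amplitude (1 reproduces feature depths).
#' @param bandwidth Upper band edge of the fluctuation model (Hz).
#' @param sd Relative fluctuation strength around 1.
#' @param n_tones Number of random tones in the fluctuation model.
#' @return A list describing the temporal model.
#' @name scene_temporal
NULL

#' @rdname scene_temporal
#' @export
temporal_static <- function() list(kind = "static")

#' @rdname scene_temporal
#' @export
temporal_periodic <- function(frequency, waveform = c("sine", "pulse"),
                              duty = 0.25, amplitude = 1) {
  waveform <- match.arg(waveform)
  stopifnot(frequency > 0, duty > 0, duty <= 1)
  list(kind = "periodic", frequency = frequency, waveform = waveform,
       duty = duty, amplitude = amplitude)
}

#' @rdname scene_temporal
#' @export
temporal_fluctuation <- function(bandwidth, sd = 0.1, n_tones = 16L) {
  stopifnot(bandwidth > 0, sd >= 0)
  list(kind = "fluctuation", bandwidth = bandwidth, sd = sd,
       n_tones = as.integer(n_tones))
}

#' Specify a synthetic deformation scene
#'
#' A scene is a ground-truth displacement field (a set of features), a
#' temporal model, a camera-noise level, and an optional global lateral
#' drift used for motion-artefact experiments. All randomness (camera noise,
#' fluctuation phases) derives from `seed`, so identical specs render
#' identical stacks.
#'
#' Feature gradients should stay below about one fringe per four pixels
#' (`d_mode / (4 * pixel_size)` per um); steeper gradients underresolve the
#' fringe pattern and are only useful for failure-mode experiments.
#'
#' @param dim Image size `c(rows, cols)` in pixels.
#' @param pixel_size Pixel pitch in um (default 0.3, a typical 40x
#'   configuration; an assumption, not a measured value).
#' @param features List of [scene_features].
#' @param temporal A [scene_temporal] model.
#' @param noise_sd Additive zero-mean Gaussian camera noise s.d. (a.u.).
#' @param drift Global lateral drift `c(vx, vy)` in um/s.
#' @param seed Integer seed controlling all scene randomness.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(dim, pixel_size = 0.3, features = list(),
                       temporal = temporal_static(), noise_sd = 0,
                       drift = c(0, 0), seed = 1L) {
  stopifnot(length(dim) == 2L, all(dim >= 1), pixel_size > 0,
            noise_sd >= 0, length(drift) == 2L)
  if (!all(vapply(features, inherits, TRUE, "warp_feature")))
    stop("'features' must be a list of warp_feature objects")
  sp <- structure(list(dim = as.integer(dim), pixel_size = pixel_size,
                       features = features, temporal = temporal,
                       noise_sd = noise_sd, drift = drift,
                       seed = as.integer(seed)),
                  class = "scene_spec")
  if (identical(temporal$kind, "fluctuation")) {
    rs <- local_rng(seed + 77L)
    sp$temporal$freqs <- rs$runif(temporal$n_tones, 0, temporal$bandwidth)
    sp$temporal$phases <- rs$runif(temporal$n_tones, 0, 2 * pi)
  }
  sp
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("Synthetic scene: %d x %d px (%.2f um/px), %d feature(s)\n",
              x$dim[1], x$dim[2], x$pixel_size, length(x$features)))
  cat(sprintf("  temporal model: %s; noise sd %g a.u.; seed %d\n",
              x$temporal$kind, x$noise_sd, x$seed))
  invisible(x)
}

# deterministic local RNG that does not disturb the global stream
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  draw <- function(fun) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    assign(".Random.seed", env$state, envir = globalenv())
    out <- fun(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(runif = draw(stats::runif), rnorm = draw(stats::rnorm))
}

temporal_scale <- function(temporal, t) {
  switch(temporal$kind,
    static = 1,
    periodic = {
      f <- temporal$frequency
      if (temporal$waveform == "sine") {
        temporal$amplitude * (1 - cos(2 * pi * f * t)) / 2
      } else {
        u <- (f * t) %% 1
        ifelse(u < temporal$duty,
               temporal$amplitude * (1 - cos(2 * pi * u / temporal$duty)) / 2,
               0)
      }
    },
    fluctuation = {
      k <- length(temporal$freqs)
      1 + temporal$sd * sqrt(2 / k) *
        sum(cos(2 * pi * temporal$freqs * t + temporal$phases))
    },
    stop("unknown temporal model: ", temporal$kind)
  )
}

feature_field <- function(feat, xg, yg, t, drift) {
  if (t < feat$t_on || t >= feat$t_off) return(0)
  off <- feat$velocity * t + drift * t
  switch(feat$kind,
    gaussian_indent = {
      cx <- feat$centre[1] + off[1]; cy <- feat$centre[2] + off[2]
      r2 <- outer((yg - cy)^2, (xg - cx)^2, `+`)
      -feat$depth * exp(-r2 / (2 * feat$sigma^2))
    },
    cylindrical_dimple = {
      cx <- feat$centre[1] + off[1]; cy <- feat$centre[2] + off[2]
      r <- sqrt(outer((yg - cy)^2, (xg - cx)^2, `+`))
      -feat$depth * 0.5 * (1 - tanh((r - feat$radius) / feat$edge))
    },
    ramp = {
      g <- if (feat$axis == "x") xg + off[1] else yg + off[2]
      u <- pmin(pmax((g - feat$from) / (feat$to - feat$from), 0), 1)
      v <- feat$value_from + (feat$value_to - feat$value_from) * u
      if (feat$axis == "x") matrix(v, nrow = length(yg), ncol = length(xg),
                                   byrow = TRUE)
      else matrix(v, nrow = length(yg), ncol = length(xg))
    },
    plateau = {
      r <- feat$rect
      sx <- 0.5 * (tanh((xg - (r[1] + off[1])) / feat$edge) -
                   tanh((xg - (r[3] + off[1])) / feat$edge))
      sy <- 0.5 * (tanh((yg - (r[2] + off[2])) / feat$edge) -
                   tanh((yg - (r[4] + off[2])) / feat$edge))
      -feat$depth * outer(sy, sx)
    },
    stop("unknown feature kind: ", feat$kind)
  )
}

#' Ground-truth displacement field of a scene at time t
#'
#' Evaluates the analytic displacement field (nm; negative = indentation into
#' the cavity) of every active feature at time `t`, applying the temporal
#' model to features that opt into temporal scaling. Deterministic given the
#' scene seed.
#'
#' @param spec A [scene_spec()].
#' @param t Time in seconds.
#' @return A numeric matrix `spec$dim` of displacements in nm.
#' @export
make_displacement_truth <- function(spec, t = 0) {
  stopifnot(inherits(spec, "scene_spec"))
  ny <- spec$dim[1]; nx <- spec$dim[2]
  xg <- (seq_len(nx) - 0.5) * spec$pixel_size
  yg <- (seq_len(ny) - 0.5) * spec$pixel_size
  out <- matrix(0, ny, nx)
  if (!length(spec$features)) return(out)
  s <- temporal_scale(spec$temporal, t)
  for (feat in spec$features) {
    fld <- feature_field(feat, xg, yg, t, spec$drift)
    if (isTRUE(feat$temporal_scaling)) fld <- fld * s
    out <- out + fld
  }
  stopifnot(all(is.finite(out)))
  out
}

#' Render one monochromatic interference frame
#'
#' Per-pixel two-beam reflected intensity at thickness `d0 + truth`, using the
#' cavity's amplitude and background fields, plus additive zero-mean Gaussian
#' camera noise. Poisson shot noise is not modelled.
#'
#' @param cavity A [cavity_spec()].
#' @param truth Displacement field in nm (matrix, negative = indentation).
#' @param lambda Illumination wavelength in nm.
#' @param noise_sd Additive noise s.d. in camera units.
#' @param seed Optional integer seed for the noise draw; when `NULL` the
#'   current RNG stream is used.
#' @return Intensity raster (matrix, a.u.).
#' @export
render_frame <- function(cavity, truth, lambda, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(cavity, "cavity_spec"), is.matrix(truth),
            all(is.finite(truth)))
  d <- cavity$d0 + truth
  if (any(d <= 0)) stop("displacement exceeds the cavity thickness")
  img <- reflectance_two_beam(cavity, d, lambda)
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      rs <- local_rng(seed)
      img <- img + matrix(rs$rnorm(length(img), 0, noise_sd), nrow(img))
    } else {
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd), nrow(img))
    }
  }
  img
}

#' Render a wavelength-alternating frame stack
#'
#' Samples the scene at `1 / frame_rate` intervals and renders each frame at
#' alternating wavelengths (`lambda1` first), as an acquisition with two
#' toggled LEDs would. A drifting or beating scene therefore produces
#' genuinely different consecutive frames, which is what the motion-artefact
#' mitigation in [pair_frames()] is tested against.
#'
#' @param cavity A [cavity_spec()].
#' @param spec A [scene_spec()]; its seed drives the camera noise.
#' @param pair A [wavelength_pair()].
#' @param frame_rate Acquisition rate in Hz.
#' @param n_frames Number of frames (>= 2).
#' @return A [frame_stack()].
#' @export
render_alternating_stack <- function(cavity, spec, pair, frame_rate, n_frames) {
  stopifnot(inherits(cavity, "cavity_spec"), inherits(spec, "scene_spec"),
            inherits(pair, "wavelength_pair"), frame_rate > 0, n_frames >= 2)
  n_frames <- as.integer(n_frames)
  times <- (seq_len(n_frames) - 1L) / frame_rate
  wl <- rep(c(pair$lambda1, pair$lambda2), length.out = n_frames)
  rs <- local_rng(spec$seed)
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    truth <- make_displacement_truth(spec, times[i])
    img <- reflectance_two_beam(cavity, cavity$d0 + truth, wl[i])
    if (spec$noise_sd > 0)
      img <- img + matrix(rs$rnorm(length(img), 0, spec$noise_sd), nrow(img))
    frames[[i]] <- img
  }
  frame_stack(frames, wl, times, spec$pixel_size,
              meta = list(lambda1 = pair$lambda1, lambda2 = pair$lambda2,
                          refractive_index = cavity$n, d0 = cavity$d0,
                          frame_rate = frame_rate))
}
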