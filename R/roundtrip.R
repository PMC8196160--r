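# Standard synthetic validation scene and forward -> inverse round trip.

#' Standard validation scene
#'
#' The scene used throughout the package's self-checks: a calibration wedge
#' along the left quarter of the image (thickness rising linearly from
#' -400 nm to 0, spanning about 3.5 fringe modes), a 200 nm deep Gaussian
#' indentation (sigma 2 um) right of centre, and a flat reference area in
#' the upper right. Gradients stay below the fringe sampling cap.
#'
#' @param size Image size in pixels (square).
#' @param pixel_size Pixel pitch in um.
#' @param depth Gaussian indentation depth in nm.
#' @param sigma Gaussian lateral scale in um.
#' @param wedge_depth Thickness deficit at the left edge of the wedge (nm).
#' @param noise_sd Camera noise s.d. (a.u.).
#' @param seed Scene seed.
#' @return A [scene_spec()] with attributes `wedge_region` and
#'   `flat_region` (index lists).
#' @export
standard_scene <- function(size = 256L, pixel_size = 0.3, depth = 200,
                           sigma = 2, wedge_depth = 400, noise_sd = 0,
                           seed = 1L) {
  size <- as.integer(size)
  ext <- size * pixel_size
  sp <- scene_spec(c(size, size), pixel_size, features = list(
    feat_ramp("x", from = 0, to = 0.25 * ext, value_from = -wedge_depth,
              value_to = 0),
    feat_gaussian(centre = c(0.55 * ext, 0.5 * ext), sigma = sigma,
                  depth = depth)),
    noise_sd = noise_sd, seed = seed)
  attr(sp, "wedge_region") <-
    list(rows = seq_len(size),
         cols = seq(2L, max(3L, floor(0.24 * size))))
  attr(sp, "flat_region") <-
    list(rows = seq(max(1L, floor(0.05 * size)), floor(0.30 * size)),
         cols = seq(floor(0.75 * size), floor(0.95 * size)))
  sp
}

#' Forward--inverse round trip on the standard scene
#'
#' Renders the standard validation scene into an alternating stack, builds
#' the lookup table from the wedge region against the known truth,
#' reconstructs the displacement map, and returns everything needed to
#' score the round trip. This is the package's basic accuracy check: for a
#' noiseless scene the reconstruction should agree with the truth to
#' within a couple of nanometres RMS.
#'
#' @param size Image size in pixels.
#' @param noise_sd Camera noise s.d. in a.u. (the default fringe amplitude
#'   is 40 a.u., so 0.4 corresponds to 1 percent of the amplitude).
#' @param seed Scene seed.
#' @param pair [wavelength_pair()] to render with.
#' @param cavity [cavity_spec()] to render with.
#' @param n_frames Frames in the rendered stack.
#' @param ... Passed on to [standard_scene()].
#' @return List with the reconstructed `map`, rebaselined ground truth
#'   `truth_rel` (matrix, nm), the `lut`, the `scene`, the `stack`, the
#'   division image `div`, the estimated background `b2`, and the truth
#'   displacement field `truth`.
#' @export
roundtrip_scene <- function(size = 256L, noise_sd = 0, seed = 1L,
                            pair = wavelength_pair(628, 633),
                            cavity = cavity_spec(), n_frames = 5L, ...) {
  scene <- standard_scene(size = size, noise_sd = noise_sd, seed = seed, ...)
  stack <- render_alternating_stack(cavity, scene, pair,
                                    frame_rate = 100, n_frames = n_frames)
  paired <- pair_frames(stack)[[1]]
  truth <- make_displacement_truth(scene, paired$t)
  sd_ <- sum_diff(paired)
  b2 <- estimate_background(sd_$sum, sd_$diff)
  div <- division_image(sd_$sum, sd_$diff, b2)
  lut <- build_lookup_from_ramp(div, truth, pair, cavity$n, d0 = cavity$d0,
                                region = attr(scene, "wedge_region"))
  flat <- attr(scene, "flat_region")
  map <- reconstruct_map(paired, lut, pixel_size = scene$pixel_size,
                         flat_region = flat, background = b2)
  truth_rel <- truth - mean(truth[flat$rows, flat$cols])
  list(map = map, truth_rel = truth_rel, truth = truth, lut = lut,
       scene = scene, stack = stack, div = div, b2 = b2, cavity = cavity,
       pair = pair)
}
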