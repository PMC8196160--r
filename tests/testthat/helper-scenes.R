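# Shared fixtures: small cavities, wedge calibration scenes, and a cached
# medium-size round trip reused by several files.

test_cavity <- function(...) cavity_spec(...)
test_pair <- function() wavelength_pair(628, 633)

# render the two monochromatic frames of a static truth field
render_pair <- function(cavity, truth, pair, noise_sd = 0, seed = NULL) {
  list(I1 = render_frame(cavity, truth, pair$lambda1, noise_sd, seed),
       I2 = render_frame(cavity, truth, pair$lambda2, noise_sd,
                         if (!is.null(seed)) seed + 1L),
       t = 0)
}

# a horizontal wedge spanning `n_modes` fringe modes, one frame pair plus
# division image with the exact background; densely samples every mode
wedge_fixture <- function(n_modes = 2.5, ncols = 256L, nrows = 24L,
                          cavity = test_cavity(), pair = test_pair(),
                          noise_sd = 0, seed = 1L, build_lut = TRUE) {
  dm <- fringe_mode_spacing(pair, cavity$n)
  px <- 0.3
  sp <- scene_spec(c(nrows, ncols), px, features = list(
    feat_ramp("x", from = 0, to = ncols * px,
              value_from = -n_modes * dm, value_to = 0)),
    noise_sd = noise_sd, seed = seed)
  truth <- make_displacement_truth(sp, 0)
  pf <- render_pair(cavity, truth, pair, noise_sd = noise_sd,
                    seed = if (noise_sd > 0) seed)
  sd_ <- sum_diff(pf)
  div <- division_image(sd_$sum, sd_$diff, 2 * mean(cavity$B))
  lut <- if (build_lut)
    build_lookup_from_ramp(div, truth, pair, cavity$n, d0 = cavity$d0)
  list(scene = sp, truth = truth, paired = pf, div = div, lut = lut,
       d_mode = dm, cavity = cavity, pair = pair)
}

# cached 96 px standard-scene round trip (built once per test run)
.rt_cache <- new.env()
cached_roundtrip <- function() {
  if (is.null(.rt_cache$rt))
    .rt_cache$rt <- roundtrip_scene(size = 96L, noise_sd = 0, seed = 7L)
  .rt_cache$rt
}
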