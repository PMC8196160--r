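test_that("moving average is a shrinking-edge boxcar", {
  tr <- time_trace(rep(3.5, 200), 100)
  expect_equal(moving_average(tr, 0.5)$values, rep(3.5, 200))
  # 0.5 s at 100 Hz is a 50-sample boxcar: a unit impulse becomes a
  # rectangle of height 1/50
  imp <- time_trace(c(rep(0, 100), 1, rep(0, 99)), 100)
  ma <- moving_average(imp, 0.5)
  expect_equal(max(ma$values), 1 / 50)
  expect_equal(sum(ma$values > 0), 50L)
  expect_equal(length(ma$values), 200L)
  expect_error(moving_average(tr, 3), "longer than the trace")
  expect_error(moving_average(tr, 0.001), "2 samples")
})

test_that("spectral high-pass removes drift and preserves fast tones", {
  t <- seq(0, 40, by = 0.01)[-1]
  expect_equal(highpass(time_trace(rep(2, 400), 100), 0.2)$values,
               rep(0, 400), tolerance = 1e-12)
  tone <- highpass(time_trace(sin(2 * pi * 1 * t), 100), 0.2)
  expect_equal(max(abs(tone$values)), 1, tolerance = 0.01)
  drift <- highpass(time_trace(5 * sin(2 * pi * 0.05 * t), 100), 0.2)
  expect_gt(5 / max(abs(drift$values)), 100)
  expect_error(highpass(time_trace(1:10, 10), 6), "Nyquist")
  # filters commute on band-limited traces
  mixed <- time_trace(sin(2 * pi * 1 * t) + 0.5 * sin(2 * pi * 4 * t), 100)
  a <- moving_average(highpass(mixed, 0.2), 0.1)$values
  b <- highpass(moving_average(mixed, 0.1), 0.2)$values
  # the shrinking edge windows break exact commutation near the ends
  expect_lt(max(abs(a - b)[200:3800]), 0.01)
})

test_that("contraction detection recovers beat timing and amplitude", {
  expect_equal(nrow(detect_contractions(time_trace(rep(1, 100), 100))), 0L)
  # 3 Hz beats at 100 Hz sampling recover the frequency to within 1%
  t <- seq(0, 10, by = 0.01)
  tr <- time_trace((1 - cos(2 * pi * 3 * t))^3, 100)
  ev <- detect_contractions(tr, prominence = 0.2, min_separation = 0.2)
  expect_equal(mean(ev$frequency, na.rm = TRUE), 3, tolerance = 0.01)
  expect_true(all(diff(ev$time) > 0))
  # two identical peaks closer than the separation merge into one event
  v <- rep(0, 100); v[c(40, 45)] <- 1
  ev2 <- detect_contractions(time_trace(v, 100), min_separation = 0.1)
  expect_equal(nrow(ev2), 1L)
  # frequency estimates stay unbiased under timing jitter
  set.seed(3)
  beats <- cumsum(stats::rnorm(40, 1 / 3, 0.01))
  vt <- rep(0, 1500)
  vt[round(beats * 100)] <- 1
  vj <- stats::filter(vt, rep(1, 5), sides = 2)
  vj[is.na(vj)] <- 0
  evj <- detect_contractions(time_trace(as.numeric(vj), 100),
                             min_separation = 0.15)
  expect_equal(mean(evj$frequency, na.rm = TRUE), 3, tolerance = 0.03)
})

test_that("contraction statistics are exact on hand-computable events", {
  ev <- data.frame(time = c(1, 2, 3), value = c(5, 6, 7),
                   amplitude = c(1, 2, 3), frequency = c(NA, 1, 1))
  st <- contraction_stats(ev)
  expect_equal(st$amplitude$mean, 2)
  expect_equal(st$amplitude$sd, 1)       # n - 1 normalisation
  expect_equal(st$amplitude$cv, 0.5)
  expect_equal(st$frequency$cv, 0)
  # identical events: CV = 0 for both quantities
  ev0 <- data.frame(time = 1:5, value = 2, amplitude = 2,
                    frequency = c(NA, rep(1, 4)))
  st0 <- contraction_stats(ev0)
  expect_equal(st0$amplitude$cv, 0)
  expect_equal(st0$frequency$cv, 0)
  # CV is scale-invariant
  ev_s <- ev; ev_s$amplitude <- ev$amplitude * 17.3
  expect_equal(contraction_stats(ev_s)$amplitude$cv, st$amplitude$cv)
  # windowing and degenerate cases
  expect_error(contraction_stats(ev, window = c(0, 1.5)), "undefined stats")
  # simulated 10% frequency jitter yields CV near 0.1
  set.seed(5)
  freqs <- stats::rnorm(400, 3, 0.3)
  evj <- data.frame(time = seq_along(freqs), value = 1, amplitude = 1,
                    frequency = freqs)
  expect_equal(contraction_stats(evj)$frequency$cv, 0.1, tolerance = 0.02)
})

test_that("peak-volume vs frequency correlation respects the cap", {
  f <- seq(1, 6, length.out = 30)
  p <- 10 - 0.8 * f
  fit <- force_frequency_correlation(p, f, cap = 8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, -0.8, tolerance = 1e-9)
  # linear below the cap, decorrelated above: restricted fit recovers slope
  set.seed(9)
  f2 <- c(stats::runif(60, 1, 7.5), stats::runif(30, 8, 14))
  p2 <- ifelse(f2 < 8, 10 - 0.8 * f2 + stats::rnorm(90, 0, 0.2),
               stats::runif(90, 2, 10))
  fit2 <- force_frequency_correlation(p2, f2, cap = 8)
  expect_equal(fit2$slope, -0.8, tolerance = 0.1)
  expect_equal(fit2$n, sum(f2 < 8))
  expect_error(force_frequency_correlation(p2[f2 >= 8], f2[f2 >= 8], cap = 8),
               "undefined fit")
})

test_that("micro-contractions are caught at 100 fps and lost at 10 fps", {
  px <- 0.3
  mk_maps <- function(times) {
    spm <- scene_spec(c(64, 64), px, features = list(
      feat_dimple(centre = c(4, 9.6), radius = 0.8, depth = 25,
                  velocity = c(20, 0), t_on = 0.20, t_off = 0.28)))
    lapply(times, function(t)
      displacement_map(make_displacement_truth(spm, t), px))
  }
  # static stack: no events
  static <- lapply(1:20, function(i) displacement_map(matrix(0, 32, 32), px))
  ev0 <- micro_contraction_detect(static, seq(0, by = 0.01, length.out = 20))
  expect_equal(nrow(ev0), 0L)
  # 80 ms, 25 nm travelling dimple at 100 fps: one event, tight recovery
  t100 <- seq(0, 0.5, by = 0.01)
  ev <- micro_contraction_detect(mk_maps(t100), t100,
                                 depth_ceiling = 30, duration_ceiling = 0.1,
                                 detect_floor = 8)
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$depth_nm - 25), 5)
  expect_lte(abs(ev$duration_s - 0.08), 0.02)
  traj <- attr(ev, "trajectory")[[1]]
  expect_gt(max(traj$x) - min(traj$x), 1)   # the dimple travels
  # at 10 fps the same event is missed or mis-timed
  t10 <- seq(0, 0.5, by = 0.1)
  ev10 <- micro_contraction_detect(mk_maps(t10), t10,
                                   depth_ceiling = 30,
                                   duration_ceiling = 0.2,
                                   detect_floor = 8)
  expect_true(nrow(ev10) == 0L || abs(ev10$duration_s[1] - 0.08) > 0.015)
})
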