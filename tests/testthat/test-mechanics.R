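test_that("flat-punch force follows the contact law and its scalings", {
  sub <- elastic_substrate(5000, 0.5)
  expect_equal(punch_force(sub, 0.5, 1), 2 * 5000 / 0.75 * 0.5 * 1e-3,
               tolerance = 1e-12)            # ~6.67 pN
  expect_equal(punch_force(sub, 0.5, 0), 0)
  # bilinearity: doubling a and halving delta leaves F unchanged
  expect_equal(punch_force(sub, 1.0, 0.5), punch_force(sub, 0.5, 1))
  # separate linearity in E, a and delta over grids
  for (s in c(2, 5)) {
    expect_equal(punch_force(elastic_substrate(s * 5000, 0.5), 0.5, 1),
                 s * punch_force(sub, 0.5, 1))
    expect_equal(punch_force(sub, s * 0.5, 1), s * punch_force(sub, 0.5, 1))
    expect_equal(punch_force(sub, 0.5, s * 1), s * punch_force(sub, 0.5, 1))
  }
  expect_error(punch_force(sub, -1, 1), "positive")
  expect_error(punch_force(sub, 1, -1), "non-negative")
  expect_error(elastic_substrate(nu = 0.7))
})

test_that("podosome records gain consistent forces and stresses", {
  sub <- elastic_substrate(5000, 0.5)
  rec <- data.frame(label = 1:2, x = 0, y = 0, area_um2 = c(1, 2),
                    depth_nm = c(1, 0), force_pN = NA, stress_Pa = NA)
  rec <- podosome_forces(rec, sub)
  expect_equal(rec$force_pN[1], 7.52252778064, tolerance = 1e-9)
  expect_equal(rec$stress_Pa[1], rec$force_pN[1] / rec$area_um2[1])
  expect_equal(rec$force_pN[2], 0)
  expect_equal(rec$stress_Pa[2], 0)
  # a population following the linear force-area law with scatter lands
  # in the few-Pa stress band typical of podosomes
  set.seed(1)
  areas <- stats::runif(60, 0.1, 5)
  force <- 4 * areas * stats::runif(60, 0.5, 2.5)   # pN, linear law
  a_eff <- sqrt(areas / pi)
  depths <- force / (2 * sub$E / (1 - sub$nu^2) * a_eff * 1e-3)
  pop <- podosome_forces(
    data.frame(label = 1:60, x = 0, y = 0, area_um2 = areas,
               depth_nm = depths, force_pN = NA, stress_Pa = NA), sub)
  expect_equal(pop$force_pN, force, tolerance = 1e-9)
  expect_true(all(pop$stress_Pa > 1 & pop$stress_Pa < 15.001))
  expect_true(all(pop$force_pN > 0.01 & pop$force_pN < 55))
})

test_that("spatial band-pass keeps the band and rejects bowl and DC", {
  px <- 0.15
  expect_equal(bandpass_spatial(matrix(5, 32, 32), 0.5, 5, pixel_size = px),
               matrix(0, 32, 32), tolerance = 1e-12)
  # integer-period in-band tone preserved within 5%
  ny <- 128
  tone <- matrix(sin(2 * pi * (1:ny) / 16), ny, ny)   # 2.4 um wavelength
  bt <- bandpass_spatial(tone, 0.5, 5, pixel_size = px)
  expect_equal(max(abs(bt)), 1, tolerance = 0.05)
  # broad bowl suppressed > 10x while dimple depth survives within 20%
  sp <- scene_spec(c(256, 256), px, features = list(
    feat_gaussian(centre = c(19.2, 19.2), sigma = 8, depth = 300),
    feat_dimple(centre = c(10, 10), radius = 0.5, depth = 30)))
  both <- make_displacement_truth(sp, 0)
  bowl <- make_displacement_truth(
    scene_spec(c(256, 256), px, features = sp$features[1]), 0)
  bp_bowl <- bandpass_spatial(bowl, 0.5, 5, pixel_size = px)
  expect_gt(max(abs(bowl)) / max(abs(bp_bowl)), 10)
  bp <- bandpass_spatial(both, 0.5, 5, pixel_size = px)
  dimple_zone <- as.matrix(expand.grid(60:74, 60:74))
  expect_equal(-min(bp[dimple_zone]), 30, tolerance = 0.2)
  expect_error(bandpass_spatial(tone, 0.2, 5, pixel_size = px), "two pixels")
  expect_error(bandpass_spatial(tone, 5, 0.5, pixel_size = px), "exceed")
})

test_that("segmentation finds seeded dimples and merges unresolved pairs", {
  px <- 0.15
  centres <- list(c(5, 5), c(13, 5), c(21, 5), c(29, 5),
                  c(5, 15), c(13, 15), c(21, 15))
  sp <- scene_spec(c(256, 256), px, features = c(list(
    feat_gaussian(centre = c(19.2, 19.2), sigma = 8, depth = 300)),
    lapply(centres, function(cc)
      feat_dimple(centre = cc, radius = 0.5, depth = 25))))
  m <- displacement_map(make_displacement_truth(sp, 0), px)
  bp <- bandpass_spatial(m, 0.5, 5)
  recs <- segment_podosomes(bp, depth_threshold = 8, min_area = 0.1,
                            depth_map = m)
  expect_equal(nrow(recs), 7L)
  # each seeded centre has exactly one record within a pixel of it
  for (cc in centres) {
    dist <- sqrt((recs$x - cc[1])^2 + (recs$y - cc[2])^2)
    expect_equal(sum(dist < 1), 1L)
    expect_lt(min(dist), px)
  }
  # flat map: no records
  expect_equal(nrow(segment_podosomes(
    displacement_map(matrix(0, 32, 32), px), 5)), 0L)
  # two dimples below the resolution merge into one record
  sp2 <- scene_spec(c(128, 128), px, features = list(
    feat_dimple(centre = c(9.0, 9.6), radius = 0.5, depth = 25),
    feat_dimple(centre = c(10.0, 9.6), radius = 0.5, depth = 25)))
  m2 <- displacement_map(make_displacement_truth(sp2, 0), px)
  expect_equal(nrow(segment_podosomes(m2, 8)), 1L)
})

test_that("force-area regression behaves on clean, noisy and degenerate data", {
  set.seed(7)
  areas <- stats::runif(81, 0.1, 5)
  # exact linear law: R^2 = 1
  exact <- data.frame(area_um2 = areas, force_pN = 2 + 3 * areas)
  fit <- force_area_fit(exact, min_area = 0.7)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 3, tolerance = 1e-9)
  # 10% multiplicative noise at n = 81 keeps R^2 above 0.8
  noisy <- data.frame(area_um2 = areas,
                      force_pN = (2 + 3 * areas) *
                        (1 + stats::rnorm(81, 0, 0.1)))
  expect_gt(force_area_fit(noisy, min_area = 0.7)$r_squared, 0.8)
  # all records below the cut
  expect_error(force_area_fit(exact[exact$area_um2 < 0.7, ], min_area = 0.7),
               "undefined fit")
  expect_error(force_area_fit(
    data.frame(area_um2 = rep(2, 5), force_pN = 1:5)), "undefined fit")
})

test_that("indented volume integrates indentation only, additively", {
  px <- 0.1
  # uniform -10 nm over 100 um^2 is 1 um^3
  m <- displacement_map(matrix(-10, 100, 100), px)
  expect_equal(indented_volume(m), 1)
  # positive (upward) displacement contributes nothing
  expect_equal(indented_volume(displacement_map(matrix(4, 50, 50), px)), 0)
  # Gaussian indentation integrates to ~ 2 pi sigma^2 h
  spv <- scene_spec(c(400, 400), px, features = list(
    feat_gaussian(centre = c(20, 20), sigma = 2, depth = 50)))
  mg <- displacement_map(make_displacement_truth(spv, 0), px)
  expect_equal(indented_volume(mg), 2 * pi * 4 * 0.05, tolerance = 0.02)
  # additive over disjoint regions
  left <- list(rows = 1:400, cols = 1:200)
  right <- list(rows = 1:400, cols = 201:400)
  expect_equal(indented_volume(mg, left) + indented_volume(mg, right),
               indented_volume(mg))
  # stable under 2x2 binning within 2%
  mb <- displacement_map(bin2x2(mg$values), 2 * px)
  expect_equal(indented_volume(mb), indented_volume(mg), tolerance = 0.02)
})

test_that("punch forces recovered from seeded scenes track the truth", {
  set.seed(11)
  sub <- elastic_substrate(5000, 0.5)
  px <- 0.15
  truth_f <- c(); est_f <- c()
  for (k in 1:12) {
    n_pod <- sample(3:5, 1)
    feats <- list(feat_gaussian(centre = c(19.2, 19.2), sigma = 8,
                                depth = stats::runif(1, 80, 150)))
    pods <- data.frame(x = stats::runif(n_pod, 4, 16),
                       y = sample(seq(4, 34, by = 4), n_pod),
                       r = stats::runif(n_pod, 0.4, 1.1),
                       depth = stats::runif(n_pod, 10, 28))
    for (i in seq_len(n_pod))
      feats <- c(feats, list(feat_dimple(centre = c(pods$x[i], pods$y[i]),
                                         radius = pods$r[i],
                                         depth = pods$depth[i])))
    sp <- scene_spec(c(256, 256), px, features = feats, seed = k)
    m <- displacement_map(make_displacement_truth(sp, 0), px)
    bp <- bandpass_spatial(m, 0.5, 5)
    recs <- segment_podosomes(bp, depth_threshold = 6, min_area = 0.1,
                              depth_map = m)
    recs <- podosome_forces(recs, sub)
    for (i in seq_len(n_pod)) {
      j <- which((recs$x - pods$x[i])^2 + (recs$y - pods$y[i])^2 < 1)
      if (length(j) == 1L) {
        truth_f <- c(truth_f, punch_force(sub, pods$r[i], pods$depth[i]))
        est_f <- c(est_f, recs$force_pN[j])
      }
    }
  }
  expect_gt(length(truth_f), 30L)
  expect_gt(stats::cor(truth_f, est_f)^2, 0.9)
})
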