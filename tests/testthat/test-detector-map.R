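# pixel-grid annulus helpers used to build maps with known properties
grid_radii <- function(n) {
  ctr <- (n + 1) / 2
  x <- matrix(rep(seq_len(n), each = n), n) - ctr
  y <- matrix(rep(seq_len(n), n), n) - ctr
  list(r = sqrt(x^2 + y^2), az = (atan2(y, x) * 180 / pi) %% 360)
}

annulus_map <- function(n = 256, r_in = 40, r_out = 100, bg = 10,
                        active = 30, sens = NULL) {
  g <- grid_radii(n)
  inside <- g$r >= r_in & g$r < r_out
  m <- matrix(bg, n, n)
  s <- if (is.null(sens)) 1 else sens(g$r[inside], g$az[inside])
  m[inside] <- bg + (active - bg) * s
  m
}

test_that("active region is the midpoint-thresholded set", {
  m <- annulus_map(128, 20, 50, bg = 0, active = 1)
  expect_identical(active_region_mask(m), m == 1)
  m2 <- annulus_map(128, 20, 50, bg = 10, active = 30)
  expect_identical(active_region_mask(m2), m2 > 20)
  expect_error(active_region_mask(matrix(5, 64, 64)), "degenerate")
})

test_that("a hot pixel empties the plain mask but not the robust one", {
  m <- annulus_map(128, 20, 50, bg = 10, active = 30)
  m[64, 64] <- 100   # hot pixel in the central hole
  plain <- active_region_mask(m)
  expect_identical(sum(plain), 1L)         # threshold 55: hot pixel only
  robust <- active_region_mask(m, robust = TRUE)
  expect_gt(sum(robust), 1000)             # annulus recovered
})

test_that("normalization maps background to 0 and active mean to 1", {
  m <- annulus_map(128, 20, 50, bg = 10, active = 30)
  mask <- active_region_mask(m)
  nm <- normalize_map(m, mask)
  expect_true(all(nm[!mask] == 0))
  expect_true(all(nm[mask] == 1))
  # idempotence on an already-normalized map
  expect_equal(normalize_map(nm, mask), nm)
  # a radial gradient still averages exactly 1 over the active region
  mg <- annulus_map(128, 20, 50, sens = function(r, az) {
    1 + 0.2 * (r - 35) / 30
  })
  maskg <- active_region_mask(mg)
  expect_equal(mean(normalize_map(mg, maskg)[maskg]), 1)
})

test_that("ellipticity recovers constructed hole axis ratios", {
  n <- 256
  g <- grid_radii(n)
  ctr <- (n + 1) / 2
  x <- matrix(rep(seq_len(n), each = n), n) - ctr
  y <- matrix(rep(seq_len(n), n), n) - ctr
  # circular hole
  mask_c <- g$r >= 40 & g$r < 100
  expect_lt(abs(ellipticity(mask_c)$ratio - 1), 0.01)
  # elliptical hole, semi-axes 40 and 20 px (diameters 80 / 40)
  hole <- (x / 40)^2 + (y / 20)^2 < 1
  mask_e <- g$r < 100 & !hole
  e <- ellipticity(mask_e)
  expect_lt(abs(e$ratio - 2), 2 * 0.02)
  expect_lt(abs(e$major - 80) / 80, 0.02)
  # rotated by 30 degrees: ratio is rotation invariant
  th <- 30 * pi / 180
  xr <- x * cos(th) + y * sin(th)
  yr <- -x * sin(th) + y * cos(th)
  hole_r <- (xr / 40)^2 + (yr / 20)^2 < 1
  er <- ellipticity(g$r < 100 & !hole_r)
  expect_lt(abs(er$ratio - 2), 2 * 0.02)
  # a filled disk has no enclosed opening
  expect_error(ellipticity(g$r < 100), "opening")
})

test_that("flatness is zero for uniform maps and matches a known ramp", {
  m <- annulus_map()
  q <- detector_qc(m)
  expect_equal(q$flatness_score, 0)
  # linear radial ramp: score equals the quadrature RMS of the
  # normalized ramp over the valid radial range
  a <- 0.2; r_in <- 40; r_out <- 100; r_mid <- 70
  mr <- annulus_map(sens = function(r, az) {
    1 + a * (r - r_mid) / (r_out - r_in)
  })
  qr <- detector_qc(mr)
  s_fun <- function(r) 1 + a * (r - r_mid) / (r_out - r_in)
  # area-weighted active mean (normalization divisor)
  mu <- stats::integrate(function(r) s_fun(r) * 2 * pi * r, r_in,
                         r_out)$value /
    stats::integrate(function(r) 2 * pi * r, r_in, r_out)$value
  rms <- sqrt(stats::integrate(function(r) (s_fun(r) / mu - 1)^2,
                               qr$r_in, qr$r_out)$value /
                (qr$r_out - qr$r_in))
  expect_lt(abs(qr$flatness_score - rms) / rms, 0.05)
})

test_that("dead wedges hit roundness but leave flatness untouched", {
  m <- annulus_map(sens = function(r, az) ifelse(az < 20, 0, 1))
  q <- detector_qc(m)
  expect_lt(q$flatness_score, 0.01)
  expect_gt(q$roundness_score, 0.1)
})

test_that("roundness matches analytic scores for known azimuth patterns", {
  # half-sensitivity 20 degree wedge: profile dips to ~0.5 there
  mw <- annulus_map(sens = function(r, az) ifelse(az < 20, 0.5, 1))
  qw <- detector_qc(mw)
  dip <- qw$roundness$profile[1:20]
  expect_lt(max(abs(dip - 0.5)), 0.05)
  rms_w <- sqrt(20 / 360 * 0.5^2)
  expect_lt(abs(qw$roundness_score - rms_w) / rms_w, 0.05)
  # sinusoidal sensitivity 1 + 0.1 sin(az): RMS = 0.1/sqrt(2)
  ms <- annulus_map(sens = function(r, az) 1 + 0.1 * sin(az * pi / 180))
  qs <- detector_qc(ms)
  expect_lt(abs(qs$roundness_score - 0.1 / sqrt(2)) / (0.1 / sqrt(2)),
            0.05)
})

test_that("smoothness measures pixel-level dispersion", {
  m <- annulus_map()
  mask <- active_region_mask(m)
  expect_equal(smoothness(normalize_map(m, mask), mask), 0)
  # one dead pixel among n active: score ~ sqrt(1/n)
  g <- grid_radii(256)
  mask_a <- g$r >= 40 & g$r < 60
  m1 <- matrix(0, 256, 256)
  m1[mask_a] <- 1
  dead <- which(mask_a)[123]
  m1[dead] <- 0
  nm1 <- normalize_map(m1, mask_a)
  n_act <- sum(mask_a)
  expect_lt(abs(smoothness(nm1, mask_a) - sqrt(1 / n_act)) /
              sqrt(1 / n_act), 0.05)
})

test_that("smoothness recovers injected pixel noise", {
  g <- annulus_geometry()
  m <- synth_detector_map(g, n = 256, noise_sd = 0.05, seed = 3)
  q <- detector_qc(m)
  expect_lt(abs(q$smoothness_score - 0.05) / 0.05, 0.10)
})

test_that("ideal synthetic detectors score (1, 0, 0, 0)", {
  q <- detector_qc(synth_detector_map(annulus_geometry(), n = 256))
  expect_lt(abs(q$ellipticity - 1), 0.01)
  expect_lt(q$flatness_score, 0.005)
  expect_lt(q$roundness_score, 0.005)
  expect_lt(q$smoothness_score, 0.005)
})

test_that("injected ellipticity round-trips through the QC analysis", {
  m <- synth_detector_map(annulus_geometry(), n = 256, ellipticity = 1.5)
  expect_lt(abs(detector_qc(m)$ellipticity - 1.5) / 1.5, 0.02)
})

test_that("segment gaps make roundness worse than flatness", {
  g6 <- geometry_quadrants_rings(gap = 4)
  m <- synth_detector_map(g6, n = 256)
  q <- detector_qc(m)
  expect_gt(q$roundness_score, q$flatness_score)
})

test_that("the QC report is invariant to intensity rescaling", {
  m <- synth_detector_map(annulus_geometry(), n = 128,
                          az_amplitude = 0.05, noise_sd = 0.02, seed = 9)
  q1 <- detector_qc(m)
  q2 <- detector_qc(m * 37.5)
  for (f in c("ellipticity", "flatness_score", "roundness_score",
              "smoothness_score")) {
    expect_equal(q1[[f]], q2[[f]], tolerance = 1e-12)
  }
})

test_that("rotating the map 90 degrees permutes azimuths, not scores", {
  m <- synth_detector_map(annulus_geometry(), n = 128,
                          az_amplitude = 0.1, seed = 4)
  m90 <- t(m)[, ncol(m):1]   # 90 degree rotation
  q <- detector_qc(m)
  q90 <- detector_qc(m90)
  expect_lt(abs(q$roundness_score - q90$roundness_score), 0.005)
  expect_lt(abs(q$flatness_score - q90$flatness_score), 0.005)
  expect_lt(abs(q$smoothness_score - q90$smoothness_score), 0.005)
  expect_lt(abs(q$ellipticity - q90$ellipticity), 0.02)
  # the sinusoidal peak moves by a quarter turn
  peak <- which.max(q$roundness$profile)
  peak90 <- which.max(q90$roundness$profile)
  shift <- (peak90 - peak) %% 360
  expect_lt(min(abs(shift - 90), abs(shift - 270)), 15)
})
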