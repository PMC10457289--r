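test_that("Poisson arrival sampling has the contracted statistics", {
  expect_identical(sample_poisson_events(0, 10, seed = 1), numeric(0))
  expect_error(sample_poisson_events(-1, 10), "non-negative")
  # determinism
  expect_identical(sample_poisson_events(5, 100, seed = 7),
                   sample_poisson_events(5, 100, seed = 7))
  # mean count at the reference beam rate
  counts <- vapply(1:200, function(i) {
    length(sample_poisson_events(3.75, 1000, seed = i))
  }, numeric(1))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 3750), 3 * se)
})

test_that("per-trace event counts are Poisson (variance ~ mean)", {
  counts <- vapply(1:500, function(i) {
    length(sample_poisson_events(3.75, 20, seed = 1000 + i))
  }, numeric(1))
  r <- stats::var(counts) / mean(counts)
  expect_gt(r, 0.9)
  expect_lt(r, 1.1)
})

test_that("pulse heights are truncated-Gaussian with the stated moments", {
  expect_identical(sample_heights(5, cv = 0), rep(1, 5))
  expect_identical(sample_heights(0), numeric(0))
  h <- sample_heights(1e5, cv = 0.2, seed = 3)
  expect_true(all(h > 0))
  expect_lt(abs(mean(h) - 1), 0.01)
})

test_that("segment assignment covers and loses events correctly", {
  prof <- radial_profile_powerlaw(30, 110)
  geom1 <- annulus_geometry(30, 110)
  ids <- assign_segments(1000, geom1, prof, seed = 2)
  expect_true(all(ids == 0L))

  # steeply falling profile: inner quadrants outnumber the outer rings
  geom6 <- geometry_quadrants_rings()
  prof6 <- radial_profile_powerlaw(30, 120)
  ids6 <- assign_segments(1e5, geom6, prof6, seed = 2)
  inner <- sum(ids6 %in% 0:3)
  outer <- sum(ids6 %in% 4:5)
  expect_gt(inner, outer)

  # a 10 degree azimuthal gap loses ~10/360 of a uniform dose
  gap_geom <- detector_geometry(data.frame(
    r_in = 40, r_out = 100, az_start = 10, az_end = 360))
  prof_u <- radial_profile(c(40, 100), c(1, 1))
  ids_g <- assign_segments(1e5, gap_geom, prof_u, seed = 4)
  lost <- mean(ids_g == -1L)
  expect_lt(abs(lost - 10 / 360), 3 * sqrt(10 / 360 * 350 / 360 / 1e5) + 1e-3)
})

test_that("landing azimuths are uniform (chi-square on wedge counts)", {
  wedges <- do.call(rbind, lapply(0:35, function(i) {
    data.frame(r_in = 40, r_out = 100, az_start = i * 10,
               az_end = (i + 1) * 10)
  }))
  geom <- detector_geometry(wedges)
  prof <- radial_profile(c(40, 100), c(1, 1))
  ids <- assign_segments(1e5, geom, prof, seed = 9)
  tab <- tabulate(ids + 1L, 36)
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.01)
})

test_that("radial draws follow the weighted profile", {
  # two shells of equal width, weights 3:1 -> expected 3:1 occupancy
  geom <- detector_geometry(data.frame(
    r_in = c(40, 70), r_out = c(70, 100), az_start = 0, az_end = 360))
  prof <- radial_profile(c(40, 70 - 1e-9, 70, 100), c(3, 3, 1, 1))
  ids <- assign_segments(4e4, geom, prof, seed = 5)
  frac_inner <- mean(ids == 0L)
  expect_lt(abs(frac_inner - 0.75), 0.01)
})

test_that("invalid geometries and profiles are rejected", {
  expect_error(detector_geometry(data.frame(
    r_in = c(10, 15), r_out = c(20, 25), az_start = 0, az_end = 360)),
    "overlap")
  expect_error(radial_profile(c(1, 2), c(0, 0)), "zero")
  expect_error(assign_segments(10, annulus_geometry(30, 110),
                               radial_profile(c(50, 60), c(1, 1))),
               "cover")
})

test_that("trace synthesis is exact linear superposition on the clock grid", {
  k <- scint_kernel()
  # no events: flat baseline
  tr0 <- synthesize_trace(event_stream(numeric(0), duration = 10), k,
                          baseline = 0.5)
  expect_true(all(tr0$samples == 0.5))
  # single event of height h peaks at exactly h above baseline
  tr1 <- synthesize_trace(event_stream(1, heights = 0.7, duration = 10), k,
                          baseline = 0.2)
  expect_equal(max(tr1$samples) - 0.2, 0.7)
  # two coincident events equal one event of the summed height
  tr2 <- synthesize_trace(
    event_stream(c(1, 1), heights = c(0.3, 0.4), duration = 10), k)
  expect_equal(tr2$samples, tr1$samples - 0.2, tolerance = 1e-12)
  expect_error(synthesize_trace(event_stream(5, duration = 5), k,
                                duration = 2), "beyond")
})

test_that("superposition splits across disjoint event subsets", {
  k <- ss_kernel()
  set.seed(11)
  tA <- sort(stats::runif(20, 0, 50))
  tB <- sort(stats::runif(15, 0, 50))
  hA <- sample_heights(20, seed = 1)
  hB <- sample_heights(15, seed = 2)
  both <- order(c(tA, tB))
  trAB <- synthesize_trace(event_stream(c(tA, tB)[both],
                                        c(hA, hB)[both], duration = 60), k)
  trA <- synthesize_trace(event_stream(tA, hA, duration = 60), k)
  trB <- synthesize_trace(event_stream(tB, hB, duration = 60), k)
  expect_equal(trAB$samples, trA$samples + trB$samples, tolerance = 1e-12)
})

test_that("FFT and direct superposition paths agree", {
  k <- ss_kernel()
  set.seed(12)
  t_few <- sort(stats::runif(50, 0, 100))
  h <- sample_heights(50, seed = 3)
  direct <- synthesize_trace(event_stream(t_few, h, duration = 110), k)
  # force the FFT path by padding with far-away events, then compare
  # the shared region against the direct loop
  t_pad <- sort(stats::runif(400, 500, 1000))
  all_ev <- event_stream(c(t_few, t_pad), c(h, rep(1, 400)),
                         duration = 1010)
  fftd <- synthesize_trace(all_ev, k, duration = 1010)
  n <- length(direct$samples)
  expect_equal(fftd$samples[seq_len(n)], direct$samples,
               tolerance = 1e-9)
})

test_that("ADC quantization clips, scales and marks the trace", {
  tr <- structure(list(samples = rep(1, 100), sample_period = 8,
                       baseline = 0, adc_bits = NULL, adc_range = NULL),
                  class = "analog_trace")
  q <- quantize_adc(tr, bits = 14, adc_range = 2)
  expect_true(all(q$samples == 8192))
  expect_identical(q$adc_bits, 14L)
  tr$samples <- rep(5, 100)
  expect_true(all(quantize_adc(tr, 14, 2)$samples == 16383))
  expect_true(all(quantize_adc(tr, 1, 2)$samples %in% c(0, 1)))
})
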