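test_that("finite gradient is the lagged difference, length preserved", {
  expect_identical(finite_gradient(rep(2, 10), 3), rep(0, 10))
  # linear ramp of slope m at lag k gives m*k
  m <- 0.25; klag <- 4
  g <- finite_gradient(m * (0:19), klag)
  expect_equal(g[(klag + 1):20], rep(m * klag, 20 - klag))
  expect_identical(g[1:klag], rep(0, klag))
  # random trace against elementwise brute force
  set.seed(21)
  x <- stats::rnorm(200)
  g3 <- finite_gradient(x, 3)
  brute <- c(0, 0, 0, x[4:200] - x[1:197])
  expect_equal(g3, brute)
  expect_error(finite_gradient(1:5, 5), "smaller")
})

test_that("a clean pulse yields one event at the first crossing sample", {
  k <- scint_kernel()
  tr <- synthesize_trace(event_stream(2, duration = 10), k)
  cfg <- discriminator_config("amplitude", 0.5,
                              min_consecutive_above = 1,
                              min_consecutive_below = 1, dead_time = 0)
  det <- discriminate(tr, cfg)
  expect_identical(det$n_detected, 1L)
  expect_identical(det$event_sample_indices,
                   which(tr$samples > 0.5)[1])
})

test_that("well-separated pulses are counted individually", {
  k <- scint_kernel()
  tr <- synthesize_trace(event_stream(c(2, 8), duration = 15), k)
  for (mode in c("amplitude", "gradient")) {
    thr <- 0.5 * working_peak(k, mode)
    det <- discriminate(tr, discriminator_config(mode, thr))
    expect_identical(det$n_detected, 2L)
  }
})

test_that("gradient mode resolves pulses on an afterglow ramp that
           amplitude mode merges", {
  # one pulse of height 0.4 on a slow 0.3->0.5 ramp, threshold 0.6:
  # amplitude mode triggers late (where ramp+pulse crosses 0.6);
  # gradient mode triggers on the rising edge
  tr1 <- afterglow_ramp_trace(n_pulses = 1)
  amp <- discriminator_config("amplitude", 0.6,
                              min_consecutive_above = 1,
                              min_consecutive_below = 1)
  grad <- discriminator_config("gradient", 0.2, gradient_lag = 4,
                               min_consecutive_above = 1,
                               min_consecutive_below = 1)
  da1 <- discriminate(tr1, amp)
  dg1 <- discriminate(tr1, grad)
  expect_identical(da1$n_detected, 1L)
  expect_identical(dg1$n_detected, 1L)
  # gradient event sits on the rising edge (within lag+2 of onset at 100)
  expect_lt(abs(dg1$event_sample_indices - 100), 7)
  # amplitude event is late: pulse onset + crossing of the ramp
  expect_gt(da1$event_sample_indices, 100)

  # two pulses: amplitude mode stays above threshold and merges to 1;
  # gradient mode resolves both
  tr2 <- afterglow_ramp_trace(n_pulses = 2)
  expect_identical(discriminate(tr2, amp)$n_detected, 1L)
  expect_identical(discriminate(tr2, grad)$n_detected, 2L)
  # cross-check both fixtures against the reference implementation
  expect_identical(discriminate(tr2, amp)$event_sample_indices,
                   ref_discriminate(tr2$samples, 0.6))
  expect_identical(discriminate(tr2, grad)$event_sample_indices,
                   ref_discriminate(finite_gradient(tr2$samples, 4), 0.2))
})

test_that("compiled state machine matches the reference on random traces", {
  set.seed(31)
  for (i in 1:40) {
    x <- stats::rnorm(300)
    above <- sample(1:3, 1)
    below <- sample(1:3, 1)
    dead <- sample(0:5, 1)
    hyst <- sample(c(0, 0.2), 1)
    cfg <- discriminator_config("amplitude", 0.8,
                                min_consecutive_above = above,
                                min_consecutive_below = below,
                                dead_time = dead, hysteresis = hyst)
    got <- discriminate(x, cfg)$event_sample_indices
    want <- ref_discriminate(x, 0.8, above, below, dead, hyst)
    expect_identical(got, want)
    # dead-time contract
    if (length(got) > 1) expect_true(all(diff(got) >= dead + 1))
  }
})

test_that("event indices are invariant to positive rescaling", {
  k <- scint_kernel()
  ev <- simulate_events(2, 50, seed = 5)
  tr <- synthesize_trace(ev, k)
  for (mode in c("amplitude", "gradient")) {
    thr <- 0.4 * working_peak(k, mode)
    base <- discriminate(tr, discriminator_config(mode, thr))
    for (scale in c(0.01, 3, 1000)) {
      tr2 <- tr
      tr2$samples <- tr$samples * scale
      d2 <- discriminate(tr2, discriminator_config(mode, thr * scale))
      expect_identical(d2$event_sample_indices,
                       base$event_sample_indices)
    }
  }
})

test_that("minimal settings count one event per two samples", {
  # alternating above/below: the fastest countable signal
  x <- rep(c(1, 0), 500)
  cfg <- discriminator_config("amplitude", 0.5,
                              min_consecutive_above = 1,
                              min_consecutive_below = 1, dead_time = 0)
  det <- discriminate(x, cfg)
  expect_identical(det$n_detected, 500L)
  expect_identical(det$event_sample_indices, seq(1L, 999L, 2L))
})

test_that("out-of-range thresholds on quantized traces warn", {
  tr <- quantize_adc(
    synthesize_trace(event_stream(1, duration = 5), scint_kernel()),
    bits = 14, adc_range = 2)
  expect_warning(
    discriminate(tr, discriminator_config("amplitude", 2e4)),
    "ADC")
})

test_that("event binning uses half-open pixel windows", {
  expect_identical(as.integer(bin_events(c(0.1, 0.9), 0.5, 2)),
                   c(1L, 1L))
  # boundary event goes to the later pixel
  expect_identical(as.integer(bin_events(0.5, 0.5, 2)), c(0L, 1L))
  b <- bin_events(c(0.2, 1.7), 0.5, 2)
  expect_identical(attr(b, "n_dropped"), 1L)
  expect_identical(sum(b) + attr(b, "n_dropped"), 2L)
})

test_that("binned uniform Poisson events keep variance ~ mean", {
  times <- sample_poisson_events(2, 5000, seed = 77)
  counts <- bin_events(times, 0.5, 1e4)
  r <- stats::var(as.numeric(counts)) / mean(counts)
  expect_gt(r, 0.9)
  expect_lt(r, 1.1)
})

test_that("detection efficiency is the detected/true count ratio", {
  expect_equal(detection_efficiency(3, 4), 0.75)
  expect_equal(detection_efficiency(4, 4), 1.0)
  expect_error(detection_efficiency(3, 0), "no true events")
  # multi-segment: summed over segments
  r1 <- structure(list(n_detected = 3L), class = "detection_result")
  r2 <- structure(list(n_detected = 2L), class = "detection_result")
  expect_equal(detection_efficiency(list(r1, r2), 5), 1.0)
})

test_that("low-rate detection is essentially lossless", {
  k <- scint_kernel()
  thr <- 0.4 * working_peak(k, "gradient")
  cfg <- discriminator_config("gradient", thr)
  effs <- vapply(1:10, function(i) {
    ev <- simulate_events(0.05, 500, seed = 400 + i)
    tr <- synthesize_trace(ev, k, duration = 500,
                           noise_sigma = thr / 10, seed = 900 + i)
    detection_efficiency(discriminate(tr, cfg), ev)
  }, numeric(1))
  expect_gte(mean(effs), 0.99)
})
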