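# shared fixtures and independent reference implementations

scint_kernel <- function(...) make_kernel("scintillator", ...)
ss_kernel <- function(...) make_kernel("solid_state", ...)

annulus_geometry <- function(r_in = 40, r_out = 100) {
  detector_geometry(data.frame(r_in = r_in, r_out = r_out,
                               az_start = 0, az_end = 360))
}

# Plain-R reference discriminator: an independent transcription of the
# threshold/hold logic used to cross-check the compiled state machine
# on arbitrary traces.
ref_discriminate <- function(x, threshold, min_above = 1, min_below = 1,
                             dead_time = 0, hysteresis = 0) {
  events <- integer(0)
  armed <- TRUE
  above <- 0L; start <- 0L; below <- 0L
  last <- -dead_time - 1L
  for (i in seq_along(x)) {
    if (armed) {
      if (x[i] > threshold) {
        if (above == 0L) start <- i
        above <- above + 1L
        if (above >= min_above) {
          events <- c(events, start)
          last <- start
          armed <- FALSE
          above <- 0L; below <- 0L
        }
      } else {
        above <- 0L
      }
    } else {
      below <- if (x[i] <= threshold - hysteresis) below + 1L else 0L
      if (below >= min_below && (i - last) >= dead_time) {
        armed <- TRUE
        above <- 0L
      }
    }
  }
  events
}

# A pulse riding on a slow baseline ramp: the fixture where amplitude
# thresholding fails (merges) but gradient thresholding succeeds.
# Returns samples of `ramp from 0.3 to 0.5` plus `n_pulses` pulses of
# height 0.4 with a sharp rise and a fall slow enough (300 samples)
# that the summed signal never drops back under an 0.6 threshold
# between the two pulses, at unit sample spacing.
afterglow_ramp_trace <- function(n = 400, n_pulses = 1,
                                 pulse_at = c(100, 250)) {
  ramp <- seq(0.3, 0.5, length.out = n)
  k <- make_kernel("custom", rise_time = 2, fall_time = 0.3,
                   sample_period = 1)
  s <- ramp
  for (p in pulse_at[seq_len(n_pulses)]) {
    j <- p:min(n, p + length(k$samples) - 1)
    s[j] <- s[j] + 0.4 * k$samples[seq_along(j)]
  }
  structure(list(samples = s, sample_period = 8, baseline = 0,
                 adc_bits = NULL, adc_range = NULL),
            class = "analog_trace")
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
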