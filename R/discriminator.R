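#' Configure the pulse discriminator
#'
#' Parameterises the counting logic that turns a digitised detector
#' trace into electron events, mirroring the real-time hardware: a
#' threshold applied either to the raw amplitude or to a finite-lag
#' gradient of the signal, with consecutive-sample requirements to
#' suppress noise and a dead time setting the minimum spacing of
#' recorded events.
#'
#' Gradient-domain thresholding detects the sharp rising edge of each
#' pulse rather than its absolute level, which makes detection immune to
#' baseline drift from accumulated afterglow and to amplitude
#' variations across the detector.
#'
#' @param mode `"amplitude"` or `"gradient"`.
#' @param threshold Threshold in signal units (amplitude mode) or
#'   signal-units-per-lag (gradient mode).
#' @param gradient_lag Lag in samples for the finite gradient
#'   (default 4, i.e. 32 ns at 8 ns sampling, spanning the ~100 ns
#'   rising edge).
#' @param min_consecutive_above Samples that must exceed the threshold
#'   consecutively before an event is recorded (default 2).
#' @param min_consecutive_below Samples at or below the (hysteresis-
#'   adjusted) threshold required before re-arming (default 2).
#' @param dead_time Minimum samples between recorded events (default 2).
#' @param output_pulse_width Width in samples of the emitted digital
#'   pulse (metadata for downstream scan controllers; does not affect
#'   detection).
#' @param record_at `"run_start"` (default) or `"run_end"`: whether the
#'   event timestamp is the first or last sample of the qualifying
#'   above-threshold run.
#' @param hysteresis Re-arm happens at `threshold - hysteresis`
#'   (default 0).
#' @return A `discriminator_config` object.
#' @export
discriminator_config <- function(mode = c("gradient", "amplitude"),
                                 threshold,
                                 gradient_lag = 4L,
                                 min_consecutive_above = 2L,
                                 min_consecutive_below = 2L,
                                 dead_time = 2L,
                                 output_pulse_width = 1L,
                                 record_at = c("run_start", "run_end"),
                                 hysteresis = 0) {
  mode <- match.arg(mode)
  record_at <- match.arg(record_at)
  stopifnot(is.finite(threshold),
            gradient_lag >= 1, min_consecutive_above >= 1,
            min_consecutive_below >= 1, dead_time >= 0,
            output_pulse_width >= 1, hysteresis >= 0)
  structure(list(mode = mode, threshold = threshold,
                 gradient_lag = as.integer(gradient_lag),
                 min_consecutive_above = as.integer(min_consecutive_above),
                 min_consecutive_below = as.integer(min_consecutive_below),
                 dead_time = as.integer(dead_time),
                 output_pulse_width = as.integer(output_pulse_width),
                 record_at = record_at, hysteresis = hysteresis),
            class = "discriminator_config")
}

#' Finite-lag gradient of a trace
#'
#' The gradient signal the hardware thresholds in gradient mode:
#' `g[i] = s[i] - s[i - lag]`, with the first `lag` entries zero so the
#' output has the same length as the input.
#'
#' @param x Numeric samples, or an `analog_trace`.
#' @param lag Time difference in samples used for the gradient
#'   (`>= 1`, less than the trace length).
#' @return Numeric vector of gradients, same length as the input.
#' @export
finite_gradient <- function(x, lag = 4L) {
  if (inherits(x, "analog_trace")) x <- x$samples
  stopifnot(is.numeric(x), lag >= 1)
  if (lag >= length(x)) {
    stop("`lag` must be smaller than the trace length", call. = FALSE)
  }
  n <- length(x)
  g <- numeric(n)
  g[(lag + 1):n] <- x[(lag + 1):n] - x[1:(n - lag)]
  g
}

#' Run the pulse discriminator over a trace
#'
#' Deterministic replica of the hardware counting logic (see
#' [discriminator_config()]). The working signal is the raw trace in
#' amplitude mode or its finite-lag gradient in gradient mode; a
#' two-state machine records an event when `min_consecutive_above`
#' consecutive working samples exceed the threshold, then holds until
#' `min_consecutive_below` samples fall back at-or-below threshold and
#' the dead time has elapsed.
#'
#' @param trace An `analog_trace` (or bare numeric samples, taken at
#'   8 ns).
#' @param config A `discriminator_config`.
#' @return A `detection_result`: list with `event_sample_indices`
#'   (1-based, strictly increasing), `event_times_us`, `n_detected`,
#'   `sample_period`, `config`.
#' @export
discriminate <- function(trace, config) {
  if (is.numeric(trace)) {
    trace <- structure(list(samples = trace, sample_period = 8,
                            baseline = 0, adc_bits = NULL, adc_range = NULL),
                       class = "analog_trace")
  }
  stopifnot(inherits(trace, "analog_trace"),
            inherits(config, "discriminator_config"))
  if (!is.null(trace$adc_bits) && config$mode == "amplitude" &&
      (config$threshold < 0 || config$threshold > 2^trace$adc_bits - 1)) {
    warning("threshold lies outside the ADC code range; no events possible",
            call. = FALSE)
  }
  working <- if (config$mode == "gradient") {
    finite_gradient(trace$samples, config$gradient_lag)
  } else {
    trace$samples
  }
  idx <- .discriminate_core(working, config$threshold,
                            config$min_consecutive_above,
                            config$min_consecutive_below,
                            config$dead_time,
                            config$record_at == "run_end",
                            config$hysteresis)
  structure(list(event_sample_indices = idx,
                 event_times_us = (idx - 1) * trace$sample_period / 1000,
                 n_detected = length(idx),
                 sample_period = trace$sample_period,
                 config = config),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("detection_result: %d events (%s mode, threshold %g)\n",
              x$n_detected, x$config$mode, x$config$threshold))
  invisible(x)
}

#' Bin detected events into scan pixels
#'
#' Pixels are acquired consecutively along the scan; pixel `p`
#' (0-based) counts events with time in the half-open window
#' `[p * dwell, (p+1) * dwell)`. Events beyond the scan window are
#' dropped and reported.
#'
#' @param times Event times in microseconds (e.g.
#'   `result$event_times_us`), or a `detection_result`.
#' @param dwell Pixel dwell time in microseconds.
#' @param n_pixels Number of pixels in the scan window.
#' @return Integer vector of per-pixel counts with attribute
#'   `n_dropped` (events outside `[0, n_pixels * dwell)`).
#' @export
bin_events <- function(times, dwell, n_pixels) {
  if (inherits(times, "detection_result")) times <- times$event_times_us
  stopifnot(is.numeric(times), dwell > 0, n_pixels >= 1)
  pix <- floor(times / dwell)
  inside <- pix >= 0 & pix < n_pixels
  counts <- tabulate(pix[inside] + 1L, nbins = n_pixels)
  attr(counts, "n_dropped") <- sum(!inside)
  counts
}

#' Detection efficiency against ground truth
#'
#' The fraction of true electrons that were detected, defined as a pure
#' count ratio `n_detected / n_true` (it can exceed 1 when noise
#' triggers false events; the value is reported as-is). For
#' multi-segment results, detections and truths are summed over
#' segments before dividing.
#'
#' @param result A `detection_result`, a list of them (one per
#'   segment), or a detected count.
#' @param truth An `event_stream`, or the true event count.
#' @return Efficiency as a plain fraction.
#' @export
detection_efficiency <- function(result, truth) {
  n_det <- if (inherits(result, "detection_result")) {
    result$n_detected
  } else if (is.list(result)) {
    sum(vapply(result, function(r) r$n_detected, numeric(1)))
  } else {
    result
  }
  n_true <- if (inherits(truth, "event_stream")) length(truth$times) else truth
  if (n_true == 0) {
    stop("efficiency undefined: no true events", call. = FALSE)
  }
  n_det / n_true
}
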