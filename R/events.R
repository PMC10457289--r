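#' Draw Poisson-distributed electron arrival times
#'
#' Electron arrivals at the detector are modelled as a homogeneous
#' Poisson process: the event count over the trace is
#' Poisson(`rate * duration`) and arrival times are i.i.d. uniform over
#' the trace, returned sorted.
#'
#' @param rate Expected electrons per microsecond (beam-current proxy);
#'   must be non-negative.
#' @param duration Trace duration in microseconds.
#' @param seed Optional integer seed; identical seeds give identical
#'   streams.
#' @return Sorted numeric vector of arrival times in microseconds.
#' @export
sample_poisson_events <- function(rate, duration, seed = NULL) {
  if (!is.numeric(rate) || rate < 0) {
    stop("`rate` must be non-negative", call. = FALSE)
  }
  stopifnot(duration > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, rate * duration)
  sort(stats::runif(n, 0, duration))
}

#' Draw single-electron pulse heights
#'
#' Pulse heights vary with scintillation strength and electron landing
#' position; they are modelled as a Gaussian truncated at zero with the
#' given mean and coefficient of variation.
#'
#' @param n Number of heights.
#' @param mean Mean pulse height (default 1, matching unit-peak kernels).
#' @param cv Coefficient of variation (sd/mean), `>= 0`; `cv = 0` gives
#'   a constant sequence.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` positive heights.
#' @export
sample_heights <- function(n, mean = 1, cv = 0.15, seed = NULL) {
  stopifnot(n >= 0, mean > 0, cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(numeric(0))
  if (cv == 0) return(rep(mean, n))
  h <- stats::rnorm(n, mean, cv * mean)
  while (any(bad <- h <= 0)) {
    h[bad] <- stats::rnorm(sum(bad), mean, cv * mean)
  }
  h
}

#' Define a segmented detector geometry
#'
#' A detector is a set of annular-sector segments, each
#' `(inner radius, outer radius, azimuth start, azimuth end)` in
#' consistent angular units (scattering angle, mrad, for the radii;
#' degrees for azimuths). Segments must not overlap; the union need not
#' cover the full annulus (inter-segment gaps lose electrons).
#'
#' @param segments A data frame (or matrix) with columns `r_in`, `r_out`,
#'   `az_start`, `az_end` (degrees, `0 <= az_start < az_end <= 360`).
#' @return A `detector_geometry` object.
#' @seealso [geometry_quadrants_rings()] for the reference 6-segment
#'   layout.
#' @export
detector_geometry <- function(segments) {
  segments <- as.data.frame(segments)
  need <- c("r_in", "r_out", "az_start", "az_end")
  if (!all(need %in% names(segments))) {
    stop("`segments` needs columns r_in, r_out, az_start, az_end",
         call. = FALSE)
  }
  with(segments, {
    stopifnot(all(r_in >= 0), all(r_out > r_in),
              all(az_start >= 0), all(az_end <= 360),
              all(az_end > az_start))
  })
  # pairwise non-overlap check
  n <- nrow(segments)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      a <- segments[i, ]; b <- segments[j, ]
      r_ov <- min(a$r_out, b$r_out) > max(a$r_in, b$r_in)
      az_ov <- min(a$az_end, b$az_end) > max(a$az_start, b$az_start)
      if (r_ov && az_ov) {
        stop(sprintf("segments %d and %d overlap", i, j), call. = FALSE)
      }
    }
  }
  structure(list(segments = segments), class = "detector_geometry")
}

#' Reference segmented-detector layout: 4 inner quadrants + 2 outer rings
#'
#' The 6-segment annular dark-field geometry used for the detection
#' efficiency study: the innermost annulus, where Rutherford-like
#' scattering concentrates most of the dose, is split into four
#' quadrants; two larger complete rings sit outside it.
#'
#' @param r Radial boundaries, a length-4 ascending vector in mrad
#'   (defaults 30, 60, 90, 120: quadrants span 30-60, rings 60-90 and
#'   90-120).
#' @param gap Azimuthal gap between quadrants in degrees (default 0;
#'   electrons in gaps are lost).
#' @return A `detector_geometry` with 6 segments: ids 0-3 the quadrants,
#'   4 and 5 the rings.
#' @export
geometry_quadrants_rings <- function(r = c(30, 60, 90, 120), gap = 0) {
  stopifnot(length(r) == 4, all(diff(r) > 0), gap >= 0, gap < 90)
  q <- do.call(rbind, lapply(0:3, function(i) {
    data.frame(r_in = r[1], r_out = r[2],
               az_start = i * 90 + gap / 2, az_end = (i + 1) * 90 - gap / 2)
  }))
  rings <- data.frame(r_in = r[2:3], r_out = r[3:4],
                      az_start = 0, az_end = 360)
  detector_geometry(rbind(q, rings))
}

#' Radial scattering-intensity profile
#'
#' Weights describing how scattered-electron intensity falls with
#' scattering angle; events draw their radius from this (linearly
#' interpolated) profile. The default emulates the steep Rutherford-like
#' fall-off of high-angle scattering with `weight ~ r^-3`.
#'
#' @param radii Ascending knot radii (mrad).
#' @param weights Non-negative weights at the knots, not all zero.
#' @return A `radial_profile` object.
#' @export
radial_profile <- function(radii, weights) {
  stopifnot(is.numeric(radii), is.numeric(weights),
            length(radii) == length(weights), length(radii) >= 2,
            all(diff(radii) > 0), all(weights >= 0))
  if (all(weights == 0)) {
    stop("`weights` must not be all zero", call. = FALSE)
  }
  structure(list(radii = radii, weights = weights), class = "radial_profile")
}

#' @rdname radial_profile
#' @param r_min,r_max Radial range covered (mrad).
#' @param exponent Power-law exponent (default -3).
#' @param n Number of knots.
#' @export
radial_profile_powerlaw <- function(r_min, r_max, exponent = -3, n = 200) {
  stopifnot(r_min > 0, r_max > r_min)
  r <- seq(r_min, r_max, length.out = n)
  radial_profile(r, r^exponent)
}

# Inverse-CDF sampling from a piecewise-linear density on the profile
# knots. CDF over each knot interval is quadratic in r; solved exactly.
.sample_radii <- function(profile, n) {
  r <- profile$radii
  w <- profile$weights
  dr <- diff(r)
  seg_mass <- dr * (w[-length(w)] + w[-1]) / 2
  total <- sum(seg_mass)
  if (total <= 0) {
    stop("radial profile is zero over its support", call. = FALSE)
  }
  cdf <- c(0, cumsum(seg_mass)) / total
  u <- stats::runif(n)
  idx <- findInterval(u, cdf, rightmost.closed = TRUE)
  idx[idx > length(dr)] <- length(dr)
  # within interval i: mass(x) = w_i*x + (w_{i+1}-w_i)/(2*dr_i)*x^2
  ui <- (u - cdf[idx]) * total          # residual mass inside interval
  w0 <- w[idx]
  slope <- (w[idx + 1] - w[idx]) / dr[idx]
  x <- ifelse(
    abs(slope) < 1e-12 * (w0 + 1e-300),
    ui / pmax(w0, 1e-300),
    (-w0 + sqrt(pmax(w0^2 + 2 * slope * ui, 0))) / slope
  )
  r[idx] + pmin(pmax(x, 0), dr[idx])
}

#' Assign electron events to detector segments
#'
#' Each event lands at a radius drawn from the radial profile and an
#' azimuth uniform on [0, 360); the event is assigned to the segment
#' containing that point, or marked lost (id -1) if it falls in a gap or
#' outside every segment.
#'
#' @param n_events Number of events (e.g. `length(times)` of a stream).
#' @param geometry A [detector_geometry()].
#' @param profile A [radial_profile()] covering the geometry's radial
#'   span.
#' @param seed Optional integer seed.
#' @return Integer vector of segment ids: 0-based row index into
#'   `geometry$segments`, or -1 for lost events.
#' @export
assign_segments <- function(n_events, geometry, profile, seed = NULL) {
  stopifnot(inherits(geometry, "detector_geometry"),
            inherits(profile, "radial_profile"), n_events >= 0)
  seg <- geometry$segments
  if (min(profile$radii) > min(seg$r_in) ||
      max(profile$radii) < max(seg$r_out)) {
    stop("radial profile does not cover the detector's radial span",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (n_events == 0) return(integer(0))
  radius <- .sample_radii(profile, n_events)
  azimuth <- stats::runif(n_events, 0, 360)
  ids <- rep(-1L, n_events)
  for (i in seq_len(nrow(seg))) {
    hit <- radius >= seg$r_in[i] & radius < seg$r_out[i] &
      azimuth >= seg$az_start[i] & azimuth < seg$az_end[i]
    ids[hit] <- i - 1L
  }
  ids
}

#' Bundle ground-truth events into an event stream
#'
#' @param times Arrival times in microseconds (sorted ascending).
#' @param heights Pulse heights, `> 0`; recycled if length 1.
#' @param segment_ids Integer segment ids (0-based; -1 = lost /
#'   monolithic default); recycled if length 1.
#' @param duration Trace duration in microseconds (must cover all times).
#' @return An `event_stream` object.
#' @export
event_stream <- function(times, heights = 1, segment_ids = -1L,
                         duration = if (length(times)) max(times) else 1) {
  stopifnot(is.numeric(times))
  if (is.unsorted(times)) stop("`times` must be sorted", call. = FALSE)
  n <- length(times)
  if (length(heights) == 1) heights <- rep(heights, n)
  if (length(segment_ids) == 1) segment_ids <- rep(as.integer(segment_ids), n)
  stopifnot(length(heights) == n, length(segment_ids) == n,
            all(heights > 0))
  if (n && (min(times) < 0 || max(times) > duration)) {
    stop("event times must lie in [0, duration]", call. = FALSE)
  }
  structure(list(times = times, heights = heights,
                 segment_ids = as.integer(segment_ids),
                 duration = duration),
            class = "event_stream")
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("event_stream: %d events over %g us (%d segments hit)\n",
              length(x$times), x$duration,
              length(unique(x$segment_ids[x$segment_ids >= 0]))))
  invisible(x)
}

#' Simulate a full ground-truth event stream
#'
#' Convenience wrapper: Poisson arrival times, truncated-Gaussian
#' heights, and (optionally) segment assignment in one call.
#'
#' @inheritParams sample_poisson_events
#' @inheritParams sample_heights
#' @param geometry,profile Optional [detector_geometry()] and
#'   [radial_profile()]; when supplied, events are distributed over
#'   segments, otherwise all ids are -1 (monolithic).
#' @param seed Optional integer seed controlling all three draws.
#' @return An `event_stream`.
#' @export
simulate_events <- function(rate, duration, cv = 0.15, geometry = NULL,
                            profile = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  times <- sample_poisson_events(rate, duration)
  heights <- sample_heights(length(times), cv = cv)
  ids <- if (!is.null(geometry)) {
    assign_segments(length(times), geometry, profile)
  } else {
    rep(-1L, length(times))
  }
  event_stream(times, heights, ids, duration)
}

#' Synthesize the analog detector trace for an event stream
#'
#' Linear superposition of one pulse-kernel copy per event, placed on
#' the ADC clock grid, plus baseline and white Gaussian noise:
#' `s[i] = baseline + sum_e h_e * kernel(t_i - t_e) + N(0, noise_sigma)`.
#' Event times are continuous; each pulse starts at the first sample
#' instant at or after its arrival (a clocked ADC sees no sub-sample
#' phase). Superposition is exact, so coincident events add linearly.
#'
#' @param events An `event_stream`, or a numeric vector of times (us).
#' @param kernel A `pulse_kernel`; resampled automatically if its clock
#'   differs from `sample_period`.
#' @param duration Trace duration in microseconds (default: the
#'   stream's).
#' @param sample_period ADC sample period in nanoseconds (default: the
#'   kernel's).
#' @param baseline Baseline level (signal units).
#' @param noise_sigma White-noise standard deviation (signal units).
#' @param seed Optional integer seed for the noise draw.
#' @return An `analog_trace`: list with `samples`, `sample_period` (ns),
#'   `baseline`, and quantisation fields (`adc_bits`, `adc_range`,
#'   NULL until [quantize_adc()]).
#' @export
synthesize_trace <- function(events, kernel, duration = NULL,
                             sample_period = kernel$sample_period,
                             baseline = 0, noise_sigma = 0, seed = NULL) {
  if (is.numeric(events)) events <- event_stream(events)
  stopifnot(inherits(events, "event_stream"),
            inherits(kernel, "pulse_kernel"))
  if (is.null(duration)) duration <- events$duration
  if (length(events$times) && max(events$times) > duration) {
    stop("event beyond trace duration", call. = FALSE)
  }
  kernel <- resample_kernel(kernel, sample_period)
  n <- max(2L, ceiling(duration * 1000 / sample_period))
  sig <- numeric(n)
  if (length(events$times)) {
    # 1-based index of first sample instant >= event time
    idx <- ceiling(events$times * 1000 / sample_period) + 1L
    idx[idx > n] <- n
    k <- kernel$samples
    nk <- length(k)
    if (length(idx) > 256L) {
      # FFT superposition: delta train (heights at start indices) * kernel
      delta <- numeric(n)
      agg <- rowsum(events$heights, idx)
      delta[as.integer(rownames(agg))] <- agg[, 1]
      m <- stats::nextn(n + nk - 1L, 2)
      conv <- Re(stats::fft(stats::fft(c(delta, numeric(m - n))) *
                            stats::fft(c(k, numeric(m - nk))),
                            inverse = TRUE)) / m
      sig <- conv[seq_len(n)]
      sig[abs(sig) < 1e-12] <- 0
    } else {
      for (e in seq_along(idx)) {
        j <- idx[e]:min(n, idx[e] + nk - 1L)
        sig[j] <- sig[j] + events$heights[e] * k[seq_along(j)]
      }
    }
  }
  if (!is.null(seed)) set.seed(seed)
  samples <- sig + baseline
  if (noise_sigma > 0) samples <- samples + stats::rnorm(n, 0, noise_sigma)
  structure(list(samples = samples, sample_period = sample_period,
                 baseline = baseline, adc_bits = NULL, adc_range = NULL),
            class = "analog_trace")
}

#' @export
print.analog_trace <- function(x, ...) {
  q <- if (is.null(x$adc_bits)) "analog" else sprintf("%d-bit", x$adc_bits)
  cat(sprintf("analog_trace: %d samples at %g ns (%.4g us, %s)\n",
              length(x$samples), x$sample_period,
              length(x$samples) * x$sample_period / 1000, q))
  invisible(x)
}

#' Quantize a trace as an ideal ADC would
#'
#' Clips the signal to `[0, adc_range]`, scales to the full code range
#' `[0, 2^bits - 1]` and rounds half-to-even, marking the trace as
#' quantized. Defaults model 14-bit converters.
#'
#' @param trace An `analog_trace`.
#' @param bits ADC resolution in bits (default 14).
#' @param adc_range Full-scale input range in signal units.
#' @return The quantized `analog_trace` (integer-valued samples).
#' @export
quantize_adc <- function(trace, bits = 14, adc_range) {
  stopifnot(inherits(trace, "analog_trace"), bits >= 1, adc_range > 0)
  top <- 2^bits - 1
  s <- pmin(pmax(trace$samples, 0), adc_range)
  trace$samples <- round(s / adc_range * top)
  trace$adc_bits <- as.integer(bits)
  trace$adc_range <- adc_range
  trace
}

#' Time axis of a trace
#'
#' @param trace An `analog_trace`.
#' @return Sample times in microseconds (first sample at 0).
#' @export
trace_times <- function(trace) {
  (seq_along(trace$samples) - 1) * trace$sample_period / 1000
}
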