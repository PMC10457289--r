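#' Raster-scan configuration
#'
#' @param nx,ny Image width (fast axis, left to right) and height
#'   (slow axis) in pixels.
#' @param dwell Pixel dwell time in nanoseconds.
#' @param frames Number of frames to acquire and average (`>= 1`).
#' @return A `scan_config` object.
#' @export
scan_config <- function(nx, ny, dwell, frames = 1L) {
  stopifnot(nx >= 1, ny >= 1, dwell > 0, frames >= 1)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 dwell = dwell, frames = as.integer(frames)),
            class = "scan_config")
}

#' Simulate simultaneous analog and counted STEM images
#'
#' Rasters a probe over a specimen map and forms, from the identical
#' per-row detector trace, both the conventional analog image
#' (integrating ADC: mean of trace samples within each pixel's dwell
#' window) and the electron-counted image (discriminated events binned
#' per pixel), alongside the ground-truth electron image.
#'
#' Per row, electrons are drawn as an inhomogeneous Poisson process with
#' rate `base_rate * specimen[pixel]` and one continuous trace is
#' synthesised for the whole row, so detector pulses straddle pixel
#' boundaries exactly as in hardware. At dwell times comparable to the
#' detector decay time this reproduces fast-scan streaking in the analog
#' image; the counted image, seeing electrons as delta functions, does
#' not streak. Frames are simulated independently and averaged.
#'
#' @param specimen Numeric matrix (`ny` rows x `nx` columns) of
#'   non-negative rate multipliers; 0 = vacuum.
#' @param base_rate Electron rate in e-/us for a specimen value of 1.
#' @param scan A [scan_config()] matching `dim(specimen)`.
#' @param kernel A `pulse_kernel`.
#' @param config A `discriminator_config`.
#' @param noise_sigma Per-sample white-noise sd (signal units).
#' @param baseline Trace baseline (signal units).
#' @param height_cv Pulse-height coefficient of variation.
#' @param flyback_carryover If `TRUE`, the detector signal persisting at
#'   the end of a row (afterglow) carries into the next row after
#'   `flyback` nanoseconds of decay, instead of being reset.
#' @param flyback Flyback time in nanoseconds (used only with
#'   carryover).
#' @param seed Optional integer seed.
#' @return A `scan_result`: list of matrices `analog`, `counted`,
#'   `truth` (frame-averaged), plus `n_events` (total electrons
#'   generated) and the configs.
#' @export
simulate_scan <- function(specimen, base_rate, scan, kernel, config,
                          noise_sigma = 0, baseline = 0, height_cv = 0.15,
                          flyback_carryover = FALSE, flyback = 0,
                          seed = NULL) {
  specimen <- as.matrix(specimen)
  stopifnot(inherits(scan, "scan_config"),
            nrow(specimen) == scan$ny, ncol(specimen) == scan$nx,
            all(specimen >= 0), base_rate >= 0)
  dt <- kernel$sample_period
  if (scan$dwell < dt) {
    stop("dwell time shorter than one sample period", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  dwell_us <- scan$dwell / 1000
  row_dur <- scan$nx * dwell_us
  n_row_samp <- max(2L, ceiling(row_dur * 1000 / dt))
  pix_of_sample <- pmin(floor((seq_len(n_row_samp) - 1) * dt / scan$dwell),
                        scan$nx - 1)
  fly_samp <- if (flyback_carryover) ceiling(flyback / dt) else 0L

  analog <- counted <- truth <- matrix(0, scan$ny, scan$nx)
  n_events_total <- 0
  for (f in seq_len(scan$frames)) {
    carry <- NULL
    for (y in seq_len(scan$ny)) {
      lam <- base_rate * specimen[y, ] * dwell_us
      k_counts <- stats::rpois(scan$nx, lam)
      n_ev <- sum(k_counts)
      n_events_total <- n_events_total + n_ev
      truth[y, ] <- truth[y, ] + k_counts
      times <- if (n_ev) {
        sort(rep((seq_len(scan$nx) - 1) * dwell_us, k_counts) +
               stats::runif(n_ev, 0, dwell_us))
      } else {
        numeric(0)
      }
      ev <- event_stream(times, sample_heights(n_ev, cv = height_cv),
                         duration = row_dur)
      # synthesise past the row end so the residual can carry over
      ext_dur <- row_dur +
        (length(kernel$samples) + fly_samp) * dt / 1000
      tr <- synthesize_trace(ev, kernel, duration = ext_dur,
                             baseline = baseline,
                             noise_sigma = noise_sigma)
      if (!is.null(carry)) {
        m <- min(length(carry), length(tr$samples))
        tr$samples[seq_len(m)] <- tr$samples[seq_len(m)] + carry[seq_len(m)]
      }
      if (flyback_carryover) {
        carry <- tr$samples[-seq_len(n_row_samp + fly_samp)] - baseline
      }
      row_samples <- tr$samples[seq_len(n_row_samp)]
      analog[y, ] <- analog[y, ] +
        as.numeric(tapply(row_samples, pix_of_sample, mean))
      tr$samples <- row_samples
      det <- discriminate(tr, config)
      counted[y, ] <- counted[y, ] +
        bin_events(det$event_times_us, dwell_us, scan$nx)
    }
  }
  structure(list(analog = analog / scan$frames,
                 counted = counted / scan$frames,
                 truth = truth / scan$frames,
                 n_events = n_events_total,
                 scan = scan, kernel_kind = kernel$kind,
                 config = config, base_rate = base_rate),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(
    "scan_result: %d x %d pixels, %g ns dwell, %d frame(s), %d electrons\n",
    x$scan$nx, x$scan$ny, x$scan$dwell, x$scan$frames, x$n_events))
  invisible(x)
}

#' Fast-axis vs slow-axis high-frequency power ratio
#'
#' Quantifies the directional high-frequency suppression that fast-scan
#' streaking produces: from the 2D periodogram of the (mean-subtracted)
#' image, the mean power in the top-quartile frequency band along the
#' fast axis (high `|f_x|`, low `|f_y|`) is divided by the mean power in
#' the mirrored band along the slow axis. An isotropic image gives ~1;
#' an image blurred along the fast axis gives < 1.
#'
#' @param image Numeric matrix, at least 16 x 16; rows are scan rows
#'   (columns = fast axis).
#' @return Scalar ratio in `(0, Inf)`.
#' @export
directional_spectrum_ratio <- function(image) {
  image <- as.matrix(image)
  if (nrow(image) < 16 || ncol(image) < 16) {
    stop("image must be at least 16 x 16", call. = FALSE)
  }
  if (diff(range(image)) == 0) {
    stop("spectrum ratio undefined for a constant image", call. = FALSE)
  }
  p <- Mod(stats::fft(image - mean(image)))^2
  fy <- .fold_freq(nrow(image))
  fx <- .fold_freq(ncol(image))
  # top-quartile band along each axis; the corner where both are high
  # is shared and dropped, and the zero-frequency lines are excluded:
  # any pattern constant along one axis (e.g. the specimen itself in a
  # step-edge scan) lives there and would contaminate the anisotropy
  # measurement
  hi_x <- fx > 0.375
  hi_y <- fy > 0.375
  fast_band <- outer(!hi_y & fy > 0, hi_x, "&")  # varies quickly along x
  slow_band <- outer(hi_y, !hi_x & fx > 0, "&")
  mean(p[fast_band]) / mean(p[slow_band])
}

# folded DFT frequencies in cycles/pixel, in [0, 0.5]
.fold_freq <- function(n) {
  f <- (seq_len(n) - 1) / n
  pmin(f, 1 - f)
}

#' Length of the decay tail past a step edge
#'
#' Measures streaking from an image of a bright region ending at a known
#' edge: the row-averaged profile is background-subtracted and the tail
#' length is the number of pixels past the edge where the profile still
#' exceeds `frac` of the step height.
#'
#' @param image Numeric matrix (columns = fast axis).
#' @param edge Last bright column (1-based); columns `> edge` are
#'   nominally vacuum.
#' @param frac Fraction of the step height defining "still bright"
#'   (default 0.1).
#' @return Integer tail length in pixels.
#' @export
edge_tail_length <- function(image, edge, frac = 0.1) {
  image <- as.matrix(image)
  stopifnot(edge >= 1, edge < ncol(image))
  prof <- colMeans(image)
  bg <- min(prof[(edge + 1):ncol(image)])
  plateau <- stats::median(prof[seq_len(edge)])
  if (plateau <= bg) stop("no step found at `edge`", call. = FALSE)
  tail_prof <- prof[(edge + 1):ncol(image)] - bg
  above <- tail_prof > frac * (plateau - bg)
  if (!any(above)) return(0L)
  max(which(above))
}
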