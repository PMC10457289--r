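#' Peak of the discriminator working signal for a unit pulse
#'
#' The height a single unit-height electron pulse reaches in the
#' discriminator's working domain: 1 in amplitude mode (kernels are
#' unit peak), or the maximum finite-lag difference of the kernel in
#' gradient mode. Thresholds are naturally expressed as fractions of
#' this value.
#'
#' @param kernel A `pulse_kernel`.
#' @param mode `"amplitude"` or `"gradient"`.
#' @param gradient_lag Lag in samples (gradient mode).
#' @return Scalar peak value.
#' @export
working_peak <- function(kernel, mode = c("gradient", "amplitude"),
                         gradient_lag = 4L) {
  mode <- match.arg(mode)
  if (mode == "amplitude") return(max(kernel$samples))
  max(finite_gradient(kernel$samples, gradient_lag))
}

# synthesize + discriminate one stream under a condition, returning the
# detected count over events that actually hit the detector
.count_detected <- function(ev, kernel, config, segmented, noise_sigma,
                            duration, noise_seed = NULL) {
  keep <- ev$segment_ids >= 0
  n_true <- sum(keep)
  if (n_true == 0) return(c(detected = 0, true = 0))
  if (!is.null(noise_seed)) set.seed(noise_seed)
  n_det <- 0
  if (segmented) {
    for (s in sort(unique(ev$segment_ids[keep]))) {
      sel <- keep & ev$segment_ids == s
      sub <- event_stream(ev$times[sel], ev$heights[sel],
                          duration = duration)
      tr <- synthesize_trace(sub, kernel, duration = duration,
                             noise_sigma = noise_sigma)
      n_det <- n_det + discriminate(tr, config)$n_detected
    }
  } else {
    sub <- event_stream(ev$times[keep], ev$heights[keep],
                        duration = duration)
    tr <- synthesize_trace(sub, kernel, duration = duration,
                           noise_sigma = noise_sigma)
    n_det <- discriminate(tr, config)$n_detected
  }
  c(detected = n_det, true = n_true)
}

.condition_config <- function(mode, threshold, ...) {
  discriminator_config(mode = mode, threshold = threshold, ...)
}

#' Optimize a discriminator threshold for a data stream
#'
#' Grid search for the threshold giving a detected count closest to the
#' true count on a held-out calibration stream at the study's rate,
#' mirroring the practice of tuning threshold levels to the specific
#' data stream before measuring efficiency.
#'
#' @param rate Electrons per microsecond of the calibration stream.
#' @param mode,kernel,segmented Condition under test.
#' @param geometry,profile Segment geometry and radial profile (used
#'   also for monolithic conditions so all conditions see the same
#'   detector acceptance).
#' @param noise_sigma Trace noise sd.
#' @param duration Calibration stream duration (us).
#' @param grid Thresholds to try, as fractions of [working_peak()].
#' @param height_cv Pulse-height coefficient of variation.
#' @param seed Integer seed for the calibration stream (held out from
#'   the measurement reps).
#' @param ... Further [discriminator_config()] settings.
#' @return The best threshold (signal units of the working domain).
#' @export
optimize_threshold <- function(rate, mode, kernel, segmented = FALSE,
                               geometry = geometry_quadrants_rings(),
                               profile = radial_profile_powerlaw(25, 130),
                               noise_sigma = 0.02, duration = 1000,
                               grid = seq(0.15, 0.85, by = 0.05),
                               height_cv = 0.15, seed = 1, ...) {
  wp <- working_peak(kernel, mode,
                     gradient_lag = list(...)$gradient_lag %||% 4L)
  ev <- simulate_events(rate, duration, cv = height_cv,
                        geometry = geometry, profile = profile,
                        seed = seed)
  best <- NULL
  best_err <- Inf
  for (fr in grid) {
    cfg <- .condition_config(mode, fr * wp, ...)
    ct <- .count_detected(ev, kernel, cfg, segmented, noise_sigma,
                          duration, noise_seed = seed + 7919L)
    err <- abs(ct["detected"] / max(ct["true"], 1) - 1)
    if (err < best_err) {
      best_err <- err
      best <- fr * wp
    }
  }
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Measure detection efficiency at one electron rate
#'
#' Repeats, `n_reps` times: draw a Poisson electron stream, distribute
#' it over the detector, synthesize the trace(s) (one per segment for
#' segmented conditions, one combined trace for monolithic), run the
#' discriminator, and record detected/true. Electrons missing every
#' segment are excluded from truth and traces alike, so segmented and
#' monolithic conditions are compared on identical events.
#'
#' @inheritParams optimize_threshold
#' @param threshold Discriminator threshold; if `NULL`, optimized first
#'   via [optimize_threshold()] on a held-out stream.
#' @param n_reps Number of repetitions (default 100).
#' @param seed Base integer seed; rep `i` uses `seed + i`, so two
#'   conditions run with the same base seed see identical events.
#' @return List with `mean`, `sd`, `efficiencies` (per rep),
#'   `threshold`, and the condition descriptors.
#' @export
run_efficiency_point <- function(rate, mode = "gradient", kernel,
                                 segmented = FALSE, threshold = NULL,
                                 duration = 1000, n_reps = 100,
                                 noise_sigma = 0.02, height_cv = 0.15,
                                 geometry = geometry_quadrants_rings(),
                                 profile = radial_profile_powerlaw(25, 130),
                                 seed = 1, ...) {
  stopifnot(rate > 0)
  if (rate * duration < 1) {
    stop("duration too short: fewer than one expected event", call. = FALSE)
  }
  if (is.null(threshold)) {
    threshold <- optimize_threshold(rate, mode, kernel, segmented,
                                    geometry, profile, noise_sigma,
                                    duration, height_cv = height_cv,
                                    seed = seed + 1000003L, ...)
  }
  cfg <- .condition_config(mode, threshold, ...)
  eff <- vapply(seq_len(n_reps), function(i) {
    ev <- simulate_events(rate, duration, cv = height_cv,
                          geometry = geometry, profile = profile,
                          seed = seed + i)
    ct <- .count_detected(ev, kernel, cfg, segmented, noise_sigma,
                          duration, noise_seed = seed + i + 500009L)
    if (ct["true"] == 0) NA_real_ else ct["detected"] / ct["true"]
  }, numeric(1))
  eff <- eff[!is.na(eff)]
  list(mean = mean(eff), sd = stats::sd(eff), efficiencies = eff,
       threshold = threshold, rate = rate, mode = mode,
       segmented = segmented, kernel = kernel$kind, n_reps = n_reps,
       seed = seed)
}

#' Detection-efficiency curves across rates and conditions
#'
#' Evaluates the cross product of electron rates and detector/
#' discriminator conditions with a common base seed, so every condition
#' is measured on identical electron events (a paired design: condition
#' orderings are then deterministic given the seed).
#'
#' @param rates Numeric vector of electron rates (e-/us).
#' @param conditions Data frame with columns `mode`
#'   (`"amplitude"`/`"gradient"`), `segmented` (logical), `kernel`
#'   (`"scintillator"`/`"solid_state"`). Default: the four
#'   scintillator conditions.
#' @inheritParams run_efficiency_point
#' @param sample_period ADC sample period (ns) for the kernels.
#' @return A data frame of class `efficiency_curve`: one row per
#'   rate x condition with `mean_eff`, `sd_eff`, `threshold`, `n_reps`,
#'   `seed`.
#' @export
run_efficiency_curve <- function(rates,
                                 conditions = expand.grid(
                                   mode = c("amplitude", "gradient"),
                                   segmented = c(FALSE, TRUE),
                                   kernel = "scintillator",
                                   stringsAsFactors = FALSE),
                                 duration = 1000, n_reps = 100,
                                 noise_sigma = 0.02, height_cv = 0.15,
                                 geometry = geometry_quadrants_rings(),
                                 profile = radial_profile_powerlaw(25, 130),
                                 sample_period = 8, seed = 1, ...) {
  stopifnot(length(rates) >= 1, nrow(conditions) >= 1)
  kernels <- list(
    scintillator = make_kernel("scintillator",
                               sample_period = sample_period),
    solid_state = make_kernel("solid_state", sample_period = sample_period)
  )
  rows <- list()
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    k <- kernels[[cond$kernel]]
    for (r in rates) {
      pt <- run_efficiency_point(
        rate = r, mode = cond$mode, kernel = k,
        segmented = cond$segmented, duration = duration,
        n_reps = n_reps, noise_sigma = noise_sigma,
        height_cv = height_cv, geometry = geometry, profile = profile,
        seed = seed, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        rate = r, mode = cond$mode, segmented = cond$segmented,
        kernel = cond$kernel, mean_eff = pt$mean, sd_eff = pt$sd,
        threshold = pt$threshold, n_reps = n_reps, seed = seed)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("efficiency_curve", class(out))
  out
}

#' @export
plot.efficiency_curve <- function(x, ...) {
  key <- interaction(x$mode, ifelse(x$segmented, "seg", "mono"), x$kernel)
  cols <- grDevices::hcl.colors(nlevels(key), "Dark 3")
  graphics::plot(range(x$rate), c(0, 1.05), type = "n", log = "x",
                 xlab = "expected electrons per us",
                 ylab = "detection efficiency", ...)
  for (i in seq_len(nlevels(key))) {
    d <- x[key == levels(key)[i], ]
    d <- d[order(d$rate), ]
    graphics::lines(d$rate, d$mean_eff, col = cols[i], type = "b", pch = 16)
  }
  graphics::legend("bottomleft", legend = levels(key), col = cols,
                   lty = 1, pch = 16, cex = 0.8, bty = "n")
  invisible(x)
}

#' Bootstrap confidence that one condition beats another
#'
#' For two paired efficiency vectors (same events, same reps), the
#' fraction of bootstrap resamples of the per-rep differences whose
#' mean is non-negative — the confidence that condition `a` is at least
#' as efficient as condition `b`.
#'
#' @param a,b Per-rep efficiency vectors of equal length (e.g.
#'   `$efficiencies` from [run_efficiency_point()]).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Optional integer seed.
#' @return Fraction in `[0, 1]`.
#' @export
bootstrap_ordering_confidence <- function(a, b, n_boot = 2000,
                                          seed = NULL) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (!is.null(seed)) set.seed(seed)
  d <- a - b
  n <- length(d)
  means <- vapply(seq_len(n_boot),
                  function(i) mean(d[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  mean(means >= 0)
}
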