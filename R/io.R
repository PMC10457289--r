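KERNEL_CSV_HEADER <- "# pulsecount-kernel v1"

#' Read and write pulse kernels as CSV
#'
#' The kernel exchange format is a two-column CSV `time_ns, amplitude`
#' with the tag line `# pulsecount-kernel v1` first, so measured
#' single-electron responses can be moved between tools.
#'
#' @param kernel A `pulse_kernel`.
#' @param path File path.
#' @return `read_kernel_csv` returns a `pulse_kernel`;
#'   `write_kernel_csv` returns `path` invisibly.
#' @export
write_kernel_csv <- function(kernel, path) {
  stopifnot(inherits(kernel, "pulse_kernel"))
  t_ns <- (seq_along(kernel$samples) - 1) * kernel$sample_period
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(KERNEL_CSV_HEADER, "time_ns,amplitude"), con)
  utils::write.table(data.frame(t_ns, kernel$samples), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel_csv
#' @export
read_kernel_csv <- function(path) {
  first <- readLines(path, n = 1)
  if (!identical(first, KERNEL_CSV_HEADER)) {
    stop("not a pulse-kernel CSV (missing '", KERNEL_CSV_HEADER, "' tag)",
         call. = FALSE)
  }
  d <- utils::read.csv(path, skip = 1)
  if (nrow(d) < 3) stop("kernel CSV has too few samples", call. = FALSE)
  dt <- unique(round(diff(d[[1]]), 9))
  if (length(dt) != 1) {
    stop("kernel CSV must be uniformly sampled", call. = FALSE)
  }
  kernel_from_samples(d[[2]], dt)
}

#' Read and write analog traces
#'
#' Two dialects round-trip losslessly: a two-column CSV
#' (`time_ns, value`) carrying the metadata in `#`-comment header
#' lines, and a raw little-endian binary (float32, or uint16 when
#' ADC-quantized) with a JSON sidecar `<path>.json` holding
#' `sample_period_ns`, `baseline`, `adc_bits`, `adc_range` and `dtype`.
#'
#' @param trace An `analog_trace`.
#' @param path Output path (sidecar written at `<path>.json` for
#'   binary).
#' @param format `"csv"` or `"binary"`; inferred from the extension
#'   (`.csv` vs anything else) when `NULL`.
#' @return `read_trace` returns an `analog_trace`; `write_trace`
#'   returns `path` invisibly.
#' @export
write_trace <- function(trace, path, format = NULL) {
  stopifnot(inherits(trace, "analog_trace"))
  format <- format %||% (if (grepl("\\.csv$", path, TRUE)) "csv" else "binary")
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# pulsecount-trace v1",
                 sprintf("# sample_period_ns=%.9g", trace$sample_period),
                 sprintf("# baseline=%.9g", trace$baseline),
                 sprintf("# adc_bits=%s", trace$adc_bits %||% "none"),
                 sprintf("# adc_range=%s",
                         if (is.null(trace$adc_range)) "none"
                         else sprintf("%.9g", trace$adc_range)),
                 "time_ns,value"), con)
    t_ns <- (seq_along(trace$samples) - 1) * trace$sample_period
    utils::write.table(data.frame(t_ns, trace$samples), con, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  } else {
    dtype <- if (is.null(trace$adc_bits)) "float32" else "uint16"
    con <- file(path, "wb")
    on.exit(close(con))
    if (dtype == "float32") {
      writeBin(as.numeric(trace$samples), con, size = 4,
               endian = "little")
    } else {
      writeBin(as.integer(trace$samples), con, size = 2,
               endian = "little")
    }
    jsonlite::write_json(
      list(format = "pulsecount-trace-v1",
           sample_period_ns = trace$sample_period,
           baseline = trace$baseline,
           adc_bits = trace$adc_bits, adc_range = trace$adc_range,
           dtype = dtype, n_samples = length(trace$samples)),
      paste0(path, ".json"), auto_unbox = TRUE, null = "null",
      digits = NA)
  }
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, format = NULL) {
  format <- format %||% (if (grepl("\\.csv$", path, TRUE)) "csv" else "binary")
  if (format == "csv") {
    hdr <- readLines(path, n = 6)
    if (!identical(hdr[1], "# pulsecount-trace v1")) {
      stop("not a pulsecount trace CSV", call. = FALSE)
    }
    meta <- function(key) sub(sprintf("^# %s=", key), "",
                              grep(sprintf("^# %s=", key), hdr, value = TRUE))
    d <- utils::read.csv(path, comment.char = "#")
    if (nrow(d) == 0) stop("trace CSV contains no samples", call. = FALSE)
    if (anyNA(d[[2]])) stop("trace contains NaN samples", call. = FALSE)
    bits <- meta("adc_bits")
    rng <- meta("adc_range")
    structure(list(samples = d[[2]],
                   sample_period = as.numeric(meta("sample_period_ns")),
                   baseline = as.numeric(meta("baseline")),
                   adc_bits = if (bits == "none") NULL else as.integer(bits),
                   adc_range = if (rng == "none") NULL else as.numeric(rng)),
              class = "analog_trace")
  } else {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      stop("binary trace requires a JSON sidecar at ", sidecar,
           call. = FALSE)
    }
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    n <- meta$n_samples
    con <- file(path, "rb")
    on.exit(close(con))
    samples <- if (identical(meta$dtype, "uint16")) {
      as.numeric(readBin(con, "integer", n = n, size = 2, signed = FALSE,
                         endian = "little"))
    } else {
      readBin(con, "numeric", n = n, size = 4, endian = "little")
    }
    if (anyNA(samples) || any(!is.finite(samples))) {
      stop("trace contains NaN samples", call. = FALSE)
    }
    bits <- meta$adc_bits
    if (!is.null(bits) && any(samples > 2^bits - 1)) {
      stop("samples exceed the ADC code range in the sidecar",
           call. = FALSE)
    }
    structure(list(samples = samples,
                   sample_period = meta$sample_period_ns,
                   baseline = meta$baseline %||% 0,
                   adc_bits = if (is.null(bits)) NULL else as.integer(bits),
                   adc_range = meta$adc_range),
              class = "analog_trace")
  }
}

#' Read and write event lists as CSV
#'
#' Columns `time_us, height, segment_id` with a standard header row.
#'
#' @param events An `event_stream`.
#' @param path File path.
#' @param duration Trace duration for the reconstructed stream
#'   (default: last event time).
#' @return `read_events_csv` returns an `event_stream`.
#' @export
write_events_csv <- function(events, path) {
  stopifnot(inherits(events, "event_stream"))
  utils::write.csv(data.frame(time_us = events$times,
                              height = events$heights,
                              segment_id = events$segment_ids),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path, duration = NULL) {
  d <- utils::read.csv(path)
  need <- c("time_us", "height", "segment_id")
  if (!all(need %in% names(d))) {
    stop("events CSV needs columns time_us, height, segment_id",
         call. = FALSE)
  }
  event_stream(d$time_us, d$height, as.integer(d$segment_id),
               duration = duration %||%
                 (if (nrow(d)) max(d$time_us) else 1))
}

#' Read and write images as TIFF
#'
#' Analog images are stored as 32-bit float TIFF; counted images as
#' 16-bit unsigned TIFF (integer counts). Float images whose values
#' exceed 1 are divided by a scale factor before writing (the TIFF
#' payload holds unit-range floats) and the factor is recorded in a
#' JSON sidecar `<path>.json`, which `read_image_tiff` applies back
#' automatically.
#'
#' @param image Numeric matrix, non-negative.
#' @param path File path.
#' @param type `"float"` (32-bit) or `"uint16"`.
#' @return `read_image_tiff` returns a numeric matrix.
#' @export
write_image_tiff <- function(image, path, type = c("float", "uint16")) {
  type <- match.arg(type)
  image <- as.matrix(image)
  if (any(image < 0)) stop("image must be non-negative", call. = FALSE)
  if (type == "float") {
    scale <- max(1, max(image))
    tiff::writeTIFF(image / scale, path, bits.per.sample = 32L,
                    reduce = FALSE)
    if (scale > 1) {
      jsonlite::write_json(list(format = "pulsecount-image-v1",
                                scale = scale),
                           paste0(path, ".json"), auto_unbox = TRUE,
                           digits = NA)
    }
  } else {
    if (any(image > 65535)) {
      stop("counts outside the uint16 range", call. = FALSE)
    }
    tiff::writeTIFF(round(image) / 65535, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  raw <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e) NULL)
  if (length(dim(img)) == 3) img <- img[, , 1]
  if (!is.null(raw) && length(dim(raw)) == 3) raw <- raw[, , 1]
  # 16-bit files: the as.is integers equal the normalized values
  # rescaled; float payloads fail that identity
  if (!is.null(raw) && max(abs(raw - img * 65535)) < 0.5) {
    return(raw)
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    img <- img * jsonlite::read_json(sidecar)$scale
  }
  img
}

#' Derive a reproducible per-module seed from a global seed
#'
#' A single run seed is expanded into independent per-module seeds by a
#' fixed affine-hash derivation, so adding one simulation stage never
#' perturbs another stage's random draws.
#'
#' @param seed Global integer seed.
#' @param module Module label (any string).
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, module) {
  stopifnot(length(seed) == 1, is.finite(seed))
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (code in utf8ToInt(module)) h <- (h * 257 + code) %% m
  s <- (abs(as.numeric(seed)) %% m)
  as.integer(max(1, (s * 16807 + h) %% m))
}

#' Read a structured run configuration
#'
#' Run configurations are YAML files whose sections mirror the
#' parameter sets of the simulation stages. Unknown keys are rejected
#' so typos fail loudly rather than silently running defaults.
#'
#' @param path YAML file path.
#' @param allowed Named list: section name -> allowed keys (defaults to
#'   the full schema used by the command-line interface).
#' @return Named list of sections.
#' @export
read_run_config <- function(path, allowed = run_config_schema()) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  bad_sec <- setdiff(names(cfg), names(allowed))
  if (length(bad_sec)) {
    stop("unknown config section(s): ", paste(bad_sec, collapse = ", "),
         call. = FALSE)
  }
  for (sec in names(cfg)) {
    if (is.list(cfg[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), allowed[[sec]])
      if (length(bad)) {
        stop(sprintf("unknown key(s) in [%s]: %s", sec,
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
    }
  }
  cfg
}

#' @rdname read_run_config
#' @export
run_config_schema <- function() {
  list(
    seed = character(0),
    output_dir = character(0),
    kernel = c("kind", "rise_time_ns", "fall_time_us", "sample_period_ns",
               "afterglow_time_us", "afterglow_fraction", "csv"),
    events = c("rate_per_us", "duration_us", "height_cv"),
    trace = c("baseline", "noise_sigma", "adc_bits", "adc_range"),
    discriminator = c("mode", "threshold", "gradient_lag",
                      "min_consecutive_above", "min_consecutive_below",
                      "dead_time", "output_pulse_width", "record_at",
                      "hysteresis"),
    scan = c("nx", "ny", "dwell_ns", "frames", "base_rate_per_us",
             "specimen", "flyback_carryover", "flyback_ns"),
    geometry = c("layout", "radii_mrad", "gap_deg"),
    radial_profile = c("r_min", "r_max", "exponent", "csv"),
    efficiency = c("rates_per_us", "modes", "segmented", "kernels",
                   "n_reps", "duration_us", "noise_sigma")
  )
}

#' Write the resolved configuration next to a run's outputs
#'
#' @param cfg Configuration list (with `seed` filled in).
#' @param dir Output directory.
#' @return The path written, invisibly.
#' @export
write_resolved_config <- function(cfg, dir) {
  path <- file.path(dir, "resolved_config.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# build kernel / discriminator / geometry objects from config sections
.kernel_from_config <- function(kc) {
  kc <- kc %||% list()
  if (!is.null(kc$csv)) return(read_kernel_csv(kc$csv))
  k <- make_kernel(kc$kind %||% "scintillator",
                   rise_time = kc$rise_time_ns,
                   fall_time = kc$fall_time_us,
                   sample_period = kc$sample_period_ns %||% 8)
  if (!is.null(kc$afterglow_fraction) && kc$afterglow_fraction > 0) {
    k <- make_afterglow_kernel(k,
                               slow_decay_time = kc$afterglow_time_us %||% 4.5,
                               slow_fraction = kc$afterglow_fraction)
  }
  k
}

.disc_from_config <- function(dc) {
  dc <- dc %||% list()
  discriminator_config(
    mode = dc$mode %||% "gradient",
    threshold = dc$threshold %||%
      stop("discriminator.threshold is required", call. = FALSE),
    gradient_lag = dc$gradient_lag %||% 4L,
    min_consecutive_above = dc$min_consecutive_above %||% 2L,
    min_consecutive_below = dc$min_consecutive_below %||% 2L,
    dead_time = dc$dead_time %||% 2L,
    output_pulse_width = dc$output_pulse_width %||% 1L,
    record_at = dc$record_at %||% "run_start",
    hysteresis = dc$hysteresis %||% 0)
}
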