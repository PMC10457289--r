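#' Active-region mask of a detector map
#'
#' The active region is every pixel whose intensity exceeds the
#' midpoint of the map intensities, `(min + max) / 2`. The region need
#' not be continuous: physically separate segments all contribute to
#' the detected signal and are all included. A robust option uses the
#' 1st/99th percentiles instead of min/max, so a single hot pixel
#' cannot shift the midpoint and empty the mask.
#'
#' @param map Numeric matrix of detector-map intensities.
#' @param robust If `TRUE`, midpoint of the 1%/99% quantiles.
#' @return Logical matrix, `TRUE` on the active region.
#' @export
active_region_mask <- function(map, robust = FALSE) {
  map <- as.matrix(map)
  if (!all(is.finite(map))) stop("map contains non-finite values",
                                 call. = FALSE)
  lim <- if (robust) {
    stats::quantile(map, c(0.01, 0.99), names = FALSE)
  } else {
    range(map)
  }
  if (diff(lim) == 0) {
    stop("degenerate map: constant intensities, no active region",
         call. = FALSE)
  }
  map > mean(lim)
}

#' Normalize a detector map
#'
#' Rescales intensities to the range spanned by the background level and
#' the mean of the active region: background maps to 0 and the active
#' region averages exactly 1, making sensitivity deviations directly
#' comparable across detectors and acquisition modes.
#'
#' @param map Numeric matrix.
#' @param mask Active-region mask from [active_region_mask()].
#' @return Normalized numeric matrix.
#' @export
normalize_map <- function(map, mask = active_region_mask(map)) {
  map <- as.matrix(map)
  stopifnot(identical(dim(map), dim(mask)))
  if (!any(mask) || all(mask)) {
    stop("mask must contain both active and background pixels",
         call. = FALSE)
  }
  bg <- mean(map[!mask])
  act <- mean(map[mask])
  if (act == bg) stop("degenerate map: active mean equals background",
                      call. = FALSE)
  (map - bg) / (act - bg)
}

# Background pixels enclosed by the active region (the detector's inner
# opening): background not reachable from the image border through
# background, found by vectorised flood fill.
.enclosed_hole <- function(mask) {
  bg <- !mask
  reach <- matrix(FALSE, nrow(bg), ncol(bg))
  reach[1, ] <- bg[1, ]; reach[nrow(bg), ] <- bg[nrow(bg), ]
  reach[, 1] <- reach[, 1] | bg[, 1]
  reach[, ncol(bg)] <- reach[, ncol(bg)] | bg[, ncol(bg)]
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-nrow(reach), ]
    grown[-nrow(reach), ] <- grown[-nrow(reach), ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -ncol(reach)]
    grown[, -ncol(reach)] <- grown[, -ncol(reach)] | reach[, -1]
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  bg & !reach
}

#' Ellipticity of the detector inner opening
#'
#' Deviation of the annular detector's inner opening from a circle,
#' as the ratio of its major to minor diameters. The opening is the
#' background region fully enclosed by the active region; an ellipse is
#' fitted to it by second-moment (covariance) analysis, which is exact
#' for a filled ellipse and rotation invariant.
#'
#' @param mask Active-region mask.
#' @return List with `ratio` (`>= 1`), `major`, `minor` (diameters in
#'   pixels), `center` (x, y in pixel coordinates) and `angle`
#'   (major-axis angle, degrees).
#' @export
ellipticity <- function(mask) {
  hole <- .enclosed_hole(mask)
  if (sum(hole) < 9) {
    stop("no enclosed inner opening found; ellipticity undefined for ",
         "non-annular detectors", call. = FALSE)
  }
  idx <- which(hole, arr.ind = TRUE)
  xy <- cbind(x = idx[, "col"], y = idx[, "row"])
  ctr <- colMeans(xy)
  cv <- stats::cov(xy) * (nrow(xy) - 1) / nrow(xy)
  ev <- eigen(cv, symmetric = TRUE)
  lambda <- pmax(ev$values, 0)
  # for a filled ellipse with semi-axes a >= b: lambda = a^2/4, b^2/4
  major <- 4 * sqrt(lambda[1])
  minor <- 4 * sqrt(lambda[2])
  ang <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi
  list(ratio = major / minor, major = major, minor = minor,
       center = ctr, angle = ang)
}

# radial distance of every pixel from a center (x, y) in pixel coords
.pixel_radii <- function(dims, center) {
  x <- matrix(rep(seq_len(dims[2]), each = dims[1]), dims[1])
  y <- matrix(rep(seq_len(dims[1]), dims[2]), dims[1])
  list(r = sqrt((x - center[1])^2 + (y - center[2])^2),
       az = (atan2(y - center[2], x - center[1]) * 180 / pi) %% 360)
}

#' Radial sensitivity profile and flatness score
#'
#' Detector sensitivity as a function of scattering angle: the
#' normalized map is averaged azimuthally (over active pixels) in
#' 1-pixel radial bins. Bins where the azimuthal average of the active
#' mask falls below 0.9 are excluded, so breaks between segments or the
#' map edges do not contaminate the profile. The flatness score is the
#' RMS deviation of the profile from 1 over the valid range (0 = ideal).
#'
#' @param nmap Normalized map from [normalize_map()].
#' @param mask Active-region mask.
#' @param center Center (x, y) in pixel coordinates; defaults to the
#'   inner-opening centroid when present, else the mask centroid.
#' @param coverage Minimum active fraction for a radial bin to count
#'   (default 0.9).
#' @return List with `radius` (bin centers, px), `profile`, `score`,
#'   `r_in`, `r_out` (valid radial range).
#' @export
flatness <- function(nmap, mask, center = NULL, coverage = 0.9) {
  if (is.null(center)) center <- .qc_center(mask)
  px <- .pixel_radii(dim(nmap), center)
  rbin <- floor(px$r) + 1L
  nb <- max(rbin)
  tot_n <- tabulate(rbin, nb)
  act_n <- tabulate(rbin[mask], nb)
  cov_bin <- act_n / pmax(tot_n, 1)
  valid <- which(cov_bin >= coverage & tot_n > 0)
  if (length(valid) < 3) {
    stop("fewer than 3 radial bins meet the coverage requirement; ",
         "annulus too thin or too broken", call. = FALSE)
  }
  act_sum <- numeric(nb)
  tmp <- rowsum(nmap[mask], rbin[mask])
  act_sum[as.integer(rownames(tmp))] <- tmp[, 1]
  profile <- act_sum[valid] / act_n[valid]
  list(radius = valid - 0.5, profile = profile,
       score = sqrt(mean((profile - 1)^2)),
       r_in = min(valid) - 1, r_out = max(valid))
}

#' Azimuthal sensitivity profile and roundness score
#'
#' Detector sensitivity around the detector: within the valid radial
#' range established by [flatness()], the normalized map is averaged
#' radially in azimuthal bins (default 360). All pixels in the annulus
#' are included — dead wedges and inter-segment gaps contribute their
#' (low) signal, which is exactly the non-uniformity this metric
#' measures. The roundness score is the RMS deviation of the profile
#' from 1.
#'
#' @inheritParams flatness
#' @param n_bins Number of azimuthal bins (default 360).
#' @return List with `azimuth` (bin centers, degrees), `profile`,
#'   `score`.
#' @export
roundness <- function(nmap, mask, center = NULL, n_bins = 360,
                      coverage = 0.9) {
  if (is.null(center)) center <- .qc_center(mask)
  fl <- flatness(nmap, mask, center, coverage)
  px <- .pixel_radii(dim(nmap), center)
  inside <- px$r >= fl$r_in & px$r < fl$r_out
  azbin <- pmin(floor(px$az[inside] / (360 / n_bins)) + 1L, n_bins)
  vals <- nmap[inside]
  s <- rowsum(vals, azbin, reorder = TRUE)
  n <- tabulate(azbin, n_bins)
  present <- sort(unique(azbin))
  profile <- rep(NA_real_, n_bins)
  profile[present] <- as.numeric(s) / n[present]
  ok <- !is.na(profile)
  list(azimuth = (seq_len(n_bins) - 0.5) * 360 / n_bins,
       profile = profile,
       score = sqrt(mean((profile[ok] - 1)^2)))
}

#' Pixel-level smoothness score
#'
#' Dispersion of individual pixel sensitivities against the detector
#' average: the RMS deviation of active-region pixels of the normalized
#' map from 1. Optionally the map is median-filter detrended first, so
#' slow radial/azimuthal structure (already captured by flatness and
#' roundness) is removed and only point-to-point variation remains.
#'
#' @inheritParams flatness
#' @param detrend If `TRUE`, subtract a 3x3 median filter before
#'   scoring (deviations are then measured around the local level).
#' @return Scalar RMS score (0 = ideal).
#' @export
smoothness <- function(nmap, mask, detrend = FALSE) {
  stopifnot(identical(dim(nmap), dim(mask)), any(mask))
  if (detrend) {
    med <- .median3(nmap)
    dev <- (nmap - med)[mask]
  } else {
    dev <- nmap[mask] - 1
  }
  sqrt(mean(dev^2))
}

# 3x3 median filter with edge replication
.median3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  stack <- vapply(1:9, function(k) {
    dy <- (k - 1) %% 3; dx <- (k - 1) %/% 3
    pad[dy + seq_len(nr), dx + seq_len(nc)]
  }, m)
  apply(stack, c(1, 2), stats::median)
}

.qc_center <- function(mask) {
  hole <- .enclosed_hole(mask)
  if (sum(hole) >= 9) {
    idx <- which(hole, arr.ind = TRUE)
    return(c(mean(idx[, "col"]), mean(idx[, "row"])))
  }
  # no enclosed opening (e.g. a dead wedge bridges the hole to the
  # outside): the bounding-box centre of the active region is robust
  # against such asymmetric drop-outs, unlike the mask centroid
  idx <- which(mask, arr.ind = TRUE)
  c(mean(range(idx[, "col"])), mean(range(idx[, "row"])))
}

#' Full detector-map quality report
#'
#' Runs the complete uniformity analysis on a detector map: active
#' region and normalization, ellipticity of the inner opening (skipped
#' with `NA` for non-annular detectors), and the flatness, roundness
#' and smoothness profiles/scores.
#'
#' @param map Numeric matrix (a detector map as scanned).
#' @param robust Passed to [active_region_mask()].
#' @param detrend Passed to [smoothness()].
#' @return A `detector_qc_report` list: `ellipticity`, `flatness`,
#'   `roundness`, `smoothness_score`, `mask`, `center`, `normalized`.
#' @export
detector_qc <- function(map, robust = FALSE, detrend = FALSE) {
  map <- as.matrix(map)
  mask <- active_region_mask(map, robust = robust)
  nmap <- normalize_map(map, mask)
  ell <- tryCatch(ellipticity(mask), error = function(e) NULL)
  center <- if (!is.null(ell)) ell$center else .qc_center(mask)
  fl <- flatness(nmap, mask, center)
  rd <- roundness(nmap, mask, center)
  structure(list(
    ellipticity = if (!is.null(ell)) ell$ratio else NA_real_,
    ellipse = ell,
    flatness = fl, roundness = rd,
    flatness_score = fl$score, roundness_score = rd$score,
    smoothness_score = smoothness(nmap, mask, detrend = detrend),
    mask = mask, center = center, normalized = nmap,
    r_in = fl$r_in, r_out = fl$r_out
  ), class = "detector_qc_report")
}

#' @export
print.detector_qc_report <- function(x, ...) {
  cat("Detector map QC\n")
  cat(sprintf("  ellipticity : %s\n",
              if (is.na(x$ellipticity)) "n/a (no inner opening)"
              else sprintf("%.4f", x$ellipticity)))
  cat(sprintf("  flatness    : %.4g (RMS, radial)\n", x$flatness_score))
  cat(sprintf("  roundness   : %.4g (RMS, azimuthal)\n", x$roundness_score))
  cat(sprintf("  smoothness  : %.4g (RMS, pixel)\n", x$smoothness_score))
  cat(sprintf("  active radii: %g - %g px\n", x$r_in, x$r_out))
  invisible(x)
}

#' Render a synthetic detector map
#'
#' Generates detector-map images with known, controllable imperfections
#' for validating the QC metrics: a segment geometry with per-segment
#' sensitivities (inter-segment gaps render at background), an injected
#' inner-opening ellipticity, a linear radial sensitivity ramp, a
#' sinusoidal azimuthal modulation, and white pixel noise.
#'
#' @param geometry A [detector_geometry()] (radii in mrad).
#' @param n Image size in pixels (n x n, default 256).
#' @param sensitivities Per-segment relative sensitivity (recycled).
#' @param bg,active Background and nominal active intensity levels.
#' @param ellipticity Axis ratio to stretch the map by (1 = circular);
#'   the x axis is widened and y narrowed so the area is preserved.
#' @param radial_ramp Amplitude `a` of a sensitivity ramp
#'   `1 + a * (r - r_mid) / (r_out - r_in)` across the detector span.
#' @param az_amplitude Amplitude of `1 + az_amplitude * sin(azimuth)`.
#' @param noise_sd Gaussian pixel noise, in units of `active - bg`.
#' @param rotate Rotation of the whole pattern, degrees.
#' @param scale Pixels per mrad; default fits the geometry with a
#'   10% margin.
#' @param seed Optional integer seed.
#' @return Numeric `n x n` matrix.
#' @export
synth_detector_map <- function(geometry, n = 256, sensitivities = 1,
                               bg = 10, active = 30, ellipticity = 1,
                               radial_ramp = 0, az_amplitude = 0,
                               noise_sd = 0, rotate = 0, scale = NULL,
                               seed = NULL) {
  stopifnot(inherits(geometry, "detector_geometry"), n >= 64,
            ellipticity >= 1, active != bg)
  seg <- geometry$segments
  r_max <- max(seg$r_out)
  if (is.null(scale)) scale <- 0.45 * n / (r_max * sqrt(ellipticity))
  if (r_max * scale * sqrt(ellipticity) > n / 2) {
    stop("grid too small for this geometry at the requested scale",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sens <- rep_len(sensitivities, nrow(seg))
  ctr <- (n + 1) / 2
  x <- matrix(rep(seq_len(n), each = n), n) - ctr
  y <- matrix(rep(seq_len(n), n), n) - ctr
  if (rotate != 0) {
    th <- rotate * pi / 180
    xr <- x * cos(th) + y * sin(th)
    yr <- -x * sin(th) + y * cos(th)
    x <- xr; y <- yr
  }
  # anisotropic radius: x axis stretched by sqrt(e), y shrunk by sqrt(e)
  r <- sqrt((x / (scale * sqrt(ellipticity)))^2 +
              (y * sqrt(ellipticity) / scale)^2)
  az <- (atan2(y, x) * 180 / pi) %% 360
  r_in_all <- min(seg$r_in); r_out_all <- max(seg$r_out)
  r_mid <- (r_in_all + r_out_all) / 2
  map <- matrix(bg, n, n)
  for (i in seq_len(nrow(seg))) {
    hit <- r >= seg$r_in[i] & r < seg$r_out[i] &
      az >= seg$az_start[i] & az < seg$az_end[i]
    s <- sens[i] *
      (1 + radial_ramp * (r[hit] - r_mid) / (r_out_all - r_in_all)) *
      (1 + az_amplitude * sin(az[hit] * pi / 180))
    map[hit] <- bg + (active - bg) * s
  }
  if (noise_sd > 0) {
    map <- map + stats::rnorm(n * n, 0, noise_sd * abs(active - bg))
  }
  map
}
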