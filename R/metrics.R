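# Peak-quality measurements: baseline, noise, apex, half-height widths,
# skewness, area, SNR, replicate retention-time difference.

#' Validate a chromatogram table
#'
#' A chromatogram is a tibble/data frame with a strictly increasing,
#' uniformly spaced `time_min` column and a finite `intensity` column of the
#' same length (at least 16 points).
#'
#' @param chrom Data frame to validate.
#' @return The chromatogram as a tibble, invisibly usable downstream.
#' @export
validate_chromatogram <- function(chrom) {
  if (!is.data.frame(chrom) ||
      !all(c("time_min", "intensity") %in% names(chrom))) {
    stop_chromaqc("Chromatogram needs `time_min` and `intensity` columns.",
                  "chromaqc_parameter_error")
  }
  t <- chrom$time_min
  y <- chrom$intensity
  if (length(t) < 16L) {
    stop_chromaqc("Chromatogram must have at least 16 points.",
                  "chromaqc_parameter_error")
  }
  if (any(!is.finite(t)) || any(!is.finite(y))) {
    stop_chromaqc("Chromatogram values must all be finite.",
                  "chromaqc_parameter_error")
  }
  dt <- diff(t)
  if (any(dt <= 0)) {
    stop_chromaqc("`time_min` must be strictly increasing.",
                  "chromaqc_parameter_error")
  }
  if (diff(range(dt)) > 1e-6 * mean(dt)) {
    stop_chromaqc("`time_min` must be a uniform grid.",
                  "chromaqc_parameter_error")
  }
  as_tibble(chrom[, c("time_min", "intensity")])
}

#' Estimate the idle-region baseline of a chromatogram
#'
#' Fits a straight line by least squares to all points outside the
#' `exclusion_windows` (the idle regions where no peak elutes) and returns
#' the fitted baseline evaluated on the full time grid.
#'
#' @param chrom Chromatogram tibble.
#' @param exclusion_windows List of length-2 time intervals (minutes) to
#'   exclude from the fit, typically one window per expected peak.
#' @return Numeric vector of baseline values, one per grid point, with the
#'   fitted `intercept` and `slope` as attributes.
#' @export
estimate_baseline <- function(chrom, exclusion_windows = list()) {
  chrom <- validate_chromatogram(chrom)
  idle <- !in_windows(chrom$time_min, exclusion_windows)
  if (sum(idle) < max(2L, 0.1 * nrow(chrom))) {
    stop_chromaqc("Exclusion windows leave too few idle points for a baseline fit.",
                  "chromaqc_baseline_error")
  }
  co <- linfit(chrom$time_min[idle], chrom$intensity[idle])
  structure(co[1] + co[2] * chrom$time_min,
            intercept = co[1], slope = co[2])
}

#' Estimate baseline noise
#'
#' Sample standard deviation of the baseline-subtracted signal over the idle
#' points. Because the baseline is removed first, the estimate is invariant
#' under adding any linear drift to the signal.
#'
#' @inheritParams estimate_baseline
#' @param baseline Baseline vector from [estimate_baseline()].
#' @return Noise standard deviation (intensity units).
#' @export
estimate_noise_sd <- function(chrom, baseline, exclusion_windows = list()) {
  chrom <- validate_chromatogram(chrom)
  idle <- !in_windows(chrom$time_min, exclusion_windows)
  if (sum(idle) < 16L) {
    stop_chromaqc("Fewer than 16 idle points; cannot estimate noise.",
                  "chromaqc_noise_error")
  }
  stats::sd(chrom$intensity[idle] - baseline[idle])
}

#' Locate the peak apex
#'
#' Finds the maximum of the baseline-subtracted signal inside
#' `search_window` and refines both apex time and height by a three-point
#' parabolic interpolation around the grid maximum, giving sub-grid
#' retention-time precision.
#'
#' @inheritParams estimate_noise_sd
#' @param search_window Length-2 time interval to search (minutes).
#' @param noise_sd Noise estimate used for the detection floor.
#' @param snr_floor Minimum apex height in units of `noise_sd` for a
#'   detection (default 3).
#' @return List with `apex_time`, `apex_height` (above baseline) and
#'   `apex_index` (grid index of the discrete maximum).
#' @export
detect_apex <- function(chrom, baseline, search_window, noise_sd = 0,
                        snr_floor = 3) {
  chrom <- validate_chromatogram(chrom)
  t <- chrom$time_min
  if (min(search_window) < t[1] || max(search_window) > t[length(t)]) {
    stop_chromaqc("`search_window` must lie inside the time grid.",
                  "chromaqc_parameter_error")
  }
  y <- chrom$intensity - baseline
  win <- which(in_windows(t, search_window))
  i0 <- win[which.max(y[win])]
  apex_time <- t[i0]
  apex_height <- y[i0]
  if (i0 > 1L && i0 < length(t)) {
    yl <- y[i0 - 1L]
    y0 <- y[i0]
    yr <- y[i0 + 1L]
    denom <- yl - 2 * y0 + yr
    if (denom < 0) {
      delta <- 0.5 * (yl - yr) / denom
      dt <- t[2] - t[1]
      apex_time <- t[i0] + delta * dt
      apex_height <- y0 - 0.25 * (yl - yr) * delta
    }
  }
  if (!is.finite(apex_height) || apex_height <= snr_floor * noise_sd) {
    stop_chromaqc("No peak found: apex does not exceed the detection floor.",
                  "chromaqc_no_peak_error")
  }
  list(apex_time = apex_time, apex_height = apex_height, apex_index = i0)
}

# First crossing of `thr` moving outward from the apex index on the
# baseline-subtracted signal; returns interpolated time or NA.
crossing_time <- function(t, y, apex_index, thr, side) {
  if (side == "left") {
    below <- which(y[seq_len(apex_index)] < thr)
    if (length(below) == 0L) return(NA_real_)
    i <- max(below)            # bracket [i, i+1]
    j <- i + 1L
  } else {
    below <- which(y[apex_index:length(y)] < thr)
    if (length(below) == 0L) return(NA_real_)
    j <- apex_index + min(below) - 1L   # bracket [j-1, j]
    i <- j - 1L
  }
  if (y[j] == y[i]) return(t[if (side == "left") j else i])
  t[i] + (thr - y[i]) / (y[j] - y[i]) * (t[j] - t[i])
}

#' Half-height peak widths
#'
#' Finds the first crossings of `x * apex_height` moving left and right from
#' the apex on the baseline-subtracted signal (linear interpolation between
#' bracketing grid points) and returns the horizontal distances from the
#' apex to each crossing.
#'
#' @inheritParams detect_apex
#' @param apex Apex list from [detect_apex()].
#' @param x Height fraction in (0, 1) at which widths are measured
#'   (default 0.5, i.e. half height).
#' @return List with `wl` and `wr` (minutes, both > 0).
#' @export
half_height_widths <- function(chrom, baseline, apex, x = 0.5) {
  chrom <- validate_chromatogram(chrom)
  if (!is.numeric(x) || x <= 0 || x >= 1) {
    stop_chromaqc("`x` must lie in (0, 1).", "chromaqc_parameter_error")
  }
  t <- chrom$time_min
  y <- chrom$intensity - baseline
  thr <- x * apex$apex_height
  tl <- crossing_time(t, y, apex$apex_index, thr, "left")
  tr <- crossing_time(t, y, apex$apex_index, thr, "right")
  if (is.na(tl) || is.na(tr)) {
    stop_chromaqc("Signal never falls below the width threshold on one side.",
                  "chromaqc_unresolved_peak_error")
  }
  list(wl = apex$apex_time - tl, wr = tr - apex$apex_time)
}

#' Peak skewness from half widths
#'
#' The asymmetry statistic is the ratio of the right to the left half-width
#' at the chosen height fraction. A value of 1 is a symmetric peak, values
#' below 1 indicate fronting (skewed to the left) and values above 1
#' tailing.
#'
#' @param wl,wr Left and right half widths (minutes).
#' @return `wr / wl` (dimensionless).
#' @export
measure_skewness <- function(wl, wr) {
  if (!is.numeric(wl) || !is.numeric(wr) || anyNA(c(wl, wr))) {
    stop_chromaqc("Widths must be numeric.", "chromaqc_parameter_error")
  }
  if (any(wl <= 0)) {
    stop_chromaqc("Degenerate peak: left width must be > 0.",
                  "chromaqc_degenerate_peak_error")
  }
  wr / wl
}

#' Peak area by trapezoidal integration
#'
#' Integrates the baseline-subtracted signal, clipped below at zero, over
#' `[left_bound, right_bound]` with the trapezoid rule; the bounds are
#' interpolated onto the grid so partial end segments are included exactly.
#'
#' @inheritParams detect_apex
#' @param left_bound,right_bound Integration window (minutes),
#'   `left_bound < right_bound`, both inside the grid.
#' @return Area in intensity x minutes (>= 0).
#' @export
measure_area <- function(chrom, baseline, left_bound, right_bound) {
  chrom <- validate_chromatogram(chrom)
  t <- chrom$time_min
  if (left_bound >= right_bound) {
    stop_chromaqc("`left_bound` must be smaller than `right_bound`.",
                  "chromaqc_parameter_error")
  }
  if (left_bound < t[1] || right_bound > t[length(t)]) {
    stop_chromaqc("Integration bounds must lie inside the time grid.",
                  "chromaqc_parameter_error")
  }
  y <- pmax(chrom$intensity - baseline, 0)
  inner <- t > left_bound & t < right_bound
  tt <- c(left_bound, t[inner], right_bound)
  yy <- c(approx(t, y, xout = left_bound)$y, y[inner],
          approx(t, y, xout = right_bound)$y)
  sum(diff(tt) * (head(yy, -1) + yy[-1]) / 2)
}

#' Signal-to-noise ratio
#'
#' Apex height above baseline divided by the standard deviation of the
#' idle-region baseline noise. Scale-invariant: multiplying the whole
#' signal (peak and noise alike) by a constant leaves it unchanged.
#'
#' @param apex_height Peak apex height above baseline.
#' @param noise_sd Baseline noise standard deviation.
#' @return SNR (dimensionless); `Inf` when `noise_sd` is exactly zero
#'   (noiseless signal).
#' @export
measure_snr <- function(apex_height, noise_sd) {
  check_number(apex_height, "apex_height", positive = TRUE)
  check_number(noise_sd, "noise_sd", finite = TRUE)
  if (noise_sd < 0) {
    stop_chromaqc("`noise_sd` must be >= 0.", "chromaqc_parameter_error")
  }
  if (noise_sd == 0) {
    return(Inf)
  }
  apex_height / noise_sd
}

#' Replicate retention-time difference
#'
#' Signed difference between the retention times of the two replicate runs,
#' `tr_run1 - tr_run2`; a negative value means the compound eluted later in
#' the second run.
#'
#' @param tr_run1,tr_run2 Retention times (minutes) of runs 1 and 2. An
#'   `NA` replicate yields an `NA` delta (missing-value sentinel).
#' @param compound_id Optional identifier carried into the result.
#' @return One-row tibble: `compound_id`, `tr_run1`, `tr_run2`, `delta`.
#' @export
compute_delta_tr <- function(tr_run1, tr_run2, compound_id = NA_character_) {
  for (v in list(tr_run1, tr_run2)) {
    if (!is.na(v) && (!is.numeric(v) || !is.finite(v) || v <= 0)) {
      stop_chromaqc("Retention times must be finite and > 0 (or NA if missing).",
                    "chromaqc_parameter_error")
    }
  }
  tibble(compound_id = compound_id, tr_run1 = tr_run1, tr_run2 = tr_run2,
         delta = tr_run1 - tr_run2)
}

# Integration bounds: first points, scanning outward from the apex, where
# the baseline-subtracted signal drops below max(0.5 * noise_sd,
# 1e-12 * height); capped at the search window.
find_integration_bounds <- function(chrom, baseline, apex, noise_sd,
                                    search_window) {
  t <- chrom$time_min
  y <- chrom$intensity - baseline
  thr <- max(0.5 * noise_sd, 1e-12 * apex$apex_height)
  lo <- max(t[1], min(search_window))
  hi <- min(t[length(t)], max(search_window))
  tl <- crossing_time(t, y, apex$apex_index, thr, "left")
  tr <- crossing_time(t, y, apex$apex_index, thr, "right")
  c(left = max(lo, if (is.na(tl)) lo else tl),
    right = min(hi, if (is.na(tr)) hi else tr))
}

#' Measure one peak on a single run
#'
#' Composes baseline estimation, noise estimation, apex detection, width
#' measurement, skewness, area and SNR for a single chromatogram and peak
#' window.
#'
#' @param chrom Chromatogram tibble.
#' @param window Length-2 time interval containing the peak; also used as
#'   the baseline exclusion window.
#' @param x Height fraction for the width measurement (default 0.5).
#' @param snr_floor Detection floor passed to [detect_apex()].
#' @return One-row tibble: `apex_time`, `apex_height`, `wl`, `wr`,
#'   `skewness`, `area`, `snr`, `noise_sd`, `left_bound`, `right_bound`.
#' @export
measure_run <- function(chrom, window, x = 0.5, snr_floor = 3) {
  chrom <- validate_chromatogram(chrom)
  baseline <- estimate_baseline(chrom, list(window))
  noise_sd <- estimate_noise_sd(chrom, baseline, list(window))
  apex <- detect_apex(chrom, baseline, window, noise_sd, snr_floor)
  w <- half_height_widths(chrom, baseline, apex, x)
  bounds <- find_integration_bounds(chrom, baseline, apex, noise_sd, window)
  area <- measure_area(chrom, baseline, bounds[["left"]], bounds[["right"]])
  tibble(
    apex_time = apex$apex_time, apex_height = apex$apex_height,
    wl = w$wl, wr = w$wr, skewness = measure_skewness(w$wl, w$wr),
    area = area, snr = measure_snr(apex$apex_height, noise_sd),
    noise_sd = noise_sd,
    left_bound = bounds[["left"]], right_bound = bounds[["right"]]
  )
}

#' Measure a replicate chromatogram pair
#'
#' Produces one quality row per compound: run 1 supplies retention time,
#' SNR, skewness and area; run 2 contributes only its retention time, from
#' which the replicate difference is computed. Failed measurements are
#' recorded as missing values and the row is flagged rather than dropped,
#' so the caller can report and then filter.
#'
#' @param run1,run2 Chromatogram tibbles for the two replicates.
#' @param compound_id Identifier for the row.
#' @param window Length-2 time interval containing the peak in both runs.
#' @param x Height fraction for widths (default 0.5).
#' @param snr_floor Detection floor in noise-sd units.
#' @return One-row tibble: `compound_id`, `delta_tr`, `snr`, `skewness`,
#'   `peak_area`, `tr`, `tr_run2`, `ok` (logical), `note` (why a metric is
#'   missing, or `""`).
#' @export
measure_peak <- function(run1, run2, compound_id, window, x = 0.5,
                         snr_floor = 3) {
  m1 <- tryCatch(measure_run(run1, window, x, snr_floor),
                 chromaqc_error = function(e) e)
  m2 <- tryCatch(measure_run(run2, window, x, snr_floor),
                 chromaqc_error = function(e) e)
  note <- character(0)
  if (inherits(m1, "error")) note <- c(note, paste("run1:", conditionMessage(m1)))
  if (inherits(m2, "error")) note <- c(note, paste("run2:", conditionMessage(m2)))
  tr1 <- if (inherits(m1, "error")) NA_real_ else m1$apex_time
  tr2 <- if (inherits(m2, "error")) NA_real_ else m2$apex_time
  tibble(
    compound_id = compound_id,
    delta_tr = tr1 - tr2,
    snr = if (inherits(m1, "error")) NA_real_ else m1$snr,
    skewness = if (inherits(m1, "error")) NA_real_ else m1$skewness,
    peak_area = if (inherits(m1, "error")) NA_real_ else m1$area,
    tr = tr1,
    tr_run2 = tr2,
    ok = length(note) == 0L,
    note = paste(note, collapse = "; ")
  )
}

#' Measure every replicate pair in a simulated cohort
#'
#' Applies [measure_peak()] to each pair, centring the measurement window
#' on the compound's true retention time (in real use the operator supplies
#' the expected elution window per compound).
#'
#' @param cohort List from [simulate_cohort()].
#' @param window_halfwidth Half width (minutes) of the per-compound peak
#'   window around the true retention time.
#' @param x Height fraction for widths.
#' @param snr_floor Detection floor in noise-sd units.
#' @return Tibble with one measurement row per compound.
#' @export
measure_cohort <- function(cohort, window_halfwidth = 2, x = 0.5,
                           snr_floor = 3) {
  purrr::map2_dfr(cohort$pairs, seq_along(cohort$pairs), function(pair, i) {
    tr <- pair$truth$true_tr_run1
    measure_peak(pair$run1, pair$run2, pair$truth$compound_id,
                 window = c(tr - window_halfwidth, tr + window_halfwidth),
                 x = x, snr_floor = snr_floor)
  })
}
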