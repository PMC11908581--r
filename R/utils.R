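# Internal helpers: error signalling, seed derivation, numeric checks.

stop_chromaqc <- function(message, class, ...) {
  abort(message, class = c(class, "chromaqc_error"), ...)
}

check_number <- function(x, name, finite = TRUE, positive = FALSE,
                         non_negative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_chromaqc(sprintf("`%s` must be a single number.", name),
                  "chromaqc_parameter_error")
  }
  if (finite && !is.finite(x)) {
    stop_chromaqc(sprintf("`%s` must be finite.", name),
                  "chromaqc_parameter_error")
  }
  if (positive && x <= 0) {
    stop_chromaqc(sprintf("`%s` must be > 0.", name),
                  "chromaqc_parameter_error")
  }
  if (non_negative && x < 0) {
    stop_chromaqc(sprintf("`%s` must be >= 0.", name),
                  "chromaqc_parameter_error")
  }
  invisible(x)
}

# Deterministic sub-stream seeds: one master seed, per-run seeds derived by a
# fixed multiplicative counter scheme (kept below 2^31 - 1 so set.seed() is
# portable). Documented so cohorts are reproducible element-wise.
derive_seed <- function(master_seed, counter) {
  master_seed <- as.double(master_seed)
  counter <- as.double(counter)
  as.integer((master_seed * 48271 + counter * 16807) %% 2147483647)
}

# Linear fit y ~ t by closed-form least squares; returns c(intercept, slope).
linfit <- function(t, y) {
  tbar <- mean(t)
  ybar <- mean(y)
  stt <- sum((t - tbar)^2)
  slope <- if (stt > 0) sum((t - tbar) * (y - ybar)) / stt else 0
  c(ybar - slope * tbar, slope)
}

# Rows of `windows` (list of length-2 numeric, or 2-column matrix) marking
# time intervals; returns logical vector, TRUE where inside any window.
in_windows <- function(time, windows) {
  if (is.null(windows) || length(windows) == 0L) {
    return(rep(FALSE, length(time)))
  }
  if (is.matrix(windows)) {
    windows <- split(windows, seq_len(nrow(windows)))
  }
  if (is.numeric(windows) && length(windows) == 2L) {
    windows <- list(windows)
  }
  inside <- rep(FALSE, length(time))
  for (w in windows) {
    if (length(w) != 2L || !is.numeric(w)) {
      stop_chromaqc("Each window must be a numeric length-2 interval.",
                    "chromaqc_parameter_error")
    }
    lo <- min(w)
    hi <- max(w)
    inside <- inside | (time >= lo & time <= hi)
  }
  inside
}
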