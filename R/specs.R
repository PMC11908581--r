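#' Describe a single chromatographic peak
#'
#' A peak is modelled as an exponentially modified Gaussian (EMG): a Gaussian
#' of width `sigma` centred at `apex_time`, convolved with a one-sided
#' exponential decay of time constant `tau`. `tau = 0` gives a pure,
#' symmetric Gaussian; increasing `tau` produces the tailing shapes typical
#' of real chromatograms. `height` is the apex intensity of the `tau = 0`
#' Gaussian; the convolution preserves area, so for `tau > 0` the rendered
#' apex is lower and shifted late.
#'
#' @param compound_id Identifier for the compound the peak belongs to.
#' @param apex_time Centre of the underlying Gaussian, in minutes.
#' @param height Apex intensity of the `tau = 0` Gaussian (must be > 0).
#' @param sigma Gaussian width in minutes (must be > 0).
#' @param tau Exponential tailing constant in minutes (>= 0; 0 = symmetric).
#' @return A `peak_spec` list.
#' @examples
#' peak_spec("cmp1", apex_time = 10, height = 100, sigma = 0.06)
#' @export
peak_spec <- function(compound_id, apex_time, height, sigma, tau = 0) {
  check_number(apex_time, "apex_time")
  check_number(height, "height", positive = TRUE)
  check_number(sigma, "sigma", positive = TRUE)
  check_number(tau, "tau", non_negative = TRUE)
  structure(
    list(compound_id = as.character(compound_id), apex_time = apex_time,
         height = height, sigma = sigma, tau = tau),
    class = "peak_spec"
  )
}

#' Describe a full chromatographic run
#'
#' Collects everything needed to render one chromatogram: the uniform time
#' grid, the peaks, a linear baseline and the standard deviation of the
#' i.i.d. Gaussian detector noise. The signal model is
#' `Y(t) = B(t) + P(t) + N(t)` with `B` linear, `P` a sum of EMG peaks and
#' `N` Gaussian noise.
#'
#' @param time_start,time_end Run window in minutes (`time_end > time_start`).
#' @param sampling_interval Grid spacing in minutes. The default 0.005 min
#'   resolves half-height crossings to well under 1% for sigma >= 0.05 min.
#' @param peaks List of [peak_spec()] objects (may be empty).
#' @param baseline_intercept,baseline_slope Linear baseline parameters
#'   (intensity, intensity/minute).
#' @param noise_sd Standard deviation of the additive Gaussian noise (>= 0).
#' @param seed Integer seed making the rendered noise reproducible.
#' @return A `run_spec` list.
#' @export
run_spec <- function(time_start = 0, time_end = 25, sampling_interval = 0.005,
                     peaks = list(), baseline_intercept = 0,
                     baseline_slope = 0, noise_sd = 0, seed = 1L) {
  check_number(time_start, "time_start")
  check_number(time_end, "time_end")
  if (time_end <= time_start) {
    stop_chromaqc("`time_end` must be greater than `time_start`.",
                  "chromaqc_parameter_error")
  }
  check_number(sampling_interval, "sampling_interval", positive = TRUE)
  check_number(baseline_intercept, "baseline_intercept")
  check_number(baseline_slope, "baseline_slope")
  check_number(noise_sd, "noise_sd", non_negative = TRUE)
  if (inherits(peaks, "peak_spec")) peaks <- list(peaks)
  for (p in peaks) {
    if (!inherits(p, "peak_spec")) {
      stop_chromaqc("`peaks` must be a list of peak_spec objects.",
                    "chromaqc_parameter_error")
    }
    if (p$apex_time < time_start || p$apex_time > time_end) {
      stop_chromaqc("Peak apex_time must lie within the run window.",
                    "chromaqc_parameter_error")
    }
  }
  structure(
    list(time_start = time_start, time_end = time_end,
         sampling_interval = sampling_interval, peaks = peaks,
         baseline_intercept = baseline_intercept,
         baseline_slope = baseline_slope, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "run_spec"
  )
}

#' Describe a compound with simulator ground truth
#'
#' @param compound_id Identifier.
#' @param length Nucleotide count (>= 1).
#' @param sulfur_count Number of phosphorothioate (sulfur) modifications;
#'   must satisfy `0 <= sulfur_count <= length - 1` (one per backbone
#'   linkage at most).
#' @param true_tr True retention time in minutes (> 0).
#' @param quality_tier One of `"high"`, `"medium"`, `"low"`.
#' @return A `compound_spec` list.
#' @export
compound_spec <- function(compound_id, length, sulfur_count, true_tr,
                          quality_tier = c("high", "medium", "low")) {
  quality_tier <- match.arg(quality_tier)
  check_number(length, "length", positive = TRUE)
  if (length < 1 || length != round(length)) {
    stop_chromaqc("`length` must be an integer >= 1.",
                  "chromaqc_parameter_error")
  }
  check_number(sulfur_count, "sulfur_count", non_negative = TRUE)
  if (sulfur_count > length - 1 || sulfur_count != round(sulfur_count)) {
    stop_chromaqc("`sulfur_count` must be an integer in [0, length - 1].",
                  "chromaqc_parameter_error")
  }
  check_number(true_tr, "true_tr", positive = TRUE)
  structure(
    list(compound_id = as.character(compound_id), length = as.integer(length),
         sulfur_count = as.integer(sulfur_count), true_tr = true_tr,
         quality_tier = quality_tier),
    class = "compound_spec"
  )
}

#' Per-tier simulation profile
#'
#' Encodes how a latent quality tier expresses itself in the raw signal:
#' noisier baselines, stronger tailing, larger replicate retention-time
#' jitter and weaker peaks all degrade the measured quality metrics. Ranges
#' are sampled uniformly per compound.
#'
#' @param noise_sd_range Length-2 range of baseline noise sd (intensity).
#' @param tau_range Length-2 range of the EMG tailing constant (minutes).
#' @param tr_jitter_sd Gaussian sd of the replicate retention-time shift
#'   (minutes).
#' @param height_range Length-2 range of peak heights (intensity).
#' @param length_range Length-2 integer range of sequence lengths.
#' @param sulfur_frac_range Length-2 range of the sulfur-modified fraction of
#'   backbone linkages; the count is `round(frac * (length - 1))`.
#' @return A `tier_profile` list.
#' @seealso [default_tier_profiles()]
#' @export
tier_profile <- function(noise_sd_range, tau_range, tr_jitter_sd,
                         height_range, length_range = c(5, 20),
                         sulfur_frac_range = c(0, 1)) {
  rng <- function(x, name, lo_ok = 0) {
    if (length(x) != 2L || !is.numeric(x) || any(!is.finite(x)) ||
        any(x < lo_ok) || x[2] < x[1]) {
      stop_chromaqc(sprintf("`%s` must be a non-decreasing numeric range.",
                            name), "chromaqc_parameter_error")
    }
    x
  }
  structure(
    list(noise_sd_range = rng(noise_sd_range, "noise_sd_range"),
         tau_range = rng(tau_range, "tau_range"),
         tr_jitter_sd = check_number(tr_jitter_sd, "tr_jitter_sd",
                                     non_negative = TRUE),
         height_range = rng(height_range, "height_range"),
         length_range = rng(length_range, "length_range", lo_ok = 1),
         sulfur_frac_range = rng(sulfur_frac_range, "sulfur_frac_range")),
    class = "tier_profile"
  )
}

#' Default quality-tier profiles
#'
#' Three tiers spanning the qualitative behaviour seen in real ion-pair
#' chromatography data: high-quality runs have low noise, nearly symmetric
#' peaks and reproducible retention times; low-quality runs are noisy,
#' strongly tailing and irreproducible. The chemistry (length, sulfur
#' fraction) is tier-linked: long, lightly modified sequences behave best,
#' short partially modified ones are intermediate, and long fully
#' phosphorothioated sequences give the weakest, most distorted signals.
#'
#' @return Named list of three [tier_profile()] objects
#'   (`high`, `medium`, `low`).
#' @export
default_tier_profiles <- function() {
  list(
    high = tier_profile(noise_sd_range = c(0.5, 1), tau_range = c(0, 0.02),
                        tr_jitter_sd = 0.005, height_range = c(950, 1050),
                        length_range = c(16, 20),
                        sulfur_frac_range = c(0, 0.15)),
    medium = tier_profile(noise_sd_range = c(2, 5), tau_range = c(0.05, 0.15),
                          tr_jitter_sd = 0.02, height_range = c(570, 630),
                          length_range = c(5, 9),
                          sulfur_frac_range = c(0.4, 0.6)),
    low = tier_profile(noise_sd_range = c(8, 15), tau_range = c(0.2, 0.5),
                       tr_jitter_sd = 0.1, height_range = c(330, 370),
                       length_range = c(16, 20),
                       sulfur_frac_range = c(0.85, 1))
  )
}
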