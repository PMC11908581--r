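#' Render a chromatogram from a run specification
#'
#' Evaluates `Y(t) = B(t) + P(t) + N(t)` on the run's uniform time grid:
#' linear baseline, sum of EMG peaks, i.i.d. Gaussian noise drawn with the
#' run's seed. Identical specs (including seed) render bit-identical
#' signals.
#'
#' @param run A [run_spec()].
#' @return A tibble with columns `time_min` and `intensity`.
#' @examples
#' run <- run_spec(peaks = list(peak_spec("a", 10, 100, 0.06)), seed = 7)
#' chrom <- render_chromatogram(run)
#' @export
render_chromatogram <- function(run) {
  if (!inherits(run, "run_spec")) {
    stop_chromaqc("`run` must be a run_spec object.",
                  "chromaqc_parameter_error")
  }
  time <- seq(run$time_start, run$time_end, by = run$sampling_interval)
  if (length(time) < 2L) {
    stop_chromaqc("Run time window is empty at this sampling interval.",
                  "chromaqc_parameter_error")
  }
  intensity <- run$baseline_intercept + run$baseline_slope * time
  for (p in run$peaks) {
    intensity <- intensity + emg_profile(time, p)
  }
  if (run$noise_sd > 0) {
    old <- .Random.seed_exists()
    set.seed(run$seed)
    intensity <- intensity + rnorm(length(time), sd = run$noise_sd)
    restore_rng(old)
  }
  tibble(time_min = time, intensity = intensity)
}

# Preserve the caller's RNG state across seeded rendering so simulation does
# not silently reset the global stream.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

with_seed <- function(seed, code) {
  old <- .Random.seed_exists()
  on.exit(restore_rng(old))
  set.seed(seed)
  code
}

#' Simulate a replicate pair of chromatograms for one compound
#'
#' Draws the signal parameters (noise sd, tailing constant, height) from the
#' compound's tier profile, renders two runs that share the same peak shape,
#' and applies the tier's Gaussian retention-time jitter to every
#' injection: run 1 elutes at the nominal retention time plus one jitter
#' draw, and run 2 at run 1's apex plus a second draw (so irreproducible
#' tiers have irreproducible retention times in both runs, not just the
#' replicate). The returned ground truth records both true apex times
#' alongside the injected parameters.
#'
#' @param compound A [compound_spec()].
#' @param tier A [tier_profile()].
#' @param seed Integer seed; all draws for the pair derive from it.
#' @param grid A [run_spec()]-like list giving `time_start`, `time_end`,
#'   `sampling_interval`, `baseline_intercept`, `baseline_slope` for both
#'   runs (peaks and noise come from the tier draw). Default 0-25 min at
#'   0.005 min with a flat zero baseline.
#' @param sigma Gaussian peak width in minutes shared by both runs.
#' @return List with elements `run1`, `run2` (chromatogram tibbles) and
#'   `truth` (one-row tibble: compound_id, length, sulfur_count, tier,
#'   true_tr_run1, true_tr_run2, noise_sd, tau, height).
#' @export
simulate_replicate_pair <- function(compound, tier, seed,
                                    grid = list(time_start = 0, time_end = 25,
                                                sampling_interval = 0.005,
                                                baseline_intercept = 0,
                                                baseline_slope = 0),
                                    sigma = 0.06) {
  if (!inherits(compound, "compound_spec")) {
    stop_chromaqc("`compound` must be a compound_spec.",
                  "chromaqc_parameter_error")
  }
  if (!inherits(tier, "tier_profile")) {
    stop_chromaqc("`tier` must be a tier_profile.",
                  "chromaqc_parameter_error")
  }
  draws <- with_seed(derive_seed(seed, 1L), {
    list(noise_sd = runif(1, tier$noise_sd_range[1], tier$noise_sd_range[2]),
         tau = runif(1, tier$tau_range[1], tier$tau_range[2]),
         height = runif(1, tier$height_range[1], tier$height_range[2]),
         jitter1 = rnorm(1, 0, tier$tr_jitter_sd),
         jitter2 = rnorm(1, 0, tier$tr_jitter_sd))
  })
  # run-to-run retention jitter affects every injection: run 1 deviates from
  # the nominal retention time and run 2 deviates again from run 1
  tr1 <- compound$true_tr + draws$jitter1
  tr2 <- tr1 + draws$jitter2
  mk_run <- function(apex, run_seed) {
    run_spec(time_start = grid$time_start, time_end = grid$time_end,
             sampling_interval = grid$sampling_interval,
             peaks = list(peak_spec(compound$compound_id, apex, draws$height,
                                    sigma, draws$tau)),
             baseline_intercept = grid$baseline_intercept %||% 0,
             baseline_slope = grid$baseline_slope %||% 0,
             noise_sd = draws$noise_sd, seed = run_seed)
  }
  run1 <- render_chromatogram(mk_run(tr1, derive_seed(seed, 2L)))
  run2 <- render_chromatogram(mk_run(tr2, derive_seed(seed, 3L)))
  truth <- tibble(
    compound_id = compound$compound_id,
    length = compound$length,
    sulfur_count = compound$sulfur_count,
    tier = compound$quality_tier,
    true_tr_run1 = tr1,
    true_tr_run2 = tr2,
    noise_sd = draws$noise_sd,
    tau = draws$tau,
    height = draws$height
  )
  list(run1 = run1, run2 = run2, truth = truth)
}

#' Default retention-time model for simulated compounds
#'
#' Retention time grows smoothly with sequence length (longer, more
#' hydrophobic sequences are retained longer) plus an offset per sulfur
#' modification and a small run-to-run lab variation.
#'
#' @param length,sulfur_count Compound chemistry.
#' @param noise Gaussian deviate (minutes) already drawn by the caller.
#' @param intercept,length_coef,sulfur_coef Model coefficients (minutes,
#'   minutes per nucleotide, minutes per sulfur).
#' @return True retention time in minutes.
#' @keywords internal
true_tr_model <- function(length, sulfur_count, noise, intercept = 1.5,
                          length_coef = 0.35, sulfur_coef = 0.10) {
  intercept + length_coef * length + sulfur_coef * sulfur_count + noise
}

#' Simulate a cohort of compounds with latent quality tiers
#'
#' Generates `n_compounds` compounds, assigns quality tiers in the exact
#' proportions of `tier_mixture` (largest-remainder rounding, order then
#' shuffled), draws each compound's chemistry from its tier profile and
#' renders a replicate chromatogram pair per compound. The truth table
#' records the tier labels and injected parameters, so downstream cluster
#' recovery can be scored against ground truth.
#'
#' @param n_compounds Number of compounds (>= 1).
#' @param tier_mixture Numeric proportions for (high, medium, low); must sum
#'   to 1.
#' @param tier_profiles Named list as from [default_tier_profiles()].
#' @param seed Master integer seed; every compound uses a derived sub-seed.
#' @param grid,sigma Passed to [simulate_replicate_pair()].
#' @param tr_noise_sd Lab-variation sd (minutes) of the true retention time
#'   around the length/sulfur trend.
#' @return List with `pairs` (list of replicate-pair lists) and `truth`
#'   (tibble, one row per compound).
#' @examples
#' cohort <- simulate_cohort(6, seed = 1)
#' cohort$truth
#' @export
simulate_cohort <- function(n_compounds,
                            tier_mixture = c(high = 1 / 3, medium = 1 / 3,
                                             low = 1 / 3),
                            tier_profiles = default_tier_profiles(),
                            seed = 1L,
                            grid = list(time_start = 0, time_end = 25,
                                        sampling_interval = 0.005,
                                        baseline_intercept = 0,
                                        baseline_slope = 0),
                            sigma = 0.06, tr_noise_sd = 0.01) {
  check_number(n_compounds, "n_compounds", positive = TRUE)
  if (length(tier_mixture) != 3L || any(tier_mixture < 0) ||
      abs(sum(tier_mixture) - 1) > 1e-8) {
    stop_chromaqc("`tier_mixture` must be 3 non-negative proportions summing to 1.",
                  "chromaqc_parameter_error")
  }
  tiers <- c("high", "medium", "low")
  counts <- floor(tier_mixture * n_compounds)
  rem <- n_compounds - sum(counts)
  if (rem > 0) {
    frac <- tier_mixture * n_compounds - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  tier_vec <- rep(tiers, times = counts)
  tier_vec <- with_seed(derive_seed(seed, 0L), sample(tier_vec))

  compounds <- vector("list", n_compounds)
  for (i in seq_len(n_compounds)) {
    prof <- tier_profiles[[tier_vec[i]]]
    ch <- with_seed(derive_seed(seed, 100000L + i), {
      len <- sample(seq(prof$length_range[1], prof$length_range[2]), 1L)
      sfrac <- runif(1, prof$sulfur_frac_range[1], prof$sulfur_frac_range[2])
      sul <- min(round(sfrac * (len - 1)), len - 1)
      trn <- rnorm(1, 0, tr_noise_sd)
      list(len = len, sul = sul, trn = trn)
    })
    tr <- true_tr_model(ch$len, ch$sul, ch$trn)
    compounds[[i]] <- compound_spec(sprintf("cmp%04d", i), ch$len, ch$sul,
                                    tr, tier_vec[i])
  }

  pairs <- vector("list", n_compounds)
  truths <- vector("list", n_compounds)
  for (i in seq_len(n_compounds)) {
    pair <- simulate_replicate_pair(compounds[[i]], tier_profiles[[tier_vec[i]]],
                                    seed = derive_seed(seed, 200000L + i),
                                    grid = grid, sigma = sigma)
    pairs[[i]] <- pair
    truths[[i]] <- pair$truth
  }
  list(pairs = pairs, truth = dplyr::bind_rows(truths))
}

#' Write a chromatogram to CSV
#'
#' Plain-text interchange format: header `time_min,intensity`, one row per
#' sample point.
#'
#' @param chrom Chromatogram tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chromatogram_csv <- function(chrom, path) {
  validate_chromatogram(chrom)
  readr::write_csv(chrom, path, progress = FALSE)
  invisible(path)
}

#' Read a chromatogram from CSV
#'
#' @param path CSV file with columns `time_min,intensity`.
#' @return Chromatogram tibble.
#' @export
read_chromatogram_csv <- function(path) {
  chrom <- readr::read_csv(path, col_types = readr::cols(
    time_min = readr::col_double(), intensity = readr::col_double()))
  validate_chromatogram(chrom)
  chrom
}
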