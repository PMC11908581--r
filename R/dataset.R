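# Quality-table assembly, cleaning and preprocessing.

#' Names of the clustering features
#'
#' The six independent variables used for quality clustering: replicate
#' retention-time difference, SNR, skewness, peak area, sequence length and
#' sulfur count. The prediction target `tr` is never a clustering feature.
#'
#' @return Character vector of feature names.
#' @export
quality_feature_names <- function() {
  c("delta_tr", "snr", "skewness", "peak_area", "length", "sulfur_count")
}

#' Assemble the per-compound quality table
#'
#' Joins peak measurements with compound metadata (length, sulfur count,
#' optional injection volume) into the feature table that feeds clustering.
#' Measurements without matching metadata (and vice versa) are dropped and
#' reported in the `orphans` attribute.
#'
#' @param measurements Tibble from [measure_cohort()] / [measure_peak()]
#'   with at least `compound_id`, `delta_tr`, `snr`, `skewness`,
#'   `peak_area`, `tr`.
#' @param metadata Tibble with `compound_id`, `length`, `sulfur_count` and
#'   optionally `injection_volume`.
#' @return A quality table tibble (one row per compound) with attribute
#'   `orphans` listing unmatched ids.
#' @export
assemble_quality_table <- function(measurements, metadata) {
  for (tbl in list(measurements, metadata)) {
    if (!is.data.frame(tbl) || !"compound_id" %in% names(tbl)) {
      stop_chromaqc("Inputs must be data frames with a `compound_id` column.",
                    "chromaqc_parameter_error")
    }
  }
  if (anyDuplicated(measurements$compound_id) ||
      anyDuplicated(metadata$compound_id)) {
    stop_chromaqc("Duplicated compound_id in measurements or metadata.",
                  "chromaqc_assembly_error")
  }
  meta_cols <- intersect(c("compound_id", "length", "sulfur_count",
                           "injection_volume"), names(metadata))
  joined <- dplyr::inner_join(measurements, metadata[meta_cols],
                              by = "compound_id")
  orphans <- union(setdiff(measurements$compound_id, metadata$compound_id),
                   setdiff(metadata$compound_id, measurements$compound_id))
  if (length(orphans) > 0) {
    inform(sprintf("%d unmatched compound id(s) dropped during assembly.",
                   length(orphans)))
  }
  keep <- intersect(c("compound_id", "delta_tr", "snr", "skewness",
                      "peak_area", "length", "sulfur_count", "tr",
                      "injection_volume", "ok", "note"), names(joined))
  out <- as_tibble(joined[keep])
  attr(out, "orphans") <- orphans
  out
}

#' Drop rows with missing features or target
#'
#' Mirrors the practice of analysing only complete ("non-null") instances:
#' any row with a missing clustering feature or missing retention-time
#' target is removed. The drop report (ids and missing fields) is attached
#' as the `drop_report` attribute.
#'
#' @param table Quality table tibble.
#' @param features Feature columns required to be complete.
#' @return Filtered tibble with attribute `drop_report`.
#' @export
drop_incomplete <- function(table, features = quality_feature_names()) {
  required <- intersect(c(features, "tr"), names(table))
  missing_by_row <- purrr::map(seq_len(nrow(table)), function(i) {
    required[vapply(table[i, required], function(v) is.na(v), logical(1))]
  })
  bad <- lengths(missing_by_row) > 0
  report <- tibble(
    compound_id = table$compound_id[bad],
    missing_fields = vapply(missing_by_row[bad], paste, character(1),
                            collapse = ",")
  )
  out <- table[!bad, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop_chromaqc("All rows dropped: no complete quality records remain.",
                  "chromaqc_empty_table_error")
  }
  attr(out, "drop_report") <- report
  out
}

#' Fit the standardize-then-normalize preprocessing transform
#'
#' Each feature is first z-scored (mean 0, variance 1) and then min-max
#' scaled to `[0, 1]`; both stages are fitted on `fit_rows` and can be
#' re-applied to new rows with [apply_preprocess()]. Because both stages are
#' affine per feature, the transform is fully described by the fitted means,
#' standard deviations, minima and maxima, which serialize to JSON via
#' [write_preprocess_json()].
#'
#' @param table Quality table tibble.
#' @param features Feature columns to transform.
#' @param fit_rows Integer row indices used to fit the transform (default:
#'   all rows, the unsupervised-clustering setting).
#' @return A `quality_preprocess` object.
#' @export
fit_preprocess <- function(table, features = quality_feature_names(),
                           fit_rows = NULL) {
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(table))
  if (length(fit_rows) == 0L) {
    stop_chromaqc("`fit_rows` must be non-empty.", "chromaqc_parameter_error")
  }
  missing_feats <- setdiff(features, names(table))
  if (length(missing_feats) > 0) {
    stop_chromaqc(paste("Missing feature column(s):",
                        paste(missing_feats, collapse = ", ")),
                  "chromaqc_parameter_error")
  }
  sub <- table[fit_rows, features, drop = FALSE]
  means <- vapply(sub, mean, numeric(1))
  sds <- vapply(sub, stats::sd, numeric(1))
  degenerate <- features[!is.finite(sds) | sds == 0]
  if (length(degenerate) > 0) {
    stop_chromaqc(paste("Zero-variance feature(s):",
                        paste(degenerate, collapse = ", ")),
                  "chromaqc_degenerate_feature_error")
  }
  z <- sweep(sweep(as.matrix(sub), 2, means), 2, sds, "/")
  mins <- apply(z, 2, min)
  maxs <- apply(z, 2, max)
  structure(list(features = features, means = means, sds = sds,
                 mins = mins, maxs = maxs),
            class = "quality_preprocess")
}

#' Apply a fitted preprocessing transform
#'
#' @param transform A `quality_preprocess` from [fit_preprocess()].
#' @param table Quality table tibble (any rows).
#' @return Numeric matrix (rows x features) of transformed values; rows used
#'   to fit the transform map exactly onto `[0, 1]` per feature.
#' @export
apply_preprocess <- function(transform, table) {
  if (!inherits(transform, "quality_preprocess")) {
    stop_chromaqc("`transform` must come from fit_preprocess().",
                  "chromaqc_parameter_error")
  }
  sub <- as.matrix(table[, transform$features, drop = FALSE])
  z <- sweep(sweep(sub, 2, transform$means), 2, transform$sds, "/")
  rng <- transform$maxs - transform$mins
  sweep(sweep(z, 2, transform$mins), 2, rng, "/")
}

#' @export
print.quality_preprocess <- function(x, ...) {
  cat("Quality preprocessing transform (z-score then min-max)\n")
  cat("Features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize / restore a preprocessing transform
#'
#' @param transform A `quality_preprocess`.
#' @param path JSON file path.
#' @return `path` (write) or the restored transform (read).
#' @export
write_preprocess_json <- function(transform, path) {
  jsonlite::write_json(
    list(features = transform$features,
         means = unname(transform$means), sds = unname(transform$sds),
         mins = unname(transform$mins), maxs = unname(transform$maxs)),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_preprocess_json
#' @export
read_preprocess_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(features = raw$features,
                 means = setNames(raw$means, raw$features),
                 sds = setNames(raw$sds, raw$features),
                 mins = setNames(raw$mins, raw$features),
                 maxs = setNames(raw$maxs, raw$features)),
            class = "quality_preprocess")
}

# Fixed 12-significant-digit float formatting for the quality-table CSV
# dialect, so write -> read round-trips exactly.
format_qt_num <- function(x) {
  ifelse(is.na(x), "", sprintf("%.12g", x))
}

#' Write / read the quality-table CSV dialect
#'
#' Columns: `compound_id,sequence,delta_tr,snr,skewness,peak_area,length,`
#' `sulfur_count,tr,injection_volume`. Missing optional values are written
#' blank. Floats use 12 significant digits, so a write/read round trip
#' reproduces the table exactly.
#'
#' @param table Quality table tibble.
#' @param path CSV file path.
#' @return `path` (write) or the table (read).
#' @export
write_quality_csv <- function(table, path) {
  num_cols <- c("delta_tr", "snr", "skewness", "peak_area", "tr",
                "injection_volume")
  out <- tibble(
    compound_id = as.character(table$compound_id),
    sequence = if ("sequence" %in% names(table)) table$sequence else "",
    delta_tr = NA_character_, snr = NA_character_, skewness = NA_character_,
    peak_area = NA_character_,
    length = if ("length" %in% names(table)) table$length else NA_integer_,
    sulfur_count = if ("sulfur_count" %in% names(table)) table$sulfur_count
                   else NA_integer_,
    tr = NA_character_, injection_volume = NA_character_
  )
  for (cc in num_cols) {
    vals <- if (cc %in% names(table)) table[[cc]] else rep(NA_real_, nrow(table))
    out[[cc]] <- format_qt_num(vals)
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_quality_csv
#' @export
read_quality_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    compound_id = readr::col_character(),
    sequence = readr::col_character(),
    delta_tr = readr::col_double(), snr = readr::col_double(),
    skewness = readr::col_double(), peak_area = readr::col_double(),
    length = readr::col_integer(), sulfur_count = readr::col_integer(),
    tr = readr::col_double(), injection_volume = readr::col_double()),
    na = c("", "NA", "-"))
}
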