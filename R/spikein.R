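#' Fit a per-sample spike-in standard curve
#'
#' Through-origin least-squares fit of spike-in reads on known copies
#' added: `reads = k * copies`. The through-origin form is deliberate —
#' zero copies must map to zero reads — and the slope has the closed form
#' `k = sum(reads * copies) / sum(copies^2)`. The goodness of fit is the
#' uncentered R-squared of the through-origin fit; a value below 0.98 is
#' recorded as a calibration warning (not an error).
#'
#' @param reads Observed spike-in read counts.
#' @param copies Known copies added (>= 3 distinct positive levels).
#' @param sample_id Identifier carried into the result.
#' @return Object of class `standard_curve`: `sample_id`, `k` (reads per
#'   copy), `r_squared`, `n_points`, `low_r2` flag.
#' @examples
#' fit_standard_curve(c(100, 1000, 10000), c(1e4, 1e5, 1e6))
#' @export
fit_standard_curve <- function(reads, copies, sample_id = "sample") {
  if (length(reads) != length(copies) || length(copies) < 3 ||
      length(unique(copies)) < 3)
    abort("need >= 3 (copies, reads) pairs at distinct copy levels",
          "spikecore_invalid_argument")
  if (any(copies <= 0) || anyNA(copies) || anyNA(reads) || any(reads < 0))
    abort("copies must be positive and reads nonnegative",
          "spikecore_invalid_argument")
  if (all(reads == 0))
    abort(sprintf("sample %s: all spike-in reads are zero", sample_id),
          "spikecore_calibration_failure")
  k <- sum(reads * copies) / sum(copies^2)
  sse <- sum((reads - k * copies)^2)
  r2 <- 1 - sse / sum(reads^2)
  structure(
    list(sample_id = sample_id, k = k, r_squared = r2,
         n_points = length(copies), low_r2 = r2 < 0.98),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Spike-in standard curve [%s]: k = %.4g reads/copy, R2 = %.4f (n = %d)%s\n",
              x$sample_id, x$k, x$r_squared, x$n_points,
              if (x$low_r2) "  [low R2]" else ""))
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) c(k = object$k)

#' Fit standard curves for every sample in a table
#'
#' @param counts Sample x column matrix that still contains the spike-in
#'   columns.
#' @param manifest Data frame with columns `sample_id`, `spike_id`,
#'   `copies`.
#' @return Named list of [fit_standard_curve()] objects, one per sample.
#' @export
fit_standard_curves <- function(counts, manifest) {
  counts <- check_count_matrix(counts, "counts")
  need <- c("sample_id", "spike_id", "copies")
  if (!all(need %in% names(manifest)))
    abort("manifest needs columns sample_id, spike_id, copies",
          "spikecore_invalid_argument")
  curves <- lapply(rownames(counts), function(s) {
    man <- manifest[manifest$sample_id == s, , drop = FALSE]
    if (nrow(man) == 0)
      abort(sprintf("no spike-in manifest rows for sample %s", s),
            "spikecore_missing_metadata")
    missing <- setdiff(man$spike_id, colnames(counts))
    if (length(missing))
      abort(sprintf("spike-in columns absent from table: %s",
                    paste(missing, collapse = ", ")),
            "spikecore_invalid_argument")
    fit_standard_curve(counts[s, man$spike_id], man$copies, sample_id = s)
  })
  names(curves) <- rownames(counts)
  curves
}

#' Convert reads to absolute copy numbers
#'
#' Applies each sample's standard curve to the ASV read counts:
#' `copies = reads / k`, then `copies/g = copies / mass_g` using the
#' per-sample wet mass from the metadata. Spike-in columns are removed.
#' Because the calibration is a per-sample scalar, within-sample ratios
#' of ASV copies equal ratios of reads.
#'
#' @param counts Sample x column read matrix (ASVs + spike-ins).
#' @param curves List of `standard_curve` objects keyed by sample
#'   (from [fit_standard_curves()]).
#' @param metadata Data frame with `sample_id` and `mass_g`; samples
#'   missing a mass fall back to `default_mass_g` and are flagged.
#' @param spike_ids Spike-in column names to strip.
#' @param default_mass_g Fallback wet mass in grams (0.03 g, the typical
#'   per-tank larval pellet).
#' @return Object of class `absolute_table`: `copies` and `per_gram`
#'   (sample x ASV matrices), `log10_total` (per-sample log10 total
#'   copies/g), `calibration` (per-sample k, R2, warnings), `metadata`.
#' @export
reads_to_copies <- function(counts, curves, metadata = NULL,
                            spike_ids = character(), default_mass_g = 0.03) {
  counts <- check_count_matrix(counts, "counts")
  samples <- rownames(counts)
  missing_curve <- setdiff(samples, names(curves))
  if (length(missing_curve))
    abort(sprintf("no standard curve for sample(s): %s",
                  paste(missing_curve, collapse = ", ")),
          "spikecore_missing_metadata")
  k <- vapply(curves[samples], function(cv) cv$k, numeric(1))
  if (any(!is.finite(k)) || any(k <= 0))
    abort("non-positive slope k: calibration unusable",
          "spikecore_calibration_failure")

  asv_cols <- setdiff(colnames(counts), spike_ids)
  reads <- counts[, asv_cols, drop = FALSE]
  copies <- sweep(reads, 1, k, "/")

  mass <- rep(default_mass_g, length(samples))
  mass_defaulted <- rep(TRUE, length(samples))
  if (!is.null(metadata)) {
    idx <- match(samples, metadata$sample_id)
    has <- !is.na(idx) & !is.na(metadata$mass_g[idx])
    mass[has] <- metadata$mass_g[idx[has]]
    mass_defaulted <- !has
  }
  if (any(mass <= 0))
    abort("wet mass must be positive", "spikecore_missing_metadata")
  per_gram <- sweep(copies, 1, mass, "/")
  total <- rowSums(per_gram)

  calibration <- data.frame(
    sample_id = samples, k = k,
    r_squared = vapply(curves[samples], function(cv) cv$r_squared, numeric(1)),
    n_points = vapply(curves[samples], function(cv) cv$n_points, numeric(1)),
    low_r2 = vapply(curves[samples], function(cv) isTRUE(cv$low_r2), logical(1)),
    mass_g = mass, mass_defaulted = mass_defaulted
  )
  structure(
    list(copies = copies, per_gram = per_gram,
         log10_total = ifelse(total > 0, log10(total), NA_real_),
         calibration = calibration, metadata = metadata),
    class = "absolute_table"
  )
}

#' @export
print.absolute_table <- function(x, ...) {
  cat("Absolute abundance table:", nrow(x$copies), "samples x",
      ncol(x$copies), "ASVs\n")
  rng <- range(x$log10_total, na.rm = TRUE)
  cat(sprintf("  log10 total copies/g: %.2f - %.2f\n", rng[1], rng[2]))
  if (any(x$calibration$low_r2))
    cat("  calibration warnings (R2 < 0.98):",
        sum(x$calibration$low_r2), "sample(s)\n")
  invisible(x)
}

#' @export
summary.absolute_table <- function(object, ...) {
  print(object)
  cat("\nCalibration report:\n")
  print(utils::head(object$calibration, 10))
  invisible(object$calibration)
}
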