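#' Occupancy-abundance records per taxon
#'
#' For each ASV: occupancy (fraction of samples at or above the detection
#' threshold), mean log10 abundance over the samples where it is
#' detected, per-stage occupancy, and the occupancy ranking score used
#' for persistent-microbiome detection. The score is the stage-mean
#' occupancy plus the replicate-consistency fraction (the fraction of
#' stages in which the taxon is present in every replicate); ties are
#' broken by mean log10 abundance.
#'
#' @param x Sample x taxon matrix (reads or copies), or an
#'   `absolute_table` (its `copies` slot is used).
#' @param stages Stage label per sample.
#' @param detection_threshold Minimum count for presence (default 1).
#' @return Data frame of class `occupancy_records` (`asv_id`,
#'   `occupancy`, `mean_log10_abundance`, `rank_index`), with attributes
#'   `stage_occupancy` (stage x taxon matrix) and `ranked_ids` (taxa in
#'   decreasing rank order).
#' @export
occupancy_abundance <- function(x, stages, detection_threshold = 1) {
  if (inherits(x, "absolute_table")) x <- x$copies
  x <- check_count_matrix(x, "table")
  if (nrow(x) == 0)
    abort("table has no samples", "spikecore_invalid_argument")
  if (length(stages) != nrow(x))
    abort("stages must match the rows of the table",
          "spikecore_invalid_argument")
  stages <- factor(as.character(stages))
  present <- x >= detection_threshold
  occupancy <- colMeans(present)
  mean_log10 <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[present[, j], j]
    if (length(v) == 0) NA_real_ else mean(log10(v))
  }, numeric(1))
  stage_occ <- do.call(rbind, lapply(levels(stages), function(st) {
    colMeans(present[stages == st, , drop = FALSE])
  }))
  dimnames(stage_occ) <- list(levels(stages), colnames(x))
  stage_mean_occ <- colMeans(stage_occ)
  replicate_consistency <- colMeans(stage_occ == 1)
  rank_index <- stage_mean_occ + replicate_consistency
  out <- data.frame(asv_id = colnames(x), occupancy = occupancy,
                    mean_log10_abundance = mean_log10,
                    rank_index = rank_index, row.names = NULL)
  ord <- order(-out$rank_index,
               ifelse(is.na(out$mean_log10_abundance), -Inf,
                      -out$mean_log10_abundance),
               out$asv_id)
  attr(out, "stage_occupancy") <- stage_occ
  attr(out, "ranked_ids") <- out$asv_id[ord]
  attr(out, "detection_threshold") <- detection_threshold
  class(out) <- c("occupancy_records", "data.frame")
  out
}

# Per-taxon Bray-Curtis contribution weights: w_i is the mean over sample
# pairs of |x_i - y_i| / sum_j |x_j - y_j|. Weights sum to 1 over taxa,
# so cumulative contributions partition the Bray-Curtis numerator.
# Identical sample pairs (zero numerator) carry no information and are
# skipped.
bc_contribution_weights <- function(x) {
  x <- check_count_matrix(x, "table")
  n <- nrow(x)
  if (n < 2)
    abort("need >= 2 samples for Bray-Curtis contributions",
          "spikecore_invalid_argument")
  w <- numeric(ncol(x))
  used <- 0L
  for (a in seq_len(n - 1)) {
    xa <- x[a, ]
    for (b in (a + 1):n) {
      delta <- abs(xa - x[b, ])
      tot <- sum(delta)
      if (tot > 0) {
        w <- w + delta / tot
        used <- used + 1L
      }
    }
  }
  if (used == 0L)
    abort("all sample pairs identical: contributions undefined",
          "spikecore_insufficient_data")
  stats::setNames(w / used, colnames(x))
}

#' Contribution of a top-k taxon set to Bray-Curtis beta-diversity
#'
#' Mean over all sample pairs of the ratio between the Bray-Curtis
#' numerator restricted to the top-k ranked taxa and the full-community
#' numerator. Because the denominator is shared, contributions are
#' exactly additive across taxa and reach 1 at `k = n_taxa`.
#'
#' @param x Sample x taxon matrix.
#' @param ranked_ids Taxa in rank order (e.g. from
#'   [occupancy_abundance()]).
#' @param k How many top-ranked taxa to include (1 <= k <= n_taxa).
#' @return A single fraction in `[0, 1]`.
#' @export
core_contribution <- function(x, ranked_ids, k) {
  if (inherits(x, "absolute_table")) x <- x$copies
  x <- check_count_matrix(x, "table")
  if (k < 1 || k > length(ranked_ids))
    abort("k out of range", "spikecore_invalid_argument")
  w <- bc_contribution_weights(x)
  sum(w[ranked_ids[seq_len(k)]])
}

#' Cumulative Bray-Curtis contribution along a taxon ranking
#'
#' @inheritParams core_contribution
#' @return Nondecreasing numeric vector of length `length(ranked_ids)`
#'   ending at 1.
#' @export
cumulative_core_contribution <- function(x, ranked_ids) {
  if (inherits(x, "absolute_table")) x <- x$copies
  x <- check_count_matrix(x, "table")
  w <- bc_contribution_weights(x)
  if (!all(ranked_ids %in% names(w)))
    abort("ranked_ids must all be table columns",
          "spikecore_invalid_argument")
  stats::setNames(cumsum(w[ranked_ids]), ranked_ids)
}

#' Elbow of a cumulative-contribution curve
#'
#' First-order-difference stopping rule: the core ends at the last rank
#' whose marginal gain still exceeds the threshold. In the default
#' relative form ("last 2% increase") the gain from adding taxon `r` is
#' compared against `threshold * cumulative[r - 1]`; the absolute form
#' compares the raw gain against `threshold`. Returns 1 when no rank
#' beyond the first clears the threshold.
#'
#' @param cumulative Nondecreasing cumulative-contribution sequence.
#' @param threshold Marginal-gain threshold (default 0.02).
#' @param type `"relative"` (default) or `"absolute"`.
#' @return The elbow rank (integer >= 1).
#' @export
find_elbow <- function(cumulative, threshold = 0.02,
                       type = c("relative", "absolute")) {
  type <- match.arg(type)
  if (length(cumulative) < 2)
    abort("cumulative sequence must have length >= 2",
          "spikecore_invalid_argument")
  if (any(diff(cumulative) < -1e-12))
    abort("cumulative sequence must be nondecreasing",
          "spikecore_invalid_argument")
  gains <- diff(cumulative)
  ref <- if (type == "relative") {
    prev <- cumulative[-length(cumulative)]
    ifelse(prev > 0, gains / prev, Inf)
  } else {
    gains
  }
  idx <- which(ref > threshold)
  if (length(idx) == 0) 1L else as.integer(max(idx) + 1L)
}

#' Persistent-microbiome detection
#'
#' Composes the abundance-occupancy workflow: rank taxa by the occupancy
#' index, accumulate their contribution to Bray-Curtis beta-diversity,
#' and stop at the elbow of the cumulative-contribution curve. Taxa up
#' to the elbow rank form the persistent set.
#'
#' @inheritParams occupancy_abundance
#' @param threshold Elbow marginal-gain threshold (default 0.02).
#' @param elbow_type `"relative"` (default) or `"absolute"` gain rule.
#' @return Object of class `core_set`: `ranked_ids`,
#'   `cumulative_contribution`, `elbow_rank`, `persistent_ids`,
#'   `abundance_share` (fraction of all counts carried by the persistent
#'   set), and `records` (the [occupancy_abundance()] table).
#' @export
classify_persistent <- function(x, stages, threshold = 0.02,
                                detection_threshold = 1,
                                elbow_type = c("relative", "absolute")) {
  elbow_type <- match.arg(elbow_type)
  if (inherits(x, "absolute_table")) x <- x$copies
  x <- check_count_matrix(x, "table")
  rec <- occupancy_abundance(x, stages,
                             detection_threshold = detection_threshold)
  ranked <- attr(rec, "ranked_ids")
  cumc <- cumulative_core_contribution(x, ranked)
  elbow <- find_elbow(cumc, threshold = threshold, type = elbow_type)
  persistent <- ranked[seq_len(elbow)]
  structure(
    list(ranked_ids = ranked,
         cumulative_contribution = cumc,
         elbow_rank = elbow,
         persistent_ids = persistent,
         abundance_share = sum(x[, persistent]) / sum(x),
         records = rec),
    class = "core_set"
  )
}

#' @export
print.core_set <- function(x, ...) {
  cat("Persistent microbiome:", x$elbow_rank, "of",
      length(x$ranked_ids), "taxa\n")
  cat(sprintf("  abundance share: %.1f%%; contribution at elbow: %.3f\n",
              100 * x$abundance_share,
              x$cumulative_contribution[x$elbow_rank]))
  cat("  top members:",
      paste(utils::head(x$persistent_ids, 5), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.core_set <- function(object, ...) {
  print(object)
  rec <- object$records
  pers <- rec[rec$asv_id %in% object$persistent_ids, ]
  cat(sprintf("  persistent occupancy: min %.2f, median %.2f\n",
              min(pers$occupancy), stats::median(pers$occupancy)))
  invisible(object)
}

#' @export
plot.core_set <- function(x, ...) {
  k <- length(x$cumulative_contribution)
  graphics::plot(seq_len(k), x$cumulative_contribution, type = "l",
                 xlab = "occupancy rank",
                 ylab = "cumulative Bray-Curtis contribution", ...)
  graphics::abline(v = x$elbow_rank, col = 2, lty = 2)
  invisible(x)
}
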