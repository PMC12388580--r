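#' Principal coordinate analysis of a dissimilarity matrix
#'
#' Classical metric scaling: Gower double-centering of the squared
#' dissimilarities followed by eigendecomposition. Coordinates are
#' returned for axes with positive eigenvalues; negative eigenvalues
#' (possible for non-Euclidean dissimilarities such as Bray-Curtis) are
#' reported, not corrected.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal.
#' @return List of class `pcoa_ordination`: `points` (samples x axes),
#'   `eigenvalues` (all, decreasing), `prop_explained` (per positive
#'   axis, relative to the sum of positive eigenvalues),
#'   `negative_eigenvalues`.
#' @export
pcoa_ordination <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    abort("dissimilarity matrix must be symmetric",
          "spikecore_invalid_argument")
  if (any(abs(diag(d)) > 1e-12))
    abort("dissimilarity matrix must have a zero diagonal",
          "spikecore_invalid_argument")
  n <- nrow(d)
  sc <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1,
                                         eig = TRUE))
  eig <- sc$eig
  tol <- max(abs(eig), 1) * 1e-9
  n_pos <- sum(eig > tol)
  if (n_pos > 0) {
    pts <- sc$points[, seq_len(min(n_pos, ncol(sc$points))), drop = FALSE]
    colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
    prop <- eig[seq_len(ncol(pts))] / sum(eig[eig > tol])
  } else {
    pts <- matrix(0, nrow = n, ncol = 0, dimnames = list(rownames(d), NULL))
    prop <- numeric(0)
  }
  structure(
    list(points = pts,
         eigenvalues = eig,
         prop_explained = prop,
         negative_eigenvalues = eig[eig < -tol]),
    class = "pcoa_ordination"
  )
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat("PCoA:", nrow(x$points), "samples,", ncol(x$points),
      "positive axes\n")
  if (length(x$prop_explained))
    cat("  first axes explain:",
        paste(sprintf("%.1f%%", 100 * utils::head(x$prop_explained, 3)),
              collapse = ", "), "\n")
  if (length(x$negative_eigenvalues))
    cat("  negative eigenvalues:", length(x$negative_eigenvalues),
        sprintf("(most negative %.3g)", min(x$negative_eigenvalues)), "\n")
  invisible(x)
}

#' @export
plot.pcoa_ordination <- function(x, groups = NULL, axes = c(1, 2), ...) {
  if (ncol(x$points) < max(axes))
    abort("not enough positive axes to plot", "spikecore_insufficient_data")
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  lab <- function(i) sprintf("PCo%d (%.1f%%)", i, 100 * x$prop_explained[i])
  graphics::plot(x$points[, axes[1]], x$points[, axes[2]], col = col,
                 pch = 19, xlab = lab(axes[1]), ylab = lab(axes[2]), ...)
  invisible(x)
}

#' Analysis of similarity (ANOSIM)
#'
#' Rank-based test of group separation on a dissimilarity matrix:
#' `R = (mean between-group rank - mean within-group rank) / (M/4)` with
#' `M` the number of sample pairs, and a permutation p-value obtained by
#' shuffling group labels.
#'
#' @param d Symmetric dissimilarity matrix.
#' @param groups Group (stage) label per sample; every group needs >= 2
#'   samples.
#' @param n_perm Number of label permutations (>= 99).
#' @param seed Integer seed for the permutations.
#' @return List of class `anosim_result`: `r_statistic`, `p_value`,
#'   `n_permutations`.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  groups <- factor(as.character(groups))
  if (nlevels(groups) < 2)
    abort("need >= 2 groups", "spikecore_invalid_argument")
  if (any(table(groups) < 2))
    abort("every group needs >= 2 samples", "spikecore_invalid_argument")
  if (n_perm < 99)
    abort("n_perm must be >= 99", "spikecore_invalid_argument")
  set.seed(as.integer(seed))
  fit <- vegan::anosim(stats::as.dist(d), groups, permutations = n_perm)
  structure(
    list(r_statistic = unname(fit$statistic),
         p_value = fit$signif,
         n_permutations = n_perm),
    class = "anosim_result"
  )
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%d permutations)\n",
              x$r_statistic, x$p_value, x$n_permutations))
  invisible(x)
}

#' Time decay of community similarity
#'
#' Fits the time-decay relationship: ordinary least squares of
#' log10(similarity) on log10(time separation) over unordered sample
#' pairs, where similarity is one minus the dissimilarity. The slope `w`
#' is the temporal turnover rate. Pairs with zero time separation are
#' excluded by construction; pairs with zero similarity cannot enter a
#' log-log fit and are dropped and counted (`n_dropped_zero_similarity`)
#' rather than epsilon-padded, since any epsilon would dominate the fit.
#'
#' @param d Symmetric dissimilarity matrix.
#' @param times Per-sample day values (e.g. days posthatch), matched to
#'   the rows of `d`.
#' @param time_mode `"interval"` (default) regresses on the pairwise
#'   separation `|t_i - t_j|`; `"age"` regresses on the pair's mean age —
#'   both readings of "similarity against age" are supported.
#' @return Object of class `time_decay_fit`: `slope_w`, `intercept`,
#'   `r_squared`, `p_value` (two-sided, on the slope), `n_pairs`,
#'   `n_dropped_zero_similarity`, and `pairs` (data frame of log10 x/y
#'   used).
#' @export
time_decay <- function(d, times, time_mode = c("interval", "age")) {
  time_mode <- match.arg(time_mode)
  d <- as.matrix(d)
  if (length(times) != nrow(d))
    abort("times must match the rows of d", "spikecore_invalid_argument")
  if (is.null(rownames(d))) rownames(d) <- paste0("S", seq_len(nrow(d)))
  n <- nrow(d)
  ij <- utils::combn(n, 2)
  dt <- abs(times[ij[1, ]] - times[ij[2, ]])
  xval <- if (time_mode == "interval") dt else (times[ij[1, ]] + times[ij[2, ]]) / 2
  sim <- 1 - d[cbind(ij[1, ], ij[2, ])]
  keep <- dt > 0 & sim > 0 & xval > 0
  n_zero_sim <- sum(dt > 0 & sim <= 0)
  pairs <- data.frame(
    sample_a = rownames(d)[ij[1, keep]],
    sample_b = rownames(d)[ij[2, keep]],
    log10_dt = log10(xval[keep]),
    log10_similarity = log10(sim[keep])
  )
  if (nrow(pairs) < 3)
    abort("fewer than 3 usable pairs for the time-decay fit",
          "spikecore_insufficient_data")
  fit <- stats::lm(log10_similarity ~ log10_dt, data = pairs)
  sm <- summary(fit)
  structure(
    list(slope_w = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared,
         p_value = sm$coefficients[2, 4],
         n_pairs = nrow(pairs),
         n_dropped_zero_similarity = n_zero_sim,
         time_mode = time_mode,
         pairs = pairs),
    class = "time_decay_fit"
  )
}

#' @export
print.time_decay_fit <- function(x, ...) {
  cat(sprintf("Time-decay fit (log10 similarity ~ log10 %s):\n",
              if (x$time_mode == "interval") "delta-t" else "age"))
  cat(sprintf("  w = %.4f, intercept = %.4f, R2 = %.4f, p = %.3g (n = %d pairs",
              x$slope_w, x$intercept, x$r_squared, x$p_value, x$n_pairs))
  if (x$n_dropped_zero_similarity > 0)
    cat(sprintf(", %d zero-similarity pairs dropped",
                x$n_dropped_zero_similarity))
  cat(")\n")
  invisible(x)
}

#' @export
coef.time_decay_fit <- function(object, ...) {
  c(intercept = object$intercept, slope_w = object$slope_w)
}

#' @export
plot.time_decay_fit <- function(x, ...) {
  graphics::plot(x$pairs$log10_dt, x$pairs$log10_similarity, pch = 19,
                 col = grDevices::adjustcolor(1, 0.4),
                 xlab = "log10 time separation (days)",
                 ylab = "log10 similarity", ...)
  graphics::abline(x$intercept, x$slope_w, col = 2, lwd = 2)
  invisible(x)
}

#' @export
predict.time_decay_fit <- function(object, log10_dt = NULL, ...) {
  if (is.null(log10_dt)) log10_dt <- object$pairs$log10_dt
  object$intercept + object$slope_w * log10_dt
}

#' Compare two time-decay slopes (ANCOVA + permutation)
#'
#' Stacks the pair-level points of two time-decay fits and tests the
#' slope difference with the interaction term of
#' `y ~ x + group + x:group` (ANCOVA F). Because pairwise points share
#' samples and are not independent, a permutation p-value is reported
#' alongside: group labels of points are shuffled `n_perm` times and the
#' interaction F recomputed.
#'
#' @param fit_a,fit_b `time_decay_fit` objects.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List of class `slope_comparison`: `slope_difference`
#'   (slope of `fit_a` minus slope of `fit_b`), `f_statistic`, `p_value`
#'   (parametric), `permutation_p`.
#' @export
compare_slopes <- function(fit_a, fit_b, n_perm = 999, seed = 1) {
  if (!inherits(fit_a, "time_decay_fit") || !inherits(fit_b, "time_decay_fit"))
    abort("fit_a and fit_b must be time_decay_fit objects",
          "spikecore_invalid_argument")
  x <- c(fit_a$pairs$log10_dt, fit_b$pairs$log10_dt)
  y <- c(fit_a$pairs$log10_similarity, fit_b$pairs$log10_similarity)
  g <- factor(rep(c("a", "b"), c(nrow(fit_a$pairs), nrow(fit_b$pairs))))
  if (length(unique(x)) < 2)
    abort("degenerate x: all time separations equal",
          "spikecore_invalid_argument")

  interaction_f <- function(g) {
    full <- stats::lm(y ~ x * g)
    red <- stats::lm(y ~ x + g)
    rss_full <- sum(stats::resid(full)^2)
    rss_red <- sum(stats::resid(red)^2)
    df_resid <- length(y) - 4
    if (rss_full <= .Machine$double.eps * sum(y^2)) {
      # perfect fit: slope difference is exact, F degenerates
      if (rss_red - rss_full <= .Machine$double.eps * sum(y^2)) return(0)
      return(Inf)
    }
    (rss_red - rss_full) / (rss_full / df_resid)
  }
  f_obs <- interaction_f(g)
  df_resid <- length(y) - 4
  p_par <- if (is.infinite(f_obs)) 0 else
    stats::pf(f_obs, 1, df_resid, lower.tail = FALSE)

  set.seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (interaction_f(sample(g)) >= f_obs) exceed <- exceed + 1L
  }
  structure(
    list(slope_difference = fit_a$slope_w - fit_b$slope_w,
         f_statistic = f_obs,
         p_value = p_par,
         permutation_p = (exceed + 1) / (n_perm + 1),
         n_permutations = n_perm),
    class = "slope_comparison"
  )
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("Slope comparison: diff = %.4f, F = %.3f, parametric p = %.3g, permutation p = %.3g\n",
              x$slope_difference, x$f_statistic, x$p_value,
              x$permutation_p))
  invisible(x)
}
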