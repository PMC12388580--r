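#' Predicted occupancy under the Sloan neutral model
#'
#' The Sloan sampling theory predicts that a taxon with mean
#' metacommunity relative abundance `p` is detected (local frequency
#' above the detection limit `d`) with probability
#' `1 - I_d(Nt*m*p, Nt*m*(1-p))`, where `I` is the regularized
#' incomplete beta function, `Nt` the community size sampled and `m` the
#' migration parameter.
#'
#' @param p Mean relative abundance(s) in `[0, 1]`.
#' @param m Migration parameter in (0, 1].
#' @param Nt Community size (counts per sample).
#' @param d Detection limit (default `1/Nt`).
#' @return Predicted occupancy in `[0, 1]`, same length as `p`.
#' @export
sloan_occupancy <- function(p, m, Nt, d = 1 / Nt) {
  if (m <= 0 || m > 1)
    abort("m must lie in (0, 1]", "spikecore_invalid_argument")
  stats::pbeta(d, Nt * m * p, Nt * m * (1 - p), lower.tail = FALSE)
}

#' Fit the Sloan neutral community model
#'
#' Estimates the migration parameter `m` by least squares between
#' observed taxon occupancies and the Sloan-predicted occupancies at the
#' taxa's mean relative abundances. `Nt` is the mean total count per
#' sample and the detection limit is `d = 1/Nt`. A 95% Wilson score
#' interval with `n = n_samples` around each predicted occupancy defines
#' the neutral band; taxa above it are classed as environmentally
#' selected (`"above"`), below it as dispersal-limited (`"below"`), and
#' inside it as `"neutral"`.
#'
#' The fit is intended for read-count tables (the detection limit is a
#' sampling-depth concept); set `allow_real = TRUE` to fit calibrated
#' copy tables, in which case `Nt` is the mean total copies.
#'
#' @param counts Sample x taxon count matrix (>= 5 samples, >= 10 taxa).
#' @param level Confidence level of the neutral band (default 0.95).
#' @param allow_real Accept non-integer tables (default FALSE).
#' @return Object of class `sloan_fit`: `m`, `Nt`, `d`, `r_squared`,
#'   `aic`, `sse`, `n_taxa`, `n_samples`, and `taxa` (per-ASV data frame
#'   with `p`, `occupancy`, `predicted`, `ci_lower`, `ci_upper`,
#'   `partition`).
#' @examples
#' src <- make_source_profile(50, 1, seed = 3)
#' tab <- sample_neutral_table(src, m = 0.5, Nt = 2000, n_samples = 60,
#'                             seed = 4)
#' fit <- sloan_fit(tab)
#' coef(fit)
#' @export
sloan_fit <- function(counts, level = 0.95, allow_real = FALSE) {
  counts <- check_count_matrix(counts, "counts")
  if (!allow_real && max(abs(counts - round(counts))) > 1e-8)
    abort("counts must be integers (set allow_real = TRUE for copy tables)",
          "spikecore_invalid_argument")
  if (ncol(counts) < 10 || nrow(counts) < 5)
    abort("need >= 10 taxa and >= 5 samples", "spikecore_invalid_argument")
  depths <- rowSums(counts)
  if (any(depths == 0))
    abort("all-zero sample(s) present", "spikecore_invalid_argument")
  rel <- sweep(counts, 1, depths, "/")
  p <- colMeans(rel)
  occ <- colMeans(counts > 0)
  Nt <- mean(depths)
  d <- 1 / Nt

  sse_of <- function(m) sum((occ - sloan_occupancy(p, m, Nt, d))^2)
  # multi-start bounded optimisation: the SSE surface can be flat in m
  starts <- c(0.01, 0.1, 0.5, 0.9)
  best <- NULL
  for (s in starts) {
    o <- try(stats::optim(s, sse_of, method = "L-BFGS-B",
                          lower = 1e-6, upper = 1), silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    abort("optimizer failed for every start", "spikecore_fit_failure")
  m_hat <- best$par
  pred <- sloan_occupancy(p, m_hat, Nt, d)
  sse <- sum((occ - pred)^2)
  sst <- sum((occ - mean(occ))^2)
  ci <- wilson_interval(pred, n = nrow(counts), level = level)
  partition <- ifelse(occ > ci[, "upper"], "above",
                      ifelse(occ < ci[, "lower"], "below", "neutral"))
  structure(
    list(m = m_hat, Nt = Nt, d = d,
         r_squared = 1 - sse / sst,
         aic = ncol(counts) * log(sse / ncol(counts)) + 2,
         sse = sse,
         n_taxa = ncol(counts), n_samples = nrow(counts), level = level,
         taxa = data.frame(asv_id = colnames(counts), p = p,
                           occupancy = occ, predicted = pred,
                           ci_lower = ci[, "lower"],
                           ci_upper = ci[, "upper"],
                           partition = partition, row.names = NULL)),
    class = "sloan_fit"
  )
}

#' @export
print.sloan_fit <- function(x, ...) {
  cat(sprintf("Sloan neutral model fit: m = %.3f, Nt = %.0f, R2 = %.3f, AIC = %.1f\n",
              x$m, x$Nt, x$r_squared, x$aic))
  tb <- table(x$taxa$partition)
  cat("  partition:",
      paste(sprintf("%s %d", names(tb), as.integer(tb)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.sloan_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  %d taxa, %d samples, detection limit d = %.3g\n",
              object$n_taxa, object$n_samples, object$d))
  cat(sprintf("  median |occupancy - predicted| = %.4f\n",
              stats::median(abs(object$taxa$occupancy -
                                object$taxa$predicted))))
  invisible(object)
}

#' @export
coef.sloan_fit <- function(object, ...) c(m = object$m)

#' @export
predict.sloan_fit <- function(object, p = NULL, ...) {
  if (is.null(p)) p <- object$taxa$p
  sloan_occupancy(p, object$m, object$Nt, object$d)
}

#' @export
residuals.sloan_fit <- function(object, ...) {
  stats::setNames(object$taxa$occupancy - object$taxa$predicted,
                  object$taxa$asv_id)
}

#' @export
plot.sloan_fit <- function(x, ...) {
  tx <- x$taxa[order(x$taxa$p), ]
  graphics::plot(log10(tx$p), tx$occupancy, pch = 19,
                 col = c(above = 3, below = 4,
                         neutral = grDevices::adjustcolor(1, 0.4))[tx$partition],
                 xlab = "log10 mean relative abundance",
                 ylab = "occupancy", ...)
  graphics::lines(log10(tx$p), tx$predicted, col = 2, lwd = 2)
  graphics::lines(log10(tx$p), tx$ci_lower, col = "grey40", lty = 2)
  graphics::lines(log10(tx$p), tx$ci_upper, col = "grey40", lty = 2)
  invisible(x)
}

#' Simulate count tables from a fitted Sloan model
#'
#' Forward-simulates tables at the fitted migration rate, using the
#' fitted mean relative abundances as the source community.
#'
#' @param object A `sloan_fit`.
#' @param nsim Number of tables.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `nsim` count matrices shaped like the fitted data.
#' @export
simulate.sloan_fit <- function(object, nsim = 1, seed = 1, ...) {
  src <- structure(list(asv_ids = object$taxa$asv_id,
                        rel_abundance = object$taxa$p /
                          sum(object$taxa$p)),
                   class = "source_profile")
  lapply(seq_len(nsim), function(i) {
    sample_neutral_table(src, m = object$m, Nt = round(object$Nt),
                         n_samples = object$n_samples,
                         seed = as.integer(seed) + i - 1L)
  })
}

#' Fit the binomial sampling null model
#'
#' Parameter-free null: a taxon with mean relative abundance `p` is
#' detected with probability `1 - (1 - p)^Nt` (at least one draw in `Nt`
#' trials). Goodness of fit and AIC are computed exactly as for the
#' Sloan fit so the two are comparable.
#'
#' @inheritParams sloan_fit
#' @return Object of class `binomial_fit`: `Nt`, `r_squared`, `aic`,
#'   `sse`, and `taxa` (per-ASV `p`, `occupancy`, `predicted`).
#' @export
binomial_fit <- function(counts, allow_real = FALSE) {
  counts <- check_count_matrix(counts, "counts")
  if (!allow_real && max(abs(counts - round(counts))) > 1e-8)
    abort("counts must be integers (set allow_real = TRUE for copy tables)",
          "spikecore_invalid_argument")
  if (ncol(counts) < 10 || nrow(counts) < 5)
    abort("need >= 10 taxa and >= 5 samples", "spikecore_invalid_argument")
  depths <- rowSums(counts)
  if (any(depths == 0))
    abort("all-zero sample(s) present", "spikecore_invalid_argument")
  rel <- sweep(counts, 1, depths, "/")
  p <- colMeans(rel)
  occ <- colMeans(counts > 0)
  Nt <- mean(depths)
  pred <- 1 - (1 - p)^Nt
  sse <- sum((occ - pred)^2)
  sst <- sum((occ - mean(occ))^2)
  structure(
    list(Nt = Nt, r_squared = 1 - sse / sst,
         aic = ncol(counts) * log(sse / ncol(counts)),
         sse = sse, n_taxa = ncol(counts), n_samples = nrow(counts),
         taxa = data.frame(asv_id = colnames(counts), p = p,
                           occupancy = occ, predicted = pred,
                           row.names = NULL)),
    class = "binomial_fit"
  )
}

#' @export
print.binomial_fit <- function(x, ...) {
  cat(sprintf("Binomial sampling null: Nt = %.0f, R2 = %.3f, AIC = %.1f\n",
              x$Nt, x$r_squared, x$aic))
  invisible(x)
}

#' Compare the neutral and binomial fits by AIC
#'
#' Gaussian-error AIC from the occupancy SSE: `n*ln(SSE/n) + 2k` with
#' `k = 1` for the Sloan model (its migration parameter) and `k = 0` for
#' the binomial null. The lower AIC wins; on a tie the binomial null is
#' preferred as the model with fewer parameters.
#'
#' @param neutral A `sloan_fit`.
#' @param binom A `binomial_fit` on the same taxa.
#' @return List of class `model_comparison`: `preferred` (`"neutral"` or
#'   `"binomial"`), `delta_aic` (binomial AIC minus neutral AIC; positive
#'   favours neutral), `aic_neutral`, `aic_binomial`.
#' @export
compare_models <- function(neutral, binom) {
  if (!inherits(neutral, "sloan_fit") || !inherits(binom, "binomial_fit"))
    abort("expected a sloan_fit and a binomial_fit",
          "spikecore_invalid_argument")
  if (!identical(neutral$taxa$asv_id, binom$taxa$asv_id))
    abort("fits cover different taxa sets", "spikecore_invalid_argument")
  delta <- binom$aic - neutral$aic
  structure(
    list(preferred = if (neutral$aic < binom$aic) "neutral" else "binomial",
         delta_aic = delta,
         aic_neutral = neutral$aic,
         aic_binomial = binom$aic),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison: %s preferred (delta AIC = %.2f)\n",
              x$preferred, x$delta_aic))
  invisible(x)
}
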