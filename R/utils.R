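# internal helpers shared across modules

#' @keywords internal
#' @noRd
abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "spikecore_error")))
}

# classed errors used across the package:
#   spikecore_invalid_argument, spikecore_calibration_failure,
#   spikecore_missing_metadata, spikecore_insufficient_data,
#   spikecore_fit_failure

check_count_matrix <- function(x, what = "table") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    abort(sprintf("%s must be a numeric sample x taxon matrix", what),
          "spikecore_invalid_argument")
  if (anyNA(x) || any(x < 0))
    abort(sprintf("%s must be nonnegative with no missing values", what),
          "spikecore_invalid_argument")
  if (is.null(colnames(x)))
    colnames(x) <- paste0("ASV", seq_len(ncol(x)))
  if (is.null(rownames(x)))
    rownames(x) <- paste0("S", seq_len(nrow(x)))
  x
}

# Wilson score interval for a proportion; bounded in [0, 1] by construction,
# which matters for occupancies near 0 or 1.
wilson_interval <- function(p_hat, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  denom <- 1 + z^2 / n
  centre <- (p_hat + z^2 / (2 * n)) / denom
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / denom
  cbind(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

# FNV-1a string hash, used only to stamp outputs with a config fingerprint.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor with a byte only touches the low 8 bits; keeps h a plain double
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    # double-precision-safe multiply modulo 2^32 (split into 16-bit halves)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
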