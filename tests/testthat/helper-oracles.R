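# Independent brute-force oracles. These deliberately share no code with
# the package: explicit loops and textbook formulas only.

oracle_bray <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    num <- 0; den <- 0
    for (j in seq_len(ncol(x))) {
      num <- num + abs(x[a, j] - x[b, j])
      den <- den + x[a, j] + x[b, j]
    }
    d[a, b] <- num / den
  }
  d
}

oracle_shannon <- function(v) {
  p <- v[v > 0] / sum(v)
  -sum(p * log(p))
}

oracle_pielou <- function(v) {
  s <- sum(v > 0)
  if (s <= 1) return(NA_real_)
  oracle_shannon(v) / log(s)
}

oracle_occupancy <- function(x, threshold = 1) {
  out <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    hit <- 0
    for (i in seq_len(nrow(x))) if (x[i, j] >= threshold) hit <- hit + 1
    out[j] <- hit / nrow(x)
  }
  out
}

# Clarke's ANOSIM R from dissimilarity ranks, plus the exhaustive
# permutation distribution over all label assignments (n small).
oracle_anosim_r <- function(d, groups) {
  n <- nrow(d)
  ij <- which(upper.tri(d), arr.ind = TRUE)
  r <- rank(d[upper.tri(d)])
  within <- groups[ij[, 1]] == groups[ij[, 2]]
  (mean(r[!within]) - mean(r[within])) / (n * (n - 1) / 4)
}

oracle_anosim_exhaustive <- function(d, groups) {
  obs <- oracle_anosim_r(d, groups)
  n <- nrow(d)
  n1 <- sum(groups == unique(groups)[1])
  combos <- utils::combn(n, n1)
  stats <- apply(combos, 2, function(idx) {
    g <- rep("B", n); g[idx] <- "A"
    oracle_anosim_r(d, g)
  })
  list(observed = obs, p = mean(stats >= obs - 1e-12),
       distribution = stats)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# small random count table with guaranteed nonempty samples
random_table <- function(n_samples, n_taxa, seed, lambda = 8) {
  set.seed(seed)
  x <- matrix(stats::rpois(n_samples * n_taxa, lambda), n_samples, n_taxa)
  empty <- rowSums(x) == 0
  x[empty, 1] <- 1
  dimnames(x) <- list(paste0("s", seq_len(n_samples)),
                      paste0("ASV", seq_len(n_taxa)))
  x
}

# noiseless log-linear time-decay geometry: similarity = 10^(w*log10(dt))
decay_matrix <- function(times, w) {
  n <- length(times)
  d <- matrix(0, n, n, dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
  for (a in 1:n) for (b in 1:n) {
    if (a != b) {
      dt <- abs(times[a] - times[b])
      d[a, b] <- 1 - 10^(w * log10(dt))
    }
  }
  d
}
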