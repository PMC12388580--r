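#' Per-sample alpha diversity
#'
#' Richness (taxa detected), Shannon-Wiener index in natural log,
#' Pielou's evenness `H / ln(richness)`, and, when a tree is supplied,
#' Faith's phylogenetic diversity (total branch length of the minimal
#' subtree connecting the observed tips, including the root connection).
#' Shannon is computed on within-sample relative frequencies, so it is
#' invariant to multiplying a sample by a constant; evenness is undefined
#' (NA) when richness <= 1, and empty samples get richness 0 with NA
#' Shannon.
#'
#' @param x Sample x taxon matrix (reads or copies), or an
#'   `absolute_table` (its `copies` slot is used).
#' @param tree Optional rooted `phylo` whose tips cover all taxa that are
#'   nonzero in any sample.
#' @return Data frame: `sample_id`, `richness`, `shannon`, `pielou`,
#'   `faith_pd` (NA column when no tree given).
#' @export
alpha_diversity <- function(x, tree = NULL) {
  if (inherits(x, "absolute_table")) x <- x$copies
  x <- check_count_matrix(x, "table")
  richness <- rowSums(x > 0)
  shannon <- vegan::diversity(x, index = "shannon")  # natural log
  shannon[richness == 0] <- NA_real_
  pielou <- ifelse(richness > 1, shannon / log(richness), NA_real_)
  faith <- rep(NA_real_, nrow(x))
  if (!is.null(tree)) {
    present <- colnames(x)[colSums(x) > 0]
    missing <- setdiff(present, tree$tip.label)
    if (length(missing))
      abort(sprintf("tree is missing observed taxa: %s",
                    paste(utils::head(missing, 5), collapse = ", ")),
            "spikecore_invalid_argument")
    nonempty <- richness > 0
    if (any(nonempty)) {
      pd <- picante::pd(x[nonempty, , drop = FALSE], tree,
                        include.root = TRUE)
      faith[nonempty] <- pd$PD
    }
    faith[richness == 0] <- 0
  }
  data.frame(sample_id = rownames(x), richness = richness,
             shannon = as.numeric(shannon), pielou = pielou,
             faith_pd = faith, row.names = NULL)
}

#' Beta-dissimilarity matrix
#'
#' Bray-Curtis dissimilarity `sum|x_i - y_i| / sum(x_i + y_i)` or
#' normalised weighted UniFrac (identical samples give 0). The table is
#' used as given — absolute or relative is the caller's choice and is
#' recorded in the result's `table_kind` attribute.
#'
#' @param x Sample x taxon matrix, or an `absolute_table`.
#' @param metric `"bray_curtis"` or `"weighted_unifrac"`.
#' @param tree Rooted `phylo`; required for weighted UniFrac.
#' @param table_kind Free-text provenance label (e.g. `"absolute"`).
#' @return Symmetric numeric matrix with zero diagonal and sample
#'   dimnames.
#' @export
beta_matrix <- function(x, metric = c("bray_curtis", "weighted_unifrac"),
                        tree = NULL, table_kind = "as-given") {
  metric <- match.arg(metric)
  if (inherits(x, "absolute_table")) x <- x$copies
  x <- check_count_matrix(x, "table")
  empty <- rowSums(x) == 0
  if (any(empty))
    abort(sprintf("all-zero sample(s): %s — dissimilarity undefined",
                  paste(rownames(x)[empty], collapse = ", ")),
          "spikecore_invalid_argument")
  if (metric == "bray_curtis") {
    d <- as.matrix(vegan::vegdist(x, method = "bray"))
  } else {
    if (is.null(tree))
      abort("weighted_unifrac requires a rooted tree",
            "spikecore_invalid_argument")
    ps <- phyloseq::phyloseq(
      phyloseq::otu_table(x, taxa_are_rows = FALSE),
      phyloseq::phy_tree(tree)
    )
    d <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
    d <- d[rownames(x), rownames(x)]
  }
  diag(d) <- 0
  attr(d, "metric") <- metric
  attr(d, "table_kind") <- table_kind
  d
}

# Dunn's pairwise rank test following a Kruskal-Wallis omnibus, with the
# standard tie correction; returns two-sided p-values per group pair.
dunn_pairwise <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[a]] + 1 / n[[b]]))
    z[j] <- (mean_rank[[a]] - mean_rank[[b]]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p)
}

# Compact letter display by insert-and-absorb: groups sharing a letter
# are not significantly different under the supplied pairwise decisions.
assign_letters <- function(lev, sig_pairs) {
  cols <- list(lev)  # letter columns, each a set of mutually-nonsig groups
  if (nrow(sig_pairs)) {
    for (j in seq_len(nrow(sig_pairs))) {
      a <- sig_pairs$group1[j]; b <- sig_pairs$group2[j]
      k <- 1
      while (k <= length(cols)) {
        if (a %in% cols[[k]] && b %in% cols[[k]]) {
          cols <- append(cols, list(setdiff(cols[[k]], b)), after = k)
          cols[[k]] <- setdiff(cols[[k]], a)
          k <- k + 1
        }
        k <- k + 1
      }
      # absorb columns that are subsets of another
      keep <- rep(TRUE, length(cols))
      for (u in seq_along(cols)) for (v in seq_along(cols)) {
        if (u != v && keep[u] && keep[v] &&
            all(cols[[u]] %in% cols[[v]])) keep[u] <- FALSE
      }
      cols <- cols[keep]
    }
  }
  letters_out <- stats::setNames(rep("", length(lev)), lev)
  for (k in seq_along(cols)) {
    lab <- letters[(k - 1) %% 26 + 1]
    if (k > 26) lab <- paste0(lab, (k - 1) %/% 26)
    for (g in cols[[k]]) letters_out[g] <- paste0(letters_out[g], lab)
  }
  letters_out
}

#' Stage-wise group comparison with compact letter display
#'
#' Kruskal-Wallis omnibus test, Dunn pairwise tests with
#' Benjamini-Hochberg correction at the chosen level, and a compact
#' letter display: stages sharing a letter are not significantly
#' different.
#'
#' @param values Numeric per-sample metric (e.g. Shannon index).
#' @param groups Stage label per sample; >= 2 groups with >= 2 samples
#'   each.
#' @param alpha Significance level for the letter display.
#' @return Data frame (`group`, `n`, `median`, `mean_rank`, `letters`)
#'   with attributes `kruskal_p`, `kruskal_statistic`, and `pairwise`
#'   (the Dunn table with BH-adjusted `q`).
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  if (length(values) != length(groups))
    abort("values and groups must have equal length",
          "spikecore_invalid_argument")
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(as.character(groups[ok]))
  if (nlevels(groups) < 2)
    abort("need >= 2 groups", "spikecore_invalid_argument")
  sizes <- table(groups)
  if (any(sizes < 2))
    abort(sprintf("group(s) with < 2 samples: %s",
                  paste(names(sizes)[sizes < 2], collapse = ", ")),
          "spikecore_invalid_argument")
  kw <- stats::kruskal.test(values, groups)
  pw <- dunn_pairwise(values, groups)
  pw$q <- stats::p.adjust(pw$p, method = "BH")
  sig <- pw[pw$q < alpha, , drop = FALSE]
  # order letters by decreasing mean rank so 'a' marks the highest group
  mean_rank <- tapply(rank(values), groups, mean)
  lev <- names(sort(mean_rank, decreasing = TRUE))
  lets <- assign_letters(lev, sig)
  out <- data.frame(
    group = levels(groups),
    n = as.integer(sizes),
    median = as.numeric(tapply(values, groups, stats::median)),
    mean_rank = as.numeric(mean_rank[levels(groups)]),
    letters = unname(lets[levels(groups)])
  )
  attr(out, "kruskal_p") <- kw$p.value
  attr(out, "kruskal_statistic") <- unname(kw$statistic)
  attr(out, "pairwise") <- pw
  out
}
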