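#' Lognormal source-community profile
#'
#' Draws a heavy-tailed metacommunity relative-abundance profile: a few
#' dominant taxa and a long tail of rare ones, the abundance structure
#' typical of 16S surveys. Entries are sorted in decreasing order so that
#' low-numbered ASV identifiers are the dominant taxa.
#'
#' @param n_taxa Number of taxa (>= 2).
#' @param lognormal_sigma Standard deviation of log abundance (>= 0).
#'   `0` gives a uniform profile.
#' @param seed Integer seed; the draw is fully reproducible.
#' @param prefix Prefix for generated ASV identifiers.
#' @return An object of class `source_profile`: a list with `asv_ids`
#'   (character) and `rel_abundance` (numeric, sums to 1).
#' @examples
#' prof <- make_source_profile(10, 1.0, seed = 42)
#' sum(prof$rel_abundance)
#' @export
make_source_profile <- function(n_taxa, lognormal_sigma = 1, seed = 1,
                                prefix = "ASV") {
  if (length(n_taxa) != 1 || is.na(n_taxa) || n_taxa < 2)
    abort("n_taxa must be a single integer >= 2", "spikecore_invalid_argument")
  if (lognormal_sigma < 0)
    abort("lognormal_sigma must be >= 0", "spikecore_invalid_argument")
  set.seed(as.integer(seed))
  x <- sort(stats::rlnorm(n_taxa, meanlog = 0, sdlog = lognormal_sigma),
            decreasing = TRUE)
  structure(
    list(asv_ids = paste0(prefix, seq_len(n_taxa)),
         rel_abundance = x / sum(x)),
    class = "source_profile"
  )
}

#' @export
print.source_profile <- function(x, ...) {
  cat("Source community profile:", length(x$asv_ids), "taxa\n")
  cat("  top taxon share:", signif(max(x$rel_abundance), 3),
      " min share:", signif(min(x$rel_abundance), 3), "\n")
  invisible(x)
}

#' Sample read-count tables under the Sloan neutral model
#'
#' Forward-simulates local communities under neutral assembly: for each
#' sample, each taxon's local relative abundance is drawn from
#' `Beta(Nt*m*p_i, Nt*m*(1-p_i))` around its source abundance `p_i`,
#' the draws are renormalised across taxa, and `Nt` reads are drawn
#' multinomially. Low migration `m` inflates between-sample variance;
#' `m = 1` reduces to sampling directly around the source profile.
#'
#' @param source A [make_source_profile()] object (or list with
#'   `asv_ids` and `rel_abundance`).
#' @param m Migration parameter in (0, 1].
#' @param Nt Reads per sample (multinomial depth).
#' @param n_samples Number of samples to draw.
#' @param seed Integer seed.
#' @return Integer matrix, `n_samples` x `n_taxa`; every row sums to `Nt`.
#' @export
sample_neutral_table <- function(source, m, Nt, n_samples, seed = 1) {
  p <- source$rel_abundance
  if (is.null(p) || length(p) < 2)
    abort("source must hold a relative-abundance profile of length >= 2",
          "spikecore_invalid_argument")
  if (length(m) != 1 || is.na(m) || m <= 0 || m > 1)
    abort("m must lie in (0, 1]", "spikecore_invalid_argument")
  if (Nt < 1 || n_samples < 1)
    abort("Nt and n_samples must be >= 1", "spikecore_invalid_argument")
  set.seed(as.integer(seed))
  S <- length(p)
  counts <- matrix(0L, nrow = n_samples, ncol = S,
                   dimnames = list(paste0("S", seq_len(n_samples)),
                                   source$asv_ids))
  a <- Nt * m * p
  b <- Nt * m * (1 - p)
  for (s in seq_len(n_samples)) {
    freq <- stats::rbeta(S, a, b)
    if (!any(freq > 0)) freq <- p  # degenerate all-zero draw; fall back
    counts[s, ] <- stats::rmultinom(1, size = Nt, prob = freq)[, 1]
  }
  counts
}

#' Default larval-stage design
#'
#' The sampling design the generator emulates: daily samples over 21 days
#' posthatch, with each day assigned to one of 12 developmental stage
#' labels (11 zoeal stages and one postlarval stage) and 6 tank
#' replicates per day, i.e. 126 samples.
#'
#' @param n_days Number of daily timepoints (default 21).
#' @param n_stages Number of stage labels spread over the days (default 12).
#' @return Data frame with columns `dph` (day posthatch) and `stage`.
#' @export
larval_design <- function(n_days = 21, n_stages = 12) {
  dph <- seq_len(n_days)
  idx <- ceiling(dph / n_days * n_stages)
  stage <- sprintf("Z%02d", idx)
  stage[idx == n_stages] <- "PL"
  data.frame(dph = dph, stage = stage)
}

#' Planted-succession count table
#'
#' Generates a longitudinal community with a known persistent microbiome:
#' a fixed set of persistent taxa present in every sample and carrying a
#' fixed fraction of the reads, plus stage-specific transient taxa drawn
#' fresh for each developmental stage. This is the ground-truth generator
#' used to validate persistent-microbiome detection.
#'
#' @param stages Data frame with columns `stage` and `dph` (one row per
#'   timepoint; the same stage label may span several timepoints), or a
#'   character vector of stage labels (then `dph` is the row index).
#' @param tanks_per_stage Number of replicate tanks sampled at each
#'   timepoint.
#' @param persistent_profile [make_source_profile()] for the persistent
#'   members.
#' @param transient_pool [make_source_profile()] for the pool transients
#'   are drawn from.
#' @param persistent_fraction Fraction of each sample's reads expected to
#'   come from persistent taxa, in (0, 1).
#' @param Nt Reads per sample.
#' @param seed Integer seed.
#' @param transients_per_stage How many pool taxa each stage's transient
#'   community contains.
#' @param stage_overlap Fraction of its transient set a stage shares with
#'   the previous stage (default 0.5). Transient sets are consecutive
#'   windows over a (seeded) shuffled pool, so overlap decays with stage
#'   distance and vanishes beyond `1 / (1 - stage_overlap)` stages —
#'   community similarity therefore decays with time separation. `0`
#'   gives disjoint stage transients.
#' @param mass_g Wet mass recorded per sample (grams).
#' @return A list of class `succession_sim` with elements `counts`
#'   (samples x taxa), `metadata` (sample_id, dph, stage, tank, mass_g),
#'   `persistent_ids`, and `stage_transients`. Persistent taxa have
#'   occupancy exactly 1.
#' @export
plant_succession_table <- function(stages, tanks_per_stage,
                                   persistent_profile, transient_pool,
                                   persistent_fraction = 0.95,
                                   Nt = 20000, seed = 1,
                                   transients_per_stage = 60,
                                   stage_overlap = 0.5,
                                   mass_g = 0.03) {
  if (is.character(stages)) stages <- data.frame(dph = seq_along(stages), stage = stages)
  if (NROW(stages) == 0)
    abort("stage list must be nonempty", "spikecore_invalid_argument")
  if (!all(c("dph", "stage") %in% names(stages)))
    abort("stages needs columns dph and stage", "spikecore_invalid_argument")
  if (persistent_fraction <= 0 || persistent_fraction >= 1)
    abort("persistent_fraction must lie in (0, 1)", "spikecore_invalid_argument")
  if (tanks_per_stage < 1) abort("tanks_per_stage must be >= 1",
                                 "spikecore_invalid_argument")
  set.seed(as.integer(seed))

  pers_ids <- persistent_profile$asv_ids
  pool_ids <- transient_pool$asv_ids
  if (any(pers_ids %in% pool_ids))
    abort("persistent and transient taxa must not overlap",
          "spikecore_invalid_argument")
  all_ids <- c(pers_ids, pool_ids)
  n_pers <- length(pers_ids)
  transients_per_stage <- min(transients_per_stage, length(pool_ids))

  if (stage_overlap < 0 || stage_overlap >= 1)
    abort("stage_overlap must lie in [0, 1)", "spikecore_invalid_argument")
  stage_labels <- unique(stages$stage)
  # sliding window over a shuffled pool: consecutive stages share
  # stage_overlap of their transients, distant stages share none
  pool_order <- sample(seq_along(pool_ids))
  step <- max(1L, as.integer(round(transients_per_stage * (1 - stage_overlap))))
  need <- transients_per_stage + (length(stage_labels) - 1L) * step
  if (need > length(pool_ids))
    abort(sprintf("transient pool too small: need %d taxa, have %d",
                  need, length(pool_ids)),
          "spikecore_invalid_argument")
  stage_transients <- lapply(seq_along(stage_labels), function(j) {
    pool_order[(j - 1L) * step + seq_len(transients_per_stage)]
  })
  names(stage_transients) <- stage_labels

  n_rows <- nrow(stages) * tanks_per_stage
  counts <- matrix(0L, nrow = n_rows, ncol = length(all_ids),
                   dimnames = list(NULL, all_ids))
  meta <- data.frame(sample_id = character(n_rows), dph = numeric(n_rows),
                     stage = character(n_rows), tank = integer(n_rows),
                     mass_g = numeric(n_rows))
  row <- 0
  for (i in seq_len(nrow(stages))) {
    st <- stages$stage[i]
    tr_idx <- stage_transients[[st]]
    q_tr <- transient_pool$rel_abundance[tr_idx]
    q <- numeric(length(all_ids))
    q[seq_len(n_pers)] <- persistent_fraction * persistent_profile$rel_abundance
    q[n_pers + tr_idx] <- (1 - persistent_fraction) * q_tr / sum(q_tr)
    for (tank in seq_len(tanks_per_stage)) {
      row <- row + 1
      x <- stats::rmultinom(1, size = Nt, prob = q)[, 1]
      # guarantee persistent presence: plant one read for any persistent
      # taxon the multinomial missed, taken from the deepest column
      zero_pers <- which(x[seq_len(n_pers)] == 0L)
      if (length(zero_pers)) {
        x[zero_pers] <- 1L
        top <- which.max(x)
        x[top] <- x[top] - length(zero_pers)
      }
      counts[row, ] <- x
      meta$sample_id[row] <- sprintf("D%02dT%d", i, tank)
      meta$dph[row] <- stages$dph[i]
      meta$stage[row] <- st
      meta$tank[row] <- tank
      meta$mass_g[row] <- mass_g
    }
  }
  rownames(counts) <- meta$sample_id
  structure(
    list(counts = counts, metadata = meta, persistent_ids = pers_ids,
         stage_transients = lapply(stage_transients, function(i) pool_ids[i])),
    class = "succession_sim"
  )
}

#' @export
print.succession_sim <- function(x, ...) {
  cat("Planted succession simulation:", nrow(x$counts), "samples x",
      ncol(x$counts), "taxa;", length(x$persistent_ids),
      "persistent taxa\n")
  invisible(x)
}

#' Append spike-in reads to a count table
#'
#' Adds synthetic spike-in columns whose expected read count is a linear
#' function of the copies added: `reads = k_sample * copies`. Noiseless by
#' default (the calibration chemistry is assumed tightly linear); optional
#' Poisson counting noise.
#'
#' @param counts Sample x taxon read-count matrix.
#' @param spike_copies Named numeric vector: copies added per spike-in
#'   (>= 3 distinct positive levels). The same gradient is added to every
#'   sample.
#' @param read_per_copy_k Reads generated per copy: a single value or one
#'   per sample (>= 0).
#' @param noise `"none"` (default) or `"poisson"`.
#' @param seed Integer seed (used only for Poisson noise).
#' @return List with `counts` (the table with spike columns appended),
#'   `manifest` (data frame sample_id, spike_id, copies), and `spike_ids`.
#' @export
add_spikein_reads <- function(counts, spike_copies, read_per_copy_k,
                              noise = c("none", "poisson"), seed = 1) {
  noise <- match.arg(noise)
  counts <- check_count_matrix(counts, "counts")
  if (is.null(names(spike_copies)))
    names(spike_copies) <- paste0("SPIKE", seq_along(spike_copies))
  if (length(unique(spike_copies)) < 3 || any(spike_copies <= 0))
    abort("spike_copies needs >= 3 distinct positive copy levels",
          "spikecore_invalid_argument")
  if (any(names(spike_copies) %in% colnames(counts)))
    abort("spike-in IDs collide with ASV IDs", "spikecore_invalid_argument")
  n <- nrow(counts)
  k <- rep_len(read_per_copy_k, n)
  if (any(k < 0)) abort("read_per_copy_k must be >= 0",
                        "spikecore_invalid_argument")
  expected <- outer(k, spike_copies)  # n x n_spike
  if (noise == "poisson") {
    set.seed(as.integer(seed))
    reads <- matrix(stats::rpois(length(expected), expected),
                    nrow = n, dimnames = dimnames(expected))
  } else {
    # noiseless reads are the exact expectation (possibly non-integer),
    # so downstream calibration can be tested for exact recovery
    reads <- expected
  }
  rownames(reads) <- rownames(counts)
  manifest <- data.frame(
    sample_id = rep(rownames(counts), times = length(spike_copies)),
    spike_id = rep(names(spike_copies), each = n),
    copies = rep(unname(spike_copies), each = n)
  )
  list(counts = cbind(counts, reads), manifest = manifest,
       spike_ids = names(spike_copies))
}

#' Random rooted phylogeny over a set of taxa
#'
#' Random rooted binary topology with exponential(1) branch lengths.
#' Supports Faith's phylogenetic diversity and weighted UniFrac on
#' synthetic data; no biological tree model is implied beyond positivity
#' of branch lengths and rootedness.
#'
#' @param asv_ids Character vector of >= 2 unique tip labels.
#' @param seed Integer seed.
#' @return An [ape::rtree()] `phylo` object, rooted, with all `asv_ids`
#'   as tips.
#' @export
random_rooted_tree <- function(asv_ids, seed = 1) {
  if (length(asv_ids) < 2)
    abort("need >= 2 tips", "spikecore_invalid_argument")
  if (anyDuplicated(asv_ids))
    abort("duplicate tip IDs", "spikecore_invalid_argument")
  set.seed(as.integer(seed))
  tr <- ape::rtree(length(asv_ids), rooted = TRUE, br = stats::rexp)
  # rtree permutes labels; assign ours in tip order
  tr$tip.label <- sample(asv_ids)
  tr
}

#' Simulate a full study-shaped dataset
#'
#' Convenience wrapper producing everything the pipeline consumes: a
#' planted-succession read table with spike-ins, sample metadata, a rooted
#' tree, the spike-in manifest, and a ground-truth record. Defaults mirror
#' the emulated design: 126 samples (21 days x 6 tanks over 12 stage
#' labels), 2000 taxa of which 80 are persistent and carry 95% of reads,
#' ~2e4 reads/sample, and per-sample read-per-copy factors that put total
#' community size at ~1e6 copies (~10^7.5 copies/g at 0.03 g wet mass).
#'
#' @param n_taxa Total number of taxa.
#' @param n_persistent Number of planted persistent taxa.
#' @param persistent_fraction Read fraction carried by persistent taxa.
#' @param Nt Reads per sample.
#' @param tanks_per_stage Replicate tanks per timepoint.
#' @param stages Design data frame (default [larval_design()]).
#' @param spike_copies Spike-in copy gradient added to every sample.
#' @param mean_k Geometric-mean reads-per-copy factor.
#' @param sigma_k Lognormal spread of the per-sample factor.
#' @param persistent_sigma,transient_sigma Lognormal shape of the two
#'   abundance profiles.
#' @param transients_per_stage Transient taxa per stage.
#' @param seed Integer seed controlling every draw.
#' @param out_dir If non-NULL, write counts/metadata/manifest TSVs, a
#'   newick tree, and a truth JSON there.
#' @return List of class `spikecore_sim`: `counts` (with spike columns),
#'   `metadata`, `manifest`, `spike_ids`, `tree`, and `truth` (persistent
#'   IDs, per-sample k, profiles, seed).
#' @export
simulate_dataset <- function(n_taxa = 2000, n_persistent = 80,
                             persistent_fraction = 0.95, Nt = 20000,
                             tanks_per_stage = 6, stages = larval_design(),
                             spike_copies = c(SPIKE1 = 1e4, SPIKE2 = 1e5,
                                              SPIKE3 = 1e6),
                             mean_k = 0.02, sigma_k = 0.2,
                             persistent_sigma = 1.5, transient_sigma = 1,
                             transients_per_stage = 60,
                             seed = 1, out_dir = NULL) {
  if (n_persistent >= n_taxa)
    abort("n_persistent must be < n_taxa", "spikecore_invalid_argument")
  seed <- as.integer(seed)
  pers <- make_source_profile(n_persistent, persistent_sigma, seed = seed)
  pool <- make_source_profile(n_taxa - n_persistent, transient_sigma,
                              seed = seed + 1L)
  pool$asv_ids <- paste0("ASV", n_persistent + seq_along(pool$asv_ids))
  sim <- plant_succession_table(stages, tanks_per_stage, pers, pool,
                                persistent_fraction = persistent_fraction,
                                Nt = Nt, seed = seed + 2L,
                                transients_per_stage = transients_per_stage)
  set.seed(seed + 3L)
  k <- stats::rlnorm(nrow(sim$counts), meanlog = log(mean_k), sdlog = sigma_k)
  names(k) <- rownames(sim$counts)
  sp <- add_spikein_reads(sim$counts, spike_copies, k, noise = "none")
  tree <- random_rooted_tree(c(pers$asv_ids, pool$asv_ids), seed = seed + 4L)
  out <- structure(
    list(counts = sp$counts, metadata = sim$metadata,
         manifest = sp$manifest, spike_ids = sp$spike_ids, tree = tree,
         truth = list(persistent_ids = sim$persistent_ids,
                      read_per_copy_k = k,
                      persistent_fraction = persistent_fraction,
                      Nt = Nt, seed = seed,
                      persistent_profile = pers$rel_abundance,
                      stage_transients = sim$stage_transients)),
    class = "spikecore_sim"
  )
  if (!is.null(out_dir)) write_simulated_dataset(out, out_dir)
  out
}

#' @export
print.spikecore_sim <- function(x, ...) {
  cat("Simulated spike-in dataset:", nrow(x$counts), "samples x",
      ncol(x$counts) - length(x$spike_ids), "taxa (+",
      length(x$spike_ids), "spike-ins)\n")
  cat("  persistent taxa:", length(x$truth$persistent_ids), "\n")
  invisible(x)
}
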