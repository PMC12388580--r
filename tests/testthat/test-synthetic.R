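test_that("source profiles are normalised, reproducible, heavy-tailed", {
  prof <- make_source_profile(10, 1.0, seed = 42)
  expect_length(prof$rel_abundance, 10)
  expect_equal(sum(prof$rel_abundance), 1, tolerance = 1e-12)
  expect_true(all(prof$rel_abundance >= 0))

  flat <- make_source_profile(2, 0.0, seed = 1)
  expect_equal(flat$rel_abundance, c(0.5, 0.5))

  a <- make_source_profile(300, 2.0, seed = 7)
  b <- make_source_profile(300, 2.0, seed = 7)
  expect_identical(a, b)
  # decreasing order: dominant taxa get low-numbered ids
  expect_true(all(diff(a$rel_abundance) <= 0))

  expect_error(make_source_profile(1, 1, 1),
               class = "spikecore_invalid_argument")
})

test_that("neutral tables conserve depth, are seed-deterministic", {
  src <- make_source_profile(40, 1, seed = 2)
  t1 <- sample_neutral_table(src, 0.3, 4000, 30, seed = 5)
  t2 <- sample_neutral_table(src, 0.3, 4000, 30, seed = 5)
  expect_identical(t1, t2)
  expect_true(all(rowSums(t1) == 4000))
  expect_error(sample_neutral_table(src, 0, 4000, 5, 1),
               class = "spikecore_invalid_argument")
  expect_error(sample_neutral_table(src, 1.2, 4000, 5, 1),
               class = "spikecore_invalid_argument")
})

test_that("at m near 1 per-taxon mean frequencies match the source", {
  src <- make_source_profile(20, 1, seed = 8)
  tab <- sample_neutral_table(src, 1, 1e6, 100, seed = 9)
  freq <- sweep(tab, 1, rowSums(tab), "/")
  se <- apply(freq, 2, stats::sd) / sqrt(nrow(freq))
  dev <- abs(colMeans(freq) - src$rel_abundance)
  expect_true(all(dev <= 3 * se + 1e-9))
})

test_that("abundant taxa are detected everywhere at study settings", {
  src <- make_source_profile(300, 1, seed = 11)
  tab <- sample_neutral_table(src, 0.6, 5000, 126, seed = 11)
  expect_equal(mean(tab[, which.max(src$rel_abundance)] > 0), 1.0)
})

test_that("generator occupancies track Sloan predictions cohort-wide", {
  src <- make_source_profile(50, 1, seed = 12)
  m <- 0.6; Nt <- 5000
  tab <- sample_neutral_table(src, m, Nt, 600, seed = 13)
  occ <- colMeans(tab > 0)
  pred <- sloan_occupancy(src$rel_abundance, m, Nt)
  wi <- spikecore:::wilson_interval(pred, nrow(tab))
  within <- occ >= wi[, "lower"] & occ <= wi[, "upper"]
  expect_gte(mean(within), 0.9)
  expect_lt(median(abs(occ - pred)), 0.02)
})

test_that("planted succession tables honour their ground truth", {
  pers <- make_source_profile(30, 1.5, seed = 2)
  pool <- make_source_profile(200, 1, seed = 3)
  pool$asv_ids <- paste0("T", seq_along(pool$asv_ids))
  sim <- plant_succession_table(larval_design(), 6, pers, pool,
                                persistent_fraction = 0.95, Nt = 5000,
                                seed = 4, transients_per_stage = 15)
  expect_equal(nrow(sim$counts), 126)
  expect_setequal(names(sim$metadata),
                  c("sample_id", "dph", "stage", "tank", "mass_g"))
  # persistent occupancy exactly 1 by construction
  expect_true(all(colMeans(sim$counts[, sim$persistent_ids] > 0) == 1))
  # per-sample persistent share concentrates near the planted fraction
  share <- rowSums(sim$counts[, sim$persistent_ids]) / rowSums(sim$counts)
  expect_true(all(share >= 0.90 & share <= 0.99))

  # 12 stages x 6 tanks when one row per stage
  st12 <- data.frame(dph = seq(1, 21, length.out = 12),
                     stage = sprintf("Z%02d", 1:12))
  sim72 <- plant_succession_table(st12, 6, pers, pool, 0.95, Nt = 2000,
                                  seed = 5, transients_per_stage = 10)
  expect_equal(nrow(sim72$counts), 72)

  expect_error(plant_succession_table(character(0), 6, pers, pool),
               class = "spikecore_invalid_argument")
})

test_that("distant stages are less similar than replicates within a stage", {
  pers <- make_source_profile(30, 1.5, seed = 2)
  pool <- make_source_profile(200, 1, seed = 3)
  pool$asv_ids <- paste0("T", seq_along(pool$asv_ids))
  sim <- plant_succession_table(larval_design(), 6, pers, pool, 0.95,
                                Nt = 5000, seed = 6,
                                transients_per_stage = 15)
  first <- sim$metadata$stage == "Z01"
  last <- sim$metadata$stage == "PL"
  # verify the two stages share no transients before comparing
  expect_length(intersect(sim$stage_transients[["Z01"]],
                          sim$stage_transients[["PL"]]), 0)
  d <- oracle_bray(sim$counts[first | last, ])
  g <- sim$metadata$stage[first | last]
  ij <- which(upper.tri(d), arr.ind = TRUE)
  within <- g[ij[, 1]] == g[ij[, 2]]
  sim_vals <- 1 - d[upper.tri(d)]
  expect_lt(mean(sim_vals[!within]), mean(sim_vals[within]))
})

test_that("spike-in reads follow the linear read-copy law", {
  tab <- random_table(4, 6, seed = 21)
  sp <- add_spikein_reads(tab, c(SP1 = 1e4, SP2 = 1e5, SP3 = 1e6), 0.01)
  expect_equal(unname(sp$counts[1, c("SP1", "SP2", "SP3")]),
               c(100, 1000, 10000))
  expect_setequal(sp$spike_ids, c("SP1", "SP2", "SP3"))
  expect_equal(nrow(sp$manifest), 12)

  zero <- add_spikein_reads(tab, c(SP1 = 1e4, SP2 = 1e5, SP3 = 1e6), 0)
  expect_true(all(zero$counts[, c("SP1", "SP2", "SP3")] == 0))

  colnames(tab)[1] <- "SP1"
  expect_error(add_spikein_reads(tab, c(SP1 = 1e4, SP2 = 1e5, SP3 = 1e6),
                                 0.01),
               class = "spikecore_invalid_argument")
  expect_error(add_spikein_reads(random_table(2, 3, 1),
                                 c(A = 1e4, B = 1e4, C = 1e4), 0.01),
               class = "spikecore_invalid_argument")
})

test_that("poisson spike noise stays within counting-error bounds", {
  tab <- random_table(50, 4, seed = 22)
  sp <- add_spikein_reads(tab, c(SP1 = 1e4, SP2 = 1e5, SP3 = 1e6), 0.01,
                          noise = "poisson", seed = 23)
  r <- sp$counts[, "SP3"]  # expectation 1e4
  expect_true(all(abs(r - 1e4) <= 4 * sqrt(1e4)))
})

test_that("random trees are rooted, binary, deterministic", {
  ids <- paste0("ASV", 1:2)
  tr2 <- random_rooted_tree(ids, seed = 1)
  expect_true(ape::is.rooted(tr2))
  expect_equal(length(tr2$edge.length), 2)
  expect_true(all(tr2$edge.length > 0))

  ids9 <- paste0("ASV", 1:9)
  tr9 <- random_rooted_tree(ids9, seed = 2)
  expect_equal(tr9$Nnode, 8)  # n - 1 internal nodes, rooted binary
  expect_setequal(tr9$tip.label, ids9)
  expect_identical(ape::write.tree(tr9),
                   ape::write.tree(random_rooted_tree(ids9, seed = 2)))
  expect_error(random_rooted_tree(c("a", "a"), 1),
               class = "spikecore_invalid_argument")
})

test_that("simulate_dataset writes a complete loadable bundle", {
  out <- file.path(tempdir(), "simds")
  sim <- simulate_dataset(n_taxa = 60, n_persistent = 8, seed = 3,
                          transients_per_stage = 4, out_dir = out)
  expect_equal(nrow(sim$counts), 126)
  expect_length(sim$truth$persistent_ids, 8)
  counts2 <- read_count_tsv(file.path(out, "counts.tsv"))
  expect_equal(counts2, sim$counts, tolerance = 1e-12)
  meta2 <- read_metadata_tsv(file.path(out, "metadata.tsv"))
  expect_equal(meta2$sample_id, sim$metadata$sample_id)
  tr <- ape::read.tree(file.path(out, "tree.nwk"))
  expect_setequal(tr$tip.label, setdiff(colnames(sim$counts), sim$spike_ids))
  truth <- jsonlite::read_json(file.path(out, "truth.json"))
  expect_length(truth$persistent_ids, 8)
  unlink(out, recursive = TRUE)
})
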