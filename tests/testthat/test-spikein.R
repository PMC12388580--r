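test_that("standard curve recovers exact and least-squares slopes", {
  exact <- fit_standard_curve(c(100, 1000, 10000), c(1e4, 1e5, 1e6))
  expect_equal(exact$k, 0.01)
  expect_equal(exact$r_squared, 1)
  expect_false(exact$low_r2)

  # independent closed-form slope
  reads <- c(120, 980, 10100); copies <- c(1e4, 1e5, 1e6)
  hand_k <- sum(reads * copies) / sum(copies^2)
  noisy <- fit_standard_curve(reads, copies)
  expect_equal(noisy$k, hand_k, tolerance = 1e-14)

  expect_error(fit_standard_curve(c(0, 0, 0), copies),
               class = "spikecore_calibration_failure")
  expect_error(fit_standard_curve(c(1, 2), c(1e4, 1e5)),
               class = "spikecore_invalid_argument")
  expect_error(fit_standard_curve(c(1, 2, 3), c(1e4, 1e4, 1e4)),
               class = "spikecore_invalid_argument")
})

test_that("reads convert to copies and copies per gram", {
  counts <- rbind(s1 = c(A = 500, SP1 = 100, SP2 = 1000, SP3 = 10000))
  manifest <- data.frame(sample_id = "s1",
                         spike_id = c("SP1", "SP2", "SP3"),
                         copies = c(1e4, 1e5, 1e6))
  curves <- fit_standard_curves(counts, manifest)
  meta <- data.frame(sample_id = "s1", mass_g = 0.03)
  at <- reads_to_copies(counts, curves, meta,
                        spike_ids = c("SP1", "SP2", "SP3"))
  expect_equal(unname(at$copies["s1", "A"]), 5e4)
  expect_equal(unname(at$per_gram["s1", "A"]), 5e4 / 0.03)
  expect_false("SP1" %in% colnames(at$copies))

  # zero reads stay zero copies
  counts0 <- rbind(s1 = c(A = 0, SP1 = 100, SP2 = 1000, SP3 = 10000))
  at0 <- reads_to_copies(counts0, fit_standard_curves(counts0, manifest),
                         meta, spike_ids = c("SP1", "SP2", "SP3"))
  expect_equal(unname(at0$copies["s1", "A"]), 0)
})

test_that("log10 total copies per gram is on the reported scale", {
  total_per_gram <- 10^7.5
  reads_a <- total_per_gram * 0.03 * 0.01  # k = 0.01, mass 0.03 g
  counts <- rbind(s1 = c(A = reads_a * 0.7, B = reads_a * 0.3,
                         SP1 = 100, SP2 = 1000, SP3 = 10000))
  manifest <- data.frame(sample_id = "s1",
                         spike_id = c("SP1", "SP2", "SP3"),
                         copies = c(1e4, 1e5, 1e6))
  at <- reads_to_copies(counts, fit_standard_curves(counts, manifest),
                        data.frame(sample_id = "s1", mass_g = 0.03),
                        spike_ids = c("SP1", "SP2", "SP3"))
  expect_equal(unname(at$log10_total), 7.5, tolerance = 1e-12)
})

test_that("noiseless spike-in round trips recover true copies exactly", {
  src <- make_source_profile(40, 1.2, seed = 31)
  tab <- sample_neutral_table(src, 0.6, 8000, 12, seed = 32)
  set.seed(33)
  k_true <- stats::rlnorm(12, log(0.02), 0.3)
  sp <- add_spikein_reads(tab, c(SP1 = 1e4, SP2 = 1e5, SP3 = 1e6), k_true)
  curves <- fit_standard_curves(sp$counts, sp$manifest)
  meta <- data.frame(sample_id = rownames(tab), mass_g = 0.03)
  at <- reads_to_copies(sp$counts, curves, meta, spike_ids = sp$spike_ids)
  true_copies <- sweep(tab, 1, k_true, "/")
  rel <- abs(at$copies - true_copies) / pmax(true_copies, 1e-300)
  expect_lt(max(rel[true_copies > 0]), 1e-10)
  expect_true(all(at$copies[true_copies == 0] == 0))
})

test_that("calibration preserves within-sample read ratios", {
  src <- make_source_profile(25, 1, seed = 41)
  tab <- sample_neutral_table(src, 0.5, 5000, 6, seed = 42)
  sp <- add_spikein_reads(tab, c(SP1 = 1e4, SP2 = 1e5, SP3 = 1e6), 0.015)
  at <- reads_to_copies(sp$counts, fit_standard_curves(sp$counts, sp$manifest),
                        data.frame(sample_id = rownames(tab), mass_g = 0.03),
                        spike_ids = sp$spike_ids)
  i <- which(tab[1, ] > 0)[1:2]
  expect_equal(at$copies[1, i[1]] / at$copies[1, i[2]],
               tab[1, i[1]] / tab[1, i[2]], tolerance = 1e-12)
})

test_that("missing curves, masses, or unusable slopes are rejected", {
  counts <- rbind(s1 = c(A = 5, SP1 = 100, SP2 = 1000, SP3 = 10000),
                  s2 = c(A = 7, SP1 = 200, SP2 = 2000, SP3 = 20000))
  manifest <- data.frame(
    sample_id = rep(c("s1", "s2"), each = 3),
    spike_id = rep(c("SP1", "SP2", "SP3"), 2),
    copies = rep(c(1e4, 1e5, 1e6), 2))
  curves <- fit_standard_curves(counts, manifest)
  expect_error(reads_to_copies(counts, curves["s1"],
                               spike_ids = c("SP1", "SP2", "SP3")),
               class = "spikecore_missing_metadata")
  broken <- curves
  broken$s2$k <- 0
  expect_error(reads_to_copies(counts, broken,
                               spike_ids = c("SP1", "SP2", "SP3")),
               class = "spikecore_calibration_failure")
  # defaulted mass is flagged, not fatal
  at <- reads_to_copies(counts, curves,
                        spike_ids = c("SP1", "SP2", "SP3"))
  expect_true(all(at$calibration$mass_defaulted))
  expect_equal(at$calibration$mass_g, c(0.03, 0.03))
})
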