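test_that("binomial null evaluates its closed form", {
  tab <- random_table(6, 12, seed = 181)
  fit <- binomial_fit(tab)
  p <- fit$taxa$p
  expect_equal(fit$taxa$predicted, 1 - (1 - p)^fit$Nt, tolerance = 1e-12)
  # direct evaluation of the detection law
  expect_equal(1 - (1 - 0.001)^1000, 0.6323, tolerance = 1e-4)
  expect_equal(unname(sloan_occupancy(0, 0.5, 1000)), 0)
  expect_equal(unname(sloan_occupancy(1, 0.5, 1000)), 1)
})

test_that("predicted occupancy is monotone in abundance and migration", {
  p_grid <- 10^seq(-5, -0.5, length.out = 40)
  for (m in c(0.05, 0.3, 0.9)) {
    occ <- sloan_occupancy(p_grid, m, 5000)
    expect_true(all(diff(occ) >= -1e-12))
  }
  # monotone in m holds above the detection limit d = 1/Nt = 2e-4
  for (p in c(1e-3, 1e-2, 0.1)) {
    occ_m <- vapply(seq(0.05, 1, by = 0.05),
                    function(m) sloan_occupancy(p, m, 5000), numeric(1))
    expect_true(all(diff(occ_m) >= -1e-9))
  }
})

test_that("sloan predictions approach the binomial null as m -> 1, Nt -> inf", {
  p_grid <- 10^seq(-4, log10(0.5), length.out = 60)
  Nt <- 1e6
  sloan <- sloan_occupancy(p_grid, 0.999, Nt)
  binom <- 1 - (1 - p_grid)^Nt
  expect_lt(max(abs(sloan - binom)), 1e-3)
})

test_that("sloan fit recovers the generating migration rate", {
  src <- make_source_profile(300, 1, seed = 191)
  tab <- sample_neutral_table(src, 0.6, 5000, 126, seed = 192)
  fit <- sloan_fit(tab)
  expect_lt(abs(fit$m - 0.6) / 0.6, 0.15)
  expect_lt(median(abs(fit$taxa$occupancy - fit$taxa$predicted)), 0.05)
  expect_true(all(fit$taxa$predicted >= 0 & fit$taxa$predicted <= 1))
  expect_true(all(fit$taxa$ci_lower <= fit$taxa$predicted + 1e-12))
  expect_true(all(fit$taxa$ci_upper >= fit$taxa$predicted - 1e-12))
  # AIC fields follow the SSE convention with k = 1 vs k = 0
  expect_equal(fit$aic, ncol(tab) * log(fit$sse / ncol(tab)) + 2,
               tolerance = 1e-12)
  nul <- binomial_fit(tab)
  expect_equal(nul$aic, ncol(tab) * log(nul$sse / ncol(tab)),
               tolerance = 1e-12)
})

test_that("partitions respect the confidence band and collapse with it", {
  src <- make_source_profile(60, 1, seed = 201)
  tab <- sample_neutral_table(src, 0.4, 3000, 40, seed = 202)
  fit <- sloan_fit(tab)
  above <- fit$taxa$partition == "above"
  below <- fit$taxa$partition == "below"
  expect_true(all(fit$taxa$occupancy[above] > fit$taxa$ci_upper[above]))
  expect_true(all(fit$taxa$occupancy[below] < fit$taxa$ci_lower[below]))
  # zero-width band: everything off the curve becomes non-neutral
  tight <- sloan_fit(tab, level = 1e-12)
  off <- abs(tight$taxa$occupancy - tight$taxa$predicted) > 1e-9
  expect_true(all(tight$taxa$partition[off] != "neutral"))
})

test_that("model comparison prefers neutral on neutral data, null on ties", {
  src <- make_source_profile(200, 1, seed = 211)
  tab <- sample_neutral_table(src, 0.3, 5000, 80, seed = 212)
  fit <- sloan_fit(tab)
  nul <- binomial_fit(tab)
  cmp <- compare_models(fit, nul)
  expect_equal(cmp$preferred, "neutral")
  expect_gt(cmp$delta_aic, 0)

  # identical SSE: the parameter-free null wins by the AIC penalty
  tie_n <- structure(list(aic = 10 + 2, sse = 1,
                          taxa = data.frame(asv_id = c("a", "b"))),
                     class = "sloan_fit")
  tie_b <- structure(list(aic = 10, sse = 1,
                          taxa = data.frame(asv_id = c("a", "b"))),
                     class = "binomial_fit")
  expect_equal(compare_models(tie_n, tie_b)$preferred, "binomial")

  mismatch <- structure(list(aic = 1,
                             taxa = data.frame(asv_id = c("a", "z"))),
                        class = "binomial_fit")
  expect_error(compare_models(fit, mismatch),
               class = "spikecore_invalid_argument")
})

test_that("simulate() round-trips a fitted model", {
  src <- make_source_profile(50, 1, seed = 221)
  tab <- sample_neutral_table(src, 0.5, 2000, 40, seed = 222)
  fit <- sloan_fit(tab)
  sims <- simulate(fit, nsim = 2, seed = 223)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), dim(tab))
  expect_true(all(rowSums(sims[[1]]) == round(fit$Nt)))
})

test_that("invalid count tables are rejected", {
  tab <- random_table(6, 12, seed = 231)
  expect_error(sloan_fit(tab + 0.5), class = "spikecore_invalid_argument")
  expect_silent(sloan_fit(tab + 0.5, allow_real = TRUE))
  expect_error(sloan_fit(tab[, 1:5]), class = "spikecore_invalid_argument")
  expect_error(sloan_fit(tab[1:3, ]), class = "spikecore_invalid_argument")
  neg <- tab; neg[1, 1] <- -1
  expect_error(sloan_fit(neg), class = "spikecore_invalid_argument")
})
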