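# spikecore

Absolute quantification and persistent-microbiome analysis for
longitudinal 16S rRNA amplicon surveys, built around the workflow used to
study bacterial succession during larval development of the giant
freshwater prawn (*Macrobrachium rosenbergii*; 126 samples over 21 days
posthatch, deposited as NMDC10019917).

## What it does

Amplicon read counts are compositional: a taxon's share of reads can rise
while its true population shrinks. Adding synthetic spike-in standards at
known copy numbers to each sample lets the read scale be calibrated back
to absolute 16S copy numbers. `spikecore` implements that calibration and
the downstream community ecology:

- **Spike-in calibration** — per-sample through-origin standard curve
  `reads = k · copies`, giving `copies = reads / k` and copies per gram of
  larval tissue, with a calibration QC report.
- **Diversity** — richness, Shannon–Wiener index (nats), Pielou's
  evenness, Faith's phylogenetic diversity; Bray–Curtis and weighted
  UniFrac dissimilarity; Kruskal–Wallis + Dunn (Benjamini–Hochberg)
  stage comparisons with a compact letter display.
- **Turnover** — PCoA ordination, ANOSIM across developmental stages, and
  the time-decay relationship: OLS of log10 community similarity on log10
  time separation, whose slope `w` is the temporal turnover rate, plus an
  ANCOVA (with permutation support) comparing taxonomic vs phylogenetic
  turnover slopes.
- **Persistent microbiome** — abundance–occupancy detection: taxa are
  ranked by stage-level occupancy (with replicate consistency, abundance
  as tie-break), their cumulative contribution to Bray–Curtis
  beta-diversity is accumulated, and the core is cut at the last rank
  whose marginal relative gain exceeds 2% (first-order-difference elbow).
- **Neutral assembly** — the Sloan neutral community model: occupancy
  predicted from mean relative abundance as
  `1 − I_d(Nt·m·p, Nt·m·(1−p))` with detection limit `d = 1/Nt`,
  migration rate `m` fitted by least squares, 95% Wilson bands
  partitioning taxa into neutral / environmentally selected /
  dispersal-limited, and an AIC comparison against the parameter-free
  binomial sampling null `1 − (1−p)^Nt`.
- **Synthetic data** — a seeded generator emulating the longitudinal
  design (12 developmental stages × 6 tank replicates, planted persistent
  taxa carrying 95% of reads, stage-specific transients with decaying
  stage overlap, spike-in reads under a per-sample linear read–copy law)
  so every stage of the pipeline is testable against known ground truth.

Each estimator is a classed S3 fit object with the usual `print()`,
`summary()`, `coef()`, `predict()`, `plot()`, `residuals()` and
`simulate()` methods where they make sense.

## Worked example

```r
library(spikecore)

sim <- simulate_dataset(seed = 1)          # 126 samples x 2000 ASVs + spikes
reads <- sim$counts[, setdiff(colnames(sim$counts), sim$spike_ids)]

curves <- fit_standard_curves(sim$counts, sim$manifest)
curves[["D01T1"]]
#> Spike-in standard curve [D01T1]: k = 0.02089 reads/copy, R2 = 1.0000 (n = 3)

absolute <- reads_to_copies(sim$counts, curves, sim$metadata,
                            spike_ids = sim$spike_ids)
absolute
#> Absolute abundance table: 126 samples x 2000 ASVs
#>   log10 total copies/g: 7.32 - 7.68

core <- classify_persistent(reads, sim$metadata$stage)
core
#> Persistent microbiome: 83 of 2000 taxa
#>   abundance share: 95.4%; contribution at elbow: 0.458
#>   top members: ASV1, ASV2, ASV3, ASV4, ASV5

src <- make_source_profile(300, 1, seed = 2)
neutral_tab <- sample_neutral_table(src, m = 0.6, Nt = 5000,
                                    n_samples = 126, seed = 3)
fit <- sloan_fit(neutral_tab)
fit
#> Sloan neutral model fit: m = 0.660, Nt = 5000, R2 = 0.939, AIC = -2061.9
#>   partition: above 165, below 14, neutral 121
compare_models(fit, binomial_fit(neutral_tab))
#> Model comparison: neutral preferred (delta AIC = 473.32)

time_decay(beta_matrix(absolute), sim$metadata$dph)
#> Time-decay fit (log10 similarity ~ log10 delta-t):
#>   w = -0.0141, intercept = -0.0611, R2 = 0.0196, p = 2e-34 (n = 7560 pairs)
```

Reading the output: the standard curve recovers the per-sample
reads-per-copy factor planted by the generator; total community size
lands at 10^7.3–10^7.7 copies/g; the elbow cuts the occupancy ranking at
83 taxa which carry 95.4% of all reads (80 were planted); the Sloan fit
recovers a migration rate near the generating 0.6 and decisively beats
the binomial null by AIC; and community similarity decays with time
separation (negative `w`).

The whole workflow can also be driven end-to-end — quantify → diversity
→ turnover → persistence → neutral — with `run_pipeline()`, or from a
shell via the thin wrapper `inst/cli/spikecore.R` (subcommands
`simulate` and `all`, YAML config, seeded).

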