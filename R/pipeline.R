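# End-to-end orchestration: quantify -> diversity -> turnover ->
# persistence -> neutral, with seeded reproducibility and provenance
# headers on every output file.

default_config <- function() {
  list(
    counts = NULL, manifest = NULL, metadata = NULL, tree = NULL,
    out_dir = "spikecore_out",
    seed = 1,
    n_permutations = 999,
    detection_threshold = 1,
    elbow_threshold = 0.02,
    ci_level = 0.95,
    metrics = c("bray_curtis"),
    time_mode = "interval",
    alpha_metric = "shannon"
  )
}

#' Read a pipeline run configuration
#'
#' YAML key-value file mirroring the arguments of [run_pipeline()];
#' missing keys fall back to package defaults.
#'
#' @param path YAML file.
#' @return Config list.
#' @export
read_run_config <- function(path) {
  cfg <- utils::modifyList(default_config(), yaml::read_yaml(path))
  cfg
}

provenance <- function(cfg) {
  # fingerprint only analysis-relevant settings, not I/O locations
  fp <- cfg[setdiff(names(cfg), c("out_dir", "counts", "manifest",
                                  "metadata", "tree"))]
  c(sprintf("spikecore %s",
            as.character(utils::packageVersion("spikecore"))),
    sprintf("seed=%d", cfg$seed),
    sprintf("config=%s",
            fnv1a(paste(deparse(fp[order(names(fp))]), collapse = ""))))
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the five stages in order — spike-in quantification, alpha /
#' beta diversity, turnover (ordination, ANOSIM, time decay, slope
#' ANCOVA), persistent-microbiome detection, and neutral-model fitting —
#' writing every result under `config$out_dir` with a provenance header
#' (package version, seed, config fingerprint). Analyses run on the
#' calibrated absolute table except the neutral model, which uses read
#' counts (its detection limit is a sampling-depth concept). Any stage
#' error aborts the run naming the stage; outputs written so far are
#' kept alongside a `FAILED` marker.
#'
#' @param config A config list (see [read_run_config()]), or a path to a
#'   YAML config. Inputs can be file paths (`counts`, `manifest`,
#'   `metadata`, `tree`) or in-memory objects passed via the `data`
#'   argument.
#' @param data Optional list with in-memory inputs (`counts`,
#'   `manifest`, `metadata`, `tree`, `spike_ids`), taking precedence
#'   over config paths.
#' @return A run report list: per-stage status, key statistics, and the
#'   paths written.
#' @export
run_pipeline <- function(config = list(), data = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- provenance(cfg)
  report <- list(stages = list(), outputs = character(0),
                 seed = cfg$seed)

  counts <- data$counts %||% (if (!is.null(cfg$counts)) read_count_tsv(cfg$counts))
  manifest <- data$manifest %||% (if (!is.null(cfg$manifest)) read_metadata_tsv(cfg$manifest))
  metadata <- data$metadata %||% (if (!is.null(cfg$metadata)) read_metadata_tsv(cfg$metadata))
  tree <- data$tree %||% (if (!is.null(cfg$tree)) ape::read.tree(cfg$tree))
  if (is.null(counts))
    abort("no count table supplied", "spikecore_invalid_argument")
  if (is.null(metadata))
    abort("no sample metadata supplied", "spikecore_invalid_argument")
  spike_ids <- data$spike_ids %||% unique(manifest$spike_id)

  fail <- function(stage, err) {
    writeLines(c(hdr, sprintf("stage=%s", stage),
                 conditionMessage(err)),
               file.path(cfg$out_dir, "FAILED"))
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(err)),
          "spikecore_pipeline_failure")
  }
  run_stage <- function(stage, fun) {
    res <- tryCatch(fun(), error = function(e) fail(stage, e))
    report$stages[[stage]] <<- res
    res
  }

  # --- quantify -------------------------------------------------------
  absolute <- NULL
  reads <- counts
  if (!is.null(manifest)) {
    quant <- run_stage("quantify", function() {
      curves <- fit_standard_curves(counts, manifest)
      abs_tab <- reads_to_copies(counts, curves, metadata,
                                 spike_ids = spike_ids)
      f1 <- file.path(cfg$out_dir, "absolute_per_gram.tsv")
      write_count_tsv(abs_tab$per_gram, f1, header = hdr)
      f2 <- file.path(cfg$out_dir, "calibration_report.tsv")
      write_metadata_tsv(abs_tab$calibration, f2, header = hdr)
      report$outputs <<- c(report$outputs, f1, f2)
      list(status = "completed", absolute = abs_tab,
           n_low_r2 = sum(abs_tab$calibration$low_r2))
    })
    absolute <- quant$absolute
    reads <- counts[, setdiff(colnames(counts), spike_ids), drop = FALSE]
  }
  analysis_tab <- if (!is.null(absolute)) absolute$copies else reads

  # --- diversity ------------------------------------------------------
  idx <- match(rownames(analysis_tab), metadata$sample_id)
  stages_vec <- metadata$stage[idx]
  dph <- metadata$dph[idx]
  div <- run_stage("diversity", function() {
    if ("weighted_unifrac" %in% cfg$metrics && is.null(tree))
      abort("weighted_unifrac requested but no tree supplied",
            "spikecore_invalid_argument")
    alpha <- alpha_diversity(analysis_tab, tree = tree)
    f1 <- file.path(cfg$out_dir, "alpha_diversity.tsv")
    write_metadata_tsv(alpha, f1, header = hdr)
    betas <- lapply(cfg$metrics, function(mt)
      beta_matrix(analysis_tab, metric = mt, tree = tree,
                  table_kind = if (is.null(absolute)) "reads" else "absolute"))
    names(betas) <- cfg$metrics
    fb <- vapply(cfg$metrics, function(mt) {
      f <- file.path(cfg$out_dir, paste0("beta_", mt, ".tsv"))
      write_count_tsv(betas[[mt]], f, header = hdr)
      f
    }, character(1))
    letters_tab <- compare_groups(alpha[[cfg$alpha_metric]], stages_vec)
    f2 <- file.path(cfg$out_dir, "alpha_letters.tsv")
    write_metadata_tsv(letters_tab, f2, header = hdr)
    report$outputs <<- c(report$outputs, f1, fb, f2)
    list(status = "completed", alpha = alpha, betas = betas,
         letters = letters_tab)
  })

  # --- turnover -------------------------------------------------------
  turn <- run_stage("turnover", function() {
    bray <- div$betas$bray_curtis %||%
      beta_matrix(analysis_tab, "bray_curtis")
    ord <- pcoa_ordination(bray)
    f1 <- file.path(cfg$out_dir, "pcoa_coordinates.tsv")
    ordinate_df <- data.frame(sample_id = rownames(bray),
                              ord$points[, seq_len(min(3, ncol(ord$points))),
                                         drop = FALSE])
    write_metadata_tsv(ordinate_df, f1, header = hdr)
    an <- anosim_test(bray, stages_vec, n_perm = cfg$n_permutations,
                      seed = cfg$seed)
    td <- time_decay(bray, dph, time_mode = cfg$time_mode)
    out <- list(status = "completed", pcoa = ord, anosim = an,
                time_decay_taxonomic = td)
    if (!is.null(div$betas$weighted_unifrac)) {
      td_p <- time_decay(div$betas$weighted_unifrac, dph,
                         time_mode = cfg$time_mode)
      out$time_decay_phylogenetic <- td_p
      out$slope_comparison <- compare_slopes(td, td_p,
                                             n_perm = cfg$n_permutations,
                                             seed = cfg$seed)
    }
    f2 <- file.path(cfg$out_dir, "time_decay_pairs.tsv")
    write_metadata_tsv(td$pairs, f2, header = hdr)
    f3 <- file.path(cfg$out_dir, "turnover_summary.json")
    write_json_out(list(
      anosim_r = an$r_statistic, anosim_p = an$p_value,
      slope_w_taxonomic = td$slope_w, r_squared = td$r_squared,
      p_value = td$p_value, n_pairs = td$n_pairs,
      slope_w_phylogenetic = out$time_decay_phylogenetic$slope_w %||% NA,
      ancova_f = out$slope_comparison$f_statistic %||% NA,
      ancova_p = out$slope_comparison$p_value %||% NA), f3)
    report$outputs <<- c(report$outputs, f1, f2, f3)
    out
  })

  # --- persistence ----------------------------------------------------
  # runs on the read table: occupancy and ranking are identical on reads
  # and copies (per-sample calibration is a positive scalar), but the
  # Bray-Curtis contribution elbow is only meaningful on the composition
  # scale — on absolute tables it is dominated by total-abundance
  # differences between samples
  pers <- run_stage("persistence", function() {
    core <- classify_persistent(reads, stages_vec,
                                threshold = cfg$elbow_threshold,
                                detection_threshold = cfg$detection_threshold)
    f1 <- file.path(cfg$out_dir, "occupancy_abundance.tsv")
    write_metadata_tsv(core$records, f1, header = hdr)
    f2 <- file.path(cfg$out_dir, "core_report.json")
    write_json_out(list(elbow_rank = core$elbow_rank,
                        abundance_share = core$abundance_share,
                        persistent_ids = core$persistent_ids), f2)
    report$outputs <<- c(report$outputs, f1, f2)
    list(status = "completed", core = core)
  })

  # --- neutral --------------------------------------------------------
  neut <- run_stage("neutral", function() {
    fit <- sloan_fit(reads, level = cfg$ci_level)
    nul <- binomial_fit(reads)
    cmp <- compare_models(fit, nul)
    f1 <- file.path(cfg$out_dir, "neutral_taxa.tsv")
    write_metadata_tsv(fit$taxa, f1, header = hdr)
    f2 <- file.path(cfg$out_dir, "neutral_fit.json")
    write_json_out(list(m = fit$m, Nt = fit$Nt, r_squared = fit$r_squared,
                        aic_neutral = fit$aic, aic_binomial = nul$aic,
                        delta_aic = cmp$delta_aic,
                        preferred = cmp$preferred), f2)
    report$outputs <<- c(report$outputs, f1, f2)
    list(status = "completed", fit = fit, null = nul, comparison = cmp)
  })

  report$stages <- list(quantify = report$stages$quantify %||%
                          list(status = "skipped (no manifest)"),
                        diversity = div, turnover = turn,
                        persistence = pers, neutral = neut)
  f <- file.path(cfg$out_dir, "run_report.json")
  write_json_out(list(
    stages = lapply(report$stages, function(s) s$status),
    seed = cfg$seed, outputs = basename(report$outputs)), f)
  report$outputs <- c(report$outputs, f)
  invisible(report)
}

#' Simulate a dataset and write it to disk
#'
#' CLI-facing wrapper around [simulate_dataset()]: builds the synthetic
#' study-shaped dataset and writes counts, metadata, spike-in manifest,
#' tree, and ground truth under `out_dir`.
#'
#' @param out_dir Output directory.
#' @param ... Passed to [simulate_dataset()].
#' @return The simulated dataset, invisibly.
#' @export
simulate_command <- function(out_dir, ...) {
  sim <- simulate_dataset(..., out_dir = out_dir)
  invisible(sim)
}
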