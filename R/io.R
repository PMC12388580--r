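# TSV/JSON/newick readers and writers. One dialect throughout: count
# tables are written samples-as-rows with a leading sample_id column;
# lines starting with '#' are provenance comments and are skipped on read.

#' Write a count table as TSV
#'
#' @param counts Sample x taxon matrix.
#' @param path Output file.
#' @param header Optional character vector of provenance lines, written
#'   as leading `#` comments.
#' @export
write_count_tsv <- function(counts, path, header = NULL) {
  counts <- check_count_matrix(counts, "counts")
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table written by [write_count_tsv()]
#' @param path TSV file, samples as rows, first column `sample_id`.
#' @return Numeric matrix with sample row names.
#' @export
read_count_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write/read sample metadata TSV (sample_id, dph, stage, tank, mass_g)
#' @param metadata Data frame.
#' @param path File path.
#' @param header Optional provenance comment lines.
#' @export
write_metadata_tsv <- function(metadata, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(metadata, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE)
}

#' Write a simulated dataset to disk
#'
#' Writes counts TSV (spike columns included), metadata TSV, spike-in
#' manifest TSV, newick tree, and ground-truth JSON.
#'
#' @param sim A [simulate_dataset()] result.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_count_tsv(sim$counts, file.path(out_dir, "counts.tsv"))
  write_metadata_tsv(sim$metadata, file.path(out_dir, "metadata.tsv"))
  write_metadata_tsv(sim$manifest, file.path(out_dir, "spike_manifest.tsv"))
  ape::write.tree(sim$tree, file.path(out_dir, "tree.nwk"))
  truth <- sim$truth
  truth$read_per_copy_k <- as.list(truth$read_per_copy_k)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Published persistent-microbiome membership table
#'
#' The persistent ASV membership by lineage reported for the
#' *Macrobrachium rosenbergii* larval development dataset (accession
#' NMDC10019917): 80 persistent members across seven phylum/class
#' lineages. One Deinococcota member is listed without an ASV identifier
#' in the published enumeration; its `asv_id` is empty here.
#'
#' @return Data frame with columns `lineage` and `asv_id` (one row per
#'   persistent member).
#' @export
persistent_membership <- function() {
  path <- system.file("extdata", "persistent_asv_membership.tsv",
                      package = "spikecore")
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    na.strings = NULL,
                    colClasses = c("character", "character"))
}
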