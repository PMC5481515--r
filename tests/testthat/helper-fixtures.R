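# shared fixtures, built in code

# minimal hand-made experiment: 4 groups x 2 replicates, equal library sizes,
# counts chosen so cpm == counts per million scaling is easy to reason about
tiny_experiment <- function(counts, biotype = NULL) {
  n <- nrow(counts)
  samples <- data.frame(
    sample_id = colnames(counts),
    compartment = rep(c("STR", "PFR"), each = ncol(counts) / 2),
    port = rep(c("S", "P5"), each = ncol(counts) / 2),
    process_time = 28,
    replicate = rep(1:2, times = ncol(counts) / 2),
    group = rep(c("S_28h", "P5_28h"), each = ncol(counts) / 2),
    stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = rownames(counts),
                      length_nt = rep(1000L, n), length_aa = rep(300L, n),
                      biotype = biotype %||% rep("mRNA", n),
                      cog = NA_character_, sigma = NA_character_,
                      baseline_tpm = rep(1, n), stringsAsFactors = FALSE)
  class(genes) <- c("gene_table", "data.frame")
  count_experiment(counts, samples, genes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small simulated experiment reused across DE tests (built once per run)
fixture_env <- new.env()

small_null_nexp <- function() {
  if (is.null(fixture_env$nexp)) {
    g <- make_genome(300, seed = 301)
    d <- make_design(str_times = c(0, 28), pfr_times = 28, ports = "P5",
                     replicates = 2)
    ex <- simulate_counts(g, d, truth = NULL, phi = 0.05, seed = 302)
    fixture_env$nexp <- normalize_experiment(filter_genes(ex))
  }
  fixture_env$nexp
}
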