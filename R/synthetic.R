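#' Generate a synthetic gene annotation table
#'
#' Emulates the analysis universe of a bacterial RNA-seq study: transcript
#' lengths drawn log-normally (median about 1 kb), protein lengths consistent
#' with coding length, COG functional letters assigned with realistic
#' marginal frequencies (about 14% of genes unannotated), sigma-factor
#' regulon memberships (about 11% unannotated, housekeeping sigma_D
#' dominant, a sigma_S/sigma_D composite class for genes under multiple
#' promoters), around 5% residual rRNA/tRNA decoys, and a heavy-tailed
#' baseline expression level in transcripts per million.
#'
#' @param n_genes number of genes (>= 50).
#' @param seed integer seed; the generator is a pure function of
#'   `(n_genes, seed)`.
#' @return A `gene_table` data frame with columns `gene_id`, `length_nt`,
#'   `length_aa`, `biotype`, `cog`, `sigma`, `baseline_tpm`.
#' @examples
#' g <- make_genome(500, seed = 1)
#' table(g$biotype)
#' @export
make_genome <- function(n_genes, seed = 1) {
  if (n_genes < 50) stopf("`n_genes` must be at least 50")
  with_seed(seed, {
    id <- sprintf("g%05d", seq_len(n_genes))
    biotype <- rep("mRNA", n_genes)
    decoy <- stats::runif(n_genes) < 0.05
    biotype[decoy] <- sample(c("rRNA", "tRNA"), sum(decoy),
                             replace = TRUE, prob = c(0.4, 0.6))
    length_nt <- round(stats::rlnorm(n_genes, log(1000), 0.55))
    length_nt <- pmax(length_nt, 150)
    length_nt[biotype == "tRNA"] <- round(stats::runif(sum(biotype == "tRNA"), 74, 95))
    length_nt[biotype == "rRNA"] <- sample(c(120, 1542, 2904),
                                           sum(biotype == "rRNA"), replace = TRUE)
    length_aa <- pmax(30, floor(length_nt / 3.2))
    length_aa[biotype != "mRNA"] <- 0

    cog_freq <- c(J = .05, K = .09, L = .05, D = .01, T = .05, M = .06,
                  N = .03, U = .02, O = .04, C = .07, G = .09, E = .10,
                  F = .03, H = .05, I = .03, P = .06, Q = .02, R = .08, S = .07)
    cog <- ifelse(stats::runif(n_genes) < 0.144, NA_character_,
                  sample(names(cog_freq), n_genes, replace = TRUE,
                         prob = cog_freq))
    cog[biotype != "mRNA"] <- NA_character_

    sigma_classes <- c("sigma_D", "sigma_S", "sigma_N", "sigma_F", "sigma_E",
                       "sigma_H", "sigma_S;sigma_D")
    sigma_freq <- c(.62, .12, .05, .04, .05, .04, .08)
    sigma <- ifelse(stats::runif(n_genes) < 0.11, NA_character_,
                    sample(sigma_classes, n_genes, replace = TRUE,
                           prob = sigma_freq))
    sigma[biotype != "mRNA"] <- NA_character_

    tpm <- stats::rlnorm(n_genes, meanlog = 4, sdlog = 1.2)
    tpm[biotype != "mRNA"] <- tpm[biotype != "mRNA"] * 0.15  # depleted decoys
    tpm <- tpm / sum(tpm) * 1e6

    structure(data.frame(gene_id = id, length_nt = length_nt,
                         length_aa = length_aa, biotype = biotype,
                         cog = cog, sigma = sigma, baseline_tpm = tpm,
                         stringsAsFactors = FALSE),
              class = c("gene_table", "data.frame"))
  })
}

# resolve a regulon/category name against the annotation
resolve_category <- function(genes, name, spec) {
  if (is.list(spec) && !is.null(spec$gene_ids)) {
    unknown <- setdiff(spec$gene_ids, genes$gene_id)
    if (length(unknown)) stopf("unknown gene ids in custom block `%s`", name)
    return(match(spec$gene_ids, genes$gene_id))
  }
  if (nchar(name) == 1L) {
    idx <- which(!is.na(genes$cog) & genes$cog == name)
    if (!length(idx)) stopf("unknown or empty COG category `%s`", name)
    return(idx)
  }
  if (grepl("^sigma_", name)) {
    hit <- which(!is.na(genes$sigma) &
                 vapply(strsplit(genes$sigma, ";", fixed = TRUE),
                        function(s) name %in% s, logical(1)))
    if (!length(hit)) stopf("unknown or empty sigma regulon `%s`", name)
    return(hit)
  }
  stopf("unknown category `%s`: use a COG letter, a sigma_* regulon, or a list(gene_ids=...)", name)
}

#' Program a ground-truth expression response
#'
#' Builds per-gene log2 fold-change programs for a synthetic STR-PFR
#' experiment. The short-term program fires along the plug-flow loop with a
#' step onset at the configured reaction delay (default 70 s: ports reached
#' later than the onset carry the effect, earlier ports do not). The
#' long-term program describes the drift from the initial steady state S0 to
#' the new steady state S1 in the stirred tank, ramping linearly with
#' process time until the steady-state time.
#'
#' Each effect block is named by a COG letter (e.g. `"E"`), a sigma regulon
#' (e.g. `"sigma_N"`), or given explicitly as
#' `list(gene_ids = ..., direction = +1, lfc = 1)`. Named blocks take
#' `c(direction, lfc)` where `lfc` is the mean absolute log2 fold change;
#' per-gene magnitudes are drawn normally around it.
#'
#' @param genes a `gene_table` from [make_genome()].
#' @param short_effects,long_effects named lists of effect blocks.
#' @param onset reaction-time onset along the PFR (s).
#' @param ss_time process time (h) at which the long-term drift saturates.
#' @param lfc_sd_frac per-gene spread of |log2FC| as a fraction of the block
#'   mean.
#' @param seed integer seed.
#' @return A `truth_program` list with `short_lfc` and `long_lfc` vectors
#'   (one entry per gene; zero outside perturbed blocks), `onset`, `ss_time`.
#' @examples
#' g <- make_genome(500, seed = 1)
#' tr <- make_truth(g, short_effects = list(sigma_N = c(1, 1.5)), seed = 2)
#' sum(tr$short_lfc != 0)
#' @export
make_truth <- function(genes, short_effects = list(), long_effects = list(),
                       onset = 70, ss_time = 25, lfc_sd_frac = 0.25,
                       seed = 1) {
  stopifnot(inherits(genes, "gene_table"))
  n <- nrow(genes)
  draw <- function(effects) {
    lfc <- numeric(n)
    for (nm in names(effects)) {
      spec <- effects[[nm]]
      idx <- resolve_category(genes, nm, spec)
      if (is.list(spec)) {
        dir <- spec$direction; m <- spec$lfc
      } else {
        dir <- spec[[1]]; m <- spec[[2]]
      }
      if (!dir %in% c(-1, 1)) stopf("direction must be +1 or -1 in block `%s`", nm)
      check_positive(m, "lfc")
      lfc[idx] <- dir * abs(stats::rnorm(length(idx), m, lfc_sd_frac * m))
    }
    lfc
  }
  with_seed(seed, {
    structure(list(short_lfc = draw(short_effects),
                   long_lfc = draw(long_effects),
                   onset = onset, ss_time = ss_time,
                   gene_id = genes$gene_id),
              class = "truth_program")
  })
}

#' Build an STR-PFR sampling design
#'
#' One row per sequencing sample: STR samples (port `"S"`) at each process
#' time and PFR port samples (`P1`-`P5` by default) at the requested process
#' times, each with the given number of biological replicates. The combined
#' `group` factor (port x process time) is the experimental factor used by
#' the differential-expression engine.
#'
#' @param str_times process times (h) at which the STR is sampled; defaults
#'   to eleven points from the initial steady state (0 h) to 28 h.
#' @param pfr_times process times (h) at which the PFR ports are sampled.
#' @param ports PFR port names.
#' @param replicates biological replicates (>= 2).
#' @return A data frame with columns `sample_id`, `compartment`, `port`,
#'   `process_time`, `replicate`, `group`.
#' @export
make_design <- function(str_times = c(0, 0.08, 0.42, 0.75, 2, 4, 8, 12, 20, 26, 28),
                        pfr_times = c(0.42, 2, 28),
                        ports = c("P1", "P2", "P3", "P4", "P5"),
                        replicates = 2) {
  if (replicates < 2) stopf("at least 2 replicates are required")
  str_part <- expand.grid(port = "S", process_time = str_times,
                          replicate = seq_len(replicates),
                          stringsAsFactors = FALSE)
  d <- str_part
  if (!is.null(pfr_times) && length(pfr_times) && length(ports)) {
    pfr_part <- expand.grid(port = ports, process_time = pfr_times,
                            replicate = seq_len(replicates),
                            stringsAsFactors = FALSE)
    d <- rbind(str_part, pfr_part)
  }
  d$compartment <- ifelse(d$port == "S", "STR", "PFR")
  d$group <- paste0(d$port, "_", d$process_time, "h")
  d$sample_id <- paste0(d$group, "_r", d$replicate)
  d[, c("sample_id", "compartment", "port", "process_time",
        "replicate", "group")]
}

#' Simulate negative-binomial counts for an STR-PFR design
#'
#' Counts are drawn as `NB(mean = L_j * p_gj, var = mean + phi_g * mean^2)`
#' where the per-sample gene proportions `p_gj` derive from the annotation's
#' baseline TPM shifted by the programmed truth (length-weighted, since read
#' counts scale with transcript length), `L_j` is the library size and
#' `phi_g` are genewise dispersions drawn log-normally around `phi`.
#'
#' A PFR sample carries the short-term program when its port's residence
#' time has passed the onset delay; all samples carry the long-term program
#' scaled by `min(1, process_time / ss_time)`.
#'
#' @param genes a `gene_table`.
#' @param design a design data frame from [make_design()].
#' @param truth optional `truth_program`; `NULL` means no perturbation.
#' @param phi median genewise NB dispersion (> 0).
#' @param phi_sdlog log-sd of the genewise dispersion distribution.
#' @param lib_size_range library sizes are drawn uniformly from this range
#'   (default 0.9-1.1 million, a 10x scale-down of typical study depth;
#'   scale up for full-depth emulation).
#' @param port_times named port residence times (s), used for the onset rule.
#' @param seed integer seed.
#' @return A [count_experiment()].
#' @examples
#' g <- make_genome(200, seed = 1)
#' d <- make_design(str_times = c(0, 28), pfr_times = 28, ports = "P5")
#' ex <- simulate_counts(g, d, phi = 0.05, seed = 3)
#' dim(ex$counts)
#' @export
simulate_counts <- function(genes, design, truth = NULL, phi = 0.05,
                            phi_sdlog = 0.3, lib_size_range = c(0.9e6, 1.1e6),
                            port_times = c(P1 = 30, P2 = 50, P3 = 70,
                                           P4 = 90, P5 = 110),
                            seed = 1) {
  stopifnot(inherits(genes, "gene_table"))
  check_positive(phi, "phi")
  check_positive(lib_size_range, "lib_size_range")
  n <- nrow(genes); m <- nrow(design)
  with_seed(seed, {
    phi_g <- exp(log(phi) + stats::rnorm(n, 0, phi_sdlog))
    L <- round(stats::runif(m, lib_size_range[1], lib_size_range[2]))
    counts <- matrix(0L, n, m, dimnames = list(genes$gene_id, design$sample_id))
    for (j in seq_len(m)) {
      lfc <- numeric(n)
      if (!is.null(truth)) {
        ramp <- min(1, design$process_time[j] / truth$ss_time)
        lfc <- truth$long_lfc * ramp
        if (design$compartment[j] == "PFR" &&
            port_times[[design$port[j]]] >= truth$onset)
          lfc <- lfc + truth$short_lfc
      }
      w <- genes$baseline_tpm * 2^lfc * genes$length_nt
      mu <- L[j] * w / sum(w)
      counts[, j] <- stats::rnbinom(n, mu = mu, size = 1 / phi_g)
    }
    samples <- design
    samples$lib_size_target <- L  # realized lib_size (column sums) is set by the container
    count_experiment(counts, samples, genes, dispersion_truth = phi_g)
  })
}

#' Count experiment container
#'
#' The central object of the statistical pipeline: an integer count matrix
#' (genes x samples), the sample sheet and the gene annotation.
#'
#' @param counts integer matrix, rows named by gene id, columns by sample id.
#' @param samples sample sheet with at least `sample_id`, `compartment`,
#'   `port`, `process_time`, `replicate`, `group`.
#' @param genes a `gene_table` (or compatible data frame) matching the rows.
#' @param dispersion_truth optional generative dispersions (kept for
#'   simulator provenance).
#' @return An object of class `count_experiment`.
#' @export
count_experiment <- function(counts, samples, genes, dispersion_truth = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("`counts` must be non-negative integers")
  if (nrow(counts) != nrow(genes)) stopf("counts rows != annotation rows")
  if (ncol(counts) != nrow(samples)) stopf("counts columns != sample rows")
  if (!all(colnames(counts) == samples$sample_id))
    stopf("count columns must match sample sheet order")
  if (max(table(samples$group)) < 2)
    stopf("at least one group must have >= 2 replicates")
  storage.mode(counts) <- "integer"
  samples$lib_size <- colSums(counts)
  structure(list(counts = counts, samples = samples, genes = genes,
                 dispersion_truth = dispersion_truth),
            class = "count_experiment")
}

#' @export
print.count_experiment <- function(x, ...) {
  cat(sprintf("count_experiment: %d genes x %d samples (%d groups, %d STR / %d PFR)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$samples$group)),
              sum(x$samples$compartment == "STR"),
              sum(x$samples$compartment == "PFR")))
  cat(sprintf("  library sizes: %.2f +- %.2f million\n",
              mean(x$samples$lib_size) / 1e6, stats::sd(x$samples$lib_size) / 1e6))
  invisible(x)
}

#' Derive gene-set collections from the annotation
#'
#' Builds GMT-style sets: one per COG letter (`COG_X`), one per sigma factor
#' (a gene under several promoters belongs to each), and one composite set
#' per observed multi-factor combination (e.g. `sigma_S_sigma_D`).
#'
#' @param genes a `gene_table`.
#' @return Named list of gene-id character vectors.
#' @export
gene_sets_from_annotation <- function(genes) {
  sets <- list()
  for (letter in sort(unique(stats::na.omit(genes$cog))))
    sets[[paste0("COG_", letter)]] <-
      genes$gene_id[!is.na(genes$cog) & genes$cog == letter]
  sig <- strsplit(ifelse(is.na(genes$sigma), "", genes$sigma), ";", fixed = TRUE)
  for (fac in sort(unique(unlist(sig))))
    if (nzchar(fac))
      sets[[fac]] <- genes$gene_id[vapply(sig, function(s) fac %in% s, logical(1))]
  comb <- unique(genes$sigma[!is.na(genes$sigma) & grepl(";", genes$sigma)])
  for (cc in comb)
    sets[[gsub(";", "_", cc, fixed = TRUE)]] <-
      genes$gene_id[!is.na(genes$sigma) & genes$sigma == cc]
  sets
}

#' Write a synthetic experiment to plain-text files
#'
#' Emits `counts.tsv` (gene_id + one column per sample), `samples.tsv`,
#' `genes.tsv` and `sets.gmt` into a directory; [read_experiment()] reads
#' them back losslessly.
#'
#' @param exp a [count_experiment()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_experiment <- function(exp, out_dir) {
  stopifnot(inherits(exp, "count_experiment"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("counts.tsv", "samples.tsv", "genes.tsv", "sets.gmt"))
  cnt <- data.frame(gene_id = rownames(exp$counts), exp$counts,
                    check.names = FALSE)
  utils::write.table(cnt, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(exp$samples, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(exp$genes, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(gene_sets_from_annotation(exp$genes), paths[4])
  invisible(paths)
}

#' Read an experiment written by [write_experiment()]
#'
#' @param dir directory containing `counts.tsv`, `samples.tsv`, `genes.tsv`.
#' @return A [count_experiment()].
#' @export
read_experiment <- function(dir) {
  cnt <- utils::read.delim(file.path(dir, "counts.tsv"), check.names = FALSE)
  counts <- as.matrix(cnt[, -1, drop = FALSE])
  rownames(counts) <- cnt$gene_id
  samples <- utils::read.delim(file.path(dir, "samples.tsv"))
  genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  class(genes) <- c("gene_table", "data.frame")
  count_experiment(counts, samples, genes)
}
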