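#' Counts per million
#'
#' @param counts count matrix or vector.
#' @param lib_sizes per-sample library sizes; defaults to column sums.
#' @return `counts * 1e6 / lib_size`, same shape as the input.
#' @examples
#' cpm(18, 9e6)  # 2
#' @export
cpm <- function(counts, lib_sizes = NULL) {
  if (is.matrix(counts)) {
    if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
    check_positive(lib_sizes, "lib_sizes")
    sweep(counts, 2, lib_sizes, "/") * 1e6
  } else {
    check_positive(lib_sizes, "lib_sizes")
    counts * 1e6 / lib_sizes
  }
}

#' Transcripts per million
#'
#' Length-normalized relative abundance: `rate = count / length`, scaled so
#' each sample sums to one million.
#'
#' @param counts count matrix (genes x samples) or vector.
#' @param lengths transcript lengths (nt), one per gene.
#' @return TPM matrix; every column sums to 1e6.
#' @export
tpm <- function(counts, lengths) {
  check_positive(lengths, "lengths")
  if (!is.matrix(counts)) counts <- matrix(counts, ncol = 1)
  rate <- counts / lengths
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

#' Remove structural RNA and low-coverage genes
#'
#' Drops genes flagged as rRNA or tRNA, then genes whose counts-per-million
#' fall below `min_cpm` in strictly more than `max_frac` of the samples
#' (both inequalities strict: a gene at exactly 2 cpm, or below threshold in
#' exactly 25% of samples, is kept). Gene order is preserved.
#'
#' @param exp a [count_experiment()].
#' @param min_cpm CPM threshold (default 2).
#' @param max_frac maximum tolerated fraction of below-threshold samples
#'   (default 0.25).
#' @return The filtered `count_experiment`; the removal report is in
#'   `attr(, "filter_report")`.
#' @export
filter_genes <- function(exp, min_cpm = 2, max_frac = 0.25) {
  stopifnot(inherits(exp, "count_experiment"))
  is_decoy <- exp$genes$biotype %in% c("rRNA", "tRNA")
  cc <- cpm(exp$counts, exp$samples$lib_size)
  frac_low <- rowMeans(cc < min_cpm)
  low <- frac_low > max_frac
  keep <- !is_decoy & !low
  if (!any(keep)) stopf("filtering removed every gene")
  out <- count_experiment(exp$counts[keep, , drop = FALSE], exp$samples,
                          exp$genes[keep, , drop = FALSE],
                          dispersion_truth = exp$dispersion_truth[keep])
  attr(out, "filter_report") <- list(
    n_input = nrow(exp$counts), n_rrna_trna = sum(is_decoy),
    n_low_coverage = sum(low & !is_decoy), n_kept = sum(keep))
  out
}

#' Trimmed mean of M-values normalization factors
#'
#' Composition-correction factors computed natively: the reference sample is
#' the library whose upper-quartile CPM is closest to the mean upper
#' quartile; for every other sample, genes expressed in both are summarized
#' by log ratios (M) and average abundances (A), the most extreme 30% of M
#' and 5% of A are trimmed on each side, and the factor is the
#' precision-weighted mean of the surviving M values. Factors are rescaled
#' to geometric mean 1.
#'
#' @param counts count matrix (>= 2 samples).
#' @param logratio_trim,abs_trim two-sided trim fractions for M and A.
#' @return Per-sample normalization factors, geometric mean 1.
#' @export
norm_factors_tmm <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stopf("TMM needs at least 2 samples")
  N <- colSums(counts)
  f75 <- apply(counts, 2, function(y) stats::quantile(y / sum(y), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  yr <- counts[, ref]; Nr <- N[ref]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    yj <- counts[, j]; Nj <- N[j]
    ok <- yj > 0 & yr > 0
    if (sum(ok) < 10) return(1)
    pj <- yj[ok] / Nj; pr <- yr[ok] / Nr
    M <- log2(pj / pr)
    A <- 0.5 * log2(pj * pr)
    w <- (Nj - yj[ok]) / (Nj * yj[ok]) + (Nr - yr[ok]) / (Nr * yr[ok])
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) return(1)
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

#' Attach normalization layers to a filtered experiment
#'
#' Computes TMM factors, the CPM matrix and (for genes with positive
#' length) the TPM matrix, and stores them on the experiment.
#'
#' @param exp a filtered [count_experiment()].
#' @return A `normalized_experiment` (also a `count_experiment`).
#' @export
normalize_experiment <- function(exp) {
  stopifnot(inherits(exp, "count_experiment"))
  exp$norm_factors <- norm_factors_tmm(exp$counts)
  exp$effective_lib <- exp$samples$lib_size * exp$norm_factors
  exp$cpm <- cpm(exp$counts, exp$effective_lib)
  exp$tpm <- tpm(exp$counts, exp$genes$length_nt)
  class(exp) <- unique(c("normalized_experiment", class(exp)))
  exp
}

# design matrix of the study convention: replicate factor plus the combined
# port x time experimental factor, with `baseline` as the reference level
design_matrix <- function(samples, baseline = NULL) {
  grp <- factor(samples$group)
  if (!is.null(baseline)) grp <- stats::relevel(grp, ref = baseline)
  rep_f <- factor(samples$replicate)
  if (nlevels(rep_f) > 1)
    X <- stats::model.matrix(~ rep_f + grp)
  else
    X <- stats::model.matrix(~ grp)
  if (qr(X)$rank < ncol(X)) stopf("design matrix is not of full rank")
  colnames(X) <- sub("^grp", "group_", colnames(X))
  X
}

# NB deviance (phi -> 0 reduces to Poisson)
nb_deviance <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  if (phi > 1e-12) {
    2 * sum(t1 - (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu)))
  } else {
    2 * sum(t1 - (y - mu))
  }
}

# single-gene NB IRLS fit; offset on the log scale
nb_irls <- function(y, X, phi, offset, tol = 1e-6, max_iter = 50) {
  mu <- pmax(y, mean(y) / 6 + 1e-4)
  eta <- log(mu)
  beta <- qr.coef(qr(X), eta - offset)
  beta[is.na(beta)] <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    new_beta <- fit$coefficients
    new_beta[is.na(new_beta)] <- 0
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta; converged <- TRUE; break
    }
    beta <- new_beta
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  list(beta = beta, mu = mu, deviance = nb_deviance(y, mu, phi),
       converged = converged)
}

#' Fit genewise negative-binomial log-linear models
#'
#' One NB GLM per gene by iteratively reweighted least squares with a log
#' link and library-size offsets; convergence when the largest coefficient
#' change falls below 1e-6 or after 50 iterations (non-convergence is
#' flagged per gene, never fatal).
#'
#' @param counts count matrix (genes x samples).
#' @param design full-rank design matrix.
#' @param dispersion genewise NB dispersions (recycled if scalar).
#' @param offset per-sample log effective library sizes (vector or matrix).
#' @return An `nb_fit` list: `coefficients` (genes x p), `deviance`,
#'   `fitted`, `converged`, `design`, `dispersion`, `offset`.
#' @export
fit_nb_glm <- function(counts, design, dispersion, offset) {
  counts <- as.matrix(counts)
  if (qr(design)$rank < ncol(design)) stopf("design matrix is not of full rank")
  n <- nrow(counts)
  dispersion <- rep_len(dispersion, n)
  if (!is.matrix(offset)) offset <- matrix(offset, n, ncol(counts), byrow = TRUE)
  coefs <- matrix(NA_real_, n, ncol(design),
                  dimnames = list(rownames(counts), colnames(design)))
  dev <- numeric(n); conv <- logical(n)
  fitted <- matrix(NA_real_, n, ncol(counts))
  for (g in seq_len(n)) {
    fg <- nb_irls(counts[g, ], design, dispersion[g], offset[g, ])
    coefs[g, ] <- fg$beta; dev[g] <- fg$deviance
    conv[g] <- fg$converged; fitted[g, ] <- fg$mu
  }
  structure(list(coefficients = coefs, deviance = dev, fitted = fitted,
                 converged = conv, design = design, dispersion = dispersion,
                 offset = offset),
            class = "nb_fit")
}

# Cox-Reid adjusted profile log-likelihood of the NB dispersion for one gene
nb_apl <- function(y, design, phi, offset) {
  fit <- nb_irls(y, design, phi, offset)
  mu <- pmax(fit$mu, 1e-10)
  w <- mu / (1 + phi * mu)
  ll <- if (phi > 1e-12)
    sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  else sum(stats::dpois(y, mu, log = TRUE))
  cr <- 0.5 * determinant(crossprod(design * sqrt(w)), logarithm = TRUE)$modulus
  ll - as.numeric(cr)
}

# argmax over a grid with quadratic interpolation around the best point
grid_argmax <- function(grid_log, values) {
  i <- which.max(values)
  if (i == 1L || i == length(values)) return(grid_log[i])
  x <- grid_log[(i - 1):(i + 1)]; v <- values[(i - 1):(i + 1)]
  denom <- (v[1] - 2 * v[2] + v[3])
  if (denom >= 0) return(grid_log[i])
  grid_log[i] - 0.5 * (x[2] - x[1]) * (v[3] - v[1]) / denom
}

#' Estimate genewise NB dispersions with empirical-Bayes shrinkage
#'
#' For every gene, the Cox-Reid adjusted profile log-likelihood (APL) of
#' the dispersion is evaluated on a log-spaced grid (the adjustment term
#' `0.5 log det(X'WX)` removes the downward bias that plain profiling
#' suffers at few residual degrees of freedom). Genes are ordered by
#' average abundance and each gene's APL curve is augmented with the moving
#' average of its neighbours' curves, weighted by `prior_df` relative to
#' the gene's own residual degrees of freedom; the maximizing dispersion of
#' the weighted curve is the shrunk genewise estimate. The maximizer of the
#' moving-average curve alone is the mean-dispersion trend; abundance
#' neighbourhoods also damp the influence of outlier genes on the trend.
#'
#' @param counts count matrix.
#' @param design design matrix.
#' @param offset log effective library sizes (vector or genes x samples
#'   matrix).
#' @param prior_df weight of the trend in notional degrees of freedom
#'   (default 10).
#' @param grid dispersion grid (log10-spaced by default).
#' @return Shrunk dispersions (floored at 1e-8), with the unshrunk
#'   genewise estimates and the trend in attributes `raw` and `trend`.
#' @export
estimate_dispersion <- function(counts, design, offset, prior_df = 10,
                                grid = 10^seq(-6, 0.7, length.out = 19)) {
  counts <- as.matrix(counts)
  n <- nrow(counts); p <- ncol(design); m <- ncol(counts)
  df_resid <- m - p
  if (df_resid < 1) stopf("no residual degrees of freedom in the design")
  if (!is.matrix(offset)) offset <- matrix(offset, n, m, byrow = TRUE)
  lgrid <- log10(grid)
  apl <- matrix(0, n, length(grid))
  for (g in seq_len(n))
    apl[g, ] <- vapply(grid, function(ph)
      nb_apl(counts[g, ], design, ph, offset[g, ]), numeric(1))
  ord <- order(rowMeans(cpm(counts)))
  width <- max(min(50L, n), ceiling(0.1 * n))
  if (width >= n) {
    avg <- matrix(colMeans(apl), n, length(grid), byrow = TRUE)
  } else {
    avg <- apply(apl[ord, , drop = FALSE], 2, function(col)
      stats::filter(col, rep(1 / width, width), sides = 2))
    avg <- as.matrix(avg)
    # pad the moving average at the abundance extremes
    for (j in seq_len(ncol(avg))) {
      ok <- which(!is.na(avg[, j]))
      avg[seq_len(ok[1] - 1), j] <- avg[ok[1], j]
      avg[seq(ok[length(ok)] + 1, length.out = n - ok[length(ok)]), j] <-
        avg[ok[length(ok)], j]
    }
    avg[ord, ] <- avg
  }
  prior_n <- prior_df / df_resid
  raw <- trend <- shrunk <- numeric(n)
  for (g in seq_len(n)) {
    raw[g] <- 10^grid_argmax(lgrid, apl[g, ])
    trend[g] <- 10^grid_argmax(lgrid, avg[g, ])
    shrunk[g] <- 10^grid_argmax(lgrid, apl[g, ] + prior_n * avg[g, ])
  }
  structure(pmax(shrunk, 1e-8), raw = raw, trend = trend)
}

#' Likelihood-ratio test between nested NB fits
#'
#' @param fit_full,fit_reduced `nb_fit` objects on nested designs.
#' @return Data frame with the per-gene LRT statistic, degrees of freedom
#'   and chi-squared p-value.
#' @export
lrt_contrast <- function(fit_full, fit_reduced) {
  df <- ncol(fit_full$design) - ncol(fit_reduced$design)
  if (df < 0) stopf("the reduced design must be nested in the full one")
  stat <- pmax(fit_reduced$deviance - fit_full$deviance, 0)
  p <- if (df == 0) rep(1, length(stat))  # identical designs: nothing to test
       else stats::pchisq(stat, df = df, lower.tail = FALSE)
  ids <- rownames(fit_full$coefficients) %||% as.character(seq_along(stat))
  data.frame(gene_id = ids, lrt_stat = stat, df = df, p = p,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment via [stats::p.adjust()].
#' @param p p-values in \[0, 1\].
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Flag differentially expressed genes
#'
#' A gene is a DEG when `q < fdr` and `|log2FC| >= lfc` (both boundaries as
#' written: strict on the FDR, inclusive on the fold change; the default
#' fold threshold 0.58 log2 units is a 1.5-fold change).
#'
#' @param result a `contrast_result` (or data frame with `log2FC` and `q`).
#' @param fdr FDR cutoff (default 0.01).
#' @param lfc absolute log2 fold-change cutoff (default 0.58).
#' @return The result with a logical `deg` column and a `deg_counts`
#'   attribute giving up/down totals.
#' @export
call_degs <- function(result, fdr = 0.01, lfc = 0.58) {
  stopifnot(all(c("log2FC", "q") %in% names(result)))
  result$deg <- result$q < fdr & abs(result$log2FC) >= lfc
  attr(result, "deg_counts") <- c(up = sum(result$deg & result$log2FC > 0),
                                  down = sum(result$deg & result$log2FC < 0))
  attr(result, "thresholds") <- c(fdr = fdr, lfc = lfc)
  result
}

#' Differential expression for one group contrast
#'
#' Runs the full engine for a comparison of two levels of the combined
#' port x time factor (e.g. P5 vs S at the same process time): genewise
#' dispersion estimation, NB GLM fit of the full design
#' (replicate + group), a reduced fit with the two tested levels merged,
#' likelihood-ratio tests, BH adjustment and DEG calling. The log2 fold
#' change is the tested group coefficient (group A relative to baseline B)
#' converted from the natural to the base-2 log scale.
#'
#' @param nexp a [normalize_experiment()] result.
#' @param group_a,group_b levels of `samples$group` to compare (A vs B).
#' @param fdr,lfc DEG thresholds, see [call_degs()].
#' @param prior_df trend weight for [estimate_dispersion()].
#' @param dispersion optional precomputed dispersions (skips estimation).
#' @return A `contrast_result` data frame (`gene_id`, `log2FC`, `lrt_stat`,
#'   `p`, `q`, `deg`) with attributes `label`, `deg_counts`, `dispersion`.
#' @export
de_contrast <- function(nexp, group_a, group_b, fdr = 0.01, lfc = 0.58,
                        prior_df = 10, dispersion = NULL) {
  stopifnot(inherits(nexp, "normalized_experiment"))
  groups <- unique(nexp$samples$group)
  if (!group_a %in% groups || !group_b %in% groups)
    stopf("contrast groups must be levels of the sample sheet's `group`")
  offset <- log(nexp$effective_lib)
  X_full <- design_matrix(nexp$samples, baseline = group_b)
  samples_red <- nexp$samples
  samples_red$group[samples_red$group == group_a] <- group_b
  X_red <- design_matrix(samples_red, baseline = group_b)
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(nexp$counts, X_full, offset,
                                      prior_df = prior_df)
  fit_full <- fit_nb_glm(nexp$counts, X_full, dispersion, offset)
  fit_red <- fit_nb_glm(nexp$counts, X_red, dispersion, offset)
  res <- lrt_contrast(fit_full, fit_red)
  res$log2FC <- fit_full$coefficients[, paste0("group_", group_a)] / log(2)
  res$q <- bh_adjust(res$p)
  res <- call_degs(res[, c("gene_id", "log2FC", "lrt_stat", "df", "p", "q")],
                   fdr = fdr, lfc = lfc)
  attr(res, "label") <- paste0(group_a, "_vs_", group_b)
  attr(res, "dispersion") <- dispersion
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' @export
print.contrast_result <- function(x, ...) {
  cnt <- attr(x, "deg_counts")
  cat(sprintf("contrast %s: %d genes tested, %d DEGs (%d up / %d down)\n",
              attr(x, "label") %||% "?", nrow(x), sum(x$deg),
              cnt["up"], cnt["down"]))
  invisible(x)
}

#' Replicate concordance screening
#'
#' Spearman rank correlation of each sample against its replicate partners
#' (samples of the same group with a different replicate id), computed on
#' the (filtered) counts. Samples falling below the threshold are listed as
#' outliers; removal is left to the caller, never done silently.
#'
#' @param exp a [count_experiment()].
#' @param threshold minimum acceptable rho (default 0.9).
#' @return Data frame `sample_id`, `group`, `replicate`, `rho`, `outlier`.
#' @export
replicate_concordance <- function(exp, threshold = 0.9) {
  stopifnot(inherits(exp, "count_experiment"))
  s <- exp$samples
  rho <- vapply(seq_len(nrow(s)), function(j) {
    partners <- which(s$group == s$group[j] & s$replicate != s$replicate[j])
    if (!length(partners)) return(NA_real_)
    mean(vapply(partners, function(k)
      stats::cor(exp$counts[, j], exp$counts[, k], method = "spearman"),
      numeric(1)))
  }, numeric(1))
  data.frame(sample_id = s$sample_id, group = s$group,
             replicate = s$replicate, rho = rho,
             outlier = !is.na(rho) & rho < threshold,
             stringsAsFactors = FALSE)
}

#' Write a contrast result as TSV
#'
#' @param result a `contrast_result`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_contrast <- function(result, path) {
  out <- result[, c("gene_id", "log2FC", "p", "q", "deg")]
  names(out)[5] <- "deg_flag"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a contrast TSV written by [write_contrast()]
#' @param path file path.
#' @return A `contrast_result` data frame.
#' @export
read_contrast <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(d)[names(d) == "deg_flag"] <- "deg"
  class(d) <- c("contrast_result", "data.frame")
  d
}
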