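test_that("cpm and tpm follow their closed forms", {
  expect_equal(cpm(18, 9e6), 2)
  expect_equal(cpm(0, 5e6), 0)
  expect_equal(cpm(16, 8e6), 2)
  m <- matrix(rpois(40, 50), 10, 4)
  expect_equal(cpm(2 * m, colSums(2 * m)), cpm(m, colSums(m)))

  tt <- tpm(c(10, 10), c(1000, 2000))
  expect_equal(drop(tt), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  expect_equal(drop(tpm(7, 500)), 1e6)
  expect_equal(tpm(2 * m, rep(1000, 10)), tpm(m, rep(1000, 10)))
  expect_true(all(abs(colSums(tpm(m, 1:10 * 100)) - 1e6) < 1e-6))
})

test_that("the coverage filter applies strict boundaries and biotype rules", {
  # library sizes forced to exactly 1e6 by a filler gene, so cpm == counts
  counts <- rbind(
    ok       = rep(100L, 8),
    low3of8  = c(1L, 1L, 1L, rep(100L, 5)),   # < 2 cpm in 37.5% -> dropped
    low2of8  = c(1L, 1L, rep(100L, 6)),       # < 2 cpm in exactly 25% -> kept
    at_thr   = c(2L, 2L, 2L, rep(100L, 5)),   # exactly 2 cpm is not "< 2"
    ribo     = rep(5000L, 8))
  counts <- rbind(counts, filler = 1e6L - colSums(counts))
  colnames(counts) <- paste0("s", 1:8)
  stopifnot(all(colSums(counts) == 1e6))
  ex <- tiny_experiment(counts,
                        biotype = c("mRNA", "mRNA", "mRNA", "mRNA", "rRNA", "mRNA"))
  fx <- filter_genes(ex)
  expect_setequal(rownames(fx$counts), c("ok", "low2of8", "at_thr", "filler"))
  rep_info <- attr(fx, "filter_report")
  expect_equal(rep_info$n_rrna_trna, 1)
  expect_equal(rep_info$n_low_coverage, 1)
  # order preserved
  expect_equal(rownames(fx$counts), c("ok", "low2of8", "at_thr", "filler"))
})

test_that("TMM factors behave and match the reference implementation", {
  set.seed(5)
  counts <- matrix(rnbinom(500 * 6, mu = rep(exp(runif(500, 2, 8)), 6),
                           size = 10), 500, 6)
  f <- norm_factors_tmm(counts)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  # identical columns: no composition difference
  same <- matrix(rep(counts[, 1], 4), ncol = 4)
  expect_equal(norm_factors_tmm(same), rep(1, 4))
  # pure depth difference, no composition change: factors stay ~1
  depth <- cbind(counts[, 1], 2 * counts[, 1], 3 * counts[, 1])
  expect_equal(norm_factors_tmm(depth), rep(1, 3), tolerance = 0.02)
  # independent oracle: edgeR's TMM with matching parameters
  library(edgeR)
  f_ref <- edgeR::calcNormFactors(edgeR::DGEList(counts))$samples$norm.factors
  expect_equal(f, f_ref, tolerance = 1e-10)
})

test_that("NB GLM fits match closed forms and the reference implementation", {
  # intercept-only on constant counts: intercept = log(c / L)
  y <- matrix(rep(100L, 6), 1)
  X <- matrix(1, 6, 1, dimnames = list(NULL, "int"))
  off <- rep(log(1e6), 6)
  fit <- fit_nb_glm(y, X, 0.05, off)
  expect_equal(unname(drop(fit$coefficients)), log(100 / 1e6),
               tolerance = 1e-8)
  expect_true(all(fit$fitted >= 0))
  # two-group consistency: true ratio 2 -> coefficient ~ log 2
  set.seed(6)
  n <- 50
  y2 <- matrix(rnbinom(100 * 2 * n, mu = rep(c(100, 200), each = n),
                       size = 20), 100, 2 * n, byrow = TRUE)
  X2 <- cbind(int = 1, grp = rep(c(0, 1), each = n))
  fit2 <- fit_nb_glm(y2, X2, 0.05, rep(0, 2 * n))
  expect_equal(median(fit2$coefficients[, "grp"]), log(2), tolerance = 0.05)
  expect_error(fit_nb_glm(y2, cbind(X2, X2[, 2]), 0.05, rep(0, 2 * n)),
               "full rank")
  # reference: edgeR glmFit / glmLRT at the same fixed dispersion
  library(edgeR)
  counts <- y2[1:100, 1:12]
  X3 <- cbind(int = 1, grp = rep(c(0, 1), each = 6))
  off3 <- log(colSums(counts))
  mine <- fit_nb_glm(counts, X3, 0.05, off3)
  ref <- edgeR::glmFit(counts, X3, dispersion = 0.05, offset = off3,
                       prior.count = 0)
  expect_equal(mine$coefficients, ref$coefficients, tolerance = 1e-6,
               ignore_attr = TRUE)
  mine0 <- fit_nb_glm(counts, X3[, 1, drop = FALSE], 0.05, off3)
  lrt <- lrt_contrast(mine, mine0)
  ref_lrt <- edgeR::glmLRT(ref, coef = 2)
  expect_equal(lrt$p, ref_lrt$table$PValue, tolerance = 1e-6)
})

test_that("an LRT against an identical design is degenerate", {
  y <- matrix(rpois(40, 50), 10, 4)
  X <- matrix(1, 4, 1)
  fit <- fit_nb_glm(y, X, 0.05, rep(0, 4))
  out <- lrt_contrast(fit, fit)
  expect_true(all(out$p == 1))
  expect_true(all(out$lrt_stat == 0))
})

test_that("dispersion estimation recovers the truth and shrinks outliers", {
  set.seed(7)
  n_s <- 20
  counts <- matrix(rnbinom(150 * n_s, mu = 200, size = 10), 150, n_s)
  X <- cbind(int = 1, grp = rep(c(0, 1), each = n_s / 2))
  phi <- estimate_dispersion(counts, X, rep(0, n_s))
  expect_gte(median(phi), 0.05)
  expect_lte(median(phi), 0.2)
  # near-Poisson data: small dispersions
  cp <- matrix(rpois(150 * n_s, 200), 150, n_s)
  php <- estimate_dispersion(cp, X, rep(0, n_s))
  expect_lte(median(php), 0.01)
  # a single outlier sample inflates the unshrunk estimate more than the shrunk one
  contam <- counts
  contam[1, 1] <- 20 * counts[1, 1]
  ph_c <- estimate_dispersion(contam, X, rep(0, n_s))
  raw_infl <- attr(ph_c, "raw")[1] / attr(phi, "raw")[1]
  shrunk_infl <- ph_c[1] / phi[1]
  expect_gt(raw_infl, shrunk_infl)
})

test_that("BH adjustment and DEG calling follow the step-up rules", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  res <- data.frame(gene_id = letters[1:4],
                    log2FC = c(1, 0.58, 0.5, -2),
                    q = c(0.005, 0.009, 0.001, 0.01))
  out <- call_degs(res)
  # q = 0.01 exactly is not significant (strict <); |lfc| = 0.58 exactly is in
  expect_equal(out$deg, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(attr(out, "deg_counts"), c(up = 2, down = 0))
  # empty input
  expect_equal(nrow(call_degs(res[0, ])), 0)
  # tightening thresholds never grows the DEG set
  loose <- call_degs(res, fdr = 0.05, lfc = 0.3)
  expect_true(all(out$deg <= loose$deg))
})

test_that("replicate concordance screening flags contaminated samples", {
  counts <- matrix(rep(1:50, 4), 50, 4,
                   dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:4)))
  ex <- tiny_experiment(counts)
  rc <- replicate_concordance(ex)
  expect_equal(rc$rho, rep(1, 4))
  expect_false(any(rc$outlier))
  # reversed ranks between replicates
  counts2 <- counts
  counts2[, 2] <- rev(counts2[, 2])
  rc2 <- replicate_concordance(tiny_experiment(counts2))
  expect_equal(rc2$rho[1], -1)
  expect_true(rc2$outlier[1])
  # extreme contamination of 5% of genes drags rho down the most
  set.seed(8)
  big <- matrix(rnbinom(400 * 4, mu = 100, size = 5), 400, 4,
                dimnames = list(sprintf("g%03d", 1:400), paste0("s", 1:4)))
  big[sample(400, 20), 3] <- 5e4
  rc3 <- replicate_concordance(tiny_experiment(big))
  expect_equal(which.min(rc3$rho) %in% c(3, 4), TRUE)
})

test_that("contrast results round-trip through TSV", {
  nexp <- small_null_nexp()
  res <- de_contrast(nexp, "P5_28h", "S_28h")
  expect_true(all(res$q >= res$p - 1e-12))
  expect_true(all(res$q >= 0 & res$q <= 1))
  path <- tempfile(fileext = ".tsv")
  write_contrast(res, path)
  back <- read_contrast(path)
  expect_equal(back$log2FC, res$log2FC, tolerance = 1e-9)
  expect_equal(back$deg, res$deg)
})
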