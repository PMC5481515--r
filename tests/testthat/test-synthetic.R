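test_that("the genome generator is deterministic and structurally sound", {
  g1 <- make_genome(500, seed = 1)
  g2 <- make_genome(500, seed = 1)
  expect_identical(g1, g2)
  expect_false(identical(g1, make_genome(500, seed = 2)))
  expect_error(make_genome(20), "at least 50")
  # ~5% structural-RNA decoys, binomial 3-sd band
  n_decoy <- sum(g1$biotype != "mRNA")
  expect_lt(abs(n_decoy - 25), 3 * sqrt(500 * 0.05 * 0.95) + 1)
  # coding lengths consistent with transcript lengths
  m <- g1$biotype == "mRNA"
  expect_true(all(g1$length_nt[m] >= 3 * g1$length_aa[m]))
  expect_equal(sum(g1$baseline_tpm), 1e6)
})

test_that("truth programs perturb exactly the requested blocks", {
  g <- make_genome(500, seed = 3)
  tr0 <- make_truth(g, seed = 4)
  expect_true(all(tr0$short_lfc == 0) && all(tr0$long_lfc == 0))
  tr <- make_truth(g, short_effects = list(sigma_N = c(1, 1.0)), seed = 4)
  in_block <- !is.na(g$sigma) & grepl("sigma_N", ifelse(is.na(g$sigma), "", g$sigma))
  expect_true(all(tr$short_lfc[!in_block] == 0))
  expect_true(all(tr$short_lfc[in_block] > 0))
  expect_error(make_truth(g, short_effects = list(bogus_set = c(1, 1))),
               "unknown category")
  # block magnitudes concentrate around the requested mean
  ids <- g$gene_id[g$biotype == "mRNA"][1:200]
  trb <- make_truth(g, short_effects = list(
    blk = list(gene_ids = ids, direction = 1, lfc = 1.0)), seed = 5)
  expect_equal(mean(abs(trb$short_lfc[match(ids, g$gene_id)])), 1.0,
               tolerance = 0.1)
})

test_that("simulated counts follow the NB mean-variance law", {
  g <- make_genome(100, seed = 11)
  d <- make_design(str_times = 0, pfr_times = NULL, replicates = 200)
  ex <- simulate_counts(g, d, phi = 0.1, phi_sdlog = 0,
                        lib_size_range = c(1e6, 1e6 + 1), seed = 12)
  mu_hat <- rowMeans(ex$counts)
  v_hat <- apply(ex$counts, 1, var)
  big <- mu_hat > 50
  phi_hat <- (v_hat[big] - mu_hat[big]) / mu_hat[big]^2
  expect_equal(median(phi_hat), 0.1, tolerance = 0.15)
  # Poisson limit
  exp0 <- simulate_counts(g, d, phi = 1e-9, phi_sdlog = 0,
                          lib_size_range = c(1e6, 1e6 + 1), seed = 13)
  mu0 <- rowMeans(exp0$counts); v0 <- apply(exp0$counts, 1, var)
  expect_equal(median(v0[mu0 > 50] / mu0[mu0 > 50]), 1, tolerance = 0.1)
  # determinism
  expect_identical(ex$counts,
                   simulate_counts(g, d, phi = 0.1, phi_sdlog = 0,
                                   lib_size_range = c(1e6, 1e6 + 1),
                                   seed = 12)$counts)
})

test_that("library sizes land on their configured targets", {
  g <- make_genome(1000, seed = 21)
  d <- make_design(str_times = c(0, 28), pfr_times = 28, ports = "P5")
  ex <- simulate_counts(g, d, phi = 0.05, seed = 22)
  expect_true(all(abs(colSums(ex$counts) / ex$samples$lib_size_target - 1) < 0.1))
  expect_true(all(ex$samples$lib_size_target >= 0.9e6 &
                  ex$samples$lib_size_target <= 1.1e6))
})

test_that("the PFR onset rule gates the short-term program by port", {
  g <- make_genome(400, seed = 31)
  ids <- g$gene_id[g$biotype == "mRNA" & g$baseline_tpm > 200][1:30]
  tr <- make_truth(g, short_effects = list(
    blk = list(gene_ids = ids, direction = 1, lfc = 2)), lfc_sd_frac = 0,
    seed = 32)
  d <- make_design(str_times = 28, pfr_times = 28,
                   ports = c("P1", "P3", "P5"), replicates = 3)
  ex <- simulate_counts(g, d, tr, phi = 0.02, seed = 33)
  cc <- cpm(ex$counts)
  blk <- rownames(cc) %in% ids
  grp_mean <- function(port) rowMeans(cc[blk, ex$samples$port == port])
  r_p1 <- mean(log2(grp_mean("P1") / grp_mean("S")))
  r_p5 <- mean(log2(grp_mean("P5") / grp_mean("S")))
  expect_lt(abs(r_p1), 0.3)      # before the 70 s onset: unperturbed
  expect_equal(r_p5, 2, tolerance = 0.15)  # after onset: programmed shift
})

test_that("experiments round-trip through plain-text files", {
  g <- make_genome(120, seed = 41)
  d <- make_design(str_times = c(0, 28), pfr_times = 28, ports = "P5")
  ex <- simulate_counts(g, d, phi = 0.05, seed = 42)
  dir <- tempfile()
  paths <- write_experiment(ex, dir)
  ex2 <- read_experiment(dir)
  expect_identical(unname(ex2$counts), unname(ex$counts))
  expect_equal(nrow(ex2$genes), nrow(g))
  sets <- gene_sets_from_annotation(g)
  expect_equal(length(readLines(file.path(dir, "sets.gmt"))), length(sets))
  g3 <- read_gmt(file.path(dir, "sets.gmt"))
  expect_equal(sort(names(g3)), sort(names(sets)))
  expect_setequal(g3[["COG_E"]], sets[["COG_E"]])
})
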