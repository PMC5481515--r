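make_universe <- function(n) sprintf("u%04d", seq_len(n))

test_that("set-size limits are inclusive at 10 and 500", {
  universe <- make_universe(600)
  sets <- list(s9 = universe[1:9], s10 = universe[1:10],
               s500 = universe[1:500], s501 = universe[1:501])
  col <- size_filter(gene_set_collection(sets, universe))
  expect_setequal(names(col$sets), c("s10", "s500"))
  empty <- size_filter(gene_set_collection(list(), universe))
  expect_equal(length(empty$sets), 0)
})

test_that("sets are intersected with the universe before sizing", {
  universe <- make_universe(100)
  sets <- list(a = c(universe[1:12], "not_in_universe"))
  col <- gene_set_collection(sets, universe)
  expect_equal(unname(col$sizes["a"]), 12)
  expect_true(all(col$sets$a %in% universe))
})

test_that("hypergeometric over-representation matches combinatorics", {
  universe <- make_universe(20)
  col <- gene_set_collection(list(s = universe[1:5]), universe)
  cluster <- c(universe[1:4], universe[10])  # n = 5, k = 4
  res <- hypergeom_ora(cluster, col)
  expect_equal(res$p, 76 / 15504, tolerance = 1e-12)
  # empty overlap: upper tail at zero is certain
  res0 <- hypergeom_ora(universe[10:14], col)
  expect_equal(res0$k, 0)
  expect_gte(res0$p, 0.5)
  expect_equal(hypergeom_ora(universe[6:20], col)$k, 0)
  # exhaustive draw: every set member is captured, p = 1
  res_all <- hypergeom_ora(universe, col)
  expect_equal(res_all$p, 1)
  expect_error(hypergeom_ora("stranger", col), "subset")
})

test_that("enlarging the overlap never increases the upper-tail p", {
  p <- sapply(0:5, function(k) phyper(k - 1, 5, 15, 5, lower.tail = FALSE))
  expect_true(all(diff(p) <= 0))
})

test_that("the set t-statistic equals the closed-form Welch t", {
  universe <- make_universe(15)
  members <- universe[1:5]
  lfc <- c(1.2, 0.8, 1.5, 1.1, 0.9,
           0.1, -0.2, 0.3, 0.05, -0.1, 0.2, -0.3, 0.15, 0.0, -0.05)
  names(lfc) <- universe
  col0 <- gene_set_collection(list(s = members), universe)
  res <- gage_t(col0, lfc)
  # hand computation
  x <- lfc[1:5]; y <- lfc[6:15]
  vx <- var(x) / 5; vy <- var(y) / 10
  t_hand <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df_hand <- (vx + vy)^2 / (vx^2 / 4 + vy^2 / 9)
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$df, df_hand, tolerance = 1e-10)
  expect_equal(res$p_up, pt(t_hand, df_hand, lower.tail = FALSE),
               tolerance = 1e-12)
  # cross-check against t.test
  tt <- t.test(x, y)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$df, unname(tt$parameter), tolerance = 1e-8)
  # direction: members shifted up
  expect_equal(res$direction, "up")
  expect_lt(res$p_up, res$p_down)
  # degenerate: members exhaust the universe
  col_all <- gene_set_collection(list(s = universe), universe)
  expect_error(gage_t(col_all, lfc), "non-member")
})

test_that("both set tests are valid under the null", {
  set.seed(9)
  universe <- make_universe(2000)
  sets <- lapply(1:500, function(i) sample(universe, sample(20:200, 1)))
  names(sets) <- paste0("s", 1:500)
  col <- size_filter(gene_set_collection(sets, universe))
  lfc <- rnorm(2000)
  names(lfc) <- universe
  gt <- gage_t(col, lfc)
  expect_gt(ks.test(gt$p_up, "punif")$p.value, 0.01)
  # the discrete hypergeometric upper tail is conservative, never liberal
  ora <- hypergeom_ora(sample(universe, 200), col)
  for (alpha in c(0.01, 0.05, 0.1, 0.25))
    expect_lte(mean(ora$p <= alpha), alpha + 2.58 * sqrt(alpha * (1 - alpha) / 500))
})

test_that("the spider table stacks contrasts with exact significance flags", {
  universe <- make_universe(200)
  set.seed(10)
  sets <- list(a = universe[1:40], b = universe[41:90], tiny = universe[1:3])
  col <- size_filter(gene_set_collection(sets, universe))
  expect_false("tiny" %in% names(col$sets))
  lfc1 <- rnorm(200); lfc2 <- rnorm(200) + c(rep(2, 40), rep(0, 160))
  names(lfc1) <- names(lfc2) <- universe
  res <- list(`25min` = gage_t(col, lfc1), `28h` = gage_t(col, lfc2))
  tab <- spider_table(res)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$significant, tab$q < 0.05)
  one <- spider_table(list(`25min` = gage_t(col, lfc1)[1, ]))
  expect_equal(nrow(one), 1)
  expect_error(spider_table(list()), "at least one")
})

test_that("GMT files round-trip", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g4", "g5"))
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_equal(length(readLines(path)), 2)
  back <- read_gmt(path)
  expect_equal(back$alpha, sets$alpha)
  expect_equal(back$beta, sets$beta)
})
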