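#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated name, description, members.
#' Parsing is delegated to [fgsea::gmtPathways()].
#'
#' @param path GMT file.
#' @return Named list of gene-id vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Write gene sets to a GMT file
#'
#' @param sets named list of gene-id vectors.
#' @param path output file.
#' @param descriptions optional per-set description column (defaults to the
#'   set name).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Gene-set collection restricted to an analysis universe
#'
#' Intersects every set with the universe (the post-filter analysis genes,
#' not the whole genome) and records annotation coverage.
#'
#' @param sets named list of gene-id vectors.
#' @param universe analysis gene ids.
#' @return A `gene_set_collection`: `sets` (intersected), `universe`,
#'   `sizes`, and `coverage` (fraction of universe genes in >= 1 set).
#' @export
gene_set_collection <- function(sets, universe) {
  if (!length(universe)) stopf("the gene universe must be non-empty")
  inter <- lapply(sets, intersect, universe)
  structure(list(sets = inter, universe = universe,
                 sizes = vapply(inter, length, integer(1)),
                 coverage = mean(universe %in% unique(unlist(inter)))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets over %d universe genes (%.0f%% annotated)\n",
              length(x$sets), length(x$universe), 100 * x$coverage))
  invisible(x)
}

#' Drop sets outside the admissible size range
#'
#' Keeps sets whose intersection with the universe has between `min_size`
#' and `max_size` members inclusive (sets with fewer than 10 or more than
#' 500 genes are omitted by default).
#'
#' @param collection a [gene_set_collection()].
#' @param min_size,max_size inclusive size bounds.
#' @return The filtered collection.
#' @export
size_filter <- function(collection, min_size = 10, max_size = 500) {
  stopifnot(inherits(collection, "gene_set_collection"))
  keep <- collection$sizes >= min_size & collection$sizes <= max_size
  collection$sets <- collection$sets[keep]
  collection$sizes <- collection$sizes[keep]
  collection
}

# closed-form Welch two-sample t (mean of x minus mean of y)
welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x) / nx; vy <- stats::var(y) / ny
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  c(t = t, df = df)
}

#' Two-sample t gene-set statistics on a fold-change vector
#'
#' For every admissible set, compares the log2 fold changes of member genes
#' against all non-member genes of the universe with a Welch two-sample t
#' statistic (Welch-Satterthwaite degrees of freedom), yielding one-sided
#' upregulation and downregulation p-values; each direction is BH-adjusted
#' across sets.
#'
#' @param collection a [gene_set_collection()] (size-filter it first).
#' @param lfc named per-gene log2 fold-change vector covering the universe.
#' @param fdr significance cutoff applied to the better direction.
#' @return A `set_test_result` data frame: `set`, `size`, `t`, `df`,
#'   `direction`, `p_up`, `p_down`, `q_up`, `q_down`, `significant`.
#' @export
gage_t <- function(collection, lfc, fdr = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.null(names(lfc))) stopf("`lfc` must be named by gene id")
  if (any(!is.finite(lfc))) stopf("fold changes must be finite")
  missing <- setdiff(collection$universe, names(lfc))
  if (length(missing)) stopf("%d universe genes lack fold changes", length(missing))
  rows <- lapply(names(collection$sets), function(nm) {
    members <- collection$sets[[nm]]
    others <- setdiff(collection$universe, members)
    if (!length(others)) stopf("set `%s` leaves no non-member genes", nm)
    wt <- welch_t(lfc[members], lfc[others])
    data.frame(set = nm, size = length(members), t = wt["t"], df = wt["df"],
               p_up = stats::pt(wt["t"], wt["df"], lower.tail = FALSE),
               p_down = stats::pt(wt["t"], wt["df"], lower.tail = TRUE),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(res)
  res$q_up <- bh_adjust(res$p_up)
  res$q_down <- bh_adjust(res$p_down)
  res$direction <- ifelse(res$t >= 0, "up", "down")
  res$significant <- pmin(res$q_up, res$q_down) < fdr
  class(res) <- c("set_test_result", "data.frame")
  res
}

#' Hypergeometric over-representation of a gene cluster
#'
#' Upper-tail probability `P(X >= k)` of drawing `k` set members in a
#' cluster of size `n` from a universe of `N` genes containing `K` set
#' members ([stats::phyper()]), BH-adjusted across sets; significant at
#' `q < 0.05` by default.
#'
#' @param cluster gene ids (e.g. a DEG set), must lie in the universe.
#' @param collection a [gene_set_collection()].
#' @param fdr significance cutoff.
#' @return A `set_test_result` data frame: `set`, `K`, `n`, `k`, `p`, `q`,
#'   `significant`.
#' @export
hypergeom_ora <- function(cluster, collection, fdr = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!all(cluster %in% collection$universe))
    stopf("the cluster must be a subset of the universe")
  N <- length(collection$universe); n <- length(cluster)
  rows <- lapply(names(collection$sets), function(nm) {
    K <- length(collection$sets[[nm]])
    k <- length(intersect(cluster, collection$sets[[nm]]))
    data.frame(set = nm, K = K, n = n, k = k,
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(res)
  res$q <- bh_adjust(res$p)
  res$significant <- res$q < fdr
  class(res) <- c("set_test_result", "data.frame")
  res
}

#' Long-format set-statistic table across time points
#'
#' Stacks per-contrast [gage_t()] results into the long format behind
#' spider-graph summaries: one row per (category, time point).
#'
#' @param results named list of `set_test_result` objects, one per time
#'   point / contrast.
#' @param fdr significance cutoff for the flag column.
#' @return Data frame `category`, `time_point`, `t`, `q`, `significant`.
#' @export
spider_table <- function(results, fdr = 0.05) {
  if (!length(results)) stopf("at least one contrast is required")
  if (is.null(names(results))) stopf("`results` must be named by time point")
  rows <- lapply(names(results), function(tp) {
    r <- results[[tp]]
    data.frame(category = r$set, time_point = tp, t = r$t,
               q = pmin(r$q_up, r$q_down),
               significant = pmin(r$q_up, r$q_down) < fdr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
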