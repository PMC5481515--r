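#' Response-strength difference between two nutrient conditions
#'
#' The delta statistic `|log2FC_N| - |log2FC_C|`: positive when the
#' ammonia-side response is stronger, negative when the glucose-side one
#' is, zero when both are equally strong regardless of direction.
#'
#' @param lfc_n,lfc_c finite log2 fold changes (vectors recycle).
#' @return `abs(lfc_n) - abs(lfc_c)`.
#' @examples
#' delta_stat(1, -1)   # 0: equal strength, direction ignored
#' delta_stat(2, 0.5)  # 1.5
#' @export
delta_stat <- function(lfc_n, lfc_c) {
  if (any(!is.finite(lfc_n)) || any(!is.finite(lfc_c)))
    stopf("fold changes must be finite")
  abs(lfc_n) - abs(lfc_c)
}

#' Pair two per-contrast DE results gene by gene
#'
#' Inner join on gene id (genes filtered out of either study's universe are
#' excluded rather than imputed), carrying fold changes, q-values and DEG
#' flags from both conditions plus the [delta_stat()].
#'
#' @param res_n,res_c `contrast_result` objects (condition N, e.g. ammonia,
#'   and condition C, e.g. glucose).
#' @return A `paired_contrast` data frame: `gene_id`, `lfc_n`, `lfc_c`,
#'   `q_n`, `q_c`, `deg_n`, `deg_c`, `delta`.
#' @export
pair_contrasts <- function(res_n, res_c) {
  need <- c("gene_id", "log2FC", "q", "deg")
  stopifnot(all(need %in% names(res_n)), all(need %in% names(res_c)))
  m <- merge(res_n[, need], res_c[, need], by = "gene_id",
             suffixes = c("_n", "_c"))
  out <- data.frame(gene_id = m$gene_id,
                    lfc_n = m$log2FC_n, lfc_c = m$log2FC_c,
                    q_n = m$q_n, q_c = m$q_c,
                    deg_n = m$deg_n, deg_c = m$deg_c,
                    stringsAsFactors = FALSE)
  out$delta <- delta_stat(out$lfc_n, out$lfc_c)
  class(out) <- c("paired_contrast", "data.frame")
  out
}

#' Classify genes by cross-nutrient response pattern
#'
#' Every gene receives exactly one class:
#' \describe{
#'   \item{`shared_same_direction`}{DEG under both nutrients, same sign.}
#'   \item{`opposite`}{DEG under both, opposite signs, comparable strength
#'     (`|delta| <= band`).}
#'   \item{`N_specific` / `C_specific`}{DEG under exactly one nutrient.}
#'   \item{`neither`}{everything else.}
#' }
#' The comparability band defaults to 0.58 log2 units (the DEG fold-change
#' threshold reused as the strength-comparability criterion).
#'
#' @param paired a [pair_contrasts()] result.
#' @param delta_band comparability band on `|delta|` for opposite-direction
#'   genes.
#' @return The input with a `class` factor column added.
#' @export
classify_genes <- function(paired, delta_band = 0.58) {
  stopifnot(inherits(paired, "paired_contrast"))
  check_nonneg(delta_band, "delta_band")
  cls <- rep("neither", nrow(paired))
  both <- paired$deg_n & paired$deg_c
  same <- sign(paired$lfc_n) == sign(paired$lfc_c)
  cls[both & same] <- "shared_same_direction"
  cls[both & !same & abs(paired$delta) <= delta_band] <- "opposite"
  cls[paired$deg_n & !paired$deg_c] <- "N_specific"
  cls[!paired$deg_n & paired$deg_c] <- "C_specific"
  paired$class <- factor(cls, levels = c("shared_same_direction", "opposite",
                                         "N_specific", "C_specific", "neither"))
  paired
}

#' Venn-style class counts with up/down splits
#'
#' @param paired a classified [classify_genes()] result.
#' @param label optional contrast label stored on the output.
#' @return A `venn_counts` list: `counts` per class, `up_down` (per class,
#'   split by each condition's sign), `genes` (per-class id lists),
#'   `n_deg_union`.
#' @export
venn_counts <- function(paired, label = NULL) {
  stopifnot(inherits(paired, "paired_contrast"))
  if (is.null(paired$class)) paired <- classify_genes(paired)
  counts <- table(paired$class)
  split_ud <- lapply(split(paired, paired$class), function(d)
    c(up_n = sum(d$deg_n & d$lfc_n > 0), down_n = sum(d$deg_n & d$lfc_n < 0),
      up_c = sum(d$deg_c & d$lfc_c > 0), down_c = sum(d$deg_c & d$lfc_c < 0)))
  structure(list(counts = counts,
                 up_down = do.call(rbind, split_ud),
                 genes = split(paired$gene_id, paired$class),
                 n_deg_union = sum(paired$deg_n | paired$deg_c),
                 label = label),
            class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  if (!is.null(x$label)) cat(sprintf("contrast: %s\n", x$label))
  print(x$counts)
  cat(sprintf("DEG union: %d genes\n", x$n_deg_union))
  invisible(x)
}

#' Binned distribution of the delta statistic
#'
#' Fixed-width, half-open `[lo, hi)` bins of the per-gene response-strength
#' difference.
#'
#' @param paired a [pair_contrasts()] result (non-empty).
#' @param width bin width in log2 units (default 0.25).
#' @param path optional TSV output path.
#' @return Data frame `bin_lo`, `bin_hi`, `count`.
#' @export
delta_histogram <- function(paired, width = 0.25, path = NULL) {
  stopifnot(inherits(paired, "paired_contrast"))
  if (!nrow(paired)) stopf("paired data must be non-empty")
  check_positive(width, "width")
  lo <- floor(min(paired$delta) / width) * width
  hi <- (floor(max(paired$delta) / width) + 1) * width  # top edge stays open
  breaks <- seq(lo, hi, by = width)
  idx <- findInterval(paired$delta, breaks, rightmost.closed = FALSE)
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                    count = tabulate(idx, nbins = length(breaks) - 1))
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
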