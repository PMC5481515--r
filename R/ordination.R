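#' Select the most variable genes
#'
#' Ranks genes by the standard deviation of their (TPM) values across
#' samples; ties are broken by lexicographic gene id so the selection is
#' deterministic.
#'
#' @param tpm_mat matrix genes x samples with gene-id rownames.
#' @param k number of genes to keep (default 600).
#' @return Character vector of the selected gene ids, highest sd first.
#' @export
select_top_variable <- function(tpm_mat, k = 600) {
  if (k > nrow(tpm_mat)) stopf("`k` exceeds the number of genes")
  sds <- apply(tpm_mat, 1, stats::sd)
  ord <- order(-sds, rownames(tpm_mat))
  rownames(tpm_mat)[ord][seq_len(k)]
}

#' Classical (metric) multidimensional scaling
#'
#' Torgerson scaling of the Euclidean distance matrix (double-centered
#' squared distances, eigendecomposition via [stats::cmdscale()]),
#' returning the first two coordinates and the goodness of fit as the
#' squared Pearson correlation between original and embedded pairwise
#' distances.
#'
#' @param x samples x features matrix (>= 3 samples).
#' @return An `mds_result`: `points` (samples x 2, centred at the origin),
#'   `R2`, `eig`, `dist_original`.
#' @export
classical_mds <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stopf("MDS needs at least 3 samples")
  d <- stats::dist(x)
  sc <- stats::cmdscale(d, k = 2, eig = TRUE)
  d_emb <- stats::dist(sc$points)
  structure(list(points = sc$points,
                 R2 = stats::cor(as.vector(d), as.vector(d_emb))^2,
                 eig = sc$eig, dist_original = d),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("classical MDS: %d samples, R2 = %.3f\n", nrow(x$points), x$R2))
  invisible(x)
}

#' @export
plot.mds_result <- function(x, labels = rownames(x$points), ...) {
  graphics::plot(x$points, xlab = "MDS 1", ylab = "MDS 2",
                 main = sprintf("metric MDS (R2 = %.2f)", x$R2), ...)
  if (!is.null(labels))
    graphics::text(x$points, labels = labels, pos = 3, cex = 0.7)
  invisible(x)
}

#' Ordination of an expression experiment
#'
#' The study convention: take the TPM matrix, keep the `top` most variable
#' genes, log2(x + 1)-transform (set `log = FALSE` for raw TPM) and embed
#' the samples by classical MDS on Euclidean distances.
#'
#' @param tpm_mat TPM matrix (genes x samples).
#' @param top number of top-variance genes (default 600, capped at the
#'   gene count).
#' @param log log2(x+1)-transform before computing distances.
#' @return An `mds_result`.
#' @export
mds_expression <- function(tpm_mat, top = 600, log = TRUE) {
  top <- min(top, nrow(tpm_mat))
  sel <- select_top_variable(tpm_mat, top)
  m <- t(tpm_mat[sel, , drop = FALSE])
  if (log) m <- log2(m + 1)
  classical_mds(m)
}

#' Robust 95% confidence ellipse of a 2-D point cloud
#'
#' Location and scatter are estimated under a multivariate t assumption
#' with fixed degrees of freedom (EM iteration, [MASS::cov.trob()]); the
#' scatter matrix is converted to the t model's covariance by the factor
#' `df / (df - 2)` and the ellipse radius is taken from the F(2, n-2)
#' quantile at the confidence level.
#'
#' @param points n x 2 matrix (n >= 3).
#' @param level confidence level (default 0.95).
#' @param df degrees of freedom of the assumed multivariate t (default 7;
#'   must exceed 2 so a covariance exists).
#' @return A `confidence_ellipse`: `center`, `shape` (2 x 2 covariance),
#'   `radius`, `level`, `n`.
#' @export
confidence_ellipse <- function(points, level = 0.95, df = 7) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stopf("`points` must be a 2-column matrix")
  n <- nrow(points)
  if (n < 3) stopf("a confidence ellipse needs at least 3 points")
  if (df <= 2) stopf("`df` must exceed 2")
  if (level <= 0 || level >= 1) stopf("`level` must lie in (0, 1)")
  fit <- tryCatch(MASS::cov.trob(points, nu = df),
                  error = function(e) stopf(
                    "scatter estimation failed (%s); are the points collinear?",
                    conditionMessage(e)))
  shape <- fit$cov * df / (df - 2)
  ev <- eigen(shape, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-10 || min(ev) <= 0)
    stopf("degenerate scatter: the points are (nearly) collinear; a 2-D ellipse is undefined")
  structure(list(center = fit$center, shape = shape,
                 radius = sqrt(2 * stats::qf(level, 2, n - 2)),
                 level = level, n = n),
            class = "confidence_ellipse")
}

#' Boundary polygon of a confidence ellipse
#'
#' @param ellipse a [confidence_ellipse()].
#' @param n_points number of boundary vertices.
#' @return n x 2 matrix of boundary coordinates.
#' @export
ellipse_boundary <- function(ellipse, n_points = 200) {
  stopifnot(inherits(ellipse, "confidence_ellipse"))
  ang <- seq(0, 2 * pi, length.out = n_points)
  circ <- cbind(cos(ang), sin(ang)) * ellipse$radius
  L <- chol(ellipse$shape)
  sweep(circ %*% L, 2, ellipse$center, "+")
}

#' Does a point lie inside a confidence ellipse?
#'
#' @param ellipse a [confidence_ellipse()].
#' @param points n x 2 matrix.
#' @return Logical vector.
#' @export
ellipse_contains <- function(ellipse, points) {
  stopifnot(inherits(ellipse, "confidence_ellipse"))
  points <- matrix(points, ncol = 2)
  stats::mahalanobis(points, ellipse$center, ellipse$shape) <=
    ellipse$radius^2
}

#' Geometric overlap test between two confidence ellipses
#'
#' Two ellipses overlap when either center lies inside the other or any
#' boundary point of one falls inside the other (dense boundary sampling).
#' Used to report whether steady-state clusters are separated.
#'
#' @param e1,e2 [confidence_ellipse()] objects.
#' @param n_points boundary sampling density.
#' @return `TRUE` if the ellipses intersect or one contains the other.
#' @export
ellipses_overlap <- function(e1, e2, n_points = 720) {
  any(ellipse_contains(e2, matrix(e1$center, ncol = 2))) ||
    any(ellipse_contains(e1, matrix(e2$center, ncol = 2))) ||
    any(ellipse_contains(e2, ellipse_boundary(e1, n_points))) ||
    any(ellipse_contains(e1, ellipse_boundary(e2, n_points)))
}

#' @export
print.confidence_ellipse <- function(x, ...) {
  cat(sprintf("%.0f%% confidence ellipse (n = %d): center (%.3g, %.3g)\n",
              100 * x$level, x$n, x$center[1], x$center[2]))
  invisible(x)
}
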