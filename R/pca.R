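#' Principal component analysis for morphometric matrices
#'
#' Column-mean-centred covariance PCA via singular value decomposition,
#' keeping min(n - 1, p) score columns (the maximum number of non-trivially
#' defined components for n observations on p variables).
#'
#' @param data numeric matrix, n observations x p variables (n >= 2). A
#'   \code{form_matrix} or \code{measurement_table} may be passed directly.
#' @return object of class \code{gm_pca}: list with \code{scores} (n x m),
#'   \code{loadings} (p x m, orthonormal columns), \code{eigenvalues}
#'   (descending), \code{explained} (proportions summing to 1 over the
#'   non-zero components), \code{center} (column means).
#' @export
gm_pca <- function(data) {
  if (inherits(data, "form_matrix")) data <- data$values
  if (inherits(data, "measurement_table")) data <- data$values
  data <- as.matrix(data)
  n <- nrow(data); p <- ncol(data)
  if (n < 2L) stop("PCA needs at least 2 observations")
  if (!all(is.finite(data))) stop("PCA input must be finite")
  center <- colMeans(data)
  xc <- sweep(data, 2, center)
  m <- min(n - 1L, p)
  sv <- svd(xc)
  eig_all <- sv$d^2 / (n - 1)
  eigenvalues <- eig_all[seq_len(m)]
  loadings <- sv$v[, seq_len(m), drop = FALSE]
  scores <- xc %*% loadings
  structure(list(scores = scores, loadings = loadings,
                 eigenvalues = eigenvalues,
                 explained = eigenvalues / sum(eig_all),
                 center = center),
            class = "gm_pca")
}

#' @export
print.gm_pca <- function(x, ...) {
  cat("PCA: ", nrow(x$scores), " observations, ", ncol(x$scores),
      " components; first two explain ",
      round(100 * sum(x$explained[seq_len(min(2, length(x$explained)))]), 1),
      "% of variance\n", sep = "")
  invisible(x)
}

#' Count PC scores under the shape- and form-space conventions
#'
#' Shape-space data from GPA are rank-deficient: translation (d), rotation
#' (d(d-1)/2) and scale (1) are removed, so non-degenerate data have exactly
#' kd - d - d(d-1)/2 - 1 informative components (10 for the 7-landmark 2D
#' model, 44 for the 17-landmark 3D model). Mode "shape" therefore counts
#' eigenvalues above \code{tol} x the largest. Form-space matrices retain all
#' kd coordinate columns, and the convention is to report every score column,
#' min(n - 1, kd) (14 for 7 x 2 data, 51 for 17 x 3 data with n = 83). Only
#' this pair of conventions reproduces all four published dimensionalities,
#' which is why they differ deliberately.
#'
#' @param result a \code{\link{gm_pca}} result.
#' @param mode "shape" (rank-based count) or "form" (column-based count).
#' @param tol relative eigenvalue tolerance for mode "shape".
#' @return integer count of PC scores.
#' @export
count_pc_scores <- function(result, mode = c("shape", "form"), tol = 1e-10) {
  mode <- match.arg(mode)
  if (mode == "shape")
    sum(result$eigenvalues > tol * result$eigenvalues[1])
  else
    ncol(result$scores)
}

#' Extreme shapes along a principal component
#'
#' Reconstructs the landmark configurations at the observed minimum and
#' maximum score on one component: consensus + score x loading vector,
#' unflattened to k x d. These are the natural reference/target pairs for
#' \code{\link{tps_warp}} deformation grids visualising what a component
#' means morphologically.
#'
#' @param pca a \code{\link{gm_pca}} of GPA tangent (or form) coordinates.
#' @param consensus the k x d consensus shape from \code{\link{gpa}}.
#' @param component component index.
#' @return list with \code{low} and \code{high} k x d matrices.
#' @export
pc_extreme_shapes <- function(pca, consensus, component) {
  consensus <- config_coords(consensus)
  if (component < 1L || component > ncol(pca$scores))
    stop("component out of range 1..", ncol(pca$scores))
  k <- nrow(consensus); d <- ncol(consensus)
  if (k * d != nrow(pca$loadings))
    stop("consensus dimensions do not match the PCA variable count")
  v <- pca$loadings[, component]
  s <- pca$scores[, component]
  list(low = consensus + unflatten_coords(min(s) * v, k, d),
       high = consensus + unflatten_coords(max(s) * v, k, d))
}
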