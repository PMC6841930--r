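#' Thin-plate-spline warp between two landmark configurations
#'
#' Fits the thin-plate-spline interpolant mapping the reference landmarks
#' exactly onto the target landmarks and evaluates it at arbitrary query
#' points (typically a deformation grid). The radial kernel is
#' U(r) = r^2 log(r^2) in 2D and U(r) = -r in 3D. The bending energy of the
#' warp (the quadratic form of the non-affine weights, zero if and only if
#' the map is affine) is attached as the attribute \code{"bending_energy"}.
#'
#' @param reference,target configurations with identical (k, d), d in {2, 3}.
#' @param query_points m x d matrix of points to map (defaults to the
#'   reference landmarks themselves).
#' @return m x d matrix of warped query points, with attribute
#'   \code{bending_energy}.
#' @export
tps_warp <- function(reference, target, query_points = NULL) {
  ref <- config_coords(reference)
  tgt <- config_coords(target)
  if (!all(dim(ref) == dim(tgt)))
    stop("reference and target must share the same (k, d)")
  d <- ncol(ref)
  if (!d %in% c(2L, 3L)) stop("TPS warps are implemented for d = 2 or 3")
  if (is.null(query_points)) query_points <- ref
  query_points <- as.matrix(query_points)
  if (ncol(query_points) != d)
    stop("query points must have ", d, " columns")
  k <- nrow(ref)

  kern <- function(r) {
    if (d == 2L) ifelse(r == 0, 0, r^2 * log(r^2)) else -r
  }
  kmat <- kern(as.matrix(stats::dist(ref)))
  p <- cbind(1, ref)
  l <- rbind(cbind(kmat, p),
             cbind(t(p), matrix(0, d + 1, d + 1)))
  rhs <- rbind(tgt, matrix(0, d + 1, d))
  coef <- tryCatch({
    cf <- solve(l, rhs)
    # iterative refinement until the residual stops improving
    res_norm <- max(abs(rhs - l %*% cf))
    for (i in 1:4) {
      if (res_norm == 0) break
      cf2 <- cf + solve(l, rhs - l %*% cf)
      res2 <- max(abs(rhs - l %*% cf2))
      if (res2 >= res_norm) break
      cf <- cf2
      res_norm <- res2
    }
    cf
  }, error = function(e)
    stop("singular thin-plate-spline system (reference landmarks too ",
         "degenerate); perturb/jitter the reference slightly"))
  w <- coef[seq_len(k), , drop = FALSE]
  a <- coef[k + seq_len(d + 1), , drop = FALSE]

  # distances via explicit differences: the |q|^2 + |x|^2 - 2 q.x expansion
  # cancels catastrophically near r = 0 and corrupts the -r kernel
  cross_d <- vapply(seq_len(k), function(j)
    sqrt(rowSums(sweep(query_points, 2, ref[j, ])^2)),
    numeric(nrow(query_points)))
  cross_d <- matrix(cross_d, nrow(query_points), k)
  out <- kern(cross_d) %*% w + cbind(1, query_points) %*% a

  # w'Kw is nonnegative for both kernels once the affine constraints P'w = 0
  # hold (the -r kernel is conditionally positive definite of order 1)
  attr(out, "bending_energy") <- sum(diag(t(w) %*% kmat %*% w))
  out
}
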