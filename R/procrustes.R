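#' Centroid size
#'
#' The standard geometric-morphometric size measure: the square root of the
#' summed squared distances of the landmarks from their centroid. Scales
#' linearly under uniform scaling of the configuration.
#'
#' @param config a \code{\link{landmark_config}} or coordinate matrix.
#' @return strictly positive scalar, in the input's length units.
#' @export
centroid_size <- function(config) {
  x <- config_coords(config)
  centered <- sweep(x, 2, colMeans(x))
  cs <- sqrt(sum(centered^2))
  if (cs < 1e-12) stop("degenerate configuration: all landmarks coincident")
  cs
}

# Center a configuration and scale it to unit centroid size.
center_scale <- function(x) {
  centered <- sweep(x, 2, colMeans(x))
  cs <- sqrt(sum(centered^2))
  if (cs < 1e-12) stop("degenerate configuration: zero centroid size")
  centered / cs
}

# Proper rotation taking a centred configuration onto its principal axes with
# a deterministic sign convention: the consensus' third coordinate moments are
# made positive where a rotation (not a reflection) can do so. In 2D the only
# sign freedom is the half-turn (flips both axes); in 3D the half-turns about
# the axes allow the first two moment signs to be chosen freely.
canonical_rotation <- function(x) {
  d <- ncol(x)
  sv <- svd(x)
  rot <- sv$v
  if (det(rot) < 0) rot[, d] <- -rot[, d]
  s <- colSums((x %*% rot)^3)
  sgn <- function(v) if (v >= 0) 1 else -1
  if (d == 2L) {
    lead <- if (abs(s[1]) > 1e-12) s[1] else s[2]
    if (lead < 0) rot <- -rot
  } else if (d == 3L) {
    f1 <- sgn(s[1]); f2 <- sgn(s[2])
    rot <- rot %*% diag(c(f1, f2, f1 * f2))
  }
  rot
}

# Optimal rotation (no reflection) of unit-scaled X onto unit-scaled Y:
# the d x d matrix R with det(R) = +1 minimising ||X R - Y||_F.
optimal_rotation <- function(x, y) {
  m <- crossprod(x, y)
  sv <- svd(m)
  j <- diag(ncol(m))
  j[ncol(m), ncol(m)] <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% j %*% t(sv$v)
}

#' Ordinary Procrustes superimposition of one configuration onto another
#'
#' Optimally translates, scales and rotates (rotations only -- tooth marks are
#' chiral, so reflections are never allowed) the source configuration onto the
#' target. The reported distance is the partial Procrustes distance: the root
#' summed squared residuals after both configurations are centred and scaled
#' to unit centroid size and the source is optimally rotated.
#'
#' @param source,target configurations with identical (k, d).
#' @return list with \code{aligned} (source mapped into the target's frame,
#'   including the optimal scale), \code{distance} (partial Procrustes
#'   distance), \code{rotation} (d x d), \code{scale} (relative scale applied
#'   to the unit-size source).
#' @export
procrustes_pair <- function(source, target) {
  xs <- config_coords(source)
  xt <- config_coords(target)
  if (!all(dim(xs) == dim(xt)))
    stop("source and target must share the same (k, d)")
  if (qr(sweep(xs, 2, colMeans(xs)))$rank < 1L)
    stop("degenerate source configuration")
  cs_t <- centroid_size(xt)
  u <- center_scale(xs)
  v <- center_scale(xt)
  r <- optimal_rotation(u, v)
  ur <- u %*% r
  beta <- sum(ur * v)  # optimal scale of unit-size source onto unit-size target
  aligned <- cs_t * beta * ur + matrix(colMeans(xt), nrow(xt), ncol(xt),
                                       byrow = TRUE)
  list(aligned = aligned,
       distance = sqrt(sum((ur - v)^2)),
       rotation = r,
       scale = beta)
}

#' Generalized Procrustes Analysis
#'
#' Iterative superimposition of a landmark sample: every configuration is
#' centred and scaled to unit centroid size, rotated onto the current
#' consensus (mean) shape, and the consensus is recomputed until its change
#' falls below \code{tol}. After convergence each configuration is also
#' orthogonally projected onto the tangent space at the consensus (projection
#' of the flattened coordinates onto the hyperplane orthogonal to the unit
#' consensus vector), which linearises the data for PCA and MANOVA.
#'
#' @param dataset a \code{\link{landmark_dataset}}.
#' @param tol convergence tolerance on the Frobenius change of the consensus.
#' @param max_iter maximum number of iterations.
#' @return object of class \code{gpa_result}: list with
#'   \describe{
#'     \item{aligned}{k x d x n array of Procrustes-aligned configurations,
#'       each centred at the origin with unit centroid size}
#'     \item{tangent}{n x (k d) matrix of tangent-projected coordinates (the
#'       input to shape-space PCA)}
#'     \item{consensus}{k x d mean shape (mean of \code{aligned})}
#'     \item{centroid_sizes}{original centroid sizes (input units)}
#'     \item{iterations, final_change, rss_trace}{convergence diagnostics}
#'     \item{labels, specimen_ids}{carried over from the dataset}
#'   }
#' @export
gpa <- function(dataset, tol = 1e-10, max_iter = 100L) {
  coords <- dataset$coords
  k <- dim(coords)[1]; d <- dim(coords)[2]; n <- dim(coords)[3]
  cs <- apply(coords, 3, centroid_size)
  aligned <- array(apply(coords, 3, center_scale), dim = c(k, d, n))

  if (n == 1L) {
    consensus <- aligned[, , 1, drop = TRUE]
    chat <- as.vector(consensus) / sqrt(sum(consensus^2))
    tangent <- matrix(as.vector(consensus) -
                        sum(as.vector(consensus) * chat) * chat, 1)
    return(structure(list(aligned = aligned, tangent = tangent,
                          consensus = consensus, centroid_sizes = cs,
                          iterations = 1L, final_change = 0,
                          rss_trace = 0, labels = dataset$labels,
                          specimen_ids = dataset$specimen_ids),
                     class = "gpa_result"))
  }

  rotate_all <- function(aligned, consensus) {
    for (i in seq_len(n))
      aligned[, , i] <- aligned[, , i] %*%
        optimal_rotation(aligned[, , i, drop = TRUE], consensus)
    aligned
  }
  consensus <- aligned[, , 1, drop = TRUE]
  rss_trace <- numeric(0)
  converged <- FALSE
  change <- NA_real_
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    aligned <- rotate_all(aligned, consensus)
    new_consensus <- apply(aligned, c(1, 2), mean)
    rss_trace <- c(rss_trace,
                   sum((aligned - array(new_consensus, dim(aligned)))^2))
    change <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (change < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("GPA did not converge after ", max_iter,
         " iterations (final consensus change ", signif(change, 3), ")")
  # final pass: align exactly to the converged consensus, then refresh it
  aligned <- rotate_all(aligned, consensus)
  consensus <- apply(aligned, c(1, 2), mean)

  # canonical orientation: rotate the whole sample so the consensus lies on
  # its principal axes, with a deterministic sign convention restricted to
  # proper rotations (never reflections -- tooth marks are chiral). This makes
  # the aligned coordinates invariant to the arbitrary initial orientation of
  # the input configurations.
  rot <- canonical_rotation(consensus)
  consensus <- consensus %*% rot
  for (i in seq_len(n)) aligned[, , i] <- aligned[, , i] %*% rot

  cvec <- as.vector(consensus)
  chat <- cvec / sqrt(sum(cvec^2))
  flat <- flatten_coords(aligned)
  tangent <- flat - (flat %*% chat) %*% t(chat)

  structure(list(aligned = aligned, tangent = tangent, consensus = consensus,
                 centroid_sizes = cs, iterations = iter,
                 final_change = change, rss_trace = rss_trace,
                 labels = dataset$labels,
                 specimen_ids = dataset$specimen_ids),
            class = "gpa_result")
}

#' @export
print.gpa_result <- function(x, ...) {
  kd <- dim(x$aligned)
  cat("GPA of ", kd[3], " configurations (", kd[1], " landmarks x ", kd[2],
      "D): converged in ", x$iterations, " iterations (final change ",
      format(x$final_change, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Form-space matrix
#'
#' Builds the form-space data matrix by rescaling each configuration's
#' Procrustes-aligned coordinates by the natural logarithm of its centroid
#' size, retaining all k x d coordinate columns (so 7-landmark 2D data yields
#' 14 columns and 17-landmark 3D data yields 51). Centroid sizes must exceed
#' 1 in the working units so every log is positive; with millimetre input,
#' pass \code{units = 1000} to work in micrometres.
#'
#' @param result a \code{\link{gpa}} result.
#' @param units multiplier applied to the stored centroid sizes before taking
#'   logs (1 = use input units as-is; 1000 converts mm to micrometres).
#' @return object of class \code{form_matrix}: list with \code{values}
#'   (n x kd matrix), \code{log_cs}, \code{labels}, \code{basis}.
#' @export
to_form_space <- function(result, units = 1) {
  if (!inherits(result, "gpa_result")) stop("result must come from gpa()")
  cs <- result$centroid_sizes * units
  if (any(cs <= 1))
    stop("centroid sizes <= 1 give non-positive logs; rescale units ",
         "(e.g. units = 1000 to convert millimetres to micrometres)")
  lncs <- log(cs)
  values <- flatten_coords(result$aligned) * lncs
  structure(list(values = values, log_cs = lncs, labels = result$labels,
                 basis = "aligned coordinates scaled by ln(centroid size)"),
            class = "form_matrix")
}
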