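#' Box's M test for homogeneity of covariance matrices
#'
#' Chi-square approximation of Box's M statistic comparing the group
#' covariance matrices. Used as the gate that chooses between the
#' Hotelling-Lawley (homogeneous) and Wilks (inhomogeneous) MANOVA statistics.
#' If any group covariance is computationally singular, the groups are
#' reported as inhomogeneous (p = 0) rather than failing.
#'
#' @param x numeric matrix, n x p.
#' @param groups factor/character vector of length n.
#' @return list with \code{statistic} (chi-square), \code{df},
#'   \code{p.value}, \code{singular}.
#' @export
box_m <- function(x, groups) {
  x <- as.matrix(x)
  groups <- factor(groups)
  g <- nlevels(groups)
  p <- ncol(x)
  ns <- table(groups)
  if (any(ns < 2L)) stop("every group needs at least 2 members")
  n_tot <- nrow(x)
  logdet <- function(s) {
    dt <- determinant(s, logarithm = TRUE)
    if (dt$sign <= 0 || !is.finite(dt$modulus)) NA_real_
    else as.numeric(dt$modulus)
  }
  covs <- lapply(levels(groups), function(l)
    stats::cov(x[groups == l, , drop = FALSE]))
  lds <- vapply(covs, logdet, numeric(1))
  sp <- Reduce(`+`, Map(function(s, n) (n - 1) * s, covs, as.list(ns))) /
    (n_tot - g)
  ld_p <- logdet(sp)
  if (anyNA(lds) || is.na(ld_p))
    return(list(statistic = NA_real_, df = NA_real_, p.value = 0,
                singular = TRUE))
  m <- (n_tot - g) * ld_p - sum((ns - 1) * lds)
  c1 <- (sum(1 / (ns - 1)) - 1 / (n_tot - g)) *
    (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (g - 1))
  stat <- m * (1 - c1)
  df <- p * (p + 1) * (g - 1) / 2
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE),
       singular = FALSE)
}

#' Pairwise MANOVA on PC scores with homogeneity-dependent statistic
#'
#' Tests whether two groups differ in multivariate location. The score
#' columns are first truncated to the leading components explaining at least
#' \code{var_threshold} of cumulative variance (and to at most
#' n_a + n_b - 3 columns so the error degrees of freedom stay positive).
#' Box's M is run on the truncated scores; when the groups are homogeneous
#' (Box's M p >= alpha) the Hotelling-Lawley trace is used, otherwise Wilks'
#' Lambda. In the two-group case both statistics reduce to Hotelling's T^2
#' and their F approximations are exact.
#'
#' @param scores numeric matrix of PC scores (columns in decreasing variance
#'   order), n x m.
#' @param labels group labels, length n.
#' @param group_a,group_b the two group labels to compare (each needs >= 3
#'   members).
#' @param alpha homogeneity-gate level for Box's M.
#' @param var_threshold cumulative-variance truncation threshold.
#' @return object of class \code{manova_result}: list with
#'   \code{statistic_name} ("Hotelling-Lawley" or "Wilks"), \code{statistic},
#'   \code{F_approx}, \code{df} (numerator, denominator), \code{p_value},
#'   \code{homogeneity_p}, \code{n_components}.
#' @export
manova_pairwise <- function(scores, labels, group_a, group_b,
                            alpha = 0.05, var_threshold = 0.95) {
  scores <- as.matrix(scores)
  keep <- labels %in% c(group_a, group_b)
  for (gl in c(group_a, group_b))
    if (sum(labels == gl) < 3L)
      stop("group '", gl, "' is absent or has fewer than 3 members")
  x <- scores[keep, , drop = FALSE]
  g <- factor(labels[keep], levels = c(group_a, group_b))
  na <- sum(g == group_a); nb <- sum(g == group_b)

  v <- apply(x, 2, stats::var)
  cum <- cumsum(v) / sum(v)
  ncomp <- which(cum >= var_threshold)[1]
  if (is.na(ncomp)) ncomp <- ncol(x)
  ncomp <- min(ncomp, na + nb - 3L, ncol(x))
  ncomp <- max(ncomp, min(2L, ncol(x)))
  y <- x[, seq_len(ncomp), drop = FALSE]
  if (qr(stats::cov(y))$rank < ncomp)
    stop("singular pooled covariance after truncation to ", ncomp,
         " components")
  if (ncomp < 2L)
    stop("MANOVA needs at least 2 response columns; got ", ncomp)

  hom <- box_m(y, g)
  statistic_name <- if (hom$p.value >= alpha) "Hotelling-Lawley" else "Wilks"
  fit <- stats::manova(y ~ g)
  sm <- summary(fit, test = statistic_name)$stats
  structure(list(statistic_name = statistic_name,
                 statistic = unname(sm[1, 2]),
                 F_approx = unname(sm[1, 3]),
                 df = c(num = unname(sm[1, 4]), den = unname(sm[1, 5])),
                 p_value = unname(sm[1, 6]),
                 homogeneity_p = hom$p.value,
                 n_components = ncomp,
                 groups = c(group_a, group_b)),
            class = "manova_result")
}

#' @export
print.manova_result <- function(x, ...) {
  cat("MANOVA ", x$groups[1], " vs ", x$groups[2], " (",
      x$statistic_name, ", ", x$n_components, " components): F = ",
      format(x$F_approx, digits = 4), ", p = ",
      format.pval(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}
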