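# Independent oracles and small generators used across the suite.

# Brute-force partial Procrustes distance for 2D configurations: both inputs
# centred and scaled to unit centroid size, then the rotation is found by a
# dense grid search over the angle. Independent of the SVD-based code path.
grid_procrustes_distance_2d <- function(a, b, step_deg = 0.01) {
  cs <- function(x) {
    xc <- sweep(x, 2, colMeans(x))
    xc / sqrt(sum(xc^2))
  }
  u <- cs(a)
  v <- cs(b)
  angles <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  best <- Inf
  for (th in angles) {
    r <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    best <- min(best, sum((u %*% r - v)^2))
  }
  sqrt(best)
}

rotation_2d <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# Random proper rotation in d dimensions.
random_rotation <- function(d) {
  m <- qr.Q(qr(matrix(stats::rnorm(d * d), d)))
  if (det(m) < 0) m[, 1] <- -m[, 1]
  m
}

# Apply a random similarity transform (rotation, positive scale, translation)
# to every configuration of a dataset.
randomly_transform_dataset <- function(dataset) {
  co <- dataset$coords
  d <- dim(co)[2]
  for (i in seq_len(dim(co)[3])) {
    co[, , i] <- co[, , i] %*% random_rotation(d) * stats::runif(1, 0.5, 3)
    co[, , i] <- sweep(co[, , i], 2, stats::runif(d, -5, 5), "+")
  }
  landmark_dataset(co, labels = dataset$labels,
                   specimen_ids = dataset$specimen_ids,
                   mark_type = dataset$mark_type)
}

random_config <- function(k, d) {
  matrix(stats::rnorm(k * d), k, d)
}

expect_dataset_equal <- function(a, b, tol = 1e-9) {
  expect_equal(dim(a$coords), dim(b$coords))
  expect_lt(max(abs(a$coords - b$coords)), tol)
  expect_identical(a$specimen_ids, b$specimen_ids)
  expect_identical(a$labels, b$labels)
}
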