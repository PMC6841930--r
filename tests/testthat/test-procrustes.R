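test_that("centroid size matches analytic values and the direct formula", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  expect_equal(centroid_size(sq), sqrt(2), tolerance = 1e-12)

  set.seed(21)
  x <- random_config(17, 3)
  # brute-force double loop over landmarks and dimensions
  ctr <- colMeans(x)
  acc <- 0
  for (i in seq_len(nrow(x)))
    for (j in seq_len(ncol(x)))
      acc <- acc + (x[i, j] - ctr[j])^2
  expect_equal(centroid_size(x), sqrt(acc), tolerance = 1e-12)

  for (c_scale in c(0.1, 2.5, 40))
    expect_equal(centroid_size(x * c_scale), c_scale * centroid_size(x),
                 tolerance = 1e-12)

  expect_error(centroid_size(matrix(1, 4, 2) + 0), "coincident|degenerate")
})

test_that("pairwise superimposition removes similarity transforms exactly", {
  set.seed(22)
  src <- random_config(6, 2)
  tgt <- sweep(src %*% rotation_2d(37 * pi / 180) * 2.5, 2, c(3, -1), "+")
  fit <- procrustes_pair(src, tgt)
  expect_lt(fit$distance, 1e-9)
  expect_lt(max(abs(fit$aligned - tgt)), 1e-8)

  same <- procrustes_pair(src, src)
  expect_lt(same$distance, 1e-12)
  expect_equal(same$rotation, diag(2), tolerance = 1e-9)
})

test_that("pairwise Procrustes distance matches a dense rotation-grid search", {
  set.seed(23)
  for (rep in 1:3) {
    a <- random_config(4, 2)
    b <- random_config(4, 2)
    expect_equal(procrustes_pair(a, b)$distance,
                 grid_procrustes_distance_2d(a, b),
                 tolerance = 1e-4)
  }
})

test_that("Procrustes distance behaves as a pseudo-metric", {
  set.seed(24)
  for (rep in 1:10) {
    a <- random_config(5, 2)
    b <- random_config(5, 2)
    cc <- random_config(5, 2)
    dab <- procrustes_pair(a, b)$distance
    dba <- procrustes_pair(b, a)$distance
    dac <- procrustes_pair(a, cc)$distance
    dcb <- procrustes_pair(cc, b)$distance
    expect_equal(dab, dba, tolerance = 1e-9)
    expect_lte(dab, dac + dcb + 1e-12)
  }
  # zero on similarity-equivalent pairs
  a <- random_config(5, 3)
  b <- sweep(a %*% random_rotation(3) * 1.7, 2, c(1, 2, 3), "+")
  expect_lt(procrustes_pair(a, b)$distance, 1e-9)
})

test_that("GPA aligns similarity-copies of one shape onto each other", {
  set.seed(25)
  base <- random_config(7, 2)
  configs <- lapply(1:8, function(i)
    sweep(base %*% random_rotation(2) * runif(1, 0.5, 2), 2,
          runif(2, -3, 3), "+"))
  ds <- landmark_dataset(lapply(configs, landmark_config))
  g <- gpa(ds)
  for (i in 2:8)
    expect_lt(max(abs(g$aligned[, , i] - g$aligned[, , 1])), 1e-8)
  expect_lt(procrustes_pair(g$consensus, base)$distance, 1e-8)
})

test_that("GPA output satisfies its contract and is invariant and idempotent", {
  s <- simulate_reference_sample(seed = 4)
  g <- gpa(s$scores)
  n <- n_configs(s$scores)
  for (i in seq_len(n)) {
    cfg <- g$aligned[, , i]
    expect_lt(max(abs(colMeans(cfg))), 1e-9)              # centred
    expect_lt(abs(sqrt(sum(cfg^2)) - 1), 1e-9)            # unit centroid size
  }
  expect_lt(max(abs(apply(g$aligned, c(1, 2), mean) - g$consensus)), 1e-9)
  expect_lt(g$final_change, 1e-10)
  expect_true(all(diff(g$rss_trace) <= 1e-12))            # monotone descent

  # invariance to arbitrary similarity transforms of the raw input
  set.seed(26)
  g2 <- gpa(randomly_transform_dataset(s$scores))
  expect_lt(max(abs(g$aligned - g2$aligned)), 1e-8)

  # idempotence: GPA of its own aligned output changes nothing
  ds_aligned <- landmark_dataset(g$aligned, labels = g$labels,
                                 specimen_ids = g$specimen_ids)
  g3 <- gpa(ds_aligned)
  expect_lt(max(abs(g3$aligned - g$aligned)), 1e-8)
})

test_that("GPA handles the single-configuration case", {
  set.seed(27)
  ds <- landmark_dataset(array(random_config(5, 2), dim = c(5, 2, 1)))
  g <- gpa(ds)
  expect_equal(g$iterations, 1L)
  expect_lt(max(abs(g$aligned[, , 1] - g$consensus)), 1e-12)
  expect_lt(abs(sqrt(sum(g$aligned^2)) - 1), 1e-12)
})

test_that("form space is aligned coordinates scaled by log centroid size", {
  set.seed(28)
  base <- random_config(7, 2)
  # configurations built with centroid size exactly e
  configs <- lapply(1:6, function(i) {
    x <- base + matrix(rnorm(14, 0, 0.02), 7, 2)
    xc <- sweep(x, 2, colMeans(x))
    landmark_config(exp(1) * xc / sqrt(sum(xc^2)))
  })
  ds <- landmark_dataset(configs)
  g <- gpa(ds)
  fm <- to_form_space(g)   # ln(e) = 1
  expect_equal(fm$values, canidmarks:::flatten_coords(g$aligned),
               tolerance = 1e-9)
  expect_equal(ncol(fm$values), 14L)

  g$centroid_sizes[2] <- 0.9
  expect_error(to_form_space(g), "rescale")
})
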