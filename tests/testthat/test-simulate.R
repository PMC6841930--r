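test_that("default generator reproduces the study sample sizes", {
  s <- simulate_reference_sample(seed = 5)
  expect_equal(n_configs(s$pits), 83L)
  expect_equal(n_configs(s$scores), 105L)
  expect_equal(as.vector(table(s$pits$labels)[c("fox", "wolf", "dog")]),
               c(29L, 24L, 30L))
  expect_equal(as.vector(table(s$scores$labels)[c("fox", "wolf", "dog")]),
               c(41L, 30L, 34L))
  expect_equal(dim(s$measurements$values), c(105L, 7L))
})

test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_dataset(simulation_spec(seed = 9), "pit")
  b <- simulate_dataset(simulation_spec(seed = 9), "pit")
  expect_identical(a$coords, b$coords)
  expect_identical(a$labels, b$labels)
  c1 <- simulate_dataset(simulation_spec(seed = 10), "pit")
  expect_false(identical(a$coords, c1$coords))
})

test_that("score templates encode the landmark-role convention", {
  spec <- simulation_spec()
  for (cl in c("dog", "fox", "wolf")) {
    tpl <- make_score_template(cl, spec)$coords
    expect_true(all(diff(tpl[, 1]) > 0))          # left-right ordered
    expect_equal(tpl[c(1, 7), 2], c(0, 0))        # surface landmarks
    expect_true(all(tpl[4, 2] < tpl[-4, 2]))      # LM4 strictly deepest
  }
  expect_error(make_score_template("bear", spec), "unknown class")
})

test_that("pit templates are craters: rim at z = 0, apex strictly deepest", {
  tpl <- make_pit_template("wolf", simulation_spec())$coords
  expect_equal(as.vector(tpl[1:8, 3]), rep(0, 8))
  expect_true(all(tpl[17, 3] < tpl[1:16, 3]))
})

test_that("class templates encode the published size and depth orderings", {
  spec <- simulation_spec()
  meas <- lapply(c(fox = "fox", dog = "dog", wolf = "wolf"), function(cl)
    compute_measurements(make_score_template(cl, spec)))
  ratio <- vapply(meas, function(m) m[["D"]] / m[["WIS"]], numeric(1))
  expect_true(ratio[["fox"]] > ratio[["dog"]])
  expect_true(ratio[["dog"]] > ratio[["wolf"]])

  cs <- vapply(c(fox = "fox", dog = "dog", wolf = "wolf"), function(cl)
    centroid_size(make_pit_template(cl, spec)), numeric(1))
  expect_true(cs[["wolf"]] > cs[["dog"]])
  expect_true(cs[["dog"]] > cs[["fox"]])
})

test_that("separation = 0 collapses all class templates onto one shape", {
  spec <- simulation_spec(separation = 0)
  s_tpl <- lapply(c("dog", "fox", "wolf"),
                  function(cl) make_score_template(cl, spec)$coords)
  expect_equal(s_tpl[[1]], s_tpl[[2]], tolerance = 1e-12)
  expect_equal(s_tpl[[2]], s_tpl[[3]], tolerance = 1e-12)
  p_tpl <- lapply(c("dog", "fox", "wolf"),
                  function(cl) make_pit_template(cl, spec)$coords)
  expect_equal(p_tpl[[1]], p_tpl[[3]], tolerance = 1e-12)
})

test_that("simulated samples show the published size and dispersion orderings", {
  s <- simulate_reference_sample(seed = 2)
  cs <- apply(s$scores$coords, 3, centroid_size)
  mean_cs <- tapply(cs, s$scores$labels, mean)
  expect_true(mean_cs[["wolf"]] > mean_cs[["dog"]])
  expect_true(mean_cs[["dog"]] > mean_cs[["fox"]])

  # mean Procrustes distance to own class consensus: fox < dog < wolf
  g <- gpa(s$scores)
  disp <- vapply(c(fox = "fox", dog = "dog", wolf = "wolf"), function(cl) {
    rows <- g$tangent[g$labels == cl, , drop = FALSE]
    ctr <- colMeans(rows)
    mean(sqrt(rowSums(sweep(rows, 2, ctr)^2)))
  }, numeric(1))
  expect_true(disp[["fox"]] < disp[["dog"]])
  expect_true(disp[["dog"]] < disp[["wolf"]])
})

test_that("invalid simulation specifications are rejected", {
  expect_error(simulation_spec(noise_sd = c(wolf = 0, dog = 0.01,
                                            fox = 0.01)),
               "strictly positive")
  expect_error(simulation_spec(separation = -1), ">= 0")
  expect_error(simulate_dataset(
    simulation_spec(n_per_class = list(fox = c(pits = 0, scores = 1),
                                       wolf = c(pits = 1, scores = 1),
                                       dog = c(pits = 1, scores = 1))),
    "pit"),
    "non-positive")
})
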