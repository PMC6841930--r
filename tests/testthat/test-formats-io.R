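test_that("morphologika write/read round trip is the identity", {
  set.seed(11)
  ds <- landmark_dataset(
    array(rnorm(3 * 2 * 2), dim = c(3, 2, 2)),
    specimen_ids = c("wolf_01", "fox_01"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_morphologika(ds, path)
  back <- read_morphologika(path)
  expect_dataset_equal(ds, back)
  expect_identical(back$labels, c("wolf", "fox"))

  ds3 <- landmark_dataset(array(rnorm(5 * 3 * 4), dim = c(5, 3, 4)),
                          specimen_ids = sprintf("dog_%02d", 1:4))
  write_morphologika(ds3, path)
  expect_match(paste(readLines(path), collapse = "\n"), "\\[dimensions\\]\n3")
  expect_dataset_equal(ds3, read_morphologika(path))
})

test_that("morphologika reading preserves individual order and validates", {
  path <- withr::local_tempfile(fileext = ".txt")
  # order preservation with a names block
  ds <- landmark_dataset(array(rnorm(3 * 2 * 2), dim = c(3, 2, 2)),
                         specimen_ids = c("wolf_01", "fox_01"))
  write_morphologika(ds, path)
  expect_identical(read_morphologika(path)$specimen_ids,
                   c("wolf_01", "fox_01"))

  # declared 17 landmarks but one individual short by a row
  lines <- c("[individuals]", "2", "[landmarks]", "17", "[dimensions]", "3",
             "[rawpoints]",
             apply(matrix(rnorm(17 * 3), 17), 1, paste, collapse = " "),
             apply(matrix(rnorm(16 * 3), 16), 1, paste, collapse = " "))
  writeLines(lines, path)
  expect_error(read_morphologika(path), "individual 2")

  # non-numeric coordinate names the line
  lines <- c("[individuals]", "1", "[landmarks]", "2", "[dimensions]", "2",
             "[rawpoints]", "0 0", "1 oops")
  writeLines(lines, path)
  expect_error(read_morphologika(path), "line 9")

  # missing header section
  writeLines(c("[individuals]", "1", "[rawpoints]", "0 0"), path)
  expect_error(read_morphologika(path), "\\[landmarks\\]")
})

test_that("writing an empty dataset errors before touching the file", {
  ds <- landmark_dataset(array(rnorm(3 * 2 * 2), dim = c(3, 2, 2)))
  ds$coords <- ds$coords[, , 0, drop = FALSE]  # forcibly emptied
  path <- file.path(withr::local_tempdir(), "empty.txt")
  expect_error(write_morphologika(ds, path), "empty")
  expect_false(file.exists(path))
})

test_that("measurement CSV round trip preserves values, labels and order", {
  vals <- matrix(c(2.0, 1.5, 1.0, 0.8, 95, 40, 42,
                   1.8, 1.2, 0.9, 0.7, 101, 38, 39,
                   2.2, 1.7, 1.1, 0.9, 88, 44, 45),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(NULL,
                                 c("WIS", "WIM", "WIB", "D", "OA",
                                   "LWA", "RWA")))
  tab <- measurement_table(vals, labels = c("wolf", "dog", "fox"))
  expect_equal(dim(tab$values), c(3L, 7L))
  expect_true("OA" %in% tab$column_names)

  path <- withr::local_tempfile(fileext = ".csv")
  write_measurement_csv(tab, path)
  back <- read_measurement_csv(path)
  expect_equal(back$values, tab$values, tolerance = 1e-12)
  expect_identical(back$labels, tab$labels)
})

test_that("measurement CSV validation names offending rows", {
  df <- data.frame(label = c("a", "b", "c"),
                   WIS = c(1, 1, 1), WIM = c(1, 1, 1), WIB = c(1, 1, 1),
                   D = c(1, 1, 1), OA = c(90, 200, 90),
                   LWA = c(45, 45, 45), RWA = c(45, 45, 45))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_error(read_measurement_csv(path), "2")

  df$OA <- 90
  df$D[3] <- -0.1
  write.csv(df, path, row.names = FALSE)
  expect_error(read_measurement_csv(path), "3")

  df$D <- 1
  names(df)[names(df) == "OA"] <- "opening"
  write.csv(df, path, row.names = FALSE)
  expect_error(read_measurement_csv(path), "OA")
})
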