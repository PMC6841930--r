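#' Groove cross-section measurements and measurement tables
#'
#' A tooth-score cross-section digitised with the 7-landmark 2D model is
#' summarised by seven measurements covering its thickness, depth and wall
#' angles:
#' \describe{
#'   \item{WIS}{surface width, distance LM1-LM7 (mm)}
#'   \item{WIM}{width at half maximal depth, LM2-LM6 (mm)}
#'   \item{WIB}{width at three-quarter maximal depth, LM3-LM5 (mm)}
#'   \item{D}{maximal depth: perpendicular distance from LM4 to the surface
#'     chord LM1-LM7 (mm)}
#'   \item{OA}{opening angle: angle at LM4 subtended by LM1 and LM7 (degrees,
#'     strictly inside (0, 180))}
#'   \item{LWA}{left wall angle, between LM1-LM4 and the chord (degrees)}
#'   \item{RWA}{right wall angle, between LM7-LM4 and the chord (degrees)}
#' }
#' The landmark-role convention is: LM1/LM7 at the bone surface, LM4 the
#' deepest point, LM2/LM6 on the walls at half depth, LM3/LM5 at three-quarter
#' depth, landmarks ordered left to right.
#'
#' @param config a 7 x 2 \code{\link{landmark_config}} (or bare matrix) of a
#'   score cross-section.
#' @return named numeric vector with elements WIS, WIM, WIB, D, OA, LWA, RWA.
#'   All are invariant under rigid motion of the input; lengths scale and
#'   angles are fixed under uniform scaling.
#' @export
compute_measurements <- function(config) {
  if (inherits(config, "landmark_config") && config$mark_type == "pit")
    stop("pits have no cross-section measurement model")
  x <- config_coords(config)
  if (nrow(x) != 7L || ncol(x) != 2L)
    stop("cross-section measurements require a 7 x 2 configuration, got ",
         nrow(x), " x ", ncol(x))
  seg <- function(a, b) sqrt(sum((a - b)^2))
  lm1 <- x[1, ]; lm4 <- x[4, ]; lm7 <- x[7, ]
  wis <- seg(lm1, lm7)
  wim <- seg(x[2, ], x[6, ])
  wib <- seg(x[3, ], x[5, ])
  # perpendicular distance from LM4 to the surface chord
  u <- (lm7 - lm1) / wis
  v <- lm4 - lm1
  depth <- abs(v[1] * u[2] - v[2] * u[1])
  if (depth < 1e-12)
    stop("degenerate cross-section: deepest landmark lies on the surface chord")
  angle <- function(a, b) {
    ca <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
    acos(max(-1, min(1, ca))) * 180 / pi
  }
  oa <- angle(lm1 - lm4, lm7 - lm4)
  lwa <- angle(lm4 - lm1, lm7 - lm1)
  rwa <- angle(lm4 - lm7, lm1 - lm7)
  c(WIS = wis, WIM = wim, WIB = wib, D = depth, OA = oa, LWA = lwa, RWA = rwa)
}

measurement_columns <- c("WIS", "WIM", "WIB", "D", "OA", "LWA", "RWA")
angle_columns <- c("OA", "LWA", "RWA")

new_measurement_table <- function(values, labels, require_oa = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values))) stop("measurement values need column names")
  n_oa <- sum(colnames(values) == "OA")
  if (require_oa && n_oa != 1L)
    stop("a measurement table must contain exactly one column named OA")
  if (n_oa > 1L) stop("duplicated OA column")
  labels <- as.character(labels)
  if (length(labels) != nrow(values))
    stop("labels must have one entry per row")
  validate_measurement_values(values)
  structure(list(values = values, labels = labels,
                 column_names = colnames(values)),
            class = "measurement_table")
}

validate_measurement_values <- function(values) {
  if (nrow(values) == 0L) return(invisible(TRUE))
  len_cols <- setdiff(colnames(values), angle_columns)
  bad <- integer(0)
  if (length(len_cols))
    bad <- union(bad, which(apply(values[, len_cols, drop = FALSE], 1,
                                  function(r) any(!is.finite(r) | r <= 0))))
  if ("OA" %in% colnames(values))
    bad <- union(bad, which(!is.finite(values[, "OA"]) |
                              values[, "OA"] <= 0 | values[, "OA"] >= 180))
  if (length(bad))
    stop("invalid measurement rows (non-positive width/depth or OA outside ",
         "(0,180)): ", paste(sort(bad), collapse = ", "))
  invisible(TRUE)
}

#' Build a measurement table
#'
#' Computes the seven cross-section measurements for every configuration of a
#' score dataset (row order = dataset order, labels copied), or wraps an
#' existing values matrix.
#'
#' @param x a \code{\link{landmark_dataset}} of scores, or an n x 7 numeric
#'   matrix with column names including OA.
#' @param include_oa when FALSE, the OA column is dropped from the result
#'   (the protocol is run both with and without the opening angle).
#' @param labels row labels, required when \code{x} is a matrix.
#' @return object of class \code{measurement_table}: list with \code{values}
#'   (numeric matrix), \code{labels}, \code{column_names}.
#' @export
measurement_table <- function(x, include_oa = TRUE, labels = NULL) {
  if (inherits(x, "landmark_dataset")) {
    if (x$mark_type == "pit")
      stop("pit datasets have no cross-section measurement model")
    n <- n_configs(x)
    values <- matrix(NA_real_, n, 7,
                     dimnames = list(NULL, measurement_columns))
    for (i in seq_len(n))
      values[i, ] <- compute_measurements(x$coords[, , i, drop = TRUE])
    tab <- new_measurement_table(values, x$labels)
  } else {
    if (is.null(labels)) stop("labels are required for matrix input")
    tab <- new_measurement_table(x, labels)
  }
  if (!include_oa) drop_oa(tab) else tab
}

#' Drop the opening-angle column
#' @param table a \code{measurement_table}.
#' @return a \code{measurement_table} view without the OA column.
#' @export
drop_oa <- function(table) {
  if (!"OA" %in% table$column_names) return(table)
  keep <- table$column_names != "OA"
  structure(list(values = table$values[, keep, drop = FALSE],
                 labels = table$labels,
                 column_names = table$column_names[keep]),
            class = "measurement_table")
}

#' @export
print.measurement_table <- function(x, ...) {
  cat("Measurement table: ", nrow(x$values), " rows x ",
      ncol(x$values), " columns (",
      paste(x$column_names, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.measurement_table <- function(x, ...) {
  data.frame(label = x$labels, x$values, check.names = FALSE)
}

#' Read a comma-delimited measurement table
#'
#' Expects a header row with a \code{label} column and seven measurement
#' columns including \code{OA}. Rows violating the measurement invariants
#' (non-positive widths/depths, OA outside (0, 180)) raise a validation error
#' naming the offending rows.
#'
#' @param path path to a CSV file.
#' @return a \code{\link{measurement_table}}, rows in file order.
#' @export
read_measurement_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"label" %in% names(df))
    stop("measurement CSV must contain a 'label' column")
  if (!"OA" %in% names(df))
    stop("measurement CSV must contain an 'OA' column")
  vals <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  if (!is.numeric(vals)) stop("measurement columns must all be numeric")
  new_measurement_table(vals, df$label)
}

#' Write a measurement table to CSV
#' @param table a \code{\link{measurement_table}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_measurement_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
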