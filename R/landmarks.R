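#' Landmark configuration
#'
#' A single tooth mark digitised as an ordered set of homologous landmarks.
#' Under the study protocol, tooth-score cross-sections use a 7-landmark 2D
#' model and tooth pits a 17-landmark 3D model; any other (k, d) is accepted
#' in generic mode.
#'
#' @param coords numeric matrix, k landmarks x d dimensions. Interpreted as
#'   millimetres by convention; the package never rescales on input.
#' @param specimen_id character scalar identifying the mark.
#' @param class_label optional character scalar (e.g. "wolf", "dog", "fox").
#' @param mark_type one of "generic", "score", "pit". "score" enforces
#'   k = 7, d = 2; "pit" enforces k = 17, d = 3.
#'
#' @return An object of class \code{landmark_config}: a list with elements
#'   \code{coords}, \code{specimen_id}, \code{class_label}, \code{mark_type}.
#' @export
landmark_config <- function(coords, specimen_id = "specimen", class_label = NULL,
                            mark_type = c("generic", "score", "pit")) {
  mark_type <- match.arg(mark_type)
  coords <- unname(as.matrix(coords))
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords)))
    stop("all landmark coordinates must be finite")
  k <- nrow(coords)
  d <- ncol(coords)
  if (k < 2L) stop("a landmark configuration needs at least 2 landmarks")
  if (mark_type == "score" && !(k == 7L && d == 2L))
    stop("score configurations must be 7 landmarks x 2 dimensions, got ",
         k, " x ", d)
  if (mark_type == "pit" && !(k == 17L && d == 3L))
    stop("pit configurations must be 17 landmarks x 3 dimensions, got ",
         k, " x ", d)
  if (any(stats::dist(coords) == 0))
    stop("landmark configuration '", specimen_id,
         "' contains exactly coincident landmarks")
  structure(list(coords = coords,
                 specimen_id = as.character(specimen_id)[1],
                 class_label = if (is.null(class_label)) NULL
                               else as.character(class_label)[1],
                 mark_type = mark_type),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("Landmark configuration '", x$specimen_id, "' (",
      x$mark_type, "): ", nrow(x$coords), " landmarks x ",
      ncol(x$coords), "D", sep = "")
  if (!is.null(x$class_label)) cat(", class ", x$class_label, sep = "")
  cat("\n")
  invisible(x)
}

# Coerce a landmark_config or bare matrix to a coordinate matrix.
config_coords <- function(x) {
  if (inherits(x, "landmark_config")) return(x$coords)
  if (is.matrix(x)) return(x)
  stop("expected a landmark_config or a coordinate matrix")
}

#' Landmark dataset
#'
#' An ordered collection of same-shaped landmark configurations with class
#' labels; the unit of I/O and analysis. Coordinates are held as a
#' k x d x n array (landmarks x dimensions x specimens), the layout used by
#' the standard geometric-morphometrics packages.
#'
#' @param configs either a list of \code{\link{landmark_config}} objects with
#'   identical (k, d), or a k x d x n numeric array.
#' @param labels character vector of class labels, length n. When NULL,
#'   labels are taken from each configuration's \code{class_label} (list
#'   input) or derived from specimen names via \code{\link{label_from_name}}.
#' @param specimen_ids character vector of specimen identifiers, length n.
#' @param mark_type "generic", "score" or "pit" (validated per configuration).
#'
#' @return Object of class \code{landmark_dataset}: list with \code{coords}
#'   (k x d x n array), \code{labels}, \code{specimen_ids}, \code{mark_type}.
#' @export
landmark_dataset <- function(configs, labels = NULL, specimen_ids = NULL,
                             mark_type = c("generic", "score", "pit")) {
  mark_type <- match.arg(mark_type)
  if (is.list(configs) && !is.array(configs)) {
    if (length(configs) == 0L) stop("empty landmark dataset")
    mats <- lapply(configs, config_coords)
    dims <- vapply(mats, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("all configurations in a dataset must share the same (k, d)")
    coords <- array(unlist(mats), dim = c(dims[1, 1], dims[2, 1], length(mats)))
    if (is.null(specimen_ids))
      specimen_ids <- vapply(configs, function(cf)
        if (inherits(cf, "landmark_config")) cf$specimen_id else "specimen",
        character(1))
    if (is.null(labels))
      labels <- vapply(configs, function(cf) {
        lb <- if (inherits(cf, "landmark_config")) cf$class_label else NULL
        if (is.null(lb)) NA_character_ else lb
      }, character(1))
  } else {
    coords <- configs
    if (!is.array(coords) || length(dim(coords)) != 3L)
      stop("configs must be a list of landmark_config or a k x d x n array")
    storage.mode(coords) <- "double"
  }
  n <- dim(coords)[3]
  if (is.null(specimen_ids))
    specimen_ids <- sprintf("specimen_%03d", seq_len(n))
  if (is.null(labels)) labels <- label_from_name(specimen_ids)
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("labels must have one entry per configuration (", n, ")")
  if (length(specimen_ids) != n)
    stop("specimen_ids must have one entry per configuration (", n, ")")
  # validate each slice (finiteness, coincidence, protocol dims)
  for (i in seq_len(n))
    landmark_config(coords[, , i, drop = TRUE], specimen_ids[i],
                    mark_type = mark_type)
  structure(list(coords = coords, labels = labels,
                 specimen_ids = as.character(specimen_ids),
                 mark_type = mark_type),
            class = "landmark_dataset")
}

#' Number of configurations in a dataset
#' @param dataset a \code{landmark_dataset}.
#' @return integer.
#' @export
n_configs <- function(dataset) dim(dataset$coords)[3]

#' Extract one configuration from a dataset
#' @param dataset a \code{landmark_dataset}.
#' @param i index.
#' @return a \code{\link{landmark_config}}.
#' @export
get_config <- function(dataset, i) {
  lb <- dataset$labels[i]
  landmark_config(dataset$coords[, , i, drop = TRUE],
                  specimen_id = dataset$specimen_ids[i],
                  class_label = if (is.na(lb)) NULL else lb,
                  mark_type = dataset$mark_type)
}

#' Subset a landmark dataset
#' @param dataset a \code{landmark_dataset}.
#' @param idx integer or logical index over configurations.
#' @return a \code{landmark_dataset}.
#' @export
subset_dataset <- function(dataset, idx) {
  landmark_dataset(dataset$coords[, , idx, drop = FALSE],
                   labels = dataset$labels[idx],
                   specimen_ids = dataset$specimen_ids[idx],
                   mark_type = dataset$mark_type)
}

#' @export
print.landmark_dataset <- function(x, ...) {
  kd <- dim(x$coords)
  cat("Landmark dataset (", x$mark_type, "): ", kd[3], " configurations, ",
      kd[1], " landmarks x ", kd[2], "D\n", sep = "")
  tb <- table(x$labels, useNA = "ifany")
  cat("  labels:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Derive a class label from a specimen name
#'
#' The deposited-style convention names specimens like \code{"wolf_03"}; the
#' label is the leading alphabetic token. Isolated here so an alternative
#' naming convention is a one-function change.
#'
#' @param name character vector of specimen names.
#' @return character vector of labels (NA where no leading alphabetic token).
#' @export
label_from_name <- function(name) {
  m <- regexpr("^[A-Za-z]+", name)
  out <- rep(NA_character_, length(name))
  out[m > 0] <- regmatches(name, m)
  out
}

# Flatten a k x d x n coordinate array to an n x (k*d) matrix, column-major
# within each configuration (all x, then all y, ...). The single flattening
# convention used throughout the package.
flatten_coords <- function(coords) {
  n <- dim(coords)[3]
  t(vapply(seq_len(n), function(i) as.vector(coords[, , i]),
           numeric(dim(coords)[1] * dim(coords)[2])))
}

# Inverse of flatten_coords for a single configuration.
unflatten_coords <- function(v, k, d) matrix(v, nrow = k, ncol = d)
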