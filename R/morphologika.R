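#' Read a morphologika landmark file
#'
#' Parses the common morphologika dialect: bracketed section keywords
#' (\code{[individuals]}, \code{[landmarks]}, \code{[dimensions]}, optional
#' \code{[names]}, \code{[rawpoints]}), case-insensitive, with
#' whitespace-separated coordinates. Lines beginning with an apostrophe inside the
#' rawpoints block (per-individual comment labels) are ignored. Class labels
#' are derived from individual names via \code{\link{label_from_name}} when a
#' names block is present.
#'
#' @param path path to a morphologika text file.
#' @param mark_type mark type to stamp on the dataset ("generic", "score",
#'   "pit").
#' @return a \code{\link{landmark_dataset}}; individual order is preserved.
#' @export
read_morphologika <- function(path, mark_type = "generic") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_hdr <- grepl("^\\s*\\[[A-Za-z]+\\]\\s*$", lines)
  keys <- tolower(gsub("[^A-Za-z]", "", lines[is_hdr]))
  hdr_at <- which(is_hdr)
  section <- function(key) {
    j <- which(keys == key)
    if (length(j) == 0L) return(NULL)
    if (length(j) > 1L)
      stop("morphologika parse error: duplicated [", key, "] section")
    from <- hdr_at[j] + 1L
    to <- if (j == length(hdr_at)) length(lines) else hdr_at[j + 1L] - 1L
    if (to < from) return(integer(0))
    from:to
  }
  read_count <- function(key) {
    idx <- section(key)
    if (is.null(idx))
      stop("morphologika parse error: missing [", key, "] section")
    vals <- trimws(lines[idx])
    vals <- vals[nzchar(vals)]
    if (length(vals) != 1L || is.na(suppressWarnings(as.integer(vals[1]))))
      stop("morphologika parse error: [", key, "] must contain a single ",
           "integer (line ", idx[1], ")")
    as.integer(vals[1])
  }
  n <- read_count("individuals")
  k <- read_count("landmarks")
  d <- read_count("dimensions")
  if (!d %in% c(2L, 3L))
    stop("morphologika parse error: dimensions must be 2 or 3, got ", d)

  names_idx <- section("names")
  ids <- NULL
  if (!is.null(names_idx)) {
    nm <- trimws(lines[names_idx])
    nm <- nm[nzchar(nm)]
    if (length(nm) != n)
      stop("morphologika parse error: [names] lists ", length(nm),
           " individuals but [individuals] declares ", n)
    ids <- nm
  }

  raw_idx <- section("rawpoints")
  if (is.null(raw_idx))
    stop("morphologika parse error: missing [rawpoints] section")
  raw_lines <- raw_idx[nzchar(trimws(lines[raw_idx])) &
                         !grepl("^\\s*'", lines[raw_idx])]
  if (length(raw_lines) != n * k)
    stop("morphologika parse error: expected ", n * k,
         " coordinate rows (", n, " individuals x ", k,
         " landmarks) but found ", length(raw_lines),
         "; individual ", min(length(raw_lines) %/% k + 1L, n),
         " is incomplete")
  coords <- array(NA_real_, dim = c(k, d, n))
  for (r in seq_along(raw_lines)) {
    ln <- raw_lines[r]
    vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[ln]),
                                                 "\\s+")[[1]]))
    if (length(vals) != d || anyNA(vals))
      stop("morphologika parse error: non-numeric or wrong-arity ",
           "coordinate row at line ", ln)
    i <- (r - 1L) %/% k + 1L
    j <- (r - 1L) %% k + 1L
    coords[j, , i] <- vals
  }
  landmark_dataset(coords,
                   labels = if (is.null(ids)) NULL else label_from_name(ids),
                   specimen_ids = ids, mark_type = mark_type)
}

#' Write a morphologika landmark file
#'
#' Writes the dialect read by \code{\link{read_morphologika}}; coordinates are
#' written with 15 significant digits so a write/read round trip is the
#' identity to well below 1e-9.
#'
#' @param dataset a non-empty \code{\link{landmark_dataset}}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_morphologika <- function(dataset, path) {
  if (!inherits(dataset, "landmark_dataset"))
    stop("dataset must be a landmark_dataset")
  n <- n_configs(dataset)
  if (n == 0L) stop("refusing to write an empty dataset")
  kd <- dim(dataset$coords)
  out <- c("[individuals]", n,
           "[landmarks]", kd[1],
           "[dimensions]", kd[2],
           "[names]", dataset$specimen_ids,
           "[rawpoints]")
  for (i in seq_len(n)) {
    out <- c(out, paste0("' ", dataset$specimen_ids[i]))
    m <- dataset$coords[, , i, drop = TRUE]
    out <- c(out, apply(m, 1, function(row)
      paste(sprintf("%.15g", row), collapse = " ")))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}
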