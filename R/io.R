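## Plain-text interchange formats: a matrix file (header line "n", then 2n
## whitespace-separated rows of n floats at full precision), a rotations CSV
## (index + 9 row-major entries per rotation), and a labels CSV.

#' Read / write a common-lines matrix
#'
#' Plain-text format: first line the image count `n`, then `2n`
#' whitespace-separated rows of `n` floats (full precision). Round-trips are
#' exact to the last bit of the decimal representation used (17 significant
#' digits).
#'
#' @param path File path.
#' @return `read_matrix` returns a 2n x n numeric matrix.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("format error at line 1: empty matrix file")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 2L)
    stop("format error at line 1: header must be an integer image count >= 2")
  if (length(lines) != 2L * n + 1L)
    stop(sprintf("format error: expected %d data rows, found %d",
                 2L * n, length(lines) - 1L))
  A <- matrix(0, 2L * n, n)
  for (r in seq_len(2L * n)) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[r + 1L]),
                                                 "\\s+")[[1L]]))
    if (length(vals) != n || anyNA(vals) || !all(is.finite(vals)))
      stop(sprintf("format error at line %d: expected %d finite numbers",
                   r + 1L, n))
    A[r, ] <- vals
  }
  A
}

#' @rdname read_matrix
#' @param A A 2n x n common-lines matrix.
#' @export
write_matrix <- function(A, path) {
  n <- cl_nimages(A)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(n), con)
  writeLines(apply(A, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  invisible(path)
}

#' Read / write rotation sets as CSV
#'
#' One row per image: `index, r11, r12, ..., r33` (row-major). On read, each
#' row is validated against the rotation invariants at tolerance `tol`;
#' mildly non-orthonormal rows are re-projected to the nearest rotation with
#' a warning, rows beyond tolerance (including reflections, det = -1) are an
#' error.
#'
#' @param path File path.
#' @param tol Validation tolerance on read.
#' @return `read_rotations` returns a list of 3x3 rotation matrices.
#' @export
read_rotations <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, header = TRUE)
  if (ncol(df) != 10L)
    stop("format error: rotations CSV must have 10 columns (index + 9 entries)")
  lapply(seq_len(nrow(df)), function(r) {
    m <- matrix(as.numeric(df[r, 2:10]), 3L, 3L, byrow = TRUE)
    if (!all(is.finite(m)))
      stop(sprintf("format error at data row %d: non-finite entries", r))
    if (det(m) < 0)
      stop(sprintf("format error at data row %d: reflection (det < 0), not a rotation", r))
    err <- max(abs(m %*% t(m) - diag(3)))
    if (err > tol)
      stop(sprintf("format error at data row %d: not a rotation (orthogonality error %.2e)",
                   r, err))
    if (err > 1e-12) {
      warning(sprintf("row %d re-projected to the nearest rotation", r))
      m <- nearest_rotation(m)
    }
    m
  })
}

#' @rdname read_rotations
#' @param rots List of 3x3 rotation matrices.
#' @export
write_rotations <- function(rots, path) {
  rows <- vapply(seq_along(rots), function(i)
    paste(c(i, sprintf("%.17g", as.vector(t(rots[[i]])))), collapse = ","),
    character(1L))
  writeLines(c(paste(c("index", paste0("r", as.vector(t(outer(1:3, 1:3,
    paste0))))), collapse = ","), rows), path)
  invisible(path)
}

#' Read / write image-cluster labels as CSV
#'
#' Two columns: `index, community`.
#'
#' @param path File path.
#' @return `read_labels` returns an integer vector ordered by index.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, header = TRUE)
  if (ncol(df) < 2L) stop("format error: labels CSV needs index,community")
  df <- df[order(df[[1L]]), ]
  as.integer(df[[2L]])
}

#' @rdname read_labels
#' @param labels Integer vector of community ids.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(data.frame(index = seq_along(labels), community = labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
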