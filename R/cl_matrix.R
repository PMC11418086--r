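#' @keywords internal
"_PACKAGE"

## Internal block-matrix helpers. A common-lines matrix for n images is a
## plain 2n x n numeric matrix; block (i, j) is the 2-vector in rows
## {2i-1, 2i} of column j (1-based), holding a representative for the common
## line between images i and j in image i's coordinates. Diagonal blocks are
## identically zero.

cl_nimages <- function(A) {
  if (!is.matrix(A) || !is.numeric(A))
    stop("a common-lines matrix must be a numeric matrix")
  n <- ncol(A)
  if (nrow(A) != 2L * n)
    stop(sprintf("a common-lines matrix must be 2n x n; got %d x %d",
                 nrow(A), ncol(A)))
  n
}

cl_check <- function(A, min_n = 2L) {
  n <- cl_nimages(A)
  if (n < min_n) stop(sprintf("need at least %d images, got %d", min_n, n))
  if (!all(is.finite(A))) stop("common-lines matrix has non-finite entries")
  n
}

## first (odd rows) and second (even rows) components of all blocks, each n x n
.row_idx_cache <- new.env(parent = emptyenv())
row_parity_idx <- function(m, odd) {
  key <- sprintf("%s%d", if (odd) "o" else "e", m)
  hit <- .row_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  .row_idx_cache[[key]] <- seq(if (odd) 1L else 2L, m, by = 2L)
}
odd_rows <- function(A) A[row_parity_idx(nrow(A), TRUE), , drop = FALSE]
even_rows <- function(A) A[row_parity_idx(nrow(A), FALSE), , drop = FALSE]

## n x n matrix of block Euclidean norms
block_norms <- function(A) sqrt(odd_rows(A)^2 + even_rows(A)^2)

## replicate an n x n per-block matrix to 2n x n (each block row doubled)
expand_rows <- function(M) M[rep(seq_len(nrow(M)), each = 2L), , drop = FALSE]

## n x n matrix of blockwise inner products <a_ij, b_ij>
block_inner <- function(A, B) {
  P <- A * B
  odd_rows(P) + even_rows(P)
}

zero_diag_blocks <- function(A) {
  n <- ncol(A)
  idx <- seq_len(n)
  A[cbind(2L * idx - 1L, idx)] <- 0
  A[cbind(2L * idx, idx)] <- 0
  A
}

#' Extract one 2x1 block of a common-lines matrix
#'
#' @param A A 2n x n common-lines matrix.
#' @param i,j Image indices (1-based); block `(i, j)` lives in rows
#'   `2i-1, 2i` of column `j`.
#' @return A length-2 numeric vector.
#' @export
cl_block <- function(A, i, j) {
  n <- cl_nimages(A)
  if (i < 1 || i > n || j < 1 || j > n) stop("block index out of range")
  A[c(2L * i - 1L, 2L * i), j]
}

#' Split a common-lines matrix into its off-diagonal blocks
#'
#' Inverse of [assemble_matrix()]: returns a named list of length-2 vectors,
#' with names `"i,j"` over all ordered pairs `i != j`.
#'
#' @param A A 2n x n common-lines matrix.
#' @return Named list of 2-vectors.
#' @export
extract_blocks <- function(A) {
  n <- cl_nimages(A)
  out <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    out[[sprintf("%d,%d", i, j)]] <- cl_block(A, i, j)
  }
  out
}

#' Assemble a common-lines matrix from per-pair blocks
#'
#' @param blocks Named list of length-2 numeric vectors; names `"i,j"` for all
#'   ordered pairs of distinct images. Missing off-diagonal entries are an
#'   error; diagonal blocks are filled with zeros.
#' @param n Number of images.
#' @return A 2n x n common-lines matrix.
#' @export
assemble_matrix <- function(blocks, n) {
  if (n < 2) stop("`n` must be at least 2")
  A <- matrix(0, 2L * n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    key <- sprintf("%d,%d", i, j)
    b <- blocks[[key]]
    if (is.null(b))
      stop(sprintf("incomplete input: missing block (%d,%d)", i, j))
    if (length(b) != 2L || !all(is.finite(b)))
      stop(sprintf("block (%d,%d) must be a finite length-2 vector", i, j))
    A[c(2L * i - 1L, 2L * i), j] <- b
  }
  A
}
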