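## The common line between images i and j, viewed in 3D, spans the cross
## product of the two viewing axes (the third rows of R_i and R_j). Its
## representative in image i's coordinates is the first two components of
## R_i (r_i x r_j), which collapses to Jt %*% R_i %*% r_j with
## Jt = [[0,-1,0],[1,0,0]]. That convention is frozen here and validated by
## the fixture tests; any globally consistent alternative differs only by
## per-pair signs which downstream scale recovery absorbs.

JTILDE <- matrix(c(0, -1, 0,
                   1, 0, 0), 2, 3, byrow = TRUE)

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Direction of the common line between two views
#'
#' The common line between the Fourier planes of two projection images spans
#' the cross product of the two viewing axes (third rows of the rotations).
#' The vector is returned unnormalised: its length is `|sin|` of the angle
#' between the viewing axes.
#'
#' @param Ri,Rj 3x3 rotation matrices.
#' @param tol Degeneracy tolerance on the cross-product norm.
#' @return A length-3 numeric vector.
#' @export
common_line_direction <- function(Ri, Rj, tol = 1e-10) {
  d <- cross3(Ri[3L, ], Rj[3L, ])
  if (sqrt(sum(d^2)) < tol)
    stop("degenerate pair: viewing axes are parallel, common line undefined")
  d
}

#' Canonical (scale-1) representative of a common line
#'
#' The representative of the common line between images `i` and `j`, expressed
#' in image `i`'s coordinates: the first two components of
#' `Ri %*% common_line_direction(Ri, Rj)`.
#'
#' @inheritParams common_line_direction
#' @return A length-2 numeric vector.
#' @examples
#' pure_block(diag(3), rot_x(90)) # c(-1, 0)
#' @export
pure_block <- function(Ri, Rj, tol = 1e-10) {
  common_line_direction(Ri, Rj, tol = tol) # degeneracy check
  as.vector(JTILDE %*% (Ri %*% Rj[3L, ]))
}

#' Pure common-lines matrix of a rotation tuple
#'
#' Assembles the 2n x n matrix whose block `(i, j)` is [pure_block()] of
#' `(R_i, R_j)` for `i != j` and zero on the diagonal. For generic rotations
#' this matrix has rank exactly 3.
#'
#' @param rots List of 3x3 rotation matrices (length >= 2).
#' @param tol Degeneracy tolerance: pairs whose viewing axes are parallel
#'   (block norm below `tol`) are an error.
#' @return A 2n x n common-lines matrix.
#' @export
pure_matrix <- function(rots, tol = 1e-10) {
  n <- length(rots)
  if (n < 2) stop("need at least 2 rotations")
  f <- factor_pure(rots)
  A <- f$B %*% f$C
  N <- block_norms(A)
  diag(N) <- 1
  if (any(N < tol)) {
    bad <- sort(which(N < tol, arr.ind = TRUE)[1L, ])
    stop(sprintf("degenerate pair (%d,%d): viewing axes are parallel",
                 bad[1L], bad[2L]))
  }
  zero_diag_blocks(A)
}

#' Rank-3 factorization of the pure common-lines matrix
#'
#' Returns the exact factors `B` (2n x 3, stacked 2x3 blocks `Jt %*% R_i`) and
#' `C` (3 x n, columns the viewing axes `t(R_j) %*% e3`) with
#' `B %*% C == pure_matrix(rots)` up to floating point. Each `B_i` has
#' orthonormal rows and each column of `C` is a unit vector.
#'
#' @param rots List of 3x3 rotation matrices (length >= 2).
#' @return A list with components `B` and `C`.
#' @export
factor_pure <- function(rots) {
  n <- length(rots)
  if (n < 2) stop("need at least 2 rotations")
  B <- matrix(0, 2L * n, 3L)
  C <- matrix(0, 3L, n)
  for (i in seq_len(n)) {
    Ri <- rots[[i]]
    if (!is.matrix(Ri) || !all(dim(Ri) == c(3L, 3L)))
      stop(sprintf("rotation %d is not a 3x3 matrix", i))
    B[c(2L * i - 1L, 2L * i), ] <- JTILDE %*% Ri
    C[, i] <- Ri[3L, ]
  }
  list(B = B, C = C)
}
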