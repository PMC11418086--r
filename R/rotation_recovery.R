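## Rotations from an estimated pure common-lines matrix: rank-3 factorize
## A ~ U V by SVD, then find the symmetric 3x3 Gram matrix H = Q Q^T that
## makes the 2x3 blocks of U Q orthonormal pairs (a linear least-squares
## problem in the 6 free entries of H), take Q = P sqrt(D) from the
## eigendecomposition of H, read off two rows of each rotation from U Q,
## complete with a cross product and project to the nearest rotation. The
## orthogonal ambiguity left in Q is exactly the global-rotation fiber; the
## sign of the matrix is the handedness ambiguity, so both A and -A are
## processed.

#' Rank-3 factorization by truncated SVD
#'
#' Factors the best rank-3 approximation of `A` as `U %*% V` with
#' `U = U3 %*% diag(d3)` (2n x 3) and `V = t(V3)` (3 x n).
#'
#' @param A A 2n x n common-lines matrix, n >= 3.
#' @return List with components `U` and `V`.
#' @export
rank3_factor <- function(A) {
  cl_check(A, min_n = 3L)
  s <- svd(A, nu = 3L, nv = 3L)
  if (s$d[3L] <= 1e-12 * s$d[1L])
    stop("degenerate factorization: third singular value is numerically zero")
  list(U = s$u %*% diag(s$d[1:3]), V = t(s$v))
}

#' Solve for the symmetric Gram matrix aligning the row-space factor
#'
#' Minimises `sum_i || U_i H t(U_i) - I2 ||_F^2` over symmetric 3x3 `H`
#' (6 unknowns, 3 independent equations per image) via the normal equations.
#' For a factor of a pure matrix, `H = G^{-1} G^{-T}` reproduces orthonormal
#' block rows exactly.
#'
#' @param U A 2n x 3 factor matrix, n >= 3.
#' @return A list of class `"cl_gram"` with `H` (symmetric 3x3), `eigvals`
#'   (descending), and `residual` (sum of squared equation residuals).
#' @export
solve_gram <- function(U) {
  if (!is.matrix(U) || ncol(U) != 3L || nrow(U) %% 2L != 0L)
    stop("`U` must be a 2n x 3 matrix")
  n <- nrow(U) %/% 2L
  if (n < 3L) stop("need at least 3 images (3n >= 6 equations)")
  ## unknown order: h11, h22, h33, h12, h13, h23
  D <- matrix(0, 3L * n, 6L)
  y <- rep(c(1, 1, 0), n)
  for (i in seq_len(n)) {
    u1 <- U[2L * i - 1L, ]; u2 <- U[2L * i, ]
    rows <- 3L * (i - 1L) + 1:3
    coefrow <- function(a, b) {
      c(a[1L] * b[1L], a[2L] * b[2L], a[3L] * b[3L],
        a[1L] * b[2L] + a[2L] * b[1L],
        a[1L] * b[3L] + a[3L] * b[1L],
        a[2L] * b[3L] + a[3L] * b[2L])
    }
    D[rows[1L], ] <- coefrow(u1, u1)
    D[rows[2L], ] <- coefrow(u2, u2)
    D[rows[3L], ] <- coefrow(u1, u2)
  }
  sv <- svd(D, nu = 0L, nv = 0L)$d
  if (sv[6L] < 1e-10 * sv[1L])
    stop("non-generic input: normal equations for the Gram matrix are singular")
  h <- qr.coef(qr(D), y)
  H <- matrix(c(h[1L], h[4L], h[5L],
                h[4L], h[2L], h[6L],
                h[5L], h[6L], h[3L]), 3L, 3L)
  structure(list(H = H,
                 eigvals = eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                 residual = sum((D %*% h - y)^2)),
            class = "cl_gram")
}

#' Rotations from a rank-3 factor and its Gram matrix
#'
#' Takes `Q = P sqrt(D)` from the eigendecomposition `H = P D t(P)` (flipping
#' the global sign of `H` if two or more eigenvalues are negative, and
#' clamping any remaining tiny negative eigenvalue to zero with a warning),
#' forms `Bhat = U Q`, reads each rotation's first row as the second row of
#' its 2x3 block and second row as minus the first (the inverse of the
#' frozen block convention), completes with a cross product, and projects to
#' the nearest rotation.
#'
#' @param U 2n x 3 factor matrix.
#' @param H Symmetric 3x3 Gram matrix (or its negative).
#' @param clamp_tol Eigenvalues within `clamp_tol * max|eig|` of zero are
#'   clamped silently; larger negative singletons trigger a warning.
#' @return List of n rotation matrices.
#' @export
rotations_from_factors <- function(U, H, clamp_tol = 1e-9) {
  H <- (H + t(H)) / 2
  e <- eigen(H, symmetric = TRUE)
  scale <- max(abs(e$values))
  if (sum(e$values < 0) >= 2L) {
    e$values <- rev(-e$values)
    e$vectors <- e$vectors[, 3:1, drop = FALSE]
  }
  if (any(e$values < -clamp_tol * scale))
    warning("mixed eigenvalue signs in the Gram matrix; clamping and proceeding")
  ## the eigenvector basis is only determined up to column signs; force a
  ## proper rotation so Q carries no reflection (the reflection is the
  ## chirality candidate handled by running the pipeline on -A)
  if (det(e$vectors) < 0) e$vectors[, 3L] <- -e$vectors[, 3L]
  d <- pmax(e$values, 0)
  Q <- e$vectors %*% diag(sqrt(d))
  Bhat <- U %*% Q
  n <- nrow(U) %/% 2L
  lapply(seq_len(n), function(i) {
    r1 <- Bhat[2L * i, ]
    r2 <- -Bhat[2L * i - 1L, ]
    nearest_rotation(rbind(r1, r2, cross3(r1, r2)))
  })
}

#' Recover rotations from an estimated pure common-lines matrix
#'
#' Runs the factor/Gram/extraction pipeline and returns both candidate
#' rotation tuples of the handedness (chirality) pair: the directly
#' recovered tuple and its mirror `J R_i J` with `J = diag(1, 1, -1)`.
#' Which of the two corresponds to the data's true hand is undecidable from
#' common lines. (Note that in this extraction convention, negating the
#' matrix flips an even number of rows in every assembled frame and lands
#' in the same chirality class, so the mirror is formed explicitly rather
#' than by rerunning on `-A`.) Either candidate is determined only up to
#' one global right rotation.
#'
#' @param Ahat A 2n x n common-lines matrix, approximately rank 3.
#' @return A list of class `"cl_rotations"` with components `plus` and
#'   `minus` (each a list of n rotation matrices) and `gram` (the
#'   [solve_gram()] solution).
#' @export
recover_rotations <- function(Ahat) {
  f <- rank3_factor(Ahat)
  g <- solve_gram(f$U)
  plus <- rotations_from_factors(f$U, g$H)
  J <- diag(c(1, 1, -1))
  minus <- lapply(plus, function(R) J %*% R %*% J)
  structure(list(plus = plus, minus = minus, gram = g),
            class = "cl_rotations")
}

#' @export
print.cl_rotations <- function(x, ...) {
  cat(sprintf("Recovered rotations for %d images (both chirality candidates)\n",
              length(x$plus)))
  cat(sprintf("  Gram eigenvalues: %s\n",
              paste(sprintf("%.4g", x$gram$eigvals), collapse = ", ")))
  cat(sprintf("  Gram residual: %.3e\n", x$gram$residual))
  invisible(x)
}
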