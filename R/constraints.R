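## Quadratic constraints on a pure common-lines matrix: one norm equality per
## unordered pair (||a_ij|| = ||a_ji||) and two determinant equalities per
## unordered triple. For a pure matrix with block (i,j) = Jt R_i r_j the
## 2x2 determinant d_i = det[a_ij a_ik] equals the scalar triple product
## det[r_i; r_j; r_k] of the viewing axes, so over a triple {i<j<k} the three
## determinants satisfy d_i = -d_j = d_k; the two independent residuals are
## |d_i + d_j| and |d_j + d_k|. The sign pattern is frozen by oracle tests on
## pure matrices.

## pair/triple index tables are requested for the same small n thousands of
## times during quadruple scoring; memoise them
.index_cache <- new.env(parent = emptyenv())

pair_index <- function(n) {
  key <- sprintf("p%d", n)
  hit <- .index_cache[[key]]
  if (!is.null(hit)) return(hit)
  .index_cache[[key]] <- t(utils::combn(n, 2L))
}

triple_index <- function(n) {
  key <- sprintf("t%d", n)
  hit <- .index_cache[[key]]
  if (!is.null(hit)) return(hit)
  .index_cache[[key]] <- t(utils::combn(n, 3L))
}

## 2x2 block determinants over all triples; rows of `trips` are (i, j, k).
## Returns a 3-column matrix (d_i, d_j, d_k) per triple.
triple_dets <- function(A, trips) {
  O <- odd_rows(A); E <- even_rows(A)
  i <- trips[, 1L]; j <- trips[, 2L]; k <- trips[, 3L]
  di <- O[cbind(i, j)] * E[cbind(i, k)] - E[cbind(i, j)] * O[cbind(i, k)]
  dj <- O[cbind(j, i)] * E[cbind(j, k)] - E[cbind(j, i)] * O[cbind(j, k)]
  dk <- O[cbind(k, i)] * E[cbind(k, j)] - E[cbind(k, i)] * O[cbind(k, j)]
  cbind(di, dj, dk)
}

#' Pairwise norm residuals
#'
#' One residual `| ||a_ij|| - ||a_ji|| |` for every unordered pair `{i, j}`,
#' in lexicographic pair order. All residuals vanish on a pure common-lines
#' matrix.
#'
#' @param A A 2n x n common-lines matrix, n >= 2.
#' @return Numeric vector of length `n(n-1)/2`.
#' @export
norm_residuals <- function(A) {
  n <- cl_check(A, min_n = 2L)
  N <- block_norms(A)
  P <- pair_index(n)
  abs(N[P] - N[P[, c(2L, 1L), drop = FALSE]])
}

#' Triple-wise determinant residuals
#'
#' For each unordered triple `{i < j < k}`, with `d_i = det[a_ij a_ik]`,
#' `d_j = det[a_ji a_jk]`, `d_k = det[a_ki a_kj]`, emits the two residuals
#' `|d_i + d_j|` and `|d_j + d_k|` (consecutively, triples in lexicographic
#' order). Both vanish on a pure common-lines matrix, where the three
#' determinants equal `+/-` the scalar triple product of the viewing axes.
#'
#' @param A A 2n x n common-lines matrix, n >= 3.
#' @return Numeric vector of length `2 * choose(n, 3)`.
#' @export
det_residuals <- function(A) {
  n <- cl_check(A, min_n = 3L)
  trips <- triple_index(n)
  D <- triple_dets(A, trips)
  as.vector(t(cbind(abs(D[, 1L] + D[, 2L]), abs(D[, 2L] + D[, 3L]))))
}

#' Number of quadratic constraints on a pure common-lines matrix
#'
#' The norm-equality family contributes one equation per unordered pair and
#' the determinant family two per unordered triple:
#' `n(n-1)/2 + 2*choose(n,3)`.
#'
#' @param n Number of images (integer >= 3).
#' @return Integer constraint count.
#' @examples
#' count_quadratic_constraints(3) # 5
#' count_quadratic_constraints(4) # 14
#' @export
count_quadratic_constraints <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n != round(n) || n < 3)
    stop("`n` must be an integer >= 3")
  as.integer(n * (n - 1) / 2 + 2 * choose(n, 3))
}

#' Third and fourth singular values
#'
#' The numerical rank-3 test: a consistent (pure) common-lines matrix has
#' `sigma4/sigma3` at floating-point level, while generic matrices do not.
#' `sigma4` is defined as 0 when the matrix has fewer than 4 singular values.
#'
#' @param A A 2n x n common-lines matrix, n >= 2.
#' @return Named list with `sigma3` and `sigma4`.
#' @export
rank3_gap <- function(A) {
  cl_check(A, min_n = 2L)
  d <- svd(A, nu = 0L, nv = 0L)$d
  list(sigma3 = d[3L], sigma4 = if (length(d) >= 4L) d[4L] else 0)
}

#' Aggregate quadratic-constraint error
#'
#' Root-mean-square of the concatenated norm and determinant residuals, after
#' rescaling the matrix to Frobenius norm `sqrt(n(n-1))` so the score is
#' scale-invariant and comparable across samples of different size. RMS (not
#' max) is used for robustness when the score drives clustering.
#'
#' @param A A 2n x n common-lines matrix, n >= 3.
#' @return Nonnegative scalar; ~0 iff the quadratic constraints hold.
#' @export
quadratic_error <- function(A) {
  n <- cl_check(A, min_n = 3L)
  fr <- sqrt(sum(A^2))
  if (fr == 0) stop("undefined for the zero matrix")
  As <- A * (sqrt(n * (n - 1)) / fr)
  r <- c(norm_residuals(As), det_residuals(As))
  sqrt(mean(r^2))
}

#' Full constraint report for a common-lines matrix
#'
#' Bundles the norm residuals, determinant residuals, third/fourth singular
#' values and the aggregate scale-invariant error into one object, suitable
#' for JSON serialisation.
#'
#' @param A A 2n x n common-lines matrix, n >= 3.
#' @return A list of class `"cl_constraint_report"`.
#' @export
constraint_report <- function(A) {
  g <- rank3_gap(A)
  structure(list(
    norm_residuals = norm_residuals(A),
    det_residuals = det_residuals(A),
    sigma3 = g$sigma3,
    sigma4 = g$sigma4,
    aggregate_error = quadratic_error(A)
  ), class = "cl_constraint_report")
}

#' @export
print.cl_constraint_report <- function(x, ...) {
  cat("Common-lines constraint report\n")
  cat(sprintf("  norm residuals : %d (max %.3e)\n",
              length(x$norm_residuals), max(x$norm_residuals)))
  cat(sprintf("  det residuals  : %d (max %.3e)\n",
              length(x$det_residuals), max(x$det_residuals)))
  cat(sprintf("  sigma3 = %.3e, sigma4 = %.3e (ratio %.3e)\n",
              x$sigma3, x$sigma4,
              if (x$sigma3 > 0) x$sigma4 / x$sigma3 else NA_real_))
  cat(sprintf("  aggregate error: %.3e\n", x$aggregate_error))
  invisible(x)
}
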