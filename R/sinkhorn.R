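## Alternating row/column scaling onto the quadratic-constraint set.
##
## Scaling block-row i by lambda_i multiplies every determinant d_i over a
## triple containing i by lambda_i^2, so the determinant constraint
## d_i lambda_i^2 + d_j lambda_j^2 = 0 becomes linear after taking signed
## square roots: lambda_i sr(d_i) + lambda_j sr(d_j) = 0 with
## sr(x) = sign(x) sqrt(|x|). Scaling column j by mu_j multiplies d_i (over
## triple {i,j,k}) by mu_j mu_k; dividing by the common factor leaves
## equations linear in mu. Norm constraints are linear in both cases. Each
## solve takes the right singular vector of the smallest singular value,
## sign-fixed so the entry sum is nonnegative.
##
## Convergence requires care: for a row/column-scaled pure matrix the row
## system (norms + signed-root determinant rows) has its null vector at a
## *half-power* of the column corruption, so alternation contracts, but the
## linear-in-mu determinant rows respond at the *square* of the row
## corruption and amplify if they dominate the column solve. The column
## solve therefore downweights its determinant rows (they are kept for
## their sign information), and one determinant-only column solve up front
## fixes the column signs, which norms cannot see. Per-block-row sign flips
## are invisible to every constraint (a row-flipped pure matrix is the pure
## matrix of an in-plane-rotated tuple), so they are a gauge this step
## neither can nor needs to fix.

signed_root <- function(x) sign(x) * sqrt(abs(x))

## Homogeneous system whose null vector holds the row (or column) scales.
## Rows: one per unordered pair (norm constraints, weight `norm_weight`)
## plus two per unordered triple (determinant constraints, weight
## `det_weight`).
scale_system <- function(A, type = "row", norm_weight = 1,
                         det_weight = 1) {
  n <- ncol(A)
  N <- block_norms(A)
  P <- pair_index(n)
  trips <- triple_index(n)
  D <- triple_dets(A, trips)
  np <- nrow(P); nt <- nrow(trips)
  M <- matrix(0, np + 2L * nt, n)
  r <- seq_len(np)
  r1 <- np + seq_len(nt); r2 <- np + nt + seq_len(nt)
  if (type == "row") {
    M[cbind(r, P[, 1L])] <- norm_weight * N[P]
    M[cbind(r, P[, 2L])] <- -norm_weight * N[P[, c(2L, 1L), drop = FALSE]]
    sr <- signed_root(D)
    M[cbind(r1, trips[, 1L])] <- det_weight * sr[, 1L]
    M[cbind(r1, trips[, 2L])] <- det_weight * sr[, 2L]
    M[cbind(r2, trips[, 2L])] <- det_weight * sr[, 2L]
    M[cbind(r2, trips[, 3L])] <- det_weight * sr[, 3L]
  } else {
    M[cbind(r, P[, 2L])] <- norm_weight * N[P]
    M[cbind(r, P[, 1L])] <- -norm_weight * N[P[, c(2L, 1L), drop = FALSE]]
    ## mu_j d_i + mu_i d_j = 0 and mu_k d_j + mu_j d_k = 0 per triple {i<j<k}
    M[cbind(r1, trips[, 2L])] <- det_weight * D[, 1L]
    M[cbind(r1, trips[, 1L])] <- det_weight * D[, 2L]
    M[cbind(r2, trips[, 3L])] <- det_weight * D[, 2L]
    M[cbind(r2, trips[, 2L])] <- det_weight * D[, 3L]
  }
  M
}

smallest_right_singular <- function(M, warn_deficient = TRUE) {
  s <- svd(M)
  n <- ncol(M)
  if (warn_deficient && s$d[1L] > 0 && s$d[n - 1L] < 1e-10 * s$d[1L])
    warning("scaling system is rank-deficient beyond tolerance; scales ambiguous")
  v <- s$v[, n]
  sgn <- sum(v)
  if (sgn == 0) sgn <- v[which.max(abs(v))]
  if (sgn < 0) v <- -v
  v
}

#' One Sinkhorn row-scaling solve
#'
#' Builds the homogeneous linear system (norm rows plus signed-root
#' determinant rows) whose null vector scales the 2-row blocks of `A`
#' towards the quadratic-constraint set, and returns the unit-norm scale
#' vector with the entry-sum sign fixed nonnegative.
#'
#' @param A A 2n x n common-lines matrix, n >= 3.
#' @return Length-n unit-norm scale vector, one scalar per image block-row.
#' @export
row_scale_step <- function(A) smallest_right_singular(scale_system(A, "row"))

#' One Sinkhorn column-scaling solve
#'
#' As [row_scale_step()] for columns. The determinant rows are downweighted
#' relative to the norm rows: they respond quadratically to residual
#' block-row corruption and destabilise the alternation at full weight,
#' while the norm rows alone solve the one-sided column problem exactly.
#'
#' @param A A 2n x n common-lines matrix, n >= 3.
#' @param det_weight Relative weight of the determinant rows.
#' @return Length-n unit-norm column scale vector.
#' @export
col_scale_step <- function(A, det_weight = 0.05) {
  smallest_right_singular(scale_system(A, "col", det_weight = det_weight))
}

apply_row_scales <- function(A, lam) A * rep(lam, each = 2L)
apply_col_scales <- function(A, mu) A * rep(mu, each = nrow(A))

#' Sinkhorn-style scaling onto the quadratic constraints
#'
#' First fixes the column signs with a determinant-only column solve (norms
#' are blind to signs), then alternates row and column scaling solves,
#' applying the scales in place and renormalising to a fixed Frobenius norm
#' (the global scale is unidentifiable), until the aggregate quadratic
#' error stabilises. Row and column scaling by nonzero scalars never
#' changes the rank, so a rank-3 input stays rank 3.
#'
#' @param A A 2n x n common-lines matrix, n >= 3, approximately rank 3 with
#'   nonzero off-diagonal blocks.
#' @param max_iters Maximum alternation rounds.
#' @param tol Stop when the change in [quadratic_error()] drops below this.
#' @param gap_warn Warn if `sigma4/sigma3` of the input exceeds this (the
#'   procedure presumes a numerically rank-3 input).
#' @param col_det_weight Determinant-row weight of the column solves.
#' @return A list of class `"cl_sinkhorn"` with the scaled matrix `Ahat` and
#'   a state list (`lambda_row`, `mu_col`: last unit-norm solves;
#'   `lambda_total`, `mu_total`: accumulated scales; `residual_trace`;
#'   `diverged`; `iterations`). Divergence (vanishing scales, residual
#'   growth beyond 10x the best seen, or non-finite values) is flagged,
#'   never silent.
#' @export
sinkhorn <- function(A, max_iters = 200L, tol = 1e-12, gap_warn = 0.1,
                     col_det_weight = 0.05) {
  n <- cl_check(A, min_n = 3L)
  N <- block_norms(A); diag(N) <- 1
  if (any(N <= 0))
    stop("zero off-diagonal block; cannot scale onto the constraint set")
  g <- rank3_gap(A)
  if (is.finite(g$sigma3) && g$sigma3 > 0 && g$sigma4 / g$sigma3 > gap_warn)
    warning(sprintf("input is not numerically rank 3 (sigma4/sigma3 = %.3g)",
                    g$sigma4 / g$sigma3))
  gauge <- scale_gauge(n)
  A <- A * (gauge / sqrt(sum(A^2)))

  ## column sign fix from the determinant-only column system
  mu0 <- smallest_right_singular(scale_system(A, "col", norm_weight = 0),
                                 warn_deficient = FALSE)
  sgn <- sign(mu0); sgn[sgn == 0] <- 1
  A <- apply_col_scales(A, sgn)
  mu_tot <- sgn
  lam_tot <- rep(1, n)

  err <- quadratic_error(A)
  trace <- err
  lam <- mu <- rep(NA_real_, n)
  diverged <- FALSE
  best <- err

  for (it in seq_len(max_iters)) {
    lam <- row_scale_step(A)
    if (any(abs(lam) < 1e-12) || !all(is.finite(lam))) { diverged <- TRUE; break }
    A <- apply_row_scales(A, lam)
    A <- A * (gauge / sqrt(sum(A^2)))
    lam_tot <- lam_tot * lam

    mu <- col_scale_step(A, det_weight = col_det_weight)
    if (any(abs(mu) < 1e-12) || !all(is.finite(mu))) { diverged <- TRUE; break }
    A <- apply_col_scales(A, mu)
    A <- A * (gauge / sqrt(sum(A^2)))
    mu_tot <- mu_tot * mu

    prev <- err
    err <- quadratic_error(A)
    trace <- c(trace, err)
    if (!is.finite(err)) { diverged <- TRUE; break }
    best <- min(best, err)
    if (err > 10 * max(best, 1e-300) && err > 1e-8) { diverged <- TRUE; break }
    if (abs(prev - err) < tol) break
  }

  structure(list(Ahat = A,
                 state = list(lambda_row = lam, mu_col = mu,
                              lambda_total = lam_tot, mu_total = mu_tot,
                              residual_trace = trace, diverged = diverged,
                              iterations = length(trace) - 1L)),
            class = "cl_sinkhorn")
}

#' @export
print.cl_sinkhorn <- function(x, ...) {
  st <- x$state
  cat(sprintf("Sinkhorn scaling: %d iterations, diverged: %s\n",
              st$iterations, st$diverged))
  cat(sprintf("  quadratic error: %.3e -> %.3e\n",
              st$residual_trace[1L], st$residual_trace[length(st$residual_trace)]))
  invisible(x)
}
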