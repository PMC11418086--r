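## Joint block-scale estimation and rank-3 denoising.
##
## The measured matrix is first normalised so every off-diagonal block has
## unit norm; the unknown per-block scales tau_ij then carry all magnitude
## and sign information. We minimise a robust misfit between the scaled data
## tau o A and a rank-3 surrogate Z by IRLS on the block norms wrapped
## around an ADMM split: primal variables (X, T) with consensus X = Z, the
## rank constraint carried by Z via truncated SVD, and dual ascent on the
## multipliers. Three numerical safeguards matter in practice:
##   * the scale matrix T is kept in a balanced gauge (block-row and column
##     norms equalised, fixed Frobenius norm) — a plain Frobenius gauge
##     admits degenerate zero-cost optima that zero out one image's row and
##     column entirely;
##   * the IRLS regulariser delta follows a homotopy from the initial
##     residual scale downward, so early rounds behave like smooth least
##     squares and later rounds approach the robust loss;
##   * the ADMM penalty is rescaled by the current mean squared weight, so
##     the data term and the consensus term stay commensurate as the
##     weights grow.
## Sign-randomised restarts handle the remaining nonconvexity (block signs
## make the landscape combinatorial); restarting with new initialisations
## is also how divergent runs are handled in practice.

#' ADMM / IRLS parameters for the common-lines denoiser
#'
#' @param rho Base ADMM penalty (> 0); the effective penalty each IRLS round
#'   is `rho` times the mean squared IRLS weight, keeping the data and
#'   consensus terms commensurate.
#' @param delta IRLS regulariser (> 0) for a fixed-regularisation run.
#'   `NULL` (default) uses a homotopy: delta starts at the mean initial
#'   block residual and halves each IRLS round (floored relative to the
#'   current residual level), so the loss hardens gradually.
#' @param outer_iters Number of IRLS reweighting rounds.
#' @param admm_iters Maximum ADMM rounds per IRLS round.
#' @param inner_iters Alternations of the (X, T) block updates per ADMM
#'   round.
#' @param tol Relative-change convergence tolerance.
#' @param restarts Maximum number of sign-randomised restarts when the run
#'   does not reach an exact rank-3 fit with healthy block norms.
#' @param divergence_cap Entry-magnitude cap beyond which a run is flagged
#'   divergent.
#' @return A list of class `"cl_admm_params"`.
#' @export
admm_params <- function(rho = 1, delta = NULL, outer_iters = 30L,
                        admm_iters = 50L, inner_iters = 4L,
                        tol = 1e-8, restarts = 6L, divergence_cap = 1e9) {
  stopifnot(rho > 0, is.null(delta) || delta > 0, outer_iters >= 1,
            admm_iters >= 1, inner_iters >= 1, tol > 0, restarts >= 1,
            divergence_cap > 0)
  structure(list(rho = rho, delta = delta,
                 outer_iters = as.integer(outer_iters),
                 admm_iters = as.integer(admm_iters),
                 inner_iters = as.integer(inner_iters), tol = tol,
                 restarts = as.integer(restarts),
                 divergence_cap = divergence_cap),
            class = "cl_admm_params")
}

#' Rescale all off-diagonal blocks to unit norm
#'
#' @param A A 2n x n common-lines matrix with nonzero off-diagonal blocks.
#' @return A common-lines matrix whose off-diagonal blocks are unit vectors.
#' @export
normalize_blocks <- function(A) {
  n <- cl_check(A, min_n = 2L)
  N <- block_norms(A)
  diag(N) <- 1
  if (any(N == 0)) {
    bad <- which(N == 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("zero off-diagonal block (%d,%d) cannot be normalized",
                 bad[1L], bad[2L]))
  }
  zero_diag_blocks(A / expand_rows(N))
}

## target Frobenius norm for the scale matrix
scale_gauge <- function(n) sqrt(n * (n - 1))

## balanced gauge: equalise row and column norms of T, then fix the
## Frobenius norm; excludes scale matrices that zero out an image
balance_scales <- function(Tm, passes = 2L) {
  n <- ncol(Tm)
  for (p in seq_len(passes)) {
    rn <- sqrt(rowSums(Tm^2) / (n - 1)); rn[rn < 1e-300] <- 1
    Tm <- Tm / rn
    cn <- sqrt(colSums(Tm^2) / (n - 1)); cn[cn < 1e-300] <- 1
    Tm <- Tm * rep(1 / cn, each = n)
  }
  fro <- sqrt(sum(Tm^2))
  if (fro == 0) Tm else Tm * (scale_gauge(n) / fro)
}

## n x n squared block residuals || tau_ij a_ij - z_ij ||^2
block_sq_resid <- function(A_unit, Tm, Z) {
  D <- expand_rows(Tm) * A_unit - Z
  block_inner(D, D)
}

#' IRLS weights for the robust block misfit
#'
#' `w_ij = 1 / sqrt(||tau_ij a_ij - z_ij||^2 + delta^2)` off the diagonal,
#' zero on the diagonal. The regulariser `delta` keeps the weights finite at
#' exact fits.
#'
#' @param A_unit Unit-block common-lines matrix.
#' @param Tm n x n scale matrix (zero diagonal).
#' @param Z 2n x n surrogate matrix.
#' @param delta Positive regulariser.
#' @return n x n weight matrix.
#' @export
irls_weights <- function(A_unit, Tm, Z, delta) {
  stopifnot(delta > 0)
  W <- 1 / sqrt(block_sq_resid(A_unit, Tm, Z) + delta^2)
  diag(W) <- 0
  W
}

#' Closed-form block-scale update
#'
#' For unit blocks the least-squares scale of `x_ij` on `a_ij` is the inner
#' product `tau_ij = <a_ij, x_ij>`; the scale matrix is then renormalised
#' into the balanced gauge (block-row and column norms equalised, Frobenius
#' norm `sqrt(n(n-1))`), which fixes the unidentifiable global scale and
#' rules out the degenerate solution that zeroes an image out of the
#' problem.
#'
#' @param A_unit Unit-block common-lines matrix.
#' @param X Current denoised estimate (2n x n).
#' @return A list with the scale matrix `T` and a `degenerate` flag (set,
#'   with a warning, when `X` is identically zero so no scale is defined).
#' @export
update_scales <- function(A_unit, X) {
  n <- cl_check(A_unit, min_n = 2L)
  Tm <- block_inner(A_unit, X)
  diag(Tm) <- 0
  if (sum(Tm^2) == 0) {
    warning("all block scales vanished; scale update is degenerate")
    return(list(T = Tm, degenerate = TRUE))
  }
  list(T = balance_scales(Tm), degenerate = FALSE)
}

## best rank-3 approximation by truncated SVD
svd_rank3 <- function(M) {
  s <- svd(M, nu = 3L, nv = 3L)
  s$u %*% (s$d[1:3] * t(s$v))
}

#' One full ADMM round
#'
#' Runs `inner_iters` alternations of the closed-form X-update (with
#' diagonal blocks projected to zero) and the scale update, then the rank-3
#' singular value projection for Z and the dual ascent step.
#'
#' @param A_unit Unit-block common-lines matrix.
#' @param state List with elements `X`, `T`, `Z`, `Gamma`, `W`, `rho` (the
#'   effective penalty for the current IRLS round).
#' @param params An [admm_params()] object.
#' @return The updated state; `diverged` is set on non-finite values.
#' @export
admm_round <- function(A_unit, state, params) {
  rho <- state$rho
  W2 <- expand_rows(state$W^2)
  Tm <- state$T
  X <- state$X
  for (it in seq_len(params$inner_iters)) {
    X <- (W2 * (expand_rows(Tm) * A_unit) + rho * state$Z - state$Gamma) /
      (W2 + rho)
    X <- zero_diag_blocks(X)
    ## inlined scale update (no re-validation in the hot path)
    Tm <- block_inner(A_unit, X)
    diag(Tm) <- 0
    if (sum(Tm^2) == 0) break
    Tm <- balance_scales(Tm)
  }
  if (!all(is.finite(X)) || max(abs(X)) > params$divergence_cap) {
    state$diverged <- TRUE
    return(state)
  }
  Z <- svd_rank3(X + state$Gamma / rho)
  Gamma <- state$Gamma + rho * (X - Z)
  state$X <- X; state$T <- Tm; state$Z <- Z; state$Gamma <- Gamma
  state$diverged <- !all(is.finite(Z))
  state
}

## one complete IRLS-ADMM run from a given scale initialisation
irls_admm_once <- function(A_unit, T0, params) {
  n <- ncol(A_unit)
  off <- which(row(diag(n)) != col(diag(n)))
  Tm <- T0
  X <- expand_rows(Tm) * A_unit
  Z <- svd_rank3(X)
  state <- list(X = X, T = Tm, Z = Z, Gamma = matrix(0, 2L * n, n),
                W = NULL, rho = params$rho, diverged = FALSE)
  R2 <- block_sq_resid(A_unit, Tm, Z)
  fixed_delta <- !is.null(params$delta)
  delta <- if (fixed_delta) params$delta else max(mean(sqrt(R2[off])), 1e-8)
  objective <- numeric(0L)
  converged <- FALSE

  ## an initialisation that already fits rank 3 exactly is a solution
  fit0 <- sqrt(sum((expand_rows(Tm) * A_unit - Z)^2)) /
    max(sqrt(sum(Z^2)), 1e-300)
  if (fit0 < 1e-12) {
    N <- block_norms(state$X)
    offN <- N[off]
    return(list(state = state, objective = sum(sqrt(R2[off] + delta^2)),
                converged = TRUE, fit = fit0,
                min_block = if (mean(offN) > 0) min(offN) / mean(offN) else 0,
                delta = delta))
  }

  for (outer in seq_len(params$outer_iters)) {
    state$W <- irls_weights(A_unit, state$T, state$Z, delta)
    state$rho <- params$rho * mean(state$W[off]^2)
    for (ad in seq_len(params$admm_iters)) {
      Xprev <- state$X
      state <- admm_round(A_unit, state, params)
      if (state$diverged) break
      xn <- sqrt(sum(state$X^2))
      if (xn > 0 &&
          sqrt(sum((state$X - Xprev)^2)) / xn < params$tol) break
    }
    if (state$diverged) break
    R2 <- block_sq_resid(A_unit, state$T, state$Z)
    objective <- c(objective, sum(sqrt(R2[off] + delta^2)))
    fit <- sqrt(sum((expand_rows(state$T) * A_unit - state$Z)^2)) /
      max(sqrt(sum(state$Z^2)), 1e-300)
    if (fit < 1e-13) { converged <- TRUE; break }
    if (outer > 1L &&
        abs(objective[length(objective)] - objective[length(objective) - 1L]) <=
        params$tol * max(objective[length(objective)], 1e-300)) {
      converged <- TRUE
      break
    }
    if (!fixed_delta)
      delta <- max(0.5 * delta, 1e-3 * mean(sqrt(R2[off])), 1e-14)
  }

  fit <- sqrt(sum((expand_rows(state$T) * A_unit - state$Z)^2)) /
    max(sqrt(sum(state$Z^2)), 1e-300)
  N <- block_norms(state$X)
  offN <- N[off]
  min_block <- if (mean(offN) > 0) min(offN) / mean(offN) else 0
  list(state = state, objective = objective, converged = converged,
       fit = fit, min_block = min_block, delta = delta)
}

#' Direct estimate of block norms from unit-normalised data
#'
#' On a unit-normalised consistent common-lines matrix the 2x2 block
#' determinants over a triple satisfy
#' `|d'_i| = D_t / (N_ij * N_ik)` where `N` are the (symmetric) block norms
#' of the underlying pure matrix and `D_t` is the triple's common
#' determinant magnitude. Taking logs gives a sparse linear system in the
#' log-norms (and one log-determinant per triple), solved here in the
#' minimum-norm least-squares sense; the one-dimensional kernel is the
#' immaterial global scale. The normalised residual is a cheap consistency
#' score: it vanishes on consistent samples and is order one on mixtures.
#'
#' @param A_unit Unit-block common-lines matrix, n >= 4 (the system is
#'   underdetermined at n = 3).
#' @return A list with `N` (symmetric positive norm matrix, zero diagonal)
#'   and `resid` (root-mean-square log-equation residual).
#' @export
estimate_block_norms <- function(A_unit) {
  n <- cl_check(A_unit, min_n = 4L)
  trips <- triple_index(n)
  D <- triple_dets(A_unit, trips)
  if (any(D == 0)) D[D == 0] <- 1e-300   # degenerate block pair
  nt <- nrow(trips)
  P <- pair_index(n)
  np <- nrow(P)
  pid <- matrix(0L, n, n)
  pid[P] <- seq_len(np)
  pid[P[, c(2L, 1L), drop = FALSE]] <- seq_len(np)
  M <- matrix(0, 3L * nt, np + nt)
  y <- numeric(3L * nt)
  r <- 0L
  for (t in seq_len(nt)) {
    tri <- trips[t, ]
    for (base in 1:3) {
      oth <- tri[-base]
      r <- r + 1L
      M[r, np + t] <- 1
      M[r, pid[tri[base], oth[1L]]] <- M[r, pid[tri[base], oth[1L]]] - 1
      M[r, pid[tri[base], oth[2L]]] <- M[r, pid[tri[base], oth[2L]]] - 1
      y[r] <- log(abs(D[t, base]))
    }
  }
  s <- svd(M)
  dinv <- ifelse(s$d > 1e-10 * s$d[1L], 1 / s$d, 0)
  sol <- s$v %*% (dinv * (t(s$u) %*% y))
  N <- matrix(0, n, n)
  N[P] <- exp(sol[seq_len(np)])
  N[P[, c(2L, 1L), drop = FALSE]] <- N[P]
  list(N = N, resid = sqrt(mean((M %*% sol - y)^2)))
}

#' Polish block scales by uniform-weight alternation
#'
#' Refines a scale matrix by alternating the exact least-squares scale
#' update with the rank-3 projection, with uniform weights (the smooth
#' limit of the robust loss). On consistent data this converges linearly to
#' an exact rank-3 fit; it is used to sharpen a denoiser solution once the
#' robust phase has resolved signs and outliers.
#'
#' @param A_unit Unit-block common-lines matrix.
#' @param Tm Starting n x n scale matrix.
#' @param iters Number of alternations.
#' @return A list with the refined `T` and the relative rank-3 misfit
#'   `fit`.
#' @export
polish_scales <- function(A_unit, Tm, iters = 80L) {
  for (k in seq_len(iters)) {
    Z <- zero_diag_blocks(svd_rank3(expand_rows(Tm) * A_unit))
    Tm <- block_inner(A_unit, Z)
    diag(Tm) <- 0
    if (sum(Tm^2) == 0) break
    Tm <- balance_scales(Tm)
  }
  X <- expand_rows(Tm) * A_unit
  Z <- svd_rank3(X)
  list(T = Tm, fit = sqrt(sum((X - Z)^2)) / max(sqrt(sum(Z^2)), 1e-300))
}

#' Denoise a common-lines matrix by IRLS-ADMM
#'
#' Jointly estimates per-block scales and a rank-3 matrix minimising a
#' robust misfit to the unit-normalised data. On consistent input (a pure
#' matrix corrupted by arbitrary nonzero per-block scales and signs) the
#' result has blocks proportional to the pure blocks with a rank-1
#' structured scale matrix, so the subsequent Sinkhorn step can reach a pure
#' matrix. The block-sign landscape is combinatorial, so when a run fails to
#' reach an exact rank-3 fit with healthy block norms the solver restarts
#' from sign-randomised scale initialisations (up to `params$restarts`
#' attempts) and returns the best attempt.
#'
#' @param A A 2n x n common-lines matrix, n >= 3, all off-diagonal blocks
#'   nonzero.
#' @param params An [admm_params()] object.
#' @param seed Optional integer seed for the restart initialisations (the
#'   first attempt is always deterministic).
#' @param T0 Optional n x n initial scale matrix (e.g. from
#'   [estimate_block_norms()]); defaults to all ones off the diagonal.
#'   Restarts keep its magnitudes and randomise block signs.
#' @return A list of class `"cl_denoise"` with components `X` (denoised
#'   2n x n matrix, zero diagonal blocks), `T` (n x n scale matrix), `Z`,
#'   `objective_trace` (robust objective per IRLS round of the returned
#'   attempt), `converged`, `diverged`, `fit` (relative rank-3 misfit),
#'   `attempts`, `iterations`.
#' @export
irls_admm <- function(A, params = admm_params(), seed = NULL, T0 = NULL) {
  n <- cl_check(A, min_n = 3L)
  A_unit <- normalize_blocks(A)
  if (!is.null(seed)) set.seed(seed)
  base_mag <- if (is.null(T0)) matrix(1, n, n) else abs(T0)
  base_sign <- if (is.null(T0)) matrix(1, n, n) else {
    s <- sign(T0); s[s == 0] <- 1; s
  }
  best <- NULL
  attempts <- 0L
  for (r in seq_len(params$restarts)) {
    attempts <- r
    Tinit <- base_mag * base_sign
    if (r > 1L)
      Tinit <- base_mag * matrix(sample(c(-1, 1), n * n, replace = TRUE), n)
    diag(Tinit) <- 0
    run <- irls_admm_once(A_unit, Tinit, params)
    ## A restart only replaces the deterministic first attempt when it is
    ## materially better: per-block-row sign flips are a gauge of the
    ## rank-3 fit, so restarts of merely equal quality would randomise the
    ## sign gauge of data whose signs were consistent to begin with.
    if (is.null(best) ||
        (!run$state$diverged &&
         (best$state$diverged || run$fit < 0.5 * best$fit ||
          (best$min_block <= 0.05 && run$min_block > 0.05 &&
           run$fit < 2 * best$fit))))
      best <- run
    if (!best$state$diverged && best$fit < 1e-10 && best$min_block > 0.05)
      break
  }
  st <- best$state
  structure(list(X = zero_diag_blocks(st$X), T = st$T, Z = st$Z,
                 objective_trace = best$objective,
                 converged = best$converged && !st$diverged,
                 diverged = st$diverged,
                 fit = best$fit, min_block = best$min_block,
                 attempts = attempts,
                 iterations = length(best$objective), delta = best$delta,
                 params = params),
            class = "cl_denoise")
}

#' @export
print.cl_denoise <- function(x, ...) {
  cat(sprintf("IRLS-ADMM denoising: n = %d images\n", ncol(x$X)))
  cat(sprintf("  IRLS rounds: %d (attempt %d), converged: %s, diverged: %s\n",
              x$iterations, x$attempts, x$converged, x$diverged))
  cat(sprintf("  relative rank-3 misfit: %.3e\n", x$fit))
  if (length(x$objective_trace))
    cat(sprintf("  objective: %.6e -> %.6e\n",
                x$objective_trace[1L],
                x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}
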