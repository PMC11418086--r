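#' Fit the common-lines model to a measured matrix
#'
#' The central estimator of the package. Given a measured common-lines
#' matrix (arbitrary per-block scales and signs, angular noise, outliers),
#' `cl_fit` (i) normalises the blocks, (ii) jointly estimates block scales
#' and a rank-3 denoised matrix by IRLS-ADMM, (iii) optionally scales rows
#' and columns onto the quadratic-constraint set (Sinkhorn), and (iv)
#' recovers the two chirality candidates for the underlying rotations. The
#' result is a classed object with the usual modelling verbs.
#'
#' @param A A 2n x n common-lines matrix, n >= 3.
#' @param admm An [admm_params()] object controlling the denoiser.
#' @param seed Optional integer seed for the denoiser's restart
#'   initialisations.
#' @param scale_correct Run the Sinkhorn constraint-scaling step (the step
#'   can be numerically delicate at high noise; when it diverges the
#'   denoised matrix is used for rotation recovery instead and the flag is
#'   recorded).
#' @param sinkhorn_iters,sinkhorn_tol Sinkhorn settings.
#' @return An object of class `"cl_fit"`: list with `A` (input),
#'   `denoise` (the [irls_admm()] result), `sinkhorn` (or `NULL`), `Ahat`
#'   (final pure-matrix estimate), `rotations` (the [recover_rotations()]
#'   pair), `report` (a [constraint_report()] of `Ahat`), `n`, `call`.
#' @examples
#' rots <- random_rotations(6, seed = 2)
#' A <- corrupt_matrix(pure_matrix(rots), noise_spec(seed = 3))
#' fit <- cl_fit(A)
#' print(fit)
#' procrustes_align(rots, coef(fit, "plus"))
#' @export
cl_fit <- function(A, admm = admm_params(), scale_correct = TRUE,
                   sinkhorn_iters = 200L, sinkhorn_tol = 1e-12, seed = NULL) {
  n <- cl_check(A, min_n = 3L)
  den <- irls_admm(A, admm, seed = seed)
  sk <- NULL
  Ahat <- den$X
  if (scale_correct && !den$diverged) {
    sk <- tryCatch(
      suppressWarnings(sinkhorn(den$X, max_iters = sinkhorn_iters,
                                tol = sinkhorn_tol)),
      error = function(e) NULL)
    if (!is.null(sk) && !sk$state$diverged) Ahat <- sk$Ahat
  }
  rot <- recover_rotations(Ahat)
  structure(list(A = A, denoise = den, sinkhorn = sk, Ahat = Ahat,
                 rotations = rot, report = constraint_report(Ahat),
                 n = n, call = match.call()),
            class = "cl_fit")
}

#' @export
print.cl_fit <- function(x, ...) {
  cat("Common-lines fit\n")
  cat(sprintf("  images: %d\n", x$n))
  cat(sprintf("  denoiser: %d IRLS rounds, converged %s, diverged %s\n",
              x$denoise$iterations, x$denoise$converged, x$denoise$diverged))
  if (!is.null(x$sinkhorn))
    cat(sprintf("  sinkhorn: %d iterations, diverged %s\n",
                x$sinkhorn$state$iterations, x$sinkhorn$state$diverged))
  else cat("  sinkhorn: skipped\n")
  cat(sprintf("  quadratic error of estimate: %.3e\n",
              x$report$aggregate_error))
  g <- x$report
  cat(sprintf("  rank-3 gap sigma4/sigma3: %.3e\n",
              if (g$sigma3 > 0) g$sigma4 / g$sigma3 else NA_real_))
  invisible(x)
}

#' @export
summary.cl_fit <- function(object, ...) {
  print(object)
  cat("\nConstraint residuals of the estimate:\n")
  r <- c(object$report$norm_residuals, object$report$det_residuals)
  print(summary(r))
  if (length(object$denoise$objective_trace) > 1L) {
    tr <- object$denoise$objective_trace
    cat(sprintf("\nDenoiser objective: %.6e -> %.6e over %d rounds\n",
                tr[1L], tr[length(tr)], length(tr)))
  }
  invisible(object)
}

#' Extract recovered rotations from a fit
#'
#' @param object A `cl_fit`.
#' @param chirality Which candidate of the handedness pair, `"plus"` or
#'   `"minus"` (indistinguishable from common lines alone).
#' @param ... Unused.
#' @return A list of 3x3 rotation matrices.
#' @export
coef.cl_fit <- function(object, chirality = c("plus", "minus"), ...) {
  chirality <- match.arg(chirality)
  object$rotations[[chirality]]
}

#' @export
fitted.cl_fit <- function(object, ...) object$Ahat

#' Constraint residuals of the fitted pure-matrix estimate
#'
#' @param object A `cl_fit`.
#' @param type `"all"` (default), `"norm"` or `"det"`.
#' @param ... Unused.
#' @export
residuals.cl_fit <- function(object, type = c("all", "norm", "det"), ...) {
  type <- match.arg(type)
  switch(type,
         norm = object$report$norm_residuals,
         det = object$report$det_residuals,
         all = c(object$report$norm_residuals, object$report$det_residuals))
}

#' Pure common-lines matrix implied by the recovered rotations
#'
#' @param object A `cl_fit`.
#' @param chirality Passed to [coef.cl_fit()].
#' @param ... Unused.
#' @return A 2n x n pure common-lines matrix.
#' @export
predict.cl_fit <- function(object, chirality = c("plus", "minus"), ...) {
  pure_matrix(coef(object, chirality))
}

#' Simulate corrupted matrices from a fitted model
#'
#' Draws `nsim` fresh corrupted common-lines matrices from the pure matrix
#' implied by the recovered rotations, using the given corruption spec.
#'
#' @param object A `cl_fit`.
#' @param nsim Number of matrices.
#' @param seed Optional seed.
#' @param spec A [noise_spec()] (its own seed field is ignored).
#' @param ... Unused.
#' @return List of `nsim` matrices.
#' @export
simulate.cl_fit <- function(object, nsim = 1L, seed = NULL,
                            spec = noise_spec(), ...) {
  if (!is.null(seed)) set.seed(seed)
  spec$seed <- NULL
  base <- predict(object)
  lapply(seq_len(nsim), function(k) corrupt_matrix(base, spec))
}

#' Diagnostic plots for a common-lines fit
#'
#' Two panels: the denoiser objective trace and the singular-value spectrum
#' of the final estimate (a consistent estimate shows three dominant values).
#'
#' @param x A `cl_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cl_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  tr <- x$denoise$objective_trace
  graphics::plot(seq_along(tr), tr, type = "b", xlab = "IRLS round",
                 ylab = "robust objective", main = "Denoiser objective", ...)
  d <- svd(x$Ahat, nu = 0L, nv = 0L)$d
  graphics::plot(seq_along(d), d, type = "h", log = "y",
                 xlab = "index", ylab = "singular value",
                 main = "Spectrum of estimate", ...)
  invisible(x)
}

#' Cluster interface in the modelling idiom
#'
#' Thin classed wrapper over [cluster_common_lines()]; see that function for
#' details.
#'
#' @inheritParams cluster_common_lines
#' @return A `cl_clusters` object.
#' @export
cl_cluster <- function(A, budget = NULL, seed = NULL,
                       params = cluster_params()) {
  cluster_common_lines(A, budget = budget, seed = seed, params = params)
}
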