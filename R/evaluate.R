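## Evaluation metrics: Procrustes rotation error with the global-rotation
## gauge removed, per-image angular error, scale-invariant matrix denoising
## error, and the adjusted Rand index for clustering.

#' Align two rotation sets by orthogonal Procrustes
#'
#' Finds the global right rotation `O` minimising
#' `sum_i || R_i O - Rhat_i ||_F^2` (via the SVD of `sum_i t(R_i) Rhat_i`
#' with determinant correction) and reports per-image squared Frobenius
#' errors, per-image angular errors, the total, and the per-image average.
#'
#' @param truth,estimate Lists of 3x3 rotation matrices of equal length.
#' @return A list of class `"cl_procrustes"`: `O`, `total_error`,
#'   `avg_error` (total divided by n), `per_image_error`,
#'   `per_image_angle_deg`.
#' @export
procrustes_align <- function(truth, estimate) {
  if (length(truth) != length(estimate) || length(truth) < 1L)
    stop("`truth` and `estimate` must be nonempty lists of equal length")
  M <- Reduce(`+`, Map(function(R, Rh) t(R) %*% Rh, truth, estimate))
  s <- svd(M)
  O <- s$u %*% diag(c(1, 1, sign(det(s$u %*% t(s$v))))) %*% t(s$v)
  per <- mapply(function(R, Rh) sum((R %*% O - Rh)^2), truth, estimate)
  ang <- mapply(function(R, Rh) angular_error(R %*% O, Rh), truth, estimate)
  structure(list(O = O, total_error = sum(per), avg_error = mean(per),
                 per_image_error = per, per_image_angle_deg = ang),
            class = "cl_procrustes")
}

#' @export
print.cl_procrustes <- function(x, ...) {
  cat(sprintf("Procrustes alignment over %d rotations\n",
              length(x$per_image_error)))
  cat(sprintf("  total error %.6e, per-image %.6e\n",
              x$total_error, x$avg_error))
  cat(sprintf("  angular error (deg): median %.4g, max %.4g\n",
              stats::median(x$per_image_angle_deg),
              max(x$per_image_angle_deg)))
  invisible(x)
}

#' Angle between two rotations
#'
#' The geodesic angle `acos((tr(t(R1) R2) - 1) / 2)` in degrees, with the
#' argument clamped to `[-1, 1]`. Satisfies
#' `||R1 - R2||_F^2 = 4 (1 - cos(theta))`.
#'
#' @param R1,R2 3x3 rotation matrices.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
angular_error <- function(R1, R2) {
  ctheta <- (sum(diag(t(R1) %*% R2)) - 1) / 2
  acos(min(1, max(-1, ctheta))) * 180 / pi
}

#' Resolve the per-image sign gauge against a reference matrix
#'
#' Flipping the sign of one image's 2-row block of a pure common-lines
#' matrix yields the pure matrix of the tuple with that image rotated 180
#' degrees in-plane: every constraint (rank, norm and determinant
#' equalities) is exactly invariant, so the sign pattern of the block-rows
#' is a discrete gauge that no common-lines computation can determine. When
#' comparing an estimate against a known reference, this helper fixes the
#' gauge by flipping each block-row to the sign that best agrees with the
#' reference.
#'
#' @param Ahat Estimated 2n x n common-lines matrix.
#' @param Aref Reference matrix of the same shape.
#' @return `Ahat` with block-row signs aligned to `Aref`.
#' @export
align_row_signs <- function(Ahat, Aref) {
  cl_nimages(Ahat)
  if (!all(dim(Ahat) == dim(Aref)))
    stop("matrices must have the same shape")
  s <- sign(rowSums(block_inner(Ahat, Aref)))
  s[s == 0] <- 1
  Ahat * rep(s, each = 2L)
}

#' Normalized correlation between two matrices up to the sign gauge
#'
#' `|<Ahat', Aref>| / (||Ahat'|| ||Aref||)` where `Ahat'` is
#' [align_row_signs()] of `Ahat`; equals 1 iff the two matrices are
#' proportional up to block-row sign flips.
#'
#' @inheritParams align_row_signs
#' @return Scalar in `[0, 1]`.
#' @export
gauge_correlation <- function(Ahat, Aref) {
  Ag <- align_row_signs(Ahat, Aref)
  abs(sum(Ag * Aref)) / sqrt(sum(Ag^2) * sum(Aref^2))
}

#' Scale-invariant denoising error between two matrices
#'
#' `min_s || Ahat - s * Atruth ||_F / || Atruth ||_F`, with the closed-form
#' minimiser `s = <Ahat, Atruth> / ||Atruth||^2` (negative `s` allowed: the
#' recovered matrix carries a global sign/scale ambiguity). Zero iff the two
#' matrices are proportional.
#'
#' @param Ahat,Atruth Numeric matrices of the same shape, `Atruth` nonzero.
#' @return Nonnegative scalar.
#' @export
denoising_error <- function(Ahat, Atruth) {
  if (!all(dim(Ahat) == dim(Atruth)))
    stop("matrices must have the same shape")
  nt2 <- sum(Atruth^2)
  if (nt2 == 0) stop("`Atruth` must be nonzero")
  s <- sum(Ahat * Atruth) / nt2
  sqrt(sum((Ahat - s * Atruth)^2) / nt2)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement between two partitions of the
#' same items: 1 for identical partitions (up to relabeling), approximately 0
#' for random assignment.
#'
#' @param labels_a,labels_b Vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("labelings must have equal length")
  as.numeric(mclust::adjustedRandIndex(labels_a, labels_b))
}
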