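## Generators for matrix-level test inputs: per-block scale/sign corruption,
## in-plane angular noise, outlier lines, and heterogeneous mixtures whose
## cross-population blocks are random unit lines hidden by a joint
## permutation.

#' Corruption specification for synthetic common-lines matrices
#'
#' Describes how a clean pure matrix is degraded into something resembling
#' detected data: unknown per-block scales with random signs, angular error
#' on the line representatives (applied as an in-plane rotation, which is how
#' detection error manifests and preserves the block norm), and a fraction of
#' outright outlier lines.
#'
#' @param scale_low,scale_high Range of the absolute per-block scale
#'   (`0 < scale_low <= scale_high`).
#' @param sign_flip_prob Probability of flipping each block's sign.
#' @param angle_sigma_deg Std. dev. of the in-plane angular noise, degrees.
#' @param outlier_frac Fraction of blocks replaced by uniformly random
#'   directions (same norm).
#' @param seed Optional integer seed.
#' @return A list of class `"cl_noise_spec"`.
#' @export
noise_spec <- function(scale_low = 0.5, scale_high = 2, sign_flip_prob = 0.5,
                       angle_sigma_deg = 0, outlier_frac = 0, seed = NULL) {
  stopifnot(scale_low > 0, scale_low <= scale_high,
            sign_flip_prob >= 0, sign_flip_prob <= 1,
            angle_sigma_deg >= 0, outlier_frac >= 0, outlier_frac <= 1)
  structure(list(scale_low = scale_low, scale_high = scale_high,
                 sign_flip_prob = sign_flip_prob,
                 angle_sigma_deg = angle_sigma_deg,
                 outlier_frac = outlier_frac, seed = seed),
            class = "cl_noise_spec")
}

## neutral spec: corrupt_matrix is the identity map
spec_is_neutral <- function(spec) {
  spec$scale_low == 1 && spec$scale_high == 1 && spec$sign_flip_prob == 0 &&
    spec$angle_sigma_deg == 0 && spec$outlier_frac == 0
}

rotate2 <- function(v, theta) {
  c(cos(theta) * v[1L] - sin(theta) * v[2L],
    sin(theta) * v[1L] + cos(theta) * v[2L])
}

#' Corrupt a pure common-lines matrix
#'
#' Independently per off-diagonal block: scale by
#' `tau ~ Uniform[scale_low, scale_high]` with the sign flipped with
#' probability `sign_flip_prob`; rotate in-plane by `N(0, angle_sigma^2)`
#' degrees; and with probability `outlier_frac` replace the block by a
#' uniformly random direction of the same norm. The diagonal is untouched.
#' A neutral spec returns the input unchanged, bit for bit.
#'
#' @param A_pure A 2n x n common-lines matrix.
#' @param spec A [noise_spec()].
#' @return The corrupted 2n x n matrix.
#' @export
corrupt_matrix <- function(A_pure, spec = noise_spec()) {
  n <- cl_check(A_pure, min_n = 2L)
  stopifnot(inherits(spec, "cl_noise_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  A <- A_pure
  m <- n * (n - 1L)          # number of off-diagonal blocks
  off <- which(row(diag(n)) != col(diag(n)))  # column-major linear indices
  tau <- stats::runif(m, spec$scale_low, spec$scale_high)
  if (spec$sign_flip_prob > 0)
    tau <- tau * (1 - 2 * (stats::runif(m) < spec$sign_flip_prob))
  ang <- if (spec$angle_sigma_deg > 0)
    stats::rnorm(m, 0, spec$angle_sigma_deg * pi / 180) else numeric(m)
  is_out <- if (spec$outlier_frac > 0)
    stats::runif(m) < spec$outlier_frac else rep(FALSE, m)
  out_ang <- stats::runif(m, 0, 2 * pi)  # drawn unconditionally: fixed RNG layout

  for (k in seq_len(m)) {
    idx <- off[k]
    i <- (idx - 1L) %% n + 1L
    j <- (idx - 1L) %/% n + 1L
    b <- A[c(2L * i - 1L, 2L * i), j]
    if (is_out[k]) {
      b <- sqrt(sum(b^2)) * c(cos(out_ang[k]), sin(out_ang[k]))
    } else if (spec$angle_sigma_deg > 0) {
      b <- rotate2(b, ang[k])
    }
    A[c(2L * i - 1L, 2L * i), j] <- tau[k] * b
  }
  A
}

#' Heterogeneous mixture of common-lines matrices
#'
#' Builds the synthetic discrete-heterogeneity setting: within-population
#' blocks come from each population's pure common-lines matrix (then
#' corrupted per `spec`); cross-population blocks carry no consistent
#' geometry and are i.i.d. uniformly random unit 2-vectors, as detected
#' representatives would be. One random permutation is applied jointly to
#' block-rows and columns so populations are hidden.
#'
#' @param rotation_sets List of rotation lists, one per population, each of
#'   size >= 3.
#' @param spec A [noise_spec()] applied to each within-population block
#'   (also seeds the cross blocks and the permutation).
#' @return A list with `A` (the permuted 2N x N matrix), `labels` (length-N
#'   integer ground-truth population of each image index), and `perm` (the
#'   permutation used, `labels == unpermuted labels[perm]`).
#' @export
heterogeneous_matrix <- function(rotation_sets, spec = noise_spec()) {
  if (length(rotation_sets) < 1L) stop("need at least one population")
  sizes <- lengths(rotation_sets)
  if (any(sizes < 3L)) stop("every population must have at least 3 rotations")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  spec_inner <- spec
  spec_inner$seed <- NULL   # RNG stream already seeded once here
  N <- sum(sizes)
  A <- matrix(0, 2L * N, N)
  offset <- c(0L, cumsum(sizes))
  labels0 <- rep(seq_along(rotation_sets), sizes)

  for (p in seq_along(rotation_sets)) {
    idx <- offset[p] + seq_len(sizes[p])
    Ap <- corrupt_matrix(pure_matrix(rotation_sets[[p]]), spec_inner)
    A[as.vector(rbind(2L * idx - 1L, 2L * idx)), idx] <- Ap
  }
  ## cross-population blocks: random unit lines
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (labels0[i] == labels0[j]) next
    th <- stats::runif(1L, 0, 2 * pi)
    A[c(2L * i - 1L, 2L * i), j] <- c(cos(th), sin(th))
  }
  perm <- sample.int(N)
  rowsel <- as.vector(rbind(2L * perm - 1L, 2L * perm))
  list(A = A[rowsel, perm, drop = FALSE], labels = labels0[perm], perm = perm)
}

#' @rdname normalize_blocks
#' @export
unit_normalize <- function(A) normalize_blocks(A)
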