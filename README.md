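# commonlines

Algebraically constrained common-lines methods for single-particle cryo-EM,
in R.

## The problem

In single-particle cryo-EM, each particle image is a 2D tomographic
projection of a 3D density at an unknown rotation `R_i ∈ SO(3)`. By the
Fourier slice theorem, the Fourier transforms of any two projections of the
same (asymmetric) molecule agree along one central line — the *common line*
— whose direction in image `i`'s coordinates is the 2-vector
`a_ij = Π(R_i (r_i × r_j))`, where `r_m` is the third row of `R_m` and `Π`
drops the (zero) third coordinate. Common lines are the classical route from
2D class averages to the viewing rotations, but detected lines are noisy and
their per-pair scales and signs are unknown.

This package works with the **common-lines matrix**: the `2n × n` block
matrix `A` whose `2×1` block `(i, j)` holds a representative of the common
line between images `i` and `j` (zero blocks on the diagonal). When every
block carries its canonical scale (the *pure* matrix), `A` enjoys strong
algebraic structure:

* **rank(A) = 3**, via the factorization `A = B C` with
  `B_i = J̃ R_i` (2×3 blocks, `J̃ = [[0,−1,0],[1,0,0]]`) and `c_j = R_jᵀ e₃`;
* `n(n−1)/2` **norm equalities** `‖a_ij‖ = ‖a_ji‖`;
* `2·C(n,3)` **determinant equalities**: for a triple `{i,j,k}`,
  `d_i = det[a_ij a_ik]` equals the scalar triple product of the three
  viewing axes up to sign, so `d_i + d_j = 0` and `d_j + d_k = 0`.

The package provides, on top of this structure:

* **Denoising / scale recovery** (`irls_admm`): jointly estimates per-block
  scales and a rank-3 surrogate by iteratively reweighted least squares
  around an ADMM split, with a balanced scale gauge, a regulariser homotopy
  and sign-randomised restarts.
* **Constraint scaling** (`sinkhorn`): alternately rescales block-rows and
  columns (homogeneous least-squares solves by smallest singular vector)
  until the quadratic constraints hold, yielding a pure-matrix estimate up
  to one global scale and the intrinsic per-image sign gauge.
* **Rotation recovery** (`recover_rotations`): rank-3 factorization by SVD,
  a linear solve for the symmetric Gram matrix that restores orthonormal
  block rows, row extraction and polar projection; returns both chirality
  candidates (`R_i` and `J R_i J`), which common lines cannot distinguish.
* **Heterogeneity clustering** (`cluster_common_lines`): scores random
  4-image subsets by how well their `8×4` submatrix scales onto the
  constraint set, builds a weighted pair graph (`−log` of the smallest
  error over hyperedges containing the pair), runs community detection, and
  refines the partition with targeted probe quadruples.
* **Synthetic data** (`pure_matrix`, `corrupt_matrix`,
  `heterogeneous_matrix`), an analytic **image pipeline**
  (`gaussian_phantom`, `project_phantom`, `detected_matrix`) and
  **metrics** (`procrustes_align`, `denoising_error`,
  `adjusted_rand_index`).

The modelling-style front end is `cl_fit()` (denoise → scale → rotations)
with `print`, `summary`, `coef`, `fitted`, `residuals`, `predict`,
`simulate` and `plot` methods, and `cl_cluster()` for heterogeneous sets.
A thin command-line tool (`exec/commonlines`, subcommands
`simulate-rotations`, `simulate-matrix`, `denoise`, `purify`, `rotations`,
`cluster`, `evaluate`) wraps the same functions.

## Worked example

```r
library(commonlines)

rots  <- random_rotations(6, seed = 2)          # ground-truth viewing angles
Astar <- pure_matrix(rots)                      # 12 x 6 pure matrix
A     <- corrupt_matrix(Astar,                  # unknown per-block scales
                        noise_spec(scale_low = 0.5, scale_high = 2,
                                   sign_flip_prob = 0, seed = 3))

fit <- cl_fit(A, seed = 11)
print(fit)
#> Common-lines fit
#>   images: 6
#>   denoiser: 30 IRLS rounds, converged FALSE, diverged FALSE
#>   sinkhorn: 81 iterations, diverged FALSE
#>   quadratic error of estimate: 4.041e-08
#>   rank-3 gap sigma4/sigma3: 2.735e-10

# the estimate equals the planted pure matrix up to global scale and the
# per-image sign gauge
gauge_correlation(fitted(fit), Astar)
#> [1] 1

# recovered rotations match the truth after Procrustes alignment, up to
# handedness (take the better chirality candidate)
min(procrustes_align(rots, coef(fit, "plus"))$avg_error,
    procrustes_align(rots, coef(fit, "minus"))$avg_error)
#> [1] 1.073597e-14
```

With random per-block *sign* flips in the corruption, the matrix is still
recovered (`gauge_correlation` remains 1) but the rotations are determined
only up to an additional 180-degree in-plane rotation of individual images:
a flipped block-row of a pure matrix is itself the pure matrix of the
in-plane-rotated tuple, so no common-lines computation can undo it.

The printed quadratic error is the root-mean-square violation of the norm
and determinant equalities of the estimate (zero for an exactly consistent
matrix); the `sigma4/sigma3` gap is its numerical rank-3 test; the
Procrustes number is the average per-image squared Frobenius distance to
the true rotations after removing the global rotation.

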