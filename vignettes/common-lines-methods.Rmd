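---
title: "Algebraic common-lines methods: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Algebraic common-lines methods: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commonlines)
```

This vignette is the package's own account of the science it implements:
the model behind the common-lines matrix, the constraints the algorithms
exploit, the numerical choices that make them work, what the synthetic
generators do and do not emulate, and the known limitations.

## The model

A cryo-EM projection image taken at rotation $R_i \in SO(3)$ has, by the
Fourier slice theorem, a Fourier transform equal to the restriction of the
molecule's 3D transform to the plane $R_i^{-1}(\cdot, \cdot, 0)$. For an
asymmetric molecule, the planes of two images intersect in one line — the
common line — spanned in 3D by $r_i \times r_j$ with $r_m$ the third row of
$R_m$ (the viewing axis). Its representative in image $i$'s coordinates is
the 2-vector

$$a_{ij} \;=\; \Pi\!\left(R_i\,(r_i \times r_j)\right)
        \;=\; \tilde J\, R_i\, r_j,
\qquad
\tilde J = \begin{pmatrix} 0 & -1 & 0\\ 1 & 0 & 0\end{pmatrix},$$

where $\Pi$ drops the identically-zero third coordinate. The $2n \times n$
block matrix $A$ with blocks $a_{ij}$ (zero diagonal) is the *pure*
common-lines matrix. It factors exactly as $A = BC$ with
$B_i = \tilde J R_i$ and $c_j = R_j^\top e_3$, hence has rank 3, and it
satisfies a family of sparse quadratic constraints: one norm equality
$\lVert a_{ij}\rVert = \lVert a_{ji}\rVert$ per unordered pair, and two
determinant equalities per unordered triple, because
$d_i = \det[a_{ij}\, a_{ik}]$ equals the scalar triple product
$\det[r_i; r_j; r_k]$ with the sign pattern $(+,-,+)$ over the triple's
three base images. The family has $n(n-1)/2 + 2\binom{n}{3}$ members
(5 at $n=3$, 14 at $n=4$); `count_quadratic_constraints()` and the residual
functions enumerate it.

Detected common lines provide the blocks only up to unknown nonzero scales
and signs, and with angular error. All computational tasks in the package
reduce to restoring the algebraic structure above from such data.

### Sign conventions and an intrinsic gauge

The sign convention $a_{ij} = \tilde J R_i R_j^\top e_3$ is frozen
throughout (it pins the determinant sign pattern $(+,-,+)$; the test suite
validates the pattern numerically on pure matrices before anything relies
on it). Note that the two blocks of a pair represent *opposite* 3D
directions, since $r_i \times r_j = -(r_j \times r_i)$: common-line
detection with oriented ray matching must therefore negate one side, which
`detect_common_line()` does.

One discrete ambiguity deserves emphasis because it shapes several API
decisions. Negating block-row $i$ of a pure matrix yields exactly the pure
matrix of the tuple in which image $i$ is rotated by 180 degrees in-plane:
the rank, every norm equality and every determinant equality are invariant
(the row enters each of its determinants twice). Consequently, when block
signs have been corrupted independently, *no* algorithm can recover the
block-row signs of the original matrix — the estimate is determined up to
one global scale **and** per-image sign flips, which correspond to
per-image in-plane 180-degree rotations downstream. The package exposes
`align_row_signs()` and `gauge_correlation()` to compare an estimate with a
reference modulo this gauge; evaluations against ground truth use them.
When the data's signs are pair-consistent (as detected data's are), the
pipeline preserves them and the gauge never materialises.

A related global ambiguity is chirality: the mirrored tuple $J R_i J$
($J = \mathrm{diag}(1,1,-1)$) produces $-A$, so the handedness cannot be
decided from common lines. `recover_rotations()` returns both candidates;
evaluations report the better one, which is also how rotation errors are
reported in practice.

## Scale recovery: IRLS around an ADMM split

`irls_admm()` minimises a robust misfit between the scaled unit-normalised
data $\tau \circ A_u$ and a rank-3 surrogate $Z$, alternating:
a closed-form blockwise update of the estimate $X$ (with diagonal blocks
projected to zero), the closed-form scale update
$\tau_{ij} = \langle a_{ij}, x_{ij}\rangle$, a rank-3 singular-value
projection for $Z$, and dual ascent on the multipliers, with IRLS weights
$w_{ij} = (\lVert \tau_{ij}a_{ij} - z_{ij}\rVert^2 + \delta^2)^{-1/2}$
re-estimated between rounds.

Four numerical choices matter; each was adopted after the corresponding
failure mode was observed on construct-and-verify cases (a pure matrix with
known planted corruption, so the correct answer is available):

* **Balanced scale gauge.** The scale matrix is renormalised each update to
  equalised block-row and column norms with fixed Frobenius norm
  $\sqrt{n(n-1)}$. A plain Frobenius gauge admits *exact* zero-cost optima
  that zero out one image's row and column entirely (fit the remaining
  $n-1$ images with rank 3 and drop the rest); the balanced gauge excludes
  them while keeping every genuine solution reachable.
* **Regulariser homotopy.** $\delta$ starts at the mean initial block
  residual and halves each round (floored relative to the current residual
  level). Early rounds behave like smooth least squares — which converge
  globally for scale-only corruption — and later rounds harden toward the
  robust loss that suppresses outliers. A small fixed $\delta$ from the
  start makes the landscape needlessly combinatorial.
* **Commensurate penalty.** The effective ADMM penalty is
  $\rho \cdot \mathrm{mean}(w^2)$ per round. With a fixed $\rho = 1$ the
  weights (up to $1/\delta$) swamp the consensus term and the rank
  constraint never engages.
* **Sign-randomised restarts.** Independent block-sign corruption makes the
  landscape combinatorial; when a run neither reaches an essentially exact
  rank-3 fit nor keeps all block norms healthy, the solver restarts from
  sign-randomised initialisations (up to `restarts`, seeded). A restart
  replaces the deterministic first attempt only when its fit is *materially*
  better (factor 2): restarts of equal quality differ only in the sign
  gauge, and honouring the first attempt preserves the data's own sign
  structure when it was consistent to begin with. Restarting after
  divergence is also the standard practical remedy for this family of
  solvers.

Defaults (30 IRLS rounds, 50 ADMM rounds, 2–4 inner alternations,
tolerance $10^{-8}$) were chosen once as a runtime/quality balance for the
problem sizes the package targets (tens of images) and are exposed in
`admm_params()`.

For consistent data the solution's scale matrix has the rank-1 structure
$\tau_{ij} = \alpha_i \beta_j \lVert a^\star_{ij}\rVert$ (in magnitude; the
signs carry the corruption's unidentifiable sign pattern), which is why a
subsequent row/column scaling can reach a pure matrix. `polish_scales()`
(uniform-weight alternation) sharpens a converged solution to machine
precision, and `estimate_block_norms()` provides a direct, non-iterative
estimate of the block norms from the triple determinants of the
unit-normalised data: $|d_i'| = D_t / (N_{ij} N_{ik})$ becomes a sparse
linear system in the log-norms, solved in the minimum-norm least-squares
sense (the one-dimensional kernel is the global scale). Its residual is
itself a cheap consistency score, and the estimate initialises the
quadruple scorer used in clustering.

## Constraint scaling (Sinkhorn-style)

`sinkhorn()` enforces the quadratic constraints by alternately scaling
block-rows and columns. Scaling block-row $i$ by $\lambda_i$ multiplies
$d_i$ by $\lambda_i^2$; taking signed square roots of the determinants
linearises the constraints in $\lambda$. Scaling column $j$ by $\mu_j$
multiplies $d_i$ by $\mu_j\mu_k$; dividing by the shared factor linearises
them in $\mu$. Norm constraints are linear in both. Each solve is the right
singular vector of the smallest singular value of the stacked system,
sign-fixed so the entry sum is nonnegative.

The stacking weights are not cosmetic. For a row/column-scaled pure matrix
one can track how each family's exact null vector responds to the *other*
side's corruption: the signed-root determinant rows of the row system
respond at the $-1/2$ power (each full round halves the error — the
alternation contracts), the norm rows respond at power $+1$ (they copy the
corruption back and forth — neutral), and the linear-in-$\mu$ determinant
rows of the column system respond at power $+2$ (they amplify). The
implementation therefore stacks the row system at equal weight, downweights
the determinant rows of the column solves (default 0.05 — they are kept for
their sign information), and performs one determinant-only column solve up
front whose *signs* fix the column signs, which norms cannot see. With this
arrangement the alternation converges to machine precision on planted
row/column scalings, including negative ones; with naive equal-weight
stacking it stalls even for 1% perturbations. Divergence (vanishing scales,
residual growth beyond ten times the best seen, non-finite values) is
flagged, never silent. The global Frobenius norm is renormalised each step
because the global scale is unidentifiable.

## Rotation recovery

`recover_rotations()` factors the estimate as $U V$ by truncated SVD and
solves the $6$-unknown linear least-squares problem for the symmetric
$3\times 3$ matrix $H$ minimising
$\sum_i \lVert U_i H U_i^\top - I_2\rVert_F^2$ via the normal equations.
With $H = PDP^\top$ (flipping $H$'s global sign if two or more eigenvalues
are negative, clamping tiny negatives, and orienting $P$ as a proper
rotation), $\hat B = U P \sqrt{D}$ has orthonormal $2\times 3$ blocks; the
convention $B_i = \tilde J R_i$ is inverted by taking row 1 of $R_i$ from
row 2 of $\hat B_i$, row 2 from minus row 1, completing with their cross
product, and projecting to the nearest rotation. The assembled frames
always have determinant $+1$ (the third row is a cross product), so the
residual orthogonal ambiguity in $Q = P\sqrt{D}$ is exactly the global
rotation when it is a rotation, and lands in the mirrored class when it is
a reflection — which is why the chirality partner is constructed explicitly
as $J R_i J$ rather than by re-running on $-A$ (negating the matrix flips
an even number of rows per frame and stays in the same class).

## Heterogeneity clustering

`cluster_common_lines()` implements the sampling-based sorting of
discretely heterogeneous image sets:

1. **Scoring.** Uniform random 4-subsets are extracted as $8\times 4$
   submatrices and scored: block-norm estimation initialises a light
   IRLS-ADMM run, `polish_scales()` sharpens it, the sample is rejected if
   the rescaled data matrix has no numerical rank-3 gap
   ($\sigma_4/\sigma_3 > 0.1$ by default) or any step diverges, and
   otherwise the error is the aggregate quadratic-constraint violation of
   the Sinkhorn-scaled submatrix. Four images is the smallest size with a
   nontrivial rank-3 constraint and keeps each score at tens of
   milliseconds. The rank-3 gap must be measured on the *rescaled data*
   (scale matrix times unit blocks): the ADMM surrogate is rank 3 by
   construction and cannot discriminate.
2. **Graph.** Accepted samples are sorted by error and the best fraction
   retained (default 5%, at least 20). Each retained sample contributes its
   six pairs a candidate weight $-\log(e / e_{\mathrm{cut}})$ with
   $e_{\mathrm{cut}}$ the retention cutoff; pair weights are the best
   candidate, clipped at zero. Measuring errors relative to the cutoff
   matters: each cross-population pair is covered by many inconsistent
   samples, and the minimum over ~20 draws of the mixed-error distribution
   comes close to typical consistent-sample errors (an extreme-value bias
   that, with raw $-\log e$ weights, leaves within- and cross-population
   weights nearly indistinguishable at realistic noise).
3. **Community detection.** The default backend is weighted Louvain
   (igraph). The local-fitness growth procedure
   ($f(C) = s_{\mathrm{in}} / (s_{\mathrm{in}} + s_{\mathrm{out}})^\alpha$,
   greedy addition with pruning, overlap resolution by node fitness) is
   implemented as `lfk_communities()` and available via
   `cluster_params(method = "lfk")`; it behaves exactly as expected on
   sparse strong graphs (disjoint cliques, weak bridges) but, having no
   null model, it either absorbs everything or fragments on graphs with a
   dense weak background, where modularity-based detection recovers the
   planted structure from the identical weights.
4. **Probe refinement.** The uniform draw gives each within-population pair
   only a handful of all-consistent quadruples, so the first partition is a
   draft. Up to three rounds score every node against three members of each
   provisional community — such a probe can only score low if all four
   lines are mutually consistent — add the probes to the sample pool and
   re-partition. A consolidation pass on the accumulated evidence then
   merges fragmented communities and reassigns each node to the community
   minimising its *median* probe error (the minimum of a handful of
   inconsistent probes reaches the consistent range at realistic noise;
   medians stay separated), topping up each node's two leading candidates
   with fresh probes. The accept/merge thresholds are calibrated against
   each community's own internal probe level (the low quartile of its
   members' evidence — consistent probes sit at ratio about one to it in
   every noise regime, while cross-population probes sit several times
   higher; an absolute threshold cannot work, because the consistent level
   at one or two degrees of noise overlaps the inconsistent level of clean
   data), with margin backstops for the machine-precision regime where
   ratios are numerical noise but the argmin margin is decisive. Nodes
   left in no sizeable community trigger a discovery cycle that samples
   quadruples among them, so a population the uniform draw missed entirely
   is still found. This is the package's concrete reading of "sample until
   sufficient": membership questions the uniform draw left open are
   answered by targeted measurement rather than by graph heuristics.

## Synthetic data and what passing tests show

The generators emulate the corruption structure the algorithms are designed
for: unknown per-block scales with random signs
(`scale_low`/`scale_high`/`sign_flip_prob`), angular error applied as an
in-plane rotation of the representative (this is how detection error
manifests, and it preserves block norms — additive vector noise would not),
a fraction of outright outlier lines, and heterogeneous mixtures whose
cross-population blocks are uniformly random unit lines hidden by a joint
row/column permutation. Within-population corruption in the mixtures
defaults to none; study conditions set the angular noise explicitly
(2 degrees in the clustering checks, 5 degrees in the robustness
comparison).

The phantom imaging path generates asymmetric sums of 3D Gaussians (8 blobs
with generic random centers in a 24-pixel ball, widths 1–2 pixels), whose
tomographic projections are available in closed form, on a
$128 \times 128$ grid at a nominal 3 Å/pixel; common lines are detected by
maximising the normalised real correlation of complex central-ray profiles
of the windowed 2D FFT over all angle pairs and both relative orientations
(1-degree grid, radial band $[3, L/2-2]$ frequency pixels, raised-cosine
edge window). The grid size is chosen so that 1-degree ray discrimination
is comfortably resolved for blobs of this sharpness; at $64^2$ the
interpolation error already costs several degrees.

What these generators do *not* emulate: contrast transfer functions,
particle-picking translation errors, class-averaging blur, correlated
detection errors across pairs, and symmetric molecules. Passing tests
therefore demonstrate the algebraic machinery under the stated corruption
models, not end-to-end performance on experimental micrographs.

## Numerical choices and degenerate inputs

* Degenerate viewing pairs (parallel axes) are rejected with the offending
  pair named; blocks with numerically zero norm cannot be normalised and
  are reported likewise.
* The gap statistic defines $\sigma_4 = 0$ when the matrix has fewer than
  four singular values ($n = 3$).
* `quadratic_error()` rescales to Frobenius norm $\sqrt{n(n-1)}$ before
  aggregating so the score is scale-invariant and comparable across sample
  sizes, and uses an RMS rather than a maximum for robustness as a
  clustering score.
* Problem sizes in the test suite (up to $n = 30$ for exact laws, $n = 20$
  for the noise comparison, $3 \times 10$ images for clustering, six
  $128^2$ images for detection) are the package's desk-scale reference
  conditions; all solvers are dimension-generic.

## Known limitations

* Chirality and per-image in-plane 180-degree flips under sign-corrupted
  data are mathematically unresolvable from common lines; the package makes
  both gauges explicit rather than hiding them.
* The Sinkhorn step assumes an approximately rank-3 input and can diverge
  on heavily noisy full-size matrices (divergence is flagged); `cl_fit()`
  falls back to the denoiser output for rotation recovery in that case.
* The quadruple scorer's error statistic is noise-limited: at a few degrees
  of angular error the consistent/inconsistent error distributions overlap,
  which is why the clustering pipeline leans on retention, probe
  enrichment and consolidation rather than on the raw graph alone.
* No CTF modelling, no symmetry groups, no 3D reconstruction.
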