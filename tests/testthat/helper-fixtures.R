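# Deterministic fixtures shared across test files.

fixture_rotations <- function() list(diag(3), rot_x(90), rot_y(90))

# the pure common-lines matrix of the fixture, written out by hand from the
# cross-product construction (columns are blocks a_.1, a_.2, a_.3)
fixture_pure <- function() {
  matrix(c(
    0, -1,  0,
    0,  0, -1,
    1,  0,  0,
    0,  0, -1,
    0, -1,  0,
    1,  0,  0
  ), nrow = 6, ncol = 3, byrow = TRUE)
}

# scale block-rows / columns of a common-lines matrix (test-side oracle)
scale_rows_oracle <- function(A, lam) A * rep(lam, each = 2L)
scale_cols_oracle <- function(A, mu) sweep(A, 2L, mu, `*`)

# normalized correlation up to the block-row sign gauge
gauge_corr <- function(Ahat, Aref) gauge_correlation(Ahat, Aref)

# best-hand Procrustes: smallest per-image average over the chirality pair
best_hand_error <- function(truth, rec) {
  min(procrustes_align(truth, rec$plus)$avg_error,
      procrustes_align(truth, rec$minus)$avg_error)
}

best_hand_angles <- function(truth, rec) {
  a1 <- procrustes_align(truth, rec$plus)$per_image_angle_deg
  a2 <- procrustes_align(truth, rec$minus)$per_image_angle_deg
  if (max(a1) <= max(a2)) a1 else a2
}
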