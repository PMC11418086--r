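make_het <- function(sizes, sigma = 0, seed = 1) {
  set.seed(seed)
  rotsets <- lapply(sizes, random_rotations)
  heterogeneous_matrix(rotsets, noise_spec(1, 1, 0, angle_sigma_deg = sigma))
}

test_that("score_sample accepts consistent quadruples and flags input errors", {
  h <- make_het(c(6, 6), seed = 41)
  expect_error(score_sample(h$A, c(1, 1, 2, 3)), "distinct")
  expect_error(score_sample(h$A, c(1, 2, 3, 99)), "in-range|distinct")

  S <- sort(which(h$labels == 1)[1:4])
  sc <- score_sample(h$A, S)
  expect_true(sc$accepted)
  expect_identical(sc$reject_reason, "none")
  expect_lt(sc$error, 1e-6)
})

test_that("mixed quadruples are rejected or score much worse than pure ones", {
  h <- make_het(c(6, 6), seed = 42)
  pure_errs <- c(); mixed_bad <- 0; n_mixed <- 0
  set.seed(43)
  for (k in 1:10) {
    Sp <- sort(sample(which(h$labels == 1), 4))
    sc <- score_sample(h$A, Sp)
    if (sc$accepted) pure_errs <- c(pure_errs, sc$error)
  }
  med_pure <- stats::median(pure_errs)
  for (k in 1:10) {
    Sm <- sort(c(sample(which(h$labels == 1), 2), sample(which(h$labels == 2), 2)))
    sc <- score_sample(h$A, Sm)
    n_mixed <- n_mixed + 1
    if (!sc$accepted || sc$error > 10 * med_pure) mixed_bad <- mixed_bad + 1
  }
  expect_gte(mixed_bad, 8)
})

test_that("sample_and_score is deterministic, ordered, and accepts clean data", {
  A <- pure_matrix(random_rotations(8, seed = 44))
  expect_length(sample_and_score(A, 0, seed = 1), 0)
  s1 <- sample_and_score(A, 25, seed = 2)
  s2 <- sample_and_score(A, 25, seed = 2)
  expect_identical(lapply(s1, `[[`, "quadruple"), lapply(s2, `[[`, "quadruple"))
  expect_gte(mean(vapply(s1, `[[`, logical(1), "accepted")), 0.9)
})

test_that("build_adjacency applies the min-error rule with clipping and coverage", {
  mk <- function(S, e) structure(list(quadruple = S, error = e, accepted = TRUE,
                                      reject_reason = "none"),
                                 class = "cl_sample_score")
  G1 <- build_adjacency(list(mk(1:4, exp(-2))), 6)
  expect_equal(sort(unique(G1$weights[1:4, 1:4][upper.tri(diag(4))])), 2)
  expect_equal(G1$weights[5, ], rep(0, 6))
  expect_true(all(G1$covered[1:4, 1:4][upper.tri(diag(4))]))
  expect_false(any(G1$covered[5:6, ]))

  # shared pair takes the smaller error; negative weights clip to zero
  G2 <- build_adjacency(list(mk(1:4, exp(-1)), mk(c(1, 2, 5, 6), exp(-3)),
                             mk(c(3, 4, 5, 6), 2)), 6)
  expect_equal(G2$weights[1, 2], 3)
  expect_equal(G2$weights[1, 3], 1)
  expect_equal(G2$weights[3, 5], 0)   # error 2 -> negative weight -> clipped
  expect_true(G2$covered[3, 5])

  # no accepted samples -> empty graph
  none <- list(structure(list(quadruple = 1:4, error = NA_real_,
                              accepted = FALSE, reject_reason = "diverged"),
                         class = "cl_sample_score"))
  expect_equal(sum(build_adjacency(none, 6)$weights), 0)

  # relative error scale: boundary samples carry no weight
  G3 <- build_adjacency(list(mk(1:4, 0.05)), 6, error_scale = 0.05)
  expect_equal(sum(G3$weights), 0)
})

test_that("local-fitness communities resolve cliques and bridges", {
  # two disjoint 4-cliques
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1
  diag(W) <- 0
  for (alpha in c(0.5, 1, 2)) {
    comms <- lfk_communities(W, alpha)
    expect_setequal(lapply(comms, sort), list(1:4, 5:8))
  }

  # single clique
  W1 <- matrix(1, 5, 5); diag(W1) <- 0
  expect_length(lfk_communities(W1, 1), 1)

  # two cliques joined by one weak edge
  W2 <- W
  W2[4, 5] <- W2[5, 4] <- 0.01
  comms <- lfk_communities(W2, 1)
  expect_setequal(lapply(comms, sort), list(1:4, 5:8))

  # empty graph: all singletons
  expect_length(lfk_communities(matrix(0, 4, 4), 1), 4)
})

test_that("clustering separates planted populations exactly on clean data", {
  h <- make_het(c(6, 6, 6), seed = 45)
  cl <- suppressWarnings(cluster_common_lines(h$A, budget = 500, seed = 46))
  expect_equal(adjusted_rand_index(h$labels, cl$partition), 1.0)
  expect_s3_class(cl, "cl_clusters")
  expect_length(cl$partition, 18)
  # weights are finite, symmetric, zero-diagonal
  W <- cl$graph$weights
  expect_true(all(is.finite(W)))
  expect_equal(W, t(W))
  expect_equal(diag(W), rep(0, 18))
})

test_that("a homogeneous matrix stays one community", {
  A <- corrupt_matrix(pure_matrix(random_rotations(8, seed = 47)),
                      noise_spec(1, 1, 0, angle_sigma_deg = 1, seed = 48))
  cl <- suppressWarnings(cluster_common_lines(A, budget = 300, seed = 49))
  main <- max(table(cl$partition))
  expect_gte(main / 8, 0.9)
})

test_that("within-population acceptance exceeds mixed acceptance across noise", {
  for (sigma in c(0, 3)) {
    h <- make_het(c(6, 6), sigma = sigma, seed = 50 + sigma)
    set.seed(51 + sigma)
    acc_w <- acc_m <- c()
    for (k in 1:8) {
      Sw <- sort(sample(which(h$labels == 1), 4))
      Sm <- sort(c(sample(which(h$labels == 1), 2),
                   sample(which(h$labels == 2), 2)))
      acc_w <- c(acc_w, score_sample(h$A, Sw)$accepted)
      acc_m <- c(acc_m, score_sample(h$A, Sm)$accepted)
    }
    expect_gt(mean(acc_w), mean(acc_m))
  }
})
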