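## Sorting a discretely heterogeneous image set into homogeneous communities.
## Random 4-subsets of images are scored by how well their 8x4 submatrix of
## common lines can be scaled onto the constraint set (rank 3 + quadratics);
## accepted samples induce a weighted graph (-log of the smallest error over
## hyperedges containing a pair) on which local-fitness community detection
## runs. Four images per sample is the smallest size with a nontrivial
## rank-3 constraint and keeps the scaling steps fast and stable.

#' Parameters for quadruple scoring and clustering
#'
#' @param admm An [admm_params()] object used on each 8x4 submatrix. The
#'   default is a lighter setting than the full-matrix denoiser since each
#'   sample is tiny and thousands are scored.
#' @param sinkhorn_iters,sinkhorn_tol Sinkhorn settings per sample.
#' @param gap_threshold Reject a sample when `sigma4/sigma3` of its scaled
#'   submatrix exceeds this (no numerical rank 3).
#' @param error_floor Errors are floored here before taking logs.
#' @param method Community-detection backend: `"louvain"` (default;
#'   weighted modularity via igraph, robust to the dense weak background of
#'   cross-population edges) or `"lfk"` (the local-fitness growth of
#'   [lfk_communities()]).
#' @param alpha Resolution exponent of the local-fitness method (used when
#'   `method = "lfk"`).
#' @return A list of class `"cl_cluster_params"`.
#' @export
cluster_params <- function(admm = admm_params(outer_iters = 2L,
                                              admm_iters = 10L,
                                              inner_iters = 2L,
                                              tol = 1e-9, restarts = 2L),
                           polish_iters = 25L,
                           sinkhorn_iters = 80L, sinkhorn_tol = 1e-13,
                           gap_threshold = 0.1, error_floor = 1e-12,
                           method = c("louvain", "lfk"),
                           alpha = 1) {
  stopifnot(gap_threshold > 0, error_floor > 0, alpha > 0, polish_iters >= 0)
  structure(list(admm = admm, polish_iters = as.integer(polish_iters),
                 sinkhorn_iters = as.integer(sinkhorn_iters),
                 sinkhorn_tol = sinkhorn_tol, gap_threshold = gap_threshold,
                 error_floor = error_floor, method = match.arg(method),
                 alpha = alpha),
            class = "cl_cluster_params")
}

#' Score one 4-image sample for common-lines consistency
#'
#' Extracts the 8x4 block submatrix over `S`, runs [irls_admm()] then
#' [sinkhorn()] on it, and rejects the sample if either diverges or the
#' scaled result is not numerically rank 3. Otherwise the sample's error is
#' the aggregate [quadratic_error()] of the scaled submatrix. Rejections are
#' returned as data, not raised as conditions.
#'
#' @param A A 2n x n common-lines matrix.
#' @param S Four distinct image indices.
#' @param params A [cluster_params()] object.
#' @return A list of class `"cl_sample_score"` with `quadruple`, `error`,
#'   `accepted`, `reject_reason` (one of `"none"`, `"diverged"`,
#'   `"no_rank3_gap"`).
#' @export
score_sample <- function(A, S, params = cluster_params()) {
  n <- cl_check(A, min_n = 4L)
  S <- as.integer(S)
  if (length(S) != 4L || anyDuplicated(S) || any(S < 1L | S > n))
    stop("`S` must be 4 distinct in-range image indices")
  sub <- A[as.vector(rbind(2L * S - 1L, 2L * S)), S, drop = FALSE]
  res <- list(quadruple = S, error = NA_real_, accepted = FALSE,
              reject_reason = "none")
  den <- tryCatch({
    su <- normalize_blocks(sub)
    est <- estimate_block_norms(su)   # near-exact start on consistent data
    irls_admm(sub, params$admm, T0 = balance_scales(est$N))
  }, error = function(e) NULL)
  if (is.null(den) || den$diverged) {
    res$reject_reason <- "diverged"
    return(structure(res, class = "cl_sample_score"))
  }
  ## the rescaled measured submatrix: if the four lines are consistent some
  ## block scaling makes it rank 3; the ADMM surrogate Z is rank 3 by
  ## construction, so the gap test must look at the scaled data instead.
  ## A uniform-weight polish sharpens consistent samples to machine
  ## precision; inconsistent samples have no exact fit to converge to.
  sub_unit <- normalize_blocks(sub)
  Tm <- polish_scales(sub_unit, den$T, iters = params$polish_iters)$T
  M <- expand_rows(Tm) * sub_unit
  g <- rank3_gap(M)
  if (!is.finite(g$sigma3) || g$sigma3 <= 0 ||
      g$sigma4 / g$sigma3 > params$gap_threshold) {
    res$reject_reason <- "no_rank3_gap"
    return(structure(res, class = "cl_sample_score"))
  }
  sk <- tryCatch(
    suppressWarnings(sinkhorn(M, max_iters = params$sinkhorn_iters,
                              tol = params$sinkhorn_tol)),
    error = function(e) NULL)
  if (is.null(sk) || sk$state$diverged) {
    res$reject_reason <- "diverged"
    return(structure(res, class = "cl_sample_score"))
  }
  res$error <- quadratic_error(sk$Ahat)
  res$accepted <- is.finite(res$error)
  if (!res$accepted) res$reject_reason <- "diverged"
  structure(res, class = "cl_sample_score")
}

#' Sample and score random quadruples
#'
#' Draws `budget` i.i.d. uniform 4-subsets (without replacement within a
#' sample) and scores each with [score_sample()].
#'
#' @param A A 2n x n common-lines matrix, n >= 5 recommended.
#' @param budget Number of samples (>= 0).
#' @param seed Optional integer seed.
#' @param params A [cluster_params()] object.
#' @return List of `cl_sample_score` objects, in sampling order.
#' @export
sample_and_score <- function(A, budget, seed = NULL,
                             params = cluster_params()) {
  n <- cl_check(A, min_n = 4L)
  if (budget < 0) stop("`budget` must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  quads <- lapply(seq_len(budget), function(b) sort(sample.int(n, 4L)))
  lapply(quads, function(S) score_sample(A, S, params))
}

#' Weighted pair graph from scored samples
#'
#' For each accepted sample with error `e`, every one of its six pairs gets
#' candidate weight `-log(max(e / error_scale, error_floor))`; the graph
#' entry is the maximum candidate (i.e. minus the log of the smallest error
#' over hyperedges containing the pair), clipped below at zero. Pairs never
#' covered by an accepted sample have weight 0. With the default
#' `error_scale = 1` this is the plain negative-log weight; passing the
#' error level of the worst retained sample turns the clipping into a
#' baseline subtraction, so samples at the retention boundary carry no
#' weight.
#'
#' @param samples List of `cl_sample_score` objects.
#' @param n Number of images.
#' @param error_floor Floor applied before the log.
#' @param error_scale Reference error scale (errors are divided by it
#'   before the log).
#' @return A list with `weights` (symmetric n x n, zero diagonal) and
#'   `covered` (symmetric logical matrix of observed pairs).
#' @export
build_adjacency <- function(samples, n, error_floor = 1e-12,
                            error_scale = 1) {
  W <- matrix(0, n, n)
  covered <- matrix(FALSE, n, n)
  for (s in samples) {
    if (!isTRUE(s$accepted)) next
    w <- max(0, -log(max(s$error / error_scale, error_floor)))
    pr <- utils::combn(s$quadruple, 2L)
    for (k in seq_len(ncol(pr))) {
      i <- pr[1L, k]; j <- pr[2L, k]
      covered[i, j] <- covered[j, i] <- TRUE
      if (w > W[i, j]) W[i, j] <- W[j, i] <- w
    }
  }
  list(weights = W, covered = covered)
}

## community fitness s_in / (s_in + s_out)^alpha with strength convention
## s_in = sum of the community submatrix (internal edges counted twice)
lfk_fitness <- function(W, strengths, members, alpha) {
  if (!length(members)) return(0)
  s_in <- sum(W[members, members])
  s_tot <- sum(strengths[members])
  if (s_tot == 0) return(0)
  s_in / s_tot^alpha        # s_in + s_out = total strength of members
}

#' Local-fitness (LFK) community detection
#'
#' Grows natural communities on a weighted graph: starting from the
#' strongest unassigned node, repeatedly add the neighbour with the largest
#' positive fitness gain, pruning any member whose node fitness turns
#' negative, until no neighbour improves the community fitness
#' `s_in / (s_in + s_out)^alpha`. The raw output may assign a node to
#' several communities (overlap); nodes with no edges become singletons.
#'
#' @param W Symmetric nonnegative weight matrix with zero diagonal.
#' @param alpha Resolution exponent (> 0); larger values favour smaller
#'   communities.
#' @return List of integer vectors (node sets), in discovery order.
#' @export
lfk_communities <- function(W, alpha = 1) {
  stopifnot(alpha > 0)
  n <- nrow(W)
  strengths <- rowSums(W)
  nbrs <- lapply(seq_len(n), function(v) which(W[v, ] > 0))
  communities <- list()
  in_any <- rep(FALSE, n)

  while (any(!in_any)) {
    cand_seeds <- which(!in_any)
    seed <- cand_seeds[which.max(strengths[cand_seeds])]
    C <- seed
    banned <- integer(0L)
    repeat {
      fC <- lfk_fitness(W, strengths, C, alpha)
      cand <- setdiff(unique(unlist(nbrs[C])), c(C, banned))
      if (!length(cand)) break
      gains <- vapply(cand, function(v)
        lfk_fitness(W, strengths, c(C, v), alpha) - fC, numeric(1L))
      if (max(gains) <= 0) break
      C <- c(C, cand[which.max(gains)])
      ## prune members whose node fitness went negative
      repeat {
        fC <- lfk_fitness(W, strengths, C, alpha)
        nodefit <- vapply(C, function(u)
          fC - lfk_fitness(W, strengths, setdiff(C, u), alpha), numeric(1L))
        worst <- which.min(nodefit)
        if (length(C) > 1L && nodefit[worst] < 0) {
          banned <- c(banned, C[worst])
          C <- C[-worst]
        } else break
      }
      if (!(seed %in% C)) break   # seed pruned: community finished
    }
    C <- sort(unique(C))
    if (length(C)) {
      communities[[length(communities) + 1L]] <- C
      in_any[C] <- TRUE
    }
    if (!in_any[seed]) {
      ## a seed pruned from its own community becomes a singleton, so the
      ## sweep always progresses
      communities[[length(communities) + 1L]] <- seed
      in_any[seed] <- TRUE
    }
  }
  communities
}

#' Cluster a heterogeneous common-lines matrix
#'
#' Full pipeline: score `budget` random quadruples; retain the
#' best-scoring fraction (sorted by error) and weight their pairs relative
#' to the retention cutoff, so samples at the boundary carry no weight;
#' run community detection on the weighted pair graph; then, for nodes
#' left without strong evidence (no retained sample ties them to any
#' community), draw a bounded round of targeted quadruples against the
#' found communities and re-partition. Nodes in no community become
#' singletons.
#'
#' @param A A 2n x n common-lines matrix, n >= 5.
#' @param budget Number of quadruple samples (default `50 * n`).
#' @param seed Optional integer seed.
#' @param params A [cluster_params()] object.
#' @param retain_frac Fraction of accepted samples kept after sorting by
#'   error (at least 20 samples are kept when available). The default is
#'   deliberately sharp: the retention cutoff also serves as the
#'   consistency threshold of the refinement passes.
#' @param topup Number of targeted top-up quadruples per weak node and
#'   candidate community (0 disables the rescue round).
#' @return An object of class `"cl_clusters"`: list with `partition`
#'   (length-n integer community ids), `communities` (node sets),
#'   `n_samples_used`, `n_accepted`, `per_sample` (data frame), `graph`.
#' @export
cluster_common_lines <- function(A, budget = NULL, seed = NULL,
                                 params = cluster_params(),
                                 retain_frac = 0.05, topup = 3L) {
  n <- cl_check(A, min_n = 5L)
  if (is.null(budget)) budget <- 50L * n
  samples <- sample_and_score(A, budget, seed = seed, params = params)

  build_graph <- function(samples) {
    acc <- Filter(function(s) isTRUE(s$accepted), samples)
    if (!length(acc))
      return(list(weights = matrix(0, n, n),
                  covered = matrix(FALSE, n, n), cutoff = NA_real_))
    errs <- vapply(acc, `[[`, numeric(1L), "error")
    K <- min(length(acc), max(20L, ceiling(retain_frac * length(acc))))
    cutoff <- sort(errs)[K]
    retained <- acc[errs <= cutoff]
    G <- build_adjacency(retained, n, error_floor = params$error_floor,
                         error_scale = max(cutoff, params$error_floor))
    ## coverage is about sampling sufficiency: measure it on all accepted
    G$covered <- build_adjacency(acc, n)$covered
    G$cutoff <- cutoff
    G$retained_median <- stats::median(errs[errs <= cutoff])
    G
  }
  G <- build_graph(samples)
  cov_frac <- mean(G$covered[upper.tri(G$covered)])
  if (cov_frac < 0.8)
    warning(sprintf("only %.0f%% of pairs covered by accepted samples; consider a larger budget",
                    100 * cov_frac))
  partition_graph <- function(G) {
    if (params$method == "louvain") {
      g <- igraph::graph_from_adjacency_matrix(G$weights, mode = "undirected",
                                               weighted = TRUE, diag = FALSE)
      return(as.integer(igraph::membership(igraph::cluster_louvain(g))))
    }
    comms <- lfk_communities(G$weights, alpha = params$alpha)
    ## resolve overlaps by node fitness
    strengths <- rowSums(G$weights)
    partition <- rep(NA_integer_, n)
    for (v in seq_len(n)) {
      hosts <- which(vapply(comms, function(C) v %in% C, logical(1L)))
      if (!length(hosts)) next
      if (length(hosts) == 1L) { partition[v] <- hosts; next }
      nodefit <- vapply(hosts, function(ci) {
        C <- comms[[ci]]
        lfk_fitness(G$weights, strengths, C, params$alpha) -
          lfk_fitness(G$weights, strengths, setdiff(C, v), params$alpha)
      }, numeric(1L))
      partition[v] <- hosts[which.max(nodefit)]  # which.max: ties -> lower id
    }
    nxt <- max(0L, partition, na.rm = TRUE)
    for (v in which(is.na(partition))) {
      nxt <- nxt + 1L
      partition[v] <- nxt
    }
    partition
  }

  partition <- partition_graph(G)

  ## Probe enrichment: the uniform draw gives each within-population pair
  ## only a handful of all-consistent quadruples, so the first partition is
  ## a rough draft. Each round scores targeted quadruples — every node
  ## against three members of every provisional community (a probe can only
  ## score low if all four lines are mutually consistent) — adds them to
  ## the sample pool, rebuilds the retained graph and re-partitions. The
  ## added evidence lets the community detection split mixed groups, merge
  ## fragments and correct stray assignments.
  if (topup > 0L) for (cycle in 1:2) {
    for (round in 1:3) {
      sizes <- table(partition)
      comm_ids <- as.integer(names(sizes[sizes >= 3L]))
      if (length(comm_ids) < 1L) break
      extra <- list()
      for (v in seq_len(n)) {
        for (cid in comm_ids) {
          members <- setdiff(which(partition == cid), v)
          if (length(members) < 3L) next
          for (k in seq_len(topup)) {
            S <- c(v, sample(members, 3L))
            extra[[length(extra) + 1L]] <- score_sample(A, S, params)
          }
        }
      }
      ## discovery: nodes in no sizeable community may form one of their
      ## own that the uniform draw simply missed — sample among them
      unassigned <- which(!(partition %in% comm_ids))
      if (length(unassigned) >= 4L) {
        for (k in seq_len(5L * length(unassigned))) {
          S <- sort(sample(unassigned, 4L))
          extra[[length(extra) + 1L]] <- score_sample(A, S, params)
        }
      }
      if (!length(extra)) break
      samples <- c(samples, extra)
      G <- build_graph(samples)
      newpart <- partition_graph(G)
      if (isTRUE(getOption("commonlines.debug")))
        cat("cycle", cycle, "round", round, "part:", newpart, "\n")
      stable <- identical(unname(split(seq_len(n), newpart)),
                          unname(split(seq_len(n), partition)))
      partition <- newpart
      if (stable) break
    }

    ## Consolidation on the accumulated evidence. For node v and community
    ## C, ev(v, C) is the smallest accepted error among cached quadruples
    ## {v} + three members of C: a quadruple scores low only if all four
    ## lines are mutually consistent, so ev is direct membership evidence.
    ## (i) merge community B into A when every member of B is individually
    ## consistent with A (median of ev over B below the retention cutoff);
    ## (ii) reassign each node to its evidence-minimising community,
    ## drawing a few fresh tie-break probes when the top two candidates are
    ## close. Iterate to a fixed point.
    acc <- Filter(function(s) isTRUE(s$accepted), samples)
    acc_err <- vapply(acc, `[[`, numeric(1L), "error")
    acc_quad <- lapply(acc, `[[`, "quadruple")
    probe_errs <- function(v, C) {
      sel <- vapply(acc_quad, function(q) v %in% q &&
                      all(q[q != v] %in% C) && length(q[q != v]) == 3L,
                    logical(1L))
      acc_err[sel]
    }
    ## median probe evidence: robust to the overlapping noise tail (the
    ## minimum of a handful of inconsistent probes reaches the consistent
    ## range at realistic noise)
    ev_med <- function(v, C) {
      e <- probe_errs(v, C)
      if (!length(e)) Inf else stats::median(e)
    }
    add_probe <- function(sc) {
      if (isTRUE(sc$accepted)) {
        acc[[length(acc) + 1L]] <<- sc
        acc_err <<- c(acc_err, sc$error)
        acc_quad[[length(acc_quad) + 1L]] <<- sc$quadruple
      }
    }
    ## Consistency thresholds are calibrated per community against its own
    ## internal probe level (the median probe error of its members against
    ## the rest of the community): consistent probes sit at ratio ~1 to it
    ## in every noise regime, while probes across genuinely different
    ## populations sit several times higher. Absolute thresholds cannot do
    ## this: the consistent level at a couple of degrees of angular noise
    ## overlaps the inconsistent level of clean data.
    internal_level <- function(C) {
      lv <- vapply(utils::head(C, 8L), function(v)
        ev_med(v, setdiff(C, v)), numeric(1L))
      lv <- lv[is.finite(lv)]
      if (!length(lv)) return(max(G$retained_median, 1e-12))
      ## low quantile: stray members of a not-yet-pure community inflate
      ## the upper half of the member evidence
      unname(stats::quantile(lv, 0.25, type = 1L))
    }
    for (pass in 1:3) {
      changed <- FALSE
      ## fragment merges
      ids <- as.integer(names(which(table(partition) >= 3L)))
      if (length(ids) >= 2L) {
        for (b in ids) for (a in ids) {
          if (a == b) next
          B <- which(partition == b); Aset <- which(partition == a)
          if (length(B) < 3L || length(Aset) < 3L) next
          ## make sure there is evidence to judge: members without cached
          ## probes against the other community get one fresh probe each
          for (v in utils::head(B, 5L)) {
            if (!length(probe_errs(v, setdiff(Aset, v)))) {
              members <- setdiff(Aset, v)
              if (length(members) >= 3L)
                add_probe(score_sample(A, c(v, sample(members, 3L)), params))
            }
          }
          evs <- vapply(B, function(v) ev_med(v, setdiff(Aset, v)),
                        numeric(1L))
          ## backstop floor: at machine-precision error levels the
          ## internal-level ratio is multiplicative noise; anything far
          ## below the retention cutoff is consistent
          thr_merge <- max(2.5 * max(internal_level(Aset), internal_level(B)),
                           0.25 * G$cutoff)
          if (isTRUE(getOption("commonlines.debug")))
            cat("  merge test b", b, "-> a", a, ": med evs",
                sprintf("%.3f", stats::median(evs)), "thr",
                sprintf("%.3f", thr_merge), "\n")
          if (is.finite(stats::median(evs)) &&
              stats::median(evs) <= thr_merge) {
            partition[B] <- a
            changed <- TRUE
            break
          }
        }
      }
      ## node reassignment: fresh probes for the two leading candidates so
      ## the medians rest on enough samples, then argmin of the median
      ids <- as.integer(names(which(table(partition) >= 3L)))
      if (length(ids)) {
        for (v in seq_len(n)) {
          cand <- vapply(ids, function(cid)
            ev_med(v, setdiff(which(partition == cid), v)), numeric(1L))
          ord <- order(cand)
          lead <- ids[ord[seq_len(min(2L, length(ids)))]]
          for (cid in lead) {
            members <- setdiff(which(partition == cid), v)
            if (length(members) < 3L) next
            for (k in seq_len(2L))
              add_probe(score_sample(A, c(v, sample(members, 3L)), params))
          }
          cand <- vapply(ids, function(cid)
            ev_med(v, setdiff(which(partition == cid), v)), numeric(1L))
          ord <- order(cand)
          best <- ids[ord[1L]]
          ## gate against absurd moves relative to the target community's
          ## own probe level, with a margin backstop: evidence far below
          ## the runner-up community is decisive whatever the ratio to the
          ## (possibly machine-precision) internal level
          thr_assign <- 3 * internal_level(setdiff(which(partition == best), v))
          if (length(ids) > 1L && is.finite(cand[ord[2L]]))
            thr_assign <- max(thr_assign, 0.01 * cand[ord[2L]])
          if (isTRUE(getOption("commonlines.debug")))
            cat("  v", v, "cand:", sprintf("%.2e", cand), "thr:",
                sprintf("%.2e", thr_assign), "best", best, "cur",
                partition[v], "\n")
          if (is.finite(cand[ord[1L]]) && cand[ord[1L]] <= thr_assign &&
              best != partition[v]) {
            partition[v] <- best
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }

    ## a population the uniform draw missed entirely surfaces as nodes in
    ## no sizeable community after consolidation: sample among them so the
    ## next cycle can discover it
    big_ids <- as.integer(names(which(table(partition) >= 3L)))
    unassigned <- which(!(partition %in% big_ids))
    if (cycle == 2L || length(unassigned) < 4L) break
    for (k in seq_len(5L * length(unassigned))) {
      S <- sort(sample(unassigned, 4L))
      samples[[length(samples) + 1L]] <- score_sample(A, S, params)
    }
    G <- build_graph(samples)
    partition <- partition_graph(G)
  }
  comms <- split(seq_len(n), partition)
  names(comms) <- NULL

  per_sample <- data.frame(
    i1 = vapply(samples, function(s) s$quadruple[1L], integer(1L)),
    i2 = vapply(samples, function(s) s$quadruple[2L], integer(1L)),
    i3 = vapply(samples, function(s) s$quadruple[3L], integer(1L)),
    i4 = vapply(samples, function(s) s$quadruple[4L], integer(1L)),
    error = vapply(samples, function(s) s$error, numeric(1L)),
    accepted = vapply(samples, function(s) s$accepted, logical(1L)),
    reject_reason = vapply(samples, function(s) s$reject_reason, character(1L))
  )
  structure(list(partition = partition, communities = comms,
                 n_samples_used = length(samples),
                 n_accepted = sum(per_sample$accepted),
                 per_sample = per_sample, graph = G,
                 coverage = cov_frac),
            class = "cl_clusters")
}

#' @export
print.cl_clusters <- function(x, ...) {
  k <- length(unique(x$partition))
  cat(sprintf("Common-lines clustering: %d images -> %d communities\n",
              length(x$partition), k))
  cat(sprintf("  samples: %d scored, %d accepted (%.0f%% pair coverage)\n",
              x$n_samples_used, x$n_accepted, 100 * x$coverage))
  sizes <- sort(table(x$partition), decreasing = TRUE)
  cat("  community sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cl_clusters <- function(object, ...) {
  acc <- object$per_sample$error[object$per_sample$accepted]
  cat("Sample error summary (accepted samples):\n")
  if (length(acc)) print(summary(acc)) else cat("  none accepted\n")
  print(object)
  invisible(object)
}
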