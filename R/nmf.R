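#' Non-negative matrix factorization by KL multiplicative updates
#'
#' Factorizes a strictly non-negative genes-by-samples matrix as `X ~ W H`
#' by the classic multiplicative updates that minimize the Kullback-Leibler
#' divergence `D(X || WH)` -- the NMF variant customarily used for expression
#' subtyping. `W` and `H` are initialized from `Uniform(0, 1)` scaled by
#' `mean(X)`; the objective trace is recorded and is non-increasing.
#'
#' @param X Non-negative numeric matrix (genes x samples).
#' @param r Rank, `2 <= r < min(dim(X))` (rank 1 allowed for diagnostics).
#' @param seed Integer seed for the random initialization.
#' @param max_iter Maximum update iterations (default 2000).
#' @param tol Relative objective-change convergence tolerance (default 1e-6).
#' @param conn_stop If positive, additionally stop once the hard sample
#'   assignment (argmax over `H`) has been unchanged for `conn_stop`
#'   consecutive checks made every `check_every` iterations -- the
#'   connectivity-based stopping rule used for consensus runs, where the
#'   co-clustering pattern matters rather than the fully polished objective.
#'   Default 0 (off).
#' @param check_every Iterations between connectivity checks (default 10).
#' @return List of class `"nmf_fit"`: `W`, `H`, `r`, `trace`, `seed`,
#'   `iterations`, `converged`.
#' @export
nmf_factorize <- function(X, r, seed = 1L, max_iter = 2000L, tol = 1e-6,
                          conn_stop = 0L, check_every = 10L) {
  X <- unclass(X)
  if (!is.matrix(X) || !is.numeric(X)) stop_input("X must be a numeric matrix")
  if (any(!is.finite(X)) || any(X < 0)) stop_input("X must be finite and non-negative")
  if (r < 1 || r >= min(dim(X))) {
    stop_input(sprintf("rank must satisfy 1 <= r < min(dim(X)) = %d", min(dim(X))))
  }
  zr <- rowSums(X) == 0
  zc <- colSums(X) == 0
  if (any(zr) || any(zc)) {
    stop_input("X has all-zero rows or columns; filter them before factorizing (see consensus_cluster, which does)")
  }
  sc <- mean(X)
  init <- with_block_seed(seed, "nmf", {
    list(W = matrix(stats::runif(nrow(X) * r), nrow(X), r) * sc,
         H = matrix(stats::runif(r * ncol(X)), r, ncol(X)) * sc)
  })
  fit <- .nmf_kl_cpp(X, init$W, init$H, as.integer(max_iter), tol,
                     as.integer(conn_stop), as.integer(check_every))
  rownames(fit$W) <- rownames(X)
  colnames(fit$H) <- colnames(X)
  niter <- length(fit$trace) - 1L
  structure(list(W = fit$W, H = fit$H, r = as.integer(r), trace = fit$trace,
                 seed = as.integer(seed), iterations = niter,
                 converged = niter < max_iter),
            class = "nmf_fit")
}

# hard assignment of samples by argmax over the r rows of H;
# ties go to the lower component index (which.max's rule)
nmf_hard_labels <- function(H) {
  apply(H, 2, which.max)
}

connectivity_matrix <- function(labels) {
  outer(labels, labels, `==`) * 1
}

# cophenetic correlation of a consensus matrix: Pearson correlation between
# the condensed distances 1 - C and the cophenetic distances of their
# average-linkage dendrogram. A consensus with zero distance spread (e.g. a
# single perfectly stable cluster) is perfectly reproduced by any dendrogram
# and scores 1 by convention.
consensus_cophenetic <- function(C) {
  d <- stats::as.dist(1 - C)
  if (stats::sd(d) == 0) return(1)
  hc <- stats::hclust(d, method = "average")
  stats::cor(d, stats::cophenetic(hc))
}

consensus_dispersion <- function(C) {
  mean(4 * (C - 0.5)^2)
}

#' Consensus clustering over NMF restarts
#'
#' Runs `n_runs` randomly restarted KL-NMF factorizations per candidate rank,
#' hard-assigns samples by the argmax of `H`, and averages the run-wise
#' connectivity matrices into a samples-by-samples consensus matrix `C`
#' (entries = fraction of runs co-clustered). Rank stability is measured by
#' the cophenetic coefficient of `1 - C`; genes with zero sum or zero
#' variance are removed before factorization.
#'
#' @param X Non-negative genes x samples matrix.
#' @param ranks Integer vector of candidate ranks (all >= 2).
#' @param n_runs Restarts per rank (>= 2; default 30). Restart seeds are
#'   `seed + run index`.
#' @param seed Master seed.
#' @param max_iter,tol Per-run budget passed to [nmf_factorize()]. Consensus
#'   runs default to a bounded budget (`max_iter = 200`, `tol = 1e-4`):
#'   the consensus matrix estimates clustering stability from restart
#'   variability, and driving every restart to full objective convergence
#'   collapses them onto identical solutions at every candidate rank, pushing
#'   the cophenetic coefficient to 1 regardless of rank and defeating rank
#'   selection, while co-clustering of well-separated samples is already
#'   stable within the bounded budget.
#' @param conn_stop,check_every Optional connectivity-based per-run stopping
#'   (see [nmf_factorize()]); off by default.
#' @return List of class `"consensus_result"`: `consensus` (named list of
#'   consensus matrices per rank), `survey` (tibble: rank, cophenetic,
#'   dispersion), `runs`, `seed`, `genes_used`.
#' @export
consensus_cluster <- function(X, ranks = 2:5, n_runs = 30L, seed = 1L,
                              max_iter = 200L, tol = 1e-4,
                              conn_stop = 0L, check_every = 10L) {
  X <- unclass(X)
  if (any(ranks < 2)) stop_input("candidate ranks must all be >= 2")
  if (n_runs < 2) stop_input("n_runs must be >= 2")
  keep <- rowSums(X) > 0 & apply(X, 1, stats::sd) > 0
  if (sum(keep) < max(ranks) + 1) stop_input("too few informative genes after filtering")
  Xf <- X[keep, , drop = FALSE]
  ns <- ncol(Xf)
  consensus <- list()
  survey <- list()
  for (r in ranks) {
    Cacc <- matrix(0, ns, ns)
    for (run in seq_len(n_runs)) {
      fit <- nmf_factorize(Xf, r, seed = seed + run, max_iter = max_iter,
                           tol = tol, conn_stop = conn_stop,
                           check_every = check_every)
      Cacc <- Cacc + connectivity_matrix(nmf_hard_labels(fit$H))
    }
    C <- Cacc / n_runs
    dimnames(C) <- list(colnames(Xf), colnames(Xf))
    consensus[[as.character(r)]] <- C
    survey[[as.character(r)]] <- tibble(
      rank = as.integer(r),
      cophenetic = consensus_cophenetic(C),
      dispersion = consensus_dispersion(C)
    )
  }
  structure(list(consensus = consensus, survey = bind_rows(survey),
                 runs = as.integer(n_runs), seed = as.integer(seed),
                 genes_used = rownames(Xf)),
            class = "consensus_result")
}

#' Select the NMF rank by cophenetic coefficient
#'
#' Returns the candidate rank maximizing the cophenetic coefficient, ties
#' broken toward the smallest rank. The full rank survey travels with the
#' result (`attr(, "survey")`).
#'
#' @param result A `"consensus_result"`.
#' @param candidate_ranks Ranks to consider (default: all surveyed).
#' @return The selected rank (integer) with the survey attached.
#' @export
select_rank <- function(result, candidate_ranks = NULL) {
  survey <- result$survey
  if (!is.null(candidate_ranks)) {
    survey <- survey[survey$rank %in% candidate_ranks, , drop = FALSE]
  }
  if (nrow(survey) == 0) stop_input("no candidate ranks with a computed cophenetic coefficient")
  survey <- survey[order(survey$rank), , drop = FALSE]
  best <- survey$rank[which.max(survey$cophenetic)]
  structure(as.integer(best), survey = survey)
}

#' Assign cluster labels from a consensus matrix
#'
#' Average-linkage hierarchical clustering of `1 - C` cut at `k = rank`;
#' cluster labels are renamed by descending cluster size (cluster 1 is the
#' largest), making the naming stable across runs.
#'
#' @param result A `"consensus_result"`.
#' @param rank Rank whose consensus matrix to cut.
#' @return Tibble with class `"cluster_assignment"`: `sample_id`, `cluster`
#'   (integer, 1 = largest).
#' @export
assign_clusters <- function(result, rank) {
  C <- result$consensus[[as.character(rank)]]
  if (is.null(C)) stop_input(sprintf("no consensus matrix computed at rank %s", rank))
  d <- stats::as.dist(1 - C)
  if (max(d) == 0) {
    warn("degenerate consensus matrix (all samples always co-cluster); labels are arbitrary")
  }
  hc <- stats::hclust(d, method = "average")
  raw <- stats::cutree(hc, k = rank)
  sizes <- sort(table(raw), decreasing = TRUE)
  remap <- stats::setNames(seq_along(sizes), names(sizes))
  lab <- unname(remap[as.character(raw)])
  out <- tibble(sample_id = colnames(C), cluster = as.integer(lab))
  class(out) <- c("cluster_assignment", class(out))
  out
}
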