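#' Single-sample GSEA scores
#'
#' Per-sample rank-based enrichment: genes are ranked descending by
#' expression (average ranks on ties) and the enrichment score of a set `S`
#' is the summed difference between the weighted in-set ECDF (in-set genes
#' weighted by `rank^alpha`) and the uniform out-of-set ECDF, accumulated
#' over every rank position. With `normalize = TRUE` all scores are divided
#' by the range (max - min) over the whole score matrix, the customary
#' ssGSEA normalization.
#'
#' @param X Expression matrix (genes x samples), non-negative log scale.
#' @param sets A `"gene_sets"` collection (or named list of gene vectors).
#' @param alpha Rank weighting exponent (default 0.25).
#' @param normalize Range-normalize the score matrix (default TRUE).
#' @return Matrix of scores (signatures x samples) with class
#'   `"score_matrix"`; parameters recorded in attributes.
#' @export
ssgsea_scores <- function(X, sets, alpha = 0.25, normalize = TRUE) {
  X <- unclass(X)
  genes <- rownames(X)
  n <- length(genes)
  sets <- lapply(sets, unique)
  keep <- vapply(sets, function(s) {
    k <- sum(s %in% genes)
    k > 0 && k < n
  }, logical(1))
  full <- vapply(sets, function(s) sum(s %in% genes) == n, logical(1))
  if (any(full)) {
    stop_input(sprintf("gene set '%s' covers every gene; out-of-set ECDF undefined",
                       names(sets)[full][1]))
  }
  if (any(!keep)) {
    warn(sprintf("skipping %d gene set(s) with no overlap: %s",
                 sum(!keep), paste(names(sets)[!keep], collapse = ", ")))
  }
  sets <- sets[keep]
  if (length(sets) == 0) stop_input("no gene set overlaps the expression matrix")

  # per sample: ranks ascending (top expression = n), order descending
  R <- apply(X, 2, rank, ties.method = "average")
  scores <- matrix(NA_real_, length(sets), ncol(X),
                   dimnames = list(names(sets), colnames(X)))
  in_set <- lapply(sets, function(s) genes %in% s)
  for (j in seq_len(ncol(X))) {
    ord <- order(R[, j], decreasing = TRUE)
    w_all <- R[ord, j]^alpha
    for (k in seq_along(sets)) {
      ins <- in_set[[k]][ord]
      w_in <- w_all * ins
      p_in <- cumsum(w_in) / sum(w_in)
      p_out <- cumsum(!ins) / sum(!ins)
      scores[k, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  structure(scores, class = c("score_matrix", class(scores)),
            method = "ssgsea", alpha = alpha, normalized = normalize)
}

# standard library-size log-normalization for raw counts (per-cell counts
# scaled to a common size factor, then log1p); used before module scoring
lognormalize_counts <- function(counts, scale_factor = 1e4) {
  cs <- Matrix::colSums(counts)
  cs[cs == 0] <- 1
  out <- log1p(counts %*% Matrix::Diagonal(x = scale_factor / cs))
  dimnames(out) <- dimnames(counts)
  out
}

#' Binned-control module scores
#'
#' Per-cell (or per-sample) gene-set score in the style used for single-cell
#' signature scoring: genes are binned into `n_bins` by average expression,
#' each set gene contributes `n_ctrl` same-bin control genes (sampled without
#' replacement, with replacement when the bin is smaller than `n_ctrl`; set
#' genes are never controls), and the score is the mean expression of the set
#' minus the mean expression of the pooled controls.
#'
#' @param M An expression matrix, or an `"sc_matrix"` whose counts are then
#'   library-size log-normalized first.
#' @param set Character vector of gene symbols.
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_ctrl Controls per set gene (default 100).
#' @param seed Seed fixing the control draw (required).
#' @return Named numeric vector of per-cell scores; control pool and
#'   parameters in attributes.
#' @export
module_scores <- function(M, set, n_bins = 24L, n_ctrl = 100L, seed) {
  if (missing(seed)) stop_input("module_scores requires an explicit seed")
  if (n_bins < 1) stop_input("n_bins must be >= 1")
  expr <- if (inherits(M, "sc_matrix")) lognormalize_counts(M$counts) else unclass(M)
  genes <- rownames(expr)
  set <- unique(set)
  set_in <- intersect(set, genes)
  if (length(set_in) == 0) stop_input("gene set has no overlap with the matrix")

  avg <- Matrix::rowMeans(expr)
  n_bins_eff <- min(n_bins, length(avg))
  # equal-occupancy bins over the rank of average expression
  bin <- ceiling(rank(avg, ties.method = "first") / length(avg) * n_bins_eff)
  names(bin) <- genes

  ctrl_pool <- with_block_seed(seed, "control", {
    pool <- character(0)
    for (g in set_in) {
      cand <- genes[bin == bin[[g]]]
      cand <- setdiff(cand, set_in)
      if (length(cand) == 0) next
      drawn <- if (length(cand) >= n_ctrl) {
        sample(cand, n_ctrl, replace = FALSE)
      } else {
        sample(cand, n_ctrl, replace = TRUE)
      }
      pool <- union(pool, drawn)
    }
    pool
  })
  if (length(ctrl_pool) == 0) stop_input("no control genes available outside the set")

  set_mean <- Matrix::colMeans(expr[set_in, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(expr[ctrl_pool, , drop = FALSE])
  out <- set_mean - ctrl_mean
  attr(out, "controls") <- ctrl_pool
  attr(out, "params") <- list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  out
}

#' First-principal-component signature score
#'
#' Restricts the matrix to a gene set, centers each gene across samples (no
#' variance scaling), and takes each sample's projection on the leading
#' principal axis as the signature score. Because an eigenvector's sign is
#' arbitrary, the score is oriented so that it correlates positively with
#' the per-sample mean expression of the set: higher score means higher
#' set expression.
#'
#' @param X Expression matrix (genes x samples).
#' @param set Character vector of gene symbols (>= 2 must match).
#' @return List of class `"pc1_score"`: `score` (named per-sample), `loadings`
#'   (unit-norm per-gene), `centers`, `genes`, `flipped` (orientation flag).
#' @export
pca_signature_score <- function(X, set) {
  X <- unclass(X)
  genes <- intersect(unique(set), rownames(X))
  if (length(genes) < 2) stop_input("signature needs >= 2 genes matched in the matrix")
  if (ncol(X) < 3) stop_input("PC1 scoring needs >= 3 samples")
  sub <- X[genes, , drop = FALSE]
  centers <- rowMeans(sub)
  Z <- sub - centers
  if (all(abs(Z) < 1e-300)) stop_input("zero-variance submatrix; PC1 undefined")
  sv <- svd(Z, nu = 1, nv = 1)
  loadings <- sv$u[, 1]
  score <- drop(crossprod(Z, loadings))
  names(score) <- colnames(X)
  names(loadings) <- genes
  set_mean <- colMeans(sub)
  flipped <- FALSE
  if (stats::sd(set_mean) > 0) {
    r <- stats::cor(score, set_mean)
    if (!is.na(r) && r < 0) {
      score <- -score
      loadings <- -loadings
      flipped <- TRUE
    }
  }
  structure(list(score = score, loadings = loadings, centers = centers,
                 genes = genes, flipped = flipped),
            class = "pc1_score")
}

# project new samples with stored loadings + centers (train/apply separation)
apply_pc1 <- function(pc1, X) {
  X <- unclass(X)
  miss <- setdiff(pc1$genes, rownames(X))
  if (length(miss) > 0) {
    stop_input(sprintf("%d signature gene(s) absent from the new matrix", length(miss)))
  }
  Z <- X[pc1$genes, , drop = FALSE] - pc1$centers
  drop(crossprod(Z, pc1$loadings))
}

#' Pearson correlation of score vectors
#'
#' Pairwise-complete Pearson correlation of `a` against a vector or against
#' every row of a score matrix. Zero-variance pairs are flagged as missing
#' rather than erroring.
#'
#' @param a Numeric vector.
#' @param b Numeric vector, or matrix/score matrix with rows to correlate.
#' @return Tibble: `signature`, `r`, `n_used`, `degenerate`.
#' @export
pearson_correlation <- function(a, b) {
  one <- function(nm, y) {
    ok <- is.finite(a) & is.finite(y)
    n_used <- sum(ok)
    if (n_used < 3) stop_input("need >= 3 paired finite observations")
    degen <- stats::sd(a[ok]) == 0 || stats::sd(y[ok]) == 0
    tibble(signature = nm,
           r = if (degen) NA_real_ else stats::cor(a[ok], y[ok]),
           n_used = n_used, degenerate = degen)
  }
  if (is.matrix(b)) {
    if (ncol(b) != length(a)) stop_input("length of a must match columns of b")
    if (is.null(rownames(b))) rownames(b) <- as.character(seq_len(nrow(b)))
    bind_rows(lapply(rownames(b), function(nm) one(nm, unclass(b)[nm, ])))
  } else {
    if (length(a) != length(b)) stop_input("vectors must have equal length")
    one("b", b)
  }
}
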