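# vectorized two-group Wilcoxon rank-sum over the rows of a matrix:
# normal approximation with tie and continuity corrections, two-sided,
# matching stats::wilcox.test(exact = FALSE, correct = TRUE)
row_wilcox <- function(X, in_group) {
  n1 <- sum(in_group)
  n2 <- sum(!in_group)
  p <- numeric(nrow(X))
  stat <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    r <- rank(X[i, ])
    W <- sum(r[in_group]) - n1 * (n1 + 1) / 2
    ties <- table(r)
    tiecor <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
    v <- n1 * n2 / 12 * ((n1 + n2 + 1) - tiecor)
    d <- W - n1 * n2 / 2
    z <- if (v > 0) (d - sign(d) * 0.5) / sqrt(v) else 0
    stat[i] <- W
    p[i] <- if (v > 0) min(1, 2 * stats::pnorm(-abs(z))) else 1
  }
  list(statistic = stat, p = p)
}

row_welch <- function(X, in_group) {
  a <- X[, in_group, drop = FALSE]
  b <- X[, !in_group, drop = FALSE]
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, stats::var); v2 <- apply(b, 1, stats::var)
  n1 <- ncol(a); n2 <- ncol(b)
  se2 <- v1 / n1 + v2 / n2
  tstat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)), 1)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tstat), df), 1)
  list(statistic = tstat, p = p)
}

#' One-vs-rest cluster marker genes
#'
#' For every cluster, tests each gene against all remaining samples and
#' reports the fold change on a natural-log scale: the difference of
#' within-group means of log2 expression times `ln 2` (the convention of the
#' common single-cell marker tools, whose lnFC thresholds of 0.25 and 0.5
#' this pipeline reuses). A gene is a marker when `q < alpha_q` and
#' `|lnFC| >= min_lnfc`.
#'
#' @param X Expression matrix (genes x samples, log2 scale).
#' @param labels A `"cluster_assignment"` tibble (sample_id, cluster) or a
#'   vector of labels named by sample.
#' @param min_lnfc Minimum absolute natural-log fold change (default 0.25).
#' @param alpha_q BH-adjusted significance threshold (default 0.05).
#' @param test `"wilcoxon"` (default) or `"welch_t"`.
#' @return Tibble of class `"de_result"`: gene, cluster, ln_fc, statistic,
#'   p, q, direction, marker.
#' @export
cluster_markers <- function(X, labels, min_lnfc = 0.25, alpha_q = 0.05,
                            test = c("wilcoxon", "welch_t")) {
  test <- match.arg(test)
  X <- unclass(X)
  if (is.data.frame(labels)) {
    lab <- stats::setNames(labels$cluster, labels$sample_id)
  } else {
    lab <- labels
  }
  lab <- lab[colnames(X)]
  if (any(is.na(lab))) stop_input("labels missing for some samples")
  tab <- table(lab)
  if (length(tab) < 2) stop_input("need >= 2 clusters")
  if (any(tab < 3)) {
    stop_input(sprintf("cluster '%s' has fewer than 3 samples", names(tab)[tab < 3][1]))
  }
  out <- list()
  for (cl in names(tab)) {
    ing <- lab == cl
    res <- if (test == "wilcoxon") row_wilcox(X, ing) else row_welch(X, ing)
    lnfc <- (rowMeans(X[, ing, drop = FALSE]) -
             rowMeans(X[, !ing, drop = FALSE])) * log(2)
    q <- bh_adjust(res$p)
    out[[cl]] <- tibble(
      gene = rownames(X), cluster = cl, ln_fc = unname(lnfc),
      statistic = res$statistic, p = res$p, q = q,
      direction = ifelse(lnfc >= 0, "up", "down"),
      marker = q < alpha_q & abs(lnfc) >= min_lnfc
    )
  }
  res <- bind_rows(out)
  attr(res, "params") <- list(min_lnfc = min_lnfc, alpha_q = alpha_q, test = test,
                              lnfc_definition = "diff of log2 group means * ln(2)")
  class(res) <- c("de_result", class(res))
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, capped at 1.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop_input("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation of gene sets
#'
#' Upper-tail hypergeometric test `P(X >= k)` of a query gene list against
#' each set of a collection, within a stated gene universe; BH-adjusted
#' across sets.
#'
#' @param query Character vector of genes (must lie within `universe`).
#' @param sets `"gene_sets"` collection (intersected with the universe).
#' @param universe Character vector, the testable gene universe.
#' @return Tibble: set, k (overlap), K (set size), n (query size),
#'   N (universe size), p, q.
#' @export
hypergeometric_enrichment <- function(query, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop_input("empty gene universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    stop_input(sprintf("%d query gene(s) outside the universe", length(outside)))
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    K <- length(s)
    k <- length(intersect(query, s))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(set = nm, k = k, K = K, n = n, N = N, p = p)
  })
  out <- bind_rows(rows)
  out$q <- bh_adjust(out$p)
  out
}

#' Pearson chi-square test of independence
#'
#' No continuity correction; expected counts are returned and a warning is
#' emitted when any expected count is below 5.
#'
#' @param table 2-D matrix/table of non-negative counts (>= 2 rows and cols).
#' @return List: statistic, df, p, expected.
#' @export
chi_square_test <- function(table) {
  tab <- as.matrix(table)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop_input("contingency table needs >= 2 rows and columns")
  if (any(tab < 0)) stop_input("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_input("zero marginal row or column in contingency table")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) warn("expected count below 5; chi-square approximation may be poor")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = expected)
}

#' Rank-based location test across groups
#'
#' Two groups: Wilcoxon rank-sum with normal approximation, tie correction
#' and continuity correction. More than two: Kruskal-Wallis H with tie
#' correction.
#'
#' @param groups List of numeric vectors, one per group (each >= 2 values).
#' @return List: statistic, p, method.
#' @export
rank_location_test <- function(groups) {
  if (length(groups) < 2) stop_input("need >= 2 groups")
  if (any(lengths(groups) < 2)) stop_input("every group needs >= 2 observations")
  if (length(groups) == 2) {
    wt <- suppressWarnings(
      stats::wilcox.test(groups[[1]], groups[[2]], exact = FALSE, correct = TRUE)
    )
    list(statistic = unname(wt$statistic), p = wt$p.value, method = "wilcoxon")
  } else {
    x <- unlist(groups)
    g <- factor(rep(seq_along(groups), lengths(groups)))
    kt <- stats::kruskal.test(x, g)
    list(statistic = unname(kt$statistic), p = kt$p.value, method = "kruskal-wallis")
  }
}

#' Tumor mutation burden per sample
#'
#' Counts mutation records per sample, restricted to nonsilent variant
#' classes when `nonsilent_only = TRUE`. Samples with no records get 0.
#' Optionally scales to mutations per megabase.
#'
#' @param mut A `"mutation_table"`.
#' @param samples Character vector of samples the burden is reported for.
#' @param nonsilent_only Count only nonsilent classes (default TRUE).
#' @param per_mb Divide by `capture_mb` (default FALSE).
#' @param capture_mb Capture size in Mb used with `per_mb` (default 38).
#' @return Tibble: sample_id, tmb.
#' @export
compute_tmb <- function(mut, samples, nonsilent_only = TRUE,
                        per_mb = FALSE, capture_mb = 38) {
  if (length(samples) == 0) stop_input("sample list must be non-empty")
  rec <- mut
  if (nonsilent_only && nrow(rec) > 0) {
    rec <- rec[rec$variant_classification %in% nonsilent_vocabulary(), , drop = FALSE]
  }
  counts <- table(factor(rec$sample_id, levels = samples))
  tmb <- as.numeric(counts)
  if (per_mb) tmb <- tmb / capture_mb
  tibble(sample_id = samples, tmb = tmb)
}
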