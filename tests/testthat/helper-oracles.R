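# Independent brute-force oracles used to pin expected values. These are
# deliberately naive re-derivations (explicit loops, enumeration, grid
# search) and never call the implementation paths they check.

# ssGSEA running sum for one sample, enumerated position by position
oracle_ssgsea_one <- function(x, set, alpha) {
  r <- rank(x, ties.method = "average")
  ord <- order(r, decreasing = TRUE)
  ins <- names(x)[ord] %in% set
  rr <- r[ord]
  w_total <- sum(rr[ins]^alpha)
  n_out <- sum(!ins)
  p_in <- 0
  p_out <- 0
  es <- 0
  for (i in seq_along(x)) {
    if (ins[i]) p_in <- p_in + rr[i]^alpha / w_total else p_out <- p_out + 1 / n_out
    es <- es + (p_in - p_out)
  }
  unname(es)
}

# Cox log partial likelihood for a single covariate, Breslow-free fixture
# (no tied event times assumed), evaluated explicitly
oracle_cox_loglik <- function(beta, x, time, event) {
  s <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    s <- s + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  s
}

# two-stage grid search maximizer of the partial likelihood
oracle_cox_beta <- function(x, time, event, lim = 5) {
  coarse <- seq(-lim, lim, by = 0.01)
  ll <- vapply(coarse, oracle_cox_loglik, numeric(1), x = x, time = time, event = event)
  b0 <- coarse[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  llf <- vapply(fine, oracle_cox_loglik, numeric(1), x = x, time = time, event = event)
  fine[which.max(llf)]
}

# two-group log-rank chi-square from the explicit event table
oracle_logrank2 <- function(time, event, group) {
  g <- as.integer(factor(group))
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g == 1)
    n <- sum(at); n1 <- sum(at & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Benjamini-Hochberg step-up computed by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# exact two-sided Wilcoxon p by full permutation enumeration (small n)
oracle_wilcox_perm_p <- function(a, b) {
  x <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(x), n1)
  obs <- abs(sum(rank(x)[seq_len(n1)]) - n1 * (length(x) + 1) / 2)
  stats <- apply(idx, 2, function(ii) {
    abs(sum(rank(x)[ii]) - n1 * (length(x) + 1) / 2)
  })
  mean(stats >= obs - 1e-12)
}

make_expr <- function(values, genes = NULL, samples = NULL) {
  genes <- genes %||% sprintf("g%03d", seq_len(nrow(values)))
  samples <- samples %||% sprintf("s%03d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tmp_tsv <- function(df) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}
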