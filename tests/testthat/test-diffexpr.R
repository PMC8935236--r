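test_that("per-gene Wilcoxon p-values agree with stats::wilcox.test", {
  set.seed(7)
  X <- make_expr(matrix(runif(20 * 24, 0, 8), 20, 24))
  lab <- rep(c(1, 2), each = 12)
  names(lab) <- colnames(X)
  de <- cluster_markers(X, lab, test = "wilcoxon")
  de1 <- de[de$cluster == "1", ]
  for (g in sample(rownames(X), 5)) {
    ref <- stats::wilcox.test(unclass(X)[g, lab == 1], unclass(X)[g, lab == 2],
                              exact = FALSE, correct = TRUE)$p.value
    expect_equal(de1$p[de1$gene == g], ref, tolerance = 1e-12)
  }
})

test_that("lnFC is the difference of log2 group means times ln 2", {
  X <- make_expr(matrix(c(rep(4, 6), rep(2, 6),
                          rep(1, 6), rep(1, 6)), 2, 12, byrow = TRUE))
  lab <- rep(c(1, 2), each = 6)
  names(lab) <- colnames(X)
  de <- cluster_markers(X, lab)
  expect_equal(de$ln_fc[de$gene == "g001" & de$cluster == "1"], 2 * log(2))
  expect_equal(de$ln_fc[de$gene == "g002" & de$cluster == "1"], 0)
})

test_that("a stricter lnFC threshold yields a subset of markers", {
  bulk <- simulate_bulk_cohort(sim_config(n_samples = 90L, n_genes = 300L,
                                          n_ferroptosis = 40L,
                                          program_sizes = c(canonical = 20L, immune = 20L, stromal = 20L),
                                          ferro_in_program = c(canonical = 4L, immune = 8L, stromal = 8L),
                                          seed = 3))
  lab <- setNames(bulk$truth$samples$cluster, bulk$truth$samples$sample_id)
  de25 <- cluster_markers(bulk$expr, lab, min_lnfc = 0.25)
  de50 <- cluster_markers(bulk$expr, lab, min_lnfc = 0.5)
  k25 <- paste(de25$gene, de25$cluster)[de25$marker]
  k50 <- paste(de50$gene, de50$cluster)[de50$marker]
  expect_true(all(k50 %in% k25))
})

test_that("planted markers are recovered with high power", {
  bulk <- simulate_bulk_cohort(sim_config(n_samples = 200L, seed = 41))
  tr <- bulk$truth
  lab <- setNames(tr$samples$cluster, tr$samples$sample_id)
  de <- cluster_markers(bulk$expr, lab, min_lnfc = 0.25)
  imm_genes <- tr$genes$gene_id[tr$genes$program == "immune"]
  hit <- de$gene[de$cluster == "immune" & de$marker & de$direction == "up"]
  expect_gte(mean(imm_genes %in% hit), 0.95)
})

test_that("the null model keeps the marker rate near the nominal level", {
  rates <- vapply(1:10, function(s) {
    bulk <- simulate_bulk_cohort(sim_config(n_samples = 60L, n_genes = 200L,
                                            n_ferroptosis = 30L,
                                            program_sizes = c(canonical = 10L, immune = 10L, stromal = 10L),
                                            ferro_in_program = c(canonical = 2L, immune = 4L, stromal = 4L),
                                            delta = 0, seed = s))
    lab <- setNames(bulk$truth$samples$cluster, bulk$truth$samples$sample_id)
    de <- cluster_markers(bulk$expr, lab, min_lnfc = 0)
    mean(de$q < 0.05)
  }, numeric(1))
  se <- sd(rates) / sqrt(length(rates))
  expect_lte(mean(rates), 0.05 + 3 * se + 0.01)
})

test_that("BH adjustment matches the hand step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(3)
  p <- runif(50)
  expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), oracle_bh(p)[perm], tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), class = "fersigr_input_error")
})

test_that("hypergeometric enrichment matches exact enumeration", {
  universe <- sprintf("u%02d", 1:20)
  sets <- gene_sets(list(S = universe[1:5]))
  res <- hypergeometric_enrichment(universe[1:5], sets, universe)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$k, 5)
  # query disjoint from the set
  res0 <- hypergeometric_enrichment(universe[6:10], sets, universe)
  expect_equal(res0$p, 1.0)
  # set equal to the universe makes the overlap certain
  setsU <- gene_sets(list(U = universe))
  resU <- hypergeometric_enrichment(universe[1:5], setsU, universe)
  expect_equal(resU$p, 1.0)
  expect_error(hypergeometric_enrichment("x", sets, universe),
               class = "fersigr_input_error")
  expect_error(hypergeometric_enrichment(character(), sets, character()),
               class = "fersigr_input_error")
})

test_that("chi-square statistic matches direct arithmetic", {
  flat <- chi_square_test(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1.0)

  tab <- matrix(c(20, 5, 5, 20), 2, 2)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  manual <- sum((tab - E)^2 / E)
  res <- chi_square_test(tab)
  expect_equal(res$statistic, manual, tolerance = 1e-10)
  res2 <- chi_square_test(tab * 2)
  expect_equal(res2$statistic, 2 * manual, tolerance = 1e-10)
  expect_error(chi_square_test(matrix(c(1, 2, 0, 0), 2, 2)),
               class = "fersigr_input_error")
})

test_that("rank location test branches and symmetry behave as declared", {
  g1 <- c(1, 2, 3, 4, 5)
  same <- rank_location_test(list(g1, g1))
  expect_gte(same$p, 0.99)
  set.seed(1)
  a <- rnorm(30); b <- rnorm(30, 1)
  expect_equal(rank_location_test(list(a, b))$p,
               rank_location_test(list(b, a))$p, tolerance = 1e-12)
  three <- rank_location_test(list(rnorm(50), rnorm(50, 1), rnorm(50, 2)))
  expect_equal(three$method, "kruskal-wallis")
  expect_lt(three$p, 0.05)
  expect_error(rank_location_test(list(a, numeric())), class = "fersigr_input_error")
})

test_that("normal-approximation Wilcoxon tracks the exact permutation p on tiny samples", {
  set.seed(12)
  for (i in 1:5) {
    a <- runif(8, 0, 10)   # continuous: tie-free permutation null
    b <- runif(8, 2, 12)
    approx_p <- rank_location_test(list(a, b))$p
    exact_p <- oracle_wilcox_perm_p(a, b)
    expect_lt(abs(approx_p - exact_p), 0.02)
  }
})

test_that("TMB counts nonsilent records with zero-fill", {
  mt <- mutation_table(tibble::tibble(
    sample_id = c("s1", "s1", "s1", "s1", "s1"),
    gene_symbol = paste0("g", 1:5),
    variant_classification = c("Missense_Mutation", "Nonsense_Mutation",
                               "Splice_Site", "Silent", "Silent")
  ))
  tmb <- compute_tmb(mt, c("s1", "s2"), nonsilent_only = TRUE)
  expect_equal(tmb$tmb, c(3, 0))
  empty <- mutation_table(tibble::tibble(sample_id = character(),
                                         gene_symbol = character(),
                                         variant_classification = character()))
  expect_equal(compute_tmb(empty, c("a", "b"))$tmb, c(0, 0))
  expect_equal(compute_tmb(mt, "s1", nonsilent_only = TRUE, per_mb = TRUE)$tmb, 3 / 38)
  expect_error(compute_tmb(mt, character()), class = "fersigr_input_error")
})
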