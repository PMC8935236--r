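small_cfg <- function(...) {
  defaults <- list(n_samples = 120L, n_genes = 400L, n_ferroptosis = 60L,
                   program_sizes = c(canonical = 30L, immune = 30L, stromal = 30L),
                   ferro_in_program = c(canonical = 5L, immune = 10L, stromal = 10L),
                   n_mut_genes = 80L, n_cells = 300L, n_icb = 80L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("bulk cohort honours mixing proportions and config invariants", {
  cfg <- sim_config(seed = 3)
  bulk <- simulate_bulk_cohort(cfg)
  counts <- table(bulk$truth$samples$cluster)[c("canonical", "immune", "stromal")]
  expected <- cfg$mixing[c("canonical", "immune", "stromal")] * cfg$n_samples
  # within 4 multinomial SDs of 150/105/45
  sds <- sqrt(expected * (1 - cfg$mixing))
  expect_true(all(abs(counts - expected) < 4 * sds))
  expect_s3_class(bulk$expr, "expr_matrix")
  expect_equal(length(bulk$sets$FERROPTOSIS), cfg$n_ferroptosis)
  roles <- table(bulk$truth$genes$role)
  expect_equal(sum(roles), cfg$n_ferroptosis)
  expect_true(all(c("driver", "suppressor", "marker") %in% names(roles)))
})

test_that("generated artifacts satisfy the core data-model invariants", {
  bulk <- simulate_bulk_cohort(small_cfg(seed = 9))
  expect_true(all(unclass(bulk$expr) >= 0))
  expect_false(anyDuplicated(rownames(bulk$expr)) > 0)
  expect_true(all(bulk$clinical$event %in% c(0, 1)))
  expect_true(all(bulk$clinical$time >= 0))
  expect_true(all(bulk$mutations$variant_classification %in%
                    fersigr:::variant_vocabulary()))
  sc <- simulate_single_cell_cohort(small_cfg(seed = 9))
  v <- sc$sc$counts@x
  expect_true(all(v >= 0) && all(v == round(v)))
  expect_equal(nrow(sc$sc$meta), length(sc$sc$cell_ids))
})

test_that("fixed seed reproduces cohorts bit-identically; blocks are independent", {
  a <- simulate_bulk_cohort(small_cfg(seed = 5))
  b <- simulate_bulk_cohort(small_cfg(seed = 5))
  expect_identical(unclass(a$expr), unclass(b$expr))
  expect_identical(a$clinical$time, b$clinical$time)
  expect_identical(a$mutations, b$mutations)
  # changing the single-cell block must not perturb the bulk expression draw
  c2 <- simulate_bulk_cohort(small_cfg(seed = 5, n_cells = 999L))
  expect_identical(unclass(a$expr), unclass(c2$expr))
})

test_that("delta = 0 removes program separation (null model)", {
  bulk <- simulate_bulk_cohort(small_cfg(seed = 21, delta = 0))
  X <- unclass(bulk$expr)
  tr <- bulk$truth
  imm_genes <- tr$genes$gene_id[tr$genes$program == "immune"]
  by_cl <- tapply(colMeans(X[imm_genes, ]), tr$samples$cluster, mean)
  expect_lt(max(by_cl) - min(by_cl), 0.15)  # Monte-Carlo error only
})

test_that("stromal cluster has the worst survival at beta_stromal = 0.8", {
  cfg <- sim_config(n_samples = 400L, seed = 13)
  bulk <- simulate_bulk_cohort(cfg)
  cl <- bulk$clinical
  tr <- bulk$truth$samples
  lr <- logrank_test(cl$time, cl$event, tr$cluster)
  expect_lt(lr$p, 0.01)
  med_time <- tapply(cl$time, tr$cluster, median)
  expect_true(med_time[["stromal"]] < med_time[["canonical"]])
  expect_true(med_time[["stromal"]] < med_time[["immune"]])
})

test_that("mutation burden is elevated in the immune cluster by the multiplier", {
  cfg <- sim_config(seed = 31)
  bulk <- simulate_bulk_cohort(cfg)
  tmb <- compute_tmb(bulk$mutations, bulk$truth$samples$sample_id,
                     nonsilent_only = FALSE)
  cl <- bulk$truth$samples$cluster[match(tmb$sample_id, bulk$truth$samples$sample_id)]
  means <- tapply(tmb$tmb, cl, mean)
  ratio <- means[["immune"]] / mean(means[c("canonical", "stromal")])
  expect_lt(abs(ratio - cfg$mut_multiplier_immune), 0.1 * cfg$mut_multiplier_immune)
})

test_that("single-cell cohort respects type proportions and program elevation", {
  cfg <- sim_config(seed = 17)
  sc <- simulate_single_cell_cohort(cfg)
  ct <- table(sc$truth$cells$cell_type)
  expect_lt(abs(ct[["epithelial"]] / cfg$n_cells - 0.4), 0.05)
  # NB mean oracle: stromal-program genes elevated by sc_marker_fold in
  # stromal cells relative to (non-program) epithelial-state-free baseline
  genes <- sc$truth$genes
  str_genes <- genes$gene_id[genes$program == "stromal"]
  counts <- sc$sc$counts
  strom_cells <- sc$truth$cells$cell_id[sc$truth$cells$cell_type == "stromal"]
  epi_cells <- sc$truth$cells$cell_id[sc$truth$cells$cell_type == "epithelial"]
  m_str <- mean(Matrix::rowMeans(counts[str_genes, strom_cells]))
  m_epi <- mean(Matrix::rowMeans(counts[str_genes, epi_cells]))
  expect_lt(abs(m_str / m_epi - cfg$sc_marker_fold), 0.1 * cfg$sc_marker_fold)
})

test_that("ICB response tracks immune-minus-stromal activity through gamma", {
  cfg0 <- sim_config(n_icb = 1000L, gamma_icb = 0, seed = 23)
  null <- simulate_icb_cohort(cfg0)
  tr <- null$truth$samples
  rate_imm <- mean(tr$response[tr$cluster == "immune"])
  rate_str <- mean(tr$response[tr$cluster == "stromal"])
  expect_lt(abs(rate_imm - rate_str), 0.05)

  cfg2 <- sim_config(n_icb = 1000L, gamma_icb = 2, seed = 23)
  eff <- simulate_icb_cohort(cfg2)
  tr2 <- eff$truth$samples
  expect_gt(mean(tr2$response[tr2$cluster == "immune"]),
            mean(tr2$response[tr2$cluster == "stromal"]) + 0.2)

  again <- simulate_icb_cohort(cfg2)
  expect_identical(unclass(eff$expr), unclass(again$expr))
  expect_identical(eff$clinical$response, again$clinical$response)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(mixing = c(canonical = 0.6, immune = 0.3, stromal = 0.3)),
               class = "fersigr_input_error")
  expect_error(sim_config(program_sizes = c(canonical = 300L, immune = 300L, stromal = 300L),
                          n_genes = 500L),
               class = "fersigr_input_error")
  expect_error(sim_config(sigma = 0), class = "fersigr_input_error")
})
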