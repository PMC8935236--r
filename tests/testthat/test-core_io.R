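test_that("expression TSV reads back what was written, at full precision", {
  set.seed(11)
  X <- make_expr(matrix(runif(30, 0, 12), 6, 5))
  out <- withr::local_tempdir()
  write_results(list(expr = X), out)
  Y <- read_expression_matrix(file.path(out, "expr.tsv"))
  expect_equal(rownames(Y), rownames(X))
  expect_equal(colnames(Y), colnames(X))
  expect_lt(max(abs(unclass(Y) - unclass(X))), 1e-12)
})

test_that("duplicate gene rows collapse to the larger-mean row", {
  df <- data.frame(gene = c("GPX4", "ACSL4", "GPX4"),
                   s1 = c(2.0, 1.0, 5.0), s2 = c(2.0, 1.0, 5.0))
  f <- write_tmp_tsv(df)
  expect_message(X <- read_expression_matrix(f), "GPX4")
  expect_equal(nrow(X), 2)
  expect_equal(unname(unclass(X)["GPX4", ]), c(5, 5))
})

test_that("malformed expression input raises typed format errors", {
  neg <- write_tmp_tsv(data.frame(gene = c("a", "b"), s1 = c(1, -1.2), s2 = c(1, 2)))
  expect_error(read_expression_matrix(neg), class = "fersigr_format_error")
  txt <- write_tmp_tsv(data.frame(gene = c("a", "b"), s1 = c("x", "y"), s2 = c(1, 2)))
  expect_error(read_expression_matrix(txt), class = "fersigr_format_error")
  expect_error(expression_matrix(matrix(1, 1, 3, dimnames = list("a", c("x", "y", "z")))),
               class = "fersigr_format_error")
})

test_that("transpose flag and log2p1 transform work together", {
  df <- data.frame(sample = c("s1", "s2", "s3"),
                   gA = c(3, 1, 0), gB = c(7, 0, 1))
  f <- write_tmp_tsv(df)
  X <- read_expression_matrix(f, transpose = TRUE, log2p1 = TRUE)
  expect_equal(dim(X), c(2L, 3L))
  expect_equal(unname(unclass(X)["gA", "s1"]), log2(4))
})

test_that("GMT parsing handles the cytotoxic marker line, dedup and name clashes", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c(
    "CYTOTOX\tna\tCST7\tGZMA\tGZMB\tIFNG\tNKG7\tPRF1",
    "DUP_MEMBERS\tna\tGPX4\tGPX4\tACSL4"
  ), f)
  gs <- read_gene_sets_gmt(f)
  expect_equal(length(gs$CYTOTOX), 6)
  expect_setequal(gs$CYTOTOX, c("CST7", "GZMA", "GZMB", "IFNG", "NKG7", "PRF1"))
  expect_equal(gs$DUP_MEMBERS, c("GPX4", "ACSL4"))

  f2 <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("A\tna\tg1", "A\tna\tg2"), f2)
  expect_error(read_gene_sets_gmt(f2), class = "fersigr_format_error")

  f3 <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("OK\trole=driver\tg1\tg2", "EMPTY\tna\t\t"), f3)
  expect_warning(gs3 <- read_gene_sets_gmt(f3), "EMPTY")
  expect_named(gs3, "OK")
  expect_equal(unname(attr(gs3, "roles")["OK"]), "driver")
})

test_that("gene sets round-trip through GMT including role tags", {
  gs <- gene_sets(list(A = c("g1", "g2"), B = c("g3")),
                  roles = c(A = "driver", B = NA))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gene_sets_gmt(gs, f)
  gs2 <- read_gene_sets_gmt(f)
  expect_equal(gs2$A, gs$A)
  expect_equal(unname(attr(gs2, "roles")["A"]), "driver")
})

test_that("clinical table validates events and flags missing survival", {
  ok <- write_tmp_tsv(data.frame(sample_id = paste0("s", 1:5),
                                 time = c(10, 20, NA, 40, 50),
                                 event = c(1, 0, 1, 0, 1),
                                 stage = c("I", "II", "III", "IV", "I")))
  cl <- read_clinical_table(ok)
  expect_equal(nrow(cl), 5)
  expect_equal(sum(cl$missing_survival), 1)
  expect_equal(cl$stage, c("I", "II", "III", "IV", "I"))

  bad <- write_tmp_tsv(data.frame(sample_id = "s1", time = 10, event = 2))
  expect_error(read_clinical_table(bad), class = "fersigr_format_error")
})

test_that("mutation table keeps unknown classes as 'other' with a warning", {
  f <- write_tmp_tsv(data.frame(
    sample_id = c("s1", "s1", "s2", "s3"),
    gene_symbol = c("TP53", "KRAS", "APC", "TTN"),
    variant_classification = c("Missense_Mutation", "Silent", "Weird_Class", "Nonsense_Mutation")
  ))
  expect_warning(mt <- read_mutation_table(f), "other")
  expect_equal(nrow(mt), 4)
  expect_equal(mt$variant_classification[3], "other")

  empty <- write_tmp_tsv(data.frame(sample_id = character(),
                                    gene_symbol = character(),
                                    variant_classification = character()))
  expect_equal(nrow(read_mutation_table(empty)), 0)
})

test_that("sparse counts reader cross-checks dimensions and integrality", {
  set.seed(5)
  m <- Matrix::rsparsematrix(10, 20, density = 0.3,
                             rand.x = function(n) rpois(n, 3) + 1)
  d <- withr::local_tempdir()
  Matrix::writeMM(m, file.path(d, "m.mtx"))
  writeLines(sprintf("g%02d", 1:10), file.path(d, "features.tsv"))
  writeLines(sprintf("c%02d", 1:20), file.path(d, "barcodes.tsv"))
  sc <- read_sparse_counts(file.path(d, "m.mtx"), file.path(d, "features.tsv"),
                           file.path(d, "barcodes.tsv"))
  expect_equal(dim(sc$counts), c(10L, 20L))
  expect_equal(sc$cell_ids, sprintf("c%02d", 1:20))

  writeLines(sprintf("c%02d", 1:19), file.path(d, "short.tsv"))
  expect_error(read_sparse_counts(file.path(d, "m.mtx"), file.path(d, "features.tsv"),
                                  file.path(d, "short.tsv")),
               class = "fersigr_format_error")

  m2 <- m; m2[1, 1] <- 2.5
  Matrix::writeMM(m2, file.path(d, "frac.mtx"))
  expect_error(read_sparse_counts(file.path(d, "frac.mtx"), file.path(d, "features.tsv"),
                                  file.path(d, "barcodes.tsv")),
               class = "fersigr_format_error")
})

test_that("write_results emits tables, JSON and a manifest", {
  out <- withr::local_tempdir()
  S <- matrix(rnorm(30), 3, 10,
              dimnames = list(paste0("sig", 1:3), paste0("s", 1:10)))
  man <- write_results(list(scores = S, meta = list(alpha = 0.25)), out)
  expect_true(file.exists(file.path(out, "scores.tsv")))
  expect_true(file.exists(file.path(out, "meta.json")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_equal(man$rows[man$file == "scores.tsv"], 3)
})

test_that("fuzzed malformed files fail with typed errors, never silent corruption", {
  set.seed(42)
  for (i in 1:100) {
    f <- withr::local_tempfile(fileext = ".tsv")
    kind <- i %% 5
    if (kind == 0) {
      writeLines(c("gene\ts1\ts2", sprintf("g1\t%f\t-3", runif(1))), f)
      expect_error(read_expression_matrix(f), class = "fersigr_format_error")
    } else if (kind == 1) {
      writeLines(c("gene\ts1\ts1", "g1\t1\t2", "g2\t1\t2"), f)
      expect_error(read_expression_matrix(f), class = "fersigr_format_error")
    } else if (kind == 2) {
      writeLines(c("sample_id\ttime\tevent", sprintf("s1\t10\t%d", sample(2:9, 1))), f)
      expect_error(read_clinical_table(f), class = "fersigr_format_error")
    } else if (kind == 3) {
      writeLines(sprintf("SET%d\tna", i), f)  # GMT line with no members
      expect_error(read_gene_sets_gmt(f), class = "fersigr_format_error")
    } else {
      writeLines(c("gene\ts1\ts2", "g1\tfoo\t2", "g2\t1\t2"), f)
      expect_error(read_expression_matrix(f), class = "fersigr_format_error")
    }
  }
})
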