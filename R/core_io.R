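#' Construct and validate an expression matrix
#'
#' The substrate of every stage of the pipeline: a genes-by-samples matrix of
#' non-negative, log-scale (log2(x+1) expected) expression values with unique
#' gene and sample identifiers.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene symbols) and colnames (sample identifiers).
#' @return The validated matrix with class `"expr_matrix"` prepended.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_format("expression values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_format("expression matrix needs gene rownames and sample colnames")
  }
  if (nrow(values) < 2 || ncol(values) < 2) {
    stop_format("expression matrix needs at least 2 genes and 2 samples")
  }
  if (anyDuplicated(rownames(values))) {
    stop_format("duplicate gene identifiers in expression matrix")
  }
  if (anyDuplicated(colnames(values))) {
    stop_format("duplicate sample identifiers in expression matrix")
  }
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_format(sprintf(
      "non-finite or negative expression value at gene '%s', sample '%s'",
      rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]
    ))
  }
  class(values) <- c("expr_matrix", class(values))
  values
}

#' Read a genes-by-samples expression TSV
#'
#' Expects gene identifiers in the first column and sample identifiers in the
#' header. Duplicate gene rows are collapsed to the row with the larger mean
#' (a message records each collapse). Values must be finite and non-negative;
#' pass `log2p1 = TRUE` to apply `log2(x + 1)` to raw non-negative counts.
#'
#' @param path Path to a tab-separated file.
#' @param transpose If `TRUE` the file is samples-by-genes and is transposed
#'   after reading.
#' @param log2p1 Apply a log2(x+1) transform after reading.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, transpose = FALSE, log2p1 = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_format("expression TSV needs an id column plus data columns")
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  # take column ids from the raw header: read.delim mangles duplicates,
  # which must instead be detected and reported
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(hdr) == ncol(df)) colnames(mat) <- hdr[-1]
  if (!is.numeric(mat)) {
    nonnum <- colnames(mat)[which(apply(mat, 2, function(z) any(is.na(suppressWarnings(as.numeric(z))) & !is.na(z))))[1]]
    stop_format(sprintf("non-numeric expression value in column '%s'", nonnum))
  }
  rownames(mat) <- ids
  if (transpose) mat <- t(mat)
  if (anyDuplicated(colnames(mat))) {
    stop_format("duplicate sample identifiers in expression TSV header")
  }
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop_format(sprintf(
      "negative value at row '%s', column '%s'",
      rownames(mat)[neg[1, 1]], colnames(mat)[neg[1, 2]]
    ))
  }
  if (anyDuplicated(rownames(mat))) {
    dups <- unique(rownames(mat)[duplicated(rownames(mat))])
    keep <- seq_len(nrow(mat))
    means <- rowMeans(mat)
    drop <- integer(0)
    for (g in dups) {
      idx <- which(rownames(mat) == g)
      best <- idx[which.max(means[idx])]
      drop <- c(drop, setdiff(idx, best))
      inform(sprintf("collapsed %d duplicate rows for gene '%s' (kept larger mean)", length(idx) - 1L, g))
    }
    mat <- mat[setdiff(keep, drop), , drop = FALSE]
  }
  if (log2p1) mat <- log2(mat + 1)
  expression_matrix(mat)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>member...`.
#' Members are de-duplicated preserving order; sets empty after de-duplication
#' are dropped with a warning. A description of the form `role=driver` (or
#' suppressor/marker/other) is stored as the set's role tag.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors with class `"gene_sets"`; roles
#'   (when present) in `attr(, "roles")`.
#' @export
read_gene_sets_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_format("empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    stop_format(sprintf("GMT line %d has fewer than 3 fields", bad[1]))
  }
  nms <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nms)) {
    stop_format(sprintf("duplicate gene-set name '%s'", nms[duplicated(nms)][1]))
  }
  desc <- vapply(parts, `[[`, character(1), 2)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- nms
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warn(sprintf("dropping %d empty gene set(s): %s",
                 sum(empty), paste(nms[empty], collapse = ", ")))
    sets <- sets[!empty]
    desc <- desc[!empty]
  }
  roles <- ifelse(grepl("^role=", desc), sub("^role=", "", desc), NA_character_)
  names(roles) <- names(sets)
  gene_sets(sets, roles = roles)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (each non-empty after
#'   de-duplication).
#' @param roles Optional named character vector of role tags
#'   (driver/suppressor/marker/other), aligned with `sets`.
#' @return The collection with class `"gene_sets"`.
#' @export
gene_sets <- function(sets, roles = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop_format("gene sets must have unique names")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0)) stop_format("gene sets must be non-empty")
  if (!is.null(roles)) roles <- roles[names(sets)]
  structure(sets, roles = roles, class = "gene_sets")
}

#' Write a gene-set collection to GMT
#'
#' @param sets A `"gene_sets"` collection.
#' @param path Output path.
#' @export
write_gene_sets_gmt <- function(sets, path) {
  roles <- attr(sets, "roles")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(roles) && !is.na(roles[[nm]])) paste0("role=", roles[[nm]]) else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical/survival table
#'
#' TSV with at least `sample_id`, `time` (non-negative days) and `event`
#' (0/1). Rows with missing time or event are flagged (`missing_survival`)
#' and should be excluded from survival computations, but are retained for
#' counting. Extra categorical columns (stage, MSI, response, ...) are kept
#' verbatim.
#'
#' @param path Path to the TSV.
#' @return A tibble with class `"clinical_table"`.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  req <- c("sample_id", "time", "event")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop_format(paste("clinical table missing column(s):", paste(miss, collapse = ", ")))
  }
  clinical_table(df)
}

#' Construct/validate a clinical table
#'
#' @param df Data frame with `sample_id`, `time`, `event` columns.
#' @return Tibble with class `"clinical_table"` and a `missing_survival` flag.
#' @export
clinical_table <- function(df) {
  df <- as_tibble(df)
  if (anyDuplicated(df$sample_id)) stop_format("duplicate sample_id in clinical table")
  df$time <- suppressWarnings(as.numeric(df$time))
  ev <- suppressWarnings(as.numeric(df$event))
  bad_ev <- !is.na(ev) & !(ev %in% c(0, 1))
  if (any(bad_ev)) {
    stop_format(sprintf("event must be 0 or 1 (sample '%s' has %s)",
                        df$sample_id[bad_ev][1], df$event[bad_ev][1]))
  }
  if (any(!is.na(df$time) & df$time < 0)) stop_format("negative survival time")
  df$event <- ev
  df$missing_survival <- is.na(df$time) | is.na(df$event)
  class(df) <- c("clinical_table", class(df))
  df
}

# controlled vocabulary for somatic variant classes; anything else is kept
# but re-tagged "other" with a warning
variant_vocabulary <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Ins",
    "Frame_Shift_Del", "Splice_Site", "In_Frame_Ins", "In_Frame_Del",
    "Translation_Start_Site", "Nonstop_Mutation", "Silent",
    "3'UTR", "5'UTR", "Intron", "RNA", "other")
}

# the subset of the vocabulary counted as nonsilent for TMB
nonsilent_vocabulary <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Ins",
    "Frame_Shift_Del", "Splice_Site", "In_Frame_Ins", "In_Frame_Del",
    "Translation_Start_Site", "Nonstop_Mutation")
}

#' Read a MAF-lite mutation table
#'
#' TSV with columns `sample_id`, `gene_symbol`, `variant_classification`
#' (extra columns are ignored). Unknown classifications are kept but tagged
#' `"other"` with a warning. An empty table (header only) is valid.
#'
#' @param path Path to the TSV.
#' @return A tibble with class `"mutation_table"`.
#' @export
read_mutation_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample_id", "gene_symbol", "variant_classification")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop_format(paste("mutation table missing column(s):", paste(miss, collapse = ", ")))
  }
  mutation_table(df[, req, drop = FALSE])
}

#' Construct/validate a mutation table
#'
#' @param df Data frame of (sample_id, gene_symbol, variant_classification).
#' @return Tibble with class `"mutation_table"`.
#' @export
mutation_table <- function(df) {
  df <- as_tibble(df)
  if (nrow(df) > 0) {
    unknown <- !(df$variant_classification %in% variant_vocabulary())
    if (any(unknown)) {
      warn(sprintf("%d mutation record(s) with unknown variant_classification tagged 'other'",
                   sum(unknown)))
      df$variant_classification[unknown] <- "other"
    }
  }
  class(df) <- c("mutation_table", class(df))
  df
}

#' Read sparse single-cell counts (MatrixMarket triplet)
#'
#' Reads a `.mtx` coordinate file plus one-column feature and barcode files;
#' dimensions are cross-checked and counts must be non-negative integers.
#'
#' @param matrix_path Path to the MatrixMarket file (genes x cells).
#' @param features_path One gene identifier per line.
#' @param barcodes_path One cell barcode per line.
#' @param metadata Optional data frame of per-cell metadata (rows align with
#'   barcodes).
#' @return A list with class `"sc_matrix"`: `counts` (dgCMatrix),
#'   `gene_ids`, `cell_ids`, `meta` (tibble).
#' @export
read_sparse_counts <- function(matrix_path, features_path, barcodes_path,
                               metadata = NULL) {
  m <- Matrix::readMM(matrix_path)
  genes <- readLines(features_path, warn = FALSE)
  cells <- readLines(barcodes_path, warn = FALSE)
  genes <- genes[nzchar(genes)]
  cells <- cells[nzchar(cells)]
  if (length(genes) != nrow(m)) {
    stop_format(sprintf("features file has %d entries for a %d-row matrix",
                        length(genes), nrow(m)))
  }
  if (length(cells) != ncol(m)) {
    stop_format(sprintf("barcodes file has %d entries for a %d-column matrix",
                        length(cells), ncol(m)))
  }
  sc_matrix(m, gene_ids = genes, cell_ids = cells, meta = metadata)
}

#' Construct/validate a single-cell count matrix
#'
#' @param counts Sparse or dense non-negative integer matrix, genes x cells.
#' @param gene_ids,cell_ids Identifiers (cell_ids unique).
#' @param meta Optional per-cell metadata aligned with `cell_ids`.
#' @return Object of class `"sc_matrix"`.
#' @export
sc_matrix <- function(counts, gene_ids, cell_ids, meta = NULL) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  v <- counts@x
  if (any(v < 0)) stop_format("negative single-cell counts")
  if (any(v != round(v))) stop_format("fractional single-cell counts")
  if (anyDuplicated(cell_ids)) stop_format("duplicate cell identifiers")
  if (length(gene_ids) != nrow(counts) || length(cell_ids) != ncol(counts)) {
    stop_format("identifier lengths do not match count matrix dimensions")
  }
  rownames(counts) <- gene_ids
  colnames(counts) <- cell_ids
  if (is.null(meta)) {
    meta <- tibble(cell_id = cell_ids)
  } else {
    meta <- as_tibble(meta)
    if (nrow(meta) != length(cell_ids)) {
      stop_format("metadata rows do not align 1:1 with cells")
    }
    if (!"cell_id" %in% names(meta)) meta$cell_id <- cell_ids
  }
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 meta = meta),
            class = "sc_matrix")
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

expr_to_tsv <- function(X, path) {
  df <- data.frame(gene_id = rownames(X), X, check.names = FALSE)
  # full precision so a write -> read round trip is exact at 1e-12
  old <- options(digits = 17)
  on.exit(options(old))
  write_tsv_plain(format(df, digits = 17, trim = TRUE, scientific = FALSE), path)
}

#' Write a results bundle to disk
#'
#' Every tabular component is written as TSV, scalar summaries as JSON; a
#' manifest (file, type, rows) is returned and written as
#' `manifest.json`. A written expression matrix re-reads bit-identically
#' within 1e-12.
#'
#' @param bundle A named list of results (expression matrices, tibbles,
#'   gene-set collections, scalar lists) or a single such object.
#' @param out_dir Output directory (created if needed).
#' @return A tibble manifest (invisibly the path list too).
#' @export
write_results <- function(bundle, out_dir) {
  if (inherits(bundle, c("expr_matrix", "gene_sets", "sc_matrix")) ||
      is.data.frame(bundle) || is.matrix(bundle)) {
    bundle <- list(result = bundle)
  }
  if (is.null(names(bundle)) || any(!nzchar(names(bundle)))) {
    stop_input("write_results needs a named bundle")
  }
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_input(sprintf("cannot create output dir '%s'", out_dir))
  rows <- list()
  add <- function(file, type, n) {
    rows[[length(rows) + 1]] <<- tibble(file = file, type = type, rows = n)
  }
  for (nm in names(bundle)) {
    x <- bundle[[nm]]
    if (inherits(x, "expr_matrix") || (is.matrix(x) && is.numeric(x))) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      expr_to_tsv(x, f)
      add(basename(f), "matrix", nrow(x))
    } else if (inherits(x, "gene_sets")) {
      f <- file.path(out_dir, paste0(nm, ".gmt"))
      write_gene_sets_gmt(x, f)
      add(basename(f), "gene_sets", length(x))
    } else if (is.data.frame(x)) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      write_tsv_plain(x, f)
      add(basename(f), "table", nrow(x))
    } else if (is.list(x) || is.atomic(x)) {
      f <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, null = "null")
      add(basename(f), "json", length(x))
    } else {
      stop_input(sprintf("don't know how to write component '%s'", nm))
    }
  }
  manifest <- bind_rows(rows)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
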