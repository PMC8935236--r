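# the ferroptosis gene universe of a collection: the set named FERROPTOSIS
# when present, otherwise the union of all role-tagged sets
ferro_genes <- function(sets) {
  if ("FERROPTOSIS" %in% names(sets)) return(sets[["FERROPTOSIS"]])
  roles <- attr(sets, "roles")
  tagged <- if (!is.null(roles)) names(sets)[!is.na(roles)] else names(sets)
  unique(unlist(sets[tagged], use.names = FALSE))
}

#' Derive immune- and stromal-activated ferroptosis signatures
#'
#' Intersects the genes up-regulated in the immune-activated cluster (one-vs-
#' rest) with the ferroptosis list to form the immune-activated signature,
#' and likewise for the stromal-activated cluster. An empty overlap yields an
#' empty signature with a warning; downstream scoring of that signature is
#' then disabled.
#'
#' @param de A `"de_result"` from [cluster_markers()].
#' @param ferro Ferroptosis `"gene_sets"` collection (role tags preserved).
#' @param immune_cluster,stromal_cluster Cluster labels (as they appear in
#'   `de$cluster`).
#' @return List of class `"signature_bundle"`: `immune_activated`,
#'   `stromal_activated` (character vectors), `roles` (named role tags).
#' @export
derive_activated_signatures <- function(de, ferro, immune_cluster, stromal_cluster) {
  fg <- ferro_genes(ferro)
  roles <- attr(ferro, "roles")
  role_of <- rep(NA_character_, length(fg))
  names(role_of) <- fg
  if (!is.null(roles)) {
    for (nm in names(ferro)) {
      if (!is.na(roles[[nm]])) role_of[intersect(ferro[[nm]], fg)] <- roles[[nm]]
    }
  }
  up_in <- function(cl) {
    unique(de$gene[de$cluster == as.character(cl) & de$marker & de$direction == "up"])
  }
  imm <- intersect(up_in(immune_cluster), fg)
  str <- intersect(up_in(stromal_cluster), fg)
  if (length(imm) == 0) warn("immune-activated signature is empty (no DEG/ferroptosis overlap)")
  if (length(str) == 0) warn("stromal-activated signature is empty (no DEG/ferroptosis overlap)")
  structure(list(immune_activated = imm, stromal_activated = str,
                 roles = role_of),
            class = "signature_bundle")
}

#' Phenotype-related differentially expressed genes
#'
#' Combines the one-vs-rest DEG lists of the clusters: `"intersection"`
#' (default) keeps genes significant in every contrast (any direction),
#' `"union"` keeps genes significant in at least one.
#'
#' @param de A `"de_result"` covering every cluster.
#' @param mode `"intersection"` or `"union"`.
#' @return Character vector of genes; mode recorded in `attr(, "mode")`.
#' @export
phenotype_related_degs <- function(de, mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  cls <- unique(de$cluster)
  if (length(cls) < 2) stop_input("phenotype DEGs need contrasts for every cluster")
  lists <- lapply(cls, function(cl) unique(de$gene[de$cluster == cl & de$marker]))
  out <- if (mode == "intersection") Reduce(intersect, lists) else Reduce(union, lists)
  structure(out, mode = mode)
}

#' Prognostic filter by univariate Cox regression
#'
#' Fits a univariate Cox model of survival on each gene's expression and
#' keeps genes with Wald `p < alpha_p`; coefficients are retained for the
#' downstream sign bookkeeping.
#'
#' @param genes Candidate gene symbols.
#' @param X Expression matrix.
#' @param clinical A `"clinical_table"` (rows flagged `missing_survival`
#'   are excluded).
#' @param alpha_p Wald p-value threshold (default 0.05).
#' @return Tibble: gene, beta, hr, p, keep.
#' @export
prognostic_filter <- function(genes, X, clinical, alpha_p = 0.05) {
  X <- unclass(X)
  genes <- intersect(genes, rownames(X))
  cl <- clinical[!clinical$missing_survival, , drop = FALSE]
  cl <- cl[cl$sample_id %in% colnames(X), , drop = FALSE]
  if (nrow(cl) < 3 || sum(cl$event) < 1) stop_input("insufficient survival data")
  rows <- lapply(genes, function(g) {
    x <- X[g, cl$sample_id]
    if (stats::sd(x) == 0) {
      return(tibble(gene = g, beta = NA_real_, hr = NA_real_, p = NA_real_, keep = FALSE))
    }
    fit <- suppressWarnings(cox_univariate(x, cl$time, cl$event))
    tibble(gene = g, beta = fit$beta, hr = fit$hr, p = fit$p, keep = fit$p < alpha_p)
  })
  out <- bind_rows(rows)
  if (!any(out$keep)) {
    stop_input("no gene passes the prognostic filter; consider a larger alpha_p")
  }
  attr(out, "alpha_p") <- alpha_p
  out
}

#' Group signature genes into stromal / immune / other clusters
#'
#' Average-linkage hierarchical clustering of the genes on correlation
#' distance (1 - Pearson across samples), cut into three groups. The group
#' whose mean expression correlates most with the stromal-activated ssGSEA
#' score is labelled `A` (stromal-related), the best immune correlate `B`,
#' the remainder `C`; when one group wins both, the larger correlation keeps
#' its label and the runner-up takes the other.
#'
#' @param phenotype_degs Genes to partition (>= 3).
#' @param X Expression matrix.
#' @param immune_activated,stromal_activated Signature gene vectors used to
#'   compute the reference ssGSEA scores.
#' @return Tibble: gene, group (A/B/C); correlations in `attr(, "cor")`.
#' @export
group_signature_genes <- function(phenotype_degs, X, immune_activated,
                                  stromal_activated) {
  X <- unclass(X)
  gs <- intersect(phenotype_degs, rownames(X))
  if (length(gs) < 3) stop_input("need >= 3 phenotype DEGs to form groups")
  if (length(intersect(immune_activated, rownames(X))) == 0 ||
      length(intersect(stromal_activated, rownames(X))) == 0) {
    stop_input("activated signatures must overlap the matrix to label gene groups")
  }
  sub <- X[gs, , drop = FALSE]
  co <- suppressWarnings(stats::cor(t(sub)))
  co[is.na(co)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - co), method = "average")
  raw <- stats::cutree(hc, k = 3)
  ref <- ssgsea_scores(X, list(immune = immune_activated,
                               stromal = stromal_activated),
                       normalize = FALSE)
  gmeans <- lapply(1:3, function(k) colMeans(sub[raw == k, , drop = FALSE]))
  cor_imm <- vapply(gmeans, function(m) stats::cor(m, ref["immune", ]), numeric(1))
  cor_str <- vapply(gmeans, function(m) stats::cor(m, ref["stromal", ]), numeric(1))
  a_pick <- which.max(cor_str)
  b_pick <- which.max(cor_imm)
  if (a_pick == b_pick) {
    if (max(cor_str) >= max(cor_imm)) {
      b_pick <- order(cor_imm, decreasing = TRUE)[2]
    } else {
      a_pick <- order(cor_str, decreasing = TRUE)[2]
    }
  }
  grp <- rep("C", length(gs))
  grp[raw == a_pick] <- "A"
  grp[raw == b_pick] <- "B"
  out <- tibble(gene = gs, group = grp)
  attr(out, "cor") <- list(immune = cor_imm, stromal = cor_str,
                           A = a_pick, B = b_pick)
  out
}

#' Compute the Fersig score
#'
#' Scores every sample on the first principal component of the
#' stromal-related gene set (A) and of the immune-related gene set (B), fits
#' a univariate Cox model to each score, and composes the Fersig score as
#' the sum of PC1 scores whose Cox coefficient is `>= 0` minus the sum of
#' those with negative coefficients (`Fersig = sum PC1_i - sum PC1_j`).
#' Samples are then split at the median into high/low groups. The stored
#' loadings, centers and sign classes are sufficient to score new cohorts
#' without survival data via [apply_fersig()].
#'
#' @param X Expression matrix of the training cohort.
#' @param genes_A Stromal-related gene set (>= 2 genes in `X`).
#' @param genes_B Immune-related gene set (>= 2 genes in `X`).
#' @param clinical A `"clinical_table"` for the training cohort.
#' @return Object of class `"fersig_fit"`: `scores` tibble (sample_id,
#'   pc1_A, pc1_B, fersig, group), `pc1` (stored projections), `cox`
#'   (per-signature fits), `sign_class`, `threshold`.
#' @export
compute_fersig <- function(X, genes_A, genes_B, clinical) {
  cl <- clinical[!clinical$missing_survival, , drop = FALSE]
  if (nrow(cl) < 3 || sum(cl$event) < 1) {
    stop_input("training the Fersig score requires survival data")
  }
  pc1 <- list(A = pca_signature_score(X, genes_A),
              B = pca_signature_score(X, genes_B))
  samples <- colnames(unclass(X))
  cox <- list()
  sign_class <- c()
  for (nm in names(pc1)) {
    sc <- pc1[[nm]]$score[cl$sample_id]
    cox[[nm]] <- cox_univariate(sc, cl$time, cl$event)
    sign_class[nm] <- if (cox[[nm]]$beta >= 0) "i" else "j"
  }
  if (length(unique(sign_class)) == 1) {
    inform(sprintf("both signature scores fall in class '%s'; Fersig is the %s of both",
                   sign_class[1], if (sign_class[1] == "i") "sum" else "negated sum"))
  }
  sgn <- ifelse(sign_class == "i", 1, -1)
  fersig <- sgn["A"] * pc1$A$score[samples] + sgn["B"] * pc1$B$score[samples]
  names(fersig) <- samples
  split <- median_split(fersig)
  scores <- tibble(sample_id = samples,
                   pc1_A = unname(pc1$A$score[samples]),
                   pc1_B = unname(pc1$B$score[samples]),
                   fersig = unname(fersig),
                   group = split$group[match(samples, split$sample_id)])
  structure(list(scores = scores, pc1 = pc1, cox = cox,
                 sign_class = sign_class,
                 threshold = attr(split, "threshold")),
            class = "fersig_fit")
}

#' Apply a trained Fersig score to a new cohort
#'
#' Projects new samples on the stored PC1 loadings (training centers reused)
#' and composes the score with the stored Cox sign classes; no survival data
#' needed. The high/low split uses the training median by default.
#'
#' @param fit A `"fersig_fit"`.
#' @param X Expression matrix of the new cohort (must contain the signature
#'   genes).
#' @param resplit Re-derive the median threshold on the new cohort instead
#'   of reusing the training threshold (default FALSE).
#' @return Tibble: sample_id, pc1_A, pc1_B, fersig, group.
#' @export
apply_fersig <- function(fit, X, resplit = FALSE) {
  sA <- apply_pc1(fit$pc1$A, X)
  sB <- apply_pc1(fit$pc1$B, X)
  sgn <- ifelse(fit$sign_class == "i", 1, -1)
  fersig <- sgn["A"] * sA + sgn["B"] * sB
  thr <- if (resplit) stats::median(fersig) else fit$threshold
  tibble(sample_id = colnames(unclass(X)), pc1_A = unname(sA),
         pc1_B = unname(sB), fersig = unname(fersig),
         group = ifelse(fersig > thr, "high", "low"))
}

#' Project bulk subtypes onto single cells
#'
#' Computes a binned-control module score per cell for each cluster's marker
#' set and labels every cell by the maximal score; exact ties go to the
#' first (lowest-index) marker set and are flagged. The margin between the
#' top two scores is reported so callers can mark low-confidence cells.
#'
#' @param sc An `"sc_matrix"` (or expression matrix).
#' @param marker_sets Named list of per-cluster marker gene sets (derived at
#'   the mapping threshold, |lnFC| >= 0.5).
#' @param n_bins,n_ctrl,seed Module-score parameters (see [module_scores()]).
#' @return Tibble of class `"cell_assignment"`: cell_id, one score column
#'   per set, label, margin, tie.
#' @export
map_clusters_to_cells <- function(sc, marker_sets, n_bins = 24L,
                                  n_ctrl = 100L, seed = 1L) {
  if (length(marker_sets) < 2) stop_input("need >= 2 marker sets to map clusters")
  genes <- if (inherits(sc, "sc_matrix")) sc$gene_ids else rownames(sc)
  for (nm in names(marker_sets)) {
    if (length(intersect(marker_sets[[nm]], genes)) == 0) {
      stop_input(sprintf("marker set '%s' has no overlap with the cells", nm))
    }
  }
  S <- vapply(seq_along(marker_sets), function(k) {
    module_scores(sc, marker_sets[[k]], n_bins = n_bins, n_ctrl = n_ctrl,
                  seed = seed + k)
  }, numeric(if (inherits(sc, "sc_matrix")) length(sc$cell_ids) else ncol(sc)))
  colnames(S) <- names(marker_sets)
  top <- apply(S, 1, which.max)
  sorted <- apply(S, 1, function(v) sort(v, decreasing = TRUE)[1:2])
  margin <- sorted[1, ] - sorted[2, ]
  tie <- margin == 0
  cells <- if (inherits(sc, "sc_matrix")) sc$cell_ids else colnames(sc)
  out <- tibble(cell_id = cells)
  for (nm in names(marker_sets)) out[[paste0("score_", nm)]] <- S[, nm]
  out$label <- names(marker_sets)[top]
  out$margin <- margin
  out$tie <- tie
  class(out) <- c("cell_assignment", class(out))
  out
}

#' Contrast stratified groups on clinical, score and mutation variables
#'
#' For each continuous variable (score-matrix rows, TMB): Wilcoxon (2
#' groups) or Kruskal-Wallis (more). For each categorical clinical column:
#' Pearson chi-square on the contingency table. Survival: KM per group plus
#' a log-rank test. When the clinical table has a `response` column a
#' response-rate table is added.
#'
#' @param groups Tibble with `sample_id` and `group` columns.
#' @param clinical Optional `"clinical_table"`.
#' @param scores Optional `"score_matrix"` (signatures x samples).
#' @param mutations Optional `"mutation_table"` (TMB is contrasted).
#' @return List of class `"contrast_report"`: `tests` (tibble: variable,
#'   type, statistic, p), `logrank`, `km` (per-group curves),
#'   `response_rates`.
#' @export
stratify_and_contrast <- function(groups, clinical = NULL, scores = NULL,
                                  mutations = NULL) {
  glev <- unique(groups$group)
  sizes <- table(groups$group)
  if (any(sizes == 0) || length(glev) < 2) stop_input("every group must be non-empty")
  tests <- list()
  add_cont <- function(name, values, ids) {
    byg <- lapply(glev, function(g) values[ids %in% groups$sample_id[groups$group == g]])
    byg <- byg[lengths(byg) >= 2]
    if (length(byg) < 2) return()
    rt <- rank_location_test(byg)
    tests[[length(tests) + 1]] <<- tibble(variable = name, type = "continuous",
                                          statistic = rt$statistic, p = rt$p)
  }
  km <- NULL; lr <- NULL; rr <- NULL
  if (!is.null(clinical)) {
    cl <- left_join(groups, clinical, by = "sample_id")
    surv_ok <- cl[!is.na(cl$time) & !is.na(cl$event), , drop = FALSE]
    if (nrow(surv_ok) > 3 && length(unique(surv_ok$group)) >= 2 &&
        sum(surv_ok$event) >= 1) {
      lr <- logrank_test(surv_ok$time, surv_ok$event, surv_ok$group)
      km <- lapply(split(surv_ok, surv_ok$group),
                   function(d) km_estimate(d$time, d$event))
    }
    skip <- c("sample_id", "time", "event", "group", "missing_survival")
    for (col in setdiff(names(cl), skip)) {
      v <- cl[[col]]
      if (is.numeric(v) && length(unique(stats::na.omit(v))) > 5) {
        add_cont(col, v, cl$sample_id)
      } else if (col == "response") {
        tab <- table(cl$group, cl[[col]])
        rr <- as_tibble(prop.table(tab, 1), .name_repair = "minimal")
        names(rr) <- c("group", "response", "rate")
        if (all(dim(tab) >= 2) && all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
          ct <- chi_square_test(tab)
          tests[[length(tests) + 1]] <- tibble(variable = col, type = "categorical",
                                               statistic = ct$statistic, p = ct$p)
        }
      } else {
        tab <- table(cl$group, v)
        if (all(dim(tab) >= 2) && all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
          ct <- chi_square_test(tab)
          tests[[length(tests) + 1]] <- tibble(variable = col, type = "categorical",
                                               statistic = ct$statistic, p = ct$p)
        }
      }
    }
  }
  if (!is.null(scores)) {
    S <- unclass(scores)
    for (nm in rownames(S)) add_cont(nm, S[nm, ], colnames(S))
  }
  if (!is.null(mutations)) {
    tmb <- compute_tmb(mutations, groups$sample_id)
    add_cont("TMB", tmb$tmb, tmb$sample_id)
  }
  structure(list(tests = bind_rows(tests), logrank = lr, km = km,
                 response_rates = rr, group_sizes = sizes),
            class = "contrast_report")
}
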