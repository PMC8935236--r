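#' Run the full ferroptosis subtyping and Fersig pipeline
#'
#' Composes the analysis end to end: consensus-NMF subtyping on the
#' ferroptosis genes, ssGSEA ferroptosis and reference scores, automatic
#' identification of the immune- and stromal-activated clusters, one-vs-rest
#' differential expression, activated-signature derivation, phenotype DEGs,
#' prognostic Cox filtering, a second consensus-NMF clustering of patients
#' on the prognostic DEGs, signature-gene grouping (A/B/C), the Fersig
#' score with median-split stratification and contrast report, and --
#' when single-cell data is supplied -- projection of the subtypes onto
#' cells. All stage outputs, parameters and seeds are collected in a
#' provenance log and optionally written to disk.
#'
#' @param expr Expression matrix (genes x samples).
#' @param sets Gene-set collection containing the ferroptosis list (set
#'   `FERROPTOSIS` or role-tagged sets) and, optionally, `IMMUNE_REFERENCE` /
#'   `STROMAL_REFERENCE` sets used to identify the activated clusters.
#' @param clinical A `"clinical_table"`.
#' @param mutations Optional `"mutation_table"` (adds TMB contrasts).
#' @param sc Optional `"sc_matrix"` (adds single-cell mapping).
#' @param ranks Candidate NMF ranks (default 2:5).
#' @param n_runs NMF restarts per rank (default 30).
#' @param min_lnfc Natural-log fold-change threshold for signature DE
#'   (default 0.25).
#' @param map_lnfc Threshold for the single-cell mapping marker sets
#'   (default 0.5).
#' @param alpha_q BH significance threshold for DE (default 0.05).
#' @param alpha_p Wald threshold of the prognostic filter (default 0.05).
#' @param deg_mode `"intersection"` (default) or `"union"` for the
#'   phenotype DEGs.
#' @param immune_cluster,stromal_cluster Optional manual overrides of the
#'   automatically identified activated clusters.
#' @param seed Master seed for every stochastic stage.
#' @param out_dir Optional output directory; each stage's tables are then
#'   written through [write_results()].
#' @return List of class `"fersig_pipeline"` with one element per stage plus
#'   `provenance`.
#' @export
run_pipeline <- function(expr, sets, clinical, mutations = NULL, sc = NULL,
                         ranks = 2:5, n_runs = 30L, min_lnfc = 0.25,
                         map_lnfc = 0.5, alpha_q = 0.05, alpha_p = 0.05,
                         deg_mode = "intersection",
                         immune_cluster = NULL, stromal_cluster = NULL,
                         seed = 1L, out_dir = NULL) {
  stage <- "setup"
  prov <- list(seed = seed, ranks = ranks, n_runs = n_runs,
               min_lnfc = min_lnfc, map_lnfc = map_lnfc, alpha_q = alpha_q,
               alpha_p = alpha_p, deg_mode = deg_mode,
               expression_assumption = "non-negative log2(x+1)-scale matrix",
               package_version = as.character(utils::packageVersion("fersigr")))
  res <- list()
  run_stage <- function(name, code) {
    stage <<- name
    tryCatch(force(code), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "fersigr_stage_error", parent = e)
    })
  }

  fg <- intersect(ferro_genes(sets), rownames(unclass(expr)))
  if (length(fg) < max(ranks) + 2) stop_input("too few ferroptosis genes matched in the matrix")

  res$consensus <- run_stage("cluster", {
    consensus_cluster(unclass(expr)[fg, , drop = FALSE], ranks = ranks,
                      n_runs = n_runs, seed = seed)
  })
  res$rank <- run_stage("select_rank", select_rank(res$consensus))
  res$fac <- run_stage("assign_clusters", assign_clusters(res$consensus, res$rank))
  prov$selected_rank <- as.integer(res$rank)

  res$ssgsea <- run_stage("ssgsea", {
    use <- intersect(c("FERROPTOSIS", "IMMUNE_REFERENCE", "STROMAL_REFERENCE"),
                     names(sets))
    ssgsea_scores(expr, sets[use])
  })

  run_stage("identify_clusters", {
    S <- unclass(res$ssgsea)
    lab <- stats::setNames(res$fac$cluster, res$fac$sample_id)[colnames(S)]
    mean_by <- function(sig) {
      if (!sig %in% rownames(S)) return(NULL)
      tapply(S[sig, ], lab, mean)
    }
    mi <- mean_by("IMMUNE_REFERENCE")
    ms <- mean_by("STROMAL_REFERENCE")
    if (is.null(immune_cluster)) {
      immune_cluster <- if (!is.null(mi)) as.integer(names(which.max(mi))) else 2L
    }
    if (is.null(stromal_cluster)) {
      if (!is.null(ms)) {
        ord <- names(sort(ms, decreasing = TRUE))
        pick <- ord[ord != as.character(immune_cluster)][1]
        stromal_cluster <- as.integer(pick)
      } else {
        stromal_cluster <- 3L
      }
    }
  })
  prov$immune_cluster <- immune_cluster
  prov$stromal_cluster <- stromal_cluster

  res$de <- run_stage("differential_expression", {
    cluster_markers(expr, res$fac, min_lnfc = min_lnfc, alpha_q = alpha_q)
  })
  res$signatures <- run_stage("derive_signatures", {
    derive_activated_signatures(res$de, sets, immune_cluster, stromal_cluster)
  })
  res$phenotype_degs <- run_stage("phenotype_degs", {
    phenotype_related_degs(res$de, mode = deg_mode)
  })
  res$prognostic <- run_stage("prognostic_filter", {
    prognostic_filter(res$phenotype_degs, expr, clinical, alpha_p = alpha_p)
  })
  prog_genes <- res$prognostic$gene[res$prognostic$keep]

  res$gene_cluster_consensus <- run_stage("gene_cluster_patients", {
    Xp <- unclass(expr)[intersect(prog_genes, rownames(unclass(expr))), , drop = FALSE]
    consensus_cluster(Xp, ranks = ranks, n_runs = n_runs, seed = seed + 1L)
  })
  res$gene_cluster <- run_stage("gene_cluster_assign", {
    assign_clusters(res$gene_cluster_consensus,
                    select_rank(res$gene_cluster_consensus))
  })

  res$gene_groups <- run_stage("group_signature_genes", {
    group_signature_genes(res$phenotype_degs, expr,
                          res$signatures$immune_activated,
                          res$signatures$stromal_activated)
  })
  genes_A <- res$gene_groups$gene[res$gene_groups$group == "A"]
  genes_B <- res$gene_groups$gene[res$gene_groups$group == "B"]

  res$fersig <- run_stage("compute_fersig", {
    compute_fersig(expr, genes_A, genes_B, clinical)
  })

  res$contrasts <- run_stage("stratify_and_contrast", {
    groups <- res$fersig$scores[, c("sample_id", "group")]
    stratify_and_contrast(groups, clinical = clinical, scores = res$ssgsea,
                          mutations = mutations)
  })

  if (!is.null(sc)) {
    res$cell_assignment <- run_stage("map_clusters_to_cells", {
      de_map <- cluster_markers(expr, res$fac, min_lnfc = map_lnfc,
                                alpha_q = alpha_q)
      marker_sets <- lapply(sort(unique(de_map$cluster)), function(cl) {
        unique(de_map$gene[de_map$cluster == cl & de_map$marker &
                             de_map$direction == "up"])
      })
      names(marker_sets) <- paste0("FAC", sort(unique(de_map$cluster)))
      marker_sets <- marker_sets[lengths(marker_sets) > 0]
      map_clusters_to_cells(sc, marker_sets, seed = seed)
    })
  } else {
    prov$single_cell <- "skipped: no input"
  }

  res$provenance <- prov

  if (!is.null(out_dir)) {
    run_stage("write_results", {
      bundle <- list(
        fac_labels = res$fac,
        rank_survey = res$consensus$survey,
        ssgsea_scores = unclass(res$ssgsea),
        de_results = as_tibble(res$de),
        signatures = gene_sets(Filter(length, list(
          IMMUNE_ACTIVATED = res$signatures$immune_activated,
          STROMAL_ACTIVATED = res$signatures$stromal_activated,
          PHENOTYPE_DEGS = as.character(res$phenotype_degs)
        ))),
        prognostic_fits = res$prognostic,
        gene_groups = res$gene_groups,
        gene_cluster_labels = res$gene_cluster,
        fersig_scores = res$fersig$scores,
        fersig_meta = list(sign_class = as.list(res$fersig$sign_class),
                           threshold = res$fersig$threshold,
                           cox_beta = lapply(res$fersig$cox, `[[`, "beta")),
        contrast_tests = res$contrasts$tests,
        provenance = prov
      )
      if (!is.null(res$cell_assignment)) {
        bundle$cell_assignment <- as_tibble(res$cell_assignment)
      }
      res$manifest <- write_results(bundle, out_dir)
    })
  }

  class(res) <- "fersig_pipeline"
  res
}
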