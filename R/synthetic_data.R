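#' Simulation configuration
#'
#' Defaults emulate the statistical structure the pipeline assumes in a
#' colorectal cohort: three latent transcriptional programs (canonical /
#' immune-activated / stromal-activated) expressed by three patient clusters
#' mixed 50/35/15, a 228-gene ferroptosis list (71 drivers, 61 suppressors,
#' 96 markers) straddling the immune and stromal programs, exponential
#' survival whose hazard rises with the stromal program and falls with the
#' immune program, stage distributions skewed toward stage IV in the stromal
#' cluster, and a doubled mutation rate in the immune cluster.
#'
#' @param n_samples Bulk cohort size (default 300).
#' @param n_genes Genes in the simulated transcriptome (default 1500).
#' @param n_ferroptosis Size of the ferroptosis list (default 228).
#' @param program_sizes Named sizes of the three program gene blocks.
#' @param ferro_in_program Ferroptosis genes planted inside each program.
#' @param delta Program effect size in log2 units (default 2).
#' @param sigma Expression noise SD (default 1), so delta/sigma = 2.
#' @param mixing Cluster mixing proportions (sum to 1).
#' @param lambda0 Baseline hazard per day (default 1/1500).
#' @param beta Per-cluster log hazard ratios.
#' @param censor_rate Probability a subject is censored uniformly before its
#'   event (default 0.3).
#' @param stage_probs Per-cluster stage I-IV probabilities.
#' @param mut_rate Per-gene per-sample mutation probability (default 0.02).
#' @param mut_multiplier_immune Immune-cluster mutation rate multiplier.
#' @param n_mut_genes Size of the mutable gene panel (default 250).
#' @param n_cells,cell_type_props,sc_marker_fold,sc_size,sc_base_mu
#'   Single-cell block: cell count, type proportions, marker/program
#'   elevation factor on the NB mean, NB size, baseline NB mean.
#' @param n_icb,gamma_icb,beta_response,beta_icb_stromal,beta_icb_immune
#'   Immunotherapy block: cohort size, logistic link of response on
#'   (immune - stromal) activity, and log hazard ratios of response and of
#'   the two activities.
#' @param seed Master seed; block-specific streams are derived from it.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 300L,
                       n_genes = 1500L,
                       n_ferroptosis = 228L,
                       program_sizes = c(canonical = 80L, immune = 80L, stromal = 80L),
                       ferro_in_program = c(canonical = 15L, immune = 25L, stromal = 25L),
                       delta = 2,
                       sigma = 1,
                       mixing = c(canonical = 0.50, immune = 0.35, stromal = 0.15),
                       lambda0 = 1 / 1500,
                       beta = c(canonical = 0, immune = -0.5, stromal = 0.8),
                       censor_rate = 0.3,
                       stage_probs = list(
                         canonical = c(I = 0.150, II = 0.350, III = 0.400, IV = 0.100),
                         immune    = c(I = 0.227, II = 0.400, III = 0.335, IV = 0.038),
                         stromal   = c(I = 0.052, II = 0.300, III = 0.493, IV = 0.155)
                       ),
                       mut_rate = 0.02,
                       mut_multiplier_immune = 2,
                       n_mut_genes = 250L,
                       n_cells = 2000L,
                       cell_type_props = c(epithelial = 0.40, T = 0.20, B = 0.10,
                                           myeloid = 0.15, stromal = 0.15),
                       sc_marker_fold = 4,
                       sc_size = 2,
                       sc_base_mu = 0.3,
                       n_icb = 150L,
                       gamma_icb = 2,
                       beta_response = -0.5,
                       beta_icb_stromal = 0.5,
                       beta_icb_immune = -0.3,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    n_ferroptosis = as.integer(n_ferroptosis),
    program_sizes = program_sizes, ferro_in_program = ferro_in_program,
    delta = delta, sigma = sigma, mixing = mixing, lambda0 = lambda0,
    beta = beta, censor_rate = censor_rate, stage_probs = stage_probs,
    mut_rate = mut_rate, mut_multiplier_immune = mut_multiplier_immune,
    n_mut_genes = as.integer(n_mut_genes),
    n_cells = as.integer(n_cells), cell_type_props = cell_type_props,
    sc_marker_fold = sc_marker_fold, sc_size = sc_size, sc_base_mu = sc_base_mu,
    n_icb = as.integer(n_icb), gamma_icb = gamma_icb,
    beta_response = beta_response, beta_icb_stromal = beta_icb_stromal,
    beta_icb_immune = beta_icb_immune,
    seed = as.integer(seed)
  )
  if (abs(sum(mixing) - 1) > 1e-8) stop_input("mixing proportions must sum to 1")
  if (abs(sum(cell_type_props) - 1) > 1e-8) stop_input("cell type proportions must sum to 1")
  if (delta < 0) stop_input("delta must be >= 0")
  if (sigma <= 0) stop_input("sigma must be > 0")
  if (lambda0 <= 0) stop_input("lambda0 must be > 0")
  if (sum(program_sizes) > n_genes) stop_input("program sizes exceed n_genes")
  if (any(ferro_in_program > program_sizes)) {
    stop_input("ferro_in_program cannot exceed the program sizes")
  }
  if (n_ferroptosis < sum(ferro_in_program)) {
    stop_input("n_ferroptosis smaller than the planted in-program ferroptosis genes")
  }
  if (n_ferroptosis - sum(ferro_in_program) > n_genes - sum(program_sizes)) {
    stop_input("not enough background genes for the ferroptosis list")
  }
  structure(cfg, class = "sim_config")
}

# gene universe shared by every simulated cohort: program blocks first,
# then background; ferroptosis membership and roles planted on top
sim_gene_truth <- function(cfg) {
  ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  program <- rep("none", cfg$n_genes)
  sizes <- cfg$program_sizes
  off <- 0L
  for (p in names(sizes)) {
    program[(off + 1):(off + sizes[[p]])] <- p
    off <- off + sizes[[p]]
  }
  ferro <- rep(FALSE, cfg$n_genes)
  fin <- cfg$ferro_in_program
  off <- 0L
  for (p in names(sizes)) {
    ferro[(off + 1):(off + fin[[p]])] <- TRUE
    off <- off + sizes[[p]]
  }
  n_bg <- cfg$n_ferroptosis - sum(fin)
  bg_idx <- which(program == "none")[seq_len(n_bg)]
  ferro[bg_idx] <- TRUE
  role <- rep(NA_character_, cfg$n_genes)
  fidx <- which(ferro)
  role_pool <- rep(c("driver", "suppressor", "marker"),
                   times = round(c(71, 61, 96) / 228 * length(fidx)))
  role_pool <- role_pool[seq_len(length(fidx))]
  if (length(role_pool) < length(fidx)) {
    role_pool <- c(role_pool, rep("marker", length(fidx) - length(role_pool)))
  }
  # interleave roles across positions so every program block carries all roles
  role[fidx] <- role_pool[order(order(fidx %% 3, fidx))]
  tibble(gene_id = ids, program = program, ferroptosis = ferro, role = role)
}

sim_gene_sets <- function(genes) {
  ferro <- genes$gene_id[genes$ferroptosis]
  sets <- list(FERROPTOSIS = ferro)
  roles <- c(FERROPTOSIS = NA_character_)
  for (r in c("driver", "suppressor", "marker")) {
    nm <- paste0("FERROPTOSIS_", toupper(r))
    sets[[nm]] <- genes$gene_id[genes$ferroptosis & genes$role == r]
    roles[nm] <- r
  }
  # non-ferroptosis program genes double as reference TME signatures for
  # identifying the immune- and stromal-activated clusters downstream
  sets$IMMUNE_REFERENCE <- genes$gene_id[genes$program == "immune" & !genes$ferroptosis]
  sets$STROMAL_REFERENCE <- genes$gene_id[genes$program == "stromal" & !genes$ferroptosis]
  roles[c("IMMUNE_REFERENCE", "STROMAL_REFERENCE")] <- NA_character_
  gene_sets(sets, roles = roles)
}

sim_draw_clusters <- function(n, mixing) {
  sample(names(mixing), n, replace = TRUE, prob = mixing)
}

sim_expression <- function(cfg, genes, cluster) {
  n <- length(cluster)
  baseline <- stats::runif(cfg$n_genes, 2, 8)
  E <- matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$sigma), cfg$n_genes, n)
  E <- E + baseline
  for (p in names(cfg$program_sizes)) {
    idx <- which(genes$program == p)
    on <- which(cluster == p)
    if (length(on) > 0) E[idx, on] <- E[idx, on] + cfg$delta
  }
  E[E < 0] <- 0
  rownames(E) <- genes$gene_id
  colnames(E) <- sprintf("S%04d", seq_len(n))
  E
}

sim_survival <- function(cfg, cluster) {
  n <- length(cluster)
  rate <- cfg$lambda0 * exp(unname(cfg$beta[cluster]))
  t_event <- stats::rexp(n, rate)
  censored <- stats::runif(n) < cfg$censor_rate
  time <- ifelse(censored, stats::runif(n) * t_event, t_event)
  tibble(time = time, event = as.numeric(!censored))
}

#' Simulate a bulk cohort with ground truth
#'
#' Expression is baseline plus a `delta` bump on each cluster's program
#' genes plus Gaussian noise, clipped at zero; survival is exponential with
#' per-cluster log hazard ratios and uniform-before-event censoring; stage
#' is sampled with cluster-skewed probabilities; mutations are Bernoulli
#' with an immune-cluster rate multiplier.
#'
#' @param config A [sim_config()].
#' @return List: `expr` (expression matrix), `clinical` (clinical table with
#'   stage), `mutations` (mutation table), `sets` (gene-set collection with
#'   the ferroptosis list and role tags), `truth` (per-sample and per-gene
#'   ground truth).
#' @export
simulate_bulk_cohort <- function(config = sim_config()) {
  cfg <- config
  genes <- sim_gene_truth(cfg)
  ex <- with_block_seed(cfg$seed, "expression", {
    cl <- sim_draw_clusters(cfg$n_samples, cfg$mixing)
    list(cluster = cl, E = sim_expression(cfg, genes, cl))
  })
  cluster <- ex$cluster
  surv <- with_block_seed(cfg$seed, "survival", sim_survival(cfg, cluster))
  stage <- with_block_seed(cfg$seed, "stage", {
    vapply(cluster, function(cl) {
      sample(names(cfg$stage_probs[[cl]]), 1, prob = cfg$stage_probs[[cl]])
    }, character(1))
  })
  samples <- colnames(ex$E)
  clinical <- clinical_table(tibble(
    sample_id = samples, time = surv$time, event = surv$event,
    stage = unname(stage), cluster_true = cluster
  ))
  mut_genes <- genes$gene_id[seq_len(cfg$n_mut_genes)]
  mut <- with_block_seed(cfg$seed, "mutation", {
    rows <- list()
    for (i in seq_along(samples)) {
      rate <- cfg$mut_rate *
        if (cluster[i] == "immune") cfg$mut_multiplier_immune else 1
      hit <- mut_genes[stats::runif(length(mut_genes)) < rate]
      if (length(hit) > 0) {
        cls <- sample(c("Missense_Mutation", "Nonsense_Mutation", "Silent",
                        "Frame_Shift_Del", "Splice_Site"),
                      length(hit), replace = TRUE,
                      prob = c(0.6, 0.1, 0.15, 0.1, 0.05))
        rows[[length(rows) + 1]] <- tibble(sample_id = samples[i],
                                           gene_symbol = hit,
                                           variant_classification = cls)
      }
    }
    if (length(rows) > 0) bind_rows(rows) else
      tibble(sample_id = character(), gene_symbol = character(),
             variant_classification = character())
  })
  truth_samples <- tibble(
    sample_id = samples, cluster = cluster,
    activity_canonical = cfg$delta * (cluster == "canonical"),
    activity_immune = cfg$delta * (cluster == "immune"),
    activity_stromal = cfg$delta * (cluster == "stromal")
  )
  list(
    expr = expression_matrix(ex$E),
    clinical = clinical,
    mutations = mutation_table(mut),
    sets = sim_gene_sets(genes),
    truth = list(samples = truth_samples, genes = genes,
                 beta = cfg$beta, config = cfg)
  )
}

#' Simulate a single-cell cohort with ground truth
#'
#' Negative-binomial counts over the same gene universe as the bulk
#' simulator. Five cell types (epithelial / T / B / myeloid / stromal) get
#' type-specific marker elevation; epithelial cells split between a
#' canonical-program and an immune-program state, and stromal cells
#' over-express the stromal program (ferroptosis members included) by
#' `sc_marker_fold` on the NB mean.
#'
#' @param config A [sim_config()].
#' @return List: `sc` (an `"sc_matrix"`), `truth` (per-cell labels plus the
#'   per-gene table and per-type marker sets).
#' @export
simulate_single_cell_cohort <- function(config = sim_config()) {
  cfg <- config
  genes <- sim_gene_truth(cfg)
  types <- names(cfg$cell_type_props)
  res <- with_block_seed(cfg$seed, "singlecell", {
    cell_type <- sample(types, cfg$n_cells, replace = TRUE,
                        prob = cfg$cell_type_props)
    program <- rep(NA_character_, cfg$n_cells)
    epi <- which(cell_type == "epithelial")
    program[epi] <- sample(c("canonical", "immune"), length(epi), replace = TRUE)
    program[cell_type == "stromal"] <- "stromal"

    # type marker blocks drawn from background genes (outside the programs)
    bg <- which(genes$program == "none" & !genes$ferroptosis)
    marker_sets <- list()
    off <- length(bg)
    k <- 40L
    for (i in seq_along(types)) {
      marker_sets[[types[i]]] <- genes$gene_id[bg[((i - 1) * k + 1):(i * k)]]
    }

    mu0 <- stats::rgamma(cfg$n_genes, shape = 0.8, rate = 0.8 / cfg$sc_base_mu)
    names(mu0) <- genes$gene_id
    counts <- matrix(0L, cfg$n_genes, cfg$n_cells)
    prog_idx <- lapply(c("canonical", "immune", "stromal"),
                       function(p) which(genes$program == p))
    names(prog_idx) <- c("canonical", "immune", "stromal")
    marker_idx <- lapply(marker_sets, function(s) match(s, genes$gene_id))
    for (j in seq_len(cfg$n_cells)) {
      mu <- mu0
      mu[marker_idx[[cell_type[j]]]] <- mu[marker_idx[[cell_type[j]]]] * cfg$sc_marker_fold
      if (!is.na(program[j])) {
        mu[prog_idx[[program[j]]]] <- mu[prog_idx[[program[j]]]] * cfg$sc_marker_fold
      }
      counts[, j] <- stats::rnbinom(cfg$n_genes, mu = mu, size = cfg$sc_size)
    }
    list(cell_type = cell_type, program = program, counts = counts,
         marker_sets = marker_sets)
  })
  cells <- sprintf("C%05d", seq_len(cfg$n_cells))
  meta <- tibble(cell_id = cells, cell_type = res$cell_type,
                 program = res$program)
  sc <- sc_matrix(Matrix::Matrix(res$counts, sparse = TRUE),
                  gene_ids = genes$gene_id, cell_ids = cells, meta = meta)
  list(sc = sc,
       truth = list(cells = meta, genes = genes,
                    marker_sets = res$marker_sets, config = cfg))
}

#' Simulate an immunotherapy (ICB) cohort
#'
#' Bulk-style expression with the same program structure; clinical response
#' is Bernoulli with logit `gamma * (immune activity - stromal activity)`
#' (activities standardized), and the hazard falls with response and with
#' immune activity while rising with stromal activity.
#'
#' @param config A [sim_config()].
#' @return List: `expr`, `clinical` (with a `response` column), `truth`.
#' @export
simulate_icb_cohort <- function(config = sim_config()) {
  cfg <- config
  genes <- sim_gene_truth(cfg)
  res <- with_block_seed(cfg$seed, "icb", {
    cl <- sim_draw_clusters(cfg$n_icb, cfg$mixing)
    E <- sim_expression(cfg, genes, cl)
    colnames(E) <- sprintf("ICB%04d", seq_len(cfg$n_icb))
    a_imm <- cfg$delta * (cl == "immune")
    a_str <- cfg$delta * (cl == "stromal")
    z <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
    eta <- cfg$gamma_icb * (z(a_imm) - z(a_str))
    response <- as.numeric(stats::runif(cfg$n_icb) < stats::plogis(eta))
    rate <- cfg$lambda0 * exp(cfg$beta_response * response +
                              cfg$beta_icb_stromal * z(a_str) +
                              cfg$beta_icb_immune * z(a_imm))
    t_event <- stats::rexp(cfg$n_icb, rate)
    censored <- stats::runif(cfg$n_icb) < cfg$censor_rate
    time <- ifelse(censored, stats::runif(cfg$n_icb) * t_event, t_event)
    list(cl = cl, E = E, a_imm = a_imm, a_str = a_str, response = response,
         time = time, event = as.numeric(!censored))
  })
  samples <- colnames(res$E)
  clinical <- clinical_table(tibble(
    sample_id = samples, time = res$time, event = res$event,
    response = res$response, cluster_true = res$cl
  ))
  truth <- tibble(sample_id = samples, cluster = res$cl,
                  activity_immune = res$a_imm, activity_stromal = res$a_str,
                  response = res$response)
  list(expr = expression_matrix(res$E), clinical = clinical,
       truth = list(samples = truth, genes = genes, config = cfg))
}
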