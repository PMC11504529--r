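#' Run the full profiling pipeline on a simulated cohort
#'
#' Composes every stage end-to-end on synthetic data with planted truth:
#' simulate a bulk mixture cohort and matched single cells; deconvolve
#' fractions; score per-cell-type activity by ssGSEA; build the composite
#' immunoactivity and partition samples into low/moderate/high groups;
#' fit the two-state abundance-activity regressions and the slope change
#' for the risk-linked cell type; run differential expression between the
#' low and high groups; discover signed co-expression modules on the DE
#' genes; fit a Cox model on module eigengenes with Kaplan-Meier and
#' time-dependent ROC; process the single cells (QC, normalization, HVG,
#' embedding, clustering, annotation); and select phenotype-linked cells by
#' graph-regularized sparse Cox, calling subpopulations and intersecting
#' their signatures with the module genes. The whole run is a deterministic
#' function of `(config, seed)`.
#'
#' The defaults describe the simulated study: 60 bulk samples, 6 cell
#' types (the first three treated as the immune compartment feeding the
#' composite score), multiplicative expression noise of SD 0.1, survival
#' risk of 2 log-hazard units per SD of the first cell type's fraction,
#' 800 single cells over three annotated types whose markers are drawn
#' from non-risk cell types, and a planted 100-cell subpopulation inside
#' the B-cell type whose shifted genes (8-fold) are the risk cell type's
#' markers — the route by which those cells become linked to poor
#' survival.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param n_samples,n_genes,n_celltypes,noise_sd Bulk cohort dimensions.
#' @param n_cells_per_type Named vector of cells per single-cell type
#'   (names Macrophage, Bcell, Tcell).
#' @param shift_size Log2 shift of the planted subpopulation's genes.
#' @param n_planted Planted subpopulation size.
#' @param risk_slope Planted log-hazard per fraction SD.
#' @param config `RunConfig` overrides via [run_config()].
#' @return A named list with every stage's inputs and outputs (see the
#'   vignette for the walk-through): `bulk`, `fractions`, `activity`,
#'   `composite`, `groups`, `state_fits`, `delta_k`, `de`, `modules`,
#'   `cox`, `km`, `roc`, `sc`, `linkage`, `calls`, `intersection`.
#' @export
run_pipeline <- function(seed = 1, n_samples = 60, n_genes = 240,
                         n_celltypes = 6, noise_sd = 0.1,
                         n_cells_per_type = c(Macrophage = 270, Bcell = 270,
                                              Tcell = 260),
                         shift_size = 3, n_planted = 100, risk_slope = 2,
                         config = run_config()) {
  seeds <- seed + seq(0, 9) * 1009L   # per-stage streams from one seed

  ## 1. simulate bulk
  bulk <- generate_bulk_cohort(n_samples, n_genes, n_celltypes,
                               dirichlet_conc = 2, noise_sd = noise_sd,
                               risk_slope = risk_slope, seed = seeds[1])
  sig <- bulk$truth$signature
  marker_sets <- gene_set_collection(
    stats::setNames(bulk$truth$marker_genes, colnames(sig)))

  ## 2. deconvolution
  fractions <- estimate_fractions(bulk$expr, sig, n_perm = 30,
                                  seed = seeds[2])

  ## 3. activity scoring; first three cell types = immune compartment
  activity <- ssgsea_score(bulk$expr, marker_sets, alpha = config$alpha)
  immune_sets <- colnames(sig)[1:3]
  composite <- composite_immunoactivity(activity, immune_sets)

  ## 4. immunoactivity groups
  groups <- partition_by_activity(composite, k_groups = config$k_groups)

  ## 5. two-state slope change for the risk cell type
  risk_ct <- bulk$truth$risk_celltype
  st <- stats::setNames(bulk$clinical$state, bulk$clinical$sample_id)
  fits <- lapply(c("tumor", "control"), function(s) {
    ids <- names(st)[st == s]
    fit_state_regression(fractions$fractions[ids, risk_ct],
                         activity$scores[ids, risk_ct], state = s)
  })
  names(fits) <- c("tumor", "control")
  dk <- delta_k(fits$tumor, fits$control, boot_reps = config$boot_reps,
                seed = seeds[3], celltype = risk_ct)

  ## 6. differential expression, low vs high group
  de <- differential_expression(bulk$expr, groups$label,
                                lfc_thresh = config$lfc_thresh,
                                padj_thresh = config$padj_thresh)
  ## module-discovery input: the DE-ranked top half of the panel (the
  ## ranked DE list feeds co-expression analysis; a hard significance
  ## cut is too brittle at these group sizes)
  n_mod_input <- ceiling(length(de$gene) / 2)
  de_genes <- de$gene[order(de$p)][seq_len(n_mod_input)]

  ## 7. co-expression modules on the DE genes
  sub <- subset_expression(bulk$expr, genes = de_genes)
  sp <- pick_soft_power(sub, candidate_powers = config$soft_powers,
                        r2_target = config$scale_free_r2,
                        default_power = config$default_power)
  adj <- signed_adjacency(sub, sp$power)
  tom <- topological_overlap(adj)
  labels0 <- detect_modules(tom, min_size = 10,
                            cut_height = config$cut_height)
  me <- module_eigengenes(sub, labels0, kme_thresh = config$kme_thresh)
  module_genes <- names(me$assignment)[me$assignment != "grey"]

  ## 8. survival on module eigengenes
  cox <- fit_cox(bulk$clinical, me$eigengenes)
  lohi <- groups$label[groups$label %in% c("low", "high")]
  km <- km_logrank(bulk$clinical[bulk$clinical$sample_id %in% names(lohi), ],
                   lohi)
  risk <- drop(as.matrix(me$eigengenes) %*% cox$coef)
  names(risk) <- rownames(me$eigengenes)
  horizon <- stats::median(bulk$clinical$time)
  roc <- time_dependent_roc(risk, bulk$clinical, horizon = horizon)

  ## 9. single cells: three annotated types with markers from non-risk
  ## cell types; the planted subpop inside B cells carries the risk
  ## type's marker program
  sc_types <- stats::setNames(colnames(sig)[c(4, 2, 3)],
                              c("Macrophage", "Bcell", "Tcell"))
  sc_marker_sets <- gene_set_collection(
    stats::setNames(lapply(sc_types, function(ct) marker_sets[[ct]]),
                    names(sc_types)))
  planted <- list(parent_type = "Bcell", n_cells = n_planted,
                  shift_genes = marker_sets[[risk_ct]],
                  shift_size = shift_size)
  ## QC thresholds scaled to the simulated gene count (the standard
  ## 300/500 rules assume genome-scale panels)
  scg <- generate_single_cells(
    n_cells_per_type,
    sc_marker_sets, gene_ids = bulk$expr$gene_ids, planted = planted,
    n_fail_low = 5, n_fail_mid = 5, n_fail_mito = 5,
    fail_features = c(low = 20, mid = 50), seed = seeds[4])
  qc <- qc_filter(scg$counts, min_cells_per_gene = 20,
                  min_features_create = 40, min_features_filter = 60)
  ln <- log_normalize(qc$counts, scale_factor = config$scale_factor)
  hvg <- select_hvg(ln, n = min(150, length(ln$gene_ids)))
  emb <- embed_cells(ln, hvg, n_pcs = 10, clip = config$clip_z)
  clust <- cluster_cells(emb$coords, k_neighbors = config$k_neighbors,
                         resolution = config$resolution)
  ann <- annotate_clusters(ln, clust, sc_marker_sets)

  ## 10. phenotype linkage within the low-group context
  corr <- cell_bulk_correlation(ln, bulk$expr)
  graph <- build_cell_graph(emb$coords, k_neighbors = config$graph_k)
  sel <- penalized_cox_select(corr, bulk$clinical, graph$L,
                              lambda = config$lambda,
                              alpha_mix = config$alpha_mix,
                              tol = config$prox_tol,
                              max_iter = config$prox_max_iter,
                              seed = seeds[5])
  calls <- classify_and_call(sel, ann, group_context = "low")
  intersection <- lapply(calls, function(cl) {
    sg <- subpopulation_signature(cl, ln, ann, module_genes)
    list(call = cl$name, parent_type = cl$parent_type, sign = cl$sign,
         n_members = length(cl$members),
         signature_genes = sg$signature_genes,
         module_intersection = sg$module_intersection)
  })

  list(seed = seed, bulk = bulk, fractions = fractions, activity = activity,
       composite = composite, groups = groups, state_fits = fits,
       delta_k = dk, de = de, de_genes = de_genes,
       modules = list(power = sp, adjacency_dim = dim(adj), tom = NULL,
                      labels = me$assignment, eigengenes = me$eigengenes,
                      kme = me$kme, module_genes = module_genes),
       cox = cox, km = km, roc = roc,
       sc = list(truth = scg$truth, qc_report = qc$report, hvg = hvg,
                 embedding = emb, clusters = clust, annotation = ann),
       linkage = sel, calls = calls, intersection = intersection)
}
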