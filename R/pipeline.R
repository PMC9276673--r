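stage_offsets <- c(sim = 1L, cluster = 2L, reference = 3L, trajectory = 4L)

#' Deterministic per-stage seeds from one global seed
#'
#' Fans a single pipeline seed out to the stochastic stages through a fixed
#' affine splitting rule, so each stage is individually reproducible.
#'
#' @param seed Global integer seed.
#' @param stage One of `"sim"`, `"cluster"`, `"reference"`, `"trajectory"`.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  off <- stage_offsets[[stage]]
  as.integer((as.numeric(seed) * 10007 + off * 7919) %% 2147483629)
}

#' Assemble and validate an end-to-end pipeline configuration
#'
#' @param sim A [sim_config()] (or argument list for one).
#' @param qc A [qc_params()] (or argument list for one).
#' @param cluster List with `resolution` and `knn` for [cluster_cells()].
#' @param deg List with `log2fc_min`, `pct_min`, `alpha` for [find_degs()].
#' @param reference List with `noise_sd`, `effect` (planted subtype effect
#'   size), and `subtype_sizes` for [simulate_reference()].
#' @param trajectory List with `span`, `n_points`, `max_iter`, `tol` for
#'   [fit_pseudotime()].
#' @param seed Global seed fanned out via [stage_seed()].
#' @param output_dir Directory for stage outputs; `NULL` keeps everything in
#'   memory.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            qc = qc_params(),
                            cluster = list(resolution = 1, knn = 15L),
                            deg = list(log2fc_min = 0.1, pct_min = 0.01,
                                       alpha = 0.05),
                            reference = list(noise_sd = 1, effect = 1,
                                             subtype_sizes = default_subtype_sizes()),
                            trajectory = list(span = 0.5, n_points = 50L,
                                              max_iter = 30L, tol = 1e-2),
                            seed = 1L,
                            output_dir = NULL) {
  if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  if (!inherits(qc, "qc_params")) qc <- do.call(qc_params, qc)
  validate_sim_config(sim)
  sim$seed <- stage_seed(seed, "sim")
  cfg <- list(sim = sim, qc = qc, cluster = cluster, deg = deg,
              reference = reference, trajectory = trajectory,
              seed = as.integer(seed), output_dir = output_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

# map inferred clusters to the planted supergroup ("0", "1", "2", "3") by
# majority vote of the planted cluster labels of their member cells
majority_supergroup <- function(assignment, true_cluster) {
  idx <- split(seq_len(nrow(assignment)), assignment$cluster)
  vapply(idx, function(i) {
    super <- substr(true_cluster[i], 1, 1)
    names(sort(table(super), decreasing = TRUE))[1]
  }, character(1))
}

#' Run the full synthetic replay pipeline
#'
#' Executes simulate, quality filtering, normalization, PCA, clustering,
#' entropy and site-composition diagnostics, site-contrast differential
#' expression, duct/TDLU signature construction, planted-reference scoring
#' with Kruskal-Wallis/Dunn comparison, and MST + principal-curve trajectory
#' inference, in order. The duct signature's planted markers double as the
#' reference's Basal up-genes and the TDLU markers as the LumA/LumB
#' up-genes, so a correct pipeline must report Basal as the duct signature's
#' top-scoring subtype. When `output_dir` is set, each stage's table is
#' written in the package's TSV/MTX dialects.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log stage progress.
#' @return A manifest list: stage cell/gene counts, seeds, per-signature
#'   top-scoring subtype and Kruskal-Wallis p, trajectory root and lineages,
#'   plus the stage result objects under `$results`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) inform(sprintf(...))
  out_dir <- config$output_dir
  t0 <- Sys.time()

  say("stage 1/7: simulate")
  cells <- simulate_cells(config$sim)
  if (!is.null(out_dir)) write_cell_dataset(cells, file.path(out_dir, "sim"))

  say("stage 2/7: quality filtering + normalization + PCA")
  filtered <- filter_cells(cells, config$qc)
  filtered <- normalize_log(filtered, config$qc$target_sum)
  emb <- embed_pca(filtered, config$qc)

  say("stage 3/7: clustering + integration diagnostics")
  assign <- cluster_cells(emb, resolution = config$cluster$resolution,
                          knn = config$cluster$knn,
                          seed = stage_seed(config$seed, "cluster"))
  ent <- cluster_entropy(assign, filtered$cell_meta$donor)
  groups <- majority_supergroup(assign, filtered$cell_meta$true_cluster)
  comp <- site_composition(assign, filtered$cell_meta$site,
                           filtered$cell_meta$donor, groups)

  say("stage 4/7: differential expression (duct vs TDLU)")
  degs <- find_degs(filtered, group_by = "site",
                    log2fc_min = config$deg$log2fc_min,
                    pct_min = config$deg$pct_min, alpha = config$deg$alpha)
  sig_duct <- signature_from_degs(degs, "duct")
  sig_tdlu <- signature_from_degs(degs, "tdlu")

  say("stage 5/7: planted bulk reference")
  tree <- config$sim$cluster_tree
  duct_clusters <- tree$cluster_id[tree$site_bias > 0.5]
  tdlu_clusters <- tree$cluster_id[tree$site_bias < 0.5]
  gm <- cells$gene_meta
  duct_markers <- gm$gene_id[gm$planted_marker_of %in% duct_clusters &
                               !is.na(gm$planted_marker_of)]
  tdlu_markers <- gm$gene_id[gm$planted_marker_of %in% tdlu_clusters &
                               !is.na(gm$planted_marker_of)]
  eff <- config$reference$effect
  ref <- simulate_reference(
    subtype_sizes = config$reference$subtype_sizes,
    planted_signatures = list(
      Basal = list(up = duct_markers, down = character(), effect = eff),
      LumA = list(up = tdlu_markers, down = character(), effect = eff),
      LumB = list(up = tdlu_markers, down = character(), effect = eff)),
    noise_sd = config$reference$noise_sd,
    seed = stage_seed(config$seed, "reference"),
    gene_ids = gm$gene_id)
  if (!is.null(out_dir)) {
    write_reference_matrix(ref, file.path(out_dir, "reference.tsv"))
  }

  say("stage 6/7: signature scoring + subtype comparison")
  scores_duct <- suppressMessages(score_samples(sig_duct, ref))
  scores_tdlu <- suppressMessages(score_samples(sig_tdlu, ref))
  cmp_duct <- compare_scores(scores_duct)
  cmp_tdlu <- compare_scores(scores_tdlu)

  say("stage 7/7: trajectory inference")
  mst <- build_mst(emb, assign)
  lin <- infer_root_and_lineages(mst)
  traj <- fit_pseudotime(emb, assign, lin, mst,
                         span = config$trajectory$span,
                         n_points = config$trajectory$n_points,
                         max_iter = config$trajectory$max_iter,
                         tol = config$trajectory$tol)

  if (!is.null(out_dir)) {
    tsv_write(assign, file.path(out_dir, "clusters.tsv"))
    tsv_write(ent, file.path(out_dir, "entropy.tsv"))
    tsv_write(comp, file.path(out_dir, "composition.tsv"))
    tsv_write(as_tibble(degs), file.path(out_dir, "degs_site.tsv"))
    write_signature(sig_duct, file.path(out_dir, "signature_duct.tsv"))
    write_signature(sig_tdlu, file.path(out_dir, "signature_tdlu.tsv"))
    tsv_write(as_tibble(scores_duct), file.path(out_dir, "scores_duct.tsv"))
    tsv_write(as_tibble(scores_tdlu), file.path(out_dir, "scores_tdlu.tsv"))
    tsv_write(traj$pseudotime, file.path(out_dir, "pseudotime.tsv"))
    tsv_write(traj$mst_edges, file.path(out_dir, "mst_edges.tsv"))
  }

  manifest <- list(
    seed = config$seed,
    stage_seeds = c(sim = config$sim$seed,
                    cluster = stage_seed(config$seed, "cluster"),
                    reference = stage_seed(config$seed, "reference")),
    n_genes = nrow(cells$counts),
    n_cells_simulated = ncol(cells$counts),
    n_cells_retained = ncol(filtered$counts),
    n_clusters = attr(assign, "k"),
    min_entropy = min(ent$entropy[!ent$small]),
    n_significant_degs = sum(degs$significant),
    signature_sizes = c(duct = length(sig_duct$weights),
                        tdlu = length(sig_tdlu$weights)),
    top_subtype = c(duct = names(cmp_duct$medians)[1],
                    tdlu = names(cmp_tdlu$medians)[1]),
    kw_p = c(duct = cmp_duct$kw_p, tdlu = cmp_tdlu$kw_p),
    trajectory_root = traj$root,
    lineages = vapply(traj$lineages, paste, character(1), collapse = "->"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    results = list(cells = cells, filtered = filtered, embedding = emb,
                   assignment = assign, entropy = ent, composition = comp,
                   degs = degs, signatures = list(duct = sig_duct, tdlu = sig_tdlu),
                   reference = ref,
                   scores = list(duct = scores_duct, tdlu = scores_tdlu),
                   comparisons = list(duct = cmp_duct, tdlu = cmp_tdlu),
                   trajectory = traj)
  )
  manifest
}

#' Percentage with half-up rounding at a stated precision
#'
#' `100 * numerator / denominator` rounded half-up to `digits` decimals —
#' the convention behind printed fractions such as "146 cells, 0.7% of the
#' total population" or "22/36 (61%)".
#'
#' @param numerator,denominator Counts; `denominator` must be positive.
#' @param digits Decimals to keep. Default 1.
#' @return The rounded percentage.
#' @examples
#' report_fraction(146, 20286, 1)  # 0.7
#' report_fraction(22, 36, 0)      # 61
#' @export
report_fraction <- function(numerator, denominator, digits = 1L) {
  if (denominator <= 0) abort("denominator must be positive")
  x <- 100 * numerator / denominator
  floor(x * 10^digits + 0.5) / 10^digits
}
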