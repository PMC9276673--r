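#' Default luminal cluster hierarchy for the cell simulator
#'
#' A tree of 11 luminal clusters emulating the structure reported for normal
#' breast luminal cells: the immature progenitor 1.1 at the origin, a
#' duct-enriched progenitor compartment (clusters 1.2-1.4, with 1.2 most
#' strongly duct-biased) branching directly off it, and a TDLU-enriched
#' mature chain running through the intermediate cluster 3 into clusters
#' 2.4-2.6 and 2.1-2.3. Latent times increase from the origin towards the
#' endpoints, so trajectories end either in the progenitor compartment
#' (1.4) or in the most mature clusters — and the origin is the central
#' vertex of the lineage tree, as an unsupervised origin search assumes.
#'
#' @return A tibble with columns `cluster_id`, `parent_id` (`NA` for the
#'   root), `site_bias` (probability mass towards the duct site),
#'   `n_markers`, `marker_log2fc`, and `latent_time` in `[0, 1]`.
#' @export
default_cluster_tree <- function() {
  tibble::tribble(
    ~cluster_id, ~parent_id, ~site_bias, ~n_markers, ~marker_log2fc, ~latent_time,
    "1.1", NA_character_, 0.85, 25, 2, 0.05,
    "1.2", "1.1",         0.95, 25, 2, 0.15,
    "1.3", "1.1",         0.85, 25, 2, 0.20,
    "1.4", "1.1",         0.85, 25, 2, 0.35,
    "3",   "1.1",         0.50, 25, 2, 0.50,
    "2.4", "3",           0.15, 25, 2, 0.60,
    "2.5", "2.4",         0.15, 25, 2, 0.70,
    "2.6", "2.5",         0.15, 25, 2, 0.75,
    "2.1", "2.6",         0.15, 25, 2, 0.85,
    "2.2", "2.1",         0.15, 25, 2, 0.90,
    "2.3", "2.2",         0.15, 25, 2, 0.95
  )
}

#' Simulation configuration for the single-cell count generator
#'
#' Bundles and validates every parameter of [simulate_cells()]. Defaults
#' emulate the study design the pipeline targets: three donors, two
#' anatomical sites (duct and TDLU) per donor, a clustered luminal hierarchy
#' with planted marker genes, and a small immune contaminant population
#' (cluster `"0"`, 0.7% of cells by default).
#'
#' @param n_donors Number of donors (biopsies). Default 3.
#' @param n_cells_per_site_donor Cells drawn per donor and site. Default 350,
#'   a desk-scale stand-in for the study's ~3,400 analyzed cells per
#'   donor-site combination.
#' @param n_genes Size of the gene universe. Default 2000.
#' @param cluster_tree Tibble describing the cluster hierarchy; see
#'   [default_cluster_tree()] for the required columns.
#' @param contaminant_fraction Fraction of cells drawn from the contaminant
#'   cluster `"0"`. Default 0.007.
#' @param contaminant_n_markers,contaminant_log2fc Marker structure of the
#'   contaminant cluster.
#' @param nb_mean_log_mu,nb_mean_log_sd Meanlog/sdlog of the log-normal
#'   distribution of per-gene baseline negative-binomial means.
#' @param nb_dispersion Negative-binomial dispersion phi, with
#'   `Var = mu + phi * mu^2`.
#' @param lib_size_log_sd Sdlog of the log-normal per-cell library-size
#'   factor.
#' @param donor_effect_sd Sd of gene-wise log-normal multiplicative donor
#'   (batch) effects; 0 means perfectly integrated donors.
#' @param inherit_markers Cells also express the marker programs of their
#'   cluster's ancestors (progenitor programs persist through
#'   differentiation), so the planted hierarchy shapes the expression
#'   geometry. Default TRUE.
#' @param mito_gene_fraction Fraction of the gene universe reserved as
#'   mitochondrial genes (prefix `"MT-"`).
#' @param time_jitter Half-width of the uniform jitter added to each
#'   cluster's latent time.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_donors = 3,
                       n_cells_per_site_donor = 350,
                       n_genes = 2000,
                       cluster_tree = default_cluster_tree(),
                       contaminant_fraction = 0.007,
                       contaminant_n_markers = 25,
                       contaminant_log2fc = 3,
                       nb_mean_log_mu = 0,
                       nb_mean_log_sd = 1,
                       nb_dispersion = 0.5,
                       lib_size_log_sd = 0.2,
                       donor_effect_sd = 0.1,
                       inherit_markers = TRUE,
                       mito_gene_fraction = 0.05,
                       time_jitter = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_donors = as.integer(n_donors),
    n_cells_per_site_donor = as.integer(n_cells_per_site_donor),
    n_genes = as.integer(n_genes),
    cluster_tree = tibble::as_tibble(cluster_tree),
    contaminant_fraction = contaminant_fraction,
    contaminant_n_markers = as.integer(contaminant_n_markers),
    contaminant_log2fc = contaminant_log2fc,
    nb_mean_log_mu = nb_mean_log_mu,
    nb_mean_log_sd = nb_mean_log_sd,
    nb_dispersion = nb_dispersion,
    lib_size_log_sd = lib_size_log_sd,
    donor_effect_sd = donor_effect_sd,
    inherit_markers = isTRUE(inherit_markers),
    mito_gene_fraction = mito_gene_fraction,
    time_jitter = time_jitter,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  tree <- cfg$cluster_tree
  needed <- c("cluster_id", "parent_id", "site_bias", "n_markers",
              "marker_log2fc", "latent_time")
  if (!all(needed %in% names(tree))) {
    abort(paste0("cluster_tree must have columns: ",
                 paste(setdiff(needed, names(tree)), collapse = ", "),
                 " missing"))
  }
  if (cfg$n_genes < 1L || cfg$n_cells_per_site_donor < 1L) {
    abort("n_genes and n_cells_per_site_donor must be positive")
  }
  if (cfg$n_donors < 1L) abort("n_donors must be positive")
  if (anyDuplicated(tree$cluster_id)) abort("cluster_ids must be unique")
  if (sum(is.na(tree$parent_id)) != 1L) {
    abort("cluster_tree must have exactly one root (one NA parent_id)")
  }
  known <- c(tree$cluster_id, NA_character_)
  if (!all(tree$parent_id %in% known)) abort("parent_id refers to unknown cluster")
  fracs <- c(tree$site_bias, tree$latent_time, cfg$contaminant_fraction,
             cfg$mito_gene_fraction)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  if (cfg$nb_dispersion <= 0) abort("nb_dispersion must be positive")
  if (cfg$donor_effect_sd < 0 || cfg$lib_size_log_sd < 0) {
    abort("donor_effect_sd and lib_size_log_sd must be non-negative")
  }
  n_mito <- ceiling(cfg$mito_gene_fraction * cfg$n_genes)
  n_marked <- sum(tree$n_markers) + cfg$contaminant_n_markers
  if (n_marked > cfg$n_genes - n_mito) {
    abort(sprintf(
      "marker genes requested (%d) exceed the non-mitochondrial gene pool (%d)",
      n_marked, cfg$n_genes - n_mito))
  }
  invisible(cfg)
}

new_cell_dataset <- function(counts, gene_meta, cell_meta, norm = NULL) {
  stopifnot(nrow(counts) == nrow(gene_meta), ncol(counts) == nrow(cell_meta))
  structure(
    list(counts = counts, gene_meta = gene_meta, cell_meta = cell_meta,
         norm = norm),
    class = "cell_dataset")
}

#' @export
print.cell_dataset <- function(x, ...) {
  cat(sprintf("<cell_dataset> %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  donors: %s\n",
              paste(levels(factor(x$cell_meta$donor)), collapse = ", ")))
  cat(sprintf("  normalized layer: %s\n",
              if (is.null(x$norm)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.cell_dataset <- function(x) dim(x$counts)

#' Simulate a clustered single-cell count dataset with known ground truth
#'
#' Draws a sparse genes-by-cells count matrix from a negative-binomial model:
#' per-gene baseline means are log-normal across genes, each cell carries a
#' log-normal library-size factor, marker genes are amplified by
#' `2^marker_log2fc` in their cluster, and each donor applies gene-wise
#' multiplicative log-normal shifts (a batch effect the entropy diagnostic
#' must detect when large). Cells are assigned to clusters with
#' site-dependent probabilities derived from each cluster's `site_bias`, and
#' a `contaminant_fraction` of cells is drawn from an extra cluster `"0"`
#' with its own markers. With `inherit_markers` (the default) a cluster's
#' cells additionally carry the marker programs of every ancestor cluster,
#' so centroid distances in expression space reflect tree-path distances of
#' the planted hierarchy. Mitochondrial fraction is computed from the realized
#' counts on `MT-` genes; the planted cluster and latent time of every cell
#' are recorded in `cell_meta`.
#'
#' @param config A [sim_config()].
#' @return A `cell_dataset`: sparse counts, `gene_meta`
#'   (`gene_id`, `is_mito`, `planted_marker_of`), `cell_meta`
#'   (`cell_id`, `donor`, `site`, `mito_fraction`, `true_cluster`,
#'   `true_time`; `true_time` is `NA` for contaminant cells).
#' @examples
#' cfg <- sim_config(n_cells_per_site_donor = 20, n_genes = 300, seed = 7)
#' sc <- simulate_cells(cfg)
#' dim(sc)
#' @export
simulate_cells <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  tree <- config$cluster_tree

  n_mito <- as.integer(ceiling(config$mito_gene_fraction * config$n_genes))
  gene_ids <- c(
    if (n_mito > 0) paste0("MT-", seq_len(n_mito)),
    sprintf("G%05d", seq_len(config$n_genes - n_mito))
  )
  is_mito <- seq_len(config$n_genes) <= n_mito
  base_mu <- rlnorm(config$n_genes, config$nb_mean_log_mu, config$nb_mean_log_sd)

  # disjoint marker assignment over the non-mito pool
  marker_of <- rep(NA_character_, config$n_genes)
  pool <- which(!is_mito)
  clusters <- tree$cluster_id
  marker_n <- setNames(tree$n_markers, clusters)
  marker_lfc <- setNames(tree$marker_log2fc, clusters)
  if (config$contaminant_fraction > 0) {
    marker_n <- c(marker_n, "0" = config$contaminant_n_markers)
    marker_lfc <- c(marker_lfc, "0" = config$contaminant_log2fc)
  }
  for (cl in names(marker_n)) {
    if (marker_n[[cl]] == 0) next
    picked <- sample(pool, marker_n[[cl]])
    marker_of[picked] <- cl
    pool <- setdiff(pool, picked)
  }

  # cell-level design: donors x sites x cells, contaminants, clusters, times
  donors <- paste0("donor", seq_len(config$n_donors))
  design <- expand.grid(donor = donors, site = c("duct", "tdlu"),
                        stringsAsFactors = FALSE)
  cell_donor <- rep(design$donor, each = config$n_cells_per_site_donor)
  cell_site <- rep(design$site, each = config$n_cells_per_site_donor)
  n_cells <- length(cell_donor)
  is_contam <- runif(n_cells) < config$contaminant_fraction

  latent <- setNames(tree$latent_time, clusters)
  cell_cluster <- character(n_cells)
  for (s in c("duct", "tdlu")) {
    w <- if (s == "duct") tree$site_bias else 1 - tree$site_bias
    if (sum(w) == 0) abort(sprintf("no cluster admits site '%s'", s))
    idx <- which(cell_site == s & !is_contam)
    cell_cluster[idx] <- sample(clusters, length(idx), replace = TRUE,
                                prob = w / sum(w))
  }
  cell_cluster[is_contam] <- "0"
  cell_time <- ifelse(is_contam, NA_real_,
                      pmin(1, pmax(0, latent[cell_cluster] +
                                     runif(n_cells, -config$time_jitter,
                                           config$time_jitter))))

  lib <- rlnorm(n_cells, 0, config$lib_size_log_sd)
  donor_fx <- matrix(exp(rnorm(config$n_genes * config$n_donors, 0,
                               config$donor_effect_sd)),
                     nrow = config$n_genes,
                     dimnames = list(NULL, donors))

  mu <- base_mu %o% lib
  for (d in donors) {
    cols <- which(cell_donor == d)
    mu[, cols] <- mu[, cols] * donor_fx[, d]
  }
  parent <- setNames(tree$parent_id, tree$cluster_id)
  active_sets <- function(cl) {
    if (cl == "0" || !config$inherit_markers) return(cl)
    out <- cl
    while (!is.na(parent[[cl]])) {
      cl <- parent[[cl]]
      out <- c(out, cl)
    }
    out
  }
  for (cl in unique(cell_cluster)) {
    cols <- which(cell_cluster == cl)
    for (prog in active_sets(cl)) {
      rows <- which(marker_of == prog)
      if (length(rows) && length(cols)) {
        mu[rows, cols] <- mu[rows, cols] * 2^marker_lfc[[prog]]
      }
    }
  }

  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                   nrow = config$n_genes)
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  dimnames(counts) <- list(gene_ids, cell_ids)
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

  totals <- Matrix::colSums(counts)
  mito_counts <- if (n_mito > 0) Matrix::colSums(counts[is_mito, , drop = FALSE]) else 0
  mito_fraction <- unname(ifelse(totals > 0, mito_counts / totals, 0))

  new_cell_dataset(
    counts,
    gene_meta = tibble(gene_id = gene_ids, is_mito = is_mito,
                       planted_marker_of = marker_of),
    cell_meta = tibble(cell_id = cell_ids, donor = cell_donor,
                       site = cell_site, mito_fraction = mito_fraction,
                       true_cluster = cell_cluster, true_time = unname(cell_time))
  )
}

#' Subtype sample sizes of the default bulk reference
#'
#' The six intrinsic breast-cancer subtype groups and sample counts used for
#' signature-score comparisons (93 samples total).
#' @return Named integer vector.
#' @export
default_subtype_sizes <- function() {
  c(Basal = 28L, Normal = 6L, ClaudinLow = 6L, Her2 = 14L,
    LumB = 17L, LumA = 22L)
}

new_reference_matrix <- function(expr, subtype) {
  stopifnot(nrow(expr) == length(subtype), !is.null(dimnames(expr)))
  structure(
    list(expr = expr, sample_ids = rownames(expr), gene_ids = colnames(expr),
         subtype = as.character(subtype)),
    class = "reference_matrix")
}

#' @export
print.reference_matrix <- function(x, ...) {
  cat(sprintf("<reference_matrix> %d samples x %d genes\n",
              nrow(x$expr), ncol(x$expr)))
  print(table(x$subtype))
  invisible(x)
}

#' Simulate a bulk reference expression matrix with planted subtype signatures
#'
#' Generates a samples-by-genes Gaussian expression matrix standing in for a
#' normalized bulk breast-cancer reference. Baseline expression is
#' `N(0, noise_sd)`; for every subtype with a planted signature, its samples
#' receive `+effect` on the signature's up genes and `-effect` on its down
#' genes.
#'
#' @param subtype_sizes Named count vector; defaults to
#'   [default_subtype_sizes()] (Basal 28, Normal 6, ClaudinLow 6, Her2 14,
#'   LumB 17, LumA 22).
#' @param n_genes Gene universe size when `gene_ids` is not supplied.
#' @param planted_signatures Named list (by subtype) of
#'   `list(up =, down =, effect =)` gene sets within the gene universe.
#' @param noise_sd Baseline Gaussian noise sd (non-negative).
#' @param seed Integer seed; identical seeds give identical matrices.
#' @param gene_ids Optional explicit gene universe (overrides `n_genes`).
#'
#' @return A `reference_matrix` with `expr`, `sample_ids`, `gene_ids`,
#'   `subtype`.
#' @examples
#' ref <- simulate_reference(seed = 1)
#' length(ref$sample_ids)  # 93
#' @export
simulate_reference <- function(subtype_sizes = default_subtype_sizes(),
                               n_genes = 500,
                               planted_signatures = list(),
                               noise_sd = 1,
                               seed = 1L,
                               gene_ids = NULL) {
  if (is.null(names(subtype_sizes)) || any(!nzchar(names(subtype_sizes)))) {
    abort("subtype_sizes must be a named vector")
  }
  if (any(subtype_sizes < 1)) abort("every subtype group must be non-empty")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (is.null(gene_ids)) gene_ids <- sprintf("G%05d", seq_len(n_genes))
  for (st in names(planted_signatures)) {
    sig <- planted_signatures[[st]]
    bad <- setdiff(c(sig$up, sig$down), gene_ids)
    if (length(bad)) {
      abort(sprintf("planted signature genes outside the gene universe: %s",
                    paste(head(bad, 5), collapse = ", ")))
    }
  }

  set.seed(seed)
  subtype <- rep(names(subtype_sizes), times = subtype_sizes)
  n_samples <- length(subtype)
  expr <- matrix(rnorm(n_samples * length(gene_ids), 0, noise_sd),
                 nrow = n_samples,
                 dimnames = list(sprintf("sample%03d", seq_len(n_samples)),
                                 gene_ids))
  for (st in names(planted_signatures)) {
    sig <- planted_signatures[[st]]
    rows <- which(subtype == st)
    if (length(sig$up)) expr[rows, sig$up] <- expr[rows, sig$up] + sig$effect
    if (length(sig$down)) expr[rows, sig$down] <- expr[rows, sig$down] - sig$effect
  }
  new_reference_matrix(expr, subtype)
}
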