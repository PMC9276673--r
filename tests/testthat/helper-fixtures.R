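# shared fixture builders -- everything is generated in code at test time

# flat hierarchy: a zero-marker root with k - 1 marked children, so marker
# inheritance cannot blur child-specific marker effects
flat_tree <- function(k, site_bias = 0.5, n_markers = 25L, marker_log2fc = 2,
                      latent_times = NULL) {
  ids <- LETTERS[seq_len(k)]
  if (is.null(latent_times)) latent_times <- seq(0, 1, length.out = k)
  tibble::tibble(
    cluster_id = ids,
    parent_id = c(NA_character_, rep(ids[1], k - 1)),
    site_bias = rep_len(site_bias, k),
    n_markers = as.integer(c(0, rep_len(n_markers, k - 1))),
    marker_log2fc = rep_len(marker_log2fc, k),
    latent_time = latent_times
  )
}

# chain hierarchy A -> B -> C -> ... with markers on every cluster
chain_tree <- function(k, n_markers = 25L, marker_log2fc = 2) {
  ids <- LETTERS[seq_len(k)]
  tibble::tibble(
    cluster_id = ids,
    parent_id = c(NA_character_, ids[-k]),
    site_bias = 0.5,
    n_markers = as.integer(n_markers),
    marker_log2fc = marker_log2fc,
    latent_time = seq(0.05, 0.95, length.out = k)
  )
}

null_sim_config <- function(seed, n_cells_per_site_donor = 167L,
                            n_genes = 2000L) {
  sim_config(
    n_cells_per_site_donor = n_cells_per_site_donor, n_genes = n_genes,
    cluster_tree = flat_tree(2, n_markers = 0L, marker_log2fc = 0),
    contaminant_fraction = 0, contaminant_n_markers = 0L,
    donor_effect_sd = 0, seed = seed)
}

# minimal cell_dataset from a dense count matrix (+ optional explicit norm)
make_dataset <- function(counts, donors = NULL, sites = NULL, mito = NULL,
                         norm = NULL) {
  n_genes <- nrow(counts)
  n_cells <- ncol(counts)
  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  cell_ids <- sprintf("c%03d", seq_len(n_cells))
  cm <- Matrix::Matrix(counts, sparse = TRUE)
  dimnames(cm) <- list(gene_ids, cell_ids)
  if (!is.null(norm)) {
    norm <- Matrix::Matrix(norm, sparse = TRUE)
    dimnames(norm) <- list(gene_ids, cell_ids)
  }
  lumascore:::new_cell_dataset(
    cm,
    gene_meta = tibble::tibble(gene_id = gene_ids, is_mito = FALSE,
                               planted_marker_of = NA_character_),
    cell_meta = tibble::tibble(
      cell_id = cell_ids,
      donor = donors %||% rep("donor1", n_cells),
      site = sites %||% rep("duct", n_cells),
      mito_fraction = mito %||% rep(0, n_cells)),
    norm = norm)
}

make_embedding <- function(coords) {
  if (is.null(rownames(coords))) {
    rownames(coords) <- sprintf("c%03d", seq_len(nrow(coords)))
  }
  structure(list(coords = coords,
                 explained_variance = rep(1, ncol(coords)),
                 hvg = character()),
            class = "embedding")
}

assignment_of <- function(coords_or_ids, cluster) {
  ids <- if (is.matrix(coords_or_ids)) rownames(coords_or_ids) else coords_or_ids
  tibble::tibble(cell_id = ids, cluster = as.character(cluster))
}

`%||%` <- rlang::`%||%`
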