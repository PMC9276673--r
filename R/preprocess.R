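#' Quality-control and embedding parameters
#'
#' @param min_features,max_features Inclusive bounds on the number of
#'   detected genes (genes with count > 0) per cell. Defaults 200 and 2000.
#' @param max_mito_fraction Maximum tolerated mitochondrial count fraction;
#'   cells strictly above it are excluded. Default 0.10.
#' @param target_sum Per-cell count total after normalization. Default 1e4.
#' @param n_hvg Number of highly variable genes entering PCA. Default 500.
#' @param n_pcs Number of principal components retained. Default 10.
#' @return A validated list of class `qc_params`.
#' @export
qc_params <- function(min_features = 200L, max_features = 2000L,
                      max_mito_fraction = 0.10, target_sum = 1e4,
                      n_hvg = 500L, n_pcs = 10L) {
  p <- list(min_features = as.integer(min_features),
            max_features = as.integer(max_features),
            max_mito_fraction = max_mito_fraction,
            target_sum = target_sum,
            n_hvg = as.integer(n_hvg), n_pcs = as.integer(n_pcs))
  if (p$min_features >= p$max_features) {
    abort("min_features must be smaller than max_features")
  }
  if (p$max_mito_fraction < 0 || p$max_mito_fraction > 1) {
    abort("max_mito_fraction must lie in [0, 1]")
  }
  if (p$target_sum <= 0) abort("target_sum must be positive")
  class(p) <- "qc_params"
  p
}

#' Per-cell quality report
#'
#' @param data A `cell_dataset`.
#' @param params A [qc_params()].
#' @return Tibble with `cell_id`, `n_features`, `mito_fraction`, `retained`.
#' @export
qc_report <- function(data, params = qc_params()) {
  n_features <- Matrix::colSums(data$counts > 0)
  mito <- data$cell_meta$mito_fraction
  if (is.null(mito)) {
    is_mito <- data$gene_meta$is_mito %||% startsWith(data$gene_meta$gene_id, "MT-")
    totals <- Matrix::colSums(data$counts)
    mito <- ifelse(totals > 0,
                   Matrix::colSums(data$counts[is_mito, , drop = FALSE]) / totals,
                   0)
  }
  tibble(
    cell_id = data$cell_meta$cell_id,
    n_features = as.integer(n_features),
    mito_fraction = as.numeric(mito),
    retained = n_features >= params$min_features &
      n_features <= params$max_features &
      mito <= params$max_mito_fraction
  )
}

#' Filter cells on detected-gene count and mitochondrial fraction
#'
#' Retains exactly the cells whose detected-gene count (genes with
#' count > 0) lies inclusively between `min_features` and `max_features` and
#' whose mitochondrial count fraction does not exceed `max_mito_fraction`.
#' The gene set is unchanged.
#'
#' @inheritParams qc_report
#' @param verbose Log retained/excluded counts to the console.
#' @return The filtered `cell_dataset`.
#' @export
filter_cells <- function(data, params = qc_params(), verbose = FALSE) {
  rep <- qc_report(data, params)
  keep <- rep$retained
  if (!any(keep)) abort("quality filtering removed every cell")
  if (verbose) {
    inform(sprintf("filter_cells: retained %d / %d cells (excluded %d)",
                   sum(keep), length(keep), sum(!keep)))
  }
  out <- data
  out$counts <- data$counts[, keep, drop = FALSE]
  out$cell_meta <- data$cell_meta[keep, , drop = FALSE]
  if (!is.null(data$norm)) out$norm <- data$norm[, keep, drop = FALSE]
  out
}

#' Library-size normalize and log-transform counts
#'
#' Scales each cell's counts to `target_sum` total and applies
#' `log(1 + x)`, storing the result as the `norm` layer alongside the raw
#' counts.
#'
#' @param data A `cell_dataset`.
#' @param target_sum Post-scaling count total per cell.
#' @return The `cell_dataset` with a `norm` layer added.
#' @export
normalize_log <- function(data, target_sum = 1e4) {
  totals <- Matrix::colSums(data$counts)
  if (any(totals == 0)) {
    abort(sprintf("cells with zero total counts cannot be normalized: %s",
                  paste(head(data$cell_meta$cell_id[totals == 0], 5),
                        collapse = ", ")))
  }
  sf <- target_sum / totals
  norm <- data$counts %*% Matrix::Diagonal(x = sf)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(data$counts)
  data$norm <- norm
  data
}

new_embedding <- function(coords, explained_variance, hvg) {
  structure(list(coords = coords, explained_variance = explained_variance,
                 hvg = hvg),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> %d cells x %d PCs (%d HVGs)\n",
              nrow(x$coords), ncol(x$coords), length(x$hvg)))
  invisible(x)
}

#' PCA embedding on highly variable genes
#'
#' Selects the `n_hvg` genes with the highest variance on the normalized
#' layer, centers and scales them, and computes a PCA. Component signs are
#' fixed so that each component's largest-magnitude gene loading is
#' positive, making the embedding reproducible across platforms.
#'
#' @param data A normalized `cell_dataset` (see [normalize_log()]).
#' @param params A [qc_params()]; uses `n_hvg` and `n_pcs`.
#' @return An `embedding` with `coords` (cells x n_pcs, rownames = cell
#'   ids), `explained_variance` (component variances, non-increasing), and
#'   the selected `hvg` gene ids.
#' @export
embed_pca <- function(data, params = qc_params()) {
  if (is.null(data$norm)) abort("normalized layer missing; run normalize_log() first")
  n_cells <- ncol(data$norm)
  x <- data$norm
  mu <- Matrix::rowMeans(x)
  ex2 <- Matrix::rowMeans(x^2)
  v <- (ex2 - mu^2) * n_cells / (n_cells - 1)
  n_hvg <- min(params$n_hvg, nrow(x))
  hvg_idx <- order(v, decreasing = TRUE)[seq_len(n_hvg)]
  hvg_idx <- hvg_idx[v[hvg_idx] > 0]
  if (length(hvg_idx) < 2) abort("fewer than two variable genes available")

  m <- t(as.matrix(x[hvg_idx, , drop = FALSE]))
  m <- scale(m, center = TRUE, scale = TRUE)
  rank_max <- min(nrow(m) - 1L, ncol(m))
  if (params$n_pcs > rank_max) {
    abort(sprintf("n_pcs = %d exceeds the attainable rank %d",
                  params$n_pcs, rank_max))
  }
  pc <- prcomp(m, center = FALSE, scale. = FALSE, rank. = params$n_pcs)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(pc$rotation))) {
    lead <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[lead, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  coords <- pc$x[, seq_len(params$n_pcs), drop = FALSE]
  rownames(coords) <- data$cell_meta$cell_id
  new_embedding(coords, pc$sdev[seq_len(params$n_pcs)]^2,
                data$gene_meta$gene_id[hvg_idx])
}
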