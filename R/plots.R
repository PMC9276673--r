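#' Box plot of signature scores by breast-cancer subtype
#'
#' @param object A `score_table` from [score_samples()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot score_table
#' @export
autoplot.score_table <- function(object, ...) {
  ord <- names(sort(tapply(object$score, object$subtype, stats::median),
                    decreasing = TRUE))
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$subtype, levels = ord),
                               y = .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "breast-cancer subtype", y = "expression signature score",
                  title = unique(object$signature)) +
    ggplot2::theme_bw()
}

#' Volcano plot of a DEG table
#'
#' @param object A `deg_table` from [find_degs()].
#' @param ... Unused.
#' @return A ggplot, faceted by group.
#' @method autoplot deg_table
#' @export
autoplot.deg_table <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(neg_log10_p = -log10(pmax(.data$p_adj, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = .data$neg_log10_p,
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p") +
    ggplot2::theme_bw()
}

#' Trajectory plot: cells, MST and principal curves in PC1/PC2
#'
#' @param object A `trajectory` from [fit_pseudotime()].
#' @param embedding The `embedding` the trajectory was fit on.
#' @param assignment The cluster assignment tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_trajectory <- function(object, embedding, assignment, ...) {
  idx <- match(rownames(embedding$coords), assignment$cell_id)
  cells <- tibble(pc1 = embedding$coords[, 1], pc2 = embedding$coords[, 2],
                  cluster = assignment$cluster[idx])
  curves <- bind_rows(lapply(names(object$curves), function(nm) {
    tibble(lineage = nm, pc1 = object$curves[[nm]][, 1],
           pc2 = object$curves[[nm]][, 2])
  }))
  cents <- tibble(cluster = rownames(object$centroids),
                  pc1 = object$centroids[, 1], pc2 = object$centroids[, 2])
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$cluster),
                        size = 0.5, alpha = 0.5) +
    ggplot2::geom_path(data = curves,
                       ggplot2::aes(group = .data$lineage), linewidth = 0.8) +
    ggplot2::geom_label(data = cents, ggplot2::aes(label = .data$cluster),
                        size = 3) +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_bw()
}

#' Bar plot of per-cluster donor-mixing entropy
#'
#' @param entropy Output of [cluster_entropy()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_entropy <- function(entropy, ...) {
  ggplot2::ggplot(entropy, ggplot2::aes(x = .data$cluster, y = .data$entropy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "cluster", y = "normalized donor entropy") +
    ggplot2::theme_bw()
}
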