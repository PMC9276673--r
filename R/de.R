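# Two-sided rank-sum p-values for many genes at once, given per-gene rank
# sums `w` in the group and per-gene tie terms sum(t^3 - t). Normal
# approximation with tie and continuity correction; exact Mann-Whitney
# distribution (pwilcox) when both groups have <= `exact_max` observations
# and a gene is tie-free.
rank_sum_p <- function(w, n1, n2, tie_term, exact_max = 10L) {
  n <- n1 + n2
  u <- w - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- ifelse(sigma2 > 0, (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2), 0)
  p <- pmin(1, 2 * pnorm(-abs(z)))
  if (n1 <= exact_max && n2 <= exact_max) {
    for (g in which(tie_term == 0)) {
      pg <- if (u[g] > mu) {
        stats::pwilcox(u[g] - 1, n1, n2, lower.tail = FALSE)
      } else {
        stats::pwilcox(u[g], n1, n2)
      }
      p[g] <- min(1, 2 * pg)
    }
  }
  p
}

# Per-gene average ranks across cells plus the tie term sum(t^3 - t).
gene_ranks <- function(mat) {
  n_genes <- nrow(mat)
  ranks <- matrix(0, n_genes, ncol(mat))
  tie_term <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    x <- mat[g, ]
    ranks[g, ] <- rank(x)
    len <- rle(sort.int(x, method = "quick"))$lengths
    tie_term[g] <- sum(len^3) - length(x)
  }
  list(ranks = ranks, tie_term = tie_term)
}

#' One-vs-rest differential expression with Wilcoxon rank-sum tests
#'
#' For every group level (cluster labels or anatomical site) and every gene:
#' log2 fold change of the mean de-logged normalized expression
#' (`log2((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))`), fractions of
#' cells with a positive raw count inside and outside the group, and a
#' two-sided Wilcoxon rank-sum p-value on the normalized values (normal
#' approximation with tie and continuity correction; exact distribution when
#' both groups have at most 10 cells and the gene is tie-free). P-values are
#' Bonferroni-corrected over all (gene, level) hypotheses tested. A gene is
#' `significant` for a level when `|log2fc| >= log2fc_min`,
#' `pct_in >= pct_min` and `p_adj < alpha`.
#'
#' @param data A normalized `cell_dataset`.
#' @param assignment Optional tibble with `cell_id`, `cluster`; when absent,
#'   `group_by = "site"` uses the site labels in `cell_meta`.
#' @param group_by `"cluster"` or `"site"`.
#' @param log2fc_min Absolute log2 fold-change cutoff. Default 0.1.
#' @param pct_min Minimum fraction of in-group cells expressing the gene.
#'   Default 0.01.
#' @param alpha Significance level on the adjusted p. Default 0.05.
#' @return Tibble of class `deg_table`: `gene_id`, `group`, `log2fc`,
#'   `pct_in`, `pct_out`, `p_raw`, `p_adj`, `significant`.
#' @export
find_degs <- function(data, assignment = NULL, group_by = c("cluster", "site"),
                      log2fc_min = 0.1, pct_min = 0.01, alpha = 0.05) {
  group_by <- match.arg(group_by)
  if (is.null(data$norm)) abort("normalized layer missing; run normalize_log() first")
  if (group_by == "cluster") {
    if (is.null(assignment)) abort("assignment required for group_by = 'cluster'")
    idx <- match(data$cell_meta$cell_id, assignment$cell_id)
    if (anyNA(idx)) abort("assignment does not cover every cell")
    labels <- assignment$cluster[idx]
  } else {
    labels <- data$cell_meta$site
  }
  labels <- as.character(labels)
  levels <- sort(unique(labels))
  if (length(levels) < 2) abort("grouping must have at least two levels")
  if (nrow(data$norm) == 0) abort("gene universe is empty")

  norm <- as.matrix(data$norm)
  expm1_mat <- expm1(norm)
  detected <- as.matrix(data$counts > 0)

  # per-gene ranks over all cells are shared by every one-vs-rest contrast
  rk <- gene_ranks(norm)

  res <- purrr::map(levels, function(lv) {
    in_group <- labels == lv
    m_in <- rowMeans(expm1_mat[, in_group, drop = FALSE])
    m_out <- rowMeans(expm1_mat[, !in_group, drop = FALSE])
    w <- as.numeric(rk$ranks %*% as.numeric(in_group))
    p <- rank_sum_p(w, sum(in_group), sum(!in_group), rk$tie_term)
    tibble(
      gene_id = data$gene_meta$gene_id,
      group = lv,
      log2fc = as.numeric(log2((m_in + 1) / (m_out + 1))),
      pct_in = as.numeric(rowMeans(detected[, in_group, drop = FALSE])),
      pct_out = as.numeric(rowMeans(detected[, !in_group, drop = FALSE])),
      p_raw = as.numeric(p)
    )
  })
  out <- bind_rows(res)
  n_tests <- sum(!is.na(out$p_raw))
  out <- out |>
    mutate(p_adj = pmin(1, .data$p_raw * n_tests),
           significant = abs(.data$log2fc) >= log2fc_min &
             .data$pct_in >= pct_min & .data$p_adj < alpha)
  class(out) <- c("deg_table", class(out))
  out
}

#' Ranked gene lists for pathway-enrichment input
#'
#' Retains, per group, genes with `log2fc > 0.5` whose fraction of
#' expressing cells in the group exceeds 1.5 times the fraction outside
#' (`pct_in / pct_out > 1.5`; a gene unseen outside the group passes the
#' ratio rule), ordered by decreasing log2 fold change — the input format of
#' external functional-profiling tools.
#'
#' @param degs A `deg_table` from [find_degs()].
#' @param log2fc_min Fold-change floor (strict). Default 0.5.
#' @param pct_ratio_min Expression-fraction ratio floor (strict). Default 1.5.
#' @return Tibble `group`, `gene_id`, `log2fc`, `rank` (1 = largest
#'   log2fc within its group).
#' @export
pathway_input_filter <- function(degs, log2fc_min = 0.5, pct_ratio_min = 1.5) {
  degs |>
    as_tibble() |>
    mutate(pct_ratio = ifelse(.data$pct_out == 0, Inf,
                              .data$pct_in / .data$pct_out)) |>
    filter(.data$log2fc > log2fc_min, .data$pct_ratio > pct_ratio_min) |>
    group_by(.data$group) |>
    arrange(desc(.data$log2fc), .by_group = TRUE) |>
    mutate(rank = dplyr::row_number()) |>
    ungroup() |>
    select("group", "gene_id", "log2fc", "rank")
}

#' Restrict a DEG table to a gene universe
#'
#' Keeps the rows whose gene is a member of `universe` (for example, the
#' cell-surface protein universe used to screen for sortable markers), in
#' their original order.
#'
#' @param degs A `deg_table`.
#' @param universe Character vector of gene ids (non-empty).
#' @return The subset `deg_table`.
#' @export
intersect_gene_universe <- function(degs, universe) {
  if (length(universe) == 0) abort("gene universe must be non-empty")
  out <- degs[degs$gene_id %in% universe, , drop = FALSE]
  out
}
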