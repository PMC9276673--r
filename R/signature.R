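new_signature <- function(weights, name) {
  weights <- weights[weights != 0]
  if (length(weights) == 0) abort("a signature needs at least one non-zero weight")
  if (anyDuplicated(names(weights))) abort("a gene may appear at most once in a signature")
  structure(list(weights = weights, name = name), class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("<signature> '%s': %d genes (%d up, %d down)\n", x$name,
              length(x$weights), sum(x$weights > 0), sum(x$weights < 0)))
  invisible(x)
}

#' Build an expression signature from significant DEGs of one group
#'
#' The signature's gene weights are the log2 fold changes of the group's
#' significant genes; markers with a negative fold change are retained with
#' their negative weight.
#'
#' @param degs A `deg_table` from [find_degs()].
#' @param group The group level whose DEGs form the signature.
#' @param name Signature name; defaults to the group label.
#' @return A `signature` (gene -> real weight map).
#' @export
signature_from_degs <- function(degs, group, name = group) {
  rows <- degs[degs$group == group & degs$significant, , drop = FALSE]
  if (nrow(rows) == 0) {
    abort(sprintf("no significant genes for group '%s'", group))
  }
  new_signature(setNames(rows$log2fc, rows$gene_id), name)
}

#' Build a +/-1 signature from up- and down-regulated gene lists
#'
#' For published classifier gene lists that come without fold-change values,
#' up-regulated genes are weighted +1 and down-regulated genes -1.
#'
#' @param up,down Character vectors of gene ids (disjoint; not both empty).
#' @param name Signature name.
#' @return A `signature`.
#' @export
signature_from_genelist <- function(up, down = character(), name = "genelist") {
  both <- intersect(up, down)
  if (length(both)) {
    abort(sprintf("gene(s) in both the up and down list: %s",
                  paste(both, collapse = ", ")))
  }
  if (length(up) + length(down) == 0) {
    abort("up and down lists are both empty")
  }
  new_signature(setNames(c(rep(1, length(up)), rep(-1, length(down))),
                         c(up, down)), name)
}

#' Score bulk reference samples against an expression signature
#'
#' The expression signature score of a sample is the inner product between
#' the signature's gene weights and the sample's expression of the same
#' genes: a high weight (log2FC) combined with high expression yields a
#' large score, so high scores indicate similarity between the cell
#' population behind the signature and the cancer sample. With
#' `standardize = TRUE` (default) each shared gene's reference expression is
#' z-scored across samples first, so no single high-abundance gene dominates;
#' zero-variance genes are dropped. Signature genes absent from the
#' reference are dropped and counted.
#'
#' @param signature A `signature`.
#' @param reference A `reference_matrix`.
#' @param standardize Z-score each shared gene across samples. Default TRUE.
#' @param mode `"sum"` (default) or `"mean"` over shared genes.
#' @return Tibble of class `score_table`: `sample_id`, `subtype`,
#'   `signature`, `score`, `n_genes_used`.
#' @export
score_samples <- function(signature, reference, standardize = TRUE,
                          mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  shared <- intersect(names(signature$weights), reference$gene_ids)
  n_dropped <- length(signature$weights) - length(shared)
  if (length(shared) == 0) {
    abort(sprintf(
      "no shared genes between signature (%d genes) and reference (%d genes)",
      length(signature$weights), length(reference$gene_ids)))
  }
  expr <- reference$expr[, shared, drop = FALSE]
  if (standardize) {
    sds <- apply(expr, 2, sd)
    keep <- sds > 0
    if (!any(keep)) {
      abort("all shared signature genes have zero variance in the reference")
    }
    if (any(!keep)) n_dropped <- n_dropped + sum(!keep)
    expr <- scale(expr[, keep, drop = FALSE])
    shared <- shared[keep]
  }
  if (n_dropped > 0) {
    inform(sprintf("score_samples: %d signature gene(s) dropped (absent or constant)",
                   n_dropped))
  }
  w <- signature$weights[shared]
  scores <- as.numeric(expr %*% w)
  if (mode == "mean") scores <- scores / length(shared)
  out <- tibble(sample_id = reference$sample_ids,
                subtype = reference$subtype,
                signature = signature$name,
                score = scores,
                n_genes_used = length(shared))
  class(out) <- c("score_table", class(out))
  out
}

# Dunn's pairwise z on mean ranks with tie correction.
dunn_pairwise <- function(values, groups, p_adjust = "holm") {
  r <- rank(values)
  N <- length(values)
  tab <- table(r)
  tie_corr <- sum(tab^3 - tab) / (12 * (N - 1))
  mean_ranks <- tapply(r, groups, mean)
  sizes <- tapply(r, groups, length)
  pairs <- combn(names(mean_ranks), 2)
  z <- apply(pairs, 2, function(p) {
    (mean_ranks[p[1]] - mean_ranks[p[2]]) /
      sqrt((N * (N + 1) / 12 - tie_corr) * (1 / sizes[p[1]] + 1 / sizes[p[2]]))
  })
  p_raw <- 2 * pnorm(-abs(z))
  tibble(group1 = pairs[1, ], group2 = pairs[2, ], z = as.numeric(z),
         p_raw = as.numeric(p_raw),
         p_adj = stats::p.adjust(p_raw, method = p_adjust))
}

#' Compare signature scores across subtype groups
#'
#' Kruskal-Wallis one-way analysis of variance on ranks (with tie
#' correction and a chi-square p-value) followed by Dunn's pairwise
#' z-statistics on mean ranks, with a configurable multiple-comparison
#' adjustment.
#'
#' @param scores A `score_table` from [score_samples()].
#' @param p_adjust Adjustment method for Dunn's pairwise p-values (any
#'   [stats::p.adjust()] method). Default `"holm"`.
#' @return Object of class `score_comparison`: list with `kw_h`, `kw_df`,
#'   `kw_p`, `dunn` (tibble `group1`, `group2`, `z`, `p_raw`, `p_adj`),
#'   `medians` (per-subtype median score, sorted decreasingly).
#' @export
compare_scores <- function(scores, p_adjust = "holm") {
  groups <- factor(scores$subtype)
  if (nlevels(groups) < 2) abort("at least two subtype groups are required")
  sizes <- table(groups)
  if (any(sizes < 2)) {
    abort(sprintf("subtype group(s) with fewer than 2 samples: %s",
                  paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  kw <- kruskal.test(scores$score, groups)
  med <- sort(tapply(scores$score, groups, stats::median), decreasing = TRUE)
  structure(
    list(kw_h = unname(kw$statistic), kw_df = unname(kw$parameter),
         kw_p = kw$p.value,
         dunn = dunn_pairwise(scores$score, groups, p_adjust),
         medians = med),
    class = "score_comparison")
}

#' @export
print.score_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g (df = %d), p = %.3g\n",
              x$kw_h, x$kw_df, x$kw_p))
  cat("median scores (decreasing):\n")
  print(round(x$medians, 3))
  invisible(x)
}

#' @rdname compare_scores
#' @param x A `score_comparison`.
#' @param ... Unused.
#' @method tidy score_comparison
#' @export
tidy.score_comparison <- function(x, ...) x$dunn

#' @rdname compare_scores
#' @method glance score_comparison
#' @export
glance.score_comparison <- function(x, ...) {
  tibble(kw_h = x$kw_h, kw_df = x$kw_df, kw_p = x$kw_p,
         top_subtype = names(x$medians)[1],
         n_pairs = nrow(x$dunn))
}

#' Nearest-centroid subtype association of a cluster expression profile
#'
#' Spearman correlation of a cluster's mean expression profile to each
#' subtype centroid over their shared genes, converted to normalized
#' probabilities by positive-part normalization (a simple monotone
#' surrogate for a posterior subtype probability). When no correlation is
#' positive the probabilities fall back to uniform with a warning flag.
#'
#' @param profile Named numeric vector: per-gene mean expression of a
#'   cluster.
#' @param centroids Genes-by-subtype numeric matrix of subtype centroids
#'   (rownames = gene ids), or a `reference_matrix` whose per-subtype mean
#'   profiles are used.
#' @return Tibble with `subtype`, `correlation`, `probability`, `call`
#'   (TRUE for the argmax), and attribute `degenerate` flagging the
#'   all-nonpositive fallback.
#' @export
centroid_subtype <- function(profile, centroids) {
  if (inherits(centroids, "reference_matrix")) {
    centroids <- t(rowsum(centroids$expr, centroids$subtype) /
                     as.vector(table(centroids$subtype)[sort(unique(centroids$subtype))]))
  }
  shared <- intersect(names(profile), rownames(centroids))
  if (length(shared) < 3) {
    abort(sprintf("need at least 3 shared genes, found %d", length(shared)))
  }
  cors <- apply(centroids[shared, , drop = FALSE], 2, function(cent) {
    cor(profile[shared], cent, method = "spearman")
  })
  pos <- pmax(cors, 0)
  degenerate <- sum(pos) == 0
  prob <- if (degenerate) {
    warn("no positive centroid correlation; probabilities set uniform")
    rep(1 / length(cors), length(cors))
  } else {
    pos / sum(pos)
  }
  out <- tibble(subtype = colnames(centroids), correlation = as.numeric(cors),
                probability = as.numeric(prob),
                call = seq_along(cors) == which.max(cors))
  attr(out, "degenerate") <- degenerate
  out
}
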