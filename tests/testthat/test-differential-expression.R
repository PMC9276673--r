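# dataset whose normalized layer is set directly, for exact-value checks
dataset_with_norm <- function(values_by_gene, groups) {
  norm <- do.call(rbind, values_by_gene)
  counts <- (norm > 0) * 1L
  make_dataset(counts, norm = norm)
}

test_that("Wilcoxon p-values match exhaustive enumeration on tiny groups", {
  groups <- rep(c("a", "b"), each = 4)
  data <- dataset_with_norm(list(c(1, 2, 3, 4, 5, 6, 7, 8)), groups)
  degs <- find_degs(data, assignment_of(data$cell_meta$cell_id, groups))
  # all 70 label assignments; the observed split is one of the 2 extremes
  expect_equal(degs$p_raw[degs$group == "a"][1], 2 / 70, tolerance = 1e-12)
  expect_equal(degs$p_raw[degs$group == "a"][1],
               enum_rank_sum_p(1:4, 5:8), tolerance = 1e-12)

  set.seed(19)
  for (rep in 1:5) {
    x <- sample(1:100, 5)
    y <- sample(101:200, 6) / 7
    groups <- rep(c("a", "b"), c(5, 6))
    data <- dataset_with_norm(list(c(x, y)), groups)
    degs <- find_degs(data, assignment_of(data$cell_meta$cell_id, groups))
    expect_equal(degs$p_raw[degs$group == "a"][1], enum_rank_sum_p(x, y),
                 tolerance = 1e-10)
  }
})

test_that("tied data uses the tie-corrected normal approximation", {
  set.seed(3)
  x <- sample(0:3, 40, replace = TRUE)
  y <- sample(0:4, 45, replace = TRUE)
  groups <- rep(c("a", "b"), c(40, 45))
  data <- dataset_with_norm(list(c(x, y)), groups)
  degs <- find_degs(data, assignment_of(data$cell_meta$cell_id, groups))
  # independent route: stats::wilcox.test normal approximation
  pw <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(degs$p_raw[degs$group == "a"][1], pw, tolerance = 1e-10)
})

test_that("DEG significance enforces every stated threshold", {
  set.seed(29)
  n_per <- 400
  groups <- rep(c("a", "b"), each = n_per)
  base <- matrix(rpois(6 * 2 * n_per, 3), 6, 2 * n_per)
  # gene 1: huge shift -> significant for a
  base[1, groups == "a"] <- base[1, groups == "a"] + 30L
  # gene 2: expressed in only 0.5% of group-a cells, strong where expressed
  base[2, ] <- 0L
  base[2, which(groups == "a")[1:2]] <- 50L
  counts <- base
  data <- normalize_log(make_dataset(counts))
  degs <- find_degs(data, assignment_of(data$cell_meta$cell_id, groups))
  a <- dplyr::filter(degs, group == "a")
  expect_true(a$significant[1])
  expect_gt(a$log2fc[1], 0.1)
  # 1% expressing rule blocks gene 2 regardless of p
  expect_equal(a$pct_in[2], 0.005)
  expect_false(a$significant[2])
  # Bonferroni: adjusted p equals raw p times number of tests, capped at 1
  expect_equal(degs$p_adj, pmin(1, degs$p_raw * nrow(degs)))
  # significance flags equal an independent row-by-row rule scan
  rescan <- abs(degs$log2fc) >= 0.1 & degs$pct_in >= 0.01 & degs$p_adj < 0.05
  expect_equal(degs$significant, rescan)
})

test_that("a sub-threshold fold change is not significant despite tiny p", {
  set.seed(57)
  n_per <- 500
  groups <- rep(c("a", "b"), each = n_per)
  # high-abundance gene with a consistent but tiny shift: p small, lfc small
  g <- c(rpois(n_per, 103), rpois(n_per, 100))
  data <- normalize_log(make_dataset(rbind(g, matrix(rpois(4 * 2 * n_per, 5),
                                                     4, 2 * n_per))))
  degs <- find_degs(data, assignment_of(data$cell_meta$cell_id, groups),
                    log2fc_min = 0.1)
  a1 <- dplyr::filter(degs, group == "a")[1, ]
  expect_lt(abs(a1$log2fc), 0.1)
  expect_false(a1$significant)
})

test_that("swapping group labels negates log2fc and preserves p", {
  set.seed(37)
  counts <- matrix(rpois(20 * 100, 2), 20, 100)
  groups <- rep(c("a", "b"), each = 50)
  data <- normalize_log(make_dataset(counts))
  d1 <- find_degs(data, assignment_of(data$cell_meta$cell_id, groups))
  a <- dplyr::filter(d1, group == "a")
  b <- dplyr::filter(d1, group == "b")
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-10)
  expect_equal(a$pct_in, b$pct_out)
  expect_equal(a$pct_out, b$pct_in)
  expect_equal(a$p_raw, b$p_raw, tolerance = 1e-12)
})

test_that("planted markers are recovered as significant", {
  cfg <- sim_config(n_cells_per_site_donor = 120, n_genes = 400,
                    cluster_tree = flat_tree(3, n_markers = 20L,
                                             marker_log2fc = 2),
                    contaminant_fraction = 0, seed = 41)
  sc <- simulate_cells(cfg)
  data <- normalize_log(filter_cells(sc))
  asgn <- assignment_of(data$cell_meta$cell_id, data$cell_meta$true_cluster)
  degs <- find_degs(data, asgn)
  markers <- dplyr::filter(data$gene_meta, !is.na(planted_marker_of))
  hits <- dplyr::inner_join(
    markers, as_tibble(degs),
    by = c(gene_id = "gene_id", planted_marker_of = "group"))
  expect_gte(mean(hits$significant), 0.9)
})

test_that("pathway input filter applies both strict thresholds in order", {
  degs <- tibble::tibble(
    gene_id = c("a", "b", "c", "d", "e"),
    group = "g1",
    log2fc = c(0.6, 0.4, 2.0, 0.8, 0.9),
    pct_in = c(0.30, 0.50, 0.20, 0.10, 0.60),
    pct_out = c(0.10, 0.10, 0.00, 0.08, 0.50),
    p_raw = 1e-6, p_adj = 1e-4, significant = TRUE)
  out <- pathway_input_filter(degs)
  # b: log2fc 0.4 <= 0.5 excluded; d: pct ratio 1.25 excluded;
  # e: ratio 1.2 excluded; c: pct_out 0 -> ratio Inf, retained
  expect_equal(out$gene_id, c("c", "a"))
  expect_equal(out$rank, c(1, 2))
  expect_equal(out$log2fc, sort(out$log2fc, decreasing = TRUE))
})

test_that("pathway filter equals a brute-force row scan on random tables", {
  set.seed(43)
  degs <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:20),
    group = rep(c("g1", "g2"), each = 10),
    log2fc = runif(20, -1, 2),
    pct_in = runif(20),
    pct_out = runif(20),
    p_raw = runif(20), p_adj = runif(20), significant = TRUE)
  out <- pathway_input_filter(degs)
  # oracle: explicit loop
  keep <- character()
  for (i in seq_len(20)) {
    ratio <- if (degs$pct_out[i] == 0) Inf else degs$pct_in[i] / degs$pct_out[i]
    if (degs$log2fc[i] > 0.5 && ratio > 1.5) keep <- c(keep, degs$gene_id[i])
  }
  expect_setequal(out$gene_id, keep)
  for (g in unique(out$group)) {
    sub <- dplyr::filter(out, group == g)
    expect_equal(sub$log2fc, sort(sub$log2fc, decreasing = TRUE))
  }
})

test_that("gene-universe intersection behaves as a set operation", {
  degs <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:200), group = "g1",
    log2fc = rnorm(200), pct_in = runif(200), pct_out = runif(200),
    p_raw = runif(200), p_adj = runif(200), significant = FALSE)
  expect_equal(nrow(intersect_gene_universe(degs, c("zz1", "zz2"))), 0)
  expect_equal(intersect_gene_universe(degs, degs$gene_id), degs)
  set.seed(47)
  uni <- sample(sprintf("g%03d", 1:400), 50)
  sub <- intersect_gene_universe(degs, uni)
  expect_setequal(sub$gene_id, intersect(degs$gene_id, uni))
  expect_equal(sub$gene_id, degs$gene_id[degs$gene_id %in% uni])  # order kept
  expect_error(intersect_gene_universe(degs, character()), "non-empty")
})

test_that("degenerate grouping inputs raise errors", {
  data <- normalize_log(make_dataset(matrix(rpois(40, 2), 4, 10)))
  expect_error(find_degs(data, assignment_of(data$cell_meta$cell_id,
                                             rep("only", 10))),
               "two levels")
  expect_error(find_degs(data, group_by = "cluster"), "assignment")
})
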