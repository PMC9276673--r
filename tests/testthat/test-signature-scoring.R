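toy_reference <- function(expr, subtype) {
  rownames(expr) <- sprintf("s%02d", seq_len(nrow(expr)))
  lumascore:::new_reference_matrix(expr, subtype)
}

test_that("DEG signatures carry signed log2FC weights of significant genes", {
  degs <- tibble::tibble(
    gene_id = c("A", "B", "C"), group = "duct",
    log2fc = c(0.8, -0.3, 2.0),
    pct_in = 0.5, pct_out = 0.1, p_raw = 1e-8,
    p_adj = c(1e-6, 1e-6, 0.2),
    significant = c(TRUE, TRUE, FALSE))
  sig <- signature_from_degs(degs, "duct")
  expect_equal(sig$weights, c(A = 0.8, B = -0.3))
  expect_error(signature_from_degs(degs, "tdlu"), "tdlu")

  set.seed(51)
  big <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:50), group = "x",
    log2fc = rnorm(50), pct_in = 0.5, pct_out = 0.1,
    p_raw = 0, p_adj = 0, significant = runif(50) < 0.6)
  sig2 <- signature_from_degs(big, "x")
  # oracle: row-wise extraction
  expect_equal(sig2$weights,
               setNames(big$log2fc[big$significant],
                        big$gene_id[big$significant]))
})

test_that("gene-list signatures use +1/-1 and reject contradictions", {
  sig <- signature_from_genelist(up = c("A", "B"), down = "C")
  expect_equal(sig$weights, c(A = 1, B = 1, C = -1))
  expect_error(signature_from_genelist(character(), character()), "empty")
  expect_error(signature_from_genelist(c("A", "B"), c("B", "C")), "B")
})

test_that("scores are the inner product of weights and expression", {
  # raw mode: weights (0.5, -0.2) on expression (2, 1) -> 0.8
  expr <- rbind(c(2, 1), c(0, 0), c(1, 1))
  colnames(expr) <- c("A", "B")
  ref <- toy_reference(expr, c("Basal", "LumA", "LumA"))
  sig <- lumascore:::new_signature(c(A = 0.5, B = -0.2), "toy")
  scores <- score_samples(sig, ref, standardize = FALSE)
  expect_equal(scores$score[1], 0.5 * 2 + (-0.2) * 1)
  expect_equal(scores$n_genes_used, rep(2L, 3))
  # standardized mode equals a hand-computed z-score inner product
  std <- score_samples(sig, ref, standardize = TRUE)
  z <- scale(expr)
  expect_equal(std$score, as.numeric(z %*% c(0.5, -0.2)))
  # mean mode rescales by the number of genes used
  m <- score_samples(sig, ref, standardize = FALSE, mode = "mean")
  expect_equal(m$score, scores$score / 2)
})

test_that("zero-variance and missing signature genes are dropped", {
  expr <- cbind(A = c(1, 1, 1), B = c(0, 1, 2))
  ref <- toy_reference(expr, c("Basal", "LumA", "LumB"))
  sig_const <- lumascore:::new_signature(c(A = 1), "const")
  expect_error(score_samples(sig_const, ref), "zero variance")
  sig_mixed <- lumascore:::new_signature(c(A = 1, B = 2, ZZZ = 1), "mixed")
  expect_message(scores <- score_samples(sig_mixed, ref), "2 signature gene")
  expect_equal(scores$n_genes_used, rep(1L, 3))
  sig_absent <- lumascore:::new_signature(c(Q = 1), "absent")
  expect_error(score_samples(sig_absent, ref), "no shared genes")
})

test_that("scoring is linear, scale-equivariant and permutation-equivariant", {
  set.seed(53)
  expr <- matrix(rnorm(20 * 10), 20, 10,
                 dimnames = list(NULL, sprintf("G%02d", 1:10)))
  ref <- toy_reference(expr, rep(c("Basal", "LumA"), each = 10))
  w1 <- setNames(rnorm(6), sprintf("G%02d", 1:6))
  w2 <- setNames(rnorm(6), sprintf("G%02d", 1:6))
  s1 <- score_samples(lumascore:::new_signature(w1, "s1"), ref)$score
  s2 <- score_samples(lumascore:::new_signature(w2, "s2"), ref)$score
  s12 <- score_samples(lumascore:::new_signature(w1 + w2, "s12"), ref)$score
  expect_equal(s12, s1 + s2, tolerance = 1e-10)
  s3 <- score_samples(lumascore:::new_signature(3 * w1, "s3"), ref)$score
  expect_equal(s3, 3 * s1, tolerance = 1e-10)

  perm <- sample(20)
  ref_p <- toy_reference(expr[perm, ], ref$subtype[perm])
  sp <- score_samples(lumascore:::new_signature(w1, "s1"), ref_p)$score
  expect_equal(sp, s1[perm], tolerance = 1e-10)
})

test_that("Kruskal-Wallis H matches a direct rank computation", {
  scores <- tibble::tibble(
    sample_id = sprintf("s%d", 1:6),
    subtype = rep(c("g1", "g2", "g3"), each = 2),
    signature = "t", score = c(1, 2, 3, 4, 5, 6), n_genes_used = 5L)
  cmp <- compare_scores(scores)
  # oracle: H = 12 / (N (N+1)) * sum n_i (Rbar_i - (N+1)/2)^2, no ties
  r <- rank(scores$score)
  rbar <- tapply(r, scores$subtype, mean)
  h <- 12 / (6 * 7) * sum(2 * (rbar - 3.5)^2)
  expect_equal(cmp$kw_h, h, tolerance = 1e-12)
  expect_equal(cmp$kw_df, 2)
  # rank statistic: permuting values within groups changes nothing
  scores2 <- scores
  scores2$score <- c(2, 1, 4, 3, 6, 5)
  expect_equal(compare_scores(scores2)$kw_h, cmp$kw_h)
  expect_error(compare_scores(dplyr::filter(scores, subtype == "g1")),
               "two subtype")
  scores3 <- scores
  scores3$subtype <- c("g1", rep("g2", 5))
  expect_error(compare_scores(scores3), "fewer than 2")
})

test_that("Dunn z-statistics match brute-force mean ranks", {
  set.seed(59)
  scores <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:12),
    subtype = rep(c("g1", "g2", "g3"), each = 4),
    signature = "t",
    score = c(rnorm(4), rnorm(4) + 1, sample(c(2, 2, 3, 4))),  # with ties
    n_genes_used = 3L)
  cmp <- compare_scores(scores, p_adjust = "none")
  # oracle: direct mean-rank formula with tie correction
  r <- rank(scores$score)
  n <- 12
  ties <- table(r)
  correction <- sum(ties^3 - ties) / (12 * (n - 1))
  for (row in seq_len(nrow(cmp$dunn))) {
    g1 <- cmp$dunn$group1[row]
    g2 <- cmp$dunn$group2[row]
    num <- mean(r[scores$subtype == g1]) - mean(r[scores$subtype == g2])
    den <- sqrt((n * (n + 1) / 12 - correction) * (1 / 4 + 1 / 4))
    expect_equal(cmp$dunn$z[row], num / den, tolerance = 1e-12)
    expect_equal(cmp$dunn$p_raw[row], 2 * pnorm(-abs(num / den)),
                 tolerance = 1e-12)
  }
  holm <- compare_scores(scores, p_adjust = "holm")
  expect_equal(holm$dunn$p_adj, p.adjust(holm$dunn$p_raw, "holm"))
  expect_s3_class(tidy(cmp), "tbl_df")
  expect_equal(glance(cmp)$kw_h, cmp$kw_h)
})

test_that("centroid subtype calls follow Spearman correlation", {
  set.seed(61)
  genes <- sprintf("G%02d", 1:30)
  basal <- setNames(rnorm(30), genes)
  luma <- setNames(rnorm(30), genes)
  centroids <- cbind(Basal = basal, LumA = luma)
  res <- centroid_subtype(basal, centroids)
  expect_equal(res$correlation[res$subtype == "Basal"], 1)
  expect_true(res$call[res$subtype == "Basal"])
  expect_equal(sum(res$probability), 1)
  # rank reversal -> correlation -1
  rev_prof <- setNames(-basal, genes)
  res2 <- suppressWarnings(centroid_subtype(rev_prof, centroids))
  expect_equal(res2$correlation[res2$subtype == "Basal"], -1)

  # 5-gene toy case against a hand-computed Spearman (Pearson on ranks)
  prof <- setNames(c(3, 1, 4, 1.5, 9), sprintf("G%02d", 1:5))
  cent <- cbind(c1 = c(2, 1, 3, 4, 5), c2 = c(5, 4, 3, 2, 1))
  rownames(cent) <- names(prof)
  res3 <- centroid_subtype(prof, cent)
  oracle <- apply(cent, 2, function(v) cor(rank(prof), rank(v)))
  expect_equal(res3$correlation, unname(oracle), tolerance = 1e-12)

  expect_error(centroid_subtype(prof[1:2], cent), "3 shared genes")
  # all-nonpositive correlations fall back to a uniform call
  expect_warning(res4 <- centroid_subtype(rev_prof, cbind(Basal = basal)),
                 "uniform")
  expect_equal(res4$probability, 1)
  expect_true(attr(res4, "degenerate"))
})

test_that("reference-derived centroids identify the planted subtype", {
  genes <- sprintf("G%05d", 1:60)
  ref <- simulate_reference(
    n_genes = 60,
    planted_signatures = list(Basal = list(up = genes[1:10],
                                           down = genes[11:20], effect = 4)),
    noise_sd = 0.5, seed = 67)
  profile <- setNames(c(rep(4, 10), rep(-4, 10), rep(0, 40)), genes) +
    rnorm(60, 0, 0.1)
  res <- centroid_subtype(profile, ref)
  expect_equal(res$subtype[res$call], "Basal")
})
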