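#' Cluster cells on a PCA embedding
#'
#' Graph-based community detection on a k-nearest-neighbour graph of the
#' embedding (Louvain modularity optimization), or k-means when an explicit
#' cluster number is requested. Labels are arbitrary but stable under a
#' fixed seed.
#'
#' @param embedding An `embedding` from [embed_pca()].
#' @param resolution Louvain resolution parameter (used when `k` is `NULL`).
#' @param k Explicit number of clusters; switches to k-means.
#' @param knn Neighbourhood size of the kNN graph.
#' @param seed Integer seed.
#' @return Tibble with `cell_id` and `cluster` (character labels), carrying
#'   the number of clusters as attribute `k`.
#' @export
cluster_cells <- function(embedding, resolution = 1, k = NULL, knn = 15L,
                          seed = 1L) {
  coords <- embedding$coords
  n <- nrow(coords)
  if (n == 0) abort("embedding has no cells")
  set.seed(seed)
  if (n == 1) {
    labels <- "1"
  } else if (!is.null(k)) {
    if (k > n) abort(sprintf("requested k = %d clusters for %d cells", k, n))
    km <- stats::kmeans(coords, centers = k, nstart = 10, iter.max = 100)
    labels <- as.character(km$cluster)
  } else {
    knn <- min(knn, n - 1L)
    d <- as.matrix(dist(coords))
    edges <- vector("list", n)
    for (i in seq_len(n)) {
      nb <- order(d[i, ])[2:(knn + 1L)]
      edges[[i]] <- rbind(i, nb)
    }
    el <- t(do.call(cbind, edges))
    el <- unique(t(apply(el, 1, sort)))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    comm <- igraph::cluster_louvain(g, resolution = resolution)
    labels <- as.character(igraph::membership(comm))
  }
  out <- tibble(cell_id = rownames(coords), cluster = labels)
  attr(out, "k") <- length(unique(labels))
  out
}

#' Donor-mixing entropy of each cluster
#'
#' Normalized Shannon entropy of the donor composition of every cluster:
#' `-sum_d p_d log(p_d) / log(n_donors)`, with zero-proportion terms
#' contributing zero. Values lie in `[0, 1]`: 1 when donors contribute
#' equally (successful integration), 0 when a cluster comes from a single
#' donor. Clusters smaller than `min_size` are flagged, not dropped.
#'
#' @param assignment Tibble with `cell_id` and `cluster` ([cluster_cells()]).
#' @param donors Per-cell donor labels aligned with `assignment` rows.
#' @param normalize Divide by `log(n_donors)` (default); otherwise raw nats.
#' @param min_size Clusters below this size are flagged in `small`.
#' @return Tibble with one row per cluster: `cluster`, `n_cells`, one
#'   `n_<donor>` count column per donor, `entropy`, `small`.
#' @export
cluster_entropy <- function(assignment, donors, normalize = TRUE,
                            min_size = 10L) {
  if (length(donors) != nrow(assignment)) {
    abort("donors must align with assignment rows")
  }
  donor_levels <- sort(unique(as.character(donors)))
  if (length(donor_levels) < 2) {
    abort("entropy requires at least two donors")
  }
  tab <- table(cluster = assignment$cluster, donor = as.character(donors))
  ent <- apply(tab, 1, function(cnt) {
    p <- cnt / sum(cnt)
    p <- p[p > 0]
    h <- -sum(p * log(p))
    if (normalize) h / log(length(donor_levels)) else h
  })
  counts <- as_tibble(as.data.frame.matrix(tab))
  names(counts) <- paste0("n_", names(counts))
  out <- tibble(cluster = rownames(tab),
                n_cells = as.integer(rowSums(tab))) |>
    dplyr::bind_cols(counts) |>
    mutate(entropy = as.numeric(ent), small = .data$n_cells < min_size)
  attr(out, "n_donors") <- length(donor_levels)
  out
}

#' Per-donor site composition of cluster supergroups
#'
#' For each donor, site (duct or TDLU) and cluster supergroup, the fraction
#' of that donor's cells of that site that fall in the supergroup — the
#' per-group contribution statistic suitable for a two-tailed t-test across
#' donors (see [test_site_composition()]).
#'
#' @param assignment Tibble with `cell_id` and `cluster`.
#' @param sites Per-cell site labels in `{duct, tdlu}`, aligned with
#'   `assignment`.
#' @param donors Per-cell donor labels, aligned with `assignment`.
#' @param groups Named character vector mapping every cluster to a
#'   supergroup.
#' @return Tibble with `donor`, `site`, `supergroup`, `n`,
#'   `freq` (fraction of the donor-site cell total, in `[0, 1]`).
#' @export
site_composition <- function(assignment, sites, donors, groups) {
  sites <- as.character(sites)
  if (!all(sites %in% c("duct", "tdlu"))) {
    abort(sprintf("unknown site label(s): %s",
                  paste(unique(setdiff(sites, c("duct", "tdlu"))), collapse = ", ")))
  }
  missing <- setdiff(unique(assignment$cluster), names(groups))
  if (length(missing)) {
    abort(sprintf("groups does not cover cluster(s): %s",
                  paste(missing, collapse = ", ")))
  }
  df <- tibble(donor = as.character(donors), site = sites,
               supergroup = unname(groups[assignment$cluster]))
  df |>
    count(.data$donor, .data$site, .data$supergroup, name = "n") |>
    tidyr::complete(.data$donor, .data$site,
                    supergroup = unique(unname(groups)),
                    fill = list(n = 0L)) |>
    group_by(.data$donor, .data$site) |>
    mutate(freq = .data$n / sum(.data$n)) |>
    ungroup()
}

#' Two-tailed t-test of duct vs TDLU contribution to a supergroup
#'
#' Compares, across donors, the duct-derived and TDLU-derived relative
#' frequencies of cells in one supergroup with a two-tailed two-sample
#' t-test.
#'
#' @param composition Output of [site_composition()].
#' @param supergroup The supergroup to test.
#' @return Tibble with `supergroup`, `mean_duct`, `mean_tdlu`, `t`, `p`.
#' @export
test_site_composition <- function(composition, supergroup) {
  sub <- filter(composition, .data$supergroup == !!supergroup)
  if (nrow(sub) == 0) abort(sprintf("supergroup '%s' not present", supergroup))
  duct <- sub$freq[sub$site == "duct"]
  tdlu <- sub$freq[sub$site == "tdlu"]
  tt <- t.test(duct, tdlu, alternative = "two.sided")
  tibble(supergroup = supergroup, mean_duct = mean(duct),
         mean_tdlu = mean(tdlu),
         t = unname(tt$statistic), p = tt$p.value)
}
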