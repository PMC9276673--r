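# independent oracle: exact two-sided rank-sum p by enumerating every
# assignment of group labels and comparing rank sums
enum_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(x)])
  combos <- combn(length(pooled), length(x))
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- mean(w_all)
  min(1, 2 * min(mean(w_all <= w_obs + 1e-9), mean(w_all >= w_obs - 1e-9)))
}


# oracle: minimum spanning tree weight by enumerating every labeled tree
# via Pruefer sequences (k^(k-2) trees, feasible for k <= 6)
brute_force_mst_length <- function(d) {
  k <- nrow(d)
  if (k == 2) return(d[1, 2])
  prufer_to_edges <- function(seq) {
    degree <- rep(1L, k)
    for (v in seq) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, k - 1, 2)
    ptr <- 1L
    seq2 <- seq
    for (i in seq_along(seq2)) {
      leaf <- which(degree == 1L)[1]
      edges[ptr, ] <- c(leaf, seq2[i])
      ptr <- ptr + 1L
      degree[leaf] <- 0L
      degree[seq2[i]] <- degree[seq2[i]] - 1L
    }
    last <- which(degree == 1L)
    edges[ptr, ] <- last
    edges
  }
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), k - 2)))
  best <- Inf
  for (i in seq_len(nrow(combos))) {
    e <- prufer_to_edges(combos[i, ])
    w <- sum(d[e])
    if (w < best) best <- w
  }
  best
}

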