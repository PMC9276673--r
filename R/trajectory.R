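# Project points onto a polyline; returns arc-length position and the
# projected coordinates. `curve` is an ordered m x d matrix of vertices.
project_to_polyline <- function(points, curve) {
  m <- nrow(curve)
  seg_vec <- curve[-1, , drop = FALSE] - curve[-m, , drop = FALSE]
  seg_len2 <- rowSums(seg_vec^2)
  seg_start_arc <- c(0, cumsum(sqrt(seg_len2)))[seq_len(m - 1)]
  n <- nrow(points)
  best_d2 <- rep(Inf, n)
  lambda <- numeric(n)
  proj <- matrix(0, n, ncol(curve))
  for (s in seq_len(m - 1)) {
    rel <- sweep(points, 2, curve[s, ])
    t_s <- if (seg_len2[s] > 0) {
      pmin(1, pmax(0, (rel %*% seg_vec[s, ]) / seg_len2[s]))
    } else {
      rep(0, n)
    }
    p_s <- matrix(curve[s, ], n, ncol(curve), byrow = TRUE) +
      as.vector(t_s) %o% seg_vec[s, ]
    d2 <- rowSums((points - p_s)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    lambda[upd] <- seg_start_arc[s] + as.vector(t_s)[upd] * sqrt(seg_len2[s])
    proj[upd, ] <- p_s[upd, , drop = FALSE]
  }
  list(lambda = lambda, proj = proj, dist2 = best_d2)
}

# Resample a polyline at `n_points` equally spaced arc-length positions.
densify_polyline <- function(curve, n_points) {
  m <- nrow(curve)
  seg_len <- sqrt(rowSums((curve[-1, , drop = FALSE] -
                             curve[-m, , drop = FALSE])^2))
  total <- sum(seg_len)
  if (total == 0) return(curve[rep(1, n_points), , drop = FALSE])
  arcs <- seq(0, total, length.out = n_points)
  cum <- c(0, cumsum(seg_len))
  out <- matrix(0, n_points, ncol(curve))
  for (i in seq_len(n_points)) {
    s <- max(1, min(m - 1, findInterval(arcs[i], cum, rightmost.closed = TRUE)))
    frac <- if (seg_len[s] > 0) (arcs[i] - cum[s]) / seg_len[s] else 0
    out[i, ] <- curve[s, ] + frac * (curve[s + 1, ] - curve[s, ])
  }
  out
}

#' Minimum spanning tree over cluster centroids
#'
#' Computes per-cluster mean positions in the embedding and the Euclidean
#' minimum spanning tree over them. Edges are ordered lexicographically by
#' cluster id so ties resolve deterministically.
#'
#' @param embedding An `embedding` from [embed_pca()].
#' @param assignment Tibble with `cell_id`, `cluster` covering the
#'   embedding's cells.
#' @return List with `centroids` (clusters x PCs, sorted rownames) and
#'   `mst_edges` (tibble `from`, `to`, `length`).
#' @export
build_mst <- function(embedding, assignment) {
  idx <- match(rownames(embedding$coords), assignment$cell_id)
  if (anyNA(idx)) abort("assignment does not cover every embedded cell")
  cl <- assignment$cluster[idx]
  ids <- sort(unique(cl))
  if (length(ids) < 2) abort("at least two clusters are required for an MST")
  centroids <- do.call(rbind, lapply(ids, function(g) {
    colMeans(embedding$coords[cl == g, , drop = FALSE])
  }))
  rownames(centroids) <- ids
  d <- as.matrix(dist(centroids))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g, algorithm = "prim")
  el <- igraph::as_edgelist(mst)
  ord <- t(apply(el, 1, sort))
  edges <- tibble(from = ord[, 1], to = ord[, 2],
                  length = igraph::E(mst)$weight) |>
    arrange(.data$from, .data$to)
  list(centroids = centroids, mst_edges = edges)
}

mst_graph <- function(mst) {
  igraph::graph_from_data_frame(
    data.frame(from = mst$mst_edges$from, to = mst$mst_edges$to,
               weight = mst$mst_edges$length),
    directed = FALSE,
    vertices = rownames(mst$centroids))
}

#' Unsupervised root selection and root-to-leaf lineages on an MST
#'
#' Without a hint, the root is the MST vertex minimizing the total tree-path
#' length to all leaves (a central-origin heuristic); ties are broken by the
#' total path length to every vertex and then lexicographically, so chains
#' with equally spaced centroids still root at the middle. Lineages are all
#' paths from the root to each leaf of the tree.
#'
#' @param mst Output of [build_mst()].
#' @param root_hint Optional cluster id forced as root.
#' @return List with `root` and `lineages` (list of ordered cluster-id
#'   vectors, each starting at the root and ending at an MST leaf).
#' @export
infer_root_and_lineages <- function(mst, root_hint = NULL) {
  g <- mst_graph(mst)
  ids <- igraph::V(g)$name
  deg <- igraph::degree(g)
  dmat <- igraph::distances(g)
  if (!is.null(root_hint)) {
    if (!root_hint %in% ids) {
      abort(sprintf("root_hint '%s' is not a cluster", root_hint))
    }
    root <- root_hint
  } else {
    leaves <- ids[deg == 1]
    to_leaves <- rowSums(dmat[, leaves, drop = FALSE])
    to_all <- rowSums(dmat)
    ord <- order(to_leaves, to_all, ids)
    root <- ids[ord[1]]
  }
  leaves <- ids[deg == 1 & ids != root]
  if (length(leaves) == 0) leaves <- setdiff(ids, root)
  lineages <- lapply(leaves, function(lf) {
    p <- igraph::shortest_paths(g, from = root, to = lf, output = "vpath")
    igraph::V(g)$name[p$vpath[[1]]]
  })
  names(lineages) <- vapply(lineages, function(p) p[length(p)], character(1))
  list(root = root, lineages = lineages)
}

# One principal-curve fit: iterated projection / arc-length-window smoothing
# initialized on the densified centroid polyline.
fit_principal_curve <- function(points, init_curve, span, n_points,
                                max_iter, tol) {
  curve <- densify_polyline(init_curve, n_points)
  lambda <- project_to_polyline(points, curve)$lambda
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lam_range <- diff(range(lambda))
    window <- max(span * lam_range, 1e-8)
    grid <- seq(min(lambda), max(lambda), length.out = n_points)
    new_curve <- matrix(0, n_points, ncol(points))
    for (i in seq_len(n_points)) {
      sel <- abs(lambda - grid[i]) <= window
      if (!any(sel)) sel <- which.min(abs(lambda - grid[i]))
      new_curve[i, ] <- colMeans(points[sel, , drop = FALSE])
    }
    # re-anchor: keep orientation from the root end of the initial curve
    if (sum((new_curve[1, ] - init_curve[1, ])^2) >
        sum((new_curve[n_points, ] - init_curve[1, ])^2)) {
      new_curve <- new_curve[n_points:1, , drop = FALSE]
    }
    new_lambda <- project_to_polyline(points, new_curve)$lambda
    shift <- mean(abs(new_lambda - lambda))
    curve <- new_curve
    lambda <- new_lambda
    if (shift < tol * max(lam_range, 1)) {
      converged <- TRUE
      break
    }
  }
  # extend both terminal segments so cells beyond the smoothed ends keep
  # distinct projections instead of piling up at the endpoints
  total_len <- sum(sqrt(rowSums(diff(curve)^2)))
  if (total_len > 0) {
    # direction from the first/last distinct curve points (wide smoothing
    # windows can duplicate terminal vertices)
    dev_head <- rowSums(sweep(curve, 2, curve[1, ])^2)
    dev_tail <- rowSums(sweep(curve, 2, curve[n_points, ])^2)
    j1 <- which(dev_head > 1e-12)[1]
    j2 <- rev(which(dev_tail > 1e-12))[1]
    ext <- function(v) v / sqrt(sum(v^2)) * total_len
    head_pt <- curve[1, ] + ext(curve[1, ] - curve[j1, ])
    tail_pt <- curve[n_points, ] + ext(curve[n_points, ] - curve[j2, ])
    curve <- rbind(head_pt, curve, tail_pt)
    lambda <- project_to_polyline(points, curve)$lambda
  }
  list(curve = curve, lambda = lambda - min(lambda), converged = converged)
}

#' Principal-curve pseudotime along each lineage
#'
#' For every lineage, a principal curve is fit to the cells of the
#' lineage's clusters: initialized on the piecewise-linear centroid path,
#' then iterated projection of cells onto the curve and local-averaging
#' smoothing of each coordinate over a fixed arc-length window, until the
#' mean projection shift falls below `tol` or `max_iter` is reached (a
#' warning flag records non-convergence). Pseudotime is the arc-length of a
#' cell's projection, anchored at 0 at the curve's root end.
#'
#' @param embedding An `embedding`.
#' @param assignment Tibble `cell_id`, `cluster`.
#' @param lineages Output of [infer_root_and_lineages()], or a list of
#'   cluster paths.
#' @param mst Output of [build_mst()] (for the centroid initialization).
#' @param span Arc-length smoothing window as a fraction of the curve
#'   length. Default 0.5 — window-average principal curves need wide
#'   smoothing windows or they chase noise in high-dimensional clouds.
#' @param n_points Number of curve vertices. Default 50.
#' @param max_iter,tol Iteration controls; `tol` is the mean projection
#'   shift relative to the curve length.
#' @return Object of class `trajectory`: `centroids`, `mst_edges`, `root`,
#'   `lineages`, `pseudotime` (tibble `cell_id`, `cluster`, `lineage`,
#'   `pseudotime`), `curves` (per-lineage polylines), `converged`
#'   (per-lineage flag).
#' @export
fit_pseudotime <- function(embedding, assignment, lineages, mst,
                           span = 0.5, n_points = 50L, max_iter = 30L,
                           tol = 1e-2) {
  if (is.list(lineages) && !is.null(lineages$lineages)) {
    root <- lineages$root
    paths <- lineages$lineages
  } else {
    paths <- lineages
    root <- paths[[1]][1]
  }
  idx <- match(rownames(embedding$coords), assignment$cell_id)
  cl <- assignment$cluster[idx]

  pt <- list()
  curves <- list()
  converged <- logical(length(paths))
  names(converged) <- names(paths)
  for (i in seq_along(paths)) {
    path <- paths[[i]]
    sel <- cl %in% path
    pts <- embedding$coords[sel, , drop = FALSE]
    init <- mst$centroids[path, , drop = FALSE]
    fit <- fit_principal_curve(pts, init, span, n_points, max_iter, tol)
    if (!fit$converged) {
      warn(sprintf("principal curve for lineage '%s' did not converge in %d iterations",
                   names(paths)[i] %||% as.character(i), max_iter))
    }
    converged[i] <- fit$converged
    curves[[i]] <- fit$curve
    pt[[i]] <- tibble(cell_id = rownames(pts), cluster = cl[sel],
                      lineage = names(paths)[i] %||% as.character(i),
                      pseudotime = fit$lambda)
  }
  names(curves) <- names(paths)
  structure(
    list(centroids = mst$centroids, mst_edges = mst$mst_edges, root = root,
         lineages = paths, pseudotime = bind_rows(pt), curves = curves,
         converged = converged),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> root '%s', %d lineage(s):\n", x$root,
              length(x$lineages)))
  for (p in x$lineages) cat("  ", paste(p, collapse = " -> "), "\n")
  invisible(x)
}

#' @rdname fit_pseudotime
#' @param x A `trajectory`.
#' @param ... Unused.
#' @method tidy trajectory
#' @export
tidy.trajectory <- function(x, ...) x$pseudotime

#' @rdname fit_pseudotime
#' @method glance trajectory
#' @export
glance.trajectory <- function(x, ...) {
  tibble(root = x$root, n_lineages = length(x$lineages),
         n_clusters = nrow(x$centroids),
         mst_total_length = sum(x$mst_edges$length),
         all_converged = all(x$converged))
}
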