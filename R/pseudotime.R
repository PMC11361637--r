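#' Trajectory-analysis parameters
#'
#' @param n_hvg Number of highly variable genes feeding the PCA (default
#'   2000, capped at the gene count).
#' @param n_pcs Number of principal components (default 30).
#' @param root_cluster Cluster treated as the trajectory root (default
#'   `"MG"`, the quiescent glial state).
#' @param n_bins Number of equal-width pseudotime bins for condition
#'   comparison (default 50).
#' @param smoothing_span Running-mean span for delta profiles, as a
#'   fraction of `n_bins` (default 0.1).
#' @param n_permutations Label permutations for the per-gene delta test.
#' @param seed Integer seed (permutations and profile clustering).
#'
#' @return A list of class `trajectory_params`.
#' @export
trajectory_params <- function(n_hvg = 2000, n_pcs = 30, root_cluster = "MG",
                              n_bins = 50, smoothing_span = 0.1,
                              n_permutations = 1000, seed = 1L) {
  structure(
    list(
      n_hvg = check_count(n_hvg, "n_hvg", min = 1),
      n_pcs = check_count(n_pcs, "n_pcs", min = 2),
      root_cluster = root_cluster,
      n_bins = check_count(n_bins, "n_bins", min = 1),
      smoothing_span = check_proportion(smoothing_span, "smoothing_span"),
      n_permutations = check_count(n_permutations, "n_permutations"),
      seed = as.integer(seed)
    ),
    class = "trajectory_params"
  )
}

#' Fit a common single-lineage pseudotime over all conditions
#'
#' Cells from every condition are embedded jointly: PCA on the top variable
#' genes, a minimum-spanning-tree path through cluster centroids starting
#' at the root cluster, orthogonal projection of each cell onto the
#' piecewise-linear path, then principal-curve-style refinement (the curve
#' nodes are recomputed as local cell averages along the current ordering
#' and cells re-projected) until assignments move by less than `1e-3` or 50
#' iterations. Pseudotime is min-max rescaled to `[0, 1]` and oriented so
#' the root cluster sits at the origin.
#'
#' Cells are internally sorted by identifier, so the result is invariant to
#' the column order of the input.
#'
#' @param norm_matrix Gene-by-cell matrix from [normalize_log()].
#' @param cluster_labels Per-cell cluster labels (in `norm_matrix` column
#'   order, or named by cell).
#' @param params A [trajectory_params()].
#'
#' @return An object of class `pseudotime_fit`: a list with `cells`
#'   (tibble `cell_id`, `t`, `cluster`), `path` (ordered cluster labels
#'   from the root) and `curve` (node coordinates in PC space).
#' @export
fit_pseudotime <- function(norm_matrix, cluster_labels,
                           params = trajectory_params()) {
  stopifnot(inherits(params, "trajectory_params"))
  if (is.null(names(cluster_labels))) {
    names(cluster_labels) <- colnames(norm_matrix)
  }
  cluster_labels <- as.character(cluster_labels[colnames(norm_matrix)])
  if (!params$root_cluster %in% cluster_labels) {
    abort_bad_arg(sprintf("root cluster '%s' not present", params$root_cluster))
  }

  # canonical cell order => permutation invariance
  ord <- order(colnames(norm_matrix))
  m <- norm_matrix[, ord, drop = FALSE]
  labs <- cluster_labels[ord]

  hvg <- select_hvg(m, min(params$n_hvg, nrow(m)))
  x <- t(m[hvg, , drop = FALSE])
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(params$n_pcs, ncol(pc$x))
  emb <- pc$x[, seq_len(k), drop = FALSE]

  path <- centroid_path(emb, labs, params$root_cluster)
  centroids <- t(vapply(path, function(cl) colMeans(emb[labs == cl, , drop = FALSE]),
                        numeric(ncol(emb))))

  # canonical direction (independent of which terminus is the root)
  canon <- path
  if (canon[1] > canon[length(canon)]) {
    canon <- rev(canon)
    centroids <- centroids[rev(seq_len(nrow(centroids))), , drop = FALSE]
  }

  nodes <- centroids
  t_cur <- project_polyline(emb, nodes)$t
  n_nodes <- max(nrow(nodes), min(50L, max(2L, nrow(emb) %/% 20L)))
  for (iter in seq_len(50)) {
    nodes <- refit_nodes(emb, t_cur, n_nodes)
    proj <- project_polyline(emb, nodes)
    t_new <- proj$t
    if (mean(abs(t_new - t_cur)) < 1e-3) {
      t_cur <- t_new
      break
    }
    t_cur <- t_new
  }

  # Pseudotime is defined only up to a monotone transform; uniformize by
  # rank so downstream equal-width bins are evenly populated, then min-max
  # rescale to [0, 1].
  t01 <- if (length(t_cur) > 1 && diff(range(t_cur)) > 0) {
    (rank(t_cur, ties.method = "average") - 1) / (length(t_cur) - 1)
  } else {
    rep(0, length(t_cur))
  }
  terminus <- if (canon[1] == params$root_cluster) canon[length(canon)] else canon[1]
  if (mean(t01[labs == params$root_cluster]) > mean(t01[labs == terminus])) {
    t01 <- 1 - t01
  }
  path <- if (canon[1] == params$root_cluster) canon else rev(canon)

  cells <- tibble::tibble(cell_id = colnames(m), t = t01, cluster = labs)
  # return in the caller's column order
  cells <- cells[match(colnames(norm_matrix), cells$cell_id), ]
  structure(
    list(cells = cells, path = path, curve = nodes, params = params),
    class = "pseudotime_fit"
  )
}

#' @export
print.pseudotime_fit <- function(x, ...) {
  cat(sprintf("<pseudotime_fit> %d cells; lineage path: %s\n",
              nrow(x$cells), paste(x$path, collapse = " -> ")))
  invisible(x)
}

# MST over cluster centroids; lineage path = path from the root to the
# farthest cluster. Errors if any cluster is stranded off that path.
centroid_path <- function(emb, labs, root) {
  clusters <- sort(unique(labs))
  cent <- t(vapply(clusters, function(cl) colMeans(emb[labs == cl, , drop = FALSE]),
                   numeric(ncol(emb))))
  if (length(clusters) == 1) return(clusters)
  d <- as.matrix(stats::dist(cent))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected", weighted = TRUE)
  mst <- igraph::mst(g)
  dists <- igraph::distances(mst, v = root)
  far <- clusters[which.max(dists[1, ])]
  path_v <- igraph::shortest_paths(mst, from = root, to = far)$vpath[[1]]
  path <- igraph::V(mst)$name[as.integer(path_v)]
  stranded <- setdiff(clusters, path)
  if (length(stranded) > 0) {
    abort_bad_arg(paste0("clusters off the root lineage path: ",
                         paste(stranded, collapse = ", ")))
  }
  path
}

# Orthogonal projection of rows of `x` onto the polyline through `nodes`;
# returns arc-length position rescaled by total length.
project_polyline <- function(x, nodes) {
  n_seg <- nrow(nodes) - 1
  seg_len <- sqrt(rowSums((nodes[-1, , drop = FALSE] -
                             nodes[-nrow(nodes), , drop = FALSE])^2))
  cum_len <- c(0, cumsum(seg_len))
  best_d2 <- rep(Inf, nrow(x))
  best_arc <- rep(0, nrow(x))
  for (s in seq_len(n_seg)) {
    a <- nodes[s, ]
    v <- nodes[s + 1, ] - a
    len2 <- sum(v^2)
    if (len2 == 0) next
    u_raw <- as.vector((sweep(x, 2, a) %*% v) / len2)
    u <- pmin(1, pmax(0, u_raw))
    # cells beyond the curve ends keep their tangential overshoot so they
    # stay ordered instead of collapsing onto the terminal node
    if (s == 1) u <- pmin(u_raw, u)
    if (s == n_seg) u <- pmax(u_raw, u)
    p <- matrix(a, nrow(x), ncol(x), byrow = TRUE) +
      outer(pmin(1, pmax(0, u)), v)
    d2 <- rowSums((x - p)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_arc[upd] <- cum_len[s] + u[upd] * seg_len[s]
  }
  total <- max(cum_len[length(cum_len)], .Machine$double.eps)
  list(t = best_arc / total, d2 = best_d2)
}

# Principal-curve-style node refit: equal-count bins of cells along the
# current ordering, node = bin mean, lightly smoothed along the path.
refit_nodes <- function(x, t_cur, n_nodes) {
  ord <- order(t_cur)
  bin <- ceiling(n_nodes * seq_along(ord) / length(ord))
  nodes <- rowsum(x[ord, , drop = FALSE], bin) / as.vector(table(bin))
  if (nrow(nodes) >= 3) {
    sm <- smoothing_matrix(nrow(nodes), 3)
    nodes <- t(sm) %*% nodes
  }
  nodes
}
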