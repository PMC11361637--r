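#' Binned expression and condition-delta profiles along pseudotime
#'
#' Pseudotime is cut into `n_bins` equal-width bins on `[0, 1]` and the
#' mean normalized expression of each gene is computed per bin and
#' condition (empty bins are filled by linear interpolation from their
#' nearest occupied neighbours). The raw per-bin difference
#' (`condition2 - condition1`) is smoothed by a running mean of width
#' `smoothing_span * n_bins` and scaled per gene by its maximum absolute
#' smoothed difference, so each gene's profile peaks at +1 or -1 (genes
#' with no difference stay at 0). Per-gene significance comes from a
#' permutation test that shuffles condition labels across cells and uses
#' the maximum absolute smoothed difference as the statistic.
#'
#' @param norm_matrix Gene-by-cell matrix from [normalize_log()].
#' @param pt A [fit_pseudotime()] result covering the same cells.
#' @param condition_labels Per-cell condition labels (named by cell, or in
#'   `pt$cells` order).
#' @param params A [trajectory_params()] (`n_bins`, `smoothing_span`,
#'   `n_permutations`, `seed`).
#' @param conditions Length-2 character giving (condition1, condition2);
#'   positive deltas mean higher expression in `condition2`.
#' @param genes Optional subset of genes to profile.
#'
#' @return An object of class `delta_profiles`: list with
#'   * `delta`: gene-by-bin matrix of normalized deltas in `[-1, 1]`;
#'   * `binned`: list of two gene-by-bin matrices of per-condition means;
#'   * `stats`: tibble (`gene`, `norm_factor`, `p`);
#'   * `bin_edges`: the `n_bins + 1` bin boundaries;
#'   * `conditions`: the condition pair.
#' @export
bin_and_delta <- function(norm_matrix, pt, condition_labels,
                          params = trajectory_params(), conditions = NULL,
                          genes = NULL) {
  stopifnot(inherits(pt, "pseudotime_fit"), inherits(params, "trajectory_params"))
  cells <- pt$cells$cell_id
  if (!all(cells %in% colnames(norm_matrix))) {
    abort_bad_arg("`norm_matrix` is missing cells present in the pseudotime fit")
  }
  condition_labels <- align_cell_vector(condition_labels, cells, "condition_labels")
  conditions <- conditions %||% sort(unique(condition_labels))[seq_len(2)]
  if (!all(conditions %in% condition_labels)) {
    abort_bad_arg("both conditions must be present among the cells")
  }
  keep <- condition_labels %in% conditions
  cells <- cells[keep]
  cond <- condition_labels[keep]
  t <- pt$cells$t[keep]
  genes <- genes %||% rownames(norm_matrix)
  m <- norm_matrix[genes, cells, drop = FALSE]

  n_bins <- params$n_bins
  bin <- pmin(n_bins, pmax(1L, findInterval(t, seq(0, 1, length.out = n_bins + 1),
                                            rightmost.closed = TRUE)))
  for (cd in conditions) {
    if (sum(tabulate(bin[cond == cd], n_bins) > 0) < n_bins / 2) {
      abort_bad_arg(sprintf(
        "condition '%s' is absent from more than half the %d bins", cd, n_bins))
    }
  }

  w <- max(1L, round(params$smoothing_span * n_bins))
  sm <- smoothing_matrix(n_bins, w)
  binned <- lapply(conditions, function(cd)
    bin_means(m[, cond == cd, drop = FALSE], bin[cond == cd], n_bins))
  names(binned) <- conditions
  raw <- binned[[2]] - binned[[1]]
  smoothed <- raw %*% sm
  norm_factor <- apply(abs(smoothed), 1, max)
  delta <- smoothed / ifelse(norm_factor == 0, 1, norm_factor)
  colnames(delta) <- paste0("bin", seq_len(n_bins))

  p <- rep(NA_real_, length(genes))
  if (params$n_permutations > 0) {
    set.seed(params$seed)
    obs <- norm_factor
    exceed <- rep(0L, length(genes))
    for (b in seq_len(params$n_permutations)) {
      cond_p <- sample(cond)
      bp <- lapply(conditions, function(cd)
        bin_means(m[, cond_p == cd, drop = FALSE], bin[cond_p == cd], n_bins))
      stat <- apply(abs((bp[[2]] - bp[[1]]) %*% sm), 1, max)
      exceed <- exceed + (stat >= obs)
    }
    p <- (1 + exceed) / (params$n_permutations + 1)
  }

  structure(
    list(
      delta = delta,
      binned = binned,
      stats = tibble::tibble(gene = genes, norm_factor = unname(norm_factor),
                             p = unname(p)),
      bin_edges = seq(0, 1, length.out = n_bins + 1),
      conditions = conditions,
      params = params
    ),
    class = "delta_profiles"
  )
}

# Gene-by-bin means; all-empty bins filled by linear interpolation
# (endpoints carried from the nearest occupied bin).
bin_means <- function(m, bin, n_bins) {
  counts <- tabulate(bin, n_bins)
  sums <- matrix(0, nrow(m), n_bins, dimnames = list(rownames(m), NULL))
  agg <- t(rowsum(t(m), bin))
  sums[, as.integer(colnames(agg))] <- agg
  means <- sweep(sums, 2, pmax(counts, 1), "/")
  means[, counts == 0] <- NA_real_
  interp_na_cols(means)
}

#' @export
print.delta_profiles <- function(x, ...) {
  cat(sprintf("<delta_profiles> %d genes x %d bins; delta = %s - %s\n",
              nrow(x$delta), ncol(x$delta), x$conditions[2], x$conditions[1]))
  invisible(x)
}

#' Cluster per-gene profiles into expression patterns
#'
#' K-means on per-gene z-scored bin profiles (constant profiles are left at
#' zero), with a fixed seed and 10 restarts, keeping the best run. Cluster
#' labels are renumbered by descending size so pattern 1 is always the
#' largest. The default `k = 11` mirrors the number of expression patterns
#' the trajectory DEGs segregate into.
#'
#' @param profiles A `delta_profiles` object or a gene-by-bin matrix.
#' @param k Number of patterns (default 11).
#' @param seed Integer seed.
#'
#' @return A tibble (`gene`, `pattern`).
#' @export
cluster_profiles <- function(profiles, k = 11, seed = 1L) {
  m <- if (inherits(profiles, "delta_profiles")) profiles$delta else profiles
  k <- check_count(k, "k", min = 1)
  if (k > nrow(m)) abort_bad_arg("`k` exceeds the number of genes")
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(s == 0, 1, s)
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = 10, iter.max = 100)
  sizes <- table(km$cluster)
  relabel <- rank(-as.vector(sizes), ties.method = "first")
  tibble::tibble(
    gene = rownames(m),
    pattern = as.integer(relabel[km$cluster])
  )
}
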