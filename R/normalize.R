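#' Library-size log-normalization
#'
#' `value = log1p(scale * count / cell_total)`: counts are scaled to a
#' common library size and log-transformed, the standard shift-log used by
#' single-cell toolkits (default scale 10,000).
#'
#' @param counts Gene-by-cell count matrix (run [qc_filter()] first).
#' @param scale Common library size.
#'
#' @return A dense numeric gene-by-cell matrix.
#' @export
normalize_log <- function(counts, scale = 1e4) {
  check_count_matrix(counts)
  check_positive(scale, "scale")
  totals <- colSums(counts)
  if (any(totals == 0)) {
    abort_bad_arg(paste0("cells with zero total counts: ",
                         paste(colnames(counts)[totals == 0], collapse = ", ")))
  }
  m <- as.matrix(counts)
  log1p(scale * sweep(m, 2, totals, "/"))
}

#' Select highly variable genes
#'
#' Ranks genes by a binned dispersion statistic: the variance of the
#' log-normalized values is z-scored within equal-frequency bins of the
#' gene mean (so highly expressed genes do not dominate), and the top `n`
#' genes are returned. Ties are broken by gene identifier, making the
#' ranking fully deterministic.
#'
#' @param norm_matrix Gene-by-cell matrix from [normalize_log()].
#' @param n Number of genes to return (default 2000).
#' @param n_bins Number of equal-frequency mean bins.
#'
#' @return Character vector of `n` gene identifiers, most variable first.
#' @export
select_hvg <- function(norm_matrix, n = 2000, n_bins = 20) {
  if (n > nrow(norm_matrix)) {
    abort_bad_arg("`n` exceeds the number of genes")
  }
  mu <- rowMeans(norm_matrix)
  v <- apply(norm_matrix, 1, stats::var)
  n_bins <- max(1L, min(n_bins, max(1L, floor(nrow(norm_matrix) / 5))))
  bin <- ceiling(n_bins * rank(mu, ties.method = "first") / length(mu))
  z <- stats::ave(v, bin, FUN = function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  ord <- order(-z, rownames(norm_matrix))
  rownames(norm_matrix)[ord][seq_len(n)]
}
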