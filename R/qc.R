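#' Quality-control parameters
#'
#' Defaults follow the standard larval whole-eye single-cell workflow:
#' cells with fewer than 200 detected genes or fewer than 1000 UMIs are
#' removed, then genes detected in fewer than three surviving cells.
#'
#' @param min_genes_per_cell Minimum detected genes per cell (kept if `>=`).
#' @param min_umis_per_cell Minimum total UMIs per cell (kept if `>=`).
#' @param min_cells_per_gene Minimum cells in which a gene must be detected.
#'
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_genes_per_cell = 200,
                      min_umis_per_cell = 1000,
                      min_cells_per_gene = 3) {
  structure(
    list(
      min_genes_per_cell = check_count(min_genes_per_cell, "min_genes_per_cell"),
      min_umis_per_cell = check_count(min_umis_per_cell, "min_umis_per_cell"),
      min_cells_per_gene = check_count(min_cells_per_gene, "min_cells_per_gene")
    ),
    class = "qc_params"
  )
}

#' Filter a count matrix by per-cell and per-gene detection
#'
#' Two fixed-order passes: first cells failing either per-cell threshold
#' are removed, then genes detected (count > 0) in fewer than
#' `min_cells_per_gene` of the *surviving* cells are removed.
#'
#' @param counts Gene-by-cell integer matrix with identifiers as dimnames.
#' @param params A [qc_params()].
#'
#' @return The filtered matrix. If every cell fails, an empty matrix is
#'   returned with a warning rather than an error.
#' @export
#' @examples
#' m <- matrix(rpois(60, 5), 6, 10,
#'             dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
#' dim(qc_filter(m, qc_params(min_genes_per_cell = 2, min_umis_per_cell = 5,
#'                            min_cells_per_gene = 1)))
qc_filter <- function(counts, params = qc_params()) {
  check_count_matrix(counts)
  stopifnot(inherits(params, "qc_params"))
  if (ncol(counts) == 0 || nrow(counts) == 0) return(counts)
  detected <- colSums(counts > 0)
  totals <- colSums(counts)
  keep_cells <- detected >= params$min_genes_per_cell &
    totals >= params$min_umis_per_cell
  if (!any(keep_cells)) {
    warning("qc_filter removed every cell", call. = FALSE)
    return(counts[, keep_cells, drop = FALSE])
  }
  out <- counts[, keep_cells, drop = FALSE]
  keep_genes <- rowSums(out > 0) >= params$min_cells_per_gene
  out[keep_genes, , drop = FALSE]
}
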