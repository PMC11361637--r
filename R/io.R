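# Readers and writers for the package's plain-text interchange formats.

#' Write a count matrix as MatrixMarket plus gene/cell tables
#'
#' @param counts Gene-by-cell matrix.
#' @param dir Output directory (created if needed); writes `matrix.mtx`,
#'   `genes.tsv`, `cells.tsv`.
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  check_count_matrix(counts)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                          "CsparseMatrix"), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(gene = rownames(counts)),
                   file.path(dir, "genes.tsv"), col_names = FALSE)
  readr::write_tsv(tibble::tibble(cell = colnames(counts)),
                   file.path(dir, "cells.tsv"), col_names = FALSE)
  invisible(dir)
}

#' Read a count matrix written by [write_counts_mtx()]
#'
#' @param dir Directory containing `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return A dense gene-by-cell integer matrix with dimnames.
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"), col_names = "gene",
                           show_col_types = FALSE)$gene
  cells <- readr::read_tsv(file.path(dir, "cells.tsv"), col_names = "cell",
                           show_col_types = FALSE)$cell
  dimnames(m) <- list(genes, cells)
  storage.mode(m) <- "integer"
  m
}

#' Write a synthetic dataset (counts, truth tables, planted network)
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  write_counts_mtx(ds$counts, dir)
  readr::write_tsv(ds$cells, file.path(dir, "cell_truth.tsv"))
  readr::write_tsv(tibble::as_tibble(ds$network), file.path(dir, "planted_network.tsv"))
  invisible(dir)
}

#' Read a plate-reader well table
#'
#' Expects the exact columns `well`, `gene`, `arm`, `genotype`,
#' `fluorescence`, `plate`.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) abort_bad_arg(sprintf("plate file not found: %s", path))
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("well", "gene", "arm", "genotype", "fluorescence", "plate")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort_bad_arg(paste0("plate file missing columns: ",
                         paste(miss, collapse = ", ")))
  }
  if (any(x$fluorescence < 0)) abort_bad_arg("negative fluorescence values")
  x
}

#' Write / read marker sets as a two-column TSV
#'
#' @param markers A [marker_sets()] object.
#' @param path TSV path (`cell_type`, `gene`).
#' @return `path`, invisibly.
#' @export
write_marker_sets <- function(markers, path) {
  stopifnot(inherits(markers, "marker_sets"))
  tab <- tibble::tibble(
    cell_type = rep(names(markers), lengths(markers)),
    gene = unlist(markers, use.names = FALSE)
  )
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_marker_sets
#' @param universe Gene universe for the sets read back.
#' @export
read_marker_sets <- function(path, universe) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  marker_sets(tab, universe)
}

#' Write a configuration object as YAML
#'
#' Serialises any of the package's configuration objects ([sim_config()],
#' [plate_sim_config()], [qc_params()], [trajectory_params()],
#' [grn_params()], [screen_params()]) as a key-value YAML file, seed
#' included, so a run can be archived and reproduced.
#'
#' @param config A configuration object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
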