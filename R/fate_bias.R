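#' Cell-type marker sets with a gene universe
#'
#' @param sets Named list mapping cell-type label to a character vector of
#'   marker genes, or a two-column data frame (`cell_type`, `gene`).
#' @param universe Character vector of all genes under consideration
#'   (typically every gene surviving QC); must contain every marker.
#'
#' @return A named list of class `marker_sets` with a `universe` attribute.
#' @export
marker_sets <- function(sets, universe) {
  if (is.data.frame(sets)) {
    sets <- split(sets$gene, sets$cell_type)
  }
  if (length(sets) == 0 || any(lengths(sets) == 0)) {
    abort_bad_arg("marker sets must be non-empty")
  }
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort_bad_arg("empty marker universe")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  stray <- setdiff(unlist(sets), universe)
  if (length(stray) > 0) {
    abort_bad_arg(paste0("markers outside the universe: ",
                         paste(utils::head(stray, 5), collapse = ", ")))
  }
  structure(sets, universe = universe, class = "marker_sets")
}

#' Derive cell-type marker sets from expression data
#'
#' Convenience wrapper: runs [rank_sum_markers()] with the cell-type marker
#' preset over the state labels and keeps, per cell type, the significant
#' genes with positive fold change.
#'
#' @param norm_matrix Gene-by-cell matrix from [normalize_log()].
#' @param state_labels Per-cell cell-type labels.
#' @param params A [deg_params()] (default: the cell-type marker preset).
#'
#' @return A [marker_sets()] object (universe = all genes in the matrix).
#' @export
derive_marker_sets <- function(norm_matrix, state_labels,
                               params = deg_params("celltype_markers")) {
  tab <- rank_sum_markers(norm_matrix, state_labels, params)
  up <- tab[tab$significant & tab$log2fc > 0, ]
  sets <- split(up$gene, up$group)
  sets <- sets[lengths(sets) > 0]
  marker_sets(sets, rownames(norm_matrix))
}

#' Tally lineage-associated expression changes
#'
#' Counts, for each cell type, how many significant DEGs fall in its marker
#' set, split by direction: `n_up` (log2fc > 0, i.e. higher in the second
#' condition) and `n_down`. A gene belonging to several marker sets counts
#' in each.
#'
#' @param deg_table A [rank_sum_markers()] table with signed `log2fc` and a
#'   `significant` flag.
#' @param markers A [marker_sets()] object.
#'
#' @return A tibble (`cell_type`, `n_up`, `n_down`).
#' @export
#' @examples
#' degs <- tibble::tibble(gene = c("a", "b", "c"), group = "progenitor",
#'                        log2fc = c(1, 2, -1), pct_in = 1, pct_out = 1,
#'                        p = 0.001, p_adj = 0.001, significant = TRUE)
#' ms <- marker_sets(list(RGC = c("a", "b"), rod = "c"),
#'                   universe = c("a", "b", "c", "d"))
#' lineage_bias_tally(degs, ms)
lineage_bias_tally <- function(deg_table, markers) {
  stopifnot(inherits(markers, "marker_sets"))
  sig <- deg_table[deg_table$significant, , drop = FALSE]
  purrr::map_dfr(names(markers), function(ct) {
    hit <- sig$gene %in% markers[[ct]]
    tibble::tibble(
      cell_type = ct,
      n_up = sum(hit & sig$log2fc > 0),
      n_down = sum(hit & sig$log2fc < 0)
    )
  })
}

#' Hypergeometric cell-type specificity score per TF
#'
#' For each TF and cell type, tests whether the TF's target set is enriched
#' in the cell type's marker set: with universe size `N`, `K` markers, `n`
#' targets and overlap `k`, the score is the upper-tail hypergeometric
#' probability `P(X >= k)` (the enrichment tail; the convention is recorded
#' in the result's metadata). No multiplicity adjustment is applied by
#' default; `adjust = "BH"` adds a `p_adj` column over all (tf, cell type)
#' pairs.
#'
#' Targets outside the marker universe are dropped (a message reports how
#' many); a TF left with zero targets is emitted with `p = 1` and flagged.
#'
#' @param edges A `signed_edges` tibble (or any tibble with `tf`, `target`).
#' @param markers A [marker_sets()] object; its universe is the population.
#' @param adjust `"none"` (default) or `"BH"`.
#'
#' @return A tibble of class `tf_specificity` (`tf`, `cell_type`,
#'   `n_targets`, `n_markers`, `overlap`, `universe_size`, `p`, `flagged`).
#' @export
#' @examples
#' ms <- marker_sets(list(RGC = c("g1", "g2", "g3", "g4")),
#'                   universe = sprintf("g%d", 1:10))
#' ed <- tibble::tibble(tf = "tfA", target = c("g1", "g2", "g3"))
#' tf_specificity(ed, ms)$p # 1/30
tf_specificity <- function(edges, markers, adjust = c("none", "BH")) {
  stopifnot(inherits(markers, "marker_sets"))
  adjust <- match.arg(adjust)
  universe <- attr(markers, "universe")
  n_univ <- length(universe)
  targets_by_tf <- lapply(split(edges$target, edges$tf), unique)
  dropped <- sum(vapply(targets_by_tf, function(s) sum(!s %in% universe),
                        integer(1)))
  if (dropped > 0) {
    message(sprintf("tf_specificity: dropped %d target(s) outside the universe",
                    dropped))
    targets_by_tf <- lapply(targets_by_tf, function(s) intersect(s, universe))
  }
  out <- purrr::map_dfr(names(targets_by_tf), function(tf) {
    tg <- targets_by_tf[[tf]]
    purrr::map_dfr(names(markers), function(ct) {
      mk <- markers[[ct]]
      k <- length(intersect(tg, mk))
      tibble::tibble(
        tf = tf, cell_type = ct,
        n_targets = length(tg), n_markers = length(mk),
        overlap = k, universe_size = n_univ,
        p = if (length(tg) == 0) 1 else
          stats::phyper(k - 1, length(mk), n_univ - length(mk), length(tg),
                        lower.tail = FALSE),
        flagged = length(tg) == 0
      )
    })
  })
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, "BH")
  structure(out, tail = "upper (P(X >= k), enrichment)",
            class = c("tf_specificity", class(tibble::tibble())))
}
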