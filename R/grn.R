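#' Gene-regulatory-network inference parameters
#'
#' @param n_trees Trees per target-gene regression forest.
#' @param min_node_size Minimum leaf size of the regression trees.
#' @param mtry Candidate features per split: `"sqrt"` (square root of the
#'   TF count), `"all"`, or a fixed integer.
#' @param importance_quantile Pooled importance quantile below which
#'   TF-target pairs are discarded (default 0.95).
#' @param cor_threshold Pearson-correlation magnitude a pair must strictly
#'   exceed to be kept and signed (default 0.03).
#' @param expression_cluster Cluster in which a TF must be expressed to
#'   keep its edges (default `"progenitor"`, the RPC compartment).
#' @param min_expr_fraction Detection fraction defining "expressed"
#'   (default 0.05, reusing the marker tests' min.pct convention).
#' @param quantile_scope `"pooled"` (one quantile over all pairs, default)
#'   or `"per_target"`.
#' @param seed Integer seed for the forests.
#'
#' @return A list of class `grn_params`.
#' @export
grn_params <- function(n_trees = 100, min_node_size = 5, mtry = "sqrt",
                       importance_quantile = 0.95, cor_threshold = 0.03,
                       expression_cluster = "progenitor",
                       min_expr_fraction = 0.05,
                       quantile_scope = c("pooled", "per_target"),
                       seed = 1L) {
  check_proportion(importance_quantile, "importance_quantile", closed = FALSE)
  check_positive(cor_threshold, "cor_threshold")
  check_proportion(min_expr_fraction, "min_expr_fraction")
  structure(
    list(n_trees = check_count(n_trees, "n_trees", min = 1),
         min_node_size = check_count(min_node_size, "min_node_size", min = 1),
         mtry = mtry,
         importance_quantile = importance_quantile,
         cor_threshold = cor_threshold,
         expression_cluster = expression_cluster,
         min_expr_fraction = min_expr_fraction,
         quantile_scope = match.arg(quantile_scope),
         seed = as.integer(seed)),
    class = "grn_params"
  )
}

#' TF-to-target importance scores from random-forest regression
#'
#' For every gene in turn (TFs included, predicted from the other TFs), a
#' random-forest regression of the target's expression on all TF
#' expressions is fitted and each TF's importance is its total impurity
#' (variance) reduction. Importances are normalized per target to sum to 1.
#' This is the GENIE3/GRNBoost2 family of tree-ensemble importance scoring;
#' the ensemble here is a random forest with `sqrt(n_tfs)` candidate
#' features per split, recorded in the result's metadata.
#'
#' @param expr_matrix Gene-by-cell expression matrix (log-normalized).
#' @param tf_list Character vector of TF gene identifiers (rows of
#'   `expr_matrix`).
#' @param params A [grn_params()].
#' @param targets Optional subset of target genes (default: all genes).
#'
#' @return A tibble of class `importance_matrix` (`tf`, `target`,
#'   `importance`) with attributes `tf_list`, `targets` and `method`.
#' @export
infer_importance <- function(expr_matrix, tf_list, params = grn_params(),
                             targets = NULL) {
  stopifnot(inherits(params, "grn_params"))
  if (length(tf_list) == 0) abort_bad_arg("`tf_list` is empty")
  missing_tf <- setdiff(tf_list, rownames(expr_matrix))
  if (length(missing_tf) > 0) {
    abort_bad_arg(paste0("TFs absent from the matrix: ",
                         paste(missing_tf, collapse = ", ")))
  }
  if (ncol(expr_matrix) < 20) abort_bad_arg("need at least 20 cells")
  targets <- targets %||% rownames(expr_matrix)
  tf_expr <- t(expr_matrix[tf_list, , drop = FALSE])

  res <- purrr::map_dfr(targets, function(tg) {
    preds <- setdiff(tf_list, tg)
    if (length(preds) == 0) return(NULL)
    mtry <- switch(as.character(params$mtry),
                   sqrt = max(1L, floor(sqrt(length(preds)))),
                   all = length(preds),
                   min(length(preds), as.integer(params$mtry)))
    x <- tf_expr[, preds, drop = FALSE]
    y <- expr_matrix[tg, ]
    fit <- ranger::ranger(
      x = x, y = y, num.trees = params$n_trees, mtry = mtry,
      min.node.size = params$min_node_size, importance = "impurity",
      num.threads = 1, seed = params$seed,
      respect.unordered.factors = FALSE, verbose = FALSE
    )
    imp <- pmax(fit$variable.importance, 0)
    tot <- sum(imp)
    imp <- if (tot > 0) imp / tot else rep(1 / length(imp), length(imp))
    tibble::tibble(tf = preds, target = tg, importance = unname(imp))
  })
  structure(res,
            tf_list = tf_list, targets = targets,
            method = sprintf("random-forest impurity importance (%d trees, mtry=%s)",
                             params$n_trees, as.character(params$mtry)),
            class = c("importance_matrix", class(tibble::tibble())))
}

#' Keep TF-target pairs at or above an importance quantile
#'
#' The quantile is computed over all (tf, target) importance values pooled
#' (linear interpolation between order statistics, the default quantile
#' convention); pairs with importance greater than or equal to the quantile
#' are retained. With 100 distinct pooled scores and `q = 0.95`, exactly
#' the top 5 survive. A `"per_target"` scope computes the quantile within
#' each target's importances instead.
#'
#' @param imp An [infer_importance()] result (or any tibble with `tf`,
#'   `target`, `importance`).
#' @param q Quantile in (0, 1), default 0.95.
#' @param scope `"pooled"` or `"per_target"`.
#'
#' @return The retained rows, as a tibble.
#' @export
filter_importance_quantile <- function(imp, q = 0.95,
                                       scope = c("pooled", "per_target")) {
  scope <- match.arg(scope)
  check_proportion(q, "q", closed = FALSE)
  if (nrow(imp) == 0) abort_bad_arg("empty importance table")
  out <- if (scope == "pooled") {
    thr <- stats::quantile(imp$importance, q, type = 7, names = FALSE)
    imp[imp$importance >= thr, , drop = FALSE]
  } else {
    dplyr::filter(
      dplyr::group_by(imp, .data$target),
      .data$importance >= stats::quantile(.data$importance, q, type = 7)
    ) |> dplyr::ungroup()
  }
  tibble::as_tibble(out)
}

# Sign decision for one correlation value under the strict +-threshold rule.
classify_sign <- function(cor, threshold = 0.03) {
  dplyr::case_when(
    is.na(cor) ~ "discarded",
    cor > threshold ~ "positive",
    cor < -threshold ~ "negative",
    .default = "discarded"
  )
}

#' Annotate edges with Pearson correlation and regulation sign
#'
#' Pearson correlation of TF and target expression across all supplied
#' cells. A pair is `positive` if its correlation strictly exceeds
#' `cor_threshold`, `negative` if strictly below `-cor_threshold`; all
#' other pairs (including undefined correlations from zero-variance genes)
#' are discarded, with the number removed recorded in the `n_discarded`
#' attribute.
#'
#' @param edges Tibble with `tf` and `target` columns (e.g. from
#'   [filter_importance_quantile()]).
#' @param expr_matrix Gene-by-cell expression matrix containing all edge genes.
#' @param cor_threshold Strict threshold (default 0.03).
#'
#' @return A tibble of class `signed_edges` (`tf`, `target`, `importance`
#'   if present, `cor`, `sign`).
#' @export
annotate_edge_sign <- function(edges, expr_matrix, cor_threshold = 0.03) {
  check_positive(cor_threshold, "cor_threshold")
  genes <- unique(c(edges$tf, edges$target))
  missing <- setdiff(genes, rownames(expr_matrix))
  if (length(missing) > 0) {
    abort_bad_arg(paste0("edge genes absent from the matrix: ",
                         paste(missing, collapse = ", ")))
  }
  x <- expr_matrix[genes, , drop = FALSE]
  ctr <- x - rowMeans(x)
  ss <- sqrt(rowSums(ctr^2))
  std <- ctr / ifelse(ss == 0, 1, ss)
  cors <- rowSums(std[edges$tf, , drop = FALSE] * std[edges$target, , drop = FALSE])
  cors[ss[edges$tf] == 0 | ss[edges$target] == 0] <- NA_real_
  sign <- classify_sign(cors, cor_threshold)
  out <- edges
  out$cor <- cors
  out$sign <- sign
  kept <- out[out$sign != "discarded", , drop = FALSE]
  n_disc <- nrow(out) - nrow(kept)
  if (n_disc > 0) {
    message(sprintf("annotate_edge_sign: discarded %d/%d pairs with |cor| <= %g or undefined",
                    n_disc, nrow(out), cor_threshold))
  }
  structure(tibble::as_tibble(kept), n_discarded = n_disc,
            cor_threshold = cor_threshold,
            class = c("signed_edges", class(tibble::tibble())))
}

#' Remove edges of TFs not expressed in a reference cluster
#'
#' A TF counts as expressed if it is detected (raw count > 0) in at least
#' `min_expr_fraction` of the cells of `expression_cluster` (by default the
#' progenitor / RPC compartment); all edges of non-expressed TFs are
#' removed.
#'
#' @param edges A `signed_edges` tibble (or any tibble with a `tf` column).
#' @param counts Gene-by-cell raw count matrix.
#' @param cluster_labels Per-cell cluster labels (named by cell or in
#'   column order of `counts`).
#' @param params A [grn_params()] (`expression_cluster`,
#'   `min_expr_fraction`).
#'
#' @return The retained edges, with attribute `removed_tfs`.
#' @export
filter_tf_expressed <- function(edges, counts, cluster_labels,
                                params = grn_params()) {
  stopifnot(inherits(params, "grn_params"))
  cluster_labels <- align_cell_vector(cluster_labels, colnames(counts),
                                      "cluster_labels")
  cl <- params$expression_cluster
  if (!cl %in% cluster_labels) {
    abort_bad_arg(sprintf("expression cluster '%s' not present", cl))
  }
  cells <- cluster_labels == cl
  tfs <- unique(edges$tf)
  frac <- rowMeans(counts[tfs, cells, drop = FALSE] > 0)
  expressed <- names(frac)[frac >= params$min_expr_fraction]
  removed <- setdiff(tfs, expressed)
  out <- edges[edges$tf %in% expressed, , drop = FALSE]
  if (length(removed) > 0) {
    message(sprintf("filter_tf_expressed: removed %d TF(s) not expressed in '%s'",
                    length(removed), cl))
  }
  attr(out, "removed_tfs") <- removed
  out
}

#' One-call GRN construction
#'
#' Runs the full network-construction chain: importance inference,
#' pooled-quantile filtering, correlation-sign annotation and the
#' TF-expression filter, returning the signed edge list plus a stage log of
#' edge counts.
#'
#' @inheritParams infer_importance
#' @param counts Raw counts for the expression filter.
#' @param cluster_labels Per-cell cluster labels for the expression filter.
#'
#' @return A `signed_edges` tibble with attribute `stage_log` (named edge
#'   counts after each stage).
#' @export
build_grn <- function(expr_matrix, tf_list, counts, cluster_labels,
                      params = grn_params()) {
  imp <- infer_importance(expr_matrix, tf_list, params)
  kept <- filter_importance_quantile(imp, params$importance_quantile,
                                     params$quantile_scope)
  signed <- annotate_edge_sign(kept, expr_matrix, params$cor_threshold)
  final <- filter_tf_expressed(signed, counts, cluster_labels, params)
  attr(final, "stage_log") <- c(
    importance_pairs = nrow(imp), after_quantile = nrow(kept),
    after_sign = nrow(signed), after_expression_filter = nrow(final)
  )
  final
}
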