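#' Differential-expression / marker test parameters
#'
#' Three presets mirror the thresholds used at different stages of the
#' analysis this package supports:
#' * `"condition"` -- condition DEGs within a cluster: `logfc_threshold
#'   = 0.2`, `min_pct = 0.05`, raw `p < 0.05` (no adjustment);
#' * `"celltype_markers"` -- cell-type marker genes: `logfc_threshold =
#'   0.5`, `min_pct = 0.05`, BH-adjusted `p < 0.05`;
#' * `"timepoint"` -- timepoint DEGs: `logfc_threshold = 0.25` (fold change
#'   1.18), `min_pct = 0.05`, BH-adjusted `p < 0.05`.
#'
#' @param preset One of `"condition"`, `"celltype_markers"`, `"timepoint"`,
#'   or `"custom"` (use the explicit arguments).
#' @param logfc_threshold Minimum `|log2 fold change|` for a gene to be
#'   tested (inclusive).
#' @param min_pct Minimum detection fraction in at least one of the two
#'   groups (inclusive).
#' @param alpha Significance level applied to `p` (or `p_adj` under BH).
#' @param adjust `"none"` or `"BH"`.
#' @param pseudocount Added to group means before the fold-change ratio.
#'
#' @return A list of class `deg_params`.
#' @export
deg_params <- function(preset = c("custom", "condition", "celltype_markers",
                                  "timepoint"),
                       logfc_threshold = 0.2, min_pct = 0.05, alpha = 0.05,
                       adjust = c("none", "BH"), pseudocount = 1) {
  preset <- match.arg(preset)
  adjust <- match.arg(adjust)
  if (preset == "condition") {
    logfc_threshold <- 0.2; min_pct <- 0.05; alpha <- 0.05; adjust <- "none"
  } else if (preset == "celltype_markers") {
    logfc_threshold <- 0.5; min_pct <- 0.05; alpha <- 0.05; adjust <- "BH"
  } else if (preset == "timepoint") {
    logfc_threshold <- 0.25; min_pct <- 0.05; alpha <- 0.05; adjust <- "BH"
  }
  check_proportion(min_pct, "min_pct")
  check_proportion(alpha, "alpha", closed = FALSE)
  check_positive(pseudocount, "pseudocount")
  structure(
    list(logfc_threshold = logfc_threshold, min_pct = min_pct, alpha = alpha,
         adjust = adjust, pseudocount = pseudocount),
    class = "deg_params"
  )
}

#' Wilcoxon rank-sum marker / DEG table
#'
#' For each gene and each focal group (versus the pooled rest, or versus a
#' named reference group) computes the log2 fold change of pseudocounted
#' group means of `expm1(normalized value)`, the detection fractions in and
#' out of the group, and a two-sided Wilcoxon rank-sum p-value. Genes are
#' pre-filtered (`|log2fc| >= logfc_threshold` and `max(pct_in, pct_out) >=
#' min_pct`) before testing; BH adjustment is applied over the tested genes
#' when requested. Rows failing the alpha criterion are flagged via the
#' `significant` column, not dropped.
#'
#' For total group sizes above 25 the p-value uses the normal approximation
#' with tie correction and continuity correction; below that an exact
#' tie-aware distribution is computed by dynamic programming (equivalent to
#' enumerating all group assignments).
#'
#' @param norm_matrix Gene-by-cell matrix from [normalize_log()].
#' @param group_labels Per-cell group labels (length `ncol(norm_matrix)`).
#' @param params A [deg_params()].
#' @param groups Focal groups to test (default: all).
#' @param reference Optional reference group; default is "all other cells".
#'
#' @return A tibble (`gene`, `group`, `log2fc`, `pct_in`, `pct_out`, `p`,
#'   `p_adj`, `significant`), one row per tested gene and focal group.
#' @export
rank_sum_markers <- function(norm_matrix, group_labels, params = deg_params(),
                             groups = NULL, reference = NULL) {
  stopifnot(inherits(params, "deg_params"))
  if (length(group_labels) != ncol(norm_matrix)) {
    abort_bad_arg("`group_labels` must match the number of cells")
  }
  group_labels <- as.character(group_labels)
  tab <- table(group_labels)
  if (length(tab) < 2) abort_bad_arg("need at least two groups")
  if (any(tab < 2)) {
    abort_bad_arg(paste0("groups with fewer than 2 cells: ",
                         paste(names(tab)[tab < 2], collapse = ", ")))
  }
  if (!is.null(reference) && !reference %in% names(tab)) {
    abort_bad_arg(sprintf("reference group '%s' not present", reference))
  }
  groups <- groups %||% setdiff(names(tab), reference)
  res <- purrr::map_dfr(groups, function(g) {
    in_idx <- group_labels == g
    out_idx <- if (is.null(reference)) !in_idx else group_labels == reference
    marker_one_group(norm_matrix, in_idx, out_idx, g, params)
  })
  res
}

marker_one_group <- function(norm_matrix, in_idx, out_idx, group, params) {
  x_in <- norm_matrix[, in_idx, drop = FALSE]
  x_out <- norm_matrix[, out_idx, drop = FALSE]
  pc <- params$pseudocount
  mean_in <- rowMeans(expm1(x_in))
  mean_out <- rowMeans(expm1(x_out))
  log2fc <- log2((mean_in + pc) / (mean_out + pc))
  pct_in <- rowMeans(x_in > 0)
  pct_out <- rowMeans(x_out > 0)
  test <- abs(log2fc) >= params$logfc_threshold &
    pmax(pct_in, pct_out) >= params$min_pct
  genes <- rownames(norm_matrix)[test]
  p <- vapply(which(test), function(i) {
    rank_sum_p(x_in[i, ], x_out[i, ])
  }, numeric(1))
  p_adj <- if (params$adjust == "BH") stats::p.adjust(p, "BH") else p
  crit <- if (params$adjust == "BH") p_adj else p
  tibble::tibble(
    gene = genes, group = group,
    log2fc = log2fc[test], pct_in = pct_in[test], pct_out = pct_out[test],
    p = p, p_adj = p_adj, significant = crit < params$alpha
  )
}

# Two-sided Wilcoxon rank-sum p-value. Exact tie-aware DP for small total
# n, normal approximation with tie and continuity correction otherwise.
rank_sum_p <- function(x, y, exact_max_n = 25) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (n <= exact_max_n) {
    return(rank_sum_exact_p(r, n1, w))
  }
  ties <- table(r)
  mu <- n1 * (n2 + n1 + 1) / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- w - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
  min(1, 2 * stats::pnorm(-abs(z)))
}

# Exact distribution of the rank-sum statistic over all C(n, n1) group
# assignments, ties included, via a subset-sum dynamic program on doubled
# midranks. Returns 2 * min(P(W <= w), P(W >= w)) capped at 1.
rank_sum_exact_p <- function(ranks, n1, w) {
  r2 <- as.integer(round(2 * ranks))
  max_s <- sum(r2)
  # dp[k + 1, s + 1] = number of size-k subsets with doubled rank-sum s
  dp <- matrix(0, nrow = n1 + 1, ncol = max_s + 1)
  dp[1, 1] <- 1
  for (v in r2) {
    for (k in seq(n1, 1, by = -1)) {
      shifted <- c(rep(0, v), dp[k, seq_len(max_s + 1 - v)])
      dp[k + 1, ] <- dp[k + 1, ] + shifted
    }
  }
  counts <- dp[n1 + 1, ]
  sums <- (seq_along(counts) - 1) / 2
  totaln <- sum(counts)
  p_le <- sum(counts[sums <= w + 1e-9]) / totaln
  p_ge <- sum(counts[sums >= w - 1e-9]) / totaln
  min(1, 2 * min(p_le, p_ge))
}
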