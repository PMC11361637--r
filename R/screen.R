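#' Crispant screen analysis parameters
#'
#' @param significance_fdr Adjusted-p cutoff for a significant hit
#'   (default 0.01).
#' @param trending_upper Upper adjusted-p bound of the "trending" class
#'   (default 0.10); hits with `significance_fdr < p_adj <= trending_upper`
#'   are trending.
#' @param design_alpha Two-sided alpha of the sample-size design.
#' @param design_power Target power of the design.
#' @param design_effect_fraction Designed detectable fractional change of
#'   mean relative fluorescence (default 0.30).
#' @param min_n Minimum wells required in the wild-type reference group.
#'
#' @return A list of class `screen_params`.
#' @export
screen_params <- function(significance_fdr = 0.01, trending_upper = 0.10,
                          design_alpha = 0.05, design_power = 0.80,
                          design_effect_fraction = 0.30, min_n = 8) {
  check_proportion(significance_fdr, "significance_fdr", closed = FALSE)
  check_proportion(trending_upper, "trending_upper", closed = FALSE)
  if (significance_fdr >= trending_upper) {
    abort_bad_arg("`significance_fdr` must be below `trending_upper`")
  }
  check_proportion(design_alpha, "design_alpha", closed = FALSE)
  check_proportion(design_power, "design_power", closed = FALSE)
  structure(
    list(significance_fdr = significance_fdr, trending_upper = trending_upper,
         design_alpha = design_alpha, design_power = design_power,
         design_effect_fraction = design_effect_fraction,
         min_n = check_count(min_n, "min_n", min = 2)),
    class = "screen_params"
  )
}

#' Normalize well fluorescence to the unablated wild-type controls
#'
#' Within each plate, every well's fluorescence is divided by the mean of
#' that plate's unablated wild-type control wells, giving "relative YFP":
#' the fraction of the unablated signal. Normalization is scale-invariant
#' within a plate.
#'
#' @param data Well table with columns `well`, `gene`, `arm`
#'   (`"unablated_control"`/`"ablated"`), `genotype`, `fluorescence`,
#'   `plate`.
#'
#' @return `data` with a `relative_yfp` column.
#' @export
normalize_relative_yfp <- function(data) {
  need <- c("well", "gene", "arm", "genotype", "fluorescence", "plate")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort_bad_arg(paste0("missing columns: ", paste(miss, collapse = ", ")))
  }
  refs <- dplyr::summarise(
    dplyr::group_by(data, .data$plate),
    n_ctrl = sum(.data$arm == "unablated_control" & .data$genotype == "wildtype"),
    ref = mean(.data$fluorescence[.data$arm == "unablated_control" &
                                    .data$genotype == "wildtype"]),
    .groups = "drop"
  )
  if (any(refs$n_ctrl < 2)) {
    abort_bad_arg(paste0("plates with fewer than 2 unablated wild-type control wells: ",
                         paste(refs$plate[refs$n_ctrl < 2], collapse = ", ")))
  }
  if (any(!is.finite(refs$ref) | refs$ref <= 0)) {
    abort_bad_arg("non-positive control mean in at least one plate")
  }
  out <- dplyr::left_join(data, refs[, c("plate", "ref")], by = "plate")
  out$relative_yfp <- out$fluorescence / out$ref
  out$ref <- NULL
  tibble::as_tibble(out)
}

#' Minimum per-group sample size for a two-sample comparison
#'
#' Normal-approximation formula for a two-sided, equal-variance two-sample
#' design: `n = ceiling(2 * (z_{1-alpha/2} + z_{power})^2 / d^2)`, floored
#' at 2 per group. At `alpha = 0.05`, `power = 0.80` this gives `n = 16`
#' for `d = 1` and `n = 8` for `d = 1.41`.
#'
#' @param alpha Two-sided type-I error rate.
#' @param power Target power.
#' @param d Standardized effect size (mean difference / SD), `> 0`.
#' @param exact If `TRUE`, additionally refines the answer by the exact
#'   noncentral-t power of the pooled t-test (smallest `n` reaching the
#'   target power).
#'
#' @return Integer per-group sample size.
#' @export
#' @examples
#' min_sample_size(0.05, 0.80, 1.0)  # 16
#' min_sample_size(0.05, 0.80, 1.41) # 8
min_sample_size <- function(alpha = 0.05, power = 0.80, d, exact = FALSE) {
  check_proportion(alpha, "alpha", closed = FALSE)
  check_proportion(power, "power", closed = FALSE)
  if (!(is.numeric(d) && length(d) == 1 && d > 0)) {
    abort_bad_arg("`d` must be a positive standardized effect size")
  }
  n <- ceiling(2 * (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 / d^2)
  n <- max(2L, as.integer(n))
  if (exact) {
    while (t_test_power(n, d, alpha) < power) n <- n + 1L
    while (n > 2L && t_test_power(n - 1L, d, alpha) >= power) n <- n - 1L
  }
  n
}

# Exact power of the two-sided pooled t-test at n per group.
t_test_power <- function(n, d, alpha) {
  df <- 2 * n - 2
  crit <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n / 2)
  1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
}

#' Two-stage linear step-up FDR-adjusted p-values
#'
#' The Benjamini-Krieger-Yekutieli (2006) two-stage sharpened procedure:
#' stage 1 runs Benjamini-Hochberg at `q' = q / (1 + q)` and estimates the
#' number of true nulls as `m0 = m - r1` from its rejection count `r1`;
#' stage 2 re-runs Benjamini-Hochberg at `q' * m / m0`. The procedure
#' returns decisions, not adjusted p-values, so the adjusted p reported
#' here is the smallest `q` on a grid of resolution `grid_res` at which the
#' hypothesis is rejected (the rejection threshold is monotone in `q`, so
#' classifying by `p_adj <= q` reproduces the procedure's decisions at any
#' grid level `q`).
#'
#' @param p Vector of raw p-values.
#' @param grid_res Resolution of the `q` grid (default `1e-4`).
#'
#' @return Adjusted p-values in `[grid_res, 1]` (1 when never rejected).
#' @export
p_adjust_bky <- function(p, grid_res = 1e-4) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  if (any(!is.finite(p) | p < 0 | p > 1)) abort_bad_arg("p-values must be in [0, 1]")
  bh <- stats::p.adjust(p, "BH")
  qs <- seq(grid_res, 1, by = grid_res)
  qprime <- qs / (1 + qs)
  # r1(q): BH rejections at level q' == #{bh <= q'}
  bh_sorted <- sort(bh)
  r1 <- findInterval(qprime, bh_sorted)
  m0 <- m - r1
  thr <- ifelse(m0 == 0, Inf, qprime * m / pmax(m0, 1))
  # thr is strictly increasing in q; adjusted p = first grid q with thr >= bh
  idx <- findInterval(bh, thr)                 # last index with thr < bh (or == bh)
  exact <- idx >= 1 & idx <= length(thr) & thr[pmax(idx, 1)] >= bh
  first <- ifelse(exact, idx, idx + 1L)
  ifelse(first > length(qs), 1, qs[pmin(first, length(qs))])
}

# Decision form of the two-stage procedure at a fixed level q.
bky_reject <- function(p, q) {
  m <- length(p)
  qprime <- q / (1 + q)
  bh <- stats::p.adjust(p, "BH")
  r1 <- sum(bh <= qprime)
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  m0 <- m - r1
  bh <= qprime * m / m0
}

#' Per-gene screen test with two-stage FDR adjustment
#'
#' Each crispant gene's ablated wells are compared with the wild-type
#' ablated reference wells by a two-group one-way ANOVA F-test (computed as
#' the equivalent two-sided pooled t-test). The family of per-gene p-values
#' is then adjusted by [p_adjust_bky()] and hits are classified by
#' [classify_hits()]. Wells with zero within-group variance take an
#' exact-difference fast path with `p` 0 or 1.
#'
#' @param data Normalized well table from [normalize_relative_yfp()]
#'   (columns `gene`, `arm`, `genotype`, `relative_yfp`).
#' @param params A [screen_params()].
#'
#' @return A tibble of class `screen_result` (`gene`, `n_wells`,
#'   `relative_yfp`, `direction`, `p`, `p_adj`, `class`) with attributes
#'   `m`, `m0_estimate`, `reference_mean` and `reference_n`.
#' @export
screen_test <- function(data, params = screen_params()) {
  stopifnot(inherits(params, "screen_params"))
  if (!"relative_yfp" %in% names(data)) {
    abort_bad_arg("run normalize_relative_yfp() first (no `relative_yfp` column)")
  }
  abl <- data[data$arm == "ablated", , drop = FALSE]
  ref <- abl$relative_yfp[abl$genotype == "wildtype"]
  if (length(ref) < params$min_n) {
    abort_bad_arg(sprintf("wild-type ablated reference has %d wells; need >= %d",
                          length(ref), params$min_n))
  }
  crisp <- abl[abl$genotype == "crispant", , drop = FALSE]
  genes <- unique(crisp$gene)
  small <- vapply(genes, function(g) sum(crisp$gene == g) < 2, logical(1))
  if (any(small)) {
    abort_bad_arg(paste0("genes with fewer than 2 wells: ",
                         paste(genes[small], collapse = ", ")))
  }
  stats_list <- lapply(genes, function(g) {
    y <- crisp$relative_yfp[crisp$gene == g]
    p <- two_group_anova_p(y, ref)
    c(n = length(y), mean = mean(y), p = p)
  })
  st <- do.call(rbind, stats_list)
  res <- tibble::tibble(
    gene = genes,
    n_wells = as.integer(unname(st[, "n"])),
    relative_yfp = unname(st[, "mean"]),
    p = unname(st[, "p"]),
    p_adj = unname(p_adjust_bky(st[, "p"]))
  )
  res <- classify_hits(res, params, reference_mean = mean(ref))
  qprime <- params$significance_fdr / (1 + params$significance_fdr)
  attr(res, "m") <- length(genes)
  attr(res, "m0_estimate") <- length(genes) -
    sum(stats::p.adjust(res$p, "BH") <= qprime)
  attr(res, "reference_mean") <- mean(ref)
  attr(res, "reference_n") <- length(ref)
  res
}

# Two-group one-way ANOVA F-test p-value (== two-sided pooled t-test).
# Zero pooled variance: p is 0 (means differ exactly) or 1 (identical).
two_group_anova_p <- function(y1, y2) {
  n1 <- length(y1); n2 <- length(y2)
  v1 <- stats::var(y1); v2 <- stats::var(y2)
  if ((n1 - 1) * v1 + (n2 - 1) * v2 <= 0) {
    return(if (isTRUE(all.equal(mean(y1), mean(y2)))) 1 else 0)
  }
  stats::t.test(y1, y2, var.equal = TRUE)$p.value
}

#' Classify screen results into hit classes
#'
#' `significant` if `p_adj <= significance_fdr` (default 0.01), `trending`
#' if strictly above that but at most `trending_upper` (default 0.1),
#' otherwise `no_effect`. Direction is `enhanced` when the gene's mean
#' relative fluorescence exceeds the wild-type ablated reference mean
#' (knockout sped regeneration up), `inhibited` when below, and `none` for
#' the `no_effect` class.
#'
#' @param result Tibble with `relative_yfp`, `p_adj` columns.
#' @param params A [screen_params()].
#' @param reference_mean Mean relative fluorescence of the wild-type
#'   ablated reference (taken from the result's attribute when absent).
#'
#' @return `result` with `class` and `direction` columns.
#' @export
classify_hits <- function(result, params = screen_params(),
                          reference_mean = NULL) {
  reference_mean <- reference_mean %||% attr(result, "reference_mean")
  if (is.null(reference_mean)) abort_bad_arg("`reference_mean` required")
  cls <- dplyr::case_when(
    result$p_adj <= params$significance_fdr ~ "significant",
    result$p_adj <= params$trending_upper ~ "trending",
    .default = "no_effect"
  )
  dir <- dplyr::case_when(
    cls == "no_effect" ~ "none",
    result$relative_yfp > reference_mean ~ "enhanced",
    result$relative_yfp < reference_mean ~ "inhibited",
    .default = "none"
  )
  result$class <- cls
  result$direction <- dir
  class(result) <- unique(c("screen_result", class(result)))
  attr(result, "reference_mean") <- reference_mean
  result
}
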