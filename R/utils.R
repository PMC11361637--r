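# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_bad_arg <- function(msg) stop(msg, call. = FALSE)

check_count_matrix <- function(counts, arg = "counts") {
  if (!is.matrix(counts) && !methods::is(counts, "Matrix")) {
    abort_bad_arg(sprintf("`%s` must be a gene-by-cell matrix", arg))
  }
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    abort_bad_arg(sprintf("`%s` must carry gene rownames and cell colnames", arg))
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    abort_bad_arg(sprintf("`%s` has duplicated gene or cell identifiers", arg))
  }
  invisible(counts)
}

check_proportion <- function(x, name, closed = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    if (closed) x >= 0 && x <= 1 else x > 0 && x < 1
  if (!ok) abort_bad_arg(sprintf("`%s` must be a proportion in %s", name,
                                 if (closed) "[0, 1]" else "(0, 1)"))
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) && (x > 0 || (!strict && x >= 0))
  if (!ok) abort_bad_arg(sprintf("`%s` must be a %s real", name,
                                 if (strict) "positive" else "non-negative"))
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x == floor(x)
  if (!ok) abort_bad_arg(sprintf("`%s` must be an integer >= %d", name, min))
  invisible(as.integer(x))
}

# Derive a child seed from a base seed, kept inside 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% .Machine$integer.max)
}

# Area under the precision-recall curve (average precision) for a score
# vector against 0/1 labels; ties broken by score order after a stable sort.
pr_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ord <- order(scores, decreasing = TRUE)
  lab <- as.integer(labels[ord])
  tp <- cumsum(lab)
  precision <- tp / seq_along(lab)
  sum(precision[lab == 1]) / sum(lab)
}

# Linear interpolation across all-NA columns of a matrix (values vary by row,
# NA pattern is shared column-wise); endpoints carried from nearest non-NA.
interp_na_cols <- function(m) {
  na_col <- apply(m, 2, function(x) all(is.na(x)))
  if (!any(na_col)) return(m)
  if (all(na_col)) abort_bad_arg("all bins empty; cannot interpolate")
  idx <- seq_len(ncol(m))
  good <- idx[!na_col]
  for (j in idx[na_col]) {
    lo <- suppressWarnings(max(good[good < j]))
    hi <- suppressWarnings(min(good[good > j]))
    if (!is.finite(lo)) m[, j] <- m[, hi]
    else if (!is.finite(hi)) m[, j] <- m[, lo]
    else {
      w <- (j - lo) / (hi - lo)
      m[, j] <- (1 - w) * m[, lo] + w * m[, hi]
    }
  }
  m
}

# Row-wise running mean with window w (centred, truncated at the edges),
# expressed as multiplication by a bins-by-bins smoothing matrix.
smoothing_matrix <- function(n_bins, w) {
  w <- max(1L, as.integer(w))
  s <- matrix(0, n_bins, n_bins)
  half <- (w - 1) %/% 2
  for (j in seq_len(n_bins)) {
    lo <- max(1L, j - half)
    hi <- min(n_bins, j + half + (w - 1) %% 2)
    s[lo:hi, j] <- 1 / (hi - lo + 1)
  }
  s
}
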