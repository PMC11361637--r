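# QC filtering, normalization, HVG selection and rank-sum marker tests.

test_that("qc_filter matches a brute-force recount on a random toy matrix", {
  m <- toy_counts(20, 15, seed = 7, lambda = 2)
  p <- qc_params(min_genes_per_cell = 5, min_umis_per_cell = 12,
                 min_cells_per_gene = 4)
  got <- qc_filter(m, p)

  keep_cells <- colnames(m)[sapply(colnames(m), function(cc) {
    sum(m[, cc] > 0) >= 5 && sum(m[, cc]) >= 12
  })]
  keep_genes <- rownames(m)[sapply(rownames(m), function(g) {
    sum(m[g, keep_cells] > 0) >= 4
  })]
  expect_identical(got, m[keep_genes, keep_cells, drop = FALSE])
})

test_that("qc_filter boundary behaviour matches the printed thresholds", {
  # cell at exactly the limits is kept; one below either limit is removed
  m <- matrix(0L, 250, 3,
              dimnames = list(sprintf("g%03d", 1:250), c("at", "few_genes", "few_umis")))
  m[1:200, "at"] <- 5L          # 200 genes, 1000 UMIs
  m[1:199, "few_genes"] <- 6L   # 199 genes, 1194 UMIs
  m[1:200, "few_umis"] <- 4L    # 200 genes, 800 UMIs
  m[201, "few_umis"] <- 199L    # 201 genes, 999 UMIs
  got <- qc_filter(m, qc_params(min_cells_per_gene = 0))
  expect_identical(colnames(got), "at")
  # gene detected in 2 cells is removed, detected in all 3 is kept
  m2 <- matrix(10L, 4, 3, dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
  m2["g1", 3] <- 0L; m2["g2", 2:3] <- 0L
  got2 <- qc_filter(m2, qc_params(min_genes_per_cell = 0, min_umis_per_cell = 0))
  expect_setequal(rownames(got2), c("g3", "g4"))
  # empty in, empty out; all-cells-removed warns
  e <- matrix(integer(), 0, 0)
  expect_identical(qc_filter(e), e)
  expect_warning(qc_filter(toy_counts(5, 4, lambda = 1)), "every cell")
})

test_that("qc_filter is idempotent on simulated data", {
  ds <- simulate_trajectory_counts(sim_config(seed = 30))
  once <- qc_filter(ds$counts)
  expect_identical(qc_filter(once), once)
})

test_that("normalize_log computes log1p of scaled fractions and is depth-invariant", {
  m <- matrix(c(1, 1, 2, 0, 0, 0), 3, 2,
              dimnames = list(c("a", "b", "c"), c("c1", "c2")))
  m[, 2] <- c(2, 2, 4)
  nm <- normalize_log(m, scale = 4)
  expect_equal(nm[, "c1"], c(a = log1p(1), b = log1p(1), c = log1p(2)))
  # doubled counts in c2 give identical normalized values
  expect_equal(nm[, "c2"], nm[, "c1"], ignore_attr = TRUE)
  # all-zero gene stays zero
  m2 <- rbind(m, z = 0)
  expect_true(all(normalize_log(m2)["z", ] == 0))
  # zero-total cell errors with its name
  m3 <- m; m3[, 2] <- 0
  expect_error(normalize_log(m3), "c2")
})

test_that("select_hvg ranks by variance on a toy with distinct variances", {
  set.seed(1)
  n <- 200
  m <- rbind(
    g_flat = rep(2, n),
    g_lo = rnorm(n, 2, 0.1),
    g_mid = rnorm(n, 2, 0.5),
    g_hi = rnorm(n, 2, 2),
    g_hi2 = rnorm(n, 2, 1.5)
  )
  colnames(m) <- paste0("c", 1:n)
  got <- select_hvg(m, 5, n_bins = 1)
  vars <- apply(m, 1, var)
  expect_identical(got, names(sort(vars, decreasing = TRUE)))
  # constant gene never outranks a variable one
  expect_identical(got[5], "g_flat")
  expect_error(select_hvg(m, 10), "exceeds")
})

test_that("rank-sum p on a 4-vs-4 split matches enumeration over all 70 assignments", {
  x <- c(10, 11, 12, 13)  # fully separated
  y <- c(1, 2, 3, 4)
  # enumeration oracle over all C(8,4) assignments of the pooled ranks
  pooled <- c(x, y)
  r <- rank(pooled)
  combos <- combn(8, 4)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  w_obs <- sum(r[1:4])
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  expected <- min(1, 2 * min(p_le, p_ge))
  expect_equal(fatescreen:::rank_sum_p(x, y), expected, tolerance = 1e-12)
  expect_equal(expected, 2 / 70)

  # and with ties, against the same enumeration
  xt <- c(5, 5, 7, 2); yt <- c(5, 1, 2, 2)
  rt <- rank(c(xt, yt))
  wt_all <- apply(combos, 2, function(idx) sum(rt[idx]))
  wt_obs <- sum(rt[1:4])
  expected_t <- min(1, 2 * min(mean(wt_all <= wt_obs), mean(wt_all >= wt_obs)))
  expect_equal(fatescreen:::rank_sum_p(xt, yt), expected_t, tolerance = 1e-12)

  # tie-free exact path agrees with wilcox.test(exact = TRUE)
  set.seed(2)
  a <- sample(1:100, 6); b <- sample(101:200, 9)
  expect_equal(fatescreen:::rank_sum_p(a, b),
               wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("rank_sum_markers filters, tests and flags as specified", {
  set.seed(5)
  n <- 40
  m <- rbind(
    up = c(rnorm(n, 4), rnorm(n, 1)),
    flat = rnorm(2 * n, 2),
    rare = rep(0, 2 * n)
  )
  m <- pmax(m, 0)
  m["rare", 1] <- 0.01  # detected in 1/80 cells < min_pct
  colnames(m) <- paste0("c", seq_len(2 * n))
  labs <- rep(c("A", "B"), each = n)
  tab <- rank_sum_markers(m, labs, deg_params("condition"), groups = "A")
  expect_true("up" %in% tab$gene)
  expect_false("rare" %in% tab$gene)     # fails min.pct
  expect_true(all(c("gene", "group", "log2fc", "pct_in", "pct_out",
                    "p", "p_adj", "significant") %in% names(tab)))
  expect_true(tab$significant[tab$gene == "up"])
  expect_true(all(tab$p_adj >= tab$p - 1e-12))

  # identical groups: no gene passes the fold-change filter
  m0 <- matrix(rep(rnorm(30), 2), nrow = 3)
  rownames(m0) <- c("a", "b", "c"); colnames(m0) <- paste0("c", 1:20)
  m0 <- pmax(m0, 0)
  m0[, 11:20] <- m0[, 1:10]
  tab0 <- rank_sum_markers(m0, rep(c("A", "B"), each = 10), deg_params("condition"))
  expect_equal(nrow(tab0), 0)

  expect_error(rank_sum_markers(m, rep("A", 2 * n)), "two groups")
  expect_error(rank_sum_markers(m, c("B", rep("A", 2 * n - 1))), "fewer than 2")
})

test_that("null two-group data give approximately uniform raw p-values", {
  set.seed(77)
  n_genes <- 5000
  m <- matrix(abs(rnorm(n_genes * 200, 2, 1)), n_genes, 200,
              dimnames = list(sprintf("g%04d", 1:n_genes), sprintf("c%03d", 1:200)))
  labs <- rep(c("A", "B"), each = 100)
  tab <- rank_sum_markers(m, labs, deg_params(logfc_threshold = 0, min_pct = 0),
                          groups = "A")
  expect_equal(nrow(tab), n_genes)
  frac <- mean(tab$p < 0.05)
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.06)
})

test_that("marker direction agrees with planted group effects", {
  set.seed(99)
  n_genes <- 60; n <- 60
  lfc <- rep(c(2, -2, 0), each = n_genes / 3)   # planted log2 effects
  base <- matrix(rnorm(n_genes * n, 3, 0.5), n_genes, n)
  eff <- base + outer(lfc, c(rep(1, n / 2), rep(0, n / 2)))
  m <- pmax(eff, 0)
  dimnames(m) <- list(sprintf("g%02d", 1:n_genes), sprintf("c%02d", 1:n))
  tab <- rank_sum_markers(m, rep(c("A", "B"), each = n / 2),
                          deg_params(logfc_threshold = 0, min_pct = 0), groups = "A")
  planted <- lfc[match(tab$gene, sprintf("g%02d", 1:n_genes))]
  strong <- abs(planted) >= 1
  agree <- sign(tab$log2fc[strong]) == sign(planted[strong])
  expect_gte(mean(agree), 0.95)
})
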