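# Pseudotime fitting, condition density, binned deltas, pattern clusters.

test_that("collinear cells are ordered exactly, with the root at the origin", {
  lm <- line_matrix()
  pt <- fit_pseudotime(lm$m, lm$clusters,
                       trajectory_params(n_hvg = 5, n_pcs = 2))
  expect_equal(cor(pt$cells$t, lm$pos, method = "spearman"), 1)
  expect_equal(pt$path, c("MG", "progenitor", "neuron"))
  means <- tapply(pt$cells$t, lm$clusters[pt$cells$cell_id], mean)
  expect_true(means["MG"] < means["progenitor"])
  expect_true(means["progenitor"] < means["neuron"])
})

test_that("reversing the root cluster reverses pseudotime exactly", {
  lm <- line_matrix()
  p1 <- fit_pseudotime(lm$m, lm$clusters, trajectory_params(n_hvg = 5, n_pcs = 2))
  p2 <- fit_pseudotime(lm$m, lm$clusters,
                       trajectory_params(n_hvg = 5, n_pcs = 2,
                                         root_cluster = "neuron"))
  expect_equal(cor(p1$cells$t, p2$cells$t, method = "spearman"), -1)
})

test_that("pseudotime is invariant to cell order permutation", {
  ds <- simulate_trajectory_counts(small_sim(seed = 3, n_cells = 300))
  q <- qc_filter(ds$counts, qc_params(40, 200, 3))
  nm <- normalize_log(q)
  labs <- setNames(ds$cells$state, ds$cells$cell_id)[colnames(nm)]
  tp <- trajectory_params(n_hvg = 60, n_pcs = 10)
  p1 <- fit_pseudotime(nm, labs, tp)
  set.seed(1)
  perm <- sample(ncol(nm))
  p2 <- fit_pseudotime(nm[, perm], labs[perm], tp)
  t2 <- p2$cells$t[match(p1$cells$cell_id, p2$cells$cell_id)]
  expect_true(max(abs(p1$cells$t - t2)) < 1e-9)
})

test_that("pseudotime errors on a missing root and on off-path clusters", {
  lm <- line_matrix()
  expect_error(fit_pseudotime(lm$m, lm$clusters,
                              trajectory_params(root_cluster = "zz",
                                                n_hvg = 5, n_pcs = 2)),
               "root cluster")
  # Y-shaped layout: cluster D hangs off the middle of the A-B-C path
  set.seed(4)
  n <- 40
  centers <- list(A = c(0, 0), B = c(4, 0), C = c(8, 0), D = c(4, 9))
  m <- do.call(cbind, lapply(names(centers), function(cl) {
    t(matrix(rnorm(2 * n, rep(centers[[cl]], each = n), 0.2), n, 2))
  }))
  m <- rbind(m, 0.1 * matrix(rnorm(3 * ncol(m)), 3))
  rownames(m) <- paste0("g", 1:5)
  colnames(m) <- sprintf("c%03d", seq_len(ncol(m)))
  labs <- setNames(rep(names(centers), each = n), colnames(m))
  expect_error(fit_pseudotime(m, labs,
                              trajectory_params(root_cluster = "A",
                                                n_hvg = 5, n_pcs = 2)),
               "off the root lineage path")
})

test_that("condition densities integrate to one and vanish for identical sets", {
  lm <- line_matrix()
  pt <- fit_pseudotime(lm$m, lm$clusters, trajectory_params(n_hvg = 5, n_pcs = 2))
  # duplicated condition labels drawn from one pool, split arbitrarily
  labs <- setNames(rep(c("x", "y"), length.out = nrow(pt$cells)), pt$cells$cell_id)
  den <- condition_density(pt, labs, conditions = c("x", "y"))
  d <- tibble::as_tibble(den)
  for (cd in c("x", "y")) {
    y <- d$density[d$condition == cd]
    expect_equal(fatescreen:::trapz(d$t[d$condition == cd], y), 1, tolerance = 1e-6)
  }
  # identical cell sets in both conditions: same density, log-ratio ~ 0
  pt2 <- pt
  pt2$cells <- rbind(pt$cells, transform(pt$cells, cell_id = paste0(cell_id, "_b")))
  labs2 <- setNames(rep(c("x", "y"), each = nrow(pt$cells)), pt2$cells$cell_id)
  den2 <- condition_density(pt2, labs2, conditions = c("x", "y"))
  expect_true(max(abs(attr(den2, "log_ratio")$log_ratio)) < 1e-9)
  expect_error(condition_density(pt, labs, conditions = c("x", "nope")),
               "unknown condition")
})

test_that("ablated cells are enriched early on the common trajectory", {
  pair <- simulate_condition_pair(sim_config(seed = 1), vary = "ablation")
  q <- qc_filter(pair$counts)
  nm <- normalize_log(q)
  info <- pair$cells[match(colnames(q), pair$cells$cell_id), ]
  pt <- fit_pseudotime(nm, setNames(info$state, info$cell_id))
  den <- condition_density(pt, setNames(info$ablation, info$cell_id),
                           conditions = c("ablated", "control"))
  lr <- attr(den, "log_ratio")
  first_quintile <- lr$log_ratio[lr$t <= 0.2]
  expect_gt(mean(first_quintile), 0)
})

test_that("bin_and_delta normalizes to a unit extreme and handles flat genes", {
  set.seed(8)
  n <- 200
  t <- seq(0, 1, length.out = n)
  m <- rbind(
    up_in_b = c(rep(1, n / 2), rep(1, n / 2)),  # filled below
    flat = rep(2, n)
  )
  colnames(m) <- sprintf("c%03d", 1:n)
  cond <- rep(c("a", "b"), length.out = n)
  m["up_in_b", cond == "b"] <- 3 + t[cond == "b"]
  m["up_in_b", cond == "a"] <- 1
  pt <- structure(list(cells = tibble::tibble(cell_id = colnames(m), t = t,
                                              cluster = "x")),
                  class = "pseudotime_fit")
  tp <- trajectory_params(n_bins = 10, n_permutations = 99, seed = 2)
  dl <- bin_and_delta(m, pt, setNames(cond, colnames(m)), tp,
                      conditions = c("a", "b"))
  expect_true(all(dl$delta >= -1 & dl$delta <= 1))
  expect_equal(max(abs(dl$delta["up_in_b", ])), 1)
  expect_true(all(dl$delta["flat", ] == 0))
  expect_equal(dl$stats$norm_factor[dl$stats$gene == "flat"], 0)
  expect_lt(dl$stats$p[dl$stats$gene == "up_in_b"], 0.05)
  # default bin count matches the 50-timepoint segmentation
  expect_equal(trajectory_params()$n_bins, 50)
  # condition missing from most bins errors
  cond_bad <- ifelse(t < 0.2, "b", "a")
  expect_error(bin_and_delta(m, pt, setNames(cond_bad, colnames(m)), tp,
                             conditions = c("a", "b")),
               "absent from more than half")
})

test_that("permutation p-values are uniform under a shuffled null", {
  # permutations are shared across genes within one run, so uniformity is
  # assessed over independent replicate datasets pooled to 2000 p-values
  set.seed(31)
  ps <- unlist(lapply(1:20, function(r) {
    n_genes <- 100; n_cells <- 200
    m <- matrix(abs(rnorm(n_genes * n_cells, 2, 1)), n_genes, n_cells,
                dimnames = list(sprintf("g%04d", 1:n_genes),
                                sprintf("c%03d", 1:n_cells)))
    t <- runif(n_cells)
    cond <- sample(rep(c("a", "b"), length.out = n_cells))
    pt <- structure(list(cells = tibble::tibble(cell_id = colnames(m), t = t,
                                                cluster = "x")),
                    class = "pseudotime_fit")
    tp <- trajectory_params(n_bins = 20, n_permutations = 99, seed = r)
    dl <- bin_and_delta(m, pt, setNames(cond, colnames(m)), tp,
                        conditions = c("a", "b"))
    dl$stats$p
  }))
  # p is discrete-uniform on the 1/(B+1) grid; the randomized probability
  # integral transform makes it exactly continuous-uniform under the null
  u <- ps - runif(length(ps)) / 100
  ks <- ks.test(u, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("profile clustering separates planted shapes and renumbers by size", {
  n_bins <- 30
  up <- t(sapply(1:40, function(i) seq(0, 1, length.out = n_bins) + rnorm(n_bins, 0, 0.02)))
  dn <- t(sapply(1:10, function(i) seq(1, 0, length.out = n_bins) + rnorm(n_bins, 0, 0.02)))
  m <- rbind(up, dn)
  rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  lab <- cluster_profiles(m, k = 2, seed = 7)
  planted <- rep(c("up", "down"), c(40, 10))
  tab <- table(lab$pattern, planted)
  # perfect agreement up to label naming (adjusted Rand index 1)
  expect_equal(sum(apply(tab, 1, max)), nrow(m))
  # largest cluster is labelled 1
  expect_equal(unname(which.max(table(lab$pattern))), 1L)
  expect_true(all(cluster_profiles(m, k = 1)$pattern == 1))
  expect_error(cluster_profiles(m, k = nrow(m) + 1), "exceeds")
})
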