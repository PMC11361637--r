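# Importance inference, quantile filtering, sign annotation, TF filter.

test_that("a copied TF wins the importance for its target across seeds", {
  wins <- sapply(1:10, function(s) {
    set.seed(100 + s)
    n <- 120
    tfs <- matrix(rnorm(6 * n), 6, n,
                  dimnames = list(paste0("tf", 1:6), paste0("c", 1:n)))
    m <- rbind(tfs, target = tfs["tf1", ])
    imp <- infer_importance(m, paste0("tf", 1:6),
                            grn_params(n_trees = 50, seed = s),
                            targets = "target")
    imp$tf[which.max(imp$importance)] == "tf1"
  })
  expect_equal(sum(wins), 10)
})

test_that("pure-noise targets spread importance near the uniform share", {
  max_imp <- sapply(1:20, function(s) {
    set.seed(200 + s)
    n <- 100
    m <- matrix(rnorm(7 * n), 7, n,
                dimnames = list(c(paste0("tf", 1:6), "target"), paste0("c", 1:n)))
    imp <- infer_importance(m, paste0("tf", 1:6),
                            grn_params(n_trees = 50, seed = s),
                            targets = "target")
    max(imp$importance)
  })
  expect_lt(mean(max_imp), 3 / 6)
})

test_that("per-target importances sum to one and inference is deterministic", {
  ds <- simulate_trajectory_counts(small_sim(seed = 5, n_cells = 150))
  nm <- normalize_log(ds$counts[, colSums(ds$counts) > 0])
  tfs <- attr(ds$network, "tf_params")$tf
  p <- grn_params(n_trees = 30, seed = 4)
  imp <- infer_importance(nm, tfs, p, targets = rownames(nm)[1:25])
  sums <- tapply(imp$importance, imp$target, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(imp$importance >= 0))
  expect_false(any(imp$tf == imp$target))
  imp2 <- infer_importance(nm, tfs, p, targets = rownames(nm)[1:25])
  expect_identical(imp, imp2)
  expect_error(infer_importance(nm, character(0), p), "empty")
  expect_error(infer_importance(nm, c(tfs, "ghost"), p), "ghost")
  expect_error(infer_importance(nm[, 1:10], tfs, p), "20 cells")
})

test_that("pooled 95th-quantile filter keeps exactly the top 5 of 100 distinct scores", {
  set.seed(6)
  imp <- tibble::tibble(
    tf = rep("tf1", 100), target = sprintf("g%03d", 1:100),
    importance = sample(seq(0.001, 0.1, length.out = 100))
  )
  kept <- filter_importance_quantile(imp, 0.95)
  expect_equal(nrow(kept), 5)
  expect_setequal(kept$target,
                  imp$target[order(-imp$importance)][1:5])
  # all-equal scores are all retained
  same <- imp; same$importance <- 0.5
  expect_equal(nrow(filter_importance_quantile(same, 0.95)), 100)
  # output size is non-increasing in q
  sizes <- sapply(c(0.1, 0.3, 0.5, 0.7, 0.9, 0.99), function(q)
    nrow(filter_importance_quantile(imp, q)))
  expect_true(all(diff(sizes) <= 0))
})

test_that("sign rule is strict at +-0.03 and discards in-between correlations", {
  expect_equal(fatescreen:::classify_sign(0.05), "positive")
  expect_equal(fatescreen:::classify_sign(-0.05), "negative")
  expect_equal(fatescreen:::classify_sign(0.01), "discarded")
  expect_equal(fatescreen:::classify_sign(0.03), "discarded")    # boundary
  expect_equal(fatescreen:::classify_sign(-0.03), "discarded")   # boundary
  expect_equal(fatescreen:::classify_sign(0.03 + 1e-9), "positive")
  expect_equal(fatescreen:::classify_sign(-0.03 - 1e-9), "negative")
  expect_equal(fatescreen:::classify_sign(NA_real_), "discarded")
})

test_that("annotate_edge_sign computes correlations and drops weak or undefined edges", {
  set.seed(10)
  n <- 400
  x <- scale(rnorm(n))[, 1]
  make_cor <- function(r) {
    z <- scale(rnorm(n))[, 1]
    z <- scale(z - sum(z * x) / sum(x * x) * x)[, 1]  # orthogonalize
    r * x + sqrt(1 - r^2) * z
  }
  m <- rbind(tfA = x, pos = make_cor(0.05), neg = make_cor(-0.05),
             weak = make_cor(0.01), flat = rep(1, n))
  colnames(m) <- paste0("c", 1:n)
  edges <- tibble::tibble(tf = "tfA", target = c("pos", "neg", "weak", "flat"))
  signed <- suppressMessages(annotate_edge_sign(edges, m, 0.03))
  expect_setequal(signed$target, c("pos", "neg"))
  expect_equal(signed$sign[signed$target == "pos"], "positive")
  expect_equal(signed$sign[signed$target == "neg"], "negative")
  expect_equal(attr(signed, "n_discarded"), 2)
  expect_true(all(abs(signed$cor) > 0.03))
  expect_error(annotate_edge_sign(tibble::tibble(tf = "ghost", target = "pos"), m),
               "ghost")
})

test_that("TF-expression filter keeps detection >= 5% and drops silent TFs", {
  counts <- matrix(0L, 3, 40,
                   dimnames = list(c("tfa", "tfb", "g1"), sprintf("c%02d", 1:40)))
  cl <- rep(c("progenitor", "MG"), each = 20)
  counts["tfa", 1:2] <- 5L      # 10% of progenitor cells
  counts["g1", ] <- 3L
  edges <- tibble::tibble(tf = c("tfa", "tfb"), target = c("g1", "g1"),
                          sign = "positive")
  out <- suppressMessages(
    filter_tf_expressed(edges, counts, setNames(cl, colnames(counts))))
  expect_equal(out$tf, "tfa")
  expect_equal(attr(out, "removed_tfs"), "tfb")
  expect_error(
    filter_tf_expressed(edges, counts, setNames(cl, colnames(counts)),
                        grn_params(expression_cluster = "nope")),
    "not present")
})

test_that("signed edge lists always satisfy their sign/correlation invariants", {
  for (s in 1:5) {
    set.seed(300 + s)
    n <- 150
    m <- matrix(rnorm(12 * n), 12, n,
                dimnames = list(sprintf("v%02d", 1:12), paste0("c", 1:n)))
    edges <- expand.grid(tf = rownames(m)[1:4], target = rownames(m)[5:12],
                         stringsAsFactors = FALSE)
    thr <- runif(1, 0.01, 0.2)
    signed <- suppressMessages(annotate_edge_sign(tibble::as_tibble(edges), m, thr))
    expect_true(all(signed$cor[signed$sign == "positive"] > thr))
    expect_true(all(signed$cor[signed$sign == "negative"] < -thr))
    expect_true(all(abs(signed$cor) > thr))
  }
})
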