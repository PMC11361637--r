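# Relative-YFP normalization, design sample size, ANOVA + two-stage FDR,
# hit classification.

make_screen_data <- function(gene_effects, seed = 1, n_wells = 8) {
  simulate_crispant_screen(gene_effects, n_wells_per_gene = n_wells, seed = seed)
}

test_that("relative YFP is the well over the plate's unablated control mean", {
  d <- tibble::tibble(
    well = paste0("w", 1:4),
    gene = c("control", "control", "control", "gA"),
    arm = c(rep("unablated_control", 3), "ablated"),
    genotype = c(rep("wildtype", 3), "crispant"),
    fluorescence = c(100, 100, 100, 32),
    plate = "p1"
  )
  out <- normalize_relative_yfp(d)
  expect_equal(out$relative_yfp[out$gene == "gA"], 0.32)
  expect_equal(out$relative_yfp[1], 1.0)
  # scale invariance within a plate
  d2 <- d; d2$fluorescence <- d$fluorescence * 7.3
  expect_equal(normalize_relative_yfp(d2)$relative_yfp, out$relative_yfp)
  # error paths: too few controls, missing plate controls, zero mean
  expect_error(normalize_relative_yfp(d[3:4, ]), "fewer than 2")
  d3 <- d; d3$fluorescence[1:3] <- 0
  expect_error(normalize_relative_yfp(d3), "non-positive")
})

test_that("minimum sample size matches the closed-form design values", {
  expect_equal(min_sample_size(0.05, 0.80, 1.0), 16L)
  expect_equal(min_sample_size(0.05, 0.80, 1.41), 8L)
  # hand arithmetic for d = 1: ceiling(2 * (1.959964 + 0.8416212)^2)
  expect_equal(min_sample_size(0.05, 0.80, 1.0),
               as.integer(ceiling(2 * (qnorm(0.975) + qnorm(0.8))^2)))
  # n is non-decreasing in power at fixed alpha
  ns <- sapply(c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95), function(pw)
    min_sample_size(0.05, pw, 1.0))
  expect_true(all(diff(ns) >= 0))
  expect_error(min_sample_size(0.05, 0.8, 0), "positive")
  # exact noncentral-t refinement never designs below the target power
  n_exact <- min_sample_size(0.05, 0.80, 1.0, exact = TRUE)
  expect_gte(fatescreen:::t_test_power(n_exact, 1.0, 0.05), 0.80)
})

test_that("two-stage adjusted p-values reproduce a hand-executed procedure", {
  p <- c(0.0001, 0.0008, 0.0019, 0.0095, 0.02, 0.04, 0.15, 0.3, 0.6, 0.9)
  adj <- p_adjust_bky(p)
  # hand-executed two-stage oracle at fixed levels q
  two_stage <- function(p, q) {
    m <- length(p)
    qp <- q / (1 + q)
    bh <- p.adjust(p, "BH")
    r1 <- sum(bh <= qp)                      # stage 1: BH at q'
    if (r1 == 0) return(integer(0))
    if (r1 == m) return(seq_len(m))
    which(bh <= qp * m / (m - r1))           # stage 2: BH at q'm/m0
  }
  for (q in c(0.01, 0.025, 0.05, 0.1, 0.2)) {
    expect_equal(which(adj <= q), two_stage(p, q), info = paste("q =", q))
  }
  # rejection set is monotone in q
  sets <- lapply(c(0.01, 0.05, 0.1, 0.2), function(q) which(adj <= q))
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
  expect_true(all(adj > 0 & adj <= 1))
  expect_error(p_adjust_bky(c(0.5, 2)), "in \\[0, 1\\]")
})

test_that("screen_test compares each gene to the wild-type ablated reference", {
  eff <- c(big_down = -0.6, null1 = 0, null2 = 0)
  sc <- make_screen_data(eff, seed = 7, n_wells = 16)
  res <- screen_test(normalize_relative_yfp(sc))
  expect_s3_class(res, "screen_result")
  expect_equal(sort(res$gene), sort(names(eff)))
  expect_equal(res$class[res$gene == "big_down"], "significant")
  expect_equal(res$direction[res$gene == "big_down"], "inhibited")
  expect_gt(min(res$p_adj[res$gene != "big_down"]), 0.1)
  # identical wells to reference give p ~ 1 via the zero-variance fast path
  d <- tibble::tibble(
    well = paste0("w", 1:23),
    gene = c(rep("control", 3), rep("control", 10), rep("gA", 10)),
    arm = c(rep("unablated_control", 3), rep("ablated", 20)),
    genotype = c(rep("wildtype", 13), rep("crispant", 10)),
    fluorescence = c(rep(100, 3), rep(32, 20)),
    plate = "p1"
  )
  res2 <- screen_test(normalize_relative_yfp(d))
  expect_equal(res2$p, 1)
  expect_equal(res2$class, "no_effect")
  # reference too small / under-replicated genes error
  d_small <- d[c(1:3, 4:6, 14:23), ]
  expect_error(screen_test(normalize_relative_yfp(d_small)), "reference")
  d_one <- d[-(15:23), ]
  expect_error(screen_test(normalize_relative_yfp(d_one)), "fewer than 2 wells")
})

test_that("hit classes follow the 0.01 / 0.1 cutoffs exactly", {
  res <- tibble::tibble(
    gene = paste0("g", 1:6),
    n_wells = 8L,
    relative_yfp = c(0.5, 0.2, 0.4, 0.32, 0.6, 0.1),
    p = 0.001,
    p_adj = c(0.005, 0.01, 0.05, 0.1, 0.2, 0.5)
  )
  out <- classify_hits(res, reference_mean = 0.32)
  expect_equal(out$class,
               c("significant", "significant", "trending", "trending",
                 "no_effect", "no_effect"))
  expect_equal(out$direction[1:4],
               c("enhanced", "inhibited", "enhanced", "none"))
  expect_equal(out$direction[5:6], c("none", "none"))
})

test_that("simulated screens at the designed effect are sensitive and FDR-controlled", {
  eff <- c(rep(0.30, 11), rep(-0.30, 7), rep(0, 73))
  names(eff) <- sprintf("g%02d", seq_along(eff))
  true_hit <- eff != 0
  n_reps <- 60
  sens <- fdr <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    sc <- make_screen_data(eff, seed = 5000 + r, n_wells = 16)
    res <- screen_test(normalize_relative_yfp(sc))
    det <- res$p_adj <= 0.01
    sens[r] <- sum(det & true_hit[res$gene]) / sum(true_hit)
    fdr[r] <- if (any(det)) sum(det & !true_hit[res$gene]) / sum(det) else 0
  }
  expect_gte(mean(sens), 0.8)
  expect_lte(mean(fdr), 0.05)
})

test_that("empirical plate power matches the normal-approximation design", {
  pw <- plate_power(d = 1.41, n_per_arm = 8, n_reps = 4000, seed = 9)
  expect_gt(pw, 0.77)
  expect_lt(pw, 0.84)
})
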