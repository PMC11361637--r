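#' Simulate a single-cell regeneration dataset with known ground truth
#'
#' Draws a latent trajectory position per cell (uniform for the control
#' condition, early-shifted Beta for the ablated condition), assigns the
#' MG / progenitor / neuron state by fixed thresholds, evaluates each TF's
#' activity curve with per-cell log-normal noise, propagates activity
#' through the planted signed network into target log-means, and samples
#' negative-binomial counts with log-normal library-size scaling. Under the
#' knockout genotype the `ko_module` TFs receive a positive activity shift
#' and `ko_tf` is silenced, emulating a knockout that redirects progenitors
#' toward the neuron (RGC) fate.
#'
#' @param config A [sim_config()].
#' @param network Optional pre-built [make_planted_network()] for `config`
#'   (built from the config seed when omitted).
#'
#' @return A list of class `synthetic_dataset`:
#'   * `counts`: gene-by-cell integer matrix;
#'   * `cells`: tibble (`cell_id`, `true_t`, `state`, `ablation`,
#'     `genotype`, `condition`);
#'   * `network`: the planted network;
#'   * `config`: the configuration;
#'   * `mu`: model mean matrix when `config$keep_means` is `TRUE`.
#' @export
#' @examples
#' ds <- simulate_trajectory_counts(sim_config(n_cells = 50, n_genes = 40,
#'                                             n_tfs = 6, targets_per_tf = 5,
#'                                             seed = 3))
#' dim(ds$counts)
simulate_trajectory_counts <- function(config, network = NULL) {
  stopifnot(inherits(config, "sim_config"))
  network <- network %||% make_planted_network(config)
  tf_params <- attr(network, "tf_params")
  gene_ids <- attr(network, "gene_ids")
  n <- config$n_cells

  set.seed(child_seed(config$seed, 1))
  t <- if (config$ablation == "ablated") {
    stats::rbeta(n, config$ablation_time_shift[1], config$ablation_time_shift[2])
  } else {
    stats::runif(n)
  }
  state <- cut(t, c(-Inf, state_thresholds, Inf),
               labels = c("MG", "progenitor", "neuron"))
  state <- as.character(state)

  ko_tf <- if (config$genotype == "knockout") resolve_ko_tf(config, tf_params) else NULL
  a <- tf_activity(t, tf_params, genotype = config$genotype, ko_tf = ko_tf,
                   ko_module = config$ko_module, ko_shift = config$ko_shift)
  if (ncol(a) > 0 && config$activity_noise_sd > 0) {
    a <- a * exp(matrix(stats::rnorm(n * ncol(a), 0, config$activity_noise_sd),
                        n, ncol(a)))
  }

  # library-size factors (mean library_size_mean); zero mean => empty matrix
  s <- if (config$library_size_mean > 0) {
    stats::rlnorm(n,
                  meanlog = log(config$library_size_mean) - config$library_size_sd^2 / 2,
                  sdlog = config$library_size_sd)
  } else {
    rep(0, n)
  }

  targets <- setdiff(gene_ids, tf_params$tf)
  base <- attr(network, "target_base")[targets]
  w <- signed_weight_matrix(network, gene_ids)

  act_floor <- 0.02
  mu_tf <- config$tf_scale * (a + act_floor)                       # cells x tfs
  log_mu_tgt <- matrix(log(base), n, length(targets), byrow = TRUE) +
    a %*% w[, targets, drop = FALSE]                               # cells x targets
  mu <- t(cbind(mu_tf, exp(log_mu_tgt))[, , drop = FALSE])         # genes x cells
  rownames(mu) <- c(tf_params$tf, targets)
  mu <- mu[gene_ids, , drop = FALSE] * rep(s, each = length(gene_ids))

  counts <- if (is.finite(config$nb_dispersion)) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = config$nb_dispersion),
           nrow(mu), ncol(mu))
  } else {
    matrix(stats::rpois(length(mu), lambda = mu), nrow(mu), ncol(mu))
  }
  cell_ids <- sprintf("%s.%s_%05d", config$ablation, config$genotype, seq_len(n))
  dimnames(counts) <- list(gene_ids, cell_ids)
  dimnames(mu) <- dimnames(counts)

  out <- list(
    counts = counts,
    cells = tibble::tibble(
      cell_id = cell_ids,
      true_t = t,
      state = state,
      ablation = config$ablation,
      genotype = config$genotype,
      condition = paste(config$ablation, config$genotype, sep = "_")
    ),
    network = network,
    config = config
  )
  if (config$keep_means) out$mu <- mu
  structure(out, class = "synthetic_dataset")
}

#' Simulate a matched pair of conditions sharing one planted network
#'
#' Generates two arms from one configuration, varying either the ablation
#' status (control vs ablated, both wildtype) or the genotype (wildtype vs
#' knockout, both ablated, as in a 24-hours-post-ablation comparison).
#' `n_cells` is split equally across the arms and both arms share the same
#' planted network, so condition-delta profiles have a ground truth.
#'
#' @param config A [sim_config()]; its `ablation`/`genotype` fields are
#'   overridden per arm.
#' @param vary `"ablation"` or `"genotype"`.
#'
#' @return A `synthetic_dataset` whose `cells` tibble spans both arms.
#' @export
simulate_condition_pair <- function(config, vary = c("ablation", "genotype")) {
  stopifnot(inherits(config, "sim_config"))
  vary <- match.arg(vary)
  network <- make_planted_network(config)
  n1 <- config$n_cells %/% 2L
  cfg1 <- cfg2 <- config
  cfg1$n_cells <- n1
  cfg2$n_cells <- config$n_cells - n1
  cfg2$seed <- child_seed(config$seed, 7919)
  if (vary == "ablation") {
    cfg1$ablation <- "control"; cfg2$ablation <- "ablated"
    cfg1$genotype <- cfg2$genotype <- config$genotype
  } else {
    cfg1$ablation <- cfg2$ablation <- "ablated"
    cfg1$genotype <- "wildtype"; cfg2$genotype <- "knockout"
  }
  d1 <- simulate_trajectory_counts(cfg1, network)
  d2 <- simulate_trajectory_counts(cfg2, network)
  out <- list(
    counts = cbind(d1$counts, d2$counts),
    cells = dplyr::bind_rows(d1$cells, d2$cells),
    network = network,
    config = config
  )
  if (config$keep_means) out$mu <- cbind(d1$mu, d2$mu)
  structure(out, class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d genes x %d cells; %d planted edges\n",
              nrow(x$counts), ncol(x$counts), nrow(x$network)))
  print(dplyr::count(x$cells, .data$condition, .data$state))
  invisible(x)
}
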