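#' Plant a signed TF-to-target regulatory network
#'
#' Builds the ground-truth network used by [simulate_trajectory_counts()].
#' TFs are assigned round-robin to the three lineage modules (MG,
#' progenitor, neuron) and given a Gaussian activity curve over trajectory
#' position whose centre sits in the module's window (with a small
#' deterministic jitter so TFs within a module are distinguishable).
#' Each TF regulates `targets_per_tf` distinct non-TF genes; a configured
#' fraction of edges is repressive.
#'
#' @param config A [sim_config()].
#'
#' @return A tibble of class `planted_network` with columns `tf`, `target`,
#'   `sign` (+1/-1) and `weight`, and attributes:
#'   * `tf_params`: tibble (`tf`, `module`, `center`, `width`) of activity curves;
#'   * `lineage_modules`: named list mapping module to its TF set;
#'   * `gene_ids`: all gene identifiers (TFs first).
#' @export
#' @examples
#' net <- make_planted_network(sim_config(n_genes = 30, n_tfs = 5,
#'                                        targets_per_tf = 4, seed = 7))
#' nrow(net) # 20 edges
make_planted_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_tfs <- config$n_tfs
  tf_ids <- if (n_tfs > 0) sprintf("tf%02d", seq_len(n_tfs)) else character()
  target_ids <- if (config$n_genes > n_tfs) {
    sprintf("g%03d", seq_len(config$n_genes - n_tfs))
  } else character()

  modules <- rep_len(names(module_centers), n_tfs)
  tf_params <- tibble::tibble(
    tf = tf_ids,
    module = modules,
    center = unname(module_centers[modules]) +
      stats::runif(n_tfs, -0.08, 0.08),
    width = stats::runif(n_tfs, 0.12, 0.2)
  )

  if (n_tfs == 0 || config$targets_per_tf == 0) {
    edges <- tibble::tibble(tf = character(), target = character(),
                            sign = integer(), weight = numeric())
  } else {
    tgt <- unlist(lapply(tf_ids, function(.)
      sample(target_ids, config$targets_per_tf)))
    n_edges <- length(tgt)
    sign <- rep(1L, n_edges)
    n_neg <- round(config$negative_edge_fraction * n_edges)
    if (n_neg > 0) sign[sample.int(n_edges, n_neg)] <- -1L
    edges <- tibble::tibble(
      tf = rep(tf_ids, each = config$targets_per_tf),
      target = tgt,
      sign = sign,
      weight = stats::runif(n_edges, config$edge_weight_range[1],
                            config$edge_weight_range[2])
    )
  }

  structure(
    edges,
    tf_params = tf_params,
    lineage_modules = split(tf_params$tf, tf_params$module),
    gene_ids = c(tf_ids, target_ids),
    # baseline target expression is a gene property shared by every
    # condition arm generated from this network
    target_base = stats::setNames(
      stats::runif(length(target_ids), config$base_expr_range[1],
                   config$base_expr_range[2]),
      target_ids),
    class = c("planted_network", class(tibble::tibble()))
  )
}

# Noise-free TF activity at trajectory positions t (cells-by-TF matrix),
# honouring the knockout genotype: module boost first, then ko_tf zeroed.
tf_activity <- function(t, tf_params, genotype = "wildtype",
                        ko_tf = NULL, ko_module = "neuron", ko_shift = 0.5) {
  if (nrow(tf_params) == 0) {
    return(matrix(0, length(t), 0))
  }
  a <- exp(-outer(t, tf_params$center, "-")^2 /
             rep(2 * tf_params$width^2, each = length(t)))
  colnames(a) <- tf_params$tf
  if (identical(genotype, "knockout")) {
    boost <- tf_params$module == ko_module
    a[, boost] <- a[, boost, drop = FALSE] + ko_shift
    a[, ko_tf] <- 0
  }
  a
}

# Resolve the knocked-out TF: explicit id (validated) or the first
# MG-module TF by default.
resolve_ko_tf <- function(config, tf_params) {
  if (!is.null(config$ko_tf)) {
    if (!config$ko_tf %in% tf_params$tf) {
      abort_bad_arg(sprintf("`ko_tf` '%s' is not a TF of the planted network",
                            config$ko_tf))
    }
    return(config$ko_tf)
  }
  mg <- tf_params$tf[tf_params$module == "MG"]
  if (length(mg) == 0) abort_bad_arg("no MG-module TF available as default `ko_tf`")
  mg[1]
}

#' Expected knockout-versus-wildtype expression delta per gene and bin
#'
#' Evaluates the simulator's noise-free mean model at the midpoints of
#' `n_bins` equal-width trajectory bins under both genotypes and returns
#' the per-gene log-mean difference (knockout minus wildtype). Baseline
#' expression cancels, so the result depends only on the planted network
#' and the knockout settings; it is the ground-truth counterpart of an
#' inferred condition-delta profile.
#'
#' @param config A [sim_config()].
#' @param network Optional [make_planted_network()] result for `config`.
#' @param n_bins Number of trajectory bins.
#'
#' @return A tibble (`gene`, `bin`, `true_delta`) in log-mean units.
#' @export
expected_condition_delta <- function(config, network = NULL, n_bins = 50) {
  stopifnot(inherits(config, "sim_config"))
  network <- network %||% make_planted_network(config)
  tf_params <- attr(network, "tf_params")
  gene_ids <- attr(network, "gene_ids")
  ko_tf <- resolve_ko_tf(config, tf_params)
  mid <- (seq_len(n_bins) - 0.5) / n_bins

  a_wt <- tf_activity(mid, tf_params)
  a_ko <- tf_activity(mid, tf_params, genotype = "knockout", ko_tf = ko_tf,
                      ko_module = config$ko_module, ko_shift = config$ko_shift)

  w <- signed_weight_matrix(network, gene_ids)
  targets <- setdiff(gene_ids, tf_params$tf)
  delta_t <- (a_ko - a_wt) %*% w[, targets, drop = FALSE]
  act_floor <- 0.02
  delta_tf <- log(a_ko + act_floor) - log(a_wt + act_floor)

  out <- cbind(delta_tf, delta_t)[, gene_ids, drop = FALSE]
  tibble::tibble(
    gene = rep(gene_ids, each = n_bins),
    bin = rep(seq_len(n_bins), length(gene_ids)),
    true_delta = as.vector(out)
  )
}

# TF-by-gene matrix of signed planted weights (zero where no edge).
signed_weight_matrix <- function(network, gene_ids) {
  tf_ids <- attr(network, "tf_params")$tf
  w <- matrix(0, length(tf_ids), length(gene_ids),
              dimnames = list(tf_ids, gene_ids))
  if (nrow(network) > 0) {
    w[cbind(network$tf, network$target)] <- network$sign * network$weight
  }
  w
}
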