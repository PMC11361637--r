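#' Configuration for the single-cell regeneration simulator
#'
#' Bundles and validates every parameter of the synthetic
#' Muller glia (MG) -> progenitor -> neuron trajectory simulator. The
#' simulator plants a known signed TF-to-target network, draws a latent
#' trajectory position per cell, and emits negative-binomial counts, so
#' that trajectory inference, network recovery and fate-bias scoring can
#' all be tested against known ground truth.
#'
#' @param n_cells Number of cells to simulate.
#' @param n_genes Total number of genes (transcription factors included).
#' @param n_tfs Number of transcription factors; must not exceed `n_genes`.
#' @param targets_per_tf Planted targets per TF. Targets are drawn from the
#'   non-TF genes, so `targets_per_tf <= n_genes - n_tfs` is required: a TF
#'   gene's expression is generated from its own activity curve and an edge
#'   into it could never manifest in the counts.
#' @param negative_edge_fraction Fraction of planted edges that repress
#'   their target, in `[0, 1]`.
#' @param edge_weight_range Length-2 positive range for planted edge weights
#'   (log-scale effect of one unit of TF activity on the target).
#' @param nb_dispersion Negative-binomial size parameter shared by all genes;
#'   larger is closer to Poisson. `Inf` draws Poisson counts.
#' @param library_size_mean Mean of the per-cell library-size factor
#'   (log-normal); `0` yields an all-zero matrix.
#' @param library_size_sd Standard deviation of log library-size factors.
#' @param ablation `"control"` (uniform trajectory occupancy) or `"ablated"`
#'   (early-shifted occupancy, Beta-distributed).
#' @param genotype `"wildtype"` or `"knockout"`.
#' @param ko_tf TF whose activity is set to zero under the knockout genotype;
#'   `NULL` selects the first MG-module TF (an early-activation factor).
#' @param ko_module Lineage module receiving a positive activity shift under
#'   the knockout genotype (default the neuron / RGC module, emulating a
#'   knockout that biases progenitors toward the ablated neuron fate).
#' @param ko_shift Size of the additive activity shift applied to
#'   `ko_module` TFs in knockouts.
#' @param ablation_time_shift Beta shape pair `(a, b)` for the ablated
#'   condition's trajectory positions; `a < b` enriches early pseudotime.
#' @param activity_noise_sd SD of per-cell log-normal noise on TF activity.
#'   This noise propagates from a TF to its targets and is what makes
#'   planted edges identifiable beyond the shared trajectory.
#' @param tf_scale Expression scale of TF genes (mean counts at peak
#'   activity, before library-size scaling).
#' @param base_expr_range Range of baseline target expression (natural
#'   scale) before TF regulation.
#' @param keep_means If `TRUE` the dataset carries the model mean matrix
#'   (`mu`), used by law-of-large-numbers checks.
#' @param seed Integer seed; the same config is bitwise reproducible.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 2000,
                       n_genes = 300,
                       n_tfs = 20,
                       targets_per_tf = 10,
                       negative_edge_fraction = 0.2,
                       edge_weight_range = c(0.3, 1.0),
                       nb_dispersion = 10,
                       library_size_mean = 5,
                       library_size_sd = 0.3,
                       ablation = c("control", "ablated"),
                       genotype = c("wildtype", "knockout"),
                       ko_tf = NULL,
                       ko_module = "neuron",
                       ko_shift = 0.3,
                       ablation_time_shift = c(1.5, 3),
                       activity_noise_sd = 0.4,
                       tf_scale = 20,
                       base_expr_range = c(0.5, 2),
                       keep_means = FALSE,
                       seed = 1L) {
  ablation <- match.arg(ablation)
  genotype <- match.arg(genotype)
  n_cells <- check_count(n_cells, "n_cells")
  n_genes <- check_count(n_genes, "n_genes", min = 1)
  n_tfs <- check_count(n_tfs, "n_tfs")
  targets_per_tf <- check_count(targets_per_tf, "targets_per_tf")
  check_proportion(negative_edge_fraction, "negative_edge_fraction")
  if (length(edge_weight_range) != 2 || any(edge_weight_range <= 0) ||
      diff(edge_weight_range) < 0) {
    abort_bad_arg("`edge_weight_range` must be an increasing pair of positive reals")
  }
  if (!(is.numeric(nb_dispersion) && length(nb_dispersion) == 1 && nb_dispersion > 0)) {
    abort_bad_arg("`nb_dispersion` must be a positive real (Inf allowed)")
  }
  check_positive(library_size_mean, "library_size_mean", strict = FALSE)
  check_positive(library_size_sd, "library_size_sd", strict = FALSE)
  if (n_tfs > n_genes) abort_bad_arg("`n_tfs` must not exceed `n_genes`")
  if (n_tfs > 0 && targets_per_tf > n_genes - n_tfs) {
    abort_bad_arg("infeasible edge count: `targets_per_tf` exceeds the non-TF gene pool")
  }
  if (length(ablation_time_shift) != 2 || any(ablation_time_shift <= 0)) {
    abort_bad_arg("`ablation_time_shift` must be a pair of positive Beta shapes")
  }
  check_positive(activity_noise_sd, "activity_noise_sd", strict = FALSE)
  check_positive(tf_scale, "tf_scale")
  structure(
    list(
      n_cells = n_cells, n_genes = n_genes, n_tfs = n_tfs,
      targets_per_tf = targets_per_tf,
      negative_edge_fraction = negative_edge_fraction,
      edge_weight_range = as.numeric(edge_weight_range),
      nb_dispersion = nb_dispersion,
      library_size_mean = library_size_mean,
      library_size_sd = library_size_sd,
      ablation = ablation, genotype = genotype,
      ko_tf = ko_tf, ko_module = ko_module, ko_shift = ko_shift,
      ablation_time_shift = as.numeric(ablation_time_shift),
      activity_noise_sd = activity_noise_sd,
      tf_scale = tf_scale,
      base_expr_range = as.numeric(base_expr_range),
      keep_means = isTRUE(keep_means),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Trajectory-position thresholds defining the three cell states.
state_thresholds <- c(MG = 1 / 3, progenitor = 2 / 3)

# Module activity-curve anchors over trajectory position t in [0, 1].
module_centers <- c(MG = 0.15, progenitor = 0.5, neuron = 0.85)

#' Configuration for the plate-reader well simulator
#'
#' Emulates a fluorescence plate-reader regeneration assay: one unablated
#' control arm and one treated arm whose mean is shifted by a fractional
#' effect, with Gaussian noise truncated at zero. The noise SD is
#' `cv * control_mean` in both arms, mirroring a screen designed around a
#' single SD measured on wild-type ablated larvae; the standardized effect
#' is therefore exactly `|effect_fraction| / cv`.
#'
#' @param n_wells_per_arm Wells per arm (`>= 2`).
#' @param control_mean Control-arm mean fluorescence (a.u.).
#' @param cv Coefficient of variation of well fluorescence (`>= 0`).
#' @param effect_fraction Signed fractional change of the treated-arm mean;
#'   the screen was designed to detect a 30 percent change (`-0.30`).
#' @param n_reps Number of independent replicate plates to draw.
#' @param seed Integer seed.
#'
#' @return A list of class `plate_sim_config`.
#' @export
plate_sim_config <- function(n_wells_per_arm = 8,
                             control_mean = 100,
                             cv = 0.213,
                             effect_fraction = -0.30,
                             n_reps = 1,
                             seed = 1L) {
  n_wells_per_arm <- check_count(n_wells_per_arm, "n_wells_per_arm", min = 2)
  check_positive(control_mean, "control_mean")
  check_positive(cv, "cv", strict = FALSE)
  if (!(is.numeric(effect_fraction) && length(effect_fraction) == 1 &&
        is.finite(effect_fraction) && effect_fraction > -1)) {
    abort_bad_arg("`effect_fraction` must be a finite real > -1")
  }
  n_reps <- check_count(n_reps, "n_reps", min = 1)
  structure(
    list(n_wells_per_arm = n_wells_per_arm, control_mean = control_mean,
         cv = cv, effect_fraction = effect_fraction, n_reps = n_reps,
         seed = as.integer(seed)),
    class = "plate_sim_config"
  )
}
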