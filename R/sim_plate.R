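#' Simulate plate-reader wells for one treated-versus-control comparison
#'
#' Draws one unablated-control arm at `control_mean` and one treated arm at
#' `control_mean * (1 + effect_fraction)`, both with Gaussian noise of SD
#' `cv * control_mean` truncated at zero (fluorescence cannot be negative).
#' A single noise SD is used for both arms because the screen this emulates
#' was designed around one SD measured on wild-type ablated larvae; the
#' standardized effect size is therefore `|effect_fraction| / cv`.
#'
#' @param config A [plate_sim_config()].
#'
#' @return A tibble of class `plate_sim` with columns `replicate`, `well`,
#'   `arm` (`"control"`/`"treated"`) and `fluorescence`.
#' @export
simulate_plate_reader <- function(config) {
  stopifnot(inherits(config, "plate_sim_config"))
  set.seed(config$seed)
  n <- config$n_wells_per_arm
  sd <- config$cv * config$control_mean
  treated_mean <- config$control_mean * (1 + config$effect_fraction)
  reps <- config$n_reps
  ctrl <- stats::rnorm(n * reps, config$control_mean, sd)
  trt <- stats::rnorm(n * reps, treated_mean, sd)
  out <- tibble::tibble(
    replicate = rep(rep(seq_len(reps), each = n), 2),
    arm = rep(c("control", "treated"), each = n * reps),
    well = paste0(rep(c("control", "treated"), each = n * reps),
                  sprintf("_%03d", rep(seq_len(n), 2 * reps))),
    fluorescence = pmax(0, c(ctrl, trt))
  )
  out <- dplyr::arrange(out, .data$replicate, .data$arm)
  class(out) <- c("plate_sim", class(out))
  out
}

#' Empirical power of the plate-reader comparison at a standardized effect
#'
#' Simulates `n_reps` replicate two-arm plates at standardized effect `d`
#' (via [simulate_plate_reader()]) and applies the two-sample z-test with
#' the known design SD -- the same normal-approximation test underlying
#' [min_sample_size()] -- returning the fraction of replicates rejecting at
#' level `alpha`.
#'
#' @param d Standardized effect size (mean difference over the design SD).
#' @param n_per_arm Wells per arm.
#' @param alpha Two-sided significance level.
#' @param n_reps Number of simulated screens.
#' @param cv Coefficient of variation used to realise `d` as a fractional
#'   mean change (`effect_fraction = -d * cv`).
#' @param seed Integer seed.
#'
#' @return Empirical power (a single proportion).
#' @export
#' @examples
#' plate_power(d = 1.41, n_per_arm = 8, n_reps = 500, seed = 2)
plate_power <- function(d, n_per_arm = 8, alpha = 0.05, n_reps = 10000,
                        cv = 0.2, seed = 1L) {
  check_positive(d, "d")
  cfg <- plate_sim_config(
    n_wells_per_arm = n_per_arm, control_mean = 1, cv = cv,
    effect_fraction = -d * cv, n_reps = n_reps, seed = seed
  )
  sim <- simulate_plate_reader(cfg)
  sd_design <- cv * cfg$control_mean
  m <- tapply(sim$fluorescence, list(sim$replicate, sim$arm), mean)
  z <- (m[, "control"] - m[, "treated"]) / (sd_design * sqrt(2 / n_per_arm))
  mean(abs(z) > stats::qnorm(1 - alpha / 2))
}

#' Simulate a multi-gene crispant plate-reader screen
#'
#' Builds a well table in the screen's native layout: unablated wild-type
#' control wells (the normalization reference), ablated wild-type reference
#' wells at `ablated_fraction` of the unablated level (the regeneration
#' level reached by wild-type larvae at the assay endpoint), and ablated
#' crispant wells per gene whose means are shifted by the gene's effect
#' fraction. All ablated wells share the SD `cv * ablated_fraction *
#' unablated_mean`; unablated wells use `cv * unablated_mean`.
#'
#' @param gene_effects Named numeric vector: per-gene signed fractional
#'   change of the ablated mean (0 = null gene).
#' @param n_wells_per_gene Wells per crispant gene.
#' @param n_reference_wells Ablated wild-type wells.
#' @param n_unablated_wells Unablated wild-type control wells.
#' @param unablated_mean Mean fluorescence of unablated controls (a.u.).
#' @param ablated_fraction Wild-type ablated level as a fraction of the
#'   unablated level (default 0.32, the regenerated fraction at endpoint).
#' @param cv Coefficient of variation.
#' @param plate Plate/batch identifier.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `well`, `gene`, `arm`
#'   (`"unablated_control"`/`"ablated"`), `genotype`
#'   (`"wildtype"`/`"crispant"`), `fluorescence`, `plate`.
#' @export
simulate_crispant_screen <- function(gene_effects,
                                     n_wells_per_gene = 16,
                                     n_reference_wells = 48,
                                     n_unablated_wells = 12,
                                     unablated_mean = 1000,
                                     ablated_fraction = 0.32,
                                     cv = 0.213,
                                     plate = "plate1",
                                     seed = 1L) {
  if (is.null(names(gene_effects)) || anyDuplicated(names(gene_effects))) {
    abort_bad_arg("`gene_effects` must be a named vector with unique gene names")
  }
  check_proportion(ablated_fraction, "ablated_fraction")
  set.seed(seed)
  abl_mean <- unablated_mean * ablated_fraction
  abl_sd <- cv * abl_mean
  rows <- list(
    tibble::tibble(
      gene = "control", arm = "unablated_control", genotype = "wildtype",
      fluorescence = pmax(0, stats::rnorm(n_unablated_wells, unablated_mean,
                                          cv * unablated_mean))
    ),
    tibble::tibble(
      gene = "control", arm = "ablated", genotype = "wildtype",
      fluorescence = pmax(0, stats::rnorm(n_reference_wells, abl_mean, abl_sd))
    )
  )
  for (g in names(gene_effects)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene = g, arm = "ablated", genotype = "crispant",
      fluorescence = pmax(0, stats::rnorm(
        n_wells_per_gene, abl_mean * (1 + gene_effects[[g]]), abl_sd))
    )
  }
  out <- dplyr::bind_rows(rows)
  out$well <- sprintf("%s_w%04d", plate, seq_len(nrow(out)))
  out$plate <- plate
  dplyr::select(out, "well", "gene", "arm", "genotype", "fluorescence", "plate")
}
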