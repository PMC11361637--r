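#' Pipeline configuration
#'
#' One object drives an end-to-end run: simulate (or load) data, QC,
#' trajectory, condition deltas, GRN construction, fate-bias scoring and
#' the crispant screen. The global `seed` is propagated to every
#' sub-configuration that was not supplied explicitly.
#'
#' @param seed Global integer seed.
#' @param sim A [sim_config()] for the single-cell simulator.
#' @param qc A [qc_params()].
#' @param trajectory A [trajectory_params()].
#' @param grn A [grn_params()].
#' @param markers_deg A [deg_params()] for marker derivation.
#' @param condition_deg A [deg_params()] for the progenitor knockout DEGs.
#' @param screen A [screen_params()].
#' @param pattern_k Number of expression patterns for profile clustering.
#' @param screen_gene_effects Named vector of per-gene fractional effects
#'   for the simulated crispant screen (`NULL` builds a default family of
#'   91 genes: 11 enhanced, 7 inhibited, 73 null, mirroring a screen with
#'   18 true hits).
#' @param marker_file Optional TSV (`cell_type`, `gene`) replacing derived
#'   marker sets.
#' @param plate_file Optional CSV of plate-reader wells replacing the
#'   simulated screen.
#' @param stages Character vector of stages to run, a subset of
#'   `c("density", "delta", "grn", "fate_bias", "screen")`.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = NULL, qc = qc_params(),
                            trajectory = NULL, grn = NULL,
                            markers_deg = deg_params("celltype_markers"),
                            condition_deg = deg_params("condition"),
                            screen = screen_params(),
                            pattern_k = 11,
                            screen_gene_effects = NULL,
                            marker_file = NULL, plate_file = NULL,
                            stages = c("density", "delta", "grn",
                                       "fate_bias", "screen")) {
  seed <- as.integer(seed)
  cfg <- list(
    seed = seed,
    sim = sim %||% sim_config(seed = seed),
    qc = qc,
    trajectory = trajectory %||% trajectory_params(seed = seed),
    grn = grn %||% grn_params(seed = seed),
    markers_deg = markers_deg,
    condition_deg = condition_deg,
    screen = screen,
    pattern_k = check_count(pattern_k, "pattern_k", min = 1),
    screen_gene_effects = screen_gene_effects %||%
      default_screen_effects(screen$design_effect_fraction),
    marker_file = marker_file,
    plate_file = plate_file,
    stages = stages
  )
  structure(cfg, class = "pipeline_config")
}

# A 91-gene screen family with 11 enhanced, 7 inhibited and 73 null genes.
default_screen_effects <- function(effect = 0.30) {
  eff <- c(rep(effect, 11), rep(-effect, 7), rep(0, 73))
  names(eff) <- sprintf("gene%02d", seq_along(eff))
  eff
}

validate_pipeline_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  bad <- setdiff(config$stages,
                 c("density", "delta", "grn", "fate_bias", "screen"))
  if (length(bad) > 0) {
    abort_bad_arg(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  for (f in c("marker_file", "plate_file")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      abort_bad_arg(sprintf("%s not found: %s", f, config[[f]]))
    }
  }
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Executes, in fixed order: simulation of a genotype pair (wild type vs
#' knockout, both ablated) and an ablation pair (control vs ablated), QC
#' and normalization, joint pseudotime, condition density, 50-bin delta
#' profiles with pattern clustering, GRN construction, marker derivation
#' and fate-bias scoring, and the simulated (or supplied) crispant screen.
#' The configuration is validated before any stage runs; a failing stage
#' aborts with its name. With the same configuration and seed, all outputs
#' are identical between runs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when given, each stage's tables are
#'   written as TSV/CSV before the next stage begins.
#'
#' @return A list of class `pipeline_result` with the per-stage results and
#'   a `report` tibble (stage, records, seconds).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  validate_pipeline_config(config)
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  report <- list()
  tick <- function(stage, records, t0) {
    report[[length(report) + 1]] <<- tibble::tibble(
      stage = stage, records = as.integer(records),
      seconds = round(as.numeric(Sys.time()) - t0, 2))
  }
  run_stage <- function(stage, fun) {
    t0 <- as.numeric(Sys.time())
    out <- tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    out
  }

  # --- simulate ---------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  ds <- run_stage("simulate", function()
    simulate_condition_pair(config$sim, vary = "genotype"))
  tick("simulate", ncol(ds$counts), t0)
  res$dataset <- ds
  if (!is.null(outdir)) write_dataset(ds, file.path(outdir, "dataset"))

  # --- preprocess -------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  pre <- run_stage("preprocess", function() {
    counts <- qc_filter(ds$counts, config$qc)
    list(counts = counts, norm = normalize_log(counts))
  })
  cells_kept <- colnames(pre$counts)
  info <- ds$cells[match(cells_kept, ds$cells$cell_id), ]
  tick("preprocess", ncol(pre$counts), t0)
  res$counts <- pre$counts
  res$norm <- pre$norm

  # --- trajectory -------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  pt <- run_stage("trajectory", function()
    fit_pseudotime(pre$norm, stats::setNames(info$state, info$cell_id),
                   config$trajectory))
  tick("trajectory", nrow(pt$cells), t0)
  res$pseudotime <- pt
  if (!is.null(outdir)) {
    readr::write_tsv(pt$cells, file.path(outdir, "pseudotime.tsv"))
  }

  if ("density" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    dens <- run_stage("density", function() {
      pair <- simulate_condition_pair(config$sim, vary = "ablation")
      counts <- qc_filter(pair$counts, config$qc)
      norm <- normalize_log(counts)
      cinfo <- pair$cells[match(colnames(counts), pair$cells$cell_id), ]
      pt_abl <- fit_pseudotime(norm, stats::setNames(cinfo$state, cinfo$cell_id),
                               config$trajectory)
      condition_density(pt_abl, stats::setNames(cinfo$ablation, cinfo$cell_id),
                        conditions = c("ablated", "control"))
    })
    tick("density", nrow(dens), t0)
    res$density <- dens
    if (!is.null(outdir)) {
      readr::write_tsv(tibble::as_tibble(dens), file.path(outdir, "density.tsv"))
    }
  }

  if ("delta" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    delta <- run_stage("delta", function()
      bin_and_delta(pre$norm, pt, stats::setNames(info$genotype, info$cell_id),
                    config$trajectory,
                    conditions = c("wildtype", "knockout")))
    patterns <- run_stage("patterns", function()
      cluster_profiles(delta, k = min(config$pattern_k, nrow(delta$delta)),
                       seed = config$seed))
    tick("delta", nrow(delta$delta), t0)
    res$delta <- delta
    res$patterns <- patterns
    if (!is.null(outdir)) {
      readr::write_tsv(tidy(delta), file.path(outdir, "delta_profiles.tsv"))
      readr::write_tsv(patterns, file.path(outdir, "patterns.tsv"))
    }
  }

  if ("grn" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    grn <- run_stage("grn", function() {
      tfs <- intersect(attr(ds$network, "tf_params")$tf, rownames(pre$norm))
      build_grn(pre$norm, tfs, pre$counts,
                stats::setNames(info$state, info$cell_id), config$grn)
    })
    tick("grn", nrow(grn), t0)
    res$grn <- grn
    if (!is.null(outdir)) {
      readr::write_tsv(tibble::as_tibble(grn), file.path(outdir, "grn_edges.tsv"))
    }
  }

  if ("fate_bias" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    fb <- run_stage("fate_bias", function() {
      markers <- if (!is.null(config$marker_file)) {
        marker_sets(utils::read.delim(config$marker_file), rownames(pre$norm))
      } else {
        derive_marker_sets(pre$norm, info$state, config$markers_deg)
      }
      prog <- info$cell_id[info$state == "progenitor"]
      degs <- rank_sum_markers(pre$norm[, prog, drop = FALSE],
                               info$genotype[info$state == "progenitor"],
                               config$condition_deg,
                               groups = "knockout", reference = "wildtype")
      bias <- lineage_bias_tally(degs, markers)
      spec <- if (!is.null(res$grn)) tf_specificity(res$grn, markers) else NULL
      list(markers = markers, degs = degs, bias = bias, specificity = spec)
    })
    tick("fate_bias", nrow(fb$bias), t0)
    res$markers <- fb$markers
    res$progenitor_degs <- fb$degs
    res$lineage_bias <- fb$bias
    res$specificity <- fb$specificity
    if (!is.null(outdir)) {
      readr::write_tsv(fb$bias, file.path(outdir, "lineage_bias.tsv"))
      if (!is.null(fb$specificity)) {
        readr::write_tsv(tibble::as_tibble(fb$specificity),
                         file.path(outdir, "tf_specificity.tsv"))
      }
    }
  }

  if ("screen" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    screen <- run_stage("screen", function() {
      wells <- if (!is.null(config$plate_file)) {
        read_plate_csv(config$plate_file)
      } else {
        simulate_crispant_screen(config$screen_gene_effects,
                                 seed = child_seed(config$seed, 11))
      }
      screen_test(normalize_relative_yfp(wells), config$screen)
    })
    tick("screen", nrow(screen), t0)
    res$screen <- screen
    if (!is.null(outdir)) {
      readr::write_tsv(tibble::as_tibble(screen), file.path(outdir, "screen_results.tsv"))
    }
  }

  res$report <- dplyr::bind_rows(report)
  if (!is.null(outdir)) {
    readr::write_tsv(res$report, file.path(outdir, "run_report.tsv"))
  }
  structure(res, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$report)
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys `seed`, `pattern_k`, `marker_file`, `plate_file`,
#' `stages` and per-module sections `sim`, `qc`, `trajectory`, `grn`,
#' `screen` (each a mapping of the corresponding constructor's arguments)
#' are recognised; anything omitted falls back to the defaults.
#'
#' @param path YAML file path.
#'
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_bad_arg(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  seed <- as.integer(y$seed %||% 1L)
  build <- function(ctor, args, seeded = TRUE) {
    args <- args %||% list()
    if (seeded && is.null(args$seed)) args$seed <- seed
    do.call(ctor, args)
  }
  pipeline_config(
    seed = seed,
    sim = build(sim_config, y$sim),
    qc = build(qc_params, y$qc, seeded = FALSE),
    trajectory = build(trajectory_params, y$trajectory),
    grn = build(grn_params, y$grn),
    screen = build(screen_params, y$screen, seeded = FALSE),
    pattern_k = y$pattern_k %||% 11,
    screen_gene_effects = if (!is.null(y$screen_gene_effects))
      unlist(y$screen_gene_effects) else NULL,
    marker_file = y$marker_file,
    plate_file = y$plate_file,
    stages = y$stages %||% c("density", "delta", "grn", "fate_bias", "screen")
  )
}
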