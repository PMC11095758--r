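#' Pipeline configuration
#'
#' One flat, auditable record of every analysis constant: tile edge, top
#' fraction, inclusion fraction, cut-point mode, consensus policy and test
#' threshold. Written back out with every run's manifest.
#'
#' @param pixel_size_um Micrometres per pixel (> 0).
#' @param tile_size_um Tile edge in micrometres, default 12.
#' @param top_fraction Top fraction for the core statistic, default 0.10.
#' @param inclusion_fraction Minimum in-mask tile coverage, default 0.5.
#' @param cut_point_mode `"derive"` (per-class minima from the data) or
#'   `"fixed"` (use `fixed_cuts`, e.g. previously published thresholds).
#' @param fixed_cuts A [cut_points()] object when `cut_point_mode = "fixed"`.
#' @param consensus_policy Passed to [consensus_dab()].
#' @param alpha Variance-gate and significance threshold, default 0.05.
#' @param seed Integer seed recorded in the manifest.
#' @return List of class `run_config`.
#' @export
run_config <- function(pixel_size_um = 0.46, tile_size_um = 12,
                       top_fraction = 0.10, inclusion_fraction = 0.5,
                       cut_point_mode = c("derive", "fixed"),
                       fixed_cuts = NULL,
                       consensus_policy = c("higher", "p1", "p2"),
                       alpha = 0.05, seed = 1L) {
  cut_point_mode <- match.arg(cut_point_mode)
  consensus_policy <- match.arg(consensus_policy)
  for (f in c(pixel_size_um, tile_size_um, top_fraction, inclusion_fraction,
              alpha)) {
    if (!is.numeric(f) || length(f) != 1L || is.na(f) || f <= 0) {
      stop("all numeric configuration fields must be single positive numbers")
    }
  }
  if (cut_point_mode == "fixed" && !inherits(fixed_cuts, "cut_points")) {
    stop("cut_point_mode \"fixed\" requires fixed_cuts = cut_points(c1, c2, c3)")
  }
  structure(
    list(pixel_size_um = pixel_size_um, tile_size_um = tile_size_um,
         top_fraction = top_fraction, inclusion_fraction = inclusion_fraction,
         cut_point_mode = cut_point_mode, fixed_cuts = fixed_cuts,
         consensus_policy = consensus_policy, alpha = alpha,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full scoring pipeline on an in-memory cohort
#'
#' Orchestrates consensus -> QC exclusion -> per-core PID scoring ->
#' cut-point classification and ultra-low flagging -> concordance reporting,
#' and (optionally) writes every intermediate artifact plus a manifest.
#' Identical inputs and configuration give identical outputs.
#'
#' @param cohort Data frame of core records (`core_id`, `exclusion_reason`,
#'   DAB readings, `is_negative_control`).
#' @param cores Named list keyed by core ID, each `list(image, mask)` as
#'   produced by [simulate_cohort()] (or loaded from disk).
#' @param config A [run_config()].
#' @param out_dir Optional output directory for `scores.csv`,
#'   `classified.csv`, `report.json` and `manifest.json`.
#' @return List: `records` (classified results), `cuts`, `ncs`
#'   (negative-control stats or `NULL`), `report` (regression, contingency,
#'   adjacent-class comparisons), `exclusion_summary`, `manifest`.
#' @export
run_pipeline <- function(cohort, cores, config = run_config(),
                         out_dir = NULL) {
  stopifnot(is.data.frame(cohort), inherits(config, "run_config"))

  # consensus stage
  if (!"dab_consensus" %in% names(cohort)) {
    if (!all(c("dab_score_p1", "dab_score_p2") %in% names(cohort))) {
      stop("consensus stage: cohort needs dab_consensus or dab_score_p1/p2")
    }
    cohort$dab_consensus <- consensus_dab(cohort$dab_score_p1,
                                          cohort$dab_score_p2,
                                          config$consensus_policy)
  }

  # qc stage
  qc <- apply_exclusions(cohort)
  if (nrow(qc$analyzable) == 0L) {
    stop("scoring stage: no analyzable cores remain after exclusion; ",
         "check the cohort's exclusion_reason annotations")
  }

  # scoring stage (analyzable cores and negative controls)
  to_score <- rbind(qc$analyzable, qc$negative_controls)
  to_score$pid_value <- NA_real_
  to_score$n_tiles <- NA_integer_
  for (i in seq_len(nrow(to_score))) {
    id <- to_score$core_id[i]
    cm <- cores[[id]]
    if (is.null(cm)) stop("scoring stage: no image/mask for core ", id)
    s <- tryCatch(
      score_core(cm$image, cm$mask,
                 pixel_size_um = config$pixel_size_um,
                 tile_size_um = config$tile_size_um,
                 fraction = config$top_fraction,
                 inclusion_fraction = config$inclusion_fraction),
      error = function(e) stop("scoring stage: core ", id, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    to_score$pid_value[i] <- s$pid_value
    to_score$n_tiles[i] <- s$n_tiles
  }
  is_nc <- to_score$is_negative_control %in% TRUE
  scored <- to_score[!is_nc, , drop = FALSE]
  nc_scored <- to_score[is_nc, , drop = FALSE]

  # classification stage
  cuts <- if (config$cut_point_mode == "fixed") {
    config$fixed_cuts
  } else {
    tryCatch(derive_cut_points(scored),
             error = function(e) stop("classification stage: ",
                                      conditionMessage(e), call. = FALSE))
  }
  scored$pid_score <- classify_pid(scored$pid_value, cuts)
  ncs <- NULL
  if (nrow(nc_scored) > 0L) {
    ncs <- negative_control_mean(nc_scored)
    scored <- flag_ultra_low(scored, cuts, ncs)
  } else {
    scored$ultra_low_flag <- NA
  }

  # concordance stage
  report <- list(
    regression = fit_score_regression(scored),
    contingency = contingency(scored),
    adjacent_comparisons = adjacent_class_comparisons(scored, config$alpha)
  )

  manifest <- list(
    package = "pidquant",
    version = as.character(utils::packageVersion("pidquant")),
    config = unclass(config),
    stage_counts = list(
      input = qc$summary$n_input,
      excluded = qc$summary$excluded_total,
      analyzable = qc$summary$analyzable,
      scored = nrow(scored),
      negative_controls = nrow(nc_scored)
    ),
    cut_points = unclass(cuts),
    negative_control_mean = if (is.null(ncs)) NULL else ncs$mean_value
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(to_score[, c("core_id", "n_tiles", "pid_value")],
                  file.path(out_dir, "scores.csv"))
    write_results(scored, file.path(out_dir, "classified.csv"))
    tab <- report$contingency$table
    cfg_json <- unclass(config)
    if (!is.null(cfg_json$fixed_cuts)) {
      cfg_json$fixed_cuts <- unclass(cfg_json$fixed_cuts)
    }
    jsonlite::write_json(
      list(regression = unclass(report$regression),
           contingency = list(table = matrix(as.integer(tab), nrow(tab),
                                             dimnames = dimnames(tab)),
                              pv_percent = report$contingency$pv_percent,
                              n = report$contingency$n),
           adjacent_comparisons = lapply(report$adjacent_comparisons, unclass),
           config = cfg_json),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    manifest_json <- manifest
    manifest_json$config <- cfg_json
    jsonlite::write_json(manifest_json, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(records = scored, negative_controls = nc_scored, cuts = cuts,
       ncs = ncs, report = report, exclusion_summary = qc$summary,
       manifest = manifest)
}

#' Simulate a cohort and run the pipeline end to end
#'
#' Convenience composition of [simulate_cohort()] and [run_pipeline()] under
#' one seed; the pipeline's pixel size is taken from the simulation
#' parameters.
#'
#' @inheritParams simulate_cohort
#' @param config A [run_config()]; its `pixel_size_um` and `seed` are
#'   overridden to match the simulation.
#' @param out_dir Optional artifact directory, see [run_pipeline()].
#' @return As [run_pipeline()], plus `truth` (the generator's ground truth).
#' @export
run_pipeline_sim <- function(params, class_counts, n_negative_controls = 0L,
                             exclusion_plan = list(), seed = params$seed,
                             config = run_config(), out_dir = NULL) {
  config$pixel_size_um <- params$pixel_size_um
  config$seed <- as.integer(seed)
  sim <- simulate_cohort(params, class_counts, n_negative_controls,
                         exclusion_plan, seed = seed)
  res <- run_pipeline(sim$truth, sim$cores, config, out_dir)
  res$truth <- sim$truth
  res
}
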