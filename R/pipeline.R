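# End-to-end orchestration: simulate -> QC -> deconvolve -> delta-beta ->
# sweep -> finalize/score -> evaluate -> decompose -> contaminate.

#' Configure an end-to-end synthetic pipeline run
#'
#' All thresholds and grids of the individual stages in one validated list.
#' A single global `seed` is expanded into per-stage seeds (seed + stage
#' index) so stages can be rerun in isolation.
#'
#' @param n_cpgs,n_cases,n_controls Cohort dimensions.
#' @param n_informative Number of CpGs carrying the planted epithelial
#'   effect (0 for a null cohort).
#' @param effect_delta Planted epithelial delta-beta.
#' @param ic_range Range of the uniform immune-fraction model.
#' @param noise_sd Measurement noise SD on the beta scale.
#' @param detection_fail_rate Probe detection-failure rate.
#' @param marker_frac Marker fraction per cell type in the profiles.
#' @param n_ref_per_type Pure reference samples per cell type.
#' @param p_thresh,sample_fail_frac,probe_fail_frac,impute_k QC parameters.
#' @param blocklists Named list of probe-id vectors to exclude.
#' @param panel_delta_min,panel_p_adj_max Reference-panel thresholds.
#' @param train_frac Training fraction of the discovery set, in (0, 1).
#' @param penalty `"ridge"` or `"lasso"`.
#' @param n_grid Index-size sweep grid.
#' @param folds Cross-validation folds.
#' @param decompose_n_cpgs Index CpGs (by |weight|) given a beta-mixture
#'   variance decomposition; 0 disables the stage.
#' @param origin_ratio Variance-ratio threshold for origin classification.
#' @param rho_grid,target_shift_sd Contamination-simulation parameters;
#'   `NULL` `rho_grid` disables the stage.
#' @param contamination_ic_max Controls with IC below this are mixed.
#' @param write_matrices Write the (large) beta matrices as TSV.
#' @param seed Global seed.
#' @return A validated list of class `wid_pipeline_config`.
#' @export
pipeline_config <- function(n_cpgs = 10000, n_cases = 200, n_controls = 400,
                            n_informative = 500, effect_delta = 0.1,
                            ic_range = c(0, 0.8), noise_sd = 0.02,
                            detection_fail_rate = 0.001,
                            marker_frac = 0.02, n_ref_per_type = 20,
                            p_thresh = 0.01, sample_fail_frac = 0.10,
                            probe_fail_frac = 0.10, impute_k = 10,
                            blocklists = list(),
                            panel_delta_min = 0.5, panel_p_adj_max = 0.01,
                            train_frac = 2 / 3,
                            penalty = "ridge",
                            n_grid = c(100, 500, 2000),
                            folds = 10,
                            decompose_n_cpgs = 100, origin_ratio = 2,
                            rho_grid = seq(0, 1, by = 0.05),
                            target_shift_sd = 1.25,
                            contamination_ic_max = 0.5,
                            write_matrices = FALSE,
                            seed = 1L) {
  cfg <- as.list(environment())
  check_scalar_number(cfg$n_cpgs, "n_cpgs", lower = 10)
  check_scalar_number(cfg$n_cases, "n_cases", lower = 10)
  check_scalar_number(cfg$n_controls, "n_controls", lower = 10)
  check_scalar_number(cfg$n_informative, "n_informative", 0, cfg$n_cpgs)
  check_scalar_number(cfg$effect_delta, "effect_delta", -1, 1)
  check_scalar_number(cfg$noise_sd, "noise_sd", lower = 0)
  check_scalar_number(cfg$detection_fail_rate, "detection_fail_rate", 0, 1)
  check_scalar_number(cfg$train_frac, "train_frac")
  if (cfg$train_frac <= 0 || cfg$train_frac >= 1) {
    abort("`train_frac` must lie strictly inside (0, 1).")
  }
  cfg$penalty <- match.arg(cfg$penalty, c("ridge", "lasso"))
  if (!length(cfg$n_grid)) abort("`n_grid` is empty.")
  if (max(cfg$n_grid) > cfg$n_cpgs) abort("`n_grid` exceeds `n_cpgs`.")
  if (max(cfg$n_grid) > 30000) abort("index sizes above 30000 are not swept.")
  check_scalar_number(cfg$n_ref_per_type, "n_ref_per_type", lower = 2)
  check_scalar_number(cfg$seed, "seed")
  structure(cfg, class = "wid_pipeline_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes every stage in order, writes each stage's tabular outputs plus a
#' manifest (parameters, per-stage seeds, output-file checksums) into
#' `out_dir`, and returns the summary. Rerunning with the same config
#' reproduces all numeric outputs exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the summary (validation AUC and CI,
#'   optimal index size, quartile table, origin-class fractions, rho*),
#'   the fitted `wid_index_model`, and stage objects.
#' @export
run_pipeline <- function(config, out_dir = tempfile("widoc_run_")) {
  if (!inherits(config, "wid_pipeline_config")) {
    abort("`config` must be built with pipeline_config().")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- setNames(vapply(1:9, derive_seed, integer(1), seed = config$seed),
                    c("simulate", "qc", "deconv", "delta", "sweep",
                      "finalize", "evaluate", "decompose", "contaminate"))

  # -- simulate ----------------------------------------------------------
  sim <- pipeline_stage("simulate", {
    profiles <- generate_profiles(config$n_cpgs, seed = seeds[["simulate"]],
                                  marker_frac = config$marker_frac)
    effect <- NULL
    if (config$n_informative > 0) {
      non_marker <- profiles$profiles |>
        dplyr::filter(.data$cell_type == "epithelial", is.na(.data$marker_for))
      ok <- beta_mean(non_marker$a, non_marker$b) + config$effect_delta
      pool <- non_marker$cpg_id[ok > 0.02 & ok < 0.98]
      effect <- effect_spec(head(pool, config$n_informative),
                            config$effect_delta)
    }
    cohort <- generate_cohort(
      profiles, config$n_cases, config$n_controls, effect = effect,
      fractions = fraction_model("ic_uniform", ic_range = config$ic_range),
      noise_sd = config$noise_sd,
      detection_fail_rate = config$detection_fail_rate,
      seed = derive_seed(seeds[["simulate"]], 1))
    ref <- generate_reference_samples(profiles, config$n_ref_per_type,
                                      seed = derive_seed(seeds[["simulate"]], 2),
                                      noise_sd = config$noise_sd,
                                      effect = effect)
    list(profiles = profiles, cohort = cohort, ref = ref, effect = effect)
  })
  readr::write_csv(sim$cohort$sheet, file.path(out_dir, "sample_sheet.csv"))
  if (config$write_matrices) {
    write_beta_tsv(sim$cohort$beta, file.path(out_dir, "beta_raw.tsv"))
  }

  # -- qc ----------------------------------------------------------------
  qc <- pipeline_stage("qc", {
    out <- qc_filter_impute(sim$cohort$beta, sim$cohort$detection_p,
                            p_thresh = config$p_thresh,
                            sample_fail_frac = config$sample_fail_frac,
                            probe_fail_frac = config$probe_fail_frac,
                            k = config$impute_k)
    out$beta <- exclude_probes(out$beta, config$blocklists)
    out
  })
  jsonlite::write_json(
    list(removed_samples = qc$report$removed_samples,
         removed_probes = qc$report$removed_probes,
         imputed_count = qc$report$imputed_count,
         not_applied = qc$report$not_applied),
    file.path(out_dir, "qc_report.json"), auto_unbox = TRUE, digits = NA)
  sheet <- sim$cohort$sheet |>
    dplyr::filter(.data$sample_id %in% colnames(qc$beta))

  # -- deconvolution -----------------------------------------------------
  deconv <- pipeline_stage("deconv", {
    panel <- build_reference_panel(sim$ref$beta, sim$ref$labels,
                                   p_adj_max = config$panel_p_adj_max,
                                   delta_min = config$panel_delta_min)
    fractions <- estimate_fractions(qc$beta, panel)
    fractions <- correct_tumour_fraction(
      fractions, sheet$sample_id[sheet$type == "control"])
    list(panel = panel, fractions = fractions)
  })
  readr::write_csv(deconv$fractions, file.path(out_dir, "cell_fractions.csv"))

  # -- split + delta-beta ------------------------------------------------
  delta <- pipeline_stage("delta", {
    split <- split_discovery(sheet, train_frac = config$train_frac,
                             seed = seeds[["delta"]])
    db <- estimate_delta_betas(qc$beta[, split$train, drop = FALSE],
                               deconv$fractions, sheet)
    list(split = split, records = db,
         ranked = rank_cpgs(db, mode = "epithelial"))
  })
  readr::write_tsv(delta$records, file.path(out_dir, "delta_betas.tsv"))

  train_ids <- delta$split$train
  val_ids <- delta$split$validation
  lab <- setNames(sheet$type, sheet$sample_id)

  # -- sweep -------------------------------------------------------------
  sweep <- pipeline_stage("sweep", {
    sweep_index_size(qc$beta[, train_ids, drop = FALSE], lab[train_ids],
                     qc$beta[, val_ids, drop = FALSE], lab[val_ids],
                     delta$ranked, n_grid = config$n_grid,
                     penalty = config$penalty, folds = config$folds,
                     seed = seeds[["sweep"]])
  })
  readr::write_csv(tidy(sweep), file.path(out_dir, "sweep.csv"))
  best <- glance(sweep)

  # -- finalize + score --------------------------------------------------
  model <- pipeline_stage("finalize", {
    finalize_index(qc$beta, lab[colnames(qc$beta)], delta$ranked,
                   n = best$optimal_n, penalty = config$penalty,
                   lambda = best$lambda, seed = seeds[["finalize"]])
  })
  write_index_model(model, file.path(out_dir, "index_model.json"))
  scores <- compute_index(model, qc$beta)
  readr::write_csv(scores, file.path(out_dir, "index_scores.csv"))

  # -- evaluate ----------------------------------------------------------
  evaluation <- pipeline_stage("evaluate", {
    val_scores <- scores$index[match(val_ids, scores$sample_id)]
    val_lab <- lab[val_ids]
    auc <- roc_auc_ci(val_scores, val_lab)
    qt <- quartile_odds_table(val_scores, val_lab,
                              val_scores[val_lab == "control"])
    list(auc_sweep = best$auc, auc_refit = auc, quartiles = qt)
  })
  readr::write_csv(tibble::as_tibble(evaluation$quartiles),
                   file.path(out_dir, "quartile_table.csv"))

  # -- decompose ---------------------------------------------------------
  decompose <- NULL
  if (config$decompose_n_cpgs > 0) {
    decompose <- pipeline_stage("decompose", {
      top <- model$cpgs[order(-abs(model$weights))]
      top <- head(top, config$decompose_n_cpgs)
      fit_beta_mixtures(qc$beta[top, , drop = FALSE], deconv$fractions,
                        ratio = config$origin_ratio)
    })
    readr::write_tsv(decompose, file.path(out_dir, "variance_decomposition.tsv"))
  }

  # -- contaminate -------------------------------------------------------
  contamination <- NULL
  if (!is.null(config$rho_grid)) {
    contamination <- pipeline_stage("contaminate", {
      tumour_profile <- rowMeans(
        sim$ref$beta[, sim$ref$labels$cell_type == "tumour", drop = FALSE])
      ctrl_ids <- intersect(
        val_ids,
        deconv$fractions$sample_id[deconv$fractions$ic < config$contamination_ic_max])
      ctrl_ids <- ctrl_ids[lab[ctrl_ids] == "control"]
      contamination_shift_curve(model, qc$beta[, ctrl_ids, drop = FALSE],
                                tumour_profile, rho_grid = config$rho_grid,
                                target_shift_sd = config$target_shift_sd)
    })
    readr::write_csv(tibble::as_tibble(contamination),
                     file.path(out_dir, "contamination_curve.csv"))
  }

  origin_fractions <- if (!is.null(decompose)) {
    as.list(table(factor(decompose$origin_class,
                         c("epithelial", "shared", "immune"))) /
              nrow(decompose))
  } else NULL

  summary <- list(
    seed = config$seed,
    n_cpgs_retained = nrow(qc$beta),
    n_samples_retained = ncol(qc$beta),
    optimal_n = best$optimal_n,
    validation_auc = best$auc,
    validation_auc_refit = evaluation$auc_refit$auc,
    validation_auc_ci = c(evaluation$auc_refit$conf_lo,
                          evaluation$auc_refit$conf_hi),
    quartile_or = setNames(evaluation$quartiles$or,
                           evaluation$quartiles$quartile),
    origin_class_fractions = origin_fractions,
    rho_star = if (!is.null(contamination)) attr(contamination, "rho_star") else NULL,
    stage_seeds = as.list(seeds)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    config = unclass(config)[setdiff(names(config), "blocklists")],
    stage_seeds = as.list(seeds),
    outputs = as.list(tools::md5sum(setdiff(files, file.path(out_dir, "manifest.json"))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(summary = summary, model = model, sweep = sweep,
                 delta = delta$records, fractions = deconv$fractions,
                 quartiles = evaluation$quartiles,
                 decomposition = decompose, contamination = contamination,
                 qc_report = qc$report, out_dir = out_dir))
}
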