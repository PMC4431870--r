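established_markers <- function() {
  c("age", "sex_male", "current_smoker", "bmi", "sbp", "dbp",
    "diabetes_duration", "ln_uacr", "hdl", "ldl", "hba1c",
    "med_raas", "med_insulin", "med_oral", "egfr0")
}

#' Pipeline run configuration
#'
#' @param gen a [gen_config()] used to simulate the cohort (ignored when
#'   `cohort` is supplied).
#' @param cohort optional pre-built `cohort_table`.
#' @param out_dir optional output directory for artifacts; when NULL the
#'   report bundle is only returned.
#' @param m,cycles multiple-imputation parameters.
#' @param B,threshold bootstrap validation parameters.
#' @param seed master seed for imputation and bootstrap substreams.
#' @param established candidate established risk markers for the first
#'   LASSO selection step (default: the baseline-table covariates).
#' @param mse_aggregation see [validation_config()].
#' @return list of class `run_config`.
#' @export
run_config <- function(gen = gen_config(), cohort = NULL, out_dir = NULL,
                       m = 10, cycles = 10, B = 1000, seed = 1,
                       threshold = -3, established = established_markers(),
                       mse_aggregation = "bagged") {
  structure(list(gen = gen, cohort = cohort, out_dir = out_dir, m = m,
                 cycles = cycles, B = B, seed = seed, threshold = threshold,
                 established = established,
                 mse_aggregation = mse_aggregation),
            class = "run_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  # paths are excluded so the hash identifies the analysis, not its location
  saveRDS(config[setdiff(names(config), "out_dir")], f, version = 2)
  unname(tools::md5sum(f))
}

# Analysis dataset for one cohort: slope outcome + transformed predictors
# built from *observed* (LOD-substituted, QC-filtered) biomarkers.
build_analysis_data <- function(cohort, config) {
  demo <- data.frame(id = cohort$clinical$id, age = cohort$clinical$age,
                     female = cohort$clinical$sex == "female")
  outcomes <- slope_outcomes(cohort$creatinine, demo,
                             threshold = config$threshold)
  qc <- qc_filter_biomarkers(cohort$biomarkers, cohort$below_lod)
  bm <- as.data.frame(cohort$biomarkers[, qc$kept, drop = FALSE])
  for (v in qc$kept)
    bm[[v]] <- substitute_lod(bm[[v]], cohort$panel$lod[cohort$panel$name == v],
                              below = cohort$below_lod[, v])
  clin <- cohort$clinical
  d <- data.frame(id = clin$id,
                  ln_uacr = clin$uacr,  # transformed below
                  current_smoker = clin$current_smoker,
                  sex_male = as.numeric(clin$sex == "male"),
                  age = clin$age, bmi = clin$bmi, sbp = clin$sbp,
                  dbp = clin$dbp, diabetes_duration = clin$diabetes_duration,
                  hdl = clin$hdl, ldl = clin$ldl, hba1c = clin$hba1c,
                  med_raas = clin$med_raas, med_insulin = clin$med_insulin,
                  med_oral = clin$med_oral, egfr0 = clin$egfr0)
  d <- cbind(d, bm)
  d <- apply_transforms(d, biomarker_cols = qc$kept, uacr_col = "ln_uacr")
  d <- merge(outcomes[c("id", "slope", "accelerated")], d, by = "id")
  d <- d[order(d$id), ]
  rownames(d) <- NULL
  list(data = d, qc = qc, outcomes = outcomes, biomarkers = qc$kept)
}

pool_numeric <- function(tables, key) {
  all_keys <- unique(unlist(lapply(tables, `[[`, key)))
  num_cols <- setdiff(names(tables[[1]])[vapply(tables[[1]], is.numeric, TRUE)],
                      key)
  rows <- lapply(all_keys, function(kv) {
    picks <- lapply(tables, function(tb) tb[tb[[key]] == kv, , drop = FALSE])
    picks <- picks[vapply(picks, nrow, 0L) == 1L]
    out <- data.frame(kv, n_imputations = length(picks))
    names(out)[1] <- key
    for (cl in num_cols)
      out[[cl]] <- mean(vapply(picks, `[[`, 0, cl))
    out
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Simulate (or accept) a cohort, construct the eGFR-slope outcome,
#' quality-control and transform the biomarkers, multiply impute, and then
#' per imputed dataset: (1) LASSO selection of established risk markers,
#' (2) univariate and (3) risk-marker-adjusted single-biomarker models,
#' (4) full LASSO over reference markers plus all retained biomarkers,
#' bootstrap validation comparing the reference and full models, and the
#' omit-one sensitivity analysis. Scalar metrics and coefficient summaries
#' are pooled across imputations by arithmetic mean (per-imputation values
#' retained in the bundle).
#'
#' @param config a [run_config()].
#' @return a report bundle (list), invisibly writing artifacts to
#'   `config$out_dir` when set.
#' @export
run_pipeline <- function(config = run_config()) {
  cohort <- if (!is.null(config$cohort)) config$cohort
            else simulate_cohort(config$gen)
  built <- build_analysis_data(cohort, config)
  d <- built$data
  model_cols <- setdiff(names(d), c("id", "slope", "accelerated"))
  imp <- impute_chained(d[c("slope", model_cols)], m = config$m,
                        cycles = config$cycles,
                        seed = substream_seed(config$seed, "imputation"))
  per_imp <- vector("list", config$m)
  for (k in seq_len(config$m)) {
    dk <- imp$datasets[[k]]
    ref_fit <- select_model(dk, model_spec("established", config$established))
    ref_markers <- ref_fit$active
    if (!length(ref_markers)) ref_markers <- config$established
    assoc <- association_table(
      list(dk), biomarkers = built$biomarkers,
      reference_markers = ref_markers,
      pathways = stats::setNames(cohort$panel$pathway, cohort$panel$name))
    ref_spec <- model_spec("reference", ref_markers)
    full_spec <- model_spec("full", c(ref_markers, built$biomarkers))
    full_fit <- select_model(dk, full_spec)
    vconf <- validation_config(B = config$B,
                               seed = substream_seed(config$seed, "validate", k),
                               threshold = config$threshold,
                               mse_aggregation = config$mse_aggregation)
    cmp <- compare_models(dk, ref_spec, full_spec, vconf)
    boot_tab <- coefficient_bootstrap_summary(cmp$full$coef_draws)
    omission <- omit_one_analysis(dk, full_spec, optimal_fit = full_fit)
    per_imp[[k]] <- list(reference_fit = ref_fit, reference_markers = ref_markers,
                         associations = assoc, full_fit = full_fit,
                         comparison = cmp, bootstrap_table = boot_tab,
                         omission = omission)
  }
  cmp_tab <- data.frame(
    imputation = seq_len(config$m),
    r2_reference = vapply(per_imp, function(z) z$comparison$reference$r2, 0),
    r2_full = vapply(per_imp, function(z) z$comparison$full$r2, 0),
    c_reference = vapply(per_imp, function(z) z$comparison$reference$c_index, 0),
    c_full = vapply(per_imp, function(z) z$comparison$full$c_index, 0),
    delta_r2 = vapply(per_imp, function(z) z$comparison$delta_r2, 0),
    delta_c = vapply(per_imp, function(z) z$comparison$delta_c, 0),
    global_p = vapply(per_imp, function(z) z$comparison$global_p, 0))
  pooled <- as.list(colMeans(cmp_tab[-1]))
  bundle <- list(
    cohort = cohort, qc_report = built$qc$report, outcomes = built$outcomes,
    imputation = imp, per_imputation = per_imp,
    associations = pool_numeric(lapply(per_imp, `[[`, "associations"),
                                "biomarker"),
    bootstrap_table = pool_numeric(lapply(per_imp, `[[`, "bootstrap_table"),
                                   "variable"),
    comparison_per_imputation = cmp_tab, comparison_pooled = pooled,
    omission = per_imp[[1]]$omission,
    config = config, config_hash = config_hash(config))
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  invisible(bundle)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  w(bundle$qc_report, "qc_report.csv")
  w(bundle$outcomes, "outcomes.csv")
  w(bundle$associations, "associations.csv")
  ref_sel <- do.call(rbind, lapply(seq_along(bundle$per_imputation), function(k) {
    f <- bundle$per_imputation[[k]]$reference_fit
    data.frame(imputation = k, variable = names(f$coefficients),
               coefficient = unname(f$coefficients),
               selected = f$coefficients != 0)
  }))
  w(ref_sel, "reference_selection.csv")
  opt <- do.call(rbind, lapply(seq_along(bundle$per_imputation), function(k) {
    f <- bundle$per_imputation[[k]]$full_fit
    data.frame(imputation = k, variable = names(f$coefficients),
               coefficient = unname(f$coefficients),
               selected = f$coefficients != 0)
  }))
  w(opt, "optimal_model.csv")
  cv <- bundle$per_imputation[[1]]$full_fit$cv
  w(data.frame(lambda = cv$lambda, cv_mse = cv$cv_mse, cv_se = cv$cv_se),
    "cv_curve.csv")
  w(bundle$bootstrap_table, "bootstrap_report.csv")
  w(bundle$omission, "omission.csv")
  jsonlite::write_json(
    list(pooled = bundle$comparison_pooled,
         per_imputation = bundle$comparison_per_imputation,
         config_hash = bundle$config_hash,
         seed = bundle$config$seed, B = bundle$config$B,
         m = bundle$config$m),
    file.path(dir, "model_comparison.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
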