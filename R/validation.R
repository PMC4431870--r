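#' Validation configuration
#'
#' @param B number of bootstrap resamples (the study used 1000).
#' @param seed integer seed; resample b draws from substream (seed, b).
#' @param threshold accelerated-decline cutoff (mL/min/1.73m^2/yr).
#' @param mse_aggregation `"bagged"` (default): squared error of each
#'   patient's resample-averaged prediction, averaged over patients;
#'   `"per_resample"`: mean over resamples of each resample-model's MSE on
#'   the original data.
#' @return list of class `validation_config`.
#' @export
validation_config <- function(B = 1000, seed = 1, threshold = -3,
                              mse_aggregation = c("bagged", "per_resample")) {
  stopifnot(B >= 1)
  structure(list(B = B, seed = seed, threshold = threshold,
                 mse_aggregation = match.arg(mse_aggregation)),
            class = "validation_config")
}

#' Bootstrap resample indices
#'
#' n indices drawn uniformly with replacement from a substream determined
#' by (seed, b), so resample sequences are reproducible and shareable
#' across model comparisons.
#'
#' @param n sample size.
#' @param seed master seed.
#' @param b resample number.
#' @return integer vector of length n.
#' @export
bootstrap_resample <- function(n, seed, b) {
  stopifnot(n >= 1)
  with_substream(seed, "bootstrap", b, sample.int(n, n, replace = TRUE))
}

#' R-squared derived from a mean squared error
#'
#' `R^2 = 1 - mse / var(y)` with the variance computed with denominator n;
#' may be negative when predictions are worse than the mean.
#'
#' @param mse mean squared prediction error.
#' @param y observed outcomes.
#' @return R-squared.
#' @export
r2_from_mse <- function(mse, y) {
  v <- mean((y - mean(y))^2)
  if (v == 0) stop("constant outcome: variance is zero")
  1 - mse / v
}

#' Concordance index for accelerated decline
#'
#' Over all (accelerated, non-accelerated) patient pairs, the fraction in
#' which the accelerated member has the higher risk score; ties in the
#' score count 0.5. Computed via midranks (Wilcoxon identity), equal to
#' exhaustive pair enumeration.
#'
#' @param risk_scores higher = higher predicted risk of accelerated
#'   decline (use the negative predicted slope).
#' @param accelerated logical event indicator.
#' @return concordance in [0, 1].
#' @export
cindex <- function(risk_scores, accelerated) {
  stopifnot(length(risk_scores) == length(accelerated))
  accelerated <- as.logical(accelerated)
  n1 <- sum(accelerated); n0 <- sum(!accelerated)
  if (n1 == 0 || n0 == 0)
    stop("both accelerated and non-accelerated patients are required")
  r <- rank(risk_scores)  # midranks handle ties as 0.5
  (sum(r[accelerated]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Shared engine: validate one or more model specs on the same bootstrap
# resample sequence. Per resample b and spec s: refit the lasso with
# leave-one-out tuned penalty on the resampled rows, predict the ORIGINAL
# data, store the coefficient vector (zeros for unselected) and the
# resample's own minimum CV MSE.
bootstrap_engine <- function(data, specs, config) {
  n <- nrow(data)
  B <- config$B
  outcome <- specs[[1]]$outcome
  y <- data[[outcome]]
  acc <- classify_decline(y, config$threshold)
  res <- lapply(specs, function(s) list(
    pred = matrix(NA_real_, n, B),
    coef = matrix(0, B, length(s$predictors),
                  dimnames = list(NULL, s$predictors)),
    cv_mse = numeric(B)))
  names(res) <- vapply(specs, `[[`, "", "name")
  indices <- matrix(NA_integer_, B, n)
  redraws <- 0L
  for (b in seq_len(B)) {
    idx <- bootstrap_resample(n, config$seed, b)
    tries <- 0L
    while (stats::var(y[idx]) == 0 && tries < 100L) {
      tries <- tries + 1L
      redraws <- redraws + 1L
      warning("resample with zero-variance outcome redrawn (b = ", b, ")")
      idx <- bootstrap_resample(n, config$seed, b + B * tries)
    }
    indices[b, ] <- idx
    boot <- data[idx, , drop = FALSE]
    for (s in seq_along(specs)) {
      fit <- select_model(boot, specs[[s]])
      res[[s]]$pred[, b] <- predict(fit, data)
      res[[s]]$coef[b, ] <- fit$coefficients
      res[[s]]$cv_mse[b] <- fit$cv$cv_mse[fit$chosen_index]
    }
  }
  both_classes <- any(acc) && !all(acc)
  per_spec <- lapply(res, function(r) {
    bagged <- rowMeans(r$pred)
    mse <- switch(config$mse_aggregation,
                  bagged = mean((y - bagged)^2),
                  per_resample = mean(colMeans((y - r$pred)^2)))
    list(mse = mse, r2 = r2_from_mse(mse, y),
         c_index = if (both_classes) cindex(-bagged, acc) else NA_real_,
         bagged_prediction = bagged,
         coef_draws = r$coef, cv_mse_draws = r$cv_mse)
  })
  list(models = per_spec, indices = indices, redraws = redraws,
       accelerated = acc, y = y)
}

#' Simple bootstrap validation of one model specification
#'
#' LASSO models (penalty tuned by leave-one-out CV within the resample) are
#' fit to B bootstrap resamples and applied to the original data without
#' modification. Each patient's bagged prediction is the average over
#' resamples; the model MSE is the average squared difference between the
#' observed outcome and the bagged prediction, R^2 derives from the MSE,
#' and the C-index compares the negative bagged predicted slope against the
#' observed accelerated-decline status.
#'
#' @param data complete data.frame (one imputed dataset).
#' @param spec a [model_spec()].
#' @param config a [validation_config()].
#' @return list of class `bootstrap_validation`: `mse`, `r2`, `c_index`,
#'   `bagged_prediction`, `coef_draws` (B x p), `cv_mse_draws`, `indices`.
#' @export
simple_bootstrap_validate <- function(data, spec, config = validation_config()) {
  eng <- bootstrap_engine(data, list(spec), config)
  out <- eng$models[[1]]
  out$indices <- eng$indices
  out$redraws <- eng$redraws
  out$spec <- spec
  class(out) <- "bootstrap_validation"
  out
}

#' @export
print.bootstrap_validation <- function(x, ...) {
  cat(sprintf("bootstrap validation '%s' (B = %d): MSE %.3f, R2 %.3f, C-index %.3f\n",
              x$spec$name, nrow(x$coef_draws), x$mse, x$r2, x$c_index))
  invisible(x)
}

#' Per-variable bootstrap coefficient summary
#'
#' Mean coefficient over resamples (zero when unselected), percentile 95%
#' CI (type-7 quantiles at 2.5/97.5), a two-sided percentile p-value
#' `2 * min(frac <= 0, frac >= 0)` clipped to [2/B, 1], and the selection
#' probability (fraction of resamples with a nonzero coefficient).
#'
#' @param coef_draws B x p matrix of bootstrap coefficient draws.
#' @return data.frame: variable, mean_beta, ci_low, ci_high, p,
#'   selection_probability, ordered by decreasing selection probability.
#' @export
coefficient_bootstrap_summary <- function(coef_draws) {
  B <- nrow(coef_draws)
  stopifnot(B >= 1)
  rows <- lapply(colnames(coef_draws), function(v) {
    d <- coef_draws[, v]
    ci <- stats::quantile(d, c(0.025, 0.975), type = 7, names = FALSE)
    p <- 2 * min(mean(d <= 0), mean(d >= 0))
    data.frame(variable = v, mean_beta = mean(d),
               ci_low = ci[1], ci_high = ci[2],
               p = min(max(p, 2 / B), 1),
               selection_probability = mean(d != 0), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out[order(-out$selection_probability, out$variable), , drop = FALSE]
}

#' Added predictive value of the biomarkers: model comparison
#'
#' Validates the reference (established risk markers) and full (reference +
#' biomarkers) specifications on the same bootstrap resample sequence.
#' Within each resample both models' leave-one-out cross-validated MSEs at
#' their tuned penalties are recorded; the global p-value for no added
#' value is the fraction of resamples in which the full model's CV MSE is
#' greater than or equal to the reference model's (ties count against the
#' richer model), floored at 1/B. Delta R^2 and delta C come from the
#' simple bootstrap validation of each model.
#'
#' @param data complete data.frame.
#' @param ref_spec,full_spec [model_spec()]s; the reference predictors must
#'   be a subset of the full predictors.
#' @param config a [validation_config()].
#' @return list of class `model_comparison`: per-model `mse`, `r2`,
#'   `c_index` and draws, plus `delta_r2`, `delta_c`, `global_p`,
#'   `indices`.
#' @export
compare_models <- function(data, ref_spec, full_spec,
                           config = validation_config()) {
  if (!all(ref_spec$predictors %in% full_spec$predictors))
    stop("reference predictors must be a subset of the full model's")
  eng <- bootstrap_engine(data, list(ref_spec, full_spec), config)
  ref <- eng$models[[1]]; full <- eng$models[[2]]
  B <- config$B
  wins <- sum(full$cv_mse_draws >= ref$cv_mse_draws)
  structure(list(reference = ref, full = full,
                 delta_r2 = full$r2 - ref$r2,
                 delta_c = full$c_index - ref$c_index,
                 global_p = max(wins, 1) / B,
                 indices = eng$indices, redraws = eng$redraws,
                 ref_spec = ref_spec, full_spec = full_spec),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("model comparison (B = %d resamples)\n", nrow(x$indices)))
  cat(sprintf("  R2:      %.3f -> %.3f (delta %+.3f)\n",
              x$reference$r2, x$full$r2, x$delta_r2))
  cat(sprintf("  C-index: %.3f -> %.3f (delta %+.3f)\n",
              x$reference$c_index, x$full$c_index, x$delta_c))
  cat(sprintf("  global p (no added value): %.4g\n", x$global_p))
  invisible(x)
}

#' Omit-one sensitivity analysis of the optimal model
#'
#' For each variable in the optimal active set: remove it from the
#' candidate pool, rerun the leave-one-out tuned LASSO selection, and
#' report which variables enter or leave relative to the optimal set.
#'
#' @param data complete data.frame.
#' @param spec the full candidate [model_spec()].
#' @param optimal_fit optional precomputed `lasso_fit` for `spec`.
#' @param ... passed to [select_model()].
#' @return data.frame: omitted, n_active, entered, left (comma-separated
#'   labels).
#' @export
omit_one_analysis <- function(data, spec, optimal_fit = NULL, ...) {
  if (is.null(optimal_fit)) optimal_fit <- select_model(data, spec, ...)
  base <- optimal_fit$active
  rows <- lapply(base, function(v) {
    sub <- model_spec(paste0(spec$name, "_minus_", v),
                      setdiff(spec$predictors, v), spec$outcome)
    fit <- select_model(data, sub, ...)
    data.frame(omitted = v, n_active = length(fit$active),
               entered = paste(setdiff(fit$active, base), collapse = ","),
               left = paste(setdiff(setdiff(base, v), fit$active),
                            collapse = ","),
               row.names = NULL)
  })
  if (!length(rows))
    return(data.frame(omitted = character(0), n_active = integer(0),
                      entered = character(0), left = character(0)))
  do.call(rbind, rows)
}
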