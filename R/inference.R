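#' Univariate association of a log2 biomarker with eGFR decline
#'
#' Ordinary least squares of the slope outcome on a single binary-log
#' biomarker; the coefficient reads as change in annual eGFR slope per
#' doubling of concentration. CI and p-value from the t distribution with
#' n - 2 degrees of freedom.
#'
#' @param x log2 biomarker values (complete).
#' @param y slope outcome.
#' @param level confidence level (default 0.95).
#' @return data.frame row: beta, se, ci_low, ci_high, p.
#' @export
univariate_association <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0) stop("zero-variance biomarker")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)$coefficients
  ci <- stats::confint(fit, "x", level = level)
  data.frame(beta = s["x", 1], se = s["x", 2],
             ci_low = ci[1], ci_high = ci[2], p = s["x", 4],
             row.names = NULL)
}

#' Risk-marker-adjusted association of a single biomarker
#'
#' OLS of the slope outcome on one log2 biomarker plus the established risk
#' markers; the biomarker coefficient is reported. Errors on rank-deficient
#' designs, naming the collinear columns.
#'
#' @param x log2 biomarker values.
#' @param covariates data.frame of established risk markers.
#' @param y slope outcome.
#' @param level confidence level.
#' @return data.frame row: beta, se, ci_low, ci_high, p.
#' @export
adjusted_association <- function(x, covariates, y, level = 0.95) {
  M <- cbind(`(Intercept)` = 1, biomarker = x, as.matrix(covariates))
  q <- qr(M)
  if (q$rank < ncol(M)) {
    alias <- colnames(M)[q$pivot[-seq_len(q$rank)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(alias, collapse = ", "))
  }
  d <- data.frame(y = y, biomarker = x, covariates)
  fit <- stats::lm(y ~ ., data = d)
  s <- summary(fit)$coefficients
  ci <- stats::confint(fit, "biomarker", level = level)
  data.frame(beta = s["biomarker", 1], se = s["biomarker", 2],
             ci_low = ci[1], ci_high = ci[2], p = s["biomarker", 4],
             row.names = NULL)
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' @param estimates per-imputation point estimates.
#' @param ses per-imputation standard errors.
#' @param df_com complete-data residual degrees of freedom (for the
#'   Barnard-Rubin small-sample adjustment).
#' @param level confidence level.
#' @return data.frame row: beta, se, ci_low, ci_high, p, df.
#' @export
pool_rubin <- function(estimates, ses, df_com, level = 0.95) {
  m <- length(estimates)
  qbar <- mean(estimates)
  W <- mean(ses^2)
  B <- if (m > 1) stats::var(estimates) else 0
  Tv <- W + (1 + 1 / m) * B
  if (B > 0) {
    r <- (1 + 1 / m) * B / W
    df_old <- (m - 1) * (1 + 1 / r)^2
    df_obs <- (df_com + 1) / (df_com + 3) * df_com * W / Tv
    df <- 1 / (1 / df_old + 1 / df_obs)
  } else df <- df_com
  se <- sqrt(Tv)
  tcrit <- stats::qt(1 - (1 - level) / 2, df)
  p <- 2 * stats::pt(abs(qbar) / se, df, lower.tail = FALSE)
  data.frame(beta = qbar, se = se, ci_low = qbar - tcrit * se,
             ci_high = qbar + tcrit * se, p = p, df = df, row.names = NULL)
}

#' Univariate and adjusted single-biomarker association table
#'
#' For each biomarker: the univariate OLS association with the slope
#' outcome and the association adjusted for the established risk markers,
#' pooled across imputed datasets by Rubin's rules.
#'
#' @param imputed an `imputed_set` (datasets containing the outcome, the
#'   biomarkers in log2, and the risk markers) or a list of completed
#'   data.frames.
#' @param biomarkers character vector of biomarker column names.
#' @param reference_markers character vector of adjustment covariates.
#' @param outcome outcome column name.
#' @param pathways optional named vector biomarker -> pathway label.
#' @return data.frame, one row per biomarker with `uni_*` and `adj_*`
#'   columns.
#' @export
association_table <- function(imputed, biomarkers, reference_markers,
                              outcome = "slope", pathways = NULL) {
  datasets <- if (inherits(imputed, "imputed_set")) imputed$datasets
              else imputed
  rows <- lapply(biomarkers, function(bm) {
    uni <- lapply(datasets, function(d)
      univariate_association(d[[bm]], d[[outcome]]))
    adj <- lapply(datasets, function(d)
      adjusted_association(d[[bm]], d[reference_markers], d[[outcome]]))
    n <- nrow(datasets[[1]])
    u <- pool_rubin(vapply(uni, `[[`, 1, "beta"),
                    vapply(uni, `[[`, 1, "se"), df_com = n - 2)
    a <- pool_rubin(vapply(adj, `[[`, 1, "beta"),
                    vapply(adj, `[[`, 1, "se"),
                    df_com = n - length(reference_markers) - 2)
    data.frame(biomarker = bm,
               pathway = if (!is.null(pathways)) pathways[[bm]] else NA,
               uni_beta = u$beta, uni_ci_low = u$ci_low,
               uni_ci_high = u$ci_high, uni_p = u$p,
               adj_beta = a$beta, adj_ci_low = a$ci_low,
               adj_ci_high = a$ci_high, adj_p = a$p, row.names = NULL)
  })
  do.call(rbind, rows)
}
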