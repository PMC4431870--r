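#' Substitute below-LOD values by the detection limit
#'
#' Censored assay values are set to the limit of detection; observed values
#' are unchanged.
#'
#' @param values numeric vector (NA allowed for missing).
#' @param lod positive detection limit.
#' @param below logical flags marking censored cells; defaults to
#'   `values < lod`.
#' @return numeric vector with censored cells set to `lod`.
#' @export
substitute_lod <- function(values, lod, below = NULL) {
  if (!is.finite(lod) || lod <= 0) stop("lod must be positive")
  if (is.null(below)) below <- !is.na(values) & values < lod
  values[below & !is.na(values)] <- lod
  values
}

#' Quality-control filter for biomarker columns
#'
#' A biomarker is retained only if at most 10% of its values are missing
#' and at most 25% are below the detection limit (strict inequalities
#' trigger exclusion).
#'
#' @param biomarkers matrix/data.frame of concentrations (NA = missing).
#' @param below_lod logical matrix of censoring flags (same shape).
#' @param max_missing,max_below_lod exclusion bounds (fractions).
#' @return list with `report` (data.frame: name, missing_fraction,
#'   below_lod_fraction, kept, reason) and `kept` (character vector of
#'   retained marker names).
#' @export
qc_filter_biomarkers <- function(biomarkers, below_lod,
                                 max_missing = 0.10, max_below_lod = 0.25) {
  X <- as.matrix(biomarkers)
  stopifnot(all(dim(below_lod) == dim(X)))
  mf <- colMeans(is.na(X))
  bf <- colMeans(below_lod & !is.na(X))
  kept <- mf <= max_missing & bf <= max_below_lod
  reason <- rep("", ncol(X))
  reason[mf > max_missing] <- sprintf(">%.0f%% missing", 100 * max_missing)
  reason[bf > max_below_lod] <- ifelse(
    reason[bf > max_below_lod] == "",
    sprintf(">%.0f%% below LOD", 100 * max_below_lod),
    paste0(reason[bf > max_below_lod], sprintf("; >%.0f%% below LOD",
                                               100 * max_below_lod)))
  list(report = data.frame(name = colnames(X), missing_fraction = mf,
                           below_lod_fraction = bf, kept = kept,
                           reason = reason, row.names = NULL),
       kept = colnames(X)[kept])
}

#' Normalizing transforms for regression
#'
#' Replaces UACR by its natural logarithm and every biomarker column by its
#' binary logarithm (so coefficients read per doubling of concentration);
#' clinical covariates are untransformed.
#'
#' @param data data.frame.
#' @param biomarker_cols names of biomarker columns present in `data`.
#' @param uacr_col name of the UACR column (ignored if absent).
#' @return data.frame with transformed columns.
#' @export
apply_transforms <- function(data, biomarker_cols,
                             uacr_col = "uacr") {
  biomarker_cols <- intersect(biomarker_cols, names(data))
  for (cl in c(if (uacr_col %in% names(data)) uacr_col, biomarker_cols)) {
    v <- data[[cl]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad))
      stop(sprintf("non-positive value in column '%s', row %d", cl, bad[1]))
  }
  if (uacr_col %in% names(data)) data[[uacr_col]] <- log(data[[uacr_col]])
  for (cl in biomarker_cols) data[[cl]] <- log2(data[[cl]])
  data
}

# One proper PMM draw for a continuous incomplete variable: Bayesian
# regression of the observed part on all other columns, predictive-mean
# matching with k nearest donors.
pmm_impute <- function(y, Xo, Xm, k = 5) {
  q <- qr(Xo)
  rank <- q$rank
  use <- q$pivot[seq_len(rank)]
  bhat <- qr.coef(q, y)[use]
  res <- y - drop(Xo[, use, drop = FALSE] %*% bhat)
  df <- max(length(y) - rank, 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- 1e-12
  XtXi <- chol2inv(chol(crossprod(Xo[, use, drop = FALSE]) +
                          diag(1e-10, rank)))
  bstar <- tryCatch(
    bhat + drop(t(chol(sigma2 * XtXi)) %*% stats::rnorm(rank)),
    error = function(e) bhat)
  yhat_obs <- drop(Xo[, use, drop = FALSE] %*% bhat)
  yhat_mis <- drop(Xm[, use, drop = FALSE] %*% bstar)
  vapply(yhat_mis, function(p) {
    d <- abs(yhat_obs - p)
    donors <- order(d)[seq_len(min(k, length(d)))]
    y[donors[sample.int(length(donors), 1)]]
  }, numeric(1))
}

logistic_impute <- function(y, Xo, Xm) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(Xo, y, family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || any(!is.finite(stats::coef(fit)))) {
    warning("logistic imputation step did not converge; drawing from the observed marginal")
    return(sample(y, nrow(Xm), replace = TRUE))
  }
  b <- stats::coef(fit)
  b[is.na(b)] <- 0
  V <- tryCatch(chol2inv(chol(crossprod(Xo * sqrt(fit$weights)) +
                                diag(1e-8, ncol(Xo)))),
                error = function(e) diag(0, ncol(Xo)))
  bstar <- b + drop(t(chol(V + diag(1e-12, ncol(Xo)))) %*%
                      stats::rnorm(ncol(Xo)))
  p <- stats::plogis(drop(Xm %*% bstar))
  stats::rbinom(nrow(Xm), 1, p)
}

#' Multiple imputation by chained equations
#'
#' Produces `m` completed datasets. Missing cells are initialized by random
#' draws from the observed marginal of each column, then the algorithm
#' cycles variable-by-variable for `cycles` iterations, regressing each
#' incomplete variable on all others: continuous variables are imputed by
#' Bayesian linear regression with predictive-mean matching (donor pool of
#' `k`); binary (two-valued 0/1) variables by a logistic draw, falling back
#' to an observed-marginal draw with a warning if the logistic fit fails.
#' Observed cells are never altered; the result is deterministic given
#' `seed`.
#'
#' @param data data.frame of numeric columns (NA = missing).
#' @param m number of completed datasets (default 10).
#' @param cycles chained-equation cycles per dataset (default 10).
#' @param k PMM donor pool size (default 5).
#' @param seed integer seed.
#' @return object of class `imputed_set`: list with `m`, `datasets`,
#'   `cycles`, `seed`.
#' @export
impute_chained <- function(data, m = 10, cycles = 10, k = 5, seed = 1) {
  stopifnot(is.data.frame(data), m >= 1, cycles >= 1)
  num <- vapply(data, is.numeric, TRUE)
  if (!all(num)) stop("all columns must be numeric (code binaries as 0/1)")
  X <- as.matrix(data)
  nmis <- colSums(is.na(X))
  if (any(nmis == nrow(X)))
    stop("column(s) with no observed values: ",
         paste(colnames(X)[nmis == nrow(X)], collapse = ", "))
  if (ncol(X) < 2 && any(nmis > 0))
    stop("need at least 2 variables to run chained equations")
  incomplete <- colnames(X)[nmis > 0][order(nmis[nmis > 0])]
  is_binary <- vapply(seq_len(ncol(X)), function(j)
    all(stats::na.omit(X[, j]) %in% c(0, 1)), TRUE)
  names(is_binary) <- colnames(X)
  datasets <- vector("list", m)
  for (imp in seq_len(m)) {
    Xi <- with_substream(seed, "impute", imp, {
      Xi <- X
      for (v in incomplete) {
        mis <- is.na(Xi[, v])
        Xi[mis, v] <- sample(X[!is.na(X[, v]), v], sum(mis), replace = TRUE)
      }
      for (cyc in seq_len(cycles)) {
        for (v in incomplete) {
          mis <- is.na(X[, v])
          others <- setdiff(colnames(X), v)
          Xo <- cbind(1, Xi[!mis, others, drop = FALSE])
          Xm <- cbind(1, Xi[mis, others, drop = FALSE])
          Xi[mis, v] <- if (is_binary[v])
            logistic_impute(Xi[!mis, v], Xo, Xm)
          else
            pmm_impute(Xi[!mis, v], Xo, Xm, k = k)
        }
      }
      Xi
    })
    df <- as.data.frame(Xi)
    names(df) <- colnames(X)
    datasets[[imp]] <- df
  }
  structure(list(m = m, datasets = datasets, cycles = cycles, seed = seed),
            class = "imputed_set")
}

#' @export
print.imputed_set <- function(x, ...) {
  cat(sprintf("imputed set: m = %d completed datasets (%d chained cycles)\n",
              x$m, x$cycles))
  invisible(x)
}
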