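#' Default penalty grid for the lasso path
#'
#' 100 log-spaced values from `lambda_max` (the smallest penalty at which
#' every slope coefficient is zero) down to `lambda_min_ratio * lambda_max`.
#'
#' @param X predictor matrix.
#' @param y response.
#' @param nlambda grid length.
#' @param lambda_min_ratio ratio of the smallest to the largest penalty.
#' @return decreasing numeric vector.
#' @export
lambda_grid <- function(X, y, nlambda = 100, lambda_min_ratio = 1e-3) {
  X <- as.matrix(X)
  n <- nrow(X)
  ctr <- colMeans(X)
  sc <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  sc[sc == 0] <- Inf
  Xs <- sweep(sweep(X, 2, ctr), 2, sc, "/")
  yc <- y - mean(y)
  lmax <- max(abs(crossprod(Xs, yc)) / n)
  if (lmax <= 0) lmax <- 1e-3
  # head inflated by 1e-9 relative so the null model holds exactly at the
  # largest grid value despite floating-point rounding
  lmax <- lmax * (1 + 1e-9)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

check_xy <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("non-finite values in X or y")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (nrow(X) < 2) stop("need at least 2 observations")
  X
}

#' Fit the lasso coefficient path by cyclic coordinate descent
#'
#' Minimizes `(1/2n) * RSS + lambda * sum(|beta|)` on internally standardized
#' predictors (mean 0, unit population SD; intercept unpenalized), with warm
#' starts along a decreasing penalty grid. Coefficients are reported on the
#' original predictor scale. Zero-variance predictors are dropped with a
#' warning (their coefficients stay 0).
#'
#' @param X numeric predictor matrix (no missing values).
#' @param y numeric response.
#' @param lambda optional decreasing penalty grid; defaults to
#'   [lambda_grid()].
#' @param tol convergence tolerance on the max standardized coefficient
#'   change per sweep.
#' @param max_sweeps sweep cap per penalty value.
#' @param nlambda,lambda_min_ratio grid parameters when `lambda` is NULL.
#' @return an object of class `lasso_path`: `lambda`, `beta` (p x L, original
#'   scale), `a0` (intercepts), `active_counts`, `dropped`.
#' @export
fit_lasso_path <- function(X, y, lambda = NULL, tol = 1e-7, max_sweeps = 1e5,
                           nlambda = 100, lambda_min_ratio = 1e-3) {
  X <- check_xy(X, y)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  sds <- sqrt(colMeans(sweep(X, 2, colMeans(X))^2))
  if (any(sds == 0))
    warning("zero-variance predictor(s) dropped: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
  if (is.null(lambda))
    lambda <- lambda_grid(X, y, nlambda, lambda_min_ratio)
  if (is.unsorted(rev(lambda))) stop("lambda must be decreasing")
  fit <- cd_path_cpp(X, as.numeric(y), as.numeric(lambda), tol,
                     as.integer(max_sweeps))
  beta <- fit$beta
  rownames(beta) <- colnames(X)
  structure(list(lambda = as.numeric(lambda), beta = beta, a0 = fit$a0,
                 active_counts = colSums(beta != 0),
                 center = fit$center, scale = fit$scale,
                 dropped = colnames(X)[sds == 0], sweeps = fit$sweeps),
            class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf("lasso path: %d predictors, %d penalty values (lambda %.4g .. %.4g)\n",
              nrow(x$beta), length(x$lambda), max(x$lambda), min(x$lambda)))
  invisible(x)
}

#' Predictions from a lasso path
#'
#' @param object a `lasso_path`.
#' @param newx matrix of predictors.
#' @param index column of the path to use (default: all).
#' @param ... unused.
#' @return matrix of predictions (nrow(newx) x length(index)).
#' @export
predict.lasso_path <- function(object, newx, index = seq_along(object$lambda),
                               ...) {
  newx <- as.matrix(newx)
  sweep(newx %*% object$beta[, index, drop = FALSE], 2,
        -object$a0[index], "-")
}

#' Leave-one-out cross-validation curve for the lasso
#'
#' For each of the n folds of size one the whole path is refit on the
#' remaining n-1 rows (re-standardizing within the fold) and the squared
#' prediction error on the held-out row is recorded. `cv_mse` is the mean
#' over folds per penalty and `cv_se` its standard error (SD/sqrt(n)).
#' The chosen index minimizes `cv_mse`; exact ties go to the larger penalty
#' (the sparser model).
#'
#' @inheritParams fit_lasso_path
#' @return an object of class `cv_curve`: `lambda`, `cv_mse`, `cv_se`,
#'   `chosen_index`, `n_folds`.
#' @export
loocv_curve <- function(X, y, lambda = NULL, tol = 1e-7, max_sweeps = 1e5,
                        nlambda = 100, lambda_min_ratio = 1e-3) {
  X <- check_xy(X, y)
  if (nrow(X) < 3) stop("need at least 3 observations for leave-one-out CV")
  if (is.null(lambda))
    lambda <- lambda_grid(X, y, nlambda, lambda_min_ratio)
  cv <- cd_loocv_cpp(X, as.numeric(y), as.numeric(lambda), tol,
                     as.integer(max_sweeps))
  structure(list(lambda = as.numeric(lambda), cv_mse = cv$cv_mse,
                 cv_se = cv$cv_se, chosen_index = which.min(cv$cv_mse),
                 n_folds = nrow(X)),
            class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  i <- x$chosen_index
  cat(sprintf("leave-one-out CV over %d folds: min MSE %.4g at lambda %.4g (index %d)\n",
              x$n_folds, x$cv_mse[i], x$lambda[i], i))
  invisible(x)
}

#' Plot a cross-validation curve (CV MSE vs log lambda)
#'
#' @param x a `cv_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cv_curve <- function(x, ...) {
  ll <- log(x$lambda)
  graphics::plot(ll, x$cv_mse, pch = 19, col = "red2",
                 xlab = "log(Lambda)", ylab = "cross-validated MSE",
                 ylim = range(x$cv_mse - x$cv_se, x$cv_mse + x$cv_se), ...)
  graphics::arrows(ll, x$cv_mse - x$cv_se, ll, x$cv_mse + x$cv_se,
                   angle = 90, code = 3, length = 0.02, col = "grey50")
  graphics::abline(v = ll[x$chosen_index], lty = 2)
  invisible(x)
}

#' Model specification: an ordered predictor set
#'
#' @param name label for the model (e.g. "reference", "full").
#' @param predictors character vector of predictor column names.
#' @param outcome outcome column name (default "slope").
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(name, predictors, outcome = "slope") {
  stopifnot(is.character(predictors), length(predictors) >= 1)
  if (anyDuplicated(predictors)) stop("predictor labels must be unique")
  structure(list(name = name, predictors = predictors, outcome = outcome),
            class = "model_spec")
}

#' Lasso model selection with leave-one-out tuned penalty
#'
#' Fits the lasso path over the spec's predictors, picks the penalty
#' minimizing the leave-one-out cross-validated MSE (ties to the larger
#' penalty), and returns the active set with coefficients at the optimum.
#' The procedure is deterministic; `seed` is accepted for interface
#' stability.
#'
#' @param data data.frame containing the outcome and all predictors.
#' @param spec a [model_spec()].
#' @param seed unused (the fit is deterministic).
#' @param ... passed to [loocv_curve()] / [fit_lasso_path()].
#' @return an object of class `lasso_fit`: `active`, `coefficients` (named,
#'   zeros included), `intercept`, `lambda_opt`, `cv`, `path`, `spec`.
#' @export
select_model <- function(data, spec, seed = NULL, ...) {
  miss <- setdiff(c(spec$predictors, spec$outcome), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  X <- as.matrix(data[spec$predictors])
  y <- data[[spec$outcome]]
  dup <- duplicated(lapply(seq_len(ncol(X)), function(j) unname(X[, j])))
  if (any(dup))
    warning("duplicated predictor column(s): ",
            paste(spec$predictors[dup], collapse = ", "),
            "; at most one of each pair can be active")
  lam <- lambda_grid(X, y, ...)
  cv <- loocv_curve(X, y, lambda = lam)
  path <- fit_lasso_path(X, y, lambda = lam)
  i <- cv$chosen_index
  beta <- path$beta[, i]
  # coefficients below the convergence tolerance on the standardized scale
  # are solver dust (e.g. the shadow of a duplicated column), not selections
  beta[abs(beta * path$scale) < 1e-7] <- 0
  structure(list(active = spec$predictors[beta != 0],
                 coefficients = beta, intercept = path$a0[i],
                 lambda_opt = lam[i], chosen_index = i,
                 cv = cv, path = path, spec = spec),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("lasso fit '%s': %d of %d predictors active at lambda %.4g\n",
              x$spec$name, length(x$active), length(x$coefficients),
              x$lambda_opt))
  if (length(x$active)) print(round(x$coefficients[x$active], 4))
  invisible(x)
}

#' @export
predict.lasso_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata[object$spec$predictors])
  drop(X %*% object$coefficients) + object$intercept
}

#' Karush-Kuhn-Tucker residual check for a lasso solution
#'
#' For each predictor returns the subgradient slack
#' `|x_j' r / n| - lambda` (active: `|x_j' r / n - lambda * sign(beta_j)|`)
#' on the standardized scale; values near zero certify optimality.
#'
#' @param X,y data the path was fit on.
#' @param path a `lasso_path`.
#' @param index which penalty value to check.
#' @return numeric vector of KKT violations (one per predictor).
#' @export
kkt_violation <- function(X, y, path, index) {
  X <- as.matrix(X)
  n <- nrow(X)
  sc <- path$scale
  keep <- sc > 0
  Xs <- sweep(sweep(X, 2, path$center), 2, ifelse(keep, sc, 1), "/")
  lam <- path$lambda[index]
  beta_std <- path$beta[, index] * sc
  r <- y - path$a0[index] - drop(X %*% path$beta[, index])
  g <- drop(crossprod(Xs, r)) / n
  viol <- ifelse(beta_std != 0, abs(g - lam * sign(beta_std)),
                 pmax(abs(g) - lam, 0))
  viol[!keep] <- 0
  viol
}
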