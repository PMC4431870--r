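test_that("penalty at or above lambda_max yields the null model", {
  set.seed(1)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- rnorm(40)
  lg <- lambda_grid(X, y)
  fit <- fit_lasso_path(X, y, lambda = c(lg[1] * 2, lg[1]))
  expect_true(all(fit$beta == 0))
  expect_equal(fit$a0, rep(mean(y), 2), tolerance = 1e-12)
})

test_that("unpenalized fit matches ordinary least squares", {
  set.seed(2)
  X <- matrix(rnorm(50 * 6), 50, 6)
  y <- drop(X %*% c(2, -1, 0.5, 0, 0, 1)) + rnorm(50)
  fit <- fit_lasso_path(X, y, lambda = c(1, 1e-12))
  ols <- coef(lm(y ~ X))
  expect_equal(unname(fit$beta[, 2]), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(fit$a0[2], unname(ols[1]), tolerance = 1e-6)
})

test_that("orthonormal designs reduce to coordinatewise soft thresholding", {
  set.seed(3)
  n <- 60; p <- 4
  raw <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  Q <- qr.Q(qr(raw))            # orthonormal, columns mean-zero
  X <- Q * sqrt(n)              # population SD exactly 1
  y <- rnorm(n)
  z <- drop(crossprod(X, y - mean(y))) / n
  for (lam in c(0.02, 0.08, 0.2)) {
    head_lam <- max(max(abs(z)) * 1.1, lam * 2)
    fit <- fit_lasso_path(X, y, lambda = c(head_lam, lam))
    soft <- sign(z) * pmax(abs(z) - lam, 0)
    expect_equal(unname(fit$beta[, 2]), soft, tolerance = 1e-7)
  }
})

test_that("KKT conditions certify path solutions on random instances", {
  for (s in 1:10) {
    set.seed(100 + s)
    n <- sample(20:60, 1); p <- sample(3:10, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X %*% (rnorm(p) * rbinom(p, 1, 0.5))) + rnorm(n)
    fit <- fit_lasso_path(X, y)
    for (idx in c(10, 50, 90))
      expect_lt(max(kkt_violation(X, y, fit, idx)), 1e-6)
  }
})

test_that("path agrees with an independent penalized-regression solver", {
  skip_if_not_installed("glmnet")
  set.seed(7)
  X <- matrix(rnorm(70 * 9), 70, 9)
  y <- drop(X[, 1:3] %*% c(1.5, -2, 1)) + rnorm(70)
  lg <- lambda_grid(X, y)
  fit <- fit_lasso_path(X, y, lambda = lg)
  g <- glmnet::glmnet(X, y, lambda = lg, thresh = 1e-14,
                      standardize = TRUE)
  expect_lt(max(abs(as.matrix(g$beta) - fit$beta)), 1e-6)
  expect_lt(max(abs(g$a0 - fit$a0)), 1e-6)
})

test_that("coefficients are scale-equivariant and predictions invariant", {
  set.seed(8)
  X <- matrix(rnorm(40 * 4), 40, 4)
  y <- drop(X %*% c(1, -1, 0, 0.5)) + rnorm(40)
  lg <- lambda_grid(X, y)
  f1 <- fit_lasso_path(X, y, lambda = lg)
  X2 <- X; X2[, 2] <- X[, 2] * 10
  f2 <- fit_lasso_path(X2, y, lambda = lg)
  expect_equal(f2$beta[2, ], f1$beta[2, ] / 10, tolerance = 1e-8)
  expect_equal(predict(f2, X2), predict(f1, X), tolerance = 1e-8)
})

test_that("the path is continuous under grid refinement", {
  set.seed(9)
  X <- matrix(rnorm(50 * 5), 50, 5)
  y <- drop(X %*% c(2, -1, 0, 0, 0)) + rnorm(50)
  gap <- function(nlam) {
    f <- fit_lasso_path(X, y, nlambda = nlam)
    max(abs(diff(t(f$beta))))
  }
  g50 <- gap(50); g200 <- gap(200); g800 <- gap(800)
  expect_gt(g50, g200)
  expect_gt(g200, g800)
})

test_that("zero-variance predictors are dropped with a warning", {
  set.seed(10)
  X <- cbind(const = rep(2, 30), x = rnorm(30))
  y <- X[, 2] + rnorm(30)
  expect_warning(fit <- fit_lasso_path(X, y), "zero-variance.*const")
  expect_true(all(fit$beta["const", ] == 0))
})

test_that("leave-one-out CV uses n folds and picks the minimum", {
  set.seed(11)
  n <- 30
  X <- matrix(rnorm(n * 4), n, 4)
  y <- X[, 1] + rnorm(n)
  cv <- loocv_curve(X, y)
  expect_equal(cv$n_folds, n)
  expect_equal(cv$chosen_index, which.min(cv$cv_mse))
  expect_true(all(cv$cv_mse >= 0))
  expect_equal(length(cv$cv_se), length(cv$lambda))
})

test_that("noiseless linear truth is recovered with near-zero CV error", {
  set.seed(12)
  X <- matrix(rnorm(20 * 2), 20, 2)
  colnames(X) <- c("x1", "x2")
  y <- drop(X %*% c(1, -2))
  d <- data.frame(slope = y, X)
  fit <- select_model(d, model_spec("noiseless", c("x1", "x2")))
  expect_setequal(fit$active, c("x1", "x2"))
  expect_lt(fit$cv$cv_mse[fit$chosen_index], 1e-3 * var(y))
})

test_that("pure-noise outcomes lead to (near-)empty selected models", {
  # The min-CV rule keeps some noise fits (it does not use the 1-SE rule),
  # so "empty" holds in the majority of replicates, not almost surely; the
  # chosen sparsity agrees with an independent leave-one-out reference.
  skip_if_not_installed("glmnet")
  sizes <- vapply(1:40, function(s) {
    set.seed(3000 + s)
    X <- matrix(rnorm(50 * 10), 50, 10)
    colnames(X) <- paste0("x", 1:10)
    y <- rnorm(50)
    d <- data.frame(slope = y, X)
    fit <- select_model(d, model_spec("null", colnames(X)))
    g <- glmnet::cv.glmnet(X, y, nfolds = 50, grouped = FALSE,
                           lambda = lambda_grid(X, y), thresh = 1e-10)
    gsize <- sum(coef(g, s = "lambda.min")[-1] != 0)
    expect_equal(length(fit$active), gsize)
    length(fit$active)
  }, numeric(1))
  expect_gte(mean(sizes == 0), 0.5)
  expect_lte(mean(sizes), 2)
})

test_that("duplicated predictor columns warn and only one can be active", {
  set.seed(13)
  x <- rnorm(40)
  d <- data.frame(slope = 2 * x + rnorm(40, 0, 0.1), a = x, b = x)
  expect_warning(fit <- select_model(d, model_spec("dup", c("a", "b"))),
                 "duplicated predictor")
  expect_lte(sum(fit$coefficients != 0), 1)
})

test_that("exact CV ties resolve to the larger penalty", {
  # with a constant-zero predictor contribution the curve is flat across the
  # whole grid (every model is the intercept), an exact all-way tie
  set.seed(14)
  X <- matrix(rnorm(20), 20, 1)
  y <- rep(c(-1, 1), 10)[order(rnorm(20))]  # unrelated to X
  cv <- loocv_curve(X, y, lambda = c(10, 5, 2))  # all above lambda_max
  expect_true(all(cv$cv_mse == cv$cv_mse[1]))
  expect_equal(cv$chosen_index, 1)  # largest penalty among the tie
})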