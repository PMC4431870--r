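# Independent oracles used across the suite. These deliberately avoid the
# package's solver path: the lasso oracle enumerates sign patterns and solves
# KKT linear systems; the concordance oracle enumerates pairs.

# Standardize like the solver does (population SD), return pieces.
std_design <- function(X, y) {
  n <- nrow(X)
  ctr <- colMeans(X)
  sc <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  list(Xs = sweep(sweep(X, 2, ctr), 2, sc, "/"), yc = y - mean(y),
       n = n, center = ctr, scale = sc)
}

# Lasso objective on the standardized scale: (1/2n)||yc - Xs b||^2 + lam ||b||_1
lasso_objective_std <- function(Xs, yc, b, lam) {
  n <- nrow(Xs)
  sum((yc - Xs %*% b)^2) / (2 * n) + lam * sum(abs(b))
}

# Exact lasso optimum by enumeration of sign patterns (p <= 6): for each
# pattern s in {-1,0,1}^p solve the active-set stationarity system
#   (Xs_A' Xs_A / n) b_A = Xs_A' yc / n - lam * s_A,
# keep patterns whose solution is sign-consistent and KKT-feasible, and
# return the smallest objective among them.
lasso_enum_objective <- function(X, y, lam) {
  sd <- std_design(as.matrix(X), y)
  Xs <- sd$Xs; yc <- sd$yc; n <- sd$n; p <- ncol(Xs)
  patterns <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), p)))
  best <- lasso_objective_std(Xs, yc, rep(0, p), lam)  # null always feasible to score
  for (r in seq_len(nrow(patterns))) {
    s <- patterns[r, ]
    A <- which(s != 0)
    if (!length(A)) next
    XA <- Xs[, A, drop = FALSE]
    G <- crossprod(XA) / n
    rhs <- drop(crossprod(XA, yc)) / n - lam * s[A]
    bA <- tryCatch(solve(G, rhs), error = function(e) NULL)
    if (is.null(bA)) next
    if (any(sign(bA) != s[A])) next
    b <- rep(0, p); b[A] <- bA
    grad_inactive <- drop(crossprod(Xs[, -A, drop = FALSE],
                                    yc - XA %*% bA)) / n
    if (length(grad_inactive) && any(abs(grad_inactive) > lam + 1e-10)) next
    obj <- lasso_objective_std(Xs, yc, b, lam)
    if (obj < best) best <- obj
  }
  best
}

# Objective achieved by a fitted path at a given penalty index, evaluated on
# the same standardized scale the oracle uses.
lasso_fit_objective <- function(X, y, path, index) {
  sd <- std_design(as.matrix(X), y)
  b_std <- path$beta[, index] * sd$scale
  lasso_objective_std(sd$Xs, sd$yc, b_std, path$lambda[index])
}

# Exhaustive pairwise concordance: fraction of (event, non-event) pairs in
# which the event member has the larger score; ties 0.5.
cindex_bruteforce <- function(score, event) {
  ev <- which(event); nev <- which(!event)
  tot <- 0
  for (i in ev) for (j in nev)
    tot <- tot + if (score[i] > score[j]) 1 else if (score[i] == score[j]) 0.5 else 0
  tot / (length(ev) * length(nev))
}

# Small complete dataset with linear signal, for modeling tests.
make_toy_regression <- function(n, p, beta, noise_sd = 1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  y <- drop(X[, seq_along(beta), drop = FALSE] %*% beta) +
    rnorm(n, 0, noise_sd)
  data.frame(slope = y, X)
}
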