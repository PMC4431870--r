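test_that("quartile-matching log-scale SD evaluates correctly", {
  # (ln 6.7 - ln 3.1) / 1.34898 evaluated independently
  expect_equal(log_sigma_from_quartiles(3.1, 6.7), 0.571324,
               tolerance = 1e-5)
  expect_error(log_sigma_from_quartiles(-1, 2), "positive")
})

test_that("biomarker marginals reproduce the panel medians and quartiles", {
  pan <- biomarker_panel()
  X <- sample_biomarkers(pan, 1e4, seed = 202)
  q <- apply(X, 2, quantile, probs = c(0.25, 0.5, 0.75))
  for (j in seq_len(nrow(pan))) {
    expect_lt(abs(q[2, j] / pan$median[j] - 1), 0.05, label = pan$name[j])
    expect_lt(abs(q[1, j] / pan$q1[j] - 1), 0.10, label = pan$name[j])
    expect_lt(abs(q[3, j] / pan$q3[j] - 1), 0.10, label = pan$name[j])
  }
})

test_that("identity correlation yields near-zero log-scale correlations", {
  pan <- biomarker_panel()
  X <- sample_biomarkers(pan, 5000, correlation = "identity", seed = 7)
  C <- cor(log(X))
  diag(C) <- 0
  expect_lt(max(abs(C)), 0.05)
})

test_that("pathway factor structure induces within-pathway correlation", {
  pan <- biomarker_panel()
  X <- sample_biomarkers(pan, 5000, correlation = pathway_factor(0.5),
                         seed = 8)
  C <- cor(log(X))
  same <- outer(pan$pathway, pan$pathway, "==")
  within <- C[same & upper.tri(C)]
  across <- C[!same & upper.tri(C)]
  expect_lt(max(abs(within - 0.25)), 0.06)
  expect_lt(max(abs(across)), 0.06)
})

test_that("non-PSD correlation specs are rejected", {
  pan <- biomarker_panel()[1:3, ]
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(sample_biomarkers(pan, 10, correlation = bad, seed = 1),
               "positive semidefinite")
  expect_error(sample_biomarkers(pan, 10, correlation = "nonsense", seed = 1),
               "invalid correlation")
})

test_that("invalid marginal specs are rejected", {
  pan <- biomarker_panel()[1:2, ]
  pan$median[1] <- -1
  expect_error(sample_biomarkers(pan, 5, seed = 1), "positive")
  pan2 <- biomarker_panel()[1:2, ]
  pan2$q1[2] <- pan2$q3[2] * 2
  expect_error(sample_biomarkers(pan2, 5, seed = 1), "q1 <= median <= q3")
})

test_that("clinical marginals match the baseline table", {
  clin <- sample_clinical(5000, seed = 11)
  expect_lt(abs(mean(clin$age) - 63.5), 0.5)
  expect_lt(abs(mean(clin$sex == "male") - 0.537), 0.03)
  expect_lt(abs(mean(clin$current_smoker) - 0.096), 0.02)
  expect_lt(abs(mean(clin$sbp) - 135.2), 1.0)
  expect_lt(abs(mean(clin$egfr0) - 77.9), 1.5)
  expect_lt(abs(median(clin$uacr) / 1.2 - 1), 0.10)
  expect_true(all(clin$age >= 35 & clin$age <= 75))
  expect_true(all(clin$uacr > 0))
})

test_that("clinical sampling is deterministic given the seed", {
  a <- sample_clinical(1, seed = 99)
  b <- sample_clinical(1, seed = 99)
  expect_identical(a, b)
  c2 <- sample_clinical(5, seed = 100)
  expect_false(identical(a$age, c2$age[1]))
})

test_that("true slopes follow the configured linear model exactly", {
  X <- data.frame(a = c(1, 2, 3), b = c(0, 1, 0))
  s0 <- assign_true_slopes(X, c(a = 0, b = 0), intercept_true = -2,
                           noise_sd = 0)
  expect_equal(s0, rep(-2, 3))
  s1 <- assign_true_slopes(X, c(a = -1), intercept_true = 0, noise_sd = 0)
  expect_equal(s1, -X$a)
  expect_error(
    assign_true_slopes(X, c(zz = 1), intercept_true = 0, noise_sd = 0),
    "unknown predictor")
})

test_that("default truth hits the reported slope mean and SD", {
  co <- simulate_cohort(gen_config(n_patients = 5000, seed = 5))
  expect_lt(abs(mean(co$truth$slopes) / -2.1 - 1), 0.10)
  expect_lt(abs(sd(co$truth$slopes) / 4.5 - 1), 0.10)
})

test_that("cohort simulation is bit-identical under one config", {
  cfg <- gen_config(n_patients = 30, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$biomarkers, b$biomarkers)
  expect_identical(a$creatinine, b$creatinine)
  expect_identical(a$truth$slopes, b$truth$slopes)
})

test_that("substreams decouple the generator stages", {
  # changing only the creatinine noise must not move clinical/biomarker draws
  a <- simulate_cohort(gen_config(n_patients = 20, seed = 3,
                                  creatinine_noise_cv = 0))
  b <- simulate_cohort(gen_config(n_patients = 20, seed = 3,
                                  creatinine_noise_cv = 0.1))
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$biomarkers, b$biomarkers)
  expect_identical(a$truth$slopes, b$truth$slopes)
})

test_that("missingness injection hits the configured rates exactly", {
  pan <- biomarker_panel()
  co <- simulate_cohort(gen_config(n_patients = 400, seed = 21))
  mf <- colMeans(is.na(co$biomarkers))
  bf <- colMeans(co$below_lod & !is.na(co$biomarkers))
  for (j in seq_len(nrow(pan))) {
    expect_lt(abs(mf[pan$name[j]] - pan$missing_rate[j]), 0.01)
    # below-LOD count is a floor (natural censoring can exceed the target)
    expect_gte(bf[pan$name[j]], round(pan$below_lod_rate[j] * 400) / 400)
    expect_lt(bf[pan$name[j]], pan$below_lod_rate[j] + 0.05)
  }
})

test_that("zero rates leave the biomarker table unchanged", {
  pan <- biomarker_panel()
  pan$missing_rate <- 0
  pan$below_lod_rate <- 0
  pan$lod <- pan$median / 1e6
  cfg <- gen_config(n_patients = 50, seed = 13, panel = pan)
  co <- simulate_cohort(cfg)
  expect_false(anyNA(co$biomarkers))
  expect_false(any(co$below_lod))
})

test_that("a marker with >10% missing subsequently fails quality control", {
  pan <- biomarker_panel()
  pan$missing_rate[pan$name == "CCL2"] <- 0.15
  co <- simulate_cohort(gen_config(n_patients = 100, seed = 31, panel = pan))
  qc <- qc_filter_biomarkers(co$biomarkers, co$below_lod)
  expect_false("CCL2" %in% qc$kept)
})

test_that("cohort files round-trip through plain text", {
  co <- simulate_cohort(gen_config(n_patients = 12, seed = 77))
  dir <- tempfile()
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  wide <- read.csv(file.path(dir, "cohort.csv"))
  expect_equal(nrow(wide), 12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$slopes, co$truth$slopes, tolerance = 1e-12)
  cre <- read.csv(file.path(dir, "creatinine.csv"))
  expect_equal(nrow(cre), 12 * 5)
  unlink(dir, recursive = TRUE)
})
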