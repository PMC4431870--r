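#' Reference biomarker panel specification
#'
#' The 28-biomarker multi-pathway panel with the marginal distribution each
#' marker is simulated from: median and quartiles in assay units (log-normal
#' marginals), assay limit of detection, and the missingness / below-LOD
#' rates the generator injects. The 23 analyzable markers carry the
#' concentrations reported for the study cohort; the five markers that were
#' excluded for excessive missingness or censoring (NPHS1, NRP1, IL1A, IL1B,
#' EGF) carry synthetic concentration scales — only their failure of quality
#' control matters downstream — and rates engineered to violate the QC
#' bounds (>10% missing or >25% below LOD).
#'
#' The LOD is placed at the `below_lod_rate` quantile of the marker's
#' marginal (so natural censoring matches the target rate), or at median/50
#' when the rate is zero.
#'
#' @return data.frame with columns name, pathway, unit, median, q1, q3,
#'   lod, missing_rate, below_lod_rate.
#' @export
biomarker_panel <- function() {
  p <- utils::read.csv(text = "name,pathway,unit,median,q1,q3,missing_rate,below_lod_rate
CCL2,inflammation,pg/mL,316.2,258.3,386.4,0.02,0
TNFR1,inflammation,ng/mL,3.8,3.1,6.7,0,0
TNFR2,inflammation,pg/mL,317.6,248.3,475.0,0.05,0
YKL40,inflammation,ng/mL,36.5,21.1,87.1,0,0
CXCL1,inflammation,pg/mL,80.0,71.1,94.7,0,0
CXCL10,inflammation,pg/mL,80.6,58.1,121.7,0.02,0
CTGF,fibrosis,nmol/L,1.0,0.8,1.5,0,0
MMP1,fibrosis,pg/mL,767.4,470.0,1315.5,0,0
MMP2,fibrosis,ng/mL,38.3,36.1,40.0,0,0
MMP7,fibrosis,ng/mL,1.6,0.6,3.0,0,0.05
MMP8,fibrosis,ng/mL,2.4,1.5,4.8,0,0
MMP13,fibrosis,pg/mL,120.0,108.5,142.4,0.02,0
NPHS2,fibrosis,ng/mL,0.9,0.3,1.2,0,0.10
LEP,fibrosis,ng/mL,15.9,10.1,33.3,0,0
COL18A1,angiogenesis,pmol/L,7.6,6.3,9.7,0,0
TEK,angiogenesis,pg/mL,666.9,315.7,1275.8,0,0
VEGFA,angiogenesis,pg/mL,66.7,30.6,155.9,0,0.05
HGF,angiogenesis,pg/mL,65.9,35.0,120.3,0.05,0
NTproCNP,endothelial,pmol/L,2.9,2.3,4.3,0,0
FGF23,mineral,pmol/L,4.0,2.6,5.5,0.02,0
SOST,mineral,pmol/L,42.7,33.4,52.2,0,0
AZGP1,lipid,ng/mL,13.4,9.0,20.2,0,0
GH1,glomerular,pg/mL,330.8,53.4,994.2,0.05,0.10
NPHS1,glomerular,ng/mL,1.1,0.5,2.2,0,0.35
NRP1,angiogenesis,ng/mL,0.6,0.3,1.2,0,0.30
IL1A,inflammation,pg/mL,0.4,0.15,0.9,0,0.40
IL1B,inflammation,pg/mL,0.6,0.25,1.3,0.15,0.10
EGF,glomerular,pg/mL,18,8,45,0.20,0
", stringsAsFactors = FALSE)
  z75 <- stats::qnorm(0.75)
  sig_lo <- (log(p$median) - log(p$q1)) / z75
  p$lod <- ifelse(p$below_lod_rate > 0,
                  exp(log(p$median) + stats::qnorm(p$below_lod_rate) * sig_lo),
                  p$median / 50)
  p
}

#' Log-scale SD matching stated quartiles of a log-normal marginal
#'
#' `sigma = (ln q3 - ln q1) / (2 * 0.6745)`: the log-IQR divided by the
#' standard-normal IQR.
#'
#' @param q1,q3 first and third quartiles (positive).
#' @return log-scale standard deviation(s).
#' @export
log_sigma_from_quartiles <- function(q1, q3) {
  if (any(q1 <= 0) || any(q3 <= 0)) stop("quartiles must be positive")
  (log(q3) - log(q1)) / (2 * stats::qnorm(0.75))
}

# Two-piece (split) log-normal: log x = ln(median) + sigma_lo * z for z < 0,
# + sigma_hi * z for z >= 0, with sigma_lo/hi = (ln med - ln q1)/0.6745 and
# (ln q3 - ln med)/0.6745. Matches median, q1 and q3 exactly even when the
# printed quartiles are asymmetric around the median on the log scale.
split_sigmas <- function(median, q1, q3) {
  z75 <- stats::qnorm(0.75)
  list(lo = (log(median) - log(q1)) / z75,
       hi = (log(q3) - log(median)) / z75)
}

split_lognormal_from_z <- function(z, median, q1, q3) {
  s <- split_sigmas(median, q1, q3)
  exp(log(median) + ifelse(z < 0, s$lo, s$hi) * z)
}

# mean of log(x) for the split log-normal (used for closed-form intercept
# calibration of the simulation truth): ln(med) + dnorm(0) * (s_hi - s_lo)
split_lognormal_meanlog <- function(median, q1, q3) {
  s <- split_sigmas(median, q1, q3)
  log(median) + stats::dnorm(0) * (s$hi - s$lo)
}

#' Reference clinical marginals for the simulated cohort
#'
#' Means/SDs, proportions, and truncation bounds emulating the baseline
#' table of the 82-patient type 2 diabetes cohort. Continuous covariates
#' are truncated Gaussians whose location is moment-matched so that the
#' truncated mean equals the stated mean; UACR (mg/mmol) is a two-piece
#' log-normal matching the stated median and quartiles exactly.
#'
#' @return a list of distribution parameters.
#' @export
clinical_reference <- function() {
  list(
    age = c(mean = 63.5, sd = 9.4, lo = 35, hi = 75),
    bmi = c(mean = 32.4, sd = 6.3, lo = 15, hi = 60),
    sbp = c(mean = 135.2, sd = 16.3, lo = 80, hi = 220),
    dbp = c(mean = 72.7, sd = 10.5, lo = 40, hi = 130),
    diabetes_duration = c(mean = 15.7, sd = 7.3, lo = 5, hi = 50),
    hdl = c(mean = 1.3, sd = 0.4, lo = 0.4, hi = 3),
    ldl = c(mean = 2.0, sd = 0.6, lo = 0.5, hi = 6),
    hba1c = c(mean = 7.7, sd = 1.3, lo = 4.5, hi = 14),
    egfr0 = c(mean = 77.9, sd = 22.6, lo = 15, hi = 150),
    uacr = c(median = 1.2, q1 = 0.5, q3 = 57.7),
    p_male = 0.537, p_smoker = 0.096,
    p_raas = 0.429, p_insulin = 0.921, p_oral = 0.556
  )
}

# Truncated normal whose *truncated* mean equals `mean`: the pre-truncation
# location is solved numerically, then sampling is by inverse CDF.
rtnorm_matched <- function(n, mean, sd, lo, hi) {
  tmean <- function(mu) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  mu <- stats::uniroot(function(m) tmean(m) - mean,
                       interval = c(mean - 6 * sd, mean + 6 * sd),
                       extendInt = "upX", tol = 1e-10)$root
  u <- stats::runif(n, stats::pnorm(lo, mu, sd), stats::pnorm(hi, mu, sd))
  stats::qnorm(u, mu, sd)
}

#' Sample clinical covariates
#'
#' @param n number of patients.
#' @param seed integer seed.
#' @param reference parameter list, see [clinical_reference()].
#' @return data.frame with id, demographics, laboratory values (including
#'   baseline eGFR `egfr0` and the consistent baseline creatinine `scr0`),
#'   and medication flags.
#' @export
sample_clinical <- function(n, seed = 1, reference = clinical_reference()) {
  stopifnot(n >= 1)
  r <- reference
  with_substream(seed, "clinical", 0L, {
    tn <- function(p) rtnorm_matched(n, p["mean"], p["sd"], p["lo"], p["hi"])
    d <- data.frame(
      id = seq_len(n),
      age = tn(r$age),
      sex = ifelse(stats::runif(n) < r$p_male, "male", "female"),
      current_smoker = as.integer(stats::runif(n) < r$p_smoker),
      bmi = tn(r$bmi),
      sbp = tn(r$sbp),
      dbp = tn(r$dbp),
      diabetes_duration = tn(r$diabetes_duration),
      uacr = split_lognormal_from_z(stats::rnorm(n), r$uacr["median"],
                                    r$uacr["q1"], r$uacr["q3"]),
      hdl = tn(r$hdl),
      ldl = tn(r$ldl),
      hba1c = tn(r$hba1c),
      med_raas = as.integer(stats::runif(n) < r$p_raas),
      med_insulin = as.integer(stats::runif(n) < r$p_insulin),
      med_oral = as.integer(stats::runif(n) < r$p_oral),
      egfr0 = tn(r$egfr0)
    )
    d$scr0 <- mdrd_scr(d$egfr0, d$age, d$sex == "female")
    rownames(d) <- NULL
    d
  })
}

#' Build a biomarker correlation structure
#'
#' `pathway_factor(loading)` gives each pathway one latent factor with the
#' stated loading on every marker of that pathway (within-pathway log-scale
#' correlation `loading^2`, zero across pathways).
#'
#' @param loading factor loading in [0, 1).
#' @return correlation spec consumed by [sample_biomarkers()].
#' @export
pathway_factor <- function(loading = 0.5) {
  stopifnot(loading >= 0, loading < 1)
  structure(list(type = "pathway_factor", loading = loading),
            class = "correlation_spec")
}

build_correlation <- function(correlation, panel) {
  p <- nrow(panel)
  if (is.matrix(correlation)) {
    if (!all(dim(correlation) == p)) stop("correlation matrix must be p x p")
    R <- correlation
  } else if (identical(correlation, "identity")) {
    R <- diag(p)
  } else if (inherits(correlation, "correlation_spec") &&
             correlation$type == "pathway_factor") {
    same <- outer(panel$pathway, panel$pathway, "==")
    R <- ifelse(same, correlation$loading^2, 0)
    diag(R) <- 1
  } else stop("invalid correlation spec")
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop("correlation spec is not positive semidefinite (min eigenvalue ",
         format(min(ev$values)), ")")
  ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow = p)
}

#' Sample biomarker concentrations
#'
#' Each marker j follows a two-piece log-normal centred at `ln(median_j)`
#' with separate lower/upper log-scale SDs matching its printed quartiles
#' exactly (the study's concentration quartiles are asymmetric on the log
#' scale); cross-marker dependence is imposed on the underlying Gaussian
#' scale by the correlation spec.
#'
#' @param panel data.frame as from [biomarker_panel()].
#' @param n number of patients.
#' @param correlation `"identity"`, a [pathway_factor()] spec, or a full
#'   correlation matrix.
#' @param seed integer seed.
#' @return n x p matrix of concentrations (assay units), columns named by
#'   marker.
#' @export
sample_biomarkers <- function(panel, n, correlation = pathway_factor(0.5),
                              seed = 1) {
  stopifnot(n >= 1)
  if (any(panel$median <= 0) || any(panel$q1 <= 0) || any(panel$q3 <= 0))
    stop("medians and quartiles must be positive")
  if (any(panel$q1 > panel$median) || any(panel$median > panel$q3))
    stop("quartiles must satisfy q1 <= median <= q3")
  A <- build_correlation(correlation, panel)
  p <- nrow(panel)
  with_substream(seed, "biomarker", 0L, {
    Z <- matrix(stats::rnorm(n * p), n, p) %*% t(A)
    X <- vapply(seq_len(p), function(j)
      split_lognormal_from_z(Z[, j], panel$median[j], panel$q1[j],
                             panel$q3[j]),
      numeric(n))
    X <- matrix(X, n, p, dimnames = list(NULL, panel$name))
    X
  })
}

#' Simulation truth: linear model for the annual eGFR slope
#'
#' `slope_i = intercept + sum_j beta_j x_ij + eps_i`, with
#' `eps ~ N(0, noise_sd^2)`. `beta_true` is named by columns of `X`
#' (transformed predictors: natural-log UACR, binary-log biomarkers, raw
#' clinical covariates).
#'
#' @param X data.frame/matrix of transformed predictors.
#' @param beta_true named effect vector (slope units per transformed unit).
#' @param intercept_true intercept, slope units.
#' @param noise_sd residual SD, slope units.
#' @param seed integer seed.
#' @return numeric vector of true slopes (mL/min/1.73m^2/year).
#' @export
assign_true_slopes <- function(X, beta_true, intercept_true, noise_sd,
                               seed = 1) {
  stopifnot(noise_sd >= 0)
  unknown <- setdiff(names(beta_true), colnames(X))
  if (length(unknown))
    stop("unknown predictor key(s) in beta_true: ",
         paste(unknown, collapse = ", "))
  lin <- intercept_true +
    drop(as.matrix(X[, names(beta_true), drop = FALSE]) %*% beta_true)
  eps <- with_substream(seed, "outcome", 0L,
                        stats::rnorm(nrow(X), 0, noise_sd))
  lin + eps
}

#' Default simulation truth for the eGFR-slope outcome
#'
#' Effects (slope units per transformed-predictor unit) on a subset of
#' established risk markers and five biomarkers spanning four pathways,
#' with magnitudes in the range of the study's reported multivariable
#' coefficients. The intercept is chosen in closed form so the expected
#' slope equals `target_mean`; `noise_sd` is calibrated so the marginal
#' slope SD is close to 4.5.
#'
#' @param target_mean expected annual eGFR slope (default -2.1).
#' @return list(beta_true, intercept_true, noise_sd).
#' @export
default_truth <- function(target_mean = -2.1) {
  beta <- c(ln_uacr = -0.5, sbp = 0.049, egfr0 = -0.072,
            current_smoker = -1.6, sex_male = 0.8, med_oral = -1.06,
            TNFR1 = -1.6, MMP7 = -0.54, MMP2 = 7.38, CTGF = -2.0,
            TEK = -0.79)
  r <- clinical_reference()
  pan <- biomarker_panel()
  mu_bm <- function(nm) {
    i <- match(nm, pan$name)
    split_lognormal_meanlog(pan$median[i], pan$q1[i], pan$q3[i]) / log(2)
  }
  mu <- c(ln_uacr = split_lognormal_meanlog(unname(r$uacr["median"]),
                                            unname(r$uacr["q1"]),
                                            unname(r$uacr["q3"])),
          sbp = unname(r$sbp["mean"]), egfr0 = unname(r$egfr0["mean"]),
          current_smoker = r$p_smoker, sex_male = r$p_male,
          med_oral = r$p_oral,
          TNFR1 = mu_bm("TNFR1"), MMP7 = mu_bm("MMP7"),
          MMP2 = mu_bm("MMP2"), CTGF = mu_bm("CTGF"), TEK = mu_bm("TEK"))
  list(beta_true = beta,
       intercept_true = target_mean - sum(beta * mu[names(beta)]),
       noise_sd = 2.55)
}

#' Generator configuration
#'
#' @param n_patients cohort size (default 82, the study's).
#' @param seed master seed; every stage draws from a named substream.
#' @param visit_times creatinine visit schedule in years (annual visits
#'   over ~4 years of follow-up by default).
#' @param beta_true,intercept_true,noise_sd simulation truth, see
#'   [default_truth()].
#' @param creatinine_noise_cv coefficient of variation of multiplicative
#'   creatinine measurement noise (default 0.05, a typical assay CV).
#' @param latent_correlation biomarker dependence spec
#'   (default [pathway_factor()] with loading 0.5).
#' @param panel,reference marginal specifications.
#' @return list of class `gen_config`.
#' @export
gen_config <- function(n_patients = 82, seed = 1, visit_times = 0:4,
                       beta_true = NULL, intercept_true = NULL,
                       noise_sd = NULL, creatinine_noise_cv = 0.05,
                       latent_correlation = pathway_factor(0.5),
                       panel = biomarker_panel(),
                       reference = clinical_reference()) {
  stopifnot(n_patients >= 1, length(visit_times) >= 3,
            all(diff(visit_times) > 0), creatinine_noise_cv >= 0)
  tr <- default_truth()
  if (is.null(beta_true)) beta_true <- tr$beta_true
  if (is.null(intercept_true)) intercept_true <- tr$intercept_true
  if (is.null(noise_sd)) noise_sd <- tr$noise_sd
  stopifnot(noise_sd >= 0)
  structure(list(n_patients = n_patients, seed = seed,
                 visit_times = visit_times, beta_true = beta_true,
                 intercept_true = intercept_true, noise_sd = noise_sd,
                 creatinine_noise_cv = creatinine_noise_cv,
                 latent_correlation = latent_correlation, panel = panel,
                 reference = reference),
            class = "gen_config")
}

#' Transformed predictor design from clinical and biomarker draws
#'
#' Natural log of UACR, binary log of every biomarker, indicator coding for
#' sex, raw scales elsewhere — the transforms used in all regressions.
#'
#' @param clinical data.frame from [sample_clinical()].
#' @param biomarkers concentration matrix from [sample_biomarkers()].
#' @return data.frame of transformed predictors.
#' @export
transformed_design <- function(clinical, biomarkers) {
  d <- data.frame(
    ln_uacr = log(clinical$uacr),
    current_smoker = clinical$current_smoker,
    sex_male = as.numeric(clinical$sex == "male"),
    age = clinical$age, bmi = clinical$bmi,
    sbp = clinical$sbp, dbp = clinical$dbp,
    diabetes_duration = clinical$diabetes_duration,
    hdl = clinical$hdl, ldl = clinical$ldl, hba1c = clinical$hba1c,
    med_raas = clinical$med_raas, med_insulin = clinical$med_insulin,
    med_oral = clinical$med_oral, egfr0 = clinical$egfr0)
  cbind(d, as.data.frame(log2(biomarkers)))
}

#' Inject missingness and below-LOD censoring into a cohort
#'
#' For each biomarker, `round(missing_rate * n)` cells are masked missing
#' (MCAR: random positions, exact count) and below-LOD flags are completed
#' to `round(below_lod_rate * n)` among non-missing cells: cells naturally
#' drawn below the assay LOD are flagged, and additional cells are forced
#' below the LOD as needed to reach the target count.
#'
#' @param cohort a `cohort_table` from [simulate_cohort()].
#' @param seed integer seed (defaults to the cohort's missingness
#'   substream).
#' @return the cohort with `biomarkers` masked (NA), `below_lod` flags set,
#'   and values of forced cells moved below the LOD.
#' @export
inject_missingness <- function(cohort, seed = NULL) {
  panel <- cohort$panel
  X <- cohort$biomarkers
  n <- nrow(X)
  below <- matrix(FALSE, n, ncol(X), dimnames = dimnames(X))
  if (is.null(seed)) seed <- substream_seed(cohort$config$seed, "missingness")
  with_substream(seed, "inject", 0L, {
    for (j in seq_len(ncol(X))) {
      sp <- panel[j, ]
      n_miss <- round(sp$missing_rate * n)
      if (n_miss > 0) X[sample.int(n, n_miss), j] <- NA
      obs <- which(!is.na(X[, j]))
      nat <- obs[X[obs, j] < sp$lod]
      below[nat, j] <- TRUE
      n_target <- round(sp$below_lod_rate * n)
      n_force <- n_target - length(nat)
      if (n_force > 0) {
        cand <- setdiff(obs, nat)
        forced <- cand[sample.int(length(cand), min(n_force, length(cand)))]
        X[forced, j] <- sp$lod * stats::runif(length(forced), 0.2, 0.9)
        below[forced, j] <- TRUE
      }
    }
    cohort$biomarkers <- X
    cohort$below_lod <- below
    cohort
  })
}

#' Simulate a complete synthetic cohort
#'
#' Draws clinical covariates and correlated biomarker concentrations,
#' assigns true annual eGFR slopes from the configured linear truth,
#' synthesizes per-patient creatinine series by exact MDRD inversion with
#' measurement noise, and injects missingness / below-LOD censoring.
#' Patients whose latent eGFR trajectory would cross 1 mL/min/1.73m^2
#' within follow-up have the true slope clamped at the boundary (the
#' recorded truth is the clamped slope).
#'
#' @param config a [gen_config()].
#' @return an object of class `cohort_table`: `clinical`, `biomarkers`
#'   (with NA for missing), `below_lod`, `panel`, `creatinine` (long
#'   format), `design` (transformed predictors), and `truth`
#'   (beta/intercept/noise, the true slopes, clamped ids, seed).
#' @export
simulate_cohort <- function(config = gen_config()) {
  n <- config$n_patients
  clin <- sample_clinical(n, seed = substream_seed(config$seed, "clinical"),
                          reference = config$reference)
  bm <- sample_biomarkers(config$panel, n,
                          correlation = config$latent_correlation,
                          seed = substream_seed(config$seed, "biomarker"))
  design <- transformed_design(clin, bm)
  slopes <- assign_true_slopes(design, config$beta_true,
                               config$intercept_true, config$noise_sd,
                               seed = substream_seed(config$seed, "outcome"))
  tmax <- max(config$visit_times)
  floor_slope <- (1 - clin$egfr0) / tmax
  clamped <- which(slopes < floor_slope)
  slopes[clamped] <- floor_slope[clamped]
  cre <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- synthesize_creatinine_series(
      clin$egfr0[i], slopes[i], clin$age[i], clin$sex[i] == "female",
      visit_times = config$visit_times,
      noise_cv = config$creatinine_noise_cv,
      seed = substream_seed(config$seed, "creatinine", i))
    cbind(id = clin$id[i], s)
  }))
  cohort <- structure(list(clinical = clin, biomarkers = bm,
                           below_lod = NULL, panel = config$panel,
                           creatinine = cre, design = design,
                           truth = list(beta_true = config$beta_true,
                                        intercept_true = config$intercept_true,
                                        noise_sd = config$noise_sd,
                                        slopes = slopes, clamped = clamped,
                                        seed = config$seed),
                           config = config),
                      class = "cohort_table")
  inject_missingness(cohort)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d patients, %d biomarkers, %d creatinine rows\n",
              nrow(x$clinical), ncol(x$biomarkers), nrow(x$creatinine)))
  cat(sprintf("true slope mean %.2f, SD %.2f mL/min/1.73m2/yr\n",
              mean(x$truth$slopes), stats::sd(x$truth$slopes)))
  invisible(x)
}

#' Write a cohort to plain-text files
#'
#' Emits `cohort.csv` (one row per patient: clinical covariates, biomarker
#' concentrations with NA for missing, below-LOD flag columns),
#' `creatinine.csv` (long format: id, time_years, scr_umol_per_l), and
#' `truth.json` (the generating truth, for recovery tests).
#'
#' @param cohort a `cohort_table`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flags <- as.data.frame(cohort$below_lod)
  names(flags) <- paste0(names(flags), "_below_lod")
  wide <- cbind(cohort$clinical, as.data.frame(cohort$biomarkers), flags)
  paths <- file.path(dir, c("cohort.csv", "creatinine.csv", "truth.json"))
  utils::write.csv(wide, paths[1], row.names = FALSE)
  utils::write.csv(cohort$creatinine, paths[2], row.names = FALSE)
  jsonlite::write_json(
    list(beta_true = as.list(cohort$truth$beta_true),
         intercept_true = cohort$truth$intercept_true,
         noise_sd = cohort$truth$noise_sd, seed = cohort$truth$seed,
         slopes = cohort$truth$slopes),
    paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
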