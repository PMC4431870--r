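#' Estimated GFR from serum creatinine (4-variable MDRD study equation)
#'
#' eGFR = C * (Scr/88.4)^-1.154 * age^-0.203 * 0.742^female * 1.212^black,
#' with serum creatinine in umol/L (divided by 88.4 to obtain mg/dL). The
#' default constant `C = 175` is the IDMS-traceable re-expression; set
#' `constant = 186` for the original calibration.
#'
#' @param scr serum creatinine, umol/L.
#' @param age age in years.
#' @param female logical, TRUE for women.
#' @param black logical, TRUE applies the 1.212 factor (default FALSE).
#' @param constant equation constant, 175 (IDMS) or 186.
#' @return eGFR in mL/min/1.73m^2.
#' @export
mdrd_egfr <- function(scr, age, female, black = FALSE, constant = 175) {
  if (any(!is.finite(scr)) || any(scr <= 0)) stop("scr must be positive")
  if (any(!is.finite(age)) || any(age <= 0)) stop("age must be positive")
  constant * (scr / 88.4)^-1.154 * age^-0.203 *
    ifelse(female, 0.742, 1) * ifelse(black, 1.212, 1)
}

#' Invert the MDRD equation: serum creatinine giving a target eGFR
#'
#' Exact algebraic inverse of [mdrd_egfr()]; used by the synthetic cohort
#' generator to map latent eGFR trajectories back to creatinine.
#'
#' @inheritParams mdrd_egfr
#' @param egfr target eGFR, mL/min/1.73m^2.
#' @return serum creatinine in umol/L.
#' @export
mdrd_scr <- function(egfr, age, female, black = FALSE, constant = 175) {
  if (any(!is.finite(egfr)) || any(egfr <= 0)) stop("egfr must be positive")
  base <- constant * age^-0.203 * ifelse(female, 0.742, 1) * ifelse(black, 1.212, 1)
  88.4 * (egfr / base)^(-1 / 1.154)
}

#' Per-patient annual eGFR slope by ordinary least squares
#'
#' Fits a straight line through the eGFR values over time. At least three
#' measurements are required, matching the study's inclusion rule for the
#' outcome.
#'
#' @param times visit times in years.
#' @param egfr eGFR values, mL/min/1.73m^2.
#' @return list with `slope` (mL/min/1.73m^2 per year), `intercept`,
#'   `n_points`.
#' @export
estimate_slope <- function(times, egfr) {
  stopifnot(length(times) == length(egfr))
  ok <- is.finite(times) & is.finite(egfr)
  times <- times[ok]; egfr <- egfr[ok]
  n <- length(times)
  if (n < 3) stop("at least 3 creatinine measurements are required")
  if (length(unique(times)) < 2) stop("visit times must not all be equal")
  tb <- mean(times); yb <- mean(egfr)
  slope <- sum((times - tb) * (egfr - yb)) / sum((times - tb)^2)
  list(slope = slope, intercept = yb - slope * tb, n_points = n)
}

#' Classify accelerated eGFR decline
#'
#' Accelerated decline is a slope strictly below the threshold (default
#' -3.0 mL/min/1.73m^2/year, the study's dichotomization).
#'
#' @param slope annual eGFR slope.
#' @param threshold cutoff, default -3.
#' @return logical vector.
#' @export
classify_decline <- function(slope, threshold = -3) {
  if (any(!is.finite(slope))) stop("slope must be finite")
  slope < threshold
}

#' Slope outcomes for a cohort from a long-format creatinine table
#'
#' Converts each patient's creatinine series to eGFR via the MDRD equation
#' and estimates the annual slope. Patients with fewer than `min_points`
#' measurements are excluded and listed with a reason.
#'
#' @param creatinine data.frame with columns `id`, `time_years`,
#'   `scr_umol_per_l`.
#' @param demographics data.frame with columns `id`, `age` (baseline years),
#'   `female` (logical).
#' @param threshold accelerated-decline cutoff.
#' @param min_points minimum creatinine measurements (default 3).
#' @param advance_age if TRUE, age is advanced by the visit time when
#'   evaluating the MDRD equation; by default age is held at baseline.
#' @param black,constant passed to [mdrd_egfr()].
#' @return data.frame (id, slope, intercept, n_points, accelerated) with an
#'   `excluded` attribute (data.frame id, reason).
#' @export
slope_outcomes <- function(creatinine, demographics, threshold = -3,
                           min_points = 3, advance_age = FALSE,
                           black = FALSE, constant = 175) {
  stopifnot(all(c("id", "time_years", "scr_umol_per_l") %in% names(creatinine)),
            all(c("id", "age", "female") %in% names(demographics)))
  ids <- demographics$id
  out <- vector("list", length(ids))
  excl <- list()
  for (k in seq_along(ids)) {
    pid <- ids[k]
    ser <- creatinine[creatinine$id == pid, , drop = FALSE]
    if (nrow(ser) < min_points) {
      excl[[length(excl) + 1L]] <- data.frame(
        id = pid, reason = sprintf("only %d creatinine measurements", nrow(ser)))
      next
    }
    age <- demographics$age[k] + if (advance_age) ser$time_years else 0
    eg <- mdrd_egfr(ser$scr_umol_per_l, age, demographics$female[k],
                    black = black, constant = constant)
    fit <- estimate_slope(ser$time_years, eg)
    out[[k]] <- data.frame(id = pid, slope = fit$slope,
                           intercept = fit$intercept, n_points = fit$n_points)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res)) stop("no patient had enough creatinine measurements")
  res$accelerated <- classify_decline(res$slope, threshold)
  attr(res, "excluded") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(id = character(0), reason = character(0))
  rownames(res) <- NULL
  res
}

#' Synthesize a creatinine series consistent with a linear eGFR trajectory
#'
#' Maps eGFR(t) = baseline + slope * t through the exact MDRD inverse (age
#' advanced by t) and applies multiplicative log-normal measurement noise
#' with the given coefficient of variation (mean 1, so eGFR recovery is
#' unbiased on the original scale at cv = 0).
#'
#' @param baseline_egfr eGFR at t = 0.
#' @param slope annual change in eGFR.
#' @param age baseline age, years.
#' @param female logical.
#' @param visit_times years since baseline (>= 0, strictly increasing).
#' @param noise_cv coefficient of variation of measurement noise.
#' @param seed integer seed (ignored if noise_cv = 0).
#' @param black,constant passed to [mdrd_scr()].
#' @return data.frame (time_years, scr_umol_per_l).
#' @export
synthesize_creatinine_series <- function(baseline_egfr, slope, age, female,
                                         visit_times = 0:4, noise_cv = 0,
                                         seed = 1, black = FALSE,
                                         constant = 175) {
  stopifnot(baseline_egfr > 0, noise_cv >= 0, all(diff(visit_times) > 0))
  egfr <- baseline_egfr + slope * visit_times
  if (any(egfr <= 0))
    stop("eGFR trajectory reaches <= 0 within follow-up; truncate visit_times")
  scr <- mdrd_scr(egfr, age + visit_times, female, black = black,
                  constant = constant)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- with_substream(seed, "creatinine_noise", 0L,
                            stats::rlnorm(length(scr), -sdlog^2 / 2, sdlog))
    scr <- scr * noise
  }
  data.frame(time_years = visit_times, scr_umol_per_l = scr)
}
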