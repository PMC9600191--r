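#' Simulate clinical covariates and survival for scored patients
#'
#' Vectorized generative model for the clinical layer:
#' * intracranial pressure: `ln(ICP) = ln(1.3) + beta_icp * score + N(0, icp_sd)`
#'   (kPa); a lumboperitoneal shunt is placed when ICP exceeds 2.5 kPa (the
#'   clinical indication for shunting severe intracranial hypertension);
#' * KPS: `round-to-10(clamp(80 - beta_kps * score + N(0, kps_sd), 10, 100))`;
#' * MFS and OS: exponential with GS-baseline medians from the config, the
#'   hazard multiplied by `hr_mfs` / `hr_os` for GI patients, and independent
#'   administrative censoring `Uniform(0, censor_horizon)`;
#' * sex, age and primary tumor type drawn to echo the cohort the defaults
#'   emulate (80% lung adenocarcinoma).
#'
#' @param status Character vector, `"GI"`/`"GS"` per patient (true status).
#' @param gi_score Numeric vector of per-patient scores in `[0, 1]` driving
#'   ICP and KPS.
#' @param config A [gi_sim_config()].
#' @return Tibble with one row per patient: `sex`, `age`, `primary_tumor`,
#'   `kps`, `icp_kpa`, `lp_shunt`, `mfs_time`, `mfs_event`, `os_time`,
#'   `os_event`.
#' @export
#' @examples
#' set.seed(1)
#' simulate_clinical(c("GI", "GS"), c(0.3, 0.02), gi_sim_config())
simulate_clinical <- function(status, gi_score, config) {
  stopifnot(length(status) == length(gi_score),
            all(status %in% c("GI", "GS")))
  if (any(gi_score < 0 | gi_score > 1)) abort("gi_score must lie in [0, 1]")
  n <- length(status)
  icp <- exp(log(1.3) + config$beta_icp * gi_score + rnorm(n, 0, config$icp_sd))
  kps_raw <- 80 - config$beta_kps * gi_score + rnorm(n, 0, config$kps_sd)
  kps <- as.integer(round(pmin(pmax(kps_raw, 10), 100) / 10) * 10)
  surv_time <- function(median_gs, hr) {
    rate <- log(2) / median_gs * ifelse(status == "GI", hr, 1)
    rexp(n, rate)
  }
  t_mfs <- surv_time(config$mfs_median, config$hr_mfs)
  t_os <- surv_time(config$os_median, config$hr_os)
  c_mfs <- runif(n, 0, config$censor_horizon)
  c_os <- runif(n, 0, config$censor_horizon)
  tumors <- c("LUAD", "BRCA", "COAD", "STAD", "SCLC", "LUSC")
  tumor_p <- c(45, 7, 1, 1, 1, 1) / 56
  tibble(
    sex = sample(c("Female", "Male"), n, replace = TRUE, prob = c(0.52, 0.48)),
    age = as.integer(pmin(pmax(round(rnorm(n, 56, 10)), 25), 85)),
    primary_tumor = sample(tumors, n, replace = TRUE, prob = tumor_p),
    kps = kps,
    icp_kpa = icp,
    lp_shunt = icp > config$lp_shunt_icp,
    mfs_time = pmin(t_mfs, c_mfs),
    mfs_event = t_mfs <= c_mfs,
    os_time = pmin(t_os, c_os),
    os_event = t_os <= c_os
  )
}
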