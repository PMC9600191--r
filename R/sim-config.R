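#' Simulation configuration for synthetic MM liquid-biopsy cohorts
#'
#' Collects every tunable of the synthetic-cohort generator with defaults that
#' echo the printed facts of the motivating cohort: 56 patients of whom 50
#' have paired plasma, a 66.1% prevalence of genomic instability (GI) in CSF,
#' panel depths within the reported 471--9770x range, and survival with
#' GS-baseline medians of 2.9 years (MFS) and 3.9 years (OS) and true hazard
#' ratios 2.338 / 2.109 for GI patients.
#'
#' @param n_patients Number of patients.
#' @param gi_prevalence Probability a patient's clone is genomically unstable.
#' @param n_het_sites Heterozygous germline SNP sites per patient (panel-like
#'   density; not a claim about any real panel).
#' @param n_plasma,n_tissue Number of patients with a paired plasma / tissue
#'   sample.
#' @param depth_mean Named list of mean sequencing depths per compartment.
#' @param tumor_fraction Named list of tumor-fraction ranges `c(lo, hi)`:
#'   `gi_csf`, `gi_plasma`, `gi_tissue` apply to GI patients; GS patients and
#'   leukocytes have tumor fraction 0.
#' @param agf_range Range of the altered genome fraction of a GI clone.
#' @param depth_model `"poisson"` or `"nbinom"`; `nb_size` is the
#'   negative-binomial size (dispersion) parameter when `"nbinom"`.
#' @param nb_size Negative-binomial size when `depth_model = "nbinom"`.
#' @param wgs_bin_size Bin width (bases) for simulated low-pass WGS tracks.
#' @param wgs_mean_depth Mean read count per diploid bin.
#' @param beta_icp Log-scale effect of the GI score on intracranial pressure:
#'   `ln(ICP) = ln(1.3) + beta_icp * score + N(0, icp_sd)` (kPa).
#' @param icp_sd Log-scale ICP noise SD.
#' @param beta_kps Linear KPS penalty per unit GI score:
#'   `KPS = round10(clamp(80 - beta_kps * score + N(0, kps_sd), 10, 100))`.
#' @param kps_sd KPS noise SD (points).
#' @param lp_shunt_icp ICP (kPa) above which a lumboperitoneal shunt is
#'   placed; 2.5 kPa is the clinical indication.
#' @param mfs_median,os_median GS-baseline median survival (years),
#'   exponential model.
#' @param hr_mfs,hr_os True hazard ratios multiplying the baseline hazard for
#'   GI patients.
#' @param censor_horizon Administrative censoring: independent
#'   `Uniform(0, censor_horizon)` years (staggered entry, fixed analysis date).
#' @param driver_probs Tibble `gene`, `p_gi`, `p_gs`: per-status Bernoulli
#'   probabilities that a driver gene carries a somatic mutation. Config
#'   entries, not claims about biology.
#' @param plasma_detect_prob Probability a CSF somatic variant is also
#'   detectable in plasma.
#' @param seed Integer RNG seed; every simulation is reproducible given it.
#'
#' @return A list of class `gi_sim_config`.
#' @export
#' @examples
#' cfg <- gi_sim_config(n_patients = 8, seed = 1)
#' cfg$gi_prevalence
gi_sim_config <- function(n_patients = 56,
                          gi_prevalence = 0.661,
                          n_het_sites = 300,
                          n_plasma = 50,
                          n_tissue = 9,
                          depth_mean = list(leukocyte = 800, plasma = 1000,
                                            csf = 1500, tissue = 1000),
                          tumor_fraction = list(gi_csf = c(0.1, 0.6),
                                                gi_plasma = c(0, 0.05),
                                                gi_tissue = c(0.1, 0.6)),
                          agf_range = c(0.2, 0.6),
                          depth_model = c("poisson", "nbinom"),
                          nb_size = 20,
                          wgs_bin_size = 3e6,
                          wgs_mean_depth = 2000,
                          beta_icp = 1.2,
                          icp_sd = 0.5,
                          beta_kps = 30,
                          kps_sd = 10,
                          lp_shunt_icp = 2.5,
                          mfs_median = 2.9,
                          os_median = 3.9,
                          hr_mfs = 2.338,
                          hr_os = 2.109,
                          censor_horizon = 10,
                          driver_probs = default_driver_probs(),
                          plasma_detect_prob = 0.15,
                          seed = 20221014L) {
  depth_model <- match.arg(depth_model)
  cfg <- list(
    n_patients = as.integer(n_patients), gi_prevalence = gi_prevalence,
    n_het_sites = as.integer(n_het_sites),
    n_plasma = as.integer(min(n_plasma, n_patients)),
    n_tissue = as.integer(min(n_tissue, n_patients)),
    depth_mean = depth_mean, tumor_fraction = tumor_fraction,
    agf_range = agf_range, depth_model = depth_model, nb_size = nb_size,
    wgs_bin_size = wgs_bin_size, wgs_mean_depth = wgs_mean_depth,
    beta_icp = beta_icp, icp_sd = icp_sd, beta_kps = beta_kps,
    kps_sd = kps_sd, lp_shunt_icp = lp_shunt_icp,
    mfs_median = mfs_median, os_median = os_median,
    hr_mfs = hr_mfs, hr_os = hr_os, censor_horizon = censor_horizon,
    driver_probs = driver_probs, plasma_detect_prob = plasma_detect_prob,
    seed = as.integer(seed)
  )
  class(cfg) <- "gi_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default per-status somatic driver mutation probabilities
#'
#' Bernoulli probabilities that a driver gene is somatically mutated in a
#' patient's clone, split by true genomic status so that TP53-anchored
#' co-mutation enrichment in the GI group is exercisable downstream.
#'
#' @return A tibble with columns `gene`, `p_gi`, `p_gs`.
#' @export
default_driver_probs <- function() {
  tibble(
    gene = c("TP53", "EGFR", "RB1", "ERBB2", "KMT2C",
             "CDKN2A", "APC", "RICTOR"),
    p_gi = c(0.70, 0.50, 0.35, 0.30, 0.30, 0.30, 0.20, 0.20),
    p_gs = c(0.25, 0.30, 0.10, 0.08, 0.08, 0.10, 0.10, 0.05)
  )
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$gi_prevalence, cfg$plasma_detect_prob,
             cfg$driver_probs$p_gi, cfg$driver_probs$p_gs)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities in a gi_sim_config must lie in [0, 1]")
  }
  if (any(unlist(cfg$depth_mean) <= 0)) {
    abort("compartment mean depths must be positive")
  }
  for (nm in names(cfg$tumor_fraction)) {
    r <- cfg$tumor_fraction[[nm]]
    if (length(r) != 2 || any(r < 0 | r > 1) || r[1] > r[2]) {
      abort(paste0("tumor_fraction$", nm, " must be an increasing range in [0, 1]"))
    }
  }
  if (any(cfg$agf_range < 0 | cfg$agf_range > 1)) {
    abort("agf_range must lie in [0, 1]")
  }
  if (cfg$mfs_median <= 0 || cfg$os_median <= 0) {
    abort("baseline survival medians must be positive")
  }
  if (cfg$hr_mfs <= 0 || cfg$hr_os <= 0) abort("hazard ratios must be positive")
  invisible(cfg)
}

#' @export
print.gi_sim_config <- function(x, ...) {
  cat("<gi_sim_config>\n")
  cat(sprintf("  %d patients (%d plasma, %d tissue), GI prevalence %.3f\n",
              x$n_patients, x$n_plasma, x$n_tissue, x$gi_prevalence))
  cat(sprintf("  %d het sites; depths leuk/plasma/CSF/tissue = %s\n",
              x$n_het_sites, paste(unlist(x$depth_mean), collapse = "/")))
  cat(sprintf("  GI tumor fraction: CSF [%.2f, %.2f], plasma [%.2f, %.2f]\n",
              x$tumor_fraction$gi_csf[1], x$tumor_fraction$gi_csf[2],
              x$tumor_fraction$gi_plasma[1], x$tumor_fraction$gi_plasma[2]))
  cat(sprintf("  survival: MFS median %.1fy (HR %.3f), OS median %.1fy (HR %.3f)\n",
              x$mfs_median, x$hr_mfs, x$os_median, x$hr_os))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
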