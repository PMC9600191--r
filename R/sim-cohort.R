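#' Simulate a complete synthetic MM liquid-biopsy cohort
#'
#' Generates, for each patient: a shared panel of heterozygous germline SNP
#' sites; one aberrant clone (allele-specific copy-number segments) whose
#' tumor fraction differs by compartment (high in CSF, near zero in plasma
#' for GI patients; zero everywhere for GS patients); leukocyte, CSF and
#' optionally plasma/tissue variant tables with binomially sampled allele
#' fractions; a somatic driver-mutation layer with status-dependent gene
#' probabilities; CNV records where the mixture copy number of a driver gene
#' is visibly altered; a low-pass WGS bin-count track for the CSF sample; and
#' clinical covariates plus MFS/OS survival driven by the realized CSF GI
#' score (see [simulate_clinical()]).
#'
#' The generator is fully reproducible: `config$seed` determines every draw,
#' and writing the same cohort twice yields byte-identical files.
#'
#' @param config A [gi_sim_config()].
#' @param dir Optional output directory; when given, per-sample VCF and TSV
#'   variant tables, CSF bin tracks, a manifest CSV, a clinical CSV and a
#'   ground-truth JSON are written under it.
#' @return A list of class `gi_cohort`: `patients` (nested tibble with
#'   list-columns `leukocyte`, `csf`, `plasma`, `tissue`, `csf_bins`),
#'   `clinical`, `truth` (per-patient true status, tumor fractions, altered
#'   genome fraction), `config`, and `files` (paths, when `dir` given).
#' @export
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(gi_sim_config(n_patients = 6, seed = 1))
#' cohort$truth
#' }
simulate_cohort <- function(config = gi_sim_config(), dir = NULL) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%02d", seq_len(n))
  status <- ifelse(runif(n) < config$gi_prevalence, "GI", "GS")
  has_plasma <- seq_len(n) %in% sample(n, config$n_plasma)
  has_tissue <- seq_len(n) %in% sample(n, config$n_tissue)
  drv <- config$driver_probs
  genes <- panel_genes()

  per_patient <- purrr::map(seq_len(n), function(i) {
    sites <- simulate_het_sites(config$n_het_sites)
    clone <- if (status[i] == "GI") {
      make_clone_segments(runif(1, config$agf_range[1], config$agf_range[2]))
    } else {
      diploid_segments()
    }
    f_of <- function(cp) draw_tumor_fraction(config, status[i], cp)
    profs <- list(
      leukocyte = new_cna_profile(diploid_segments(), 0),
      csf = new_cna_profile(clone, f_of("csf")),
      plasma = if (has_plasma[i]) new_cna_profile(clone, f_of("plasma")),
      tissue = if (has_tissue[i]) new_cna_profile(clone, f_of("tissue"))
    )
    p_mut <- if (status[i] == "GI") drv$p_gi else drv$p_gs
    somatic_genes <- drv$gene[runif(nrow(drv)) < p_mut]
    in_plasma <- runif(length(somatic_genes)) < config$plasma_detect_prob
    tabs <- purrr::imap(profs, function(pr, cp) {
      if (is.null(pr)) return(NULL)
      v <- simulate_sample_variants(
        pr, sites, mean_depth = config$depth_mean[[cp]], config = config,
        sample_id = paste0(ids[i], "_", cp), patient_id = ids[i],
        compartment = cp
      )
      if (cp == "leukocyte") return(v)
      som_genes <- if (cp == "plasma") somatic_genes[in_plasma] else somatic_genes
      extra <- bind_rows(
        somatic_records(som_genes, pr, config$depth_mean[[cp]], config, genes),
        cnv_records(pr, genes)
      )
      if (nrow(extra) > 0) {
        v <- bind_rows(
          v,
          variant_table(extra, sample_id = paste0(ids[i], "_", cp),
                        patient_id = ids[i], compartment = cp)
        ) %>% validate_variant_tbl()
      }
      v
    })
    bins <- simulate_wgs_bins(profs$csf, config$wgs_bin_size,
                              config$wgs_mean_depth,
                              sample_id = paste0(ids[i], "_csf"))
    list(tabs = tabs, bins = bins,
         f_csf = profs$csf$tumor_fraction,
         f_plasma = if (has_plasma[i]) profs$plasma$tumor_fraction else NA_real_,
         f_tissue = if (has_tissue[i]) profs$tissue$tumor_fraction else NA_real_,
         agf = profile_agf(profs$csf))
  })

  patients <- tibble(
    patient_id = ids,
    leukocyte = purrr::map(per_patient, ~ .x$tabs$leukocyte),
    csf = purrr::map(per_patient, ~ .x$tabs$csf),
    plasma = purrr::map(per_patient, ~ .x$tabs$plasma),
    tissue = purrr::map(per_patient, ~ .x$tabs$tissue),
    csf_bins = purrr::map(per_patient, "bins")
  )
  truth <- tibble(
    patient_id = ids, status_true = status,
    f_csf = purrr::map_dbl(per_patient, "f_csf"),
    f_plasma = purrr::map_dbl(per_patient, "f_plasma"),
    f_tissue = purrr::map_dbl(per_patient, "f_tissue"),
    agf_true = purrr::map_dbl(per_patient, "agf")
  )
  csf_scores <- score_cohort(patients, compartments = "csf")
  score_for_clin <- csf_scores$score[match(ids, csf_scores$patient_id)]
  score_for_clin[is.na(score_for_clin)] <- 0
  clinical <- simulate_clinical(status, score_for_clin, config) %>%
    mutate(patient_id = ids, .before = 1)

  cohort <- structure(
    list(patients = patients, clinical = clinical, truth = truth,
         config = config, files = NULL),
    class = "gi_cohort"
  )
  if (!is.null(dir)) cohort <- write_cohort(cohort, dir)
  cohort
}

# Somatic driver SNVs of the clone: placed just downstream of the gene
# anchor, with allele fraction driven by the compartment's tumor fraction.
somatic_records <- function(som_genes, profile, mean_depth, config, genes) {
  if (length(som_genes) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), kind = character(), gene = character(),
                  alt_depth = integer(), total_depth = integer(),
                  af = double(), copy_number = double()))
  }
  g <- genes[match(som_genes, genes$gene), ]
  depth <- draw_depths(nrow(g), mean_depth, config)
  p <- pmax(profile$tumor_fraction * 0.4, 0.005)
  alt_depth <- rbinom(nrow(g), depth, p)
  tibble(
    chrom = g$chrom, pos = as.integer(g$pos + 501L), ref = "C", alt = "T",
    kind = "SNV", gene = g$gene,
    alt_depth = as.integer(alt_depth), total_depth = as.integer(depth),
    af = alt_depth / depth, copy_number = NA_real_
  )
}

# CNV records: one per panel gene whose mixture copy number deviates from
# diploid by more than 0.2 on the log2 scale in this compartment.
cnv_records <- function(profile, genes, log2_tol = 0.2) {
  idx <- site_segment_index(tibble(chrom = genes$chrom, pos = genes$pos),
                            profile$segments)
  f <- profile$tumor_fraction
  cn <- (1 - f) * 2 +
    f * (profile$segments$c_major[idx] + profile$segments$c_minor[idx])
  keep <- abs(log2(cn / 2)) > log2_tol
  tibble(
    chrom = genes$chrom[keep], pos = as.integer(genes$pos[keep]),
    ref = "N", alt = "<CNV>", kind = "CNV", gene = genes$gene[keep],
    alt_depth = NA_integer_, total_depth = NA_integer_, af = NA_real_,
    copy_number = round(cn[keep], 4)
  )
}

#' Write a simulated cohort to disk
#'
#' Emits per-sample variant tables (VCF v4.2 and TSV mirror), CSF bin tracks
#' (BED-like TSV), a manifest CSV, a clinical CSV and a ground-truth JSON.
#' Output is byte-deterministic for a fixed config.
#'
#' @param cohort A `gi_cohort`.
#' @param dir Output directory (created if needed).
#' @return The cohort with `files` filled in, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  vdir <- file.path(dir, "variants")
  bdir <- file.path(dir, "bins")
  for (d in c(dir, vdir, bdir)) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  if (!dir.exists(dir)) abort(paste0("cannot create output directory: ", dir))
  pts <- cohort$patients
  man <- purrr::map_dfr(seq_len(nrow(pts)), function(i) {
    purrr::map_dfr(COMPARTMENTS, function(cp) {
      tab <- pts[[cp]][[i]]
      if (is.null(tab)) return(NULL)
      sid <- tab$sample_id[1]
      vcf <- file.path(vdir, paste0(sid, ".vcf"))
      tsv <- file.path(vdir, paste0(sid, ".tsv"))
      write_variant_table(tab, vcf, format = "vcf")
      write_variant_table(tab, tsv, format = "tsv")
      tibble(patient_id = pts$patient_id[i], sample_id = sid,
             compartment = cp, path = file.path("variants", paste0(sid, ".tsv")))
    })
  })
  for (i in seq_len(nrow(pts))) {
    write_bin_track(pts$csf_bins[[i]],
                    file.path(bdir, paste0(pts$patient_id[i], "_csf.bins.tsv")))
  }
  manifest_path <- file.path(dir, "manifest.csv")
  clinical_path <- file.path(dir, "clinical.csv")
  truth_path <- file.path(dir, "ground_truth.json")
  readr::write_csv(man, manifest_path, progress = FALSE)
  readr::write_csv(cohort$clinical, clinical_path, progress = FALSE)
  jsonlite::write_json(cohort$truth, truth_path, digits = NA, pretty = TRUE)
  cohort$files <- list(dir = dir, manifest = manifest_path,
                       clinical = clinical_path, truth = truth_path)
  invisible(cohort)
}

#' @export
print.gi_cohort <- function(x, ...) {
  cat(sprintf("<gi_cohort> %d patients (%d GI true), %d plasma, %d tissue; seed %d\n",
              nrow(x$patients), sum(x$truth$status_true == "GI"),
              sum(!purrr::map_lgl(x$patients$plasma, is.null)),
              sum(!purrr::map_lgl(x$patients$tissue, is.null)),
              x$config$seed))
  invisible(x)
}

#' Read a ground-truth JSON back as a tibble
#'
#' @param path Path to a `ground_truth.json` written by [write_cohort()].
#' @return Tibble matching the cohort's `truth` slot.
#' @export
read_ground_truth <- function(path) {
  as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}
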