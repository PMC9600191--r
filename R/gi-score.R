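#' Retain germline heterozygous variants from a leukocyte table
#'
#' Leukocyte variants with mutant allele fraction below 0.2 or above 0.8 are
#' filtered out, so that the variants entering the score are germline-derived
#' common heterozygous mutations (expected AF 0.5). The removal rule is a
#' strict inequality: AF exactly 0.2 or 0.8 is retained. CNV records never
#' pass the filter; the score is defined on SNVs and indels only.
#'
#' @param leukocyte A `gi_variant_tbl` with `compartment == "leukocyte"` —
#'   the filter is defined on the reference compartment only.
#' @param af_bounds Lower/upper retained AF bounds (inclusive).
#' @return The filtered `gi_variant_tbl`.
#' @export
#' @examples
#' t <- variant_table(
#'   data.frame(chrom = "chr1", pos = 1:5, ref = "A", alt = "G", kind = "SNV",
#'              alt_depth = c(19, 20, 50, 80, 81), total_depth = 100),
#'   "L1", "P1", "leukocyte"
#' )
#' filter_germline_hets(t)$af  # 0.20, 0.50, 0.80
filter_germline_hets <- function(leukocyte, af_bounds = c(0.2, 0.8)) {
  if (!identical(unique(leukocyte$compartment), "leukocyte") &&
      nrow(leukocyte) > 0) {
    abort("the germline het filter is defined on the leukocyte (reference) compartment")
  }
  leukocyte %>%
    filter(.data$kind != "CNV",
           !is.na(.data$af),
           .data$af >= af_bounds[1], .data$af <= af_bounds[2]) %>%
    validate_variant_tbl()
}

#' Shared germline mutations between the leukocyte reference and an assay sample
#'
#' Screens an assay compartment (CSF, plasma or tissue) for mutations shared
#' with the filtered leukocyte reference of the same patient. Matching is by
#' normalized variant key `(chrom, pos, ref, alt)` (see
#' [normalize_variants()]); CNV records never match.
#'
#' @param leuk_filtered Leukocyte table after [filter_germline_hets()].
#' @param assay Assay-compartment `gi_variant_tbl` of the same patient.
#' @return A tibble of shared mutations: key columns plus `gene`,
#'   `leukocyte_af`, `sample_af`, `alt_depth`, `total_depth`, and the assay
#'   `sample_id`/`compartment`.
#' @export
shared_mutations <- function(leuk_filtered, assay) {
  if (nrow(leuk_filtered) > 0 && nrow(assay) > 0 &&
      !identical(leuk_filtered$patient_id[1], assay$patient_id[1])) {
    abort(sprintf("patient mismatch: leukocyte table is %s, assay table is %s",
                  leuk_filtered$patient_id[1], assay$patient_id[1]))
  }
  ln <- normalize_variants(leuk_filtered) %>%
    filter(.data$kind != "CNV") %>%
    mutate(key = variant_key(.))
  an <- normalize_variants(assay) %>%
    filter(.data$kind != "CNV") %>%
    mutate(key = variant_key(.))
  inner_join(
    ln %>% select("key", "chrom", "pos", "ref", "alt", "gene",
                  leukocyte_af = "af"),
    an %>% select("key", sample_af = "af", "alt_depth", "total_depth",
                  "sample_id", "compartment"),
    by = "key"
  )
}

#' Classify a shared mutation as a GI mutation
#'
#' A shared germline heterozygous mutation counts as a GI mutation when its
#' allele fraction in the assay sample falls outside the theoretical quartile
#' band around the diploid heterozygous expectation of 0.5: AF below 0.25 or
#' above 0.75. The band boundaries themselves are not GI.
#'
#' @param sample_af Allele fraction(s) in `[0, 1]`.
#' @param band Quartile band; AF strictly outside it is GI.
#' @return Logical vector.
#' @export
#' @examples
#' classify_gi_mutation(c(0.5, 0.76, 0.24, 0.25, 0.75))
classify_gi_mutation <- function(sample_af, band = c(0.25, 0.75)) {
  if (any(is.na(sample_af)) || any(sample_af < 0 | sample_af > 1)) {
    abort("sample_af must lie in [0, 1]")
  }
  sample_af < band[1] | sample_af > band[2]
}

#' Compute the GI score of one sample
#'
#' The GI score is the proportion of shared germline mutations that are GI
#' mutations:
#' \deqn{GI\_Score = N_{GI} / N_{common}}
#' where `N_common` counts the shared germline heterozygous mutations and
#' `N_GI` those with assay AF outside the quartile band (see
#' [classify_gi_mutation()]). Samples with fewer than `min_common` shared
#' mutations are reported `indeterminate` with an undefined (`NA`) score
#' rather than an unstable ratio of tiny counts.
#'
#' @param shared Shared-mutation tibble from [shared_mutations()].
#' @param min_common Minimum `N_common` required to score a sample.
#' @param band Quartile band passed to [classify_gi_mutation()].
#' @return One-row tibble: `sample_id`, `compartment`, `n_common`, `n_gi`,
#'   `score`, `status` (`NA` until classified by [classify_status()], or
#'   `"indeterminate"`), `cutoff_used` (`NA`).
#' @export
#' @examples
#' sh <- tibble::tibble(sample_af = c(rep(0.5, 8), 0.9, 0.1),
#'                      sample_id = "S1", compartment = "csf")
#' compute_gi_score(sh, min_common = 5) # score 0.2
compute_gi_score <- function(shared, min_common = 20, band = c(0.25, 0.75)) {
  n_common <- nrow(shared)
  sample_id <- if (n_common > 0) shared$sample_id[1] else NA_character_
  compartment <- if (n_common > 0) shared$compartment[1] else NA_character_
  if (n_common < min_common) {
    return(tibble(sample_id = sample_id, compartment = compartment,
                  n_common = n_common, n_gi = NA_integer_, score = NA_real_,
                  status = "indeterminate", cutoff_used = NA_real_))
  }
  n_gi <- sum(classify_gi_mutation(shared$sample_af, band = band))
  tibble(sample_id = sample_id, compartment = compartment,
         n_common = n_common, n_gi = as.integer(n_gi),
         score = n_gi / n_common, status = NA_character_,
         cutoff_used = NA_real_)
}

#' Score every assay sample of a cohort
#'
#' Runs the full scoring chain — germline het filter, shared-mutation screen,
#' GI score — for each assay compartment of each patient in a nested cohort
#' tibble (as returned by [load_manifest()] or [simulate_cohort()]).
#'
#' @param patients Nested cohort tibble with list-columns `leukocyte`, `csf`,
#'   `plasma`, `tissue`.
#' @param compartments Assay compartments to score.
#' @param min_common,band,af_bounds Passed through to the scoring chain.
#' @return Tibble with one row per scored sample: `patient_id` plus the
#'   columns of [compute_gi_score()].
#' @export
score_cohort <- function(patients, compartments = c("csf", "plasma", "tissue"),
                         min_common = 20, band = c(0.25, 0.75),
                         af_bounds = c(0.2, 0.8)) {
  purrr::map_dfr(seq_len(nrow(patients)), function(i) {
    leuk <- patients$leukocyte[[i]]
    if (is.null(leuk)) return(NULL)
    lf <- filter_germline_hets(leuk, af_bounds = af_bounds)
    purrr::map_dfr(compartments, function(cp) {
      assay <- patients[[cp]][[i]]
      if (is.null(assay)) return(NULL)
      compute_gi_score(shared_mutations(lf, assay),
                       min_common = min_common, band = band) %>%
        mutate(patient_id = patients$patient_id[i], .before = 1)
    })
  })
}
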