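#' Run the full GI analysis pipeline
#'
#' Orchestrates the stages end to end: obtain a cohort (simulate one, or load
#' a manifest from a prior run), score every assay sample, fit the GI/GS
#' cutoff on the configured compartment and classify, run the copy-number
#' validation arm on the CSF bin tracks, and compute the cohort statistics
#' (burden comparison, clinical group comparison, MFS/OS survival,
#' co-mutation enrichment, ICP-score correlation). Every output is stamped
#' with the seed and a hash of the effective configuration; a fixed
#' configuration yields a byte-identical report.
#'
#' @param sim_config A [gi_sim_config()] used when `manifest` is `NULL`.
#' @param manifest,clinical Paths to a manifest CSV and clinical CSV from a
#'   prior run; when given, simulation is skipped (the `bins_dir` next to the
#'   manifest is used for the CNV stage when present).
#' @param dir Optional output directory for stage outputs and the report
#'   (JSON and markdown).
#' @param stages Which stages to run after the cohort is obtained.
#' @param min_common,band,af_bounds Scoring parameters (see
#'   [compute_gi_score()], [filter_germline_hets()]).
#' @param cutoff_method,fixed_cutoff,cutoff_compartment Cutoff stage: method
#'   passed to [fit_cutoff()], and the compartment whose scores the cutoff is
#'   fitted on (CSF by default).
#' @param agf_threshold,merge_tol,call_tol CNV stage thresholds (see
#'   [segment_track()], [gi_concordance()]).
#' @param seed Seed for the cutoff EM restarts.
#' @return A list of class `gi_run`: `scores` (classified score table),
#'   `cutoff` (the `gi_cutoff` model), `cnv` (per-sample AGF and
#'   concordance), `cohort_stats` (burden, group comparisons, survival,
#'   co-mutation, correlations), `config_hash`, `seed`, `files`.
#' @export
#' @examples
#' \donttest{
#' run <- run_gi_pipeline(gi_sim_config(n_patients = 10, seed = 42))
#' run$scores
#' }
run_gi_pipeline <- function(sim_config = gi_sim_config(),
                            manifest = NULL, clinical = NULL,
                            dir = NULL,
                            stages = c("score", "cutoff", "cnv", "cohort"),
                            min_common = 20, band = c(0.25, 0.75),
                            af_bounds = c(0.2, 0.8),
                            cutoff_method = "mixture", fixed_cutoff = 0.07,
                            cutoff_compartment = "csf",
                            agf_threshold = 0.10, merge_tol = 0.1,
                            call_tol = 0.25, seed = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  seed <- as.integer(seed %||% sim_config$seed)
  if (!is.null(manifest)) {
    if (!file.exists(manifest)) abort(paste0("manifest not found: ", manifest))
    if (is.null(clinical) || !file.exists(clinical)) {
      abort("loading a manifest requires an existing clinical CSV")
    }
    patients <- load_manifest(manifest, clinical)
    clin <- purrr::map_dfr(patients$clinical, identity)
    bdir <- file.path(dirname(manifest), "bins")
    patients$csf_bins <- purrr::map(patients$patient_id, function(p) {
      f <- file.path(bdir, paste0(p, "_csf.bins.tsv"))
      if (file.exists(f)) read_bin_track(f)
    })
    truth <- NULL
  } else {
    cohort <- simulate_cohort(sim_config, dir = if (!is.null(dir)) {
      file.path(dir, "cohort")
    })
    patients <- cohort$patients
    clin <- cohort$clinical
    truth <- cohort$truth
  }
  eff <- list(min_common = min_common, band = band, af_bounds = af_bounds,
              cutoff_method = cutoff_method, fixed_cutoff = fixed_cutoff,
              cutoff_compartment = cutoff_compartment,
              agf_threshold = agf_threshold, merge_tol = merge_tol,
              call_tol = call_tol, seed = seed,
              sim = if (is.null(manifest)) unclass(sim_config))
  run <- list(scores = NULL, cutoff = NULL, cnv = NULL, cohort_stats = NULL,
              truth = truth, config = eff, config_hash = rlang::hash(eff),
              seed = seed, files = NULL)

  scores <- NULL
  if (any(c("score", "cutoff", "cnv", "cohort") %in% stages)) {
    scores <- score_cohort(patients, min_common = min_common, band = band,
                           af_bounds = af_bounds)
    run$scores <- scores
  }
  model <- NULL
  if (any(c("cutoff", "cnv", "cohort") %in% stages)) {
    fit_scores <- scores$score[scores$compartment == cutoff_compartment &
                                 is.finite(scores$score)]
    if (cutoff_method == "mixture" && length(fit_scores) < 10) {
      inform(sprintf(
        "only %d finite %s scores; using the fixed cutoff %.3f instead of a mixture fit",
        length(fit_scores), cutoff_compartment, fixed_cutoff
      ))
      cutoff_method <- "fixed"
    }
    model <- fit_cutoff(fit_scores, method = cutoff_method,
                        fixed_cutoff = fixed_cutoff, seed = seed)
    scores <- classify_status(scores, model)
    run$scores <- scores
    run$cutoff <- model
  }
  if ("cnv" %in% stages && "csf_bins" %in% names(patients)) {
    run$cnv <- purrr::map_dfr(seq_len(nrow(patients)), function(i) {
      bins <- patients$csf_bins[[i]]
      if (is.null(bins)) return(NULL)
      sm <- segment_track(compute_log2_ratios(bins), merge_tol = merge_tol,
                          call_tol = call_tol)
      res <- scores[scores$patient_id == patients$patient_id[i] &
                      scores$compartment == "csf", ]
      tibble(patient_id = patients$patient_id[i],
             agf = sm$altered_genome_fraction,
             cnv_status = ifelse(sm$altered_genome_fraction >= agf_threshold,
                                 "GI", "GS"),
             concordant = if (nrow(res) > 0) gi_concordance(sm, res,
                                                            agf_threshold) else NA)
    })
  }
  if ("cohort" %in% stages) {
    csf <- scores[scores$compartment == "csf", ]
    clin2 <- clin %>%
      left_join(csf %>% select("patient_id", "score", "status"),
                by = "patient_id") %>%
      filter(.data$status %in% c("GI", "GS"))
    stats <- list()
    stats$burden <- tryCatch(variant_burden_summary(patients),
                             error = function(e) NULL)
    if (nlevels(factor(clin2$status)) == 2) {
      stats$group_comparisons <- compare_groups(
        clin2, "status",
        intersect(c("sex", "age", "lp_shunt", "kps", "icp_kpa", "score"),
                  names(clin2))
      )
      stats$survival <- purrr::map(
        setNames(c("mfs", "os"), c("mfs", "os")),
        function(ep) {
          tryCatch(
            survival_analysis(clin2, endpoint = ep,
                              covariates = intersect(
                                c("status", "sex", "age", "lp_shunt", "kps"),
                                names(clin2)
                              )),
            error = function(e) NULL
          )
        }
      )
      stats$comutation <- comutation_enrichment(
        patients,
        csf %>% select("patient_id", "status"),
        scores = csf %>% select("patient_id", "score")
      )
      if (all(c("icp_kpa", "score") %in% names(clin2))) {
        stats$correlations <- correlate(clin2$icp_kpa, clin2$score) %>%
          mutate(pair = "icp_vs_score", .before = 1)
      }
    }
    run$cohort_stats <- stats
  }
  class(run) <- "gi_run"
  if (!is.null(dir)) run <- write_run_report(run, dir)
  run
}

#' @export
print.gi_run <- function(x, ...) {
  cat(sprintf("<gi_run> seed %d, config %s\n", x$seed, x$config_hash))
  if (!is.null(x$scores)) {
    tab <- table(x$scores$compartment, x$scores$status)
    cat("classified samples:\n")
    print(tab)
  }
  if (!is.null(x$cutoff)) {
    cat(sprintf("cutoff: %.4f (%s)\n", x$cutoff$cutoff, x$cutoff$method))
  }
  if (!is.null(x$cnv)) {
    cat(sprintf("CNV concordance: %.1f%%\n",
                100 * mean(x$cnv$concordant, na.rm = TRUE)))
  }
  invisible(x)
}

#' Write the run report (JSON and markdown)
#'
#' @param run A `gi_run`.
#' @param dir Output directory.
#' @return The run with `files` filled in, invisibly.
#' @export
write_run_report <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$scores, file.path(dir, "scores.csv"), progress = FALSE)
  if (!is.null(run$cutoff)) {
    write_cutoff_report(run$cutoff, file.path(dir, "cutoff.json"))
  }
  if (!is.null(run$cnv)) {
    readr::write_csv(run$cnv, file.path(dir, "cnv_concordance.csv"),
                     progress = FALSE)
  }
  surv_summary <- function(s) {
    if (is.null(s)) return(NULL)
    list(km = s$km, logrank_p = s$logrank_p, univariate = s$univariate,
         multivariate = s$multivariate)
  }
  report <- list(
    seed = run$seed, config_hash = run$config_hash, config = run$config,
    n_samples = nrow(run$scores %||% tibble()),
    status_counts = if (!is.null(run$scores)) {
      as.list(table(paste(run$scores$compartment, run$scores$status)))
    },
    cutoff = if (!is.null(run$cutoff)) {
      list(method = run$cutoff$method, cutoff = run$cutoff$cutoff)
    },
    cnv_concordance = if (!is.null(run$cnv)) {
      mean(run$cnv$concordant, na.rm = TRUE)
    },
    cohort_stats = if (!is.null(run$cohort_stats)) {
      s <- run$cohort_stats
      list(
        burden = if (!is.null(s$burden)) {
          list(count_tests = s$burden$count_tests,
               rate_tests = s$burden$rate_tests)
        },
        group_comparisons = s$group_comparisons,
        survival = purrr::map(s$survival %||% list(), surv_summary),
        comutation = if (!is.null(s$comutation)) s$comutation$pairs,
        correlations = s$correlations
      )
    }
  )
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  md <- c(
    "# GI pipeline run report",
    sprintf("- seed: %d", run$seed),
    sprintf("- config hash: %s", run$config_hash),
    if (!is.null(run$cutoff)) {
      sprintf("- cutoff: %.4f (method %s; score >= cutoff is GI)",
              run$cutoff$cutoff, run$cutoff$method)
    },
    if (!is.null(run$scores)) {
      csf <- run$scores[run$scores$compartment == "csf", ]
      sprintf("- CSF samples classified GI: %d / %d",
              sum(csf$status == "GI", na.rm = TRUE), nrow(csf))
    },
    if (!is.null(run$cnv)) {
      sprintf("- CNV/score concordance: %.1f%%",
              100 * mean(run$cnv$concordant, na.rm = TRUE))
    }
  )
  writeLines(md, file.path(dir, "report.md"))
  run$files <- list(dir = dir, json = json_path,
                    md = file.path(dir, "report.md"))
  invisible(run)
}
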