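#' Per-compartment variant burden and detection-rate comparison
#'
#' Counts total variants, SNVs/indels and CNVs per sample for patients with
#' paired CSF and plasma tables, compares the paired per-sample counts with
#' the Wilcoxon signed-rank test, and compares detection rates (any CNV
#' detected; each requested gene somatically mutated) between compartments
#' with the categorical-test rule of [compare_groups()]. A gene counts as
#' somatically mutated in a sample when it carries an SNV/indel absent from
#' the patient's leukocyte table.
#'
#' @param patients Nested cohort tibble (see [score_cohort()]).
#' @param genes Genes whose per-compartment detection rate is compared.
#' @return A list of class `gi_burden`: `per_sample` (tibble `patient_id`,
#'   `compartment`, `n_total`, `n_snv`, `n_cnv`), `count_tests` (paired
#'   Wilcoxon rows) and `rate_tests` (detection-rate rows).
#' @export
variant_burden_summary <- function(patients, genes = c("EGFR", "TP53")) {
  paired <- !purrr::map_lgl(patients$csf, is.null) &
    !purrr::map_lgl(patients$plasma, is.null)
  if (sum(paired) < 2) {
    abort("variant burden comparison needs >= 2 patients with paired CSF and plasma")
  }
  pts <- patients[paired, ]
  per_sample <- purrr::map_dfr(seq_len(nrow(pts)), function(i) {
    purrr::map_dfr(c("csf", "plasma"), function(cp) {
      tab <- somatic_only(pts[[cp]][[i]], pts$leukocyte[[i]])
      tibble(
        patient_id = pts$patient_id[i], compartment = cp,
        n_total = nrow(tab),
        n_snv = sum(tab$kind != "CNV"),
        n_cnv = sum(tab$kind == "CNV"),
        mutated_genes = list(unique(tab$gene[tab$kind != "CNV"]))
      )
    })
  })
  wide <- function(col) {
    m <- matrix(per_sample[[col]], ncol = 2, byrow = TRUE)
    list(csf = m[, 1], plasma = m[, 2])
  }
  count_tests <- purrr::map_dfr(
    c(total = "n_total", snv = "n_snv", cnv = "n_cnv"),
    .id = "variable",
    function(col) {
      w <- wide(col)
      p <- if (all(w$csf == w$plasma)) 1 else {
        suppressWarnings(stats::wilcox.test(w$csf, w$plasma, paired = TRUE)$p.value)
      }
      tibble(csf_mean = mean(w$csf), plasma_mean = mean(w$plasma),
             test = "Wilcoxon signed-rank", p_value = p)
    }
  )
  rate_rows <- list(
    any_cnv = list(
      csf = wide("n_cnv")$csf > 0,
      plasma = wide("n_cnv")$plasma > 0
    )
  )
  for (g in genes) {
    gm <- matrix(purrr::map_lgl(per_sample$mutated_genes, ~ g %in% .x),
                 ncol = 2, byrow = TRUE)
    rate_rows[[paste0(g, "_mutated")]] <- list(csf = gm[, 1], plasma = gm[, 2])
  }
  rate_tests <- purrr::map_dfr(rate_rows, .id = "variable", function(r) {
    tab <- rbind(csf = table(factor(r$csf, c(FALSE, TRUE))),
                 plasma = table(factor(r$plasma, c(FALSE, TRUE))))
    ct <- categorical_test(tab)
    tibble(csf_rate = mean(r$csf), plasma_rate = mean(r$plasma),
           test = ct$test, p_value = ct$p_value)
  })
  structure(list(per_sample = select(per_sample, -"mutated_genes"),
                 count_tests = count_tests, rate_tests = rate_tests),
            class = "gi_burden")
}

#' @export
print.gi_burden <- function(x, ...) {
  cat("<gi_burden> paired CSF/plasma burden comparison\n")
  print(x$count_tests)
  print(x$rate_tests)
  invisible(x)
}

# Records of an assay table whose normalized key is absent from the
# patient's leukocyte table (plus all CNV records): the somatic layer.
somatic_only <- function(assay, leukocyte) {
  if (is.null(assay)) return(NULL)
  lk <- variant_key(normalize_variants(leukocyte))
  an <- normalize_variants(assay)
  an[an$kind == "CNV" | !(variant_key(an) %in% lk), ]
}

# Pearson chi-squared without continuity correction when all expected cell
# counts are >= 5, Fisher's exact otherwise.
categorical_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(test = "none (degenerate table)", p_value = NA_real_))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    list(test = "Pearson chi-squared",
         p_value = stats::chisq.test(tab, correct = FALSE)$p.value)
  } else {
    list(test = "Fisher exact", p_value = stats::fisher.test(tab)$p.value)
  }
}

#' Compare clinical variables between two groups
#'
#' Reproduces the standard clinical baseline-table layout: categorical
#' variables are tested with Pearson's chi-squared without continuity
#' correction when every expected cell count is at least 5 and with Fisher's
#' exact test otherwise, and summarized as `n (%)` per level; continuous
#' variables are tested with the Wilcoxon rank-sum test and summarized as
#' `median (IQR)`. Variables constant across both groups are skipped with a
#' note in the `test` column.
#'
#' @param data Data frame with one row per patient.
#' @param group_var Name of the two-level grouping column (e.g. `"status"`).
#' @param vars Character vector of variable names to compare.
#' @return Tibble: `variable`, `level` (`NA` for continuous), one summary
#'   column per group, `test`, `p_value` (repeated across a variable's
#'   level rows).
#' @export
#' @examples
#' d <- data.frame(status = rep(c("GI", "GS"), c(37, 19)),
#'                 lp_shunt = rep(c(TRUE, FALSE, TRUE, FALSE), c(17, 20, 3, 16)))
#' compare_groups(d, "status", "lp_shunt")
compare_groups <- function(data, group_var = "status", vars) {
  g <- factor(data[[group_var]])
  if (nlevels(g) != 2 || any(table(g) == 0)) {
    abort("compare_groups requires exactly two non-empty groups")
  }
  lv <- levels(g)
  purrr::map_dfr(vars, function(v) {
    x <- data[[v]]
    if (is.numeric(x) && !is.logical(x)) {
      if (var(x, na.rm = TRUE) == 0) {
        return(tibble(variable = v, level = NA_character_,
                      !!lv[1] := summary_miqr(x[g == lv[1]]),
                      !!lv[2] := summary_miqr(x[g == lv[2]]),
                      test = "skipped (constant)", p_value = NA_real_))
      }
      p <- suppressWarnings(
        stats::wilcox.test(x[g == lv[1]], x[g == lv[2]])$p.value
      )
      tibble(variable = v, level = NA_character_,
             !!lv[1] := summary_miqr(x[g == lv[1]]),
             !!lv[2] := summary_miqr(x[g == lv[2]]),
             test = "Wilcoxon rank-sum", p_value = p)
    } else {
      xf <- factor(x)
      if (nlevels(xf) < 2) {
        return(tibble(variable = v, level = levels(xf)[1] %||% NA_character_,
                      !!lv[1] := NA_character_, !!lv[2] := NA_character_,
                      test = "skipped (constant)", p_value = NA_real_))
      }
      tab <- table(xf, g)
      ct <- categorical_test(tab)
      purrr::map_dfr(levels(xf), function(l) {
        tibble(variable = v, level = l,
               !!lv[1] := sprintf("%d (%.0f%%)", tab[l, lv[1]],
                                  100 * tab[l, lv[1]] / sum(tab[, lv[1]])),
               !!lv[2] := sprintf("%d (%.0f%%)", tab[l, lv[2]],
                                  100 * tab[l, lv[2]] / sum(tab[, lv[2]])),
               test = ct$test, p_value = ct$p_value)
      })
    }
  })
}

summary_miqr <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
  sprintf("%.2g (%.2g, %.2g)", q[2], q[1], q[3])
}

#' Kaplan-Meier and Cox survival analysis for one endpoint
#'
#' Fits Kaplan-Meier curves (Greenwood confidence intervals) per group with a
#' log-rank test, a univariate Cox proportional-hazards model for each
#' covariate, and a multivariate Cox model over the covariates whose
#' univariate p-value is below `entry_p` (0.05). A group with no events
#' makes the corresponding hazard ratio unstable; such terms are flagged.
#'
#' @param clinical Data frame with one row per patient.
#' @param endpoint `"mfs"` or `"os"`; the time and event columns are
#'   `<endpoint>_time` (years, non-negative) and `<endpoint>_event`
#'   (logical).
#' @param covariates Covariate column names for the Cox models.
#' @param group_var Grouping column for the KM curves and log-rank test.
#' @param entry_p Univariate p-value below which a covariate enters the
#'   multivariate model.
#' @return An object of class `gi_survival`: `endpoint`, `km` (per-group
#'   `n`, `events`, `median`, CI), `logrank_p`, `univariate` /
#'   `multivariate` (term-level `hr`, `ci_lo`, `ci_hi`, `p_value`,
#'   `unstable`), and the underlying `survfit` object in `km_fit`.
#' @export
survival_analysis <- function(clinical, endpoint = c("mfs", "os"),
                              covariates = "status", group_var = "status",
                              entry_p = 0.05) {
  endpoint <- match.arg(endpoint)
  time <- clinical[[paste0(endpoint, "_time")]]
  event <- clinical[[paste0(endpoint, "_event")]]
  if (is.null(time) || is.null(event)) {
    abort(paste0("clinical table lacks ", endpoint, "_time / ", endpoint, "_event"))
  }
  if (any(time < 0)) abort("survival times must be non-negative")
  df <- as.data.frame(clinical)
  df$.time <- time
  df$.event <- as.integer(event)
  df$.group <- factor(df[[group_var]])
  if (any(tapply(df$.event, df$.group, sum) == 0)) {
    warn("a group has no events; log-rank and group HR are unstable")
  }
  km_fit <- survival::survfit(survival::Surv(.time, .event) ~ .group, data = df)
  km_sum <- summary(km_fit)$table
  km <- tibble(
    group = sub("^\\.group=", "", rownames(km_sum)),
    n = unname(km_sum[, "records"]), events = unname(km_sum[, "events"]),
    median = unname(km_sum[, "median"]),
    ci_lo = unname(km_sum[, "0.95LCL"]), ci_hi = unname(km_sum[, "0.95UCL"])
  )
  logrank_p <- tryCatch({
    lr <- survival::survdiff(survival::Surv(.time, .event) ~ .group, data = df)
    stats::pchisq(lr$chisq, length(lr$n) - 1, lower.tail = FALSE)
  }, error = function(e) {
    warn(paste0("log-rank test degenerate (", conditionMessage(e),
                "); p reported as NA"))
    NA_real_
  })
  cox_rows <- function(fit) {
    s <- summary(fit)
    co <- s$coefficients
    ci <- s$conf.int
    tibble(
      term = rownames(co), hr = co[, "exp(coef)"],
      ci_lo = ci[, "lower .95"], ci_hi = ci[, "upper .95"],
      p_value = co[, "Pr(>|z|)"],
      unstable = !is.finite(co[, "se(coef)"]) | co[, "se(coef)"] > 10
    )
  }
  uni <- purrr::map_dfr(covariates, function(v) {
    fit <- survival::coxph(
      stats::as.formula(paste0("survival::Surv(.time, .event) ~ ", v)),
      data = df
    )
    cox_rows(fit) %>% mutate(covariate = v, .before = 1)
  })
  selected <- unique(uni$covariate[uni$p_value < entry_p])
  multi <- if (length(selected) > 0) {
    fit <- survival::coxph(
      stats::as.formula(paste0("survival::Surv(.time, .event) ~ ",
                               paste(selected, collapse = " + "))),
      data = df
    )
    cox_rows(fit)
  } else {
    tibble(term = character(), hr = double(), ci_lo = double(),
           ci_hi = double(), p_value = double(), unstable = logical())
  }
  structure(
    list(endpoint = endpoint, km = km, logrank_p = logrank_p,
         univariate = uni, multivariate = multi, km_fit = km_fit),
    class = "gi_survival"
  )
}

#' @export
print.gi_survival <- function(x, ...) {
  cat(sprintf("<gi_survival> endpoint %s, log-rank p = %.4g\n",
              toupper(x$endpoint), x$logrank_p))
  print(x$km)
  if (nrow(x$multivariate) > 0) {
    cat("multivariate Cox:\n")
    print(x$multivariate)
  }
  invisible(x)
}

#' @rdname survival_analysis
#' @param x A `gi_survival` object.
#' @param ... Unused.
#' @export
tidy.gi_survival <- function(x, ...) {
  bind_rows(
    mutate(x$univariate, model = "univariate"),
    mutate(x$multivariate, covariate = NA_character_, model = "multivariate")
  )
}

#' @rdname survival_analysis
#' @export
glance.gi_survival <- function(x, ...) {
  tibble(endpoint = x$endpoint, logrank_p = x$logrank_p,
         n = sum(x$km$n), events = sum(x$km$events))
}

#' Co-mutation enrichment between GI and GS patients
#'
#' For each gene pair, builds the 2x2 co-mutation-present by status table and
#' tests enrichment with Fisher's exact test (two-sided, with the conditional
#' odds-ratio estimate); also reports per-gene somatic mutation frequencies
#' per group and, when scores are supplied, a Wilcoxon comparison of GI
#' scores between co-mutated and non-co-mutated patients. Gene-level somatic
#' status is derived from the CSF tables: a gene is mutated when it carries
#' an SNV/indel absent from the patient's leukocyte table (CNV records count
#' only when `include_cnv = TRUE`).
#'
#' @param patients Nested cohort tibble.
#' @param status_tbl Tibble `patient_id`, `status` (`"GI"`/`"GS"`).
#' @param gene_pairs Two-column matrix or data frame of gene pairs; defaults
#'   to TP53 paired with EGFR, RB1, ERBB2 and KMT2C.
#' @param scores Optional tibble `patient_id`, `score` for the score
#'   comparison.
#' @param include_cnv Count CNV records as gene mutations.
#' @return A list of class `gi_comutation`: `pairs` (per-pair counts,
#'   `odds_ratio`, `p_value`), `genes` (per-gene frequencies and Fisher p),
#'   `score_tests` (per-pair Wilcoxon, when scores given).
#' @export
comutation_enrichment <- function(patients, status_tbl,
                                  gene_pairs = default_gene_pairs(),
                                  scores = NULL, include_cnv = FALSE) {
  gene_pairs <- as.data.frame(gene_pairs)
  names(gene_pairs) <- c("gene_a", "gene_b")
  muts <- purrr::map(seq_len(nrow(patients)), function(i) {
    tab <- somatic_only(patients$csf[[i]], patients$leukocyte[[i]])
    if (is.null(tab)) return(character())
    keep <- if (include_cnv) rep(TRUE, nrow(tab)) else tab$kind != "CNV"
    unique(tab$gene[keep & !is.na(tab$gene)])
  })
  names(muts) <- patients$patient_id
  st <- status_tbl$status[match(patients$patient_id, status_tbl$patient_id)]
  keep <- st %in% c("GI", "GS")
  muts <- muts[keep]
  st <- st[keep]
  is_gi <- st == "GI"
  all_genes <- sort(unique(unlist(muts)))
  genes <- purrr::map_dfr(all_genes, function(g) {
    has <- purrr::map_lgl(muts, ~ g %in% .x)
    tab <- table(factor(has, c(TRUE, FALSE)), factor(is_gi, c(TRUE, FALSE)))
    ft <- stats::fisher.test(tab)
    tibble(gene = g, freq_gi = mean(has[is_gi]), freq_gs = mean(has[!is_gi]),
           p_value = ft$p.value)
  })
  pairs <- purrr::map_dfr(seq_len(nrow(gene_pairs)), function(j) {
    a <- gene_pairs$gene_a[j]
    b <- gene_pairs$gene_b[j]
    co <- purrr::map_lgl(muts, ~ a %in% .x && b %in% .x)
    if (!any(co)) {
      return(tibble(gene_a = a, gene_b = b,
                    n_co_gi = 0L, n_gi = sum(is_gi),
                    n_co_gs = 0L, n_gs = sum(!is_gi),
                    freq_gi = 0, freq_gs = 0,
                    odds_ratio = NA_real_, p_value = 1))
    }
    tab <- table(factor(co, c(TRUE, FALSE)), factor(is_gi, c(TRUE, FALSE)))
    ft <- stats::fisher.test(tab)
    tibble(gene_a = a, gene_b = b,
           n_co_gi = sum(co & is_gi), n_gi = sum(is_gi),
           n_co_gs = sum(co & !is_gi), n_gs = sum(!is_gi),
           freq_gi = mean(co[is_gi]), freq_gs = mean(co[!is_gi]),
           odds_ratio = unname(ft$estimate), p_value = ft$p.value)
  })
  score_tests <- NULL
  if (!is.null(scores)) {
    sc <- scores$score[match(names(muts), scores$patient_id)]
    score_tests <- purrr::map_dfr(seq_len(nrow(gene_pairs)), function(j) {
      a <- gene_pairs$gene_a[j]
      b <- gene_pairs$gene_b[j]
      co <- purrr::map_lgl(muts, ~ a %in% .x && b %in% .x)
      ok <- !is.na(sc)
      p <- if (length(unique(co[ok])) < 2) NA_real_ else {
        suppressWarnings(stats::wilcox.test(sc[ok & co], sc[ok & !co])$p.value)
      }
      tibble(gene_a = a, gene_b = b,
             median_co = median(sc[ok & co]),
             median_other = median(sc[ok & !co]), p_value = p)
    })
  }
  structure(list(pairs = pairs, genes = genes, score_tests = score_tests),
            class = "gi_comutation")
}

#' Default TP53-anchored co-mutation pairs
#' @return Two-column data frame of gene pairs.
#' @export
default_gene_pairs <- function() {
  data.frame(gene_a = "TP53", gene_b = c("EGFR", "RB1", "ERBB2", "KMT2C"))
}

#' @export
print.gi_comutation <- function(x, ...) {
  cat("<gi_comutation>\n")
  print(x$pairs)
  invisible(x)
}

#' Correlation between two paired measurements
#'
#' Thin wrapper around [stats::cor.test()] returning a broom-style one-row
#' tibble. Pearson by default (`r`); Spearman by flag.
#'
#' @param x,y Paired finite numeric vectors, length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return One-row tibble: `method`, `r`, `p_value`, `n`.
#' @export
#' @examples
#' correlate(1:10, (1:10) * 2)
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) abort("correlation needs at least 3 finite pairs")
  if (var(x) == 0 || var(y) == 0) {
    abort("zero variance in one of the vectors; correlation undefined")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  tibble(method = method, r = unname(ct$estimate), p_value = ct$p.value,
         n = length(x))
}
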