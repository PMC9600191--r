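test_that("published clinical contingency rows reproduce at printed precision", {
  status <- rep(c("GI", "GS"), c(37, 19))
  # lumboperitoneal shunt: 17/37 GI vs 3/19 GS
  d <- data.frame(
    status = status,
    lp_shunt = c(rep(c(TRUE, FALSE), c(17, 20)), rep(c(TRUE, FALSE), c(3, 16))),
    sex = c(rep(c("Female", "Male"), c(16, 21)), rep(c("Female", "Male"), c(13, 6))),
    age_grp = c(rep(c("<=55", ">55"), c(17, 20)), rep(c("<=55", ">55"), c(10, 9)))
  )
  cmp <- compare_groups(d, "status", c("lp_shunt", "sex", "age_grp"))
  p_of <- function(v) cmp$p_value[cmp$variable == v][1]
  expect_identical(unique(cmp$test[cmp$variable == "lp_shunt"]),
                   "Pearson chi-squared")
  expect_equal(round(p_of("lp_shunt"), 3), 0.026)
  expect_equal(round(p_of("sex"), 3), 0.074)
  expect_equal(round(p_of("age_grp"), 1), 0.6)
})

test_that("the categorical rule switches to Fisher when expected counts drop", {
  d <- data.frame(status = rep(c("GI", "GS"), c(10, 10)),
                  rare = rep(c(TRUE, FALSE, FALSE), c(2, 8, 10)))
  cmp <- compare_groups(d, "status", "rare")
  expect_identical(unique(cmp$test), "Fisher exact")
  # identical groups give chi-squared p = 1
  d2 <- data.frame(status = rep(c("GI", "GS"), each = 20),
                   flag = rep(c(TRUE, FALSE), 20))
  cmp2 <- compare_groups(d2, "status", "flag")
  expect_equal(cmp2$p_value[1], 1)
})

test_that("continuous variables use Wilcoxon and constants are skipped", {
  set.seed(21)
  d <- data.frame(status = rep(c("GI", "GS"), each = 30),
                  kps = c(rnorm(30, 60, 10), rnorm(30, 80, 10)),
                  fixed = 5)
  cmp <- compare_groups(d, "status", c("kps", "fixed"))
  expect_identical(cmp$test[cmp$variable == "kps"], "Wilcoxon rank-sum")
  expect_lt(cmp$p_value[cmp$variable == "kps"], 0.001)
  expect_match(cmp$test[cmp$variable == "fixed"], "skipped")
  expect_error(compare_groups(d[d$status == "GI", ], "status", "kps"),
               "two non-empty groups")
})

test_that("paired burden comparison detects the CSF excess and handles ties", {
  co <- simulate_cohort(gi_sim_config(n_patients = 16, n_plasma = 16,
                                      n_tissue = 0, seed = 61L))
  b <- variant_burden_summary(co$patients)
  tot <- b$count_tests[b$count_tests$variable == "total", ]
  expect_gt(tot$csf_mean, tot$plasma_mean)
  expect_true(all(b$rate_tests$csf_rate >= b$rate_tests$plasma_rate - 1e-9))
  # identical paired tables: p = 1 everywhere, zero rate differences
  same <- co$patients
  same$plasma <- same$csf
  b2 <- variant_burden_summary(same)
  expect_true(all(b2$count_tests$p_value == 1))
  expect_equal(b2$rate_tests$csf_rate, b2$rate_tests$plasma_rate)
  # a single paired patient is not comparable
  expect_error(variant_burden_summary(co$patients[1, ]), ">= 2 patients")
})

test_that("KM medians, log-rank and Cox behave on canonical inputs", {
  # everyone fails at t = 5: median 5 in both arms, no censoring
  d <- data.frame(status = rep(c("GI", "GS"), each = 10),
                  mfs_time = 5, mfs_event = TRUE)
  expect_warning(s <- survival_analysis(d, "mfs", covariates = "status"),
                 "degenerate")
  expect_equal(s$km$median, c(5, 5))
  expect_equal(sum(s$km$events), 20)
  # a single gating covariate: multivariate model equals univariate exactly
  set.seed(22)
  cfg <- gi_sim_config(censor_horizon = 10)
  st <- rep(c("GI", "GS"), each = 200)
  cl <- simulate_clinical(st, ifelse(st == "GI", 0.3, 0.02), cfg)
  cl$status <- st
  s2 <- survival_analysis(cl, "mfs", covariates = "status")
  expect_lt(s2$logrank_p, 0.01)
  expect_identical(s2$multivariate$term, "statusGS")
  expect_equal(s2$multivariate$hr,
               s2$univariate$hr[s2$univariate$covariate == "status"])
  # estimated HR near the generating truth at this sample size
  hr_gi <- 1 / s2$multivariate$hr # GS is the non-reference level here
  expect_gt(hr_gi, 1.9)
  expect_lt(hr_gi, 2.9)
  # no events in a group: flagged unstable with a warning
  d3 <- data.frame(status = rep(c("GI", "GS"), each = 8),
                   mfs_time = c(rexp(8, 1), rep(10, 8)),
                   mfs_event = rep(c(TRUE, FALSE), each = 8))
  expect_warning(s3 <- survival_analysis(d3, "mfs", covariates = "status"),
                 "no events")
  expect_error(survival_analysis(data.frame(status = "GI", mfs_time = -1,
                                            mfs_event = TRUE), "mfs"),
               "non-negative")
})

test_that("co-mutation enrichment matches the hypergeometric oracle", {
  # 10/20 co-mutated in GI vs 0/20 in GS: expected two-sided exact p
  p_oracle <- hyper_fisher_p(10, 10, 0, 20)
  expect_equal(p_oracle, 4.36e-4, tolerance = 0.01)
  genes <- csfgi:::panel_genes()
  tp53 <- genes[genes$gene == "TP53", ]
  egfr <- genes[genes$gene == "EGFR", ]
  mk_patient <- function(pid, comut) {
    rec <- tibble::tibble(chrom = "chr1", pos = 1000L, ref = "A", alt = "G",
                          kind = "SNV", gene = NA_character_,
                          alt_depth = 50L, total_depth = 100L)
    som <- if (comut) {
      tibble::tibble(chrom = c(tp53$chrom, egfr$chrom),
                     pos = as.integer(c(tp53$pos, egfr$pos)),
                     ref = "C", alt = "T", kind = "SNV",
                     gene = c("TP53", "EGFR"),
                     alt_depth = 30L, total_depth = 100L)
    } else {
      rec[0, ]
    }
    list(
      leukocyte = variant_table(rec, paste0(pid, "_l"), pid, "leukocyte"),
      csf = variant_table(dplyr::bind_rows(rec, som), paste0(pid, "_c"),
                          pid, "csf")
    )
  }
  ids <- sprintf("Q%02d", 1:40)
  comut <- c(rep(TRUE, 10), rep(FALSE, 10), rep(FALSE, 20))
  built <- purrr::map2(ids, comut, mk_patient)
  patients <- tibble::tibble(
    patient_id = ids,
    leukocyte = purrr::map(built, "leukocyte"),
    csf = purrr::map(built, "csf"),
    plasma = list(NULL), tissue = list(NULL)
  )
  status <- tibble::tibble(patient_id = ids,
                           status = rep(c("GI", "GS"), each = 20))
  enr <- comutation_enrichment(patients, status,
                               gene_pairs = data.frame(a = "TP53", b = "EGFR"))
  expect_equal(enr$pairs$n_co_gi, 10L)
  expect_equal(enr$pairs$n_co_gs, 0L)
  expect_equal(enr$pairs$p_value, p_oracle, tolerance = 1e-8)
  # germline het records never count as somatic gene mutations
  expect_false("GENE001" %in% enr$genes$gene && any(enr$genes$freq_gs == 1))
  # all patients co-mutated: no enrichment signal
  status_all <- tibble::tibble(patient_id = ids[1:10],
                               status = rep(c("GI", "GS"), 5))
  enr2 <- comutation_enrichment(patients[1:10, ], status_all,
                                gene_pairs = data.frame(a = "TP53", b = "EGFR"))
  expect_equal(enr2$pairs$p_value, 1)
  # zero carriers: p = 1, odds ratio undefined
  enr3 <- comutation_enrichment(patients[21:40, ],
                                tibble::tibble(patient_id = ids[21:40],
                                               status = rep(c("GI", "GS"), 10)),
                                gene_pairs = data.frame(a = "TP53", b = "EGFR"))
  expect_equal(enr3$pairs$p_value, 1)
  expect_true(is.na(enr3$pairs$odds_ratio))
})

test_that("package Fisher p equals hypergeometric enumeration across 2x2 tables", {
  for (n in c(8, 20, 40)) {
    for (a in 0:n) {
      for (b in 0:(n - a)) {
        for (c in 0:(n - a - b)) {
          d <- n - a - b - c
          tab <- matrix(c(a, b, c, d), 2, byrow = TRUE)
          if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
          expect_equal(stats::fisher.test(tab)$p.value,
                       hyper_fisher_p(a, b, c, d), tolerance = 1e-10,
                       info = paste(a, b, c, d))
        }
      }
    }
  }
})

test_that("correlate wraps cor.test with guard rails", {
  expect_equal(correlate(1:10, 1:10 * 3)$r, 1)
  expect_equal(correlate(1:10, -(1:10))$r, -1)
  sp <- correlate(1:20, (1:20)^3, method = "spearman")
  expect_equal(sp$r, 1)
  expect_error(correlate(1:10, rep(2, 10)), "zero variance")
  expect_error(correlate(1:2, 2:3), "at least 3")
})
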