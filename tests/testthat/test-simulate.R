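test_that("AF mixing formula has the exact algebraic limits", {
  # f = 0 reduces to the diploid heterozygous expectation 0.5; f = 1 to the
  # clone's allelic ratio, for every integer state with at least one copy
  for (cm in 0:4) {
    for (cn in 0:cm) {
      if (cm + cn == 0) next
      for (c_alt in c(cm, cn)) {
        expect_identical(expected_het_af(0, c_alt, cm, cn), 0.5)
        expect_equal(expected_het_af(1, c_alt, cm, cn), c_alt / (cm + cn))
      }
    }
  }
  # worked case: f = 0.5, copy-neutral LOH, ALT on the retained haplotype
  expect_equal(expected_het_af(0.5, 2, 2, 0), 0.75)
  expect_equal(expected_het_af(0.5, 0, 2, 0), 0.25)
  # pure-clone limit of a hemizygous deletion
  expect_setequal(expected_het_af(1, c(1, 0), 1, 0), c(1, 0))
  # homozygous deletion at f = 1 leaves nothing to sequence
  expect_error(expected_het_af(1, 0, 0, 0), "undefined")
})

test_that("GS status and plasma compartments give near-diploid, low-f profiles", {
  cfg <- gi_sim_config()
  set.seed(1)
  p_gs <- simulate_cna_profile(cfg, "GS", "csf")
  expect_true(csfgi:::is_diploid(p_gs))
  expect_identical(p_gs$tumor_fraction, 0)
  p_pl <- simulate_cna_profile(cfg, "GI", "plasma")
  expect_lte(p_pl$tumor_fraction, cfg$tumor_fraction$gi_plasma[2])
  p_csf <- simulate_cna_profile(cfg, "GI", "csf")
  expect_gte(p_csf$tumor_fraction, cfg$tumor_fraction$gi_csf[1])
  expect_lte(p_csf$tumor_fraction, cfg$tumor_fraction$gi_csf[2])
  agf <- csfgi:::profile_agf(p_csf)
  expect_gte(agf, cfg$agf_range[1] * 0.8) # greedy fill overshoots, never undershoots much
  expect_error(simulate_cna_profile(cfg, "weird", "csf"))
  expect_error(simulate_cna_profile(cfg, "GI", "serum"))
})

test_that("simulated AFs concentrate on the mixing expectation", {
  set.seed(42)
  # law of large numbers at extreme depth: diploid sample AFs pin to 0.5
  prof <- one_segment_profile(1, 1, 0)
  v <- simulate_sample_variants(prof, toy_sites(50), mean_depth = 1e6)
  expect_lt(max(abs(v$af - 0.5)), 3 * sqrt(0.25 / 1e6) + 1e-3)
  # mean AF at a site converges to p within 3 * sqrt(p(1-p)/(n*depth))
  prof2 <- one_segment_profile(2, 0, 0.5)
  n_rep <- 200
  depth <- 500
  afs <- replicate(n_rep, {
    v <- simulate_sample_variants(prof2, toy_sites(1), mean_depth = depth)
    v$af
  })
  p_both <- c(0.75, 0.25) # ALT lands on either haplotype with prob 1/2
  expect_lt(abs(mean(afs) - 0.5), 3 * sqrt(0.25 / n_rep) + 0.01)
  expect_lt(min(abs(mean(afs[afs > 0.5]) - p_both[1]),
                abs(mean(afs) - 0.5)), 0.02)
})

test_that("sites outside every segment are rejected by name", {
  prof <- one_segment_profile(1, 1, 0, len = 1000)
  bad <- tibble::tibble(chrom = "chr1", pos = 5000L, ref = "A", alt = "G")
  expect_error(simulate_sample_variants(prof, bad, mean_depth = 100),
               "chr1:5000")
  bad2 <- tibble::tibble(chrom = "chr9", pos = 10L, ref = "A", alt = "G")
  expect_error(simulate_sample_variants(prof, bad2, mean_depth = 100), "chr9")
})

test_that("expected band-escape fraction is non-decreasing in tumor fraction", {
  # analytic check on the mixing formula itself, no sampling
  states <- csfgi:::alt_states()
  for (j in seq_len(nrow(states))) {
    cm <- states$c_major[j]
    cn <- states$c_minor[j]
    frac_out <- vapply(seq(0, 1, by = 0.1), function(f) {
      p <- expected_het_af(f, c(cm, cn), cm, cn)
      mean(p < 0.25 | p > 0.75)
    }, numeric(1))
    expect_true(all(diff(frac_out) >= 0))
  }
})

test_that("WGS bins carry the expected coverage log2 ratios", {
  set.seed(3)
  # diploid: self-normalized to 0
  tr <- simulate_wgs_bins(new_diploid_profile(), bin_size = 2e7,
                          mean_depth = 2000)
  tr <- compute_log2_ratios(tr)
  expect_lt(abs(mean(tr$log2_ratio)), 0.01)
  # pure clone, total CN 4 on one arm of a diploid-majority genome
  segs <- tibble::tibble(chrom = c("chr1", "chr2"), start = 0,
                         end = c(2e8, 6e8),
                         c_major = c(2L, 1L), c_minor = c(2L, 1L))
  prof <- csfgi:::new_cna_profile(segs, 1)
  tr <- compute_log2_ratios(simulate_wgs_bins(prof, 1e6, 2000))
  m <- mean(tr$log2_ratio[tr$chrom == "chr1"])
  expect_lt(abs(m - 1), 0.05) # small residual shift from median normalization
  # mixture: f = 0.5, total CN 3 -> log2(2.5/2)
  prof2 <- csfgi:::new_cna_profile(dplyr::mutate(segs, c_major = c(2L, 1L),
                                                 c_minor = c(1L, 1L)), 0.5)
  tr2 <- compute_log2_ratios(simulate_wgs_bins(prof2, 1e6, 2000))
  expect_lt(abs(mean(tr2$log2_ratio[tr2$chrom == "chr1"]) - log2(2.5 / 2)),
            0.05)
})

test_that("clinical model has the documented intercepts and baselines", {
  cfg <- gi_sim_config(icp_sd = 0, kps_sd = 0)
  set.seed(1)
  cl <- simulate_clinical(c("GS", "GS"), c(0, 0), cfg)
  expect_equal(cl$icp_kpa, c(1.3, 1.3))
  expect_false(any(cl$lp_shunt))
  expect_true(all(cl$kps == 80))
  expect_error(simulate_clinical("GS", 1.5, cfg), "\\[0, 1\\]")
  # GS-baseline MFS median ~ 2.9 years, checked by sampling without censoring
  cfg2 <- gi_sim_config(censor_horizon = 1e6)
  set.seed(2)
  cl2 <- simulate_clinical(rep("GS", 1e4), rep(0, 1e4), cfg2)
  expect_equal(median(cl2$mfs_time), 2.9, tolerance = 0.05)
  expect_true(all(cl2$mfs_event))
  # GI arm: median scales by 1/HR under the exponential model
  set.seed(3)
  cl3 <- simulate_clinical(rep("GI", 1e4), rep(0, 1e4), cfg2)
  expect_equal(median(cl3$mfs_time), 2.9 / cfg2$hr_mfs, tolerance = 0.05)
})

test_that("cohort generation hits the configured prevalence and round-trips truth", {
  cfg <- gi_sim_config(n_patients = 56, gi_prevalence = 0.661, seed = 202L)
  dir1 <- withr::local_tempdir()
  co <- simulate_cohort(cfg, dir = dir1)
  n_gi <- sum(co$truth$status_true == "GI")
  expect_gt(n_gi, 37 - 9) # Binomial(56, 0.661), +-3.5 sd
  expect_lt(n_gi, 37 + 9)
  # ground truth round-trips through the JSON on disk
  rt <- read_ground_truth(co$files$truth)
  expect_identical(rt$status_true, co$truth$status_true)
  expect_equal(rt$f_csf, co$truth$f_csf)
  # GS patients are diploid everywhere; GI CSF tumor fractions in range
  expect_true(all(rt$f_csf[rt$status_true == "GS"] == 0))
  gi_f <- rt$f_csf[rt$status_true == "GI"]
  expect_true(all(gi_f >= 0.1 & gi_f <= 0.6))
})

test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- gi_sim_config(n_patients = 4, n_plasma = 3, n_tissue = 1, seed = 77L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_cohort(cfg, dir = d1)
  simulate_cohort(cfg, dir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("a zero-prevalence cohort classifies ~0% GI at the fixed 0.07 cutoff", {
  cfg <- gi_sim_config(n_patients = 12, gi_prevalence = 0, n_plasma = 0,
                       n_tissue = 0, seed = 9L)
  co <- simulate_cohort(cfg)
  sc <- classify_status(score_cohort(co$patients, compartments = "csf"), 0.07)
  expect_identical(unique(sc$status), "GS")
})
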