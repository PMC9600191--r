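test_that("the leukocyte het filter keeps the closed band [0.2, 0.8]", {
  tbl <- make_af_table(c(0.19, 0.20, 0.50, 0.80, 0.81))
  kept <- filter_germline_hets(tbl)
  expect_equal(sort(kept$af), c(0.20, 0.50, 0.80))
  # empty in, empty out
  expect_equal(nrow(filter_germline_hets(tbl[0, ])), 0)
  # perfect hets all retained
  expect_equal(nrow(filter_germline_hets(make_af_table(rep(0.5, 7)))), 7)
  # the filter is only defined on the reference compartment
  expect_error(filter_germline_hets(make_af_table(0.5, compartment = "csf")),
               "leukocyte")
  # CNV records never pass
  cnv <- variant_table(
    tibble::tibble(chrom = "chr1", pos = 1L, ref = "N", alt = "<CNV>",
                   kind = "CNV", copy_number = 4),
    "L1", "P1", "leukocyte"
  )
  expect_equal(nrow(filter_germline_hets(cnv)), 0)
})

test_that("shared mutations are the normalized key intersection", {
  leuk <- make_af_table(rep(0.5, 3)) # keys at pos 1000, 2000, 3000
  assay <- variant_table(
    tibble::tibble(chrom = "chr1", pos = c(2000L, 3000L, 4000L), ref = "A",
                   alt = "G", kind = "SNV", alt_depth = 50L,
                   total_depth = 100L),
    "C1", "P1", "csf"
  )
  sh <- shared_mutations(filter_germline_hets(leuk), assay)
  expect_equal(sort(sh$pos), c(2000L, 3000L))
  expect_true(all(sh$leukocyte_af == 0.5))
  # disjoint keys: empty screen, score later indeterminate
  far <- variant_table(
    tibble::tibble(chrom = "chr9", pos = 1L, ref = "A", alt = "G",
                   kind = "SNV", alt_depth = 10L, total_depth = 20L),
    "C1", "P1", "csf"
  )
  expect_equal(nrow(shared_mutations(filter_germline_hets(leuk), far)), 0)
  res <- compute_gi_score(shared_mutations(filter_germline_hets(leuk), far))
  expect_identical(res$status, "indeterminate")
  # different patients cannot be screened against each other
  other <- make_af_table(0.5, compartment = "csf", patient_id = "P2")
  expect_error(shared_mutations(filter_germline_hets(leuk), other),
               "patient mismatch")
})

test_that("GI-mutation classification uses the open quartile band", {
  expect_false(classify_gi_mutation(0.50))
  expect_true(classify_gi_mutation(0.76))
  expect_true(classify_gi_mutation(0.24))
  # boundaries belong to the stable band
  expect_false(classify_gi_mutation(0.25))
  expect_false(classify_gi_mutation(0.75))
  expect_identical(classify_gi_mutation(c(0, 1)), c(TRUE, TRUE))
  expect_error(classify_gi_mutation(1.2), "\\[0, 1\\]")
  expect_error(classify_gi_mutation(-0.1), "\\[0, 1\\]")
})

test_that("the GI score is the exact proportion outside the band", {
  expect_equal(compute_gi_score(make_shared(rep(0.5, 10)), 5)$score, 0)
  sh <- make_shared(c(rep(0.5, 8), 0.9, 0.1, 0.05, 0.99))
  res <- compute_gi_score(sh, min_common = 5)
  expect_equal(res$n_common, 12L)
  expect_equal(res$n_gi, 4L)
  expect_equal(res$score, 1 / 3)
  expect_equal(compute_gi_score(make_shared(rep(0.9, 8)), 5)$score, 1)
  # below min_common: indeterminate with undefined score, not 0
  res2 <- compute_gi_score(make_shared(rep(0.5, 19)), min_common = 20)
  expect_identical(res2$status, "indeterminate")
  expect_true(is.na(res2$score))
  res3 <- compute_gi_score(make_shared(numeric(0)))
  expect_identical(res3$status, "indeterminate")
})

test_that("compute_gi_score equals brute-force counting on 1000 random lists", {
  set.seed(515)
  for (i in 1:1000) {
    n <- sample(20:120, 1)
    afs <- round(runif(n), 3)
    res <- compute_gi_score(make_shared(afs), min_common = 20)
    # independent oracle: plain loop over the band definition
    n_gi <- 0L
    for (a in afs) if (a < 0.25 || a > 0.75) n_gi <- n_gi + 1L
    expect_identical(res$n_gi, n_gi)
    expect_identical(res$score, n_gi / n)
  }
})

test_that("simulated GS samples score at the binomial-noise floor", {
  set.seed(88)
  prof <- one_segment_profile(1, 1, 0)
  sites <- toy_sites(200)
  leuk <- simulate_sample_variants(prof, sites, 500, sample_id = "L",
                                   compartment = "leukocyte")
  csf <- simulate_sample_variants(prof, sites, 500, sample_id = "C",
                                  compartment = "csf")
  res <- score_pair(leuk, csf)
  expect_lte(res$score, 0.01)
})

test_that("score_cohort runs the whole chain per sample", {
  co <- simulate_cohort(gi_sim_config(n_patients = 4, n_plasma = 2,
                                      n_tissue = 1, seed = 5L))
  sc <- score_cohort(co$patients)
  expect_equal(sum(sc$compartment == "csf"), 4)
  expect_equal(sum(sc$compartment == "plasma"), 2)
  expect_equal(sum(sc$compartment == "tissue"), 1)
  expect_true(all(sc$n_common > 250)) # nearly all 300 hets survive the screen
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  expect_true(all(sc$n_gi <= sc$n_common))
})
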