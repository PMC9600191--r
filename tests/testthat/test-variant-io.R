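test_that("VCF parsing computes AF from AD/DP and splits multi-allelic rows", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t50\t.\tA\tG\t.\tPASS\t.\tGT:AD:DP\t0/1:50,50:100",
    "chr1\t100\t.\tAT\tA,ATT\t.\tPASS\t.\tGT:AD:DP\t1/2:10,60,30:100",
    "chr2\t7\t.\tC\tT\t.\tPASS\t.\tGT\t0/1"
  ), vcf)
  expect_warning(
    tbl <- read_variant_table(vcf, sample_id = "S1", patient_id = "P1",
                              compartment = "csf"),
    "neither AF nor AD"
  )
  expect_equal(nrow(tbl), 3) # chr2 record dropped: no AF derivable
  expect_equal(tbl$af[tbl$pos == 50], 0.5)
  multi <- tbl[tbl$chrom == "chr1" & tbl$pos == 100, ]
  expect_equal(nrow(multi), 2)
  expect_setequal(multi$alt, c("A", "ATT"))
  expect_equal(sort(multi$af), c(0.3, 0.6))
  expect_setequal(multi$kind, "indel")
  # keys stay distinct after normalization
  norm <- normalize_variants(multi)
  expect_equal(length(unique(csfgi:::variant_key(norm))), 2)
})

test_that("unparseable files raise errors naming the path", {
  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines("this is not a vcf", bad)
  expect_error(read_variant_table(bad), bad, fixed = TRUE)
  expect_error(read_variant_table("/nonexistent/file.vcf"), "no such file")
})

test_that("variant tables round-trip through both formats", {
  set.seed(101)
  prof <- one_segment_profile(2, 0, 0.4)
  for (i in 1:100) {
    n <- sample(5:25, 1)
    tbl <- simulate_sample_variants(prof, toy_sites(n), mean_depth = 300,
                                    sample_id = "S1", patient_id = "P1",
                                    compartment = "csf")
    # attach a CNV record to every third table
    if (i %% 3 == 0) {
      cnv <- tibble::tibble(chrom = "chr1", pos = 999999L, ref = "N",
                            alt = "<CNV>", kind = "CNV", gene = "TP53",
                            alt_depth = NA_integer_, total_depth = NA_integer_,
                            af = NA_real_, copy_number = 3.25)
      tbl <- csfgi:::validate_variant_tbl(dplyr::bind_rows(
        tbl, variant_table(cnv, "S1", "P1", "csf")
      ))
    }
    fmt <- if (i %% 2 == 0) "vcf" else "tsv"
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_variant_table(tbl, path, format = fmt)
    back <- read_variant_table(path, sample_id = "S1", patient_id = "P1",
                               compartment = "csf")
    cols <- c("chrom", "pos", "ref", "alt", "kind", "gene", "alt_depth",
              "total_depth", "af", "copy_number")
    expect_equal(as.data.frame(back[, cols]), as.data.frame(tbl[, cols]),
                 info = paste("table", i, fmt))
  }
})

test_that("an empty table writes a valid header-only file", {
  empty <- variant_table(
    tibble::tibble(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), kind = character()),
    "S0", "P0", "csf"
  )
  for (fmt in c("vcf", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_variant_table(empty, path, format = fmt)
    back <- read_variant_table(path)
    expect_equal(nrow(back), 0)
  }
})

test_that("duplicate keys are rejected with the offending key named", {
  rec <- tibble::tibble(chrom = "chr1", pos = c(5L, 5L), ref = "A", alt = "G",
                        kind = "SNV", alt_depth = 10L, total_depth = 20L)
  expect_error(variant_table(rec, "S1", "P1", "csf"), "chr1:5:A:G")
})

test_that("AF disagreeing with depths is recomputed with a warning", {
  rec <- tibble::tibble(chrom = "chr1", pos = 1L, ref = "A", alt = "G",
                        kind = "SNV", alt_depth = 30L, total_depth = 100L,
                        af = 0.9)
  expect_warning(tbl <- variant_table(rec, "S1", "P1", "csf"),
                 "recomputed from depths")
  expect_equal(tbl$af, 0.3)
})

test_that("indel padding variants normalize to one canonical representation", {
  a <- csfgi:::normalize_allele_pair(100L, "GCA", "GCTA")
  b <- csfgi:::normalize_allele_pair(101L, "C", "CT")
  expect_identical(a, b)
  expect_identical(a$pos, 101L)
  expect_identical(a$ref, "C")
  expect_identical(a$alt, "CT")
  # and the shared-mutation screen matches across the two spellings
  leuk <- variant_table(
    tibble::tibble(chrom = "chr1", pos = 100L, ref = "GCA", alt = "GCTA",
                   kind = "indel", alt_depth = 50L, total_depth = 100L),
    "L1", "P1", "leukocyte"
  )
  assay <- variant_table(
    tibble::tibble(chrom = "chr1", pos = 101L, ref = "C", alt = "CT",
                   kind = "indel", alt_depth = 90L, total_depth = 100L),
    "C1", "P1", "csf"
  )
  sh <- shared_mutations(filter_germline_hets(leuk), assay)
  expect_equal(nrow(sh), 1)
  expect_equal(sh$sample_af, 0.9)
})

test_that("manifest loading assembles patient sets and reports problems", {
  cfg <- gi_sim_config(n_patients = 6, n_plasma = 4, n_tissue = 1, seed = 31L)
  dir <- withr::local_tempdir()
  co <- simulate_cohort(cfg, dir = dir)
  sets <- load_manifest(co$files$manifest, co$files$clinical)
  expect_equal(nrow(sets), 6)
  expect_equal(sum(!purrr::map_lgl(sets$plasma, is.null)), 4)
  expect_true(all(purrr::map_lgl(sets$leukocyte, ~ !is.null(.x))))
  expect_equal(nrow(sets$clinical[[1]]), 1)
  # loaded tables score identically to the in-memory cohort
  sc_disk <- score_cohort(sets, compartments = "csf")
  sc_mem <- score_cohort(co$patients, compartments = "csf")
  expect_equal(
    sc_disk$score[order(sc_disk$patient_id)],
    sc_mem$score[order(sc_mem$patient_id)]
  )

  # a manifest row pointing nowhere fails by row
  man <- readr::read_csv(co$files$manifest, show_col_types = FALSE)
  man$path[2] <- "variants/absent.tsv"
  bad_man <- file.path(dir, "manifest_bad.csv")
  readr::write_csv(man, bad_man)
  expect_error(load_manifest(bad_man, co$files$clinical), "row 2")

  # duplicate (patient, compartment) rejected
  man2 <- readr::read_csv(co$files$manifest, show_col_types = FALSE)
  dup_man <- file.path(dir, "manifest_dup.csv")
  readr::write_csv(rbind(man2, man2[1, ]), dup_man)
  expect_error(load_manifest(dup_man, co$files$clinical), "duplicate")

  # a patient with only non-leukocyte tables is excluded with a message
  man3 <- readr::read_csv(co$files$manifest, show_col_types = FALSE)
  man3 <- man3[!(man3$patient_id == "P01" & man3$compartment == "leukocyte"), ]
  noleuk_man <- file.path(dir, "manifest_noleuk.csv")
  readr::write_csv(man3, noleuk_man)
  expect_message(sets3 <- load_manifest(noleuk_man, co$files$clinical),
                 "without a leukocyte")
  expect_false("P01" %in% sets3$patient_id)
})
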