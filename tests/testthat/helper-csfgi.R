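# Shared test fixtures, built in code.

# A variant table with exact allele fractions (depth 100).
make_af_table <- function(afs, compartment = "leukocyte", patient_id = "P1",
                          sample_id = paste0(patient_id, "_", compartment),
                          kind = "SNV") {
  n <- length(afs)
  variant_table(
    tibble::tibble(
      chrom = "chr1", pos = seq_len(n) * 1000L, ref = "A", alt = "G",
      kind = kind, gene = NA_character_,
      alt_depth = as.integer(round(afs * 100)), total_depth = 100L
    ),
    sample_id = sample_id, patient_id = patient_id, compartment = compartment
  )
}

# A shared-mutation list with given assay AFs.
make_shared <- function(afs, sample_id = "S1", compartment = "csf") {
  tibble::tibble(
    key = paste0("chr1:", seq_along(afs) * 1000, ":A:G"),
    chrom = "chr1", pos = seq_along(afs) * 1000L, ref = "A", alt = "G",
    gene = NA_character_, leukocyte_af = 0.5, sample_af = afs,
    alt_depth = as.integer(round(afs * 100)), total_depth = 100L,
    sample_id = sample_id, compartment = compartment
  )
}

# One-segment profile spanning a single toy chromosome.
one_segment_profile <- function(c_major, c_minor, f, len = 1e6) {
  csfgi:::new_cna_profile(
    tibble::tibble(chrom = "chr1", start = 0, end = len,
                   c_major = as.integer(c_major),
                   c_minor = as.integer(c_minor)),
    tumor_fraction = f
  )
}

toy_sites <- function(n, len = 1e6) {
  tibble::tibble(chrom = "chr1",
                 pos = as.integer(round(seq(1, len - 1, length.out = n))),
                 ref = "A", alt = "G", gene = NA_character_)
}

# Truncated-normal scores for cutoff-recovery cohorts.
rtrunc01 <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < 0 | x > 1)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

# Score one (leukocyte, assay) pair of simulated tables end to end.
score_pair <- function(leuk, assay, min_common = 20) {
  compute_gi_score(
    shared_mutations(filter_germline_hets(leuk), assay),
    min_common = min_common
  )
}

# Two-sided Fisher p by direct hypergeometric enumeration (independent
# oracle for the package's enrichment tests).
hyper_fisher_p <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  xs <- max(0, k - m2):min(k, m1)
  px <- dhyper(xs, m1, m2, k)
  sum(px[px <= dhyper(a, m1, m2, k) * (1 + 1e-7)])
}
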