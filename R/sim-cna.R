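#' Expected heterozygous-site allele fraction under an allele-specific CNA
#'
#' In a cfDNA mixture where a fraction `f` of molecules derive from an
#' aberrant clone carrying `c_major` copies of one parental haplotype and
#' `c_minor` of the other, a germline heterozygous site whose ALT allele sits
#' on a haplotype with `c_alt` copies has expected ALT allele fraction
#'
#' \deqn{p = \frac{(1-f) \cdot 1 + f \cdot c_{alt}}{(1-f) \cdot 2 + f (c_{major}+c_{minor})}}
#'
#' At `f = 0` this is 0.5 (the diploid germline expectation); at `f = 1` it is
#' `c_alt / (c_major + c_minor)`.
#'
#' @param f Tumor fraction in `[0, 1]`.
#' @param c_alt Copy number of the haplotype carrying the ALT allele.
#' @param c_major,c_minor Clone copy numbers of the two parental haplotypes.
#' @return Expected ALT allele fraction (vectorized).
#' @export
#' @examples
#' expected_het_af(0, 2, 2, 0)    # 0.5: no tumor contribution
#' expected_het_af(0.5, 2, 2, 0)  # 0.75: ALT on the retained haplotype
#' expected_het_af(1, 0, 1, 0)    # 0: pure clone, ALT haplotype lost
expected_het_af <- function(f, c_alt, c_major, c_minor) {
  stopifnot(all(f >= 0 & f <= 1), all(c_major >= 0), all(c_minor >= 0))
  denom <- (1 - f) * 2 + f * (c_major + c_minor)
  if (any(denom == 0)) {
    abort("total copy number is zero at f = 1; expected AF is undefined")
  }
  ((1 - f) + f * c_alt) / denom
}

new_cna_profile <- function(segments, tumor_fraction) {
  stopifnot(is.data.frame(segments),
            all(c("chrom", "start", "end", "c_major", "c_minor") %in%
                  names(segments)))
  if (any(segments$start >= segments$end)) abort("segment start must be < end")
  if (any(segments$c_major < segments$c_minor) || any(segments$c_minor < 0)) {
    abort("segments require c_major >= c_minor >= 0")
  }
  if (tumor_fraction < 0 || tumor_fraction > 1) {
    abort("tumor_fraction must lie in [0, 1]")
  }
  structure(
    list(segments = as_tibble(segments), tumor_fraction = tumor_fraction),
    class = "cna_profile"
  )
}

is_diploid <- function(profile) {
  all(profile$segments$c_major == 1 & profile$segments$c_minor == 1)
}

# Altered allele-specific states a GI clone can carry, with sampling
# weights. The clone model is LOH-rich: copy-neutral LOH (2,0), amplified
# LOH (3,0) and hemizygous deletion (1,0) — single-retained-haplotype states,
# which are the lesions that generate maximal allelic imbalance at
# heterozygous sites and therefore the signal the score is built to detect.
alt_states <- function() {
  tibble(
    c_major = c(2L, 3L, 1L),
    c_minor = c(0L, 0L, 0L),
    weight = c(0.3, 0.6, 0.1)
  )
}

diploid_segments <- function(autosomes = autosome_lengths()) {
  tibble(
    chrom = autosomes$chrom, start = 0, end = autosomes$length,
    c_major = 1L, c_minor = 1L
  )
}

# Build the segment structure of a GI clone: chromosomes are split at random
# breakpoints and segments flipped to altered states until the altered genome
# fraction reaches `agf_target`. Segments tile the autosomes.
make_clone_segments <- function(agf_target, autosomes = autosome_lengths()) {
  segs <- purrr::map_dfr(seq_len(nrow(autosomes)), function(i) {
    L <- autosomes$length[i]
    n_bk <- sample(0:2, 1)
    bk <- sort(floor(runif(n_bk, 0.15, 0.85) * L))
    bounds <- unique(c(0, bk, L))
    tibble(
      chrom = autosomes$chrom[i],
      start = head(bounds, -1), end = tail(bounds, -1),
      c_major = 1L, c_minor = 1L
    )
  })
  total <- sum(segs$end - segs$start)
  states <- alt_states()
  ord <- sample(nrow(segs))
  altered <- 0
  for (j in ord) {
    if (altered / total >= agf_target) break
    st <- states[sample(nrow(states), 1, prob = states$weight), ]
    segs$c_major[j] <- st$c_major
    segs$c_minor[j] <- st$c_minor
    altered <- altered + (segs$end[j] - segs$start[j])
  }
  segs
}

draw_tumor_fraction <- function(config, status, compartment) {
  if (status == "GS" || compartment == "leukocyte") return(0)
  key <- paste0("gi_", compartment)
  r <- config$tumor_fraction[[key]]
  if (is.null(r)) abort(paste0("no tumor-fraction range configured for ", key))
  runif(1, r[1], r[2])
}

#' Simulate an allele-specific copy-number profile for one sample
#'
#' Draws the copy-number state of the cfDNA-shedding clone for one sample.
#' Genomically stable (GS) patients, and leukocytes of any patient, are
#' diploid with tumor fraction 0. For GI patients the clone alters a fraction
#' of the genome (range `config$agf_range`) with allele-specific states (LOH,
#' deletions, gains), and the compartment determines the tumor fraction: CSF
#' draws from `tumor_fraction$gi_csf`, plasma from `gi_plasma`, tissue from
#' `gi_tissue`. Uses the current RNG stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param config A [gi_sim_config()].
#' @param status `"GI"` or `"GS"` — the true genomic status of the patient.
#' @param compartment `"leukocyte"`, `"plasma"`, `"csf"` or `"tissue"`.
#' @return A `cna_profile`: list with `segments` (tibble `chrom`, `start`,
#'   `end`, `c_major`, `c_minor`; 0-based half-open, tiling the autosomes)
#'   and `tumor_fraction`.
#' @export
#' @examples
#' set.seed(1)
#' p <- simulate_cna_profile(gi_sim_config(), "GI", "csf")
#' p$tumor_fraction
simulate_cna_profile <- function(config, status, compartment) {
  status <- arg_match0(status, c("GI", "GS"))
  compartment <- arg_match0(compartment,
                            c("leukocyte", "plasma", "csf", "tissue"))
  f <- draw_tumor_fraction(config, status, compartment)
  segments <- if (status == "GS") {
    diploid_segments()
  } else {
    make_clone_segments(runif(1, config$agf_range[1], config$agf_range[2]))
  }
  new_cna_profile(segments, f)
}

#' @export
print.cna_profile <- function(x, ...) {
  segs <- x$segments
  altered <- sum((segs$end - segs$start)[segs$c_major != 1L | segs$c_minor != 1L])
  cat(sprintf("<cna_profile> tumor fraction %.3f, %d segments, AGF %.2f\n",
              x$tumor_fraction, nrow(segs),
              altered / sum(segs$end - segs$start)))
  invisible(x)
}

# True altered genome fraction of a clone's segment table.
profile_agf <- function(profile) {
  segs <- profile$segments
  alt <- segs$c_major != 1L | segs$c_minor != 1L
  sum((segs$end - segs$start)[alt]) / sum(segs$end - segs$start)
}
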