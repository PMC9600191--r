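#' Draw a panel of heterozygous germline SNP sites
#'
#' Sites are placed uniformly along the autosomes (length-weighted), each with
#' distinct REF/ALT alleles and a panel gene symbol attached by nearest gene.
#' One patient's compartments share the same site panel (same germline).
#'
#' @param n Number of sites.
#' @param autosomes Autosome table, as [autosome_lengths()].
#' @return Tibble `chrom`, `pos` (1-based), `ref`, `alt`, `gene`.
#' @export
simulate_het_sites <- function(n, autosomes = autosome_lengths()) {
  stopifnot(n >= 1)
  genes <- panel_genes()
  chrom_idx <- sample(nrow(autosomes), n, replace = TRUE,
                      prob = autosomes$length)
  pos <- floor(runif(n, 0, autosomes$length[chrom_idx])) + 1
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- purrr::map_chr(ref, function(r) sample(setdiff(bases, r), 1))
  tibble(chrom = autosomes$chrom[chrom_idx], pos = pos, ref = ref, alt = alt) %>%
    mutate(gene = nearest_gene(.data$chrom, .data$pos, genes)) %>%
    arrange(match(.data$chrom, autosomes$chrom), .data$pos)
}

nearest_gene <- function(chrom, pos, genes) {
  out <- rep(NA_character_, length(chrom))
  for (ch in unique(chrom)) {
    si <- which(chrom == ch)
    g <- genes[genes$chrom == ch, ]
    if (nrow(g) == 0) next
    o <- order(g$pos)
    gp <- g$pos[o]
    mids <- (head(gp, -1) + tail(gp, -1)) / 2
    out[si] <- g$gene[o][findInterval(pos[si], mids) + 1]
  }
  out
}

# Map 1-based site positions onto 0-based half-open segments; errors if a
# site falls outside all segments of its chromosome.
site_segment_index <- function(sites, segments) {
  idx <- integer(nrow(sites))
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    seg <- which(segments$chrom == ch)
    if (length(seg) == 0) {
      abort(paste0("site ", ch, ":", sites$pos[si[1]],
                   " falls outside all segments"))
    }
    sg <- segments[seg, ]
    ord <- order(sg$start)
    sg <- sg[ord, ]
    j <- findInterval(sites$pos[si] - 1, sg$start)
    bad <- j == 0 | (sites$pos[si] - 1) >= sg$end[pmax(j, 1)]
    if (any(bad)) {
      abort(paste0("site ", ch, ":", sites$pos[si][bad][1],
                   " falls outside all segments"))
    }
    idx[si] <- seg[ord][j]
  }
  idx
}

draw_depths <- function(n, mean_depth, config) {
  stopifnot(mean_depth > 0)
  d <- if (!is.null(config) && config$depth_model == "nbinom") {
    stats::rnbinom(n, size = config$nb_size, mu = mean_depth)
  } else {
    rpois(n, mean_depth)
  }
  pmax(d, 1L)
}

#' Simulate a variant table of heterozygous germline sites for one sample
#'
#' For each site one parental haplotype is chosen to carry the ALT allele
#' (probability 1/2 each); the expected ALT allele fraction follows the cfDNA
#' mixing formula of [expected_het_af()] with the copy numbers of the segment
#' containing the site; the ALT read count is binomial at the site's total
#' depth (Poisson or negative-binomial around `mean_depth`).
#'
#' @param profile A `cna_profile` from [simulate_cna_profile()].
#' @param sites Site tibble from [simulate_het_sites()] (columns `chrom`,
#'   `pos`; `ref`/`alt`/`gene` optional).
#' @param mean_depth Mean total depth per site.
#' @param config Optional [gi_sim_config()] controlling the depth model
#'   (default Poisson).
#' @param sample_id,patient_id,compartment Sample metadata attached to the
#'   result.
#' @return A variant table (see [variant_table()]) of SNV records with
#'   `alt_depth`, `total_depth` and `af = alt_depth / total_depth`.
#' @export
#' @examples
#' set.seed(1)
#' prof <- new_diploid_profile()
#' sites <- simulate_het_sites(20)
#' v <- simulate_sample_variants(prof, sites, mean_depth = 500)
#' mean(v$af) # near 0.5: diploid germline
simulate_sample_variants <- function(profile, sites, mean_depth,
                                     config = NULL,
                                     sample_id = "S1", patient_id = "P1",
                                     compartment = "csf") {
  stopifnot(inherits(profile, "cna_profile"))
  n <- nrow(sites)
  idx <- site_segment_index(sites, profile$segments)
  cmaj <- profile$segments$c_major[idx]
  cmin <- profile$segments$c_minor[idx]
  alt_on_major <- runif(n) < 0.5
  c_alt <- ifelse(alt_on_major, cmaj, cmin)
  p <- expected_het_af(profile$tumor_fraction, c_alt, cmaj, cmin)
  depth <- draw_depths(n, mean_depth, config)
  alt_depth <- rbinom(n, depth, p)
  rec <- tibble(
    chrom = sites$chrom, pos = sites$pos,
    ref = if ("ref" %in% names(sites)) sites$ref else "A",
    alt = if ("alt" %in% names(sites)) sites$alt else "G",
    kind = "SNV",
    gene = if ("gene" %in% names(sites)) sites$gene else NA_character_,
    alt_depth = as.integer(alt_depth), total_depth = as.integer(depth),
    af = alt_depth / depth, copy_number = NA_real_
  )
  variant_table(rec, sample_id = sample_id, patient_id = patient_id,
                compartment = compartment)
}

#' A fully diploid copy-number profile (tumor fraction 0)
#'
#' Convenience constructor for the germline/GS reference state.
#' @return A `cna_profile`.
#' @export
new_diploid_profile <- function() new_cna_profile(diploid_segments(), 0)

#' Simulate a low-pass WGS bin-count track from a copy-number profile
#'
#' The autosomes are tiled into fixed-width bins; the expected read count of
#' a bin is proportional to the mixture copy number of its segment,
#' `((1 - f) * 2 + f * (c_major + c_minor)) / 2`, relative to diploid, and
#' counts are Poisson. Bins are assigned to segments by midpoint.
#'
#' @param profile A `cna_profile`.
#' @param bin_size Bin width in bases.
#' @param mean_depth Expected count of a diploid bin.
#' @param sample_id Sample label attached to the track.
#' @return A bin track: tibble `chrom`, `start`, `end` (0-based half-open),
#'   `count`, with attributes `bin_size` and `sample_id`.
#' @export
#' @examples
#' set.seed(1)
#' b <- simulate_wgs_bins(new_diploid_profile(), bin_size = 1e7, mean_depth = 200)
#' head(b)
simulate_wgs_bins <- function(profile, bin_size, mean_depth,
                              sample_id = "S1") {
  stopifnot(inherits(profile, "cna_profile"), bin_size > 0, mean_depth > 0)
  segs <- profile$segments
  f <- profile$tumor_fraction
  chrom_len <- segs %>%
    group_by(.data$chrom) %>%
    summarise(len = max(.data$end), .groups = "drop")
  bins <- purrr::map_dfr(seq_len(nrow(chrom_len)), function(i) {
    L <- chrom_len$len[i]
    starts <- seq(0, L - 1, by = bin_size)
    ends <- pmin(starts + bin_size, L)
    keep <- (ends - starts) >= bin_size / 2
    tibble(chrom = chrom_len$chrom[i], start = starts[keep], end = ends[keep])
  })
  mid <- floor((bins$start + bins$end) / 2) + 1
  idx <- site_segment_index(
    tibble(chrom = bins$chrom, pos = mid), segs
  )
  rel <- ((1 - f) * 2 + f * (segs$c_major[idx] + segs$c_minor[idx])) / 2
  bins$count <- rpois(nrow(bins), mean_depth * rel)
  attr(bins, "bin_size") <- bin_size
  attr(bins, "sample_id") <- sample_id
  bins
}
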