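#' Autosome model used by the simulator
#'
#' The generator works on the 22 human autosomes. Sex chromosomes are
#' excluded: the expected heterozygous allele fraction of 0.5 does not hold
#' for male X, so they carry no information for an allelic-imbalance score.
#' Lengths are GRCh37 autosome lengths, optionally scaled down for fast
#' desk-scale simulation.
#'
#' @param scale Divisor applied to the physical lengths (default 1, i.e.
#'   full-size autosomes).
#' @return A tibble with columns `chrom` (e.g. `"chr1"`) and `length` (bases).
#' @export
#' @examples
#' autosome_lengths()
autosome_lengths <- function(scale = 1) {
  stopifnot(is.numeric(scale), length(scale) == 1, scale >= 1)
  # GRCh37 autosome lengths (bases)
  len <- c(
    249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
    159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
    115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
    59128983, 63025520, 48129895, 51304566
  )
  tibble(
    chrom = paste0("chr", 1:22),
    length = floor(len / scale)
  )
}

# Deterministic panel gene model: driver genes plus filler symbols laid out
# round-robin across the autosomes. Positions are only used to attach a gene
# symbol to simulated sites.
panel_genes <- function(n_filler = 100) {
  drivers <- c(
    "TP53", "EGFR", "RB1", "ERBB2", "KMT2C",
    "CDKN2A", "APC", "RICTOR", "PIK3CA", "MDM2",
    "FGFR1", "FGFR2"
  )
  genes <- c(drivers, sprintf("GENE%03d", seq_len(n_filler)))
  auto <- autosome_lengths()
  idx <- ((seq_along(genes) - 1) %% nrow(auto)) + 1
  k <- ceiling(seq_along(genes) / nrow(auto))
  tibble(
    gene = genes,
    driver = genes %in% drivers,
    chrom = auto$chrom[idx],
    # spread genes along each chromosome, away from the telomeres
    pos = floor(auto$length[idx] * (k / (max(k) + 1)))
  )
}
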