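COMPARTMENTS <- c("leukocyte", "plasma", "csf", "tissue")
VARIANT_KINDS <- c("SNV", "indel", "CNV")

variant_cols <- c("sample_id", "patient_id", "compartment", "chrom", "pos",
                  "ref", "alt", "kind", "gene", "alt_depth", "total_depth",
                  "af", "copy_number")

#' Construct and validate a variant table
#'
#' The package's working representation of one sample's variant calls: a
#' tibble with one row per called variant and the sample metadata carried in
#' columns, so tables from many samples stack with [dplyr::bind_rows()].
#' Positions are 1-based (VCF convention). Invariants enforced:
#' `0 <= alt_depth <= total_depth`; for SNV/indel records with depths, `af`
#' agrees with `alt_depth / total_depth` to within 0.01 (recomputed from
#' depths with a warning otherwise); the key `(chrom, pos, ref, alt)` is
#' unique within the table; CNV records carry `copy_number` and need no `af`.
#'
#' @param records Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `kind` (`"SNV"`, `"indel"` or `"CNV"`), and optionally `gene`,
#'   `alt_depth`, `total_depth`, `af`, `copy_number`.
#' @param sample_id,patient_id Sample and patient identifiers.
#' @param compartment One of `"leukocyte"`, `"plasma"`, `"csf"`, `"tissue"`.
#' @return A tibble of class `gi_variant_tbl`.
#' @export
#' @examples
#' variant_table(
#'   data.frame(chrom = "chr1", pos = 100, ref = "A", alt = "G",
#'              kind = "SNV", alt_depth = 50, total_depth = 100),
#'   sample_id = "S1", patient_id = "P1", compartment = "leukocyte"
#' )
variant_table <- function(records, sample_id, patient_id, compartment) {
  compartment <- arg_match0(compartment, COMPARTMENTS)
  rec <- as_tibble(records)
  for (col in c("gene")) if (!col %in% names(rec)) rec[[col]] <- NA_character_
  for (col in c("alt_depth", "total_depth")) {
    if (!col %in% names(rec)) rec[[col]] <- NA_integer_
  }
  for (col in c("af", "copy_number")) {
    if (!col %in% names(rec)) rec[[col]] <- NA_real_
  }
  rec <- rec %>%
    mutate(sample_id = sample_id, patient_id = patient_id,
           compartment = compartment,
           pos = as.integer(.data$pos),
           alt_depth = as.integer(.data$alt_depth),
           total_depth = as.integer(.data$total_depth)) %>%
    select(dplyr::all_of(variant_cols))
  validate_variant_tbl(rec)
}

validate_variant_tbl <- function(rec) {
  if (nrow(rec) > 0) {
    if (!all(rec$kind %in% VARIANT_KINDS)) {
      abort("variant kind must be one of SNV, indel, CNV")
    }
    if (any(rec$pos < 1)) abort("positions are 1-based; pos must be >= 1")
    has_depth <- !is.na(rec$alt_depth) & !is.na(rec$total_depth)
    if (any(has_depth & (rec$alt_depth < 0 | rec$alt_depth > rec$total_depth))) {
      abort("alt_depth must satisfy 0 <= alt_depth <= total_depth")
    }
    # depths win over a disagreeing AF field
    snv <- rec$kind != "CNV" & has_depth & rec$total_depth > 0
    dp_af <- rec$alt_depth / rec$total_depth
    clash <- snv & !is.na(rec$af) & abs(rec$af - dp_af) > 0.01
    if (any(clash)) {
      warn(sprintf("%d record(s) had AF disagreeing with AD/DP by > 0.01; recomputed from depths",
                   sum(clash)))
    }
    rec$af[snv] <- dp_af[snv]
    if (any(rec$kind == "CNV" & is.na(rec$copy_number))) {
      abort("CNV records must carry copy_number")
    }
    key <- variant_key(rec)
    if (anyDuplicated(key)) {
      abort(paste0("duplicate variant key within table: ",
                   key[duplicated(key)][1]))
    }
  }
  class(rec) <- c("gi_variant_tbl", class(tibble()))
  rec
}

variant_key <- function(tbl) {
  paste(tbl$chrom, tbl$pos, tbl$ref, tbl$alt, sep = ":")
}

#' Normalize variant representations for cross-sample matching
#'
#' Trims the common suffix, then the common prefix, of each REF/ALT pair
#' (always keeping at least one base of each and advancing `pos` for trimmed
#' prefix bases), so the same indel written with different padding collapses
#' to one canonical key. CNV records are left untouched. Matching of shared
#' mutations across compartments always uses the normalized key.
#'
#' @param tbl A `gi_variant_tbl`.
#' @return The table with canonical `pos`, `ref`, `alt`.
#' @export
#' @examples
#' t <- variant_table(
#'   data.frame(chrom = "chr1", pos = 100, ref = "GCA", alt = "GCTA",
#'              kind = "indel", alt_depth = 10, total_depth = 20),
#'   "S1", "P1", "csf"
#' )
#' normalize_variants(t)[, c("pos", "ref", "alt")] # 101, C, CT
normalize_variants <- function(tbl) {
  # single-base REF/ALT pairs are already canonical
  idx <- which(tbl$kind != "CNV" & (nchar(tbl$ref) > 1 | nchar(tbl$alt) > 1))
  if (length(idx) == 0) return(tbl)
  norm <- purrr::pmap(
    list(tbl$pos[idx], tbl$ref[idx], tbl$alt[idx]),
    normalize_allele_pair
  )
  tbl$pos[idx] <- purrr::map_int(norm, "pos")
  tbl$ref[idx] <- purrr::map_chr(norm, "ref")
  tbl$alt[idx] <- purrr::map_chr(norm, "alt")
  validate_variant_tbl(as_tibble(tbl))
}

normalize_allele_pair <- function(pos, ref, alt) {
  r <- strsplit(toupper(ref), "")[[1]]
  a <- strsplit(toupper(alt), "")[[1]]
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

#' Read a variant table from VCF or TSV
#'
#' VCF (v4.2) is parsed with \pkg{vcfR}; multi-allelic rows are split into
#' one record per ALT allele with per-allele AD counts; allele fraction is
#' computed from AD/DP when no AF is given; records with neither AF nor
#' depths are dropped with a warning. `ALT = "<CNV>"` rows with an INFO `CN`
#' field become CNV records. The TSV dialect is a header row with columns
#' `chrom, pos, ref, alt, kind, gene, alt_depth, total_depth, af,
#' copy_number`.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param sample_id,patient_id,compartment Sample metadata (the manifest is
#'   the source of truth for these, not the file).
#' @return A `gi_variant_tbl`.
#' @export
read_variant_table <- function(path, format = c("auto", "vcf", "tsv"),
                               sample_id = NA_character_,
                               patient_id = NA_character_,
                               compartment = "csf") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  rec <- if (format == "vcf") read_vcf_records(path) else read_tsv_records(path)
  variant_table(rec, sample_id = sample_id, patient_id = patient_id,
                compartment = compartment)
}

read_vcf_records <- function(path) {
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("failed to parse VCF ", path, ": ",
                                     conditionMessage(e)))
  )
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), kind = character(), gene = character(),
                  alt_depth = integer(), total_depth = integer(),
                  af = double(), copy_number = double()))
  }
  gt <- v@gt
  fmt_keys <- strsplit(gt[, "FORMAT"], ":")
  smp <- strsplit(gt[, 2], ":")
  fmt_field <- function(i, key) {
    j <- match(key, fmt_keys[[i]])
    if (is.na(j) || j > length(smp[[i]])) NA_character_ else smp[[i]][j]
  }
  info_field <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  out <- vector("list", nrow(fix))
  dropped <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    info <- fix$INFO[i]
    gene <- info_field(info, "GENE")
    if (identical(gene, ".")) gene <- NA_character_
    dp <- suppressWarnings(as.integer(fmt_field(i, "DP")))
    ad_raw <- fmt_field(i, "AD")
    ad <- if (is.na(ad_raw)) NULL else suppressWarnings(
      as.integer(strsplit(ad_raw, ",", fixed = TRUE)[[1]])
    )
    rows <- purrr::map_dfr(seq_along(alts), function(k) {
      alt <- alts[k]
      if (identical(alt, "<CNV>")) {
        cn <- suppressWarnings(as.numeric(info_field(info, "CN")))
        return(tibble(chrom = fix$CHROM[i],
                      pos = as.integer(fix$POS[i]),
                      ref = fix$REF[i], alt = alt, kind = "CNV", gene = gene,
                      alt_depth = NA_integer_, total_depth = NA_integer_,
                      af = NA_real_, copy_number = cn))
      }
      kind <- if (nchar(fix$REF[i]) == 1 && nchar(alt) == 1) "SNV" else "indel"
      alt_depth <- if (!is.null(ad) && length(ad) >= k + 1) ad[k + 1] else NA_integer_
      af <- suppressWarnings(as.numeric(
        strsplit(fmt_field(i, "AF"), ",")[[1]][k]
      ))
      if (is.na(af) && !is.na(alt_depth) && !is.na(dp) && dp > 0) {
        af <- alt_depth / dp
      }
      tibble(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
             ref = fix$REF[i], alt = alt, kind = kind, gene = gene,
             alt_depth = alt_depth, total_depth = dp, af = af,
             copy_number = NA_real_)
    })
    keep <- rows$kind == "CNV" | !is.na(rows$af)
    dropped <- dropped + sum(!keep)
    out[[i]] <- rows[keep, ]
  }
  if (dropped > 0) {
    warn(sprintf("%d record(s) had neither AF nor AD/DP and were dropped", dropped))
  }
  bind_rows(out)
}

read_tsv_records <- function(path) {
  rec <- tryCatch(
    readr::read_tsv(
      path, show_col_types = FALSE, progress = FALSE,
      col_types = readr::cols(
        chrom = readr::col_character(), pos = readr::col_integer(),
        ref = readr::col_character(), alt = readr::col_character(),
        kind = readr::col_character(), gene = readr::col_character(),
        alt_depth = readr::col_integer(), total_depth = readr::col_integer(),
        af = readr::col_double(), copy_number = readr::col_double()
      )
    ),
    error = function(e) abort(paste0("failed to parse TSV ", path, ": ",
                                     conditionMessage(e)))
  )
  probs <- readr::problems(rec)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed TSV %s: first problem at line %d (%s)",
                  path, probs$row[1], probs$expected[1]))
  }
  rec
}

#' Write a variant table to VCF v4.2 or TSV
#'
#' The emitted VCF carries GT:AD:DP in FORMAT (AD as `ref,alt` counts) and
#' `GENE`/`KIND` (plus `CN` for CNV records, written as `ALT = "<CNV>"`) in
#' INFO. Reading the file back with [read_variant_table()] reproduces the
#' table on all retained fields.
#'
#' @param tbl A `gi_variant_tbl`.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(tbl, path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf$", path)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    readr::write_tsv(tbl[, setdiff(variant_cols,
                                   c("sample_id", "patient_id", "compartment"))],
                     path, progress = FALSE)
    return(invisible(path))
  }
  sid <- if (is.na(tbl$sample_id[1] %||% NA)) "SAMPLE" else tbl$sample_id[1]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=csfgi",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=KIND,Number=1,Type=String,Description=\"Variant kind: SNV, indel or CNV\">",
    "##INFO=<ID=CN,Number=1,Type=Float,Description=\"Mixture copy number (CNV records)\">",
    "##ALT=<ID=CNV,Description=\"Copy number variant\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read depth per allele\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sid)
  )
  body <- character(nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    r <- tbl[i, ]
    if (r$kind == "CNV") {
      info <- sprintf("GENE=%s;KIND=CNV;CN=%s",
                      r$gene %|% ".", format(r$copy_number, digits = 10))
      body[i] <- paste(r$chrom, r$pos, ".", r$ref, "<CNV>", ".", "PASS",
                       info, "GT:DP", "./.:.", sep = "\t")
    } else {
      info <- sprintf("GENE=%s;KIND=%s", r$gene %|% ".", r$kind)
      gt <- "0/1"
      ad <- paste0(r$total_depth - r$alt_depth, ",", r$alt_depth)
      body[i] <- paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS",
                       info, "GT:AD:DP",
                       paste(gt, ad, r$total_depth, sep = ":"), sep = "\t")
    }
  }
  writeLines(c(header, body), path)
  invisible(path)
}

`%|%` <- function(x, y) if (is.na(x)) y else x

#' Load a cohort from a manifest and a clinical table
#'
#' The manifest is a CSV with columns `patient_id, sample_id, compartment,
#' path` (paths relative to the manifest's directory or absolute); the
#' clinical table is a CSV with one row per patient. Each patient becomes one
#' row of a nested tibble with one list-column of variant tables per
#' compartment. Patients without a leukocyte table cannot be scored and are
#' dropped with a message.
#'
#' @param manifest_path,clinical_path CSV paths.
#' @return A nested tibble: `patient_id`, `leukocyte`, `csf`, `plasma`,
#'   `tissue` (list-columns of `gi_variant_tbl` or `NULL`), `clinical`
#'   (list-column of one-row tibbles).
#' @export
load_manifest <- function(manifest_path, clinical_path) {
  man <- readr::read_csv(manifest_path, show_col_types = FALSE, progress = FALSE)
  need <- c("patient_id", "sample_id", "compartment", "path")
  if (!all(need %in% names(man))) {
    abort(paste0("manifest must have columns ", paste(need, collapse = ", ")))
  }
  if (!all(man$compartment %in% COMPARTMENTS)) {
    abort("manifest compartments must be leukocyte/plasma/csf/tissue")
  }
  dup <- duplicated(man[, c("patient_id", "compartment")])
  if (any(dup)) {
    abort(paste0("duplicate (patient, compartment) pair in manifest: ",
                 man$patient_id[dup][1], "/", man$compartment[dup][1]))
  }
  base <- dirname(manifest_path)
  man$path <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                     file.path(base, man$path))
  missing <- !file.exists(man$path)
  if (any(missing)) {
    abort(paste0("manifest row ", which(missing)[1], " points to missing file: ",
                 man$path[missing][1]))
  }
  clin <- readr::read_csv(clinical_path, show_col_types = FALSE, progress = FALSE)
  if (!"patient_id" %in% names(clin)) {
    abort("clinical table must have a patient_id column")
  }
  if (anyDuplicated(clin$patient_id)) {
    abort("clinical table must have one row per patient")
  }
  pts <- unique(man$patient_id)
  no_leuk <- pts[!pts %in% man$patient_id[man$compartment == "leukocyte"]]
  if (length(no_leuk) > 0) {
    inform(paste0("excluding ", length(no_leuk),
                  " patient(s) without a leukocyte table: ",
                  paste(no_leuk, collapse = ", ")))
    pts <- setdiff(pts, no_leuk)
  }
  sets <- purrr::map(pts, function(p) {
    rows <- man[man$patient_id == p, ]
    tabs <- setNames(vector("list", length(COMPARTMENTS)), COMPARTMENTS)
    for (j in seq_len(nrow(rows))) {
      tabs[[rows$compartment[j]]] <- read_variant_table(
        rows$path[j], sample_id = rows$sample_id[j], patient_id = p,
        compartment = rows$compartment[j]
      )
    }
    tabs
  })
  tibble(
    patient_id = pts,
    leukocyte = purrr::map(sets, "leukocyte"),
    csf = purrr::map(sets, "csf"),
    plasma = purrr::map(sets, "plasma"),
    tissue = purrr::map(sets, "tissue"),
    clinical = purrr::map(pts, function(p) clin[clin$patient_id == p, ])
  )
}
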