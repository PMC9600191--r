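#' Normalize a bin-count track to copy-number log2 ratios
#'
#' Each bin's log2 ratio is computed against the median autosomal raw count,
#' so a diploid genome centers at 0 and a clonal single-copy gain at
#' `log2(3/2)`. Zero-count bins get `NA` (flagged missing) rather than
#' `-Inf`. Multiplying all counts by a constant leaves the ratios unchanged.
#'
#' @param track Bin tibble with columns `chrom`, `start`, `end`, `count`
#'   (as from [simulate_wgs_bins()] or [read_bin_track()]).
#' @return The track with a `log2_ratio` column.
#' @export
#' @examples
#' t <- tibble::tibble(chrom = "chr1", start = 0:3 * 100, end = 1:4 * 100,
#'                     count = c(100, 100, 200, 100))
#' compute_log2_ratios(t)$log2_ratio
compute_log2_ratios <- function(track) {
  if (all(track$count == 0)) {
    abort("all bins have zero counts; cannot normalize the track")
  }
  med <- median(track$count[track$count > 0])
  track$log2_ratio <- ifelse(track$count > 0, log2(track$count / med), NA_real_)
  track
}

#' Segment a log2-ratio track by greedy mean-merging
#'
#' Within each chromosome, adjacent bins are merged into a segment while the
#' running segment mean and the next bin's value differ by less than
#' `merge_tol`; a larger jump starts a new segment. The summary also reports
#' the altered genome fraction (AGF): the length fraction of segments whose
#' mean |log2 ratio| exceeds `call_tol` (a gain or loss call). The default
#' call threshold of 0.25 is chosen to align the coverage arm's
#' tumor-fraction sensitivity with that of the allele-fraction quartile
#' band: a single-copy gain on an LOH background crosses |log2| = 0.25 at
#' about the same tumor fraction (~0.4) at which its heterozygous-site AF
#' leaves the (0.25, 0.75) band, so the two arms call the same samples.
#'
#' @param track Normalized track from [compute_log2_ratios()]; `NA` bins are
#'   skipped.
#' After the greedy pass, runs of fewer than `min_bins` bins (single noisy
#' outliers) are absorbed into the neighboring segment with the closer mean,
#' and adjacent segments whose means then differ by less than `merge_tol`
#' are re-merged.
#'
#' @param merge_tol Maximum deviation of a bin from the running segment mean
#'   (log2 units).
#' @param call_tol |log2 ratio| above which a segment is called gained/lost.
#' @param min_bins Minimum bins per segment; shorter runs are absorbed.
#' @return An object of class `cnv_summary`: list with `segments` (tibble
#'   `chrom`, `start`, `end`, `n_bins`, `mean_log2`, `called`),
#'   `altered_genome_fraction`, `call_tol`, `merge_tol`, `sample_id`.
#' @export
segment_track <- function(track, merge_tol = 0.1, call_tol = 0.25,
                          min_bins = 3L) {
  stopifnot("log2_ratio" %in% names(track))
  segs <- purrr::map_dfr(unique(track$chrom), function(ch) {
    b <- track[track$chrom == ch & !is.na(track$log2_ratio), ]
    if (nrow(b) == 0) return(NULL)
    b <- b[order(b$start), ]
    seg_id <- integer(nrow(b))
    cur <- 1L
    run_sum <- b$log2_ratio[1]
    run_n <- 1L
    seg_id[1] <- cur
    for (i in seq_len(nrow(b))[-1]) {
      if (abs(b$log2_ratio[i] - run_sum / run_n) < merge_tol) {
        run_sum <- run_sum + b$log2_ratio[i]
        run_n <- run_n + 1L
      } else {
        cur <- cur + 1L
        run_sum <- b$log2_ratio[i]
        run_n <- 1L
      }
      seg_id[i] <- cur
    }
    # absorb sub-minimum runs into the neighbor with the closer mean
    seg_id <- absorb_short_runs(seg_id, b$log2_ratio, min_bins)
    # re-merge adjacent segments whose means converged
    seg_id <- remerge_similar(seg_id, b$log2_ratio, merge_tol)
    b %>%
      mutate(.seg = seg_id) %>%
      group_by(.data$.seg) %>%
      summarise(chrom = ch, start = min(.data$start), end = max(.data$end),
                n_bins = n(), mean_log2 = mean(.data$log2_ratio),
                .groups = "drop") %>%
      select(-".seg")
  })
  segs$called <- abs(segs$mean_log2) > call_tol
  agf <- sum((segs$end - segs$start)[segs$called]) / sum(segs$end - segs$start)
  structure(
    list(segments = segs, altered_genome_fraction = agf,
         call_tol = call_tol, merge_tol = merge_tol,
         sample_id = attr(track, "sample_id") %||% NA_character_),
    class = "cnv_summary"
  )
}

absorb_short_runs <- function(seg_id, x, min_bins) {
  repeat {
    runs <- rle(seg_id)
    if (length(runs$lengths) <= 1 || all(runs$lengths >= min_bins)) break
    j <- which(runs$lengths < min_bins)[1]
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    idx <- starts[j]:ends[j]
    mu <- mean(x[idx])
    left <- if (j > 1) mean(x[starts[j - 1]:ends[j - 1]]) else NA
    right <- if (j < length(runs$lengths)) mean(x[starts[j + 1]:ends[j + 1]]) else NA
    target <- if (is.na(right) || (!is.na(left) && abs(mu - left) <= abs(mu - right))) {
      runs$values[j - 1]
    } else {
      runs$values[j + 1]
    }
    seg_id[idx] <- target
  }
  seg_id
}

remerge_similar <- function(seg_id, x, merge_tol) {
  repeat {
    runs <- rle(seg_id)
    if (length(runs$lengths) <= 1) break
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    means <- vapply(seq_along(starts),
                    function(j) mean(x[starts[j]:ends[j]]), numeric(1))
    gap <- abs(diff(means))
    if (all(gap >= merge_tol)) break
    j <- which.min(gap)
    seg_id[starts[j + 1]:ends[j + 1]] <- runs$values[j]
  }
  seg_id
}

#' @export
print.cnv_summary <- function(x, ...) {
  cat(sprintf("<cnv_summary> %d segments, %d called, AGF %.3f (|log2| > %.2f)\n",
              nrow(x$segments), sum(x$segments$called),
              x$altered_genome_fraction, x$call_tol))
  invisible(x)
}

#' Concordance between the score-based and copy-number-based GI call
#'
#' The copy-number arm calls a sample genomically unstable when its altered
#' genome fraction reaches `agf_threshold`; this checks whether that call
#' agrees with the score-based GI/GS status of the same sample.
#'
#' @param summary A `cnv_summary` from [segment_track()].
#' @param result One-row score tibble with a `status` column.
#' @param agf_threshold AGF at or above which the copy-number arm calls GI.
#' @return `TRUE`/`FALSE`, or `NA` when the status is indeterminate.
#' @export
gi_concordance <- function(summary, result, agf_threshold = 0.10) {
  status <- result$status[1]
  if (is.na(status) || status == "indeterminate") return(NA)
  cnv_gi <- summary$altered_genome_fraction >= agf_threshold
  cnv_gi == (status == "GI")
}

#' Read / write bin-count tracks as BED-like TSV
#'
#' Columns `chrom, start, end, count` with 0-based half-open coordinates.
#'
#' @param path File path.
#' @return [read_bin_track()]: a bin tibble; [write_bin_track()]: `path`.
#' @export
read_bin_track <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          chrom = readr::col_character(),
                          start = readr::col_double(),
                          end = readr::col_double(),
                          count = readr::col_integer()
                        ))
  if (any(tr$start >= tr$end)) abort("bin start must be < end")
  tr
}

#' @rdname read_bin_track
#' @param track Bin tibble.
#' @export
write_bin_track <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "start", "end", "count")], path,
                   progress = FALSE)
  invisible(path)
}
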