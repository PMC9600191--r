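#' Plot a fitted score cutoff over the cohort score distribution
#'
#' Histogram of the scores with the fitted mixture components (when
#' available) and the cutoff as a dashed vertical line.
#'
#' @param object A `gi_cutoff` from [fit_cutoff()].
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gi_cutoff <- function(object, bins = 30, ...) {
  df <- tibble(score = object$scores)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", color = "grey40") +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed",
                        color = "red") +
    ggplot2::labs(x = "GI score", y = "density",
                  title = sprintf("GI/GS cutoff %.3f (%s)", object$cutoff,
                                  object$method)) +
    ggplot2::theme_minimal()
  if (!is.null(object$means)) {
    grid <- seq(0, max(df$score) * 1.1, length.out = 400)
    comp <- bind_rows(
      tibble(score = grid, component = "GS-like",
             d = object$weights[1] * dnorm(grid, object$means[1], object$sds[1])),
      tibble(score = grid, component = "GI-like",
             d = object$weights[2] * dnorm(grid, object$means[2], object$sds[2]))
    )
    p <- p + ggplot2::geom_line(
      data = comp,
      ggplot2::aes(x = .data$score, y = .data$d, color = .data$component)
    )
  }
  p
}

#' Allele-fraction profile of shared mutations along the genome
#'
#' The compartment-level view that makes allelic imbalance visible: shared
#' germline heterozygous mutations plotted by genomic order with their
#' leukocyte and assay allele fractions; a stable sample hugs 0.5, an
#' unstable one splits away from it. The quartile band (0.25, 0.75) is shown.
#'
#' @param shared Shared-mutation tibble from [shared_mutations()].
#' @param band Quartile band drawn as dotted lines.
#' @return A ggplot.
#' @export
plot_af_profile <- function(shared, band = c(0.25, 0.75)) {
  df <- shared %>%
    mutate(order = row_number()) %>%
    tidyr::pivot_longer(c("leukocyte_af", "sample_af"),
                        names_to = "compartment", values_to = "af") %>%
    mutate(compartment = ifelse(.data$compartment == "leukocyte_af",
                                "leukocyte", .data$compartment))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$order, y = .data$af,
                                   color = .data$compartment)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0.5, color = "grey40") +
    ggplot2::geom_hline(yintercept = band, linetype = "dotted") +
    ggplot2::facet_wrap(~compartment, ncol = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "shared mutation (genome order)", y = "allele fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a copy-number log2-ratio track with its segmentation
#'
#' @param track Normalized bin track ([compute_log2_ratios()]).
#' @param summary Optional `cnv_summary` from [segment_track()]; segment
#'   means are overlaid in red.
#' @return A ggplot.
#' @export
plot_log2_track <- function(track, summary = NULL) {
  chroms <- unique(track$chrom)
  track$chrom <- factor(track$chrom, levels = chroms)
  p <- ggplot2::ggplot(track,
                       ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    y = .data$log2_ratio)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5, color = "grey30") +
    ggplot2::geom_hline(yintercept = 0, color = "grey60") +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "log2 ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing = ggplot2::unit(0.1, "lines"))
  if (!is.null(summary)) {
    segs <- summary$segments
    segs$chrom <- factor(segs$chrom, levels = chroms)
    p <- p + ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$mean_log2, yend = .data$mean_log2),
      color = "red", linewidth = 0.8
    )
  }
  p
}

#' @rdname segment_track
#' @param object A `cnv_summary`.
#' @param track The normalized track the summary was computed from.
#' @param ... Unused.
#' @export
autoplot.cnv_summary <- function(object, track, ...) {
  plot_log2_track(track, object)
}

#' Kaplan-Meier curves for a fitted survival analysis
#'
#' @param object A `gi_survival` from [survival_analysis()].
#' @param ... Unused.
#' @return A ggplot of the per-group KM step curves.
#' @export
autoplot.gi_survival <- function(object, ...) {
  fit <- object$km_fit
  strata <- rep(sub("^\\.group=", "", names(fit$strata)), fit$strata)
  df <- bind_rows(
    tibble(time = 0, surv = 1,
           group = sub("^\\.group=", "", names(fit$strata))),
    tibble(time = fit$time, surv = fit$surv, group = strata)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "years", y = "survival",
                  title = sprintf("%s (log-rank p = %.3g)",
                                  toupper(object$endpoint), object$logrank_p)) +
    ggplot2::theme_minimal()
}

#' Paired compartment score comparison plot
#'
#' Paired CSF vs plasma GI scores with within-patient connecting lines.
#'
#' @param scores Classified score tibble ([score_cohort()]).
#' @param compartments The two compartments to pair.
#' @return A ggplot.
#' @export
plot_score_compartments <- function(scores, compartments = c("csf", "plasma")) {
  df <- scores %>%
    filter(.data$compartment %in% compartments, is.finite(.data$score))
  paired <- df %>%
    count(.data$patient_id) %>%
    filter(.data$n == 2) %>%
    pull(.data$patient_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$compartment, y = .data$score)) +
    ggplot2::geom_line(
      data = df %>% filter(.data$patient_id %in% paired),
      ggplot2::aes(group = .data$patient_id), color = "grey70"
    ) +
    ggplot2::geom_point(ggplot2::aes(color = .data$status)) +
    ggplot2::labs(x = NULL, y = "GI score") +
    ggplot2::theme_minimal()
}
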