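#' Fit a GI/GS score cutoff from a cohort's score distribution
#'
#' The score distribution of a mixed cohort is bimodal: a tight mode near
#' zero (genomically stable samples, residual binomial noise only) and a
#' broad mode of unstable samples. The default `"mixture"` method fits a
#' two-component Gaussian mixture on the raw score scale by EM (50 random
#' restarts under a fixed seed, best log-likelihood kept) and returns the
#' score at which posterior component membership flips — the valley between
#' the modes. `"otsu"` minimizes the within-class variance over a 1000-point
#' grid; `"fixed"` returns a user constant (e.g. the published 0.07).
#'
#' A degenerate mixture fit — a component weight below 0.05, component means
#' closer than 0.02, or no genuine valley between the modes (the mixture
#' density at the flip point is at least 30% of the density at the shallower
#' mode, as happens when EM splits one tight cluster in two) — falls back to
#' Otsu with a warning; fewer than 10 finite scores is an error directing
#' the user to `method = "fixed"`.
#'
#' @param scores Numeric GI scores in `[0, 1]`; `NA`s (indeterminate samples)
#'   are dropped.
#' @param method `"mixture"`, `"otsu"` or `"fixed"`.
#' @param fixed_cutoff Constant used by `method = "fixed"`.
#' @param seed RNG seed for the EM restarts.
#' @param restarts Number of EM restarts.
#' @return An object of class `gi_cutoff`: list with `method`, `cutoff`, and
#'   for the mixture fit `means`, `sds`, `weights`, `loglik`, plus `seed` and
#'   the input `scores`.
#' @export
#' @examples
#' set.seed(7)
#' x <- c(pmax(rnorm(19, 0.03, 0.01), 0), rnorm(37, 0.28, 0.08))
#' fit <- fit_cutoff(x, seed = 1)
#' fit$cutoff
fit_cutoff <- function(scores, method = c("mixture", "otsu", "fixed"),
                       fixed_cutoff = 0.07, seed = 1L, restarts = 50L) {
  method <- match.arg(method)
  x <- scores[is.finite(scores)]
  if (any(x < 0 | x > 1)) abort("GI scores must lie in [0, 1]")
  out <- list(method = method, seed = as.integer(seed), scores = x,
              means = NULL, sds = NULL, weights = NULL, loglik = NULL)
  if (method == "fixed") {
    out$cutoff <- fixed_cutoff
    class(out) <- "gi_cutoff"
    return(out)
  }
  if (method == "otsu") {
    out$cutoff <- otsu_threshold(x)
    class(out) <- "gi_cutoff"
    return(out)
  }
  if (length(x) < 10) {
    abort("mixture cutoff fitting needs >= 10 finite scores; use method = \"fixed\"")
  }
  fit <- withr::with_seed(seed, em_mixture_1d(x, restarts = restarts))
  degenerate <- min(fit$weights) < 0.05 || abs(diff(fit$means)) < 0.02
  if (!degenerate && !has_point_mass(fit, x)) {
    cut_try <- posterior_flip_point(fit)
    dens <- function(t) {
      fit$weights[1] * dnorm(t, fit$means[1], fit$sds[1]) +
        fit$weights[2] * dnorm(t, fit$means[2], fit$sds[2])
    }
    degenerate <- dens(cut_try) >= 0.3 * min(dens(fit$means[1]),
                                             dens(fit$means[2]))
  }
  if (degenerate) {
    warn("degenerate mixture fit (tiny component or indistinct means); falling back to Otsu")
    out$method <- "otsu"
    out$cutoff <- otsu_threshold(x)
    class(out) <- "gi_cutoff"
    return(out)
  }
  out$means <- fit$means
  out$sds <- fit$sds
  out$weights <- fit$weights
  out$loglik <- fit$loglik
  out$cutoff <- posterior_flip_point(fit)
  class(out) <- "gi_cutoff"
  out
}

# Two-component univariate Gaussian EM with random restarts; returns the
# restart with the best log-likelihood, components ordered by mean.
em_mixture_1d <- function(x, restarts = 50L, max_iter = 200L, tol = 1e-8) {
  n <- length(x)
  best <- NULL
  for (r in seq_len(restarts)) {
    mu <- sort(sample(x, 2))
    if (diff(mu) < 1e-6) mu <- mu + c(-1e-3, 1e-3)
    sg <- rep(max(sd(x) / 2, 1e-4), 2)
    w <- c(0.5, 0.5)
    ll_old <- -Inf
    ll <- -Inf
    for (it in seq_len(max_iter)) {
      d1 <- w[1] * dnorm(x, mu[1], sg[1])
      d2 <- w[2] * dnorm(x, mu[2], sg[2])
      tot <- d1 + d2
      tot[tot <= 0] <- .Machine$double.xmin
      g <- d1 / tot
      ll <- sum(log(tot))
      w1 <- mean(g)
      w <- c(w1, 1 - w1)
      mu <- c(sum(g * x) / sum(g), sum((1 - g) * x) / sum(1 - g))
      sg <- sqrt(c(sum(g * (x - mu[1])^2) / sum(g),
                   sum((1 - g) * (x - mu[2])^2) / sum(1 - g)))
      sg <- pmax(sg, 1e-4)
      if (is.finite(ll) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    if (is.null(best) || ll > best$loglik) {
      best <- list(loglik = ll, means = mu, sds = sg, weights = w)
    }
  }
  o <- order(best$means)
  list(loglik = best$loglik, means = best$means[o], sds = best$sds[o],
       weights = best$weights[o])
}

# A variance-floor component whose claimed points are all tied (e.g. a mass
# of exactly-zero scores from samples with no GI mutations) is genuine
# zero-inflation, not an EM pathology; the valley-depth heuristic does not
# apply to it.
has_point_mass <- function(fit, x) {
  for (k in 1:2) {
    if (fit$sds[k] > 1e-3) next
    dk <- fit$weights[k] * dnorm(x, fit$means[k], fit$sds[k])
    do <- fit$weights[3 - k] * dnorm(x, fit$means[3 - k], fit$sds[3 - k])
    claimed <- x[dk > do]
    if (length(claimed) >= 2 && diff(range(claimed)) < 1e-8) return(TRUE)
  }
  FALSE
}

# Score where posterior membership flips between the low and high component:
# the root of log(w1 f1) - log(w2 f2) between the two means.
posterior_flip_point <- function(fit) {
  mu <- fit$means
  sg <- fit$sds
  w <- fit$weights
  h <- function(t) {
    log(w[1]) + dnorm(t, mu[1], sg[1], log = TRUE) -
      log(w[2]) - dnorm(t, mu[2], sg[2], log = TRUE)
  }
  if (h(mu[1]) > 0 && h(mu[2]) < 0) {
    uniroot(h, c(mu[1], mu[2]), tol = 1e-10)$root
  } else {
    # posteriors do not cross between the means (heavy overlap): use the
    # weight-balanced midpoint
    (mu[1] * w[2] + mu[2] * w[1]) / sum(w)
  }
}

# Otsu's threshold: minimize within-class variance over an even grid.
otsu_threshold <- function(x, grid_n = 1000L) {
  lo <- min(x)
  hi <- max(x)
  if (hi - lo < .Machine$double.eps) {
    abort("cannot place a threshold: all scores identical")
  }
  grid <- seq(lo, hi, length.out = grid_n + 2)[2:(grid_n + 1)]
  wcv <- vapply(grid, function(t) {
    a <- x[x < t]
    b <- x[x >= t]
    if (length(a) == 0 || length(b) == 0) return(Inf)
    va <- if (length(a) > 1) var(a) else 0
    vb <- if (length(b) > 1) var(b) else 0
    (length(a) * va + length(b) * vb) / length(x)
  }, numeric(1))
  grid[which.min(wcv)]
}

#' Classify samples as GI or GS with a fitted cutoff
#'
#' Applies a [fit_cutoff()] model to scored samples: `status = "GI"` when
#' `score >= cutoff`, else `"GS"` (the boundary is assigned to the unstable
#' class). Indeterminate rows pass through unchanged. The cutoff used is
#' recorded per row.
#'
#' @param results Score tibble from [compute_gi_score()] / [score_cohort()].
#' @param model A `gi_cutoff` object, or a bare numeric cutoff.
#' @return `results` with `status` and `cutoff_used` filled in.
#' @export
#' @examples
#' res <- tibble::tibble(score = c(0.28, 0.03), status = NA, cutoff_used = NA)
#' classify_status(res, 0.07)$status # "GI" "GS"
classify_status <- function(results, model) {
  cutoff <- if (inherits(model, "gi_cutoff")) model$cutoff else as.numeric(model)
  stopifnot(is.finite(cutoff))
  results %>%
    mutate(
      status = case_when(
        .data$status %in% "indeterminate" ~ "indeterminate",
        .data$score >= cutoff ~ "GI",
        TRUE ~ "GS"
      ),
      cutoff_used = ifelse(.data$status == "indeterminate", NA_real_, cutoff)
    )
}

#' @export
print.gi_cutoff <- function(x, ...) {
  cat(sprintf("<gi_cutoff> method %s, cutoff %.4f (n = %d scores)\n",
              x$method, x$cutoff, length(x$scores)))
  if (!is.null(x$means)) {
    cat(sprintf("  components: N(%.3f, %.3f) w=%.2f | N(%.3f, %.3f) w=%.2f\n",
                x$means[1], x$sds[1], x$weights[1],
                x$means[2], x$sds[2], x$weights[2]))
  }
  cat("  tie rule: score >= cutoff is classified GI\n")
  invisible(x)
}

#' @rdname fit_cutoff
#' @param x A `gi_cutoff` object.
#' @param ... Unused.
#' @export
tidy.gi_cutoff <- function(x, ...) {
  if (is.null(x$means)) {
    return(tibble(component = character(), mean = double(), sd = double(),
                  weight = double()))
  }
  tibble(component = c("GS", "GI"), mean = x$means, sd = x$sds,
         weight = x$weights)
}

#' @rdname fit_cutoff
#' @export
glance.gi_cutoff <- function(x, ...) {
  tibble(method = x$method, cutoff = x$cutoff, n = length(x$scores),
         loglik = x$loglik %||% NA_real_, seed = x$seed)
}

#' Export a cutoff model as a JSON report
#'
#' @param model A `gi_cutoff`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cutoff_report <- function(model, path) {
  jsonlite::write_json(
    list(method = model$method, cutoff = model$cutoff,
         components = tidy(model), n_scores = length(model$scores),
         seed = model$seed, tie_rule = "score >= cutoff -> GI"),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
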