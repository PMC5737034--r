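#' Expected detection frequency under the Sloan neutral model
#'
#' Under neutral demographic drift with immigration, a taxon with regional
#' relative abundance p has local relative abundance distributed
#' Beta(N m p, N m (1 - p)) where N is the local community size (reads per
#' sample) and m the migration probability. The probability of detecting it
#' — its local abundance exceeding the detection limit d — is therefore
#' 1 - BetaCDF(d; N m p, N m (1 - p)). The frequency is non-decreasing in
#' both p and m.
#'
#' @param p Regional mean relative abundance(s) in \[0, 1\].
#' @param N Community size (reads per sample), >= 1.
#' @param m Migration probability in (0, 1].
#' @param d Detection limit as a relative abundance (default one read,
#'   1/N).
#' @return Expected occurrence frequency, same length as `p`.
#' @export
predict_ncm_frequency <- function(p, N, m, d = 1 / N) {
  stopifnot(N >= 1, m > 0, m <= 1, d > 0, d < 1, all(p >= 0), all(p <= 1))
  out <- numeric(length(p))
  inner <- p > 0 & p < 1
  out[p == 0] <- 0
  out[p == 1] <- 1
  out[inner] <- stats::pbeta(d, N * m * p[inner], N * m * (1 - p[inner]),
                             lower.tail = FALSE)
  out
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param phat Observed proportion(s) in \[0, 1\].
#' @param n Number of trials (>= 1).
#' @param z Normal quantile (default 1.959964, the two-sided 95% level).
#' @return A tibble with columns `lower`, `upper`; bounds always bracket
#'   `phat` and stay inside \[0, 1\].
#' @export
wilson_interval <- function(phat, n, z = 1.959964) {
  stopifnot(n >= 1, all(phat >= 0), all(phat <= 1))
  z2 <- z^2
  centre <- (phat + z2 / (2 * n)) / (1 + z2 / n)
  half <- z * sqrt(phat * (1 - phat) / n + z2 / (4 * n^2)) / (1 + z2 / n)
  tibble::tibble(lower = pmax(0, centre - half),
                 upper = pmin(1, centre + half))
}

#' Probability of detecting a taxon in a finite multinomial sample
#'
#' Under the neutral beta marginal, a taxon's local relative abundance x is
#' Beta(N m p, N m (1 - p)); a sequencing sample of N reads then misses it
#' with probability E\[(1 - x)^N\] = B(a, b + N) / B(a, b). The detection
#' probability 1 - B(a, b + N) / B(a, b) is the finite-depth counterpart
#' of the threshold form [predict_ncm_frequency()] and converges to it as
#' N grows; for count data it is the quantity an observed occurrence
#' (count > 0) actually estimates.
#'
#' @inheritParams predict_ncm_frequency
#' @return Detection probability, same length as `p`.
#' @export
predict_ncm_detection <- function(p, N, m) {
  stopifnot(N >= 1, m > 0, m <= 1, all(p >= 0), all(p <= 1))
  a <- N * m * p
  b <- N * m * (1 - p)
  out <- 1 - exp(lbeta(a, b + N) - lbeta(a, b))
  out[p == 0] <- 0
  out[p == 1] <- 1
  out
}

#' Fit the Sloan neutral community model to an OTU table
#'
#' Each OTU contributes a point (mean relative abundance p_i, occurrence
#' frequency f_i = fraction of samples where it was detected). The single
#' free parameter m is estimated by bounded least squares of f_i on the
#' neutral prediction with N fixed at the per-sample depth: a 200-point
#' log-spaced scan of m over (1e-6, 1] locates the global basin and
#' golden-section search refines the minimum, so local minima cannot trap
#' the fit.
#' Goodness of fit is R-squared = 1 - SSE/SST over the frequency points
#' (negative values possible for a poor fit). A Wilson 95% envelope around
#' the predicted frequencies (n = number of samples) classifies each OTU
#' as above, within or below the neutral expectation.
#'
#' Two detection models are available. `"sampling"` (the default) predicts
#' occurrence as the probability of at least one read in an N-read sample
#' ([predict_ncm_detection()]) — the quantity an observed count > 0
#' actually estimates, which keeps the fitted m consistent on finite-depth
#' count data. `"threshold"` is the classic abundance-threshold form
#' ([predict_ncm_frequency()] with detection limit d = 1/N); the two agree
#' as N grows, but on count data the threshold form inflates m because
#' taxa just below the limit are still sometimes sequenced.
#'
#' @param x A rarefied [otu_table()] (uniform depth required).
#' @param z Normal quantile for the Wilson envelope.
#' @param detection `"sampling"` (default) or `"threshold"`; see Details.
#' @return An `ncm_fit`: list with `m`, `N`, `Nm`, `d`, `r_squared`,
#'   `detection`, `n_samples`, and `otus` — a tibble (`otu_id`, `p`,
#'   `freq`, `predicted`, `lower`, `upper`, `position` in
#'   above/within/below).
#' @export
fit_ncm <- function(x, z = 1.959964,
                    detection = c("sampling", "threshold")) {
  detection <- match.arg(detection)
  x <- as_otu_table(x)
  if (!isTRUE(attr(x, "rarefied"))) {
    stop("fit_ncm requires a rarefied table (uniform depth)", call. = FALSE)
  }
  if (nrow(x) < 8L) {
    warning("fewer than 8 samples; frequency estimates are coarse",
            call. = FALSE)
  }
  N <- rowSums(x)[1L]
  d <- 1 / N
  m0 <- unclass(x)
  keep <- colSums(m0) > 0L
  m0 <- m0[, keep, drop = FALSE]
  p <- colMeans(m0 / N)
  f <- colMeans(m0 > 0)
  if (all(f == 1)) {
    stop("all OTUs occur in every sample; no signal to fit m", call. = FALSE)
  }
  pred_of <- function(m) {
    if (detection == "sampling") predict_ncm_detection(p, N, m)
    else predict_ncm_frequency(p, N, m, d)
  }
  sse_of <- function(log_m) sum((f - pred_of(exp(log_m)))^2)
  # one bounded parameter: scan a log grid for the global basin, then
  # polish with golden-section/parabolic search inside the best bracket
  grid <- log(10^seq(-6, 0, length.out = 200))
  grid_sse <- vapply(grid, sse_of, numeric(1))
  i <- which.min(grid_sse)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(sse_of, lower = lo, upper = hi, tol = 1e-10)
  if (opt$objective <= grid_sse[i]) {
    fit_m <- exp(opt$minimum)
    best_sse <- opt$objective
  } else {
    fit_m <- exp(grid[i])
    best_sse <- grid_sse[i]
  }
  if (!is.finite(fit_m) || !is.finite(best_sse)) {
    stop("neutral-model fit failed to converge", call. = FALSE)
  }
  pred <- pred_of(fit_m)
  r2 <- 1 - best_sse / sum((f - mean(f))^2)
  wb <- wilson_interval(pred, nrow(x), z)
  position <- ifelse(f > wb$upper, "above",
              ifelse(f < wb$lower, "below", "within"))
  otus <- tibble::tibble(
    otu_id = colnames(m0), p = p, freq = f, predicted = pred,
    lower = wb$lower, upper = wb$upper,
    position = factor(position, levels = c("above", "within", "below")))
  structure(list(m = fit_m, N = as.numeric(N), Nm = as.numeric(N) * fit_m,
                 d = d, r_squared = r2, detection = detection,
                 n_samples = nrow(x), otus = otus),
            class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("<ncm_fit> m = %.4g, Nm = %.4g, N = %g, R2 = %.3f (%d OTUs)\n",
              x$m, x$Nm, x$N, x$r_squared, nrow(x$otus)))
  invisible(x)
}

#' @export
tidy.ncm_fit <- function(x, ...) x$otus

#' @export
glance.ncm_fit <- function(x, ...) {
  tibble::tibble(m = x$m, N = x$N, Nm = x$Nm, d = x$d,
                 r_squared = x$r_squared, detection = x$detection,
                 n_samples = x$n_samples, n_otus = nrow(x$otus))
}

#' Plot a neutral-model fit
#'
#' Occurrence frequency against log10 mean relative abundance with the
#' fitted neutral expectation and its Wilson 95% envelope; OTUs coloured
#' by their position relative to the envelope.
#'
#' @param object An [fit_ncm()] result.
#' @param ... Unused.
#' @export
autoplot.ncm_fit <- function(object, ...) {
  df <- object$otus[order(object$otus$p), ]
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$p))) +
    ggplot2::geom_point(ggplot2::aes(y = .data$freq,
                                     colour = .data$position),
                        alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted), colour = "blue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper), linetype = 2) +
    ggplot2::labs(x = "log10 mean relative abundance",
                  y = "occurrence frequency",
                  colour = NULL,
                  caption = sprintf("m = %.3g, Nm = %.3g, R2 = %.2f",
                                    object$m, object$Nm,
                                    object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Neutral-model fit along taxonomic ranks
#'
#' Aggregates the table at each rank (conserving depth), refits the
#' neutral model and reports its R-squared — the per-rank neutral
#' counterpart of [dbrda_by_rank()]'s environmental explained variation.
#'
#' @param x A rarefied [otu_table()].
#' @param taxonomy Taxonomy tibble.
#' @param ranks Ranks to profile.
#' @param detection Detection model passed to [fit_ncm()].
#' @return A tibble: `rank`, `n_taxa`, `m`, `r_squared`, `low_confidence`
#'   (TRUE when a rank has fewer than 10 taxa).
#' @export
ncm_by_rank <- function(x, taxonomy,
                        ranks = c("otu", "genus", "family", "order",
                                  "class", "phylum"),
                        detection = c("sampling", "threshold")) {
  x <- as_otu_table(x)
  detection <- match.arg(detection)
  purrr::map_dfr(ranks, function(rk) {
    agg <- aggregate_by_rank(x, taxonomy, rk)
    fit <- try(suppressWarnings(fit_ncm(agg, detection = detection)),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      tibble::tibble(rank = rk, n_taxa = ncol(agg), m = NA_real_,
                     r_squared = NA_real_,
                     low_confidence = ncol(agg) < 10L)
    } else {
      tibble::tibble(rank = rk, n_taxa = ncol(agg), m = fit$m,
                     r_squared = fit$r_squared,
                     low_confidence = ncol(agg) < 10L)
    }
  })
}
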