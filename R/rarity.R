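#' Partition OTUs into abundant, conditionally rare and rare
#'
#' Categories follow relative-abundance cut-offs: *rare* taxa stay below
#' `rare_cut` (default 0.01%) in every sample; *conditionally rare* taxa
#' drop below `rare_cut` in at least one sample but never reach
#' `abundant_cut` (default 1%); *abundant* taxa are the literal complement
#' — everything not rare or conditionally rare. Note the complement also
#' captures OTUs that are never below 0.01% yet never reach 1%; their count
#' is reported in the summary (`n_never_reaching_abundant_cut`) so the
#' consequence of the rule is visible.
#'
#' @param rel A relative-abundance matrix ([to_relative()]) or an
#'   [otu_table()] (converted internally).
#' @param rare_cut,abundant_cut Relative-abundance thresholds,
#'   0 < rare_cut < abundant_cut <= 1.
#' @return A `rarity_partition`: list with `otus` (tibble: `otu_id`,
#'   `max_rel`, `min_rel`, `category`), the thresholds, and `counts` if
#'   built from a count table.
#' @export
classify_rarity <- function(rel, rare_cut = 1e-4, abundant_cut = 1e-2) {
  stopifnot(rare_cut > 0, rare_cut < abundant_cut, abundant_cut <= 1)
  counts <- NULL
  if (inherits(rel, "otu_table") || !is_relative(rel)) {
    counts <- as_otu_table(rel)
    rel <- to_relative(counts)
  }
  m <- unclass(rel)
  mx <- apply(m, 2L, max)
  mn <- apply(m, 2L, min)
  if (any(mx == 0)) {
    warning(sum(mx == 0), " OTU(s) absent from all samples classified rare",
            call. = FALSE)
  }
  category <- ifelse(mx < rare_cut, "rare",
              ifelse(mn < rare_cut & mx < abundant_cut, "conditionally_rare",
                     "abundant"))
  otus <- tibble::tibble(
    otu_id = colnames(m), max_rel = mx, min_rel = mn,
    category = factor(category,
                      levels = c("abundant", "conditionally_rare", "rare")))
  structure(list(otus = otus, rare_cut = rare_cut,
                 abundant_cut = abundant_cut,
                 read_totals = if (!is.null(counts)) colSums(counts)),
            class = "rarity_partition")
}

#' @export
print.rarity_partition <- function(x, ...) {
  cat(sprintf("<rarity_partition> %d OTUs (rare < %g, abundant >= %g)\n",
              nrow(x$otus), x$rare_cut, x$abundant_cut))
  print(table(x$otus$category))
  invisible(x)
}

#' @export
tidy.rarity_partition <- function(x, ...) x$otus

#' Per-category OTU and read accounting of a rarity partition
#'
#' @param partition A [classify_rarity()] result.
#' @param x The [otu_table()] the partition was built from (optional if the
#'   partition was built from counts directly).
#' @return A tibble with one row per category: `n_otus`, `n_reads`,
#'   `pct_otus`, `pct_reads` (percentages of the table totals, full
#'   precision). Attribute `n_never_reaching_abundant_cut` counts
#'   "abundant" OTUs whose maximum never reaches the abundant cut-off.
#' @export
rarity_summary <- function(partition, x = NULL) {
  reads <- partition$read_totals
  if (!is.null(x)) {
    x <- as_otu_table(x)
    if (!identical(sort(colnames(x)), sort(partition$otus$otu_id))) {
      stop("partition and table OTU sets differ", call. = FALSE)
    }
    reads <- colSums(x)[partition$otus$otu_id]
  }
  if (is.null(reads)) {
    stop("supply the count table the partition was built from", call. = FALSE)
  }
  out <- category_percentages(
    tapply(rep(1L, nrow(partition$otus)), partition$otus$category, sum,
           default = 0L),
    tapply(reads, partition$otus$category, sum, default = 0))
  flagged <- sum(partition$otus$category == "abundant" &
                   partition$otus$max_rel < partition$abundant_cut)
  attr(out, "n_never_reaching_abundant_cut") <- flagged
  out
}

#' Percentages from per-category OTU and read counts
#'
#' The accounting step behind [rarity_summary()], exposed so printed
#' category counts (e.g. from a publication table) can be turned into
#' percentages of totals directly.
#'
#' @param n_otus,n_reads Named numeric vectors of per-category OTU and read
#'   counts (same names, e.g. abundant / conditionally_rare / rare).
#' @return A tibble: `category`, `n_otus`, `n_reads`, `pct_otus`,
#'   `pct_reads`, plus a `total` row.
#' @export
category_percentages <- function(n_otus, n_reads) {
  stopifnot(length(n_otus) == length(n_reads))
  tot_o <- sum(n_otus)
  tot_r <- sum(n_reads)
  otus_col <- c(as.numeric(n_otus), tot_o)
  reads_col <- c(as.numeric(n_reads), tot_r)
  tibble::tibble(
    category = c(names(n_otus), "total"),
    n_otus = otus_col,
    n_reads = reads_col,
    pct_otus = 100 * otus_col / tot_o,
    pct_reads = 100 * reads_col / tot_r)
}

#' MultiCoLA cutoff-sensitivity profile
#'
#' Multivariate cutoff level analysis: remove OTUs whose whole-dataset
#' relative abundance falls below an increasing series of cut-offs and
#' measure how much the Bray-Curtis structure of the truncated table still
#' resembles the full one (Spearman rank correlation between the lower
#' triangles of the two distance matrices). A correlation staying near 1
#' while most OTUs are removed means the rare tail contributes little to
#' the between-sample structure.
#'
#' @param x A rarefied [otu_table()].
#' @param cutoffs Ascending whole-dataset relative-abundance cut-offs in
#'   \[0, 1).
#' @return A `multicola_profile` tibble: `cutoff`, `n_otus_retained`,
#'   `fraction_reads_retained`, `spearman_rho` (NA when fewer than two OTUs
#'   survive a cutoff).
#' @export
multicola_profile <- function(x, cutoffs = c(0, 1e-5, 2e-5, 5e-5, 1e-4,
                                             5e-4, 1e-3, 1e-2)) {
  x <- as_otu_table(x)
  stopifnot(!is.unsorted(cutoffs), all(cutoffs >= 0), all(cutoffs < 1))
  overall <- colSums(x) / sum(x)
  d_full <- lower_tri(bray_curtis(x))
  rows <- purrr::map(cutoffs, function(cut) {
    keep <- overall >= cut | (cut == 0)
    n_kept <- sum(keep)
    frac_reads <- sum(colSums(x)[keep]) / sum(x)
    rho <- NA_real_
    if (n_kept >= 1L) {
      trunc <- unclass(x)[, keep, drop = FALSE]
      if (all(rowSums(trunc) > 0)) {
        d_trunc <- lower_tri(vegan::vegdist(trunc, method = "bray"))
        rho <- suppressWarnings(
          stats::cor(d_full, d_trunc, method = "spearman"))
      }
    }
    tibble::tibble(cutoff = cut, n_otus_retained = n_kept,
                   fraction_reads_retained = frac_reads,
                   spearman_rho = rho)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("multicola_profile", class(out))
  out
}

#' @export
autoplot.multicola_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$cutoff, y = .data$spearman_rho)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_otus_retained)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "abundance cutoff (whole-dataset relative abundance)",
                  y = "Spearman correlation with full Bray-Curtis structure",
                  size = "OTUs retained") +
    ggplot2::theme_minimal()
}
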