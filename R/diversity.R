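#' Per-sample alpha-diversity estimators
#'
#' Observed richness, bias-corrected Chao1, ACE (rare threshold 10,
#' coefficient-of-variation correction floored at 0), Shannon-Wiener H'
#' (natural log), Simpson concentration D = sum p^2 (with Gini-Simpson
#' 1 - D also reported) and Pielou evenness J = H' / ln S.
#'
#' Chao1 uses the bias-corrected form S_obs + F1 (F1 - 1) / (2 (F2 + 1))
#' with F1/F2 the singleton/doubleton counts, so Chao1 = S_obs whenever a
#' sample has no singletons.
#'
#' @param x An [otu_table()] with positive per-sample totals.
#' @return A tibble with one row per sample: `sample_id`, `n_reads`,
#'   `s_obs`, `chao1`, `ace`, `shannon`, `simpson` (D), `gini_simpson`,
#'   `pielou` (NA when `s_obs` = 1).
#' @export
alpha_diversity <- function(x) {
  x <- as_otu_table(x)
  if (any(rowSums(x) == 0)) {
    stop("empty sample(s): ",
         paste(rownames(x)[rowSums(x) == 0], collapse = ", "), call. = FALSE)
  }
  m <- unclass(x)
  est <- vegan::estimateR(m) # S.obs, S.chao1, S.ACE with the standard forms
  sh <- vegan::diversity(m, index = "shannon")
  gini <- vegan::diversity(m, index = "simpson")
  s_obs <- est["S.obs", ]
  ace <- est["S.ACE", ]
  # no OTU at or below the rare threshold: the ACE correction vanishes
  no_rare <- apply(m, 1L, function(r) !any(r > 0 & r <= 10))
  ace[no_rare] <- s_obs[no_rare]
  tibble::tibble(
    sample_id = rownames(m),
    n_reads = rowSums(m),
    s_obs = as.numeric(s_obs),
    chao1 = as.numeric(est["S.chao1", ]),
    ace = as.numeric(ace),
    shannon = as.numeric(sh),
    simpson = 1 - as.numeric(gini),
    gini_simpson = as.numeric(gini),
    pielou = ifelse(s_obs > 1, as.numeric(sh) / log(s_obs), NA_real_))
}

#' Analytic rarefaction curve for one sample
#'
#' Expected richness at a subsampling depth d:
#' E\[S(d)\] = sum_i (1 - choose(N - N_i, d) / choose(N, d)), evaluated via
#' log-gamma arithmetic (no resampling noise).
#'
#' @param counts Integer count vector for one sample (or a 1-row
#'   [otu_table()]).
#' @param depths Depths at which to evaluate; all must be <= the sample
#'   total.
#' @return A tibble: `depth`, `expected_s`.
#' @export
rarefaction_curve <- function(counts, depths) {
  if (inherits(counts, "otu_table")) {
    stopifnot(nrow(counts) == 1L)
    counts <- as.integer(unclass(counts)[1L, ])
  }
  counts <- counts[counts > 0]
  total <- sum(counts)
  if (any(depths > total)) {
    stop("depth(s) exceed the sample total of ", total, call. = FALSE)
  }
  es <- vapply(depths, function(d) {
    as.numeric(vegan::rarefy(matrix(counts, nrow = 1L), sample = d))
  }, numeric(1))
  tibble::tibble(depth = as.numeric(depths), expected_s = es)
}

#' Coefficient of variation of within-group dissimilarities
#'
#' For each group, collects the pairwise dissimilarities among its members
#' and reports their mean, sample standard deviation (n - 1 denominator)
#' and CV = SD / mean — a scale-free measure of how variable a habitat's
#' community turnover is.
#'
#' @param dm A `dist` over samples.
#' @param grouping Factor (or vector) of group labels, one per sample in
#'   `dm` order.
#' @return A tibble: `group`, `n_members`, `n_pairs`, `mean`, `sd`, `cv`
#'   (NA when the group mean is 0 or the group has fewer than 2 pairs' SD
#'   support).
#' @export
dissimilarity_cv <- function(dm, grouping) {
  m <- as.matrix(dm)
  grouping <- as.factor(grouping)
  stopifnot(length(grouping) == nrow(m))
  purrr::map_dfr(levels(grouping), function(g) {
    idx <- which(grouping == g)
    if (length(idx) < 2L) {
      stop("group '", g, "' has fewer than 2 members", call. = FALSE)
    }
    vals <- m[idx, idx][lower.tri(matrix(0, length(idx), length(idx)))]
    mu <- mean(vals)
    s <- stats::sd(vals)
    tibble::tibble(group = g, n_members = length(idx),
                   n_pairs = length(vals), mean = mu, sd = s,
                   cv = ifelse(mu > 0, s / mu, NA_real_))
  })
}

#' Compare a per-sample quantity between groups
#'
#' One of: classical one-way ANOVA; all-pairs Welch t-tests with Bonferroni
#' correction plus a compact letters display (letters shared by two groups
#' mean their difference is not significant, computed as connected
#' components of the non-significant-pair graph); or all-pairs
#' Mann-Whitney U tests (exact when both groups have <= 8 observations and
#' no ties, normal approximation with tie correction otherwise).
#'
#' @param values Numeric vector (e.g. a diversity index per sample).
#' @param grouping Factor of group labels, same length.
#' @param method `"anova"`, `"t_bonferroni"` or `"mannwhitney"`.
#' @param alpha Significance level for the letters display.
#' @return For `"anova"` a one-row tibble (`statistic`, `df1`, `df2`,
#'   `p_value`); otherwise a tibble of pairwise comparisons (`group1`,
#'   `group2`, `statistic`, `p_value`, `p_adjusted`) with a `letters`
#'   attribute mapping groups to letter codes.
#' @export
group_tests <- function(values, grouping,
                        method = c("anova", "t_bonferroni", "mannwhitney"),
                        alpha = 0.05) {
  method <- match.arg(method)
  grouping <- droplevels(as.factor(grouping))
  stopifnot(length(values) == length(grouping), nlevels(grouping) >= 2L)
  if (method == "anova") {
    sds <- tapply(values, grouping, stats::sd)
    if (any(!is.na(sds) & sds == 0) && all(sds == 0, na.rm = TRUE) &&
        stats::var(values) == 0) {
      return(tibble::tibble(method = "anova", statistic = 0,
                            df1 = nlevels(grouping) - 1L,
                            df2 = length(values) - nlevels(grouping),
                            p_value = 1))
    }
    fit <- stats::aov(values ~ grouping)
    tab <- summary(fit)[[1L]]
    return(tibble::tibble(method = "anova", statistic = tab$`F value`[1L],
                          df1 = tab$Df[1L], df2 = tab$Df[2L],
                          p_value = tab$`Pr(>F)`[1L]))
  }
  lev <- levels(grouping)
  pairs <- utils::combn(lev, 2L)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1L, k]; g2 <- pairs[2L, k]
    v1 <- values[grouping == g1]; v2 <- values[grouping == g2]
    if (method == "t_bonferroni") {
      if (stats::sd(v1) == 0 && stats::sd(v2) == 0 && mean(v1) == mean(v2)) {
        tt <- list(statistic = 0, p.value = 1)
      } else if (stats::sd(c(v1 - mean(v1), v2 - mean(v2))) == 0) {
        stop("zero within-group variance in groups ", g1, ", ", g2,
             call. = FALSE)
      } else {
        tt <- stats::t.test(v1, v2)
      }
      tibble::tibble(group1 = g1, group2 = g2,
                     statistic = unname(tt$statistic), p_value = tt$p.value)
    } else {
      exact <- length(v1) <= 8L && length(v2) <= 8L &&
        !any(duplicated(c(v1, v2)))
      wt <- suppressWarnings(stats::wilcox.test(v1, v2, exact = exact,
                                                correct = !exact))
      tibble::tibble(group1 = g1, group2 = g2,
                     statistic = unname(wt$statistic), p_value = wt$p.value)
    }
  })
  res$p_adjusted <- pmin(res$p_value * nrow(res), 1)
  res$method <- method
  attr(res, "letters") <- letters_display(res, lev, alpha)
  res
}

# compact letters display: connected components of the graph whose edges
# are non-significant pairs (adjusted p >= alpha)
letters_display <- function(pairwise, groups, alpha = 0.05) {
  comp <- stats::setNames(seq_along(groups), groups)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(pairwise))) {
      if (pairwise$p_adjusted[k] >= alpha) {
        a <- comp[[pairwise$group1[k]]]
        b <- comp[[pairwise$group2[k]]]
        if (a != b) {
          comp[comp == max(a, b)] <- min(a, b)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  stats::setNames(letters[match(comp, sort(unique(comp)))], groups)
}
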