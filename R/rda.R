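#' Prepare an RDA predictor table from sample metadata
#'
#' Quantitative covariates are log(x+1)-transformed (pH excepted) and
#' standardized; categorical covariates (habitat, season) are dummy-coded
#' with the first level dropped.
#'
#' @param meta Sample metadata tibble.
#' @param predictors Character vector of metadata columns.
#' @return A numeric data frame of model-ready predictors, rownames =
#'   sample ids.
#' @export
prepare_predictors <- function(meta, predictors) {
  miss <- setdiff(predictors, names(meta))
  if (length(miss)) {
    stop("metadata missing predictor(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num <- predictors[vapply(meta[predictors], is.numeric, logical(1))]
  cat_ <- setdiff(predictors, num)
  parts <- list()
  if (length(num)) {
    parts$num <- as.data.frame(transform_env(meta, num))
  }
  for (v in cat_) {
    f <- droplevels(as.factor(meta[[v]]))
    mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
    colnames(mm) <- paste0(v, "_", levels(f)[-1L])
    parts[[v]] <- as.data.frame(mm)
  }
  out <- do.call(cbind, unname(parts))
  rownames(out) <- meta$sample_id
  out
}

# response matrix for constrained ordination: relative abundances of a
# count table (optionally Hellinger-transformed); numeric matrices pass
# through
prepare_response <- function(x, hellinger = FALSE) {
  y <- if (inherits(x, "otu_table")) unclass(to_relative(x)) else
    unclass(as_relative_or_numeric(x))
  if (hellinger) y <- vegan::decostand(y, method = "hellinger")
  y
}

as_relative_or_numeric <- function(x) {
  if (is.matrix(x) && is.numeric(x)) x else unclass(to_relative(as_otu_table(x)))
}

# iterative VIF pruning: drop the worst predictor until all VIFs <= cut;
# aliased (perfectly collinear) columns have VIF NA/Inf and go first
prune_vif <- function(y, X, vif_cut = 20) {
  dropped <- tibble::tibble(variable = character(), vif = numeric())
  repeat {
    if (ncol(X) <= 1L) break
    fit <- vegan::rda(y ~ ., data = X)
    v <- vegan::vif.cca(fit)
    v <- v[colnames(X)]
    v[is.na(v)] <- Inf
    if (max(v) <= vif_cut) break
    worst <- names(which.max(v))
    dropped <- dplyr::bind_rows(dropped,
                                tibble::tibble(variable = worst,
                                               vif = unname(v[worst])))
    X <- X[, setdiff(colnames(X), worst), drop = FALSE]
  }
  list(X = X, dropped = dropped)
}

#' Redundancy analysis with VIF filtering and forward selection
#'
#' Constrained ordination of community composition on environmental
#' predictors: the response (centered relative abundances, optionally
#' Hellinger) is regressed on the predictor table; collinear predictors
#' with VIF above `vif_cut` are iteratively removed; forward selection then
#' adds, at each step, the candidate with the largest added explained
#' variance provided its conditional (partial-model) permutation p-value is
#' below `forward_alpha`. Reports per-axis eigenvalues, total explained
#' variance, Ezekiel-adjusted R-squared and a global pseudo-F permutation
#' test.
#'
#' @param x A rarefied [otu_table()] (or numeric response matrix).
#' @param meta Sample metadata aligned with `x`.
#' @param predictors Metadata columns to offer as constraints.
#' @param n_perm Permutations for significance tests.
#' @param seed Integer seed.
#' @param vif_cut Variance-inflation threshold (default 20).
#' @param forward_alpha Entry threshold for forward selection (default
#'   0.05).
#' @param forward_select Set `FALSE` to keep every VIF-surviving predictor.
#' @param hellinger Hellinger-transform the response first.
#' @return An `rda_result`: list with the vegan fit, `selected` predictors,
#'   `dropped_vif`, `selection_path`, `explained` (proportion), `adj_r2`,
#'   `p_value`, `eigenvalues`, `scores`.
#' @export
rda_analysis <- function(x, meta, predictors, n_perm = 999, seed = 1,
                         vif_cut = 20, forward_alpha = 0.05,
                         forward_select = TRUE, hellinger = FALSE) {
  y <- prepare_response(x, hellinger)
  meta <- check_samples_match_matrix(y, meta)
  X <- prepare_predictors(meta, predictors)
  pruned <- prune_vif(y, X, vif_cut)
  X <- pruned$X

  path <- tibble::tibble(variable = character(), added_r2 = numeric(),
                         p_value = numeric(), selected = logical())
  if (forward_select && ncol(X) > 1L) {
    selected <- character()
    remaining <- colnames(X)
    repeat {
      if (!length(remaining) || length(selected) >= nrow(y) - 2L) break
      gains <- vapply(remaining, function(v) {
        f <- vegan::rda(y ~ ., data = X[, c(selected, v), drop = FALSE])
        f$CCA$tot.chi / f$tot.chi
      }, numeric(1))
      base_r2 <- if (length(selected)) {
        f0 <- vegan::rda(y ~ ., data = X[, selected, drop = FALSE])
        f0$CCA$tot.chi / f0$tot.chi
      } else 0
      cand <- names(which.max(gains))
      # conditional permutation test of the candidate given the current set
      dat <- X[, c(selected, cand), drop = FALSE]
      fml <- if (length(selected)) {
        stats::as.formula(paste("y ~", cand, "+ Condition(",
                                paste(selected, collapse = " + "), ")"))
      } else stats::as.formula(paste("y ~", cand))
      pfit <- vegan::rda(fml, data = dat)
      p <- withr::with_seed(as.integer(seed) + length(selected), {
        as.data.frame(vegan::anova.cca(pfit,
                                       permutations = n_perm))$`Pr(>F)`[1L]
      })
      ok <- p < forward_alpha
      path <- dplyr::bind_rows(path, tibble::tibble(
        variable = cand, added_r2 = max(gains) - base_r2, p_value = p,
        selected = ok))
      if (!ok) break
      selected <- c(selected, cand)
      remaining <- setdiff(remaining, cand)
    }
    if (!length(selected)) {
      # keep the single best candidate so a model always exists, but flag it
      selected <- path$variable[1L]
    }
    X <- X[, selected, drop = FALSE]
  }

  fit <- vegan::rda(y ~ ., data = X)
  if (!is.null(fit$CCA$alias)) {
    stop("rank-deficient design; aliased predictor(s): ",
         paste(fit$CCA$alias, collapse = ", "), call. = FALSE)
  }
  explained <- fit$CCA$tot.chi / fit$tot.chi
  adj <- vegan::RsquareAdj(fit)
  pval <- withr::with_seed(as.integer(seed), {
    as.data.frame(vegan::anova.cca(fit, permutations = n_perm))$`Pr(>F)`[1L]
  })
  eig <- fit$CCA$eig
  sc <- vegan::scores(fit, display = "sites",
                      choices = seq_len(min(2L, length(eig))))
  structure(list(fit = fit, selected = colnames(X),
                 dropped_vif = pruned$dropped, selection_path = path,
                 explained = explained, adj_r2 = adj$adj.r.squared,
                 r2 = adj$r.squared, p_value = pval, eigenvalues = eig,
                 scores = tibble::as_tibble(sc, rownames = "sample_id"),
                 n_perm = n_perm),
            class = "rda_result")
}

check_samples_match_matrix <- function(y, meta) {
  ids <- rownames(y)
  if (is.null(ids)) return(meta)
  miss <- setdiff(ids, meta$sample_id)
  if (length(miss)) {
    stop("sample(s) missing from metadata: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  meta[match(ids, meta$sample_id), , drop = FALSE]
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf(paste0("<rda_result> %d predictor(s), explained = %.3f, ",
                     "adj R2 = %.3f, p = %.4g\n"),
              length(x$selected), x$explained, x$adj_r2, x$p_value))
  invisible(x)
}

#' @export
tidy.rda_result <- function(x, ...) {
  tibble::tibble(axis = names(x$eigenvalues),
                 eigenvalue = as.numeric(x$eigenvalues),
                 proportion = as.numeric(x$eigenvalues) / x$fit$tot.chi)
}

#' @export
glance.rda_result <- function(x, ...) {
  tibble::tibble(explained = x$explained, adj_r2 = x$adj_r2, r2 = x$r2,
                 p_value = x$p_value, n_predictors = length(x$selected),
                 n_perm = x$n_perm)
}

#' Three-block variation partitioning (environment, vegetation, season)
#'
#' Partitions the RDA-explained variation of community composition into
#' the pure and shared fractions of three predictor blocks via adjusted
#' R-squared and inclusion-exclusion over the seven block unions. Pure and
#' shared fractions sum to the adjusted R-squared of the full model; the
#' residual is its complement. Individual fractions can be negative
#' (adjusted R-squared is unbiased, not bounded below).
#'
#' @param x A rarefied [otu_table()] (or numeric response matrix).
#' @param meta Sample metadata.
#' @param block_E,block_V,block_S Character vectors of metadata columns for
#'   the environment, vegetation and season blocks.
#' @param hellinger Hellinger-transform the response.
#' @return A `vpa_result`: list with `fractions` tibble (pure E/V/S,
#'   pairwise shared, three-way shared, residual), `unions` tibble
#'   (adjusted R-squared of the 7 block unions), and the vegan `varpart`
#'   object.
#' @export
vpa <- function(x, meta, block_E, block_V, block_S, hellinger = FALSE) {
  y <- prepare_response(x, hellinger)
  meta <- check_samples_match_matrix(y, meta)
  XE <- prepare_predictors(meta, block_E)
  XV <- prepare_predictors(meta, block_V)
  XS <- prepare_predictors(meta, block_S)
  vp <- vegan::varpart(y, XE, XV, XS)
  fr <- vp$part$indfract
  un <- vp$part$fract
  # varpart's indfract rows: [a] pure X1, [b] pure X2, [c] pure X3,
  # [d] X1&X2, [e] X2&X3, [f] X1&X3, [g] all three, [h] residual
  fractions <- tibble::tibble(
    fraction = c("pure_E", "pure_V", "pure_S", "shared_EV", "shared_VS",
                 "shared_ES", "shared_EVS", "residual"),
    adj_r2 = fr$Adj.R.square[1:8])
  unions <- tibble::tibble(
    union = c("E", "V", "S", "E+V", "E+S", "V+S", "E+V+S"),
    adj_r2 = un$Adj.R.square[1:7])
  structure(list(fractions = fractions, unions = unions, varpart = vp),
            class = "vpa_result")
}

#' @export
print.vpa_result <- function(x, ...) {
  cat("<vpa_result>\n")
  print(as.data.frame(x$fractions))
  invisible(x)
}

#' @export
tidy.vpa_result <- function(x, ...) x$fractions

#' Distance-based RDA explained variation along taxonomic ranks
#'
#' At each rank the table is aggregated, Bray-Curtis dissimilarities are
#' computed, the Gower-centered matrix is decomposed into principal
#' coordinates (non-negative-eigenvalue axes retained; Lingoes correction
#' optional) and those coordinates are constrained on the predictor table
#' (same transform and VIF pipeline as [rda_analysis()]). The explained
#' proportion per rank quantifies how strongly environment structures
#' composition at that taxonomic resolution.
#'
#' @param x A rarefied [otu_table()].
#' @param taxonomy Taxonomy tibble.
#' @param meta Sample metadata.
#' @param predictors Metadata columns used as constraints.
#' @param ranks Ranks to profile, finest to broadest.
#' @param vif_cut VIF threshold.
#' @param lingoes Apply the Lingoes correction for negative eigenvalues.
#' @param distance `"bray"` (default) or `"euclidean"`; with Euclidean
#'   distances on relative abundances the dbRDA explained variation equals
#'   plain RDA's, a useful cross-check.
#' @return A `rank_gradient` tibble: `rank`, `n_taxa`, `explained`,
#'   `adj_r2` (NA when a rank collapses to a single taxon).
#' @export
dbrda_by_rank <- function(x, taxonomy, meta, predictors,
                          ranks = c("otu", "genus", "family", "order",
                                    "class", "phylum"),
                          vif_cut = 20, lingoes = FALSE,
                          distance = c("bray", "euclidean")) {
  x <- as_otu_table(x)
  distance <- match.arg(distance)
  meta <- check_samples_match(x, meta)
  rows <- purrr::map(ranks, function(rk) {
    agg <- aggregate_by_rank(x, taxonomy, rk)
    n_taxa <- ncol(agg)
    if (n_taxa < 2L) {
      return(tibble::tibble(rank = rk, n_taxa = n_taxa,
                            explained = NA_real_, adj_r2 = NA_real_))
    }
    dm <- if (distance == "bray") bray_curtis(agg) else
      stats::dist(unclass(to_relative(agg)))
    X <- prepare_predictors(meta, predictors)
    Xp <- prune_vif(pcoa_axes(dm, lingoes), X, vif_cut)$X
    fit <- vegan::capscale(dm ~ ., data = Xp,
                           add = if (lingoes) "lingoes" else FALSE)
    tibble::tibble(rank = rk, n_taxa = n_taxa,
                   explained = fit$CCA$tot.chi / fit$tot.chi,
                   adj_r2 = vegan::RsquareAdj(fit)$adj.r.squared)
  })
  out <- dplyr::bind_rows(rows)
  out$rank <- factor(out$rank, levels = ranks)
  class(out) <- c("rank_gradient", class(out))
  out
}

# principal coordinates (non-negative eigenvalues) used for VIF screening
pcoa_axes <- function(dm, lingoes = FALSE) {
  fit <- suppressWarnings(
    stats::cmdscale(dm, k = attr(dm, "Size") - 1L, eig = TRUE,
                    add = lingoes))
  keep <- fit$eig > 1e-10
  fit$points[, keep[seq_len(ncol(fit$points))], drop = FALSE]
}

#' @export
autoplot.rank_gradient <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$explained,
                                       group = 1L)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "taxonomic rank",
                  y = "dbRDA explained variation") +
    ggplot2::theme_minimal()
}
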