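#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 NMDS (vegan's monoMDS engine, weak-tie monotone
#' regression): best solution over `restarts` random starts plus one
#' metric-scaling start, stress reported as a proportion in \[0, 1\].
#'
#' @param dm A `dist` (typically Bray-Curtis) over >= 4 samples.
#' @param k Number of axes (default 2).
#' @param restarts Random restarts (default 20).
#' @param seed Integer seed.
#' @return An `nmds_result`: list with `scores` tibble (`sample_id`,
#'   `NMDS1` ...), `stress`, `converged`, `restarts`.
#' @export
nmds <- function(dm, k = 2, restarts = 20, seed = 1) {
  n <- attr(dm, "Size")
  if (is.null(n) || n < 4L) stop("need a dist over >= 4 samples",
                                 call. = FALSE)
  fit <- withr::with_seed(as.integer(seed), {
    best <- NULL
    # metric-scaling start, then random starts; keep the lowest stress
    starts <- c(list(stats::cmdscale(dm, k = k)),
                replicate(restarts,
                          matrix(stats::rnorm(n * k), n, k),
                          simplify = FALSE))
    for (init in starts) {
      cand <- vegan::monoMDS(dm, y = init, k = k, model = "global")
      if (is.null(best) || cand$stress < best$stress) best <- cand
    }
    best
  })
  scores <- tibble::as_tibble(fit$points, .name_repair = "minimal")
  names(scores) <- paste0("NMDS", seq_len(k))
  scores <- dplyr::bind_cols(
    tibble::tibble(sample_id = labels(dm) %||% as.character(seq_len(n))),
    scores)
  structure(list(scores = scores, stress = fit$stress,
                 converged = fit$icause != 1L,
                 restarts = restarts, k = k),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("<nmds_result> k = %d, stress = %.4f\n", x$k, x$stress))
  invisible(x)
}

#' @export
tidy.nmds_result <- function(x, ...) x$scores

#' @export
glance.nmds_result <- function(x, ...) {
  tibble::tibble(stress = x$stress, k = x$k, converged = x$converged)
}

#' Plot NMDS sample scores
#' @param object An [nmds()] result.
#' @param colour Optional vector (e.g. habitat) to colour points by.
#' @param ... Unused.
#' @export
autoplot.nmds_result <- function(object, colour = NULL, ...) {
  df <- object$scores
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2)) +
    ggplot2::labs(caption = sprintf("stress = %.3f", object$stress)) +
    ggplot2::theme_minimal()
  if (is.null(colour)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour)) +
    ggplot2::labs(colour = NULL)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based comparison of between-group versus within-group community
#' dissimilarities: R = (mean between-group rank - mean within-group rank)
#' / (M / 4), M = n (n - 1) / 2. R near 1 means complete separation, near 0
#' none. Significance by permutation of group labels — exhaustive over all
#' distinct relabelings when feasible, otherwise `n_perm` random
#' permutations, add-one convention in both cases.
#'
#' @param dm A `dist` over the samples.
#' @param grouping Factor of group labels (each group >= 2 members).
#' @param n_perm Random permutations when enumeration is infeasible.
#' @param seed Integer seed.
#' @param exhaustive_limit Enumerate when distinct relabelings <= this.
#' @return An `anosim_result`: list with `R`, `p_value`, `n_perm`,
#'   `exhaustive`, `grouping_label`.
#' @export
anosim <- function(dm, grouping, n_perm = 999, seed = 1,
                   exhaustive_limit = 10000) {
  grouping <- droplevels(as.factor(grouping))
  if (any(table(grouping) < 2L)) {
    stop("every group needs >= 2 members", call. = FALSE)
  }
  stopifnot(attr(dm, "Size") == length(grouping))
  obs <- anosim_R(dm, grouping)
  perms <- permutation_set(as.character(grouping), n_perm, seed,
                           exhaustive_limit)
  stats_perm <- vapply(seq_len(nrow(perms$idx)), function(k) {
    anosim_R(dm, grouping[perms$idx[k, ]])
  }, numeric(1))
  p <- (sum(stats_perm >= obs - 1e-12) + 1) / (nrow(perms$idx) + 1)
  structure(list(R = obs, p_value = p, n_perm = nrow(perms$idx),
                 exhaustive = perms$exhaustive),
            class = "anosim_result")
}

# the ANOSIM R statistic from dissimilarity ranks (mid-ranks for ties)
anosim_R <- function(dm, grouping) {
  m <- as.matrix(dm)
  n <- nrow(m)
  lt <- lower.tri(m)
  r <- rank(m[lt])
  same <- outer(grouping, grouping, "==")[lt]
  (mean(r[!same]) - mean(r[same])) / (n * (n - 1) / 4)
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("<anosim> R = %.4f, p = %.4g (%s, %d permutations)\n",
              x$R, x$p_value,
              if (x$exhaustive) "exhaustive" else "random", x$n_perm))
  invisible(x)
}

#' @export
glance.anosim_result <- function(x, ...) {
  tibble::tibble(R = x$R, p_value = x$p_value, n_perm = x$n_perm,
                 exhaustive = x$exhaustive)
}

#' Mantel-style Spearman correlation between two distance matrices
#'
#' Spearman rank correlation over corresponding lower-triangle entries,
#' with significance by simultaneous row/column permutation of the second
#' matrix (exhaustive over all permutations when feasible).
#'
#' @param dm1,dm2 `dist` objects over the same items in the same order
#'   (checked by labels when both carry them).
#' @param n_perm Random permutations when enumeration is infeasible.
#' @param seed Integer seed.
#' @param exhaustive_limit Enumerate when n! <= this.
#' @return A one-row tibble: `rho`, `p_value`, `n_perm`, `exhaustive`.
#' @export
matrix_correlation <- function(dm1, dm2, n_perm = 999, seed = 1,
                               exhaustive_limit = 10000) {
  n <- attr(dm1, "Size")
  stopifnot(n == attr(dm2, "Size"))
  l1 <- labels(dm1); l2 <- labels(dm2)
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2)) {
    stop("distance matrices are over different item sets/orders",
         call. = FALSE)
  }
  m1 <- as.matrix(dm1); m2 <- as.matrix(dm2)
  lt <- lower.tri(m1)
  rho_of <- function(perm) {
    suppressWarnings(stats::cor(m1[lt], m2[perm, perm][lt],
                                method = "spearman"))
  }
  obs <- rho_of(seq_len(n))
  # permutations of items, not of a label multiset: all n! orders
  if (factorial(n) <= exhaustive_limit) {
    idx <- all_relabelings(as.character(seq_len(n)))
    exhaustive <- TRUE
  } else {
    idx <- withr::with_seed(as.integer(seed),
                            t(replicate(n_perm, sample.int(n))))
    exhaustive <- FALSE
  }
  stats_perm <- vapply(seq_len(nrow(idx)),
                       function(k) rho_of(idx[k, ]), numeric(1))
  p <- (sum(stats_perm >= obs - 1e-12) + 1) / (nrow(idx) + 1)
  tibble::tibble(rho = obs, p_value = p, n_perm = nrow(idx),
                 exhaustive = exhaustive)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
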