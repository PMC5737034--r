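#' Levins niche breadth and generalist/specialist classification
#'
#' For each OTU j passing the abundance filter, the habitat utilization
#' profile P_ij is the OTU's mean relative abundance in habitat i divided
#' by the sum of its habitat means (seasons act as replicates within a
#' habitat), and the Levins breadth is B_j = 1 / sum_i P_ij^2 — the inverse
#' Simpson concentration of the profile, ranging from 1 (all use in one
#' habitat) to the number of habitats (perfectly even use). OTUs with
#' B above `generalist_cut` are habitat generalists, below
#' `specialist_cut` specialists, otherwise neither.
#'
#' @param rel Relative-abundance matrix ([to_relative()]) or [otu_table()]
#'   of a rarefied table.
#' @param habitat Factor of habitat labels, one per sample.
#' @param min_mean_abund OTUs with overall mean relative abundance below
#'   this are marked `excluded` (default 2e-5).
#' @param generalist_cut,specialist_cut Breadth thresholds (defaults 3 and
#'   1.5 for a four-habitat design).
#' @param pooled Use pooled habitat counts instead of means of per-sample
#'   relative abundance (identical at uniform depth and balanced design).
#' @return A `niche_profile` tibble: `otu_id`, `mean_rel`, `breadth`,
#'   `niche_class` (generalist / specialist / neither / excluded) and one
#'   `P_<habitat>` column per habitat.
#' @export
niche_breadth <- function(rel, habitat, min_mean_abund = 2e-5,
                          generalist_cut = 3, specialist_cut = 1.5,
                          pooled = FALSE) {
  if (inherits(rel, "otu_table") || !is_relative(rel)) {
    rel <- to_relative(as_otu_table(rel))
  }
  m <- unclass(rel)
  habitat <- droplevels(as.factor(habitat))
  stopifnot(length(habitat) == nrow(m), nlevels(habitat) >= 2L,
            specialist_cut < generalist_cut)
  hm <- if (pooled) {
    hs <- rowsum(m, habitat)
    hs / rowSums(hs)
  } else {
    rowsum(m, habitat) / as.vector(table(habitat))
  }
  mean_rel <- colMeans(m)
  included <- mean_rel >= min_mean_abund
  hm_tot <- colSums(hm)
  if (any(included & hm_tot == 0)) {
    stop("included OTU(s) with all-zero habitat means", call. = FALSE)
  }
  P <- sweep(hm, 2L, ifelse(hm_tot > 0, hm_tot, 1), "/")
  B <- 1 / colSums(P^2)
  cls <- ifelse(!included, "excluded",
         ifelse(B > generalist_cut, "generalist",
         ifelse(B < specialist_cut, "specialist", "neither")))
  out <- tibble::tibble(
    otu_id = colnames(m), mean_rel = mean_rel,
    breadth = ifelse(included, B, NA_real_),
    niche_class = factor(cls, levels = c("generalist", "specialist",
                                         "neither", "excluded")))
  Ptab <- tibble::as_tibble(t(P))
  names(Ptab) <- paste0("P_", levels(habitat))
  Ptab[!included, ] <- NA_real_
  out <- dplyr::bind_cols(out, Ptab)
  class(out) <- c("niche_profile", class(out))
  attr(out, "thresholds") <- list(min_mean_abund = min_mean_abund,
                                  generalist_cut = generalist_cut,
                                  specialist_cut = specialist_cut)
  out
}

#' Indicator species analysis (IndVal, Dufrene-Legendre)
#'
#' For OTU j and group i, specificity A_ij is the OTU's mean relative
#' abundance in group i divided by the sum of its group means (unweighted
#' group means, the original formulation) and fidelity B_ij is the fraction
#' of group-i samples where the OTU occurs. IndVal_j = max_i A_ij * B_ij;
#' the best group is the argmax (ties broken towards the first group level
#' and flagged). Significance is by permutation of the sample-group labels:
#' exhaustive over all distinct relabelings when there are at most
#' `exhaustive_limit` of them, otherwise `n_perm` random permutations, with
#' the add-one convention p = (b + 1) / (m + 1) counting the observed
#' labeling among the b.
#'
#' Strict habitat specialists are OTUs with p < `alpha` and both A and B at
#' the best group >= `min_component`.
#'
#' @param x A rarefied [otu_table()] (relative abundances are computed
#'   internally; A uses group means of relative abundance, so uniform depth
#'   is required and asserted).
#' @param grouping Factor of group (habitat) labels per sample.
#' @param n_perm Random permutations when enumeration is infeasible.
#' @param seed Integer seed for the permutations.
#' @param alpha Significance threshold for the strict flag.
#' @param min_component Minimum specificity and fidelity for the strict
#'   flag (default 0.8).
#' @param abundance_filter Drop OTUs with overall mean relative abundance
#'   below this before testing (default 2e-5, matching the niche-breadth
#'   screen).
#' @param exhaustive_limit Enumerate all distinct relabelings when their
#'   number is at most this (default 10,000).
#' @return An `indval_result` tibble: `otu_id`, `best_group`,
#'   `specificity`, `fidelity`, `indval`, `p_value`, `strict_specialist`,
#'   `tie`. Attributes: `n_perm_used`, `exhaustive`.
#' @export
indval <- function(x, grouping, n_perm = 999, seed = 1, alpha = 0.05,
                   min_component = 0.8, abundance_filter = 2e-5,
                   exhaustive_limit = 10000) {
  x <- as_otu_table(x)
  if (!isTRUE(attr(x, "rarefied"))) {
    stop("indval requires a rarefied table (uniform depth); rarefy first",
         call. = FALSE)
  }
  stopifnot(n_perm >= 1)
  grouping <- droplevels(as.factor(grouping))
  stopifnot(length(grouping) == nrow(x), nlevels(grouping) >= 2L)
  if (any(table(grouping) == 0L)) stop("empty group", call. = FALSE)
  rel <- unclass(to_relative(x))
  keep <- colMeans(rel) >= abundance_filter
  rel <- rel[, keep, drop = FALSE]
  if (!ncol(rel)) stop("no OTU passes the abundance filter", call. = FALSE)

  obs <- indval_stat(rel, grouping)
  perms <- permutation_set(as.character(grouping), n_perm, seed,
                           exhaustive_limit)
  exceed <- integer(ncol(rel))
  for (k in seq_len(nrow(perms$idx))) {
    stat_k <- indval_stat(rel, grouping[perms$idx[k, ]])$indval
    exceed <- exceed + (stat_k >= obs$indval - 1e-12)
  }
  p <- (exceed + 1) / (nrow(perms$idx) + 1)
  strict <- p < alpha & obs$A_best >= min_component &
    obs$B_best >= min_component
  out <- tibble::tibble(
    otu_id = colnames(rel),
    best_group = factor(levels(grouping)[obs$best], levels(grouping)),
    specificity = obs$A_best, fidelity = obs$B_best, indval = obs$indval,
    p_value = p, strict_specialist = strict, tie = obs$tie)
  class(out) <- c("indval_result", class(out))
  attr(out, "n_perm_used") <- nrow(perms$idx)
  attr(out, "exhaustive") <- perms$exhaustive
  attr(out, "settings") <- list(alpha = alpha,
                                min_component = min_component,
                                abundance_filter = abundance_filter)
  out
}

# A (group-mean concentration), B (occurrence), IndVal and argmax per OTU;
# rel is samples x OTUs, vectorized over OTUs
indval_stat <- function(rel, grouping) {
  gm <- rowsum(rel, grouping) / as.vector(table(grouping))
  tot <- colSums(gm)
  A <- sweep(gm, 2L, ifelse(tot > 0, tot, 1), "/")
  occ <- rowsum((rel > 0) + 0, grouping) / as.vector(table(grouping))
  iv <- A * occ
  best <- apply(iv, 2L, which.max)
  n_max <- colSums(abs(sweep(iv, 2L, apply(iv, 2L, max), "-")) < 1e-12)
  j <- seq_len(ncol(rel))
  list(best = best,
       A_best = A[cbind(best, j)],
       B_best = occ[cbind(best, j)],
       indval = iv[cbind(best, j)],
       tie = n_max > 1L)
}

#' Count strict habitat specialists per group
#'
#' @param result An [indval()] result (or any tibble with `best_group` and
#'   `strict_specialist` columns).
#' @return A tibble of per-group strict-specialist counts plus a `total`
#'   row.
#' @export
strict_specialist_counts <- function(result) {
  sel <- result[result$strict_specialist, , drop = FALSE]
  counts <- table(sel$best_group)
  tibble::tibble(group = c(names(counts), "total"),
                 n_strict = c(as.integer(counts), sum(counts)))
}

#' @export
glance.indval_result <- function(x, ...) {
  tibble::tibble(n_otus_tested = nrow(x),
                 n_strict = sum(x$strict_specialist),
                 n_perm = attr(x, "n_perm_used"),
                 exhaustive = attr(x, "exhaustive"))
}

# ---- permutation machinery shared by indval / anosim / mantel ------------

# number of distinct arrangements of a label multiset
n_distinct_relabelings <- function(labels) {
  tab <- table(labels)
  exp(lgamma(length(labels) + 1) - sum(lgamma(tab + 1)))
}

# all distinct arrangements of `labels` as index permutations into the
# original vector (identity row first); recursion over multiset positions
all_relabelings <- function(labels) {
  n <- length(labels)
  uniq <- unique(labels)
  pos <- lapply(uniq, function(u) which(labels == u))
  out <- list()
  rec <- function(remaining_counts, slots, acc) {
    if (!length(slots)) {
      out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    for (u in seq_along(uniq)) {
      if (remaining_counts[u] > 0L) {
        rc <- remaining_counts
        rc[u] <- rc[u] - 1L
        acc2 <- acc
        # place label uniq[u] at position slots[1]: record which source
        # index supplies it (first unused index of that label)
        acc2[slots[1L]] <- u
        rec(rc, slots[-1L], acc2)
      }
    }
  }
  rec(vapply(pos, length, integer(1)), seq_len(n), integer(n))
  # convert label-assignment vectors to index permutations: for each
  # arrangement, map slot -> an index of the original vector carrying that
  # label (consumed in order)
  idx <- t(vapply(out, function(assign) {
    used <- integer(length(uniq))
    vapply(assign, function(u) {
      used[u] <<- used[u] + 1L
      pos[[u]][used[u]]
    }, integer(1))
  }, integer(n)))
  idx
}

# permutation index matrix: exhaustive (all distinct relabelings, identity
# included) when feasible, otherwise n_perm random permutations under seed
permutation_set <- function(labels, n_perm, seed, exhaustive_limit = 10000) {
  n <- length(labels)
  m <- n_distinct_relabelings(labels)
  if (m <= exhaustive_limit) {
    list(idx = all_relabelings(labels), exhaustive = TRUE)
  } else {
    idx <- withr::with_seed(as.integer(seed), {
      t(replicate(n_perm, sample.int(n)))
    })
    list(idx = idx, exhaustive = FALSE)
  }
}
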