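#' Construct an OTU count table
#'
#' An `otu_table` is an integer matrix of sequence counts with samples as
#' rows and OTUs as columns. It is the object every downstream stage
#' consumes: rarefaction, rarity partitioning, diversity, ordination and
#' neutral-model fitting all start from one.
#'
#' @param counts A numeric matrix or data frame of non-negative counts,
#'   samples in rows and OTUs in columns. Dimnames are required (or supplied
#'   via `sample_ids` / `otu_ids`). Values within `1e-6` of an integer are
#'   rounded; anything else is rejected.
#' @param sample_ids,otu_ids Optional character vectors overriding the
#'   dimnames of `counts`.
#'
#' @return An `otu_table`: an integer matrix with class `"otu_table"` and a
#'   logical attribute `rarefied` that is `TRUE` iff all row sums are equal.
#' @export
#' @examples
#' otu_table(matrix(c(5, 3, 5, 7), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("otu1", "otu2"))))
otu_table <- function(counts, sample_ids = NULL, otu_ids = NULL) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix or data frame", call. = FALSE)
  }
  if (!is.null(sample_ids)) rownames(counts) <- sample_ids
  if (!is.null(otu_ids)) colnames(counts) <- otu_ids
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry sample (row) and OTU (column) identifiers",
         call. = FALSE)
  }
  if (nrow(counts) < 1L || ncol(counts) < 1L) {
    stop("an otu_table needs at least one sample and one OTU", call. = FALSE)
  }
  dup_s <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_s)) {
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  }
  dup_o <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_o)) {
    stop("duplicate OTU id(s): ", paste(dup_o, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(counts)) stop("counts contain missing values", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  off <- abs(counts - round(counts)) > 1e-6
  if (any(off)) {
    idx <- which(off, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count at sample '%s', OTU '%s'",
                 rownames(counts)[idx[1L]], colnames(counts)[idx[2L]]),
         call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  structure(counts,
            rarefied = length(unique(rowSums(counts))) == 1L,
            class = c("otu_table", class(matrix())))
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d samples x %d OTUs, %s reads%s\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ","),
              if (isTRUE(attr(x, "rarefied")))
                sprintf(" (rarefied, depth %s)",
                        format(rowSums(x)[1L], big.mark = ",")) else ""))
  invisible(x)
}

as_otu_table <- function(x) {
  if (inherits(x, "otu_table")) x else otu_table(x)
}

#' Tidy an OTU table into long form
#'
#' @param x An [otu_table()].
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `otu_id`, `count`.
#' @export
tidy.otu_table <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(rownames(x), times = ncol(x)),
    otu_id = rep(colnames(x), each = nrow(x)),
    count = as.integer(x)
  )
}

#' Rarefy an OTU table to uniform depth
#'
#' Randomly subsamples each sample's reads without replacement (multivariate
#' hypergeometric) down to a common depth, the standard normalization before
#' comparing communities sequenced to different effort. OTUs that drop to
#' zero in every sample are retained so that table dimensions are stable;
#' use [drop_empty_otus()] to remove them.
#'
#' @param x An [otu_table()] (or coercible matrix).
#' @param depth Target reads per sample; every sample must have at least
#'   this many reads.
#' @param seed Integer seed; mandatory so that runs are reproducible.
#' @return A rarefied `otu_table` with all row sums equal to `depth`.
#' @export
rarefy_table <- function(x, depth, seed) {
  x <- as_otu_table(x)
  if (missing(seed)) stop("`seed` is required for rarefaction", call. = FALSE)
  depth <- as.integer(depth)
  tot <- rowSums(x)
  short <- rownames(x)[tot < depth]
  if (length(short)) {
    stop("sample(s) below rarefaction depth ", depth, ": ",
         paste(short, collapse = ", "), call. = FALSE)
  }
  out <- withr::with_seed(as.integer(seed), {
    # rrarefy's "smallest count" heuristic misfires on legitimate count
    # tables without singletons; silence that warning only
    withCallingHandlers(
      vegan::rrarefy(unclass(x), depth),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  })
  otu_table(out)
}

#' Drop OTUs absent from every sample
#' @param x An [otu_table()].
#' @return An `otu_table` without all-zero OTU columns.
#' @export
drop_empty_otus <- function(x) {
  x <- as_otu_table(x)
  keep <- colSums(x) > 0L
  if (!any(keep)) stop("all OTUs are empty", call. = FALSE)
  otu_table(unclass(x)[, keep, drop = FALSE])
}

#' Convert counts to relative abundances
#'
#' @param x An [otu_table()].
#' @return A numeric matrix (class `rel_abundance`) with the same axes where
#'   each row sums to 1.
#' @export
to_relative <- function(x) {
  x <- as_otu_table(x)
  tot <- rowSums(x)
  bad <- rownames(x)[tot == 0]
  if (length(bad)) {
    stop("sample(s) with zero total reads: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rel <- unclass(x) / tot
  structure(rel, class = c("rel_abundance", class(matrix())))
}

is_relative <- function(x) {
  inherits(x, "rel_abundance") ||
    (is.matrix(x) && all(abs(rowSums(x) - 1) < 1e-9) && all(x <= 1))
}

as_relative <- function(x) {
  if (is_relative(x)) {
    structure(unclass(x), class = c("rel_abundance", class(matrix())))
  } else {
    to_relative(x)
  }
}

#' Aggregate an OTU table at a taxonomic rank
#'
#' Sums counts of OTUs that share the same lineage down to `rank`. Lineages
#' unresolved at `rank` are grouped by their deepest resolved prefix, so
#' "unclassified" taxa from different phyla are never merged. Per-sample
#' totals are conserved exactly at every rank.
#'
#' @param x An [otu_table()].
#' @param taxonomy A taxonomy tibble as returned by [read_taxonomy()] or
#'   [simulate_metacommunity()]: `otu_id` plus rank columns
#'   `kingdom` ... `species`. OTUs missing from it get an all-unclassified
#'   lineage.
#' @param rank One of `"otu"`, `"genus"`, `"family"`, `"order"`, `"class"`,
#'   `"phylum"`. `"otu"` (the finest unit, standing in for species) returns
#'   the input unchanged.
#' @return An `otu_table` whose columns are taxa at the requested rank.
#' @export
aggregate_by_rank <- function(x, taxonomy, rank) {
  x <- as_otu_table(x)
  rank <- match.arg(rank, c("otu", "genus", "family", "order", "class",
                            "phylum"))
  if (rank == "otu") return(x)
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")
  depth_idx <- match(rank, ranks)
  lin <- taxonomy[match(colnames(x), taxonomy$otu_id), ranks, drop = FALSE]
  lin[is.na(lin)] <- "unclassified"
  for (r in ranks) {
    if (!r %in% names(lin)) lin[[r]] <- "unclassified"
    lin[[r]][is.na(lin[[r]]) | lin[[r]] == ""] <- "unclassified"
  }
  # group key: lineage down to `rank`, truncated at the first unresolved
  # level so unclassified taxa stay inside their deepest resolved clade
  keys <- vapply(seq_len(ncol(x)), function(j) {
    parts <- unlist(lin[j, seq_len(depth_idx)], use.names = FALSE)
    unres <- which(parts == "unclassified")
    if (length(unres)) {
      keep <- seq_len(unres[1L] - 1L)
      if (!length(keep)) return("unclassified")
      paste0(paste(parts[keep], collapse = ";"), ";unclassified")
    } else {
      paste(parts, collapse = ";")
    }
  }, character(1))
  agg <- rowsum(t(unclass(x)), group = keys)
  otu_table(t(agg))
}
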