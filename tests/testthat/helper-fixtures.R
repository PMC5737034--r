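# small deterministic fixtures shared across test files

tiny_table <- function() {
  otu_table(matrix(c(5, 3, 5, 7), 2, 2,
                   dimnames = list(c("s1", "s2"), c("otu1", "otu2"))))
}

# 8 samples (2 per habitat x 4 habitats) at uniform depth 100, with one
# perfect indicator OTU per habitat plus shared background OTUs
indicator_table <- function() {
  habitats <- rep(c("A", "B", "C", "D"), each = 2L)
  n <- length(habitats)
  counts <- matrix(0L, n, 8L)
  # OTUs 1-4: perfect indicators of habitats A-D
  for (h in 1:4) counts[habitats == LETTERS[h], h] <- 20L
  # OTUs 5-8: even background everywhere
  counts[, 5:8] <- 20L
  rownames(counts) <- paste0("s", seq_len(n))
  colnames(counts) <- paste0("otu", 1:8)
  list(otu = otu_table(counts), habitat = factor(habitats))
}

# metadata frame for a sample id vector with habitat/season/coords/env
make_meta <- function(sample_ids, habitat, season = NULL) {
  n <- length(sample_ids)
  tibble::tibble(
    sample_id = sample_ids,
    habitat = factor(habitat),
    season = factor(season %||% rep("spring", n)),
    latitude = 24.4 + seq_len(n) * 0.01,
    longitude = 117.9 + seq_len(n) * 0.01,
    pH = 7 + as.integer(factor(habitat)) * 0.2,
    TC = 10 + as.integer(factor(habitat)) * 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic random nested taxonomy for an arbitrary OTU id set
simulate_taxonomy_for <- function(otu_ids) {
  withr::with_seed(1L, rarebiome:::simulate_taxonomy(otu_ids))
}

# brute-force ANOSIM R: mean rank difference over M/4, straight from the
# definition, independent of the package implementation
brute_anosim_R <- function(dm, grouping) {
  m <- as.matrix(dm)
  lt <- lower.tri(m)
  r <- rank(m[lt])
  within <- outer(grouping, grouping, "==")[lt]
  (mean(r[!within]) - mean(r[within])) / (nrow(m) * (nrow(m) - 1) / 4)
}

# all distinct arrangements of a label vector (plain recursion; test-side
# oracle, independent of the package's enumeration)
brute_label_arrangements <- function(labels) {
  if (length(labels) <= 1L) return(matrix(labels, nrow = 1L))
  out <- NULL
  for (u in unique(labels)) {
    rest <- labels[-match(u, labels)]
    sub <- brute_label_arrangements(rest)
    out <- rbind(out, cbind(u, sub, deparse.level = 0))
  }
  unique(out)
}
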