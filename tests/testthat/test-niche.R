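test_that("Levins breadth hits its closed forms and thresholds", {
  # 4 habitats, 1 sample each; rows sum to 1 via a filler OTU
  build <- function(profiles) {
    filler <- 1 - rowSums(profiles)
    m <- cbind(profiles, filler = filler)
    rownames(m) <- paste0("s", 1:4)
    structure(m, class = c("rel_abundance", "matrix", "array"))
  }
  rel <- build(cbind(even = rep(0.04, 4),
                     single = c(0.04, 0, 0, 0),
                     two = c(0.04, 0.04, 0, 0)))
  hab <- factor(paste0("h", 1:4))
  nb <- niche_breadth(rel, hab)
  b <- setNames(nb$breadth, nb$otu_id)
  cls <- setNames(as.character(nb$niche_class), nb$otu_id)
  expect_equal(unname(b["even"]), 4)
  expect_equal(unname(cls["even"]), "generalist") # B > 3
  expect_equal(unname(b["single"]), 1)
  expect_equal(unname(cls["single"]), "specialist") # B < 1.5
  expect_equal(unname(b["two"]), 2)
  expect_equal(unname(cls["two"]), "neither")
  # P rows sum to 1 for included OTUs
  P <- as.matrix(nb[, paste0("P_", levels(hab))])
  expect_equal(unname(rowSums(P[!is.na(P[, 1]), ])), rep(1, 4))
})

test_that("breadth extremes occur iff the profile is uniform or singular", {
  set.seed(11)
  for (i in 1:25) {
    P <- stats::runif(4)
    P <- P / sum(P)
    B <- 1 / sum(P^2)
    expect_gte(B, 1)
    expect_lte(B, 4 + 1e-12)
    if (max(P) < 1) expect_gt(B, 1)
    if (stats::sd(P) > 1e-9) expect_lt(B, 4)
  }
})

test_that("the abundance filter excludes scarce OTUs from classification", {
  sim <- simulate_metacommunity(
    metacommunity_design(n_otus = 300, depth = 1000), seed = 17)
  nb <- niche_breadth(sim$otu, sim$metadata$habitat, min_mean_abund = 2e-5)
  scarce <- colMeans(unclass(to_relative(sim$otu))) < 2e-5
  expect_true(all(nb$niche_class[scarce] == "excluded"))
  expect_true(all(is.na(nb$breadth[scarce])))
  expect_false(any(nb$niche_class[!scarce] == "excluded"))
})

test_that("IndVal components reach their textbook values", {
  fix <- indicator_table()
  res <- indval(fix$otu, fix$habitat, n_perm = 99, seed = 1,
                abundance_filter = 0)
  stats_ <- res[match(paste0("otu", 1:8), res$otu_id), ]
  # perfect indicators: A = 1, B = 1, IndVal = 1, best group = home
  expect_equal(stats_$specificity[1:4], rep(1, 4))
  expect_equal(stats_$fidelity[1:4], rep(1, 4))
  expect_equal(stats_$indval[1:4], rep(1, 4))
  expect_equal(as.character(stats_$best_group[1:4]), c("A", "B", "C", "D"))
  # ubiquitous even OTUs: A = 1/4, B = 1, IndVal = 1/4
  expect_equal(stats_$specificity[5:8], rep(0.25, 4))
  expect_equal(stats_$indval[5:8], rep(0.25, 4))
  expect_true(all(stats_$tie[5:8]))
})

test_that("exhaustive permutation p matches full enumeration", {
  # 4 samples in 2+2 groups; a perfect indicator of group a
  counts <- matrix(c(10L, 10L, 0L, 0L,
                     5L, 5L, 15L, 15L), 4, 2,
                   dimnames = list(paste0("s", 1:4), c("ind", "bg")))
  tab <- otu_table(counts)
  grp <- factor(c("a", "a", "b", "b"))
  res <- indval(tab, grp, n_perm = 999, seed = 1, abundance_filter = 0)
  expect_true(attr(res, "exhaustive"))
  expect_equal(attr(res, "n_perm_used"), 6L) # C(4,2) labelings

  # test-side oracle: recompute IndVal for every labeling by definition
  rel <- unclass(to_relative(tab))
  iv_of <- function(g) {
    g <- factor(g)
    gm <- rowsum(rel, g) / as.vector(table(g))
    A <- sweep(gm, 2, colSums(gm), "/")
    B <- rowsum((rel > 0) + 0, g) / as.vector(table(g))
    apply(A * B, 2, max)
  }
  labelings <- brute_label_arrangements(c("a", "a", "b", "b"))
  expect_equal(nrow(labelings), 6L)
  obs <- iv_of(c("a", "a", "b", "b"))
  per_otu_p <- vapply(seq_len(ncol(rel)), function(j) {
    stats_j <- apply(labelings, 1, function(g) iv_of(g)[j])
    (sum(stats_j >= obs[j] - 1e-12) + 1) / (nrow(labelings) + 1)
  }, numeric(1))
  expect_equal(res$p_value, unname(per_otu_p))
  # smallest attainable p here is 3/7: IndVal maximizes over groups, so
  # the complementary labeling (bbaa) ties the observed maximum and both
  # count into b of (b + 1) / (m + 1)
  expect_equal(res$p_value[res$otu_id == "ind"], 3 / 7)
})

test_that("permutation p is bit-reproducible under a fixed seed", {
  sim <- simulate_metacommunity(
    metacommunity_design(n_otus = 150, depth = 800), seed = 23)
  r1 <- indval(sim$otu, sim$metadata$habitat, n_perm = 49, seed = 7)
  r2 <- indval(sim$otu, sim$metadata$habitat, n_perm = 49, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("planted specialists are assigned to their home habitat", {
  # recovery across seeds: best group must equal the planted home habitat
  # for at least 90% of the specialists abundant enough to be tested
  for (s in 1:5) {
    sim <- simulate_metacommunity(
      metacommunity_design(n_otus = 2000, depth = 10000,
                           specialist_effect = 10), seed = 300 + s)
    res <- indval(sim$otu, sim$metadata$habitat, n_perm = 49, seed = s)
    tr <- sim$truth$otus
    merged <- merge(res, tr[tr$specialist, ], by = "otu_id")
    rate <- mean(as.character(merged$best_group) == merged$home_habitat)
    expect_gte(rate, 0.9)
  }
})

test_that("strict-specialist accounting sums per-zone counts", {
  fix <- indicator_table()
  res <- indval(fix$otu, fix$habitat, n_perm = 99, seed = 1,
                abundance_filter = 0)
  counts <- strict_specialist_counts(res)
  expect_equal(counts$n_strict[counts$group == "total"],
               sum(counts$n_strict[counts$group != "total"]))
})
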