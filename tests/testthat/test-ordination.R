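test_that("NMDS recovers perfectly embeddable configurations", {
  set.seed(3)
  pts <- matrix(rnorm(12), 6, 2)
  rownames(pts) <- paste0("s", 1:6)
  dm <- dist(pts)
  fit <- nmds(dm, k = 2, restarts = 10, seed = 1)
  expect_lt(fit$stress, 0.01)
  expect_equal(fit$scores$sample_id, paste0("s", 1:6))
  expect_true(fit$stress >= 0 && fit$stress <= 1)
})

test_that("ANOSIM attains its limiting values", {
  # all between-group dissimilarities exceed all within-group: R = 1
  m <- matrix(5, 6, 6)
  m[1:3, 1:3] <- 1
  m[4:6, 4:6] <- 1
  diag(m) <- 0
  dimnames(m) <- list(paste0("s", 1:6), paste0("s", 1:6))
  grp <- factor(rep(c("a", "b"), each = 3))
  res <- anosim(as.dist(m), grp, seed = 1)
  expect_equal(res$R, 1)
  expect_true(res$exhaustive)

  # all dissimilarities equal: R = 0
  flat <- matrix(1, 6, 6)
  diag(flat) <- 0
  res0 <- anosim(as.dist(flat), grp, seed = 1)
  expect_equal(res0$R, 0)

  expect_error(anosim(as.dist(m), factor(c("a", rep("b", 5)))), ">= 2")
})

test_that("ANOSIM R and exhaustive p match brute-force enumeration", {
  set.seed(9)
  m <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
  dimnames(m) <- list(paste0("s", 1:4), paste0("s", 1:4))
  dm <- as.dist(m)
  grp <- factor(c("a", "a", "b", "b"))
  res <- anosim(dm, grp, seed = 1)
  expect_true(res$exhaustive)
  expect_equal(res$R, brute_anosim_R(dm, grp), tolerance = 1e-12)

  labelings <- brute_label_arrangements(c("a", "a", "b", "b"))
  stats_ <- apply(labelings, 1, function(g) brute_anosim_R(dm, factor(g)))
  p_oracle <- (sum(stats_ >= res$R - 1e-12) + 1) / (nrow(labelings) + 1)
  expect_equal(res$p_value, p_oracle)

  # cross-check the statistic against vegan on a larger instance
  sim <- simulate_metacommunity(
    metacommunity_design(n_otus = 150, depth = 500), seed = 19)
  bc <- bray_curtis(sim$otu)
  mine <- anosim(bc, sim$metadata$habitat, n_perm = 99, seed = 2)
  veg <- vegan::anosim(bc, sim$metadata$habitat, permutations = 99)
  expect_equal(mine$R, unname(veg$statistic), tolerance = 1e-12)

  # R is invariant under monotone transforms of the dissimilarities
  mono <- anosim(sqrt(bc), sim$metadata$habitat, n_perm = 9, seed = 2)
  expect_equal(mono$R, mine$R, tolerance = 1e-12)
})

test_that("Mantel-Spearman correlation matches limits and enumeration", {
  set.seed(4)
  m <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
  dimnames(m) <- list(paste0("s", 1:4), paste0("s", 1:4))
  dm <- as.dist(m)
  self <- matrix_correlation(dm, dm, seed = 1)
  expect_equal(self$rho, 1)
  expect_true(self$exhaustive)

  rev <- as.dist(max(m) + 1 - m)
  expect_equal(matrix_correlation(dm, rev, seed = 1)$rho, -1)

  # exhaustive p against an all-permutations oracle
  perms <- brute_label_arrangements(as.character(1:4))
  lt <- lower.tri(m)
  rho_of <- function(perm) {
    perm <- as.integer(perm)
    suppressWarnings(cor(m[lt], m[perm, perm][lt], method = "spearman"))
  }
  stats_ <- apply(perms, 1, rho_of)
  p_oracle <- (sum(stats_ >= self$rho - 1e-12) + 1) / (nrow(perms) + 1)
  expect_equal(self$p_value, p_oracle)
  expect_equal(self$n_perm, 24L)

  # mismatched labels rejected
  m2 <- m
  dimnames(m2) <- list(paste0("x", 1:4), paste0("x", 1:4))
  expect_error(matrix_correlation(dm, as.dist(m2)), "different item")
})

test_that("RDA explained variance equals a least-squares oracle", {
  set.seed(5)
  n <- 12
  meta <- tibble::tibble(sample_id = paste0("s", 1:n),
                         pH = runif(n, 6, 8),
                         TC = runif(n, 5, 20))
  X <- rarebiome:::prepare_predictors(meta, c("pH", "TC"))
  Y <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(meta$sample_id, paste0("v", 1:5)))
  Y[, 1] <- Y[, 1] + 2 * X$pH
  res <- rda_analysis(Y, meta, c("pH", "TC"), n_perm = 99, seed = 1,
                      forward_select = FALSE)
  # oracle: summed regression SS over response columns / total SS
  Yc <- scale(Y, scale = FALSE)
  H <- as.matrix(X) %*% solve(crossprod(as.matrix(X)), t(as.matrix(X)))
  fitted <- H %*% Yc
  expect_equal(res$explained, sum(fitted^2) / sum(Yc^2), tolerance = 1e-10)

  # a single response equal to a single predictor is fully explained
  Y1 <- matrix(X$pH, n, 1, dimnames = list(meta$sample_id, "v"))
  r1 <- rda_analysis(Y1, meta, "pH", n_perm = 19, seed = 1,
                     forward_select = FALSE)
  expect_equal(r1$explained, 1, tolerance = 1e-10)
})

test_that("duplicated predictors are removed by the VIF screen", {
  set.seed(6)
  n <- 12
  meta <- tibble::tibble(sample_id = paste0("s", 1:n),
                         pH = runif(n, 6, 8))
  meta$pH2 <- meta$pH # exact duplicate -> aliased, infinite VIF
  Y <- matrix(rnorm(n * 4), n, 4, dimnames = list(meta$sample_id, NULL))
  res <- rda_analysis(Y, meta, c("pH", "pH2"), n_perm = 19, seed = 1,
                      forward_select = FALSE)
  expect_equal(nrow(res$dropped_vif), 1L)
  expect_equal(length(res$selected), 1L)
})

test_that("an orthogonal predictor explains ~nothing with uniform p", {
  # type-I behaviour: response independent of the predictor
  set.seed(8)
  n <- 12
  pvals <- replicate(100, {
    meta <- tibble::tibble(sample_id = paste0("s", 1:n),
                           TC = runif(n, 5, 20))
    Y <- matrix(rnorm(n * 4), n, 4, dimnames = list(meta$sample_id, NULL))
    r <- rda_analysis(Y, meta, "TC", n_perm = 49, seed = sample.int(1e6, 1),
                      forward_select = FALSE)
    r$p_value
  })
  # rejection rate at alpha = 0.1 within its binomial 95% band
  rej <- sum(pvals <= 0.1)
  expect_gte(rej, qbinom(0.025, 100, 0.1))
  expect_lte(rej, qbinom(0.975, 100, 0.1))
})

test_that("VPA fractions obey inclusion-exclusion exactly", {
  sim <- simulate_metacommunity(
    metacommunity_design(n_otus = 300, depth = 900), seed = 25)
  v <- vpa(sim$otu, sim$metadata, block_E = c("pH", "TC"),
           block_V = "habitat", block_S = "season")
  full <- v$unions$adj_r2[v$unions$union == "E+V+S"]
  parts <- v$fractions$adj_r2[v$fractions$fraction != "residual"]
  expect_equal(sum(parts), full, tolerance = 1e-10)
  expect_equal(v$fractions$adj_r2[v$fractions$fraction == "residual"],
               1 - full, tolerance = 1e-10)
})

test_that("orthogonal blocks yield pure fractions and no sharing", {
  # three mutually orthogonal balanced two-level predictors, each driving
  # its own response columns; n large enough that the small-sample
  # adjustment of R-squared (which is not exactly additive across unions)
  # stays negligible
  set.seed(10)
  n <- 48
  xE <- rep(c(10, 20), n / 2)
  xV <- rep(c(10, 10, 20, 20), n / 4)
  xS <- rep(c(rep(10, 4), rep(20, 4)), n / 8)
  meta <- tibble::tibble(sample_id = paste0("s", 1:n),
                         TC = xE, TN = xV, TS = xS)
  Y <- cbind(scale(xE)[, 1] + rnorm(n, 0, 0.5),
             scale(xV)[, 1] + rnorm(n, 0, 0.5),
             scale(xS)[, 1] + rnorm(n, 0, 0.5))
  dimnames(Y) <- list(meta$sample_id, paste0("v", 1:3))
  v <- vpa(Y, meta, block_E = "TC", block_V = "TN", block_S = "TS")
  fr <- setNames(v$fractions$adj_r2, v$fractions$fraction)
  shared <- fr[c("shared_EV", "shared_VS", "shared_ES", "shared_EVS")]
  expect_true(all(abs(shared) < 0.05))
  un <- setNames(v$unions$adj_r2, v$unions$union)
  expect_lt(abs(fr[["pure_E"]] - un[["E"]]), 0.05)
  expect_lt(abs(fr[["pure_V"]] - un[["V"]]), 0.05)
  expect_lt(abs(fr[["pure_S"]] - un[["S"]]), 0.05)
})

test_that("identical V and E blocks show up as wholly shared variation", {
  set.seed(12)
  n <- 48
  x <- rep(c(10, 20), n / 2)
  meta <- tibble::tibble(sample_id = paste0("s", 1:n),
                         TC = x, TN = x,
                         TS = rep(c(rep(10, 4), rep(20, 4)), n / 8))
  Y <- cbind(scale(x)[, 1] + rnorm(n, 0, 0.2),
             rnorm(n))
  dimnames(Y) <- list(meta$sample_id, c("v1", "v2"))
  # duplicated blocks are deliberately collinear; varpart warns about it
  v <- suppressWarnings(
    vpa(Y, meta, block_E = "TC", block_V = "TN", block_S = "TS"))
  fr <- setNames(v$fractions$adj_r2, v$fractions$fraction)
  un <- setNames(v$unions$adj_r2, v$unions$union)
  expect_lt(abs(fr["pure_E"]), 0.05)
  expect_lt(abs(fr["pure_V"]), 0.05)
  # everything the duplicated block explains is shared, and it carries
  # (essentially) the whole explained variation of the full model
  expect_equal(unname(fr["shared_EV"]), unname(un["E+V+S"]),
               tolerance = 0.05)
})

test_that("dbRDA equals RDA under Euclidean distance and handles ranks", {
  sim <- simulate_metacommunity(
    metacommunity_design(n_otus = 200, depth = 600), seed = 29)
  tab <- drop_empty_otus(sim$otu)
  preds <- c("pH", "TC")
  g_euc <- dbrda_by_rank(tab, sim$taxonomy, sim$metadata, preds,
                         ranks = "otu", distance = "euclidean")
  r <- rda_analysis(tab, sim$metadata, preds, n_perm = 19, seed = 1,
                    forward_select = FALSE, vif_cut = Inf)
  expect_equal(g_euc$explained, r$explained, tolerance = 1e-8)

  # rank = otu with Bray-Curtis reproduces the unaggregated analysis and
  # aggregation keeps the gradient well-defined
  g <- dbrda_by_rank(tab, sim$taxonomy, sim$metadata, preds,
                     ranks = c("otu", "genus", "phylum"))
  expect_equal(nrow(g), 3L)
  expect_true(all(g$explained >= 0 & g$explained <= 1, na.rm = TRUE))
})

test_that("a phylum-level signal strengthens toward coarse ranks", {
  # construct counts whose habitat signal exists only between phyla
  set.seed(30)
  n_otus <- 60
  otu_ids <- sprintf("o%02d", 1:n_otus)
  phyla <- rep(c("P1", "P2"), each = n_otus / 2)
  tax <- parse_lineages(otu_ids,
                        paste("Bacteria", phyla, "c", "o", "f",
                              paste0("g", 1:n_otus), otu_ids, sep = ";"))
  hab <- rep(c("A", "B"), each = 8)
  depth <- 2000
  counts <- t(vapply(seq_along(hab), function(i) {
    w <- ifelse(phyla == "P1",
                ifelse(hab[i] == "A", 3, 1),
                ifelse(hab[i] == "A", 1, 3))
    # within-phylum composition is noisy, masking the signal at OTU level
    w <- w * rlnorm(n_otus, 0, 1)
    rmultinom(1, depth, w / sum(w))[, 1]
  }, integer(n_otus)))
  dimnames(counts) <- list(paste0("s", seq_along(hab)), otu_ids)
  meta <- tibble::tibble(sample_id = rownames(counts),
                         habitat = factor(hab),
                         TC = ifelse(hab == "A", 10, 20) + rnorm(16, 0, 0.1))
  g <- dbrda_by_rank(otu_table(counts), tax, meta, "TC",
                     ranks = c("otu", "phylum"))
  expect_gt(g$explained[g$rank == "phylum"],
            g$explained[g$rank == "otu"])
})
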