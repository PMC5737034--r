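test_that("predicted detection frequency matches a quadrature oracle", {
  N <- 1000
  m <- 0.1
  d <- 1 / N
  for (p in c(1e-5, 1e-4, 1e-3, 1e-2, 0.1)) {
    oracle <- stats::integrate(function(x) {
      stats::dbeta(x, N * m * p, N * m * (1 - p))
    }, lower = d, upper = 1, rel.tol = 1e-10)$value
    expect_equal(predict_ncm_frequency(p, N, m, d), oracle,
                 tolerance = 1e-6)
  }
  # limits
  expect_equal(predict_ncm_frequency(0, N, m), 0)
  expect_equal(predict_ncm_frequency(1, N, m), 1)
  expect_lt(predict_ncm_frequency(1e-9, N, m), 1e-3)
  expect_gt(predict_ncm_frequency(0.5, N, m), 0.999)
})

test_that("predicted frequency is monotone in p and in m", {
  N <- 500
  ps <- 10^seq(-5, -0.5, length.out = 30)
  for (m in c(0.01, 0.1, 0.5, 1)) {
    f <- predict_ncm_frequency(ps, N, m)
    expect_true(all(diff(f) >= -1e-12))
  }
  # monotone in m for taxa above the detection limit (p > d); below it,
  # concentration around p pushes the frequency down instead
  for (p in c(5e-3, 1e-2, 0.1)) {
    f <- vapply(c(0.01, 0.05, 0.2, 1), function(m) {
      predict_ncm_frequency(p, N, m)
    }, numeric(1))
    expect_true(all(diff(f) >= -1e-12))
  }
})

test_that("sampling detection converges to the threshold form at depth", {
  p <- 10^seq(-4, -1, length.out = 20)
  m <- 0.1
  big_N <- 2e5
  expect_equal(predict_ncm_detection(p, big_N, m),
               predict_ncm_frequency(p, big_N, m),
               tolerance = 0.02)
  # detection exceeds the threshold frequency at modest depth for the
  # rare tail (taxa below d are still sometimes sequenced)
  rare <- 1e-4
  expect_gt(predict_ncm_detection(rare, 1000, m),
            predict_ncm_frequency(rare, 1000, m))
})

test_that("Wilson interval matches its closed form and brackets phat", {
  wi <- wilson_interval(0.5, 16)
  expect_equal(wi$lower, 0.2800, tolerance = 5e-5)
  expect_equal(wi$upper, 0.7200, tolerance = 5e-5)
  expect_equal(wilson_interval(0, 10)$lower, 0)
  expect_equal(wilson_interval(1, 10)$upper, 1)
  set.seed(2)
  ph <- runif(50)
  wi2 <- wilson_interval(ph, 16)
  expect_true(all(wi2$lower <= ph & ph <= wi2$upper))
  expect_true(all(wi2$lower >= 0 & wi2$upper <= 1))
})

test_that("a self-consistent frequency pattern refits its own m", {
  # frequencies generated exactly from the model at m = 0.1 must refit to
  # m ~ 0.1 with R^2 ~ 1; counts are constructed so that p and f match the
  # prediction closely
  N <- 1000
  m_true <- 0.1
  set.seed(13)
  p <- rlnorm(800, -9, 2)
  p <- p / sum(p) # mean rel abundances
  f <- predict_ncm_frequency(p, N, m_true)
  # synthesize a table whose columns have the given p and f: n samples,
  # occurrence in round(f*n) samples with counts placed to preserve p
  n <- 50
  occ <- pmax(1L, round(f * n))
  counts <- matrix(0L, n, length(p))
  for (j in seq_along(p)) {
    tot <- round(p[j] * N * n)
    if (tot < 1) tot <- 1
    rows <- seq_len(occ[j])
    base <- tot %/% occ[j]
    extra <- tot %% occ[j]
    counts[rows, j] <- base + c(rep(1L, extra), rep(0L, occ[j] - extra))
  }
  # pad each sample to equal depth with a house-keeping OTU
  pad <- max(rowSums(counts)) + 10L - rowSums(counts)
  counts <- cbind(counts, pad)
  dimnames(counts) <- list(sprintf("s%02d", 1:n),
                           sprintf("o%04d", seq_len(ncol(counts))))
  # the pattern was built from the threshold model, so refit with it
  fit <- fit_ncm(otu_table(counts), detection = "threshold")
  # the reconstruction quantizes f at 1/n, so recovery is approximate
  expect_equal(fit$m, m_true, tolerance = 0.35)
  expect_gt(fit$r_squared, 0.85)
})

test_that("fitted m is a global minimum over the log grid", {
  ne <- simulate_neutral(30, 800, m = 0.05,
                         regional_p = {
                           set.seed(3)
                           x <- rlnorm(400, 0, 2)
                           x / sum(x)
                         }, seed = 5)
  fit <- fit_ncm(ne$otu)
  p <- fit$otus$p
  f <- fit$otus$freq
  sse <- function(m) sum((f - predict_ncm_detection(p, fit$N, m))^2)
  best <- sse(fit$m)
  grid <- 10^seq(-6, 0, length.out = 200)
  expect_true(all(vapply(grid, sse, numeric(1)) >= best - 1e-9))
})

test_that("the fit is invariant to sample order and flags partition OTUs", {
  ne <- simulate_neutral(25, 600, m = 0.2,
                         regional_p = rep(1 / 300, 300), seed = 7)
  fit <- fit_ncm(ne$otu)
  shuffled <- otu_table(unclass(ne$otu)[sample(nrow(ne$otu)), ])
  fit2 <- fit_ncm(shuffled)
  expect_equal(fit$m, fit2$m)
  expect_equal(fit$r_squared, fit2$r_squared)
  # above/within/below partition the tested OTUs
  expect_false(anyNA(fit$otus$position))
  expect_equal(sum(table(fit$otus$position)), nrow(fit$otus))
  expect_true(all(fit$otus$lower <= fit$otus$predicted + 1e-12))
  expect_true(all(fit$otus$upper >= fit$otus$predicted - 1e-12))
})

test_that("migration rate is recovered from neutral simulations", {
  set.seed(1)
  pool <- rlnorm(2000, 0, 2)
  pool <- pool / sum(pool)
  fits <- lapply(1:10, function(s) {
    ne <- simulate_neutral(50, 1000, m = 0.1, regional_p = pool,
                          seed = 1000 + s)
    fit_ncm(ne$otu)
  })
  ms <- vapply(fits, function(f) f$m, numeric(1))
  r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
  expect_lt(abs(median(ms) - 0.1) / 0.1, 0.2)
  expect_gt(median(r2), 0.9)
})

test_that("rank-wise refits behave at the identity and on neutral data", {
  sim <- simulate_metacommunity(
    metacommunity_design(n_otus = 400, depth = 1500), seed = 33)
  tab <- drop_empty_otus(sim$otu)
  by_rank <- ncm_by_rank(tab, sim$taxonomy, ranks = c("otu", "genus"))
  base <- fit_ncm(tab)
  expect_equal(by_rank$r_squared[by_rank$rank == "otu"], base$r_squared)
  expect_equal(by_rank$m[by_rank$rank == "otu"], base$m)
  # deterministic: same input, same fit
  expect_identical(ncm_by_rank(tab, sim$taxonomy, ranks = "genus"),
                   by_rank[by_rank$rank == "genus", ])

  # neutral data stay near-neutral after aggregation
  set.seed(2)
  pool <- rlnorm(600, 0, 2)
  pool <- pool / sum(pool)
  ne <- simulate_neutral(30, 1000, m = 0.1, regional_p = pool, seed = 44)
  tax <- simulate_taxonomy_for(colnames(ne$otu))
  nr <- ncm_by_rank(ne$otu, tax, ranks = c("otu", "genus", "family"))
  expect_true(all(nr$r_squared > 0.5, na.rm = TRUE))
})
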