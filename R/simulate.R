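#' Design of a synthetic structured metacommunity
#'
#' Describes the sampling design and statistical structure the generator
#' emulates: a regional species pool with a long-tailed (lognormal)
#' abundance distribution, a fraction of habitat specialists enriched in
#' one home habitat, samples laid out as habitats crossed with seasons at
#' uniform sequencing depth, and environmental covariates that differ
#' between habitats (hence are collinear with vegetation).
#'
#' Defaults follow a 4-habitat x 4-season estuarine sediment design with
#' 10,342 reads per sample and 10,000 OTUs.
#'
#' @param n_otus Number of OTUs in the regional pool.
#' @param n_habitats Number of habitats (vegetation zones).
#' @param n_seasons Seasons per habitat (replicates).
#' @param depth Reads per sample.
#' @param sad_meanlog,sad_sdlog Lognormal species-abundance-distribution
#'   parameters of the regional pool (pre-normalization).
#' @param specialist_fraction Fraction of OTUs planted as habitat
#'   specialists.
#' @param specialist_effect Multiplicative enrichment of a specialist in its
#'   home habitat (>= 1; 1 disables the effect).
#' @param env_noise_sd Standard deviation of Gaussian noise added to the
#'   habitat-level environmental means, as a fraction of each covariate's
#'   between-habitat spread.
#' @param seed Integer seed (required at simulation time).
#' @return A `metacommunity_design` list.
#' @export
metacommunity_design <- function(n_otus = 10000, n_habitats = 4,
                                 n_seasons = 4, depth = 10342,
                                 sad_meanlog = 0, sad_sdlog = 2,
                                 specialist_fraction = 0.10,
                                 specialist_effect = 10,
                                 env_noise_sd = 0.15, seed = NULL) {
  stopifnot(n_otus >= 2, n_habitats >= 2, n_seasons >= 1, depth >= 1,
            sad_sdlog > 0,
            specialist_fraction >= 0, specialist_fraction <= 1,
            specialist_effect >= 1, env_noise_sd >= 0)
  structure(list(n_otus = as.integer(n_otus),
                 n_habitats = as.integer(n_habitats),
                 n_seasons = as.integer(n_seasons),
                 depth = as.integer(depth),
                 sad_meanlog = sad_meanlog, sad_sdlog = sad_sdlog,
                 specialist_fraction = specialist_fraction,
                 specialist_effect = specialist_effect,
                 env_noise_sd = env_noise_sd, seed = seed),
            class = "metacommunity_design")
}

# habitat-level environmental means for an estuarine intertidal gradient:
# bare mudflat -> invading cordgrass -> ecotone -> native mangrove.
# pH unitless; salinity (porewater); TC/TN/TS/TP mg per g dry sediment;
# NH4-N / NOx-N micrograms per g dry sediment.
.habitat_env_means <- data.frame(
  pH       = c(7.9, 7.4, 7.1, 6.8),
  salinity = c(22, 18, 15, 12),
  TC       = c(8, 16, 19, 23),
  TN       = c(0.8, 1.6, 1.9, 2.4),
  TS       = c(1.5, 3.0, 4.0, 5.5),
  TP       = c(0.45, 0.60, 0.65, 0.75),
  NH4.N    = c(12, 22, 28, 38),
  NOx.N    = c(9, 6, 5, 3)
)
.habitat_names <- c("mudflat", "cordgrass", "ecotone", "mangrove")
.season_names <- c("spring", "summer", "autumn", "winter")

#' Simulate a habitat-structured metacommunity with known ground truth
#'
#' Regional relative abundances are drawn lognormal and normalized ("few
#' abundant, many rare"). Each sample's expected composition is the regional
#' pool with planted specialists multiplied by `specialist_effect` in their
#' home habitat, renormalized; observed counts are multinomial at `depth`.
#' Environmental covariates are habitat-specific means plus Gaussian noise,
#' so environment is collinear with vegetation, as in real invaded
#' estuarine gradients. Lineages are assigned by random nested clustering
#' into ~7 phyla.
#'
#' @param design A [metacommunity_design()].
#' @param seed Integer seed; overrides `design$seed` if given.
#' @return A list with elements `otu` ([otu_table()]), `taxonomy` (tibble),
#'   `metadata` (tibble) and `truth` (list: per-OTU tibble with `specialist`
#'   flag, `home_habitat` and regional `p`; `design`).
#' @export
simulate_metacommunity <- function(design = metacommunity_design(),
                                   seed = design$seed) {
  if (is.null(seed)) stop("a seed is required", call. = FALSE)
  d <- design
  withr::with_seed(as.integer(seed), {
    p <- stats::rlnorm(d$n_otus, d$sad_meanlog, d$sad_sdlog)
    p <- p / sum(p)
    otu_ids <- sprintf("OTU_%05d", seq_len(d$n_otus))
    n_spec <- round(d$specialist_fraction * d$n_otus)
    spec_idx <- sort(sample.int(d$n_otus, n_spec))
    home <- rep(NA_integer_, d$n_otus)
    home[spec_idx] <- sample.int(d$n_habitats, n_spec, replace = TRUE)

    habitats <- .habitat_names[seq_len(min(d$n_habitats, 4L))]
    if (d$n_habitats > 4L) {
      habitats <- c(habitats, sprintf("habitat_%d", 5:d$n_habitats))
    }
    seasons <- .season_names[seq_len(min(d$n_seasons, 4L))]
    if (d$n_seasons > 4L) {
      seasons <- c(seasons, sprintf("season_%d", 5:d$n_seasons))
    }

    counts <- matrix(0L, d$n_habitats * d$n_seasons, d$n_otus)
    sample_ids <- character(nrow(counts))
    k <- 0L
    for (h in seq_len(d$n_habitats)) {
      lambda <- p
      boost <- !is.na(home) & home == h
      lambda[boost] <- lambda[boost] * d$specialist_effect
      lambda <- lambda / sum(lambda)
      for (s in seq_len(d$n_seasons)) {
        k <- k + 1L
        counts[k, ] <- stats::rmultinom(1L, d$depth, lambda)[, 1L]
        sample_ids[k] <- paste(habitats[h], seasons[s], sep = "_")
      }
    }
    dimnames(counts) <- list(sample_ids, otu_ids)

    taxonomy <- simulate_taxonomy(otu_ids)

    env_means <- .habitat_env_means[
      ((seq_len(d$n_habitats) - 1L) %% 4L) + 1L, , drop = FALSE]
    env_spread <- apply(.habitat_env_means, 2L, function(v) diff(range(v)))
    meta_rows <- expand.grid(season = seq_len(d$n_seasons),
                             habitat = seq_len(d$n_habitats))[, 2:1]
    env <- env_means[meta_rows$habitat, , drop = FALSE] +
      matrix(stats::rnorm(nrow(meta_rows) * ncol(env_means), 0, 1),
             nrow(meta_rows)) %*% diag(d$env_noise_sd * env_spread)
    colnames(env) <- colnames(env_means)
    # stations ~1 km apart along the estuary, shared by all seasons
    st_lat <- 24.43 + (seq_len(d$n_habitats) - 1L) * 0.009
    st_lon <- 117.90 + (seq_len(d$n_habitats) - 1L) * 0.006
    metadata <- dplyr::bind_cols(
      tibble::tibble(sample_id = sample_ids,
                     habitat = factor(habitats[meta_rows$habitat],
                                      levels = habitats),
                     season = factor(seasons[meta_rows$season],
                                     levels = seasons),
                     latitude = st_lat[meta_rows$habitat],
                     longitude = st_lon[meta_rows$habitat]),
      tibble::as_tibble(as.data.frame(env)))

    truth_tbl <- tibble::tibble(
      otu_id = otu_ids, p = p,
      specialist = !is.na(home),
      home_habitat = ifelse(is.na(home), NA_character_, habitats[home]))

    list(otu = otu_table(counts), taxonomy = taxonomy, metadata = metadata,
         truth = list(otus = truth_tbl, design = d))
  })
}

# random nested lineages: ~7 phyla, each splitting into a few classes,
# orders, families and genera; species label = the OTU itself
simulate_taxonomy <- function(otu_ids, n_phyla = 7L) {
  n <- length(otu_ids)
  phyla <- sprintf("Phylum_%d", sample.int(n_phyla, n, replace = TRUE,
                                           prob = stats::rlnorm(n_phyla)))
  split_level <- function(parent, tag, k) {
    child <- integer(n)
    for (p in unique(parent)) {
      idx <- which(parent == p)
      child[idx] <- sample.int(k, length(idx), replace = TRUE)
    }
    paste0(parent, "|", tag, child)
  }
  cls <- split_level(phyla, "c", 3L)
  ord <- split_level(cls, "o", 3L)
  fam <- split_level(ord, "f", 3L)
  gen <- split_level(fam, "g", 4L)
  tibble::tibble(otu_id = otu_ids, kingdom = "Bacteria", phylum = phyla,
                 class = cls, order = ord, family = fam, genus = gen,
                 species = otu_ids)
}

#' Simulate samples from the Sloan neutral model's marginal distribution
#'
#' For each sample, every OTU's local relative abundance is drawn from
#' Beta(N m p_i, N m (1 - p_i)) with N = `depth`, the sample vector is
#' renormalized, and counts are drawn multinomially at `depth`. This is
#' exactly the marginal the fitted neutral model assumes, so [fit_ncm()]
#' should recover `m` from the output.
#'
#' @param n_samples Number of samples.
#' @param depth Reads per sample (also the community size N).
#' @param m Migration probability in (0, 1].
#' @param regional_p Regional relative abundances (probability vector).
#' @param seed Integer seed.
#' @return A list with `otu` ([otu_table()]) and `truth`
#'   (list: `m`, `N`, `p`).
#' @export
simulate_neutral <- function(n_samples, depth, m, regional_p, seed) {
  stopifnot(n_samples >= 1, depth >= 1, m > 0, m <= 1)
  p <- regional_p / sum(regional_p)
  if (any(p < 0)) stop("regional_p must be non-negative", call. = FALSE)
  if (length(p) > 1L && any(p == 1)) {
    stop("a regional abundance of 1 with more than one OTU is degenerate",
         call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    Nm <- depth * m
    counts <- matrix(0L, n_samples, length(p))
    for (i in seq_len(n_samples)) {
      x <- stats::rbeta(length(p), Nm * p, Nm * (1 - p))
      x[p == 0] <- 0
      if (sum(x) == 0) x[] <- p
      counts[i, ] <- stats::rmultinom(1L, depth, x / sum(x))[, 1L]
    }
    dimnames(counts) <- list(sprintf("sample_%03d", seq_len(n_samples)),
                             sprintf("OTU_%05d", seq_along(p)))
    list(otu = otu_table(counts),
         truth = list(m = m, N = depth, p = p))
  })
}
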