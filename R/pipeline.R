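#' Default pipeline configuration
#'
#' Returns the configuration list [run_all()] consumes, pre-filled with the
#' package defaults: a simulated 4-habitat x 4-season metacommunity,
#' rarefaction to 10,342 reads, the standard rarity cut-offs, niche and
#' IndVal thresholds, permutation counts, the eight environmental
#' covariates as RDA predictors and habitat/season as the V and S blocks of
#' the variation partitioning.
#'
#' @param output_dir Where [run_all()] writes results.
#' @param seed Master seed recorded in the config; stage seeds derive from
#'   it.
#' @return A `run_config` list; serialize with [yaml::write_yaml()] and
#'   reload with [read_run_config()].
#' @export
default_run_config <- function(output_dir = "rarebiome_results", seed = 1) {
  structure(list(
    input = list(simulate = list(n_otus = 10000, n_habitats = 4,
                                 n_seasons = 4, depth = 10342,
                                 sad_meanlog = 0, sad_sdlog = 2,
                                 specialist_fraction = 0.10,
                                 specialist_effect = 10,
                                 env_noise_sd = 0.15)),
    seed = seed,
    rarefaction = list(depth = 10342),
    rarity = list(rare_cut = 1e-4, abundant_cut = 1e-2),
    niche = list(min_mean_abund = 2e-5, generalist_cut = 3,
                 specialist_cut = 1.5),
    indval = list(n_perm = 199, alpha = 0.05, min_component = 0.8),
    permutations = list(anosim = 999, mantel = 999, rda = 199),
    env_variables = c("pH", "salinity", "TC", "TN", "TS", "TP",
                      "NH4.N", "NOx.N"),
    ranks = c("otu", "genus", "family", "order", "class", "phylum"),
    output_dir = output_dir), class = c("run_config", "list"))
}

#' Read a pipeline configuration from YAML
#'
#' Fields missing from the file fall back to [default_run_config()] values;
#' the config round-trips losslessly through YAML.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  for (k in names(cfg)) base[[k]] <- modify_defaults(base[[k]], cfg[[k]])
  base
}

modify_defaults <- function(base, value) {
  if (is.list(base) && is.list(value)) {
    for (k in names(value)) base[[k]] <- modify_defaults(base[[k]], value[[k]])
    base
  } else value
}

#' Run the full analysis pipeline
#'
#' Executes the workflow end to end: load or simulate the inputs, rarefy,
#' partition rarity (with MultiCoLA), compute diversity and group tests,
#' niche breadth and IndVal, NMDS/ANOSIM/Mantel, RDA/VPA/dbRDA along ranks,
#' and the neutral-model fit. Each stage writes TSVs into
#' `config$output_dir` and a manifest (package version, config hash, seed,
#' per-stage wall time) is written at the end. Runs are deterministic under
#' a fixed config.
#'
#' @param config A `run_config` list ([default_run_config()],
#'   [read_run_config()]) or a path to a YAML config.
#' @param stages Subset of stage names to run (default: all of `"input"`,
#'   `"rarefy"`, `"rarity"`, `"diversity"`, `"niche"`, `"ordination"`,
#'   `"constrained"`, `"ncm"`). Later stages recompute what they need from
#'   the inputs, so subsets remain self-contained.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of every stage's in-memory results plus the
#'   manifest.
#' @export
run_all <- function(config = default_run_config(),
                    stages = c("input", "rarefy", "rarity", "diversity",
                               "niche", "ordination", "constrained", "ncm"),
                    quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  timings <- list()
  res <- list()
  seed <- as.integer(config$seed)
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    value
  }

  # -- input -----------------------------------------------------------
  say("stage input")
  res$input <- clock("input", {
    if (!is.null(config$input$simulate)) {
      design <- do.call(metacommunity_design, config$input$simulate)
      sim <- simulate_metacommunity(design, seed = seed)
      write_otu_table(sim$otu, file.path(out_dir, "input_otu_table.tsv"))
      write_taxonomy(sim$taxonomy, file.path(out_dir, "input_taxonomy.tsv"))
      write_sample_metadata(sim$metadata,
                            file.path(out_dir, "input_metadata.tsv"))
      readr::write_tsv(sim$truth$otus,
                       file.path(out_dir, "ground_truth.tsv"),
                       progress = FALSE)
      sim
    } else {
      list(otu = read_otu_table(config$input$otu_table,
                                config$input$orientation %||%
                                  "otus_as_rows"),
           taxonomy = read_taxonomy(config$input$taxonomy),
           metadata = read_sample_metadata(config$input$metadata))
    }
  })
  otu <- res$input$otu
  meta <- check_samples_match(otu, res$input$metadata)
  taxonomy <- res$input$taxonomy
  if (!"input" %in% stages) res$input <- NULL

  # -- rarefy ----------------------------------------------------------
  if (any(stages != "input")) {
    say("stage rarefy")
    res$rarefy <- clock("rarefy", {
      depth <- config$rarefaction$depth
      rar <- if (isTRUE(attr(otu, "rarefied")) &&
                 rowSums(otu)[1L] == depth) otu
             else rarefy_table(otu, depth, seed = seed + 1L)
      rar <- drop_empty_otus(rar)
      write_otu_table(rar, file.path(out_dir, "rarefied_otu_table.tsv"))
      rar
    })
  }
  rar <- res$rarefy
  env_vars <- intersect(config$env_variables, names(meta))

  if ("rarity" %in% stages) {
    say("stage rarity")
    res$rarity <- clock("rarity", {
      part <- classify_rarity(rar, config$rarity$rare_cut,
                              config$rarity$abundant_cut)
      summ <- rarity_summary(part, rar)
      prof <- multicola_profile(rar)
      readr::write_tsv(tidy(part),
                       file.path(out_dir, "rarity_partition.tsv"),
                       progress = FALSE)
      readr::write_tsv(summ, file.path(out_dir, "rarity_summary.tsv"),
                       progress = FALSE)
      readr::write_tsv(prof, file.path(out_dir, "multicola_profile.tsv"),
                       progress = FALSE)
      list(partition = part, summary = summ, multicola = prof)
    })
  }

  if ("diversity" %in% stages) {
    say("stage diversity")
    res$diversity <- clock("diversity", {
      alpha <- alpha_diversity(rar)
      tests <- purrr::map_dfr(
        c("s_obs", "chao1", "ace", "shannon", "pielou"),
        function(idx) {
          dplyr::mutate(group_tests(alpha[[idx]], meta$habitat, "anova"),
                        index = idx, .before = 1L)
        })
      cv <- dissimilarity_cv(bray_curtis(rar), meta$habitat)
      readr::write_tsv(alpha, file.path(out_dir, "alpha_diversity.tsv"),
                       progress = FALSE)
      readr::write_tsv(tests, file.path(out_dir, "alpha_anova.tsv"),
                       progress = FALSE)
      readr::write_tsv(cv, file.path(out_dir, "dissimilarity_cv.tsv"),
                       progress = FALSE)
      list(alpha = alpha, anova = tests, cv = cv)
    })
  }

  if ("niche" %in% stages) {
    say("stage niche")
    res$niche <- clock("niche", {
      nb <- niche_breadth(rar, meta$habitat,
                          min_mean_abund = config$niche$min_mean_abund,
                          generalist_cut = config$niche$generalist_cut,
                          specialist_cut = config$niche$specialist_cut)
      iv <- indval(rar, meta$habitat, n_perm = config$indval$n_perm,
                   seed = seed + 2L, alpha = config$indval$alpha,
                   min_component = config$indval$min_component,
                   abundance_filter = config$niche$min_mean_abund)
      readr::write_tsv(nb, file.path(out_dir, "niche_breadth.tsv"),
                       progress = FALSE)
      readr::write_tsv(iv, file.path(out_dir, "indval.tsv"),
                       progress = FALSE)
      readr::write_tsv(strict_specialist_counts(iv),
                       file.path(out_dir, "strict_specialists.tsv"),
                       progress = FALSE)
      list(niche = nb, indval = iv)
    })
  }

  if ("ordination" %in% stages) {
    say("stage ordination")
    res$ordination <- clock("ordination", {
      bc <- bray_curtis(rar)
      ord <- nmds(bc, seed = seed + 3L)
      an_h <- anosim(bc, meta$habitat,
                     n_perm = config$permutations$anosim, seed = seed + 4L)
      an_s <- anosim(bc, meta$season,
                     n_perm = config$permutations$anosim, seed = seed + 5L)
      mant <- NULL
      if (length(env_vars)) {
        ed <- env_distance(meta, env_vars)
        gd <- geographic_distance(meta)
        mant <- dplyr::bind_rows(
          dplyr::mutate(matrix_correlation(bc, ed,
                                           config$permutations$mantel,
                                           seed = seed + 6L),
                        pair = "bray_vs_env", .before = 1L),
          dplyr::mutate(matrix_correlation(bc, gd,
                                           config$permutations$mantel,
                                           seed = seed + 7L),
                        pair = "bray_vs_geo", .before = 1L))
        readr::write_tsv(mant, file.path(out_dir, "mantel.tsv"),
                         progress = FALSE)
      }
      readr::write_tsv(ord$scores, file.path(out_dir, "nmds_scores.tsv"),
                       progress = FALSE)
      readr::write_tsv(dplyr::bind_rows(
        dplyr::mutate(glance(an_h), grouping = "habitat", .before = 1L),
        dplyr::mutate(glance(an_s), grouping = "season", .before = 1L)),
        file.path(out_dir, "anosim.tsv"), progress = FALSE)
      list(nmds = ord, anosim_habitat = an_h, anosim_season = an_s,
           mantel = mant)
    })
  }

  if ("constrained" %in% stages && length(env_vars)) {
    say("stage constrained")
    res$constrained <- clock("constrained", {
      rda_fit <- rda_analysis(rar, meta, env_vars,
                              n_perm = config$permutations$rda,
                              seed = seed + 8L)
      vp <- vpa(rar, meta, block_E = env_vars, block_V = "habitat",
                block_S = "season")
      grad <- dbrda_by_rank(rar, taxonomy, meta, env_vars,
                            ranks = config$ranks)
      readr::write_tsv(glance(rda_fit), file.path(out_dir, "rda_summary.tsv"),
                       progress = FALSE)
      readr::write_tsv(rda_fit$selection_path,
                       file.path(out_dir, "rda_forward_selection.tsv"),
                       progress = FALSE)
      readr::write_tsv(vp$fractions, file.path(out_dir, "vpa_fractions.tsv"),
                       progress = FALSE)
      readr::write_tsv(grad, file.path(out_dir, "dbrda_by_rank.tsv"),
                       progress = FALSE)
      list(rda = rda_fit, vpa = vp, dbrda = grad)
    })
  }

  if ("ncm" %in% stages) {
    say("stage ncm")
    res$ncm <- clock("ncm", {
      fit <- fit_ncm(rar)
      by_rank <- ncm_by_rank(rar, taxonomy, ranks = config$ranks)
      readr::write_tsv(glance(fit), file.path(out_dir, "ncm_summary.tsv"),
                       progress = FALSE)
      readr::write_tsv(fit$otus, file.path(out_dir, "ncm_otus.tsv"),
                       progress = FALSE)
      readr::write_tsv(by_rank, file.path(out_dir, "ncm_by_rank.tsv"),
                       progress = FALSE)
      list(fit = fit, by_rank = by_rank)
    })
  }

  manifest <- list(
    package = "rarebiome",
    version = as.character(utils::packageVersion("rarebiome")),
    # hash of the analysis-relevant configuration (where outputs land is
    # not part of the analysis identity)
    config_hash = rlang::hash(config[setdiff(names(config), "output_dir")]),
    seed = seed,
    stages = names(timings),
    wall_time_s = timings)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  res$manifest <- manifest
  invisible(res)
}
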