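#' Run the full attribution pipeline on a synthetic world
#'
#' Chains every stage end to end: world simulation, data-hygiene filters
#' and diversity statistics, admixture summaries (K selection, population
#' means, Simpson index), the ensemble distribution model with glacial
#' refugia and stability areas, and the Gaussian-GLM/AIC attribution of
#' diversity to admixture versus distance-to-refugium predictors. All
#' randomness derives from the single `seed` in the configuration, so a
#' rerun with the same configuration reproduces every artifact.
#'
#' @param config configuration list (see [default_run_config()]); missing
#'   entries take the standard defaults.
#' @param out_dir optional directory; when given, every intermediate
#'   artifact and the final report are written there.
#' @return list of class `meltpot_run`: `report` (per-stage parameters,
#'   seeds and counts), `world`, `diversity`, `pop_q`, `selected_k`,
#'   `ensemble`, `refugia`, `stability`, `predictors`, `models`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  config <- utils::modifyList(default_run_config(), config)
  set.seed(config$seed)
  stage_seed <- sample.int(.Machine$integer.max - 1L, 8L)
  report <- list(schema = config$schema, seed = config$seed,
                 stages = list())
  note <- function(stage, ...) {
    report$stages[[stage]] <<- list(...)
  }

  ## 1. simulate ------------------------------------------------------
  wcfg <- do.call(world_config,
                  utils::modifyList(list(seed = stage_seed[1L]),
                                    config$world))
  world <- generate_world(wcfg)
  if (!is.null(out_dir)) write_world(world, file.path(out_dir, "world"))
  note("simulate", seed = stage_seed[1L],
       n_populations = nrow(world$populations),
       driver_mode = world$truth$driver_mode)

  ## 2. diversity statistics -----------------------------------------
  filt <- filter_populations(world$genotypes, min_n = config$min_n)
  gt <- filt$genotypes
  if (!is.null(config$null_allele_flags)) {
    lf <- filter_loci(gt, config$null_allele_flags,
                      max_flagged = config$max_flagged)
    gt <- lf$genotypes
  }
  div <- diversity_table(world$sequences[unique(as.character(gt$population))],
                         gt)
  note("divstats", min_n = config$min_n,
       dropped_populations = unique(filt$report$population),
       n_retained = length(unique(gt$population)))

  ## 3. admixture summaries ------------------------------------------
  selected_k <- select_k_plateau(world$dic_table,
                                 epsilon = config$dic_epsilon)
  pop_q <- population_mean_q(world$q_matrix)
  note("admix", selected_k = selected_k, top_m = config$top_m)

  ## 4. ensemble distribution model ----------------------------------
  occ <- clean_occurrences(world$occurrences)
  thinned <- thin_occurrences(occ, d_min = config$thin_d_min,
                              n_datasets = config$thin_datasets,
                              seed = stage_seed[2L])
  region <- raster_grid(
    matrix(1, world$config$grid_rows, world$config$grid_cols),
    cellsize = world$config$cell_size, crs = "planar")
  bg <- target_group_background(world$target_group, region)
  Xall <- values_at(world$env_current, names(world$env_current$layers),
                    rbind(occ[c("lon", "lat")], bg[c("lon", "lat")]))
  vars <- vif_select(Xall[stats::complete.cases(Xall), , drop = FALSE],
                     threshold = config$vif_threshold)
  ensemble <- fit_ensemble(thinned, bg, world$env_current, vars,
                           auc_cutoff = config$auc_cutoff,
                           n_validation_bg = config$n_validation_bg,
                           seed = stage_seed[3L])
  current_suit <- project_suitability(ensemble, world$env_current)
  current_bin <- binarize(current_suit, ensemble$threshold)
  gcm_bins <- lapply(world$env_gcm, function(e)
    binarize(project_suitability(ensemble, e), ensemble$threshold))
  note("sdm", thin_d_min = config$thin_d_min,
       n_occurrences = nrow(occ), n_background = nrow(bg),
       vars = vars, aucs = ensemble$aucs,
       maxtss_threshold = ensemble$threshold, seed = stage_seed[3L])

  ## 5. refugia and stability ----------------------------------------
  refugia <- gcm_consensus(gcm_bins, min_agree = config$min_agree)
  stability <- stability_areas(current_bin, refugia,
                               world$ancestral_areas)
  if (!any(stability$values == 1, na.rm = TRUE)) {
    ## fall back to the refugium/ancestral overlap when the triple
    ## intersection is empty on this landscape
    stability <- suppressWarnings(
      stability_areas(current_bin, refugia, world$ancestral_areas,
                      include_current = FALSE))
  }
  if (!any(stability$values == 1, na.rm = TRUE)) {
    ## still empty: take the refugium cell closest to an ancestral area,
    ## keeping stability a (minimal) subset of the refugia
    cells <- cell_centres(refugia)
    on <- which(refugia$values[cbind(cells$row, cells$col)] == 1)
    anchors <- t(vapply(world$ancestral_areas, function(a)
      colMeans(a$coords[-nrow(a$coords), , drop = FALSE]), numeric(2)))
    D <- point_distances(cells[on, c("x", "y")], anchors, refugia$crs)
    pick <- on[which.min(apply(D, 1L, min))]
    m <- matrix(0, nrow(refugia$values), ncol(refugia$values))
    m[cells$row[pick], cells$col[pick]] <- 1
    stability <- raster_grid(m, xll = refugia$xll, yll = refugia$yll,
                             cellsize = refugia$cellsize, crs = refugia$crs,
                             nodata = refugia$nodata)
  }
  note("refugia", min_agree = config$min_agree,
       refugium_cells = sum(refugia$values == 1, na.rm = TRUE),
       stability_cells = sum(stability$values == 1, na.rm = TRUE))

  ## 6. attribution ---------------------------------------------------
  pops <- world$populations
  names(pops)[names(pops) == "id"] <- "population"
  pops <- pops[pops$population %in% div$population, , drop = FALSE]
  predictors <- build_predictor_table(pops, pop_q, refugia, stability)
  if (!is.null(config$subset_ids)) {
    predictors <- subset_populations(predictors, config$subset_ids)
  }
  models <- run_model_set(div, predictors,
                          include_interactions = config$include_interactions)
  note("attribute", n_models = length(models$responses[[1L]]$fits),
       n_populations = models$n,
       include_interactions = config$include_interactions)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(div, file.path(out_dir, "diversity.csv"),
                     row.names = FALSE)
    simpson <- data.frame(
      population = predictors$population, simpson = predictors$simpson)
    utils::write.csv(pop_q, file.path(out_dir, "pop_admixture.csv"),
                     row.names = FALSE)
    utils::write.csv(predictors, file.path(out_dir, "predictors.csv"),
                     row.names = FALSE)
    write_ascii_grid(current_bin, file.path(out_dir, "current_binary.asc"))
    for (g in seq_along(gcm_bins))
      write_ascii_grid(gcm_bins[[g]],
                       file.path(out_dir, sprintf("gcm%d_binary.asc", g)))
    write_ascii_grid(refugia, file.path(out_dir, "refugia_consensus.asc"))
    write_ascii_grid(stability, file.path(out_dir, "stability.asc"))
    write_model_report(models, file.path(out_dir, "model_comparison"))
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(report = report, world = world, diversity = div,
                 pop_q = pop_q, selected_k = selected_k,
                 ensemble = ensemble, refugia = refugia,
                 stability = stability, predictors = predictors,
                 models = models),
            class = "meltpot_run")
}

#' Write a model-comparison report (CSV + JSON)
#'
#' Flattens the per-model coefficient and sequential-ANOVA blocks into one
#' CSV (mirroring the usual per-model layout: estimate, `Pr(>|t|)`, df,
#' residual df, F, `Pr(>F)`, AIC) and writes the same content as JSON.
#'
#' @param models a `meltpot_model_comparison`.
#' @param stem output path without extension.
#' @return `stem`, invisibly.
#' @export
write_model_report <- function(models, stem) {
  rows <- list()
  js <- list()
  for (resp in names(models$responses)) {
    r <- models$responses[[resp]]
    for (i in seq_along(r$fits)) {
      f <- r$fits[[i]]
      co <- f$ols$coefficients
      an <- f$anova
      terms <- co$term[co$term != "(Intercept)"]
      for (t in terms) {
        ci <- match(t, co$term); ai <- match(t, an$term)
        rows[[length(rows) + 1L]] <- data.frame(
          response = resp, model = f$ols$formula_tag, term = t,
          estimate = co$estimate[ci], p_coef = co$p[ci],
          df = if (!is.na(ai)) an$df[ai] else NA,
          df_resid = f$ols$df_residual,
          F = if (!is.na(ai)) an$F[ai] else NA,
          p_F = if (!is.na(ai)) an$p[ai] else NA,
          aic = f$ols$aic)
      }
    }
    js[[resp]] <- list(
      aic_ranking = r$aic,
      best_model = r$fits[[r$best]]$ols$formula_tag)
  }
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(c(js, list(table = tab)), paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(stem)
}
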