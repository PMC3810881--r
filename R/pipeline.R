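#' Beta-diversity analysis of one dataset: MRM and variance partition
#'
#' The core analysis graph for one set of inputs: split the flora into
#' endemic and nonendemic elements; build each element's Sorensen
#' dissimilarity matrix; run separate BIO-ENV searches over the
#' climatic (codes 1-18) and altitudinal (E1-E4) variables; turn the
#' winning subsets into standardized Euclidean distance matrices; build
#' the geographic (mean cell-pair) matrix and, when a lithology table
#' is supplied, the Bray-Curtis substrate matrix; then fit the multiple
#' regression on distance matrices and the unique/joint/unexplained
#' variance partition for each element. Omitting `lith` runs the
#' three-predictor (climatic + altitudinal + geographic) analysis.
#'
#' @param occ an `occurrence_matrix` over the analysed ecoregions.
#' @param env environmental table for the same ecoregions.
#' @param grid cell grid for the same ecoregions.
#' @param lith optional lithology table (adds the lithological
#'   predictor).
#' @param nperm MRM permutations.
#' @param seed integer seed (MRM permutations; geographic subsampling
#'   if enabled).
#' @param max_k BIO-ENV subset-size cap (default: all candidates).
#' @param geo_method `"exact"` or `"subsample"` cell-pair distances.
#' @return an `element_analysis` list, one entry per floristic
#'   element, each with `bioenv_climatic`, `bioenv_altitudinal`,
#'   `mrm`, `partition`, `predictors`.
#' @export
run_beta_analysis <- function(occ, env, grid, lith = NULL,
                              nperm = 999L, seed = 1L, max_k = NULL,
                              geo_method = "exact") {
  elements <- split_by_endemism(occ)
  labs <- occ$ecoregions
  env <- env[match(labs, env$ecoregion), , drop = FALSE]
  geo <- geographic_distance_matrix(grid, method = geo_method,
                                    seed = seed)
  geo <- subset_distance_matrix(geo, labs)
  lith_d <- if (!is.null(lith)) {
    lith <- lith[match(labs, lith$ecoregion), , drop = FALSE]
    braycurtis_matrix(lith)
  }
  out <- lapply(names(elements), function(el) {
    occ_el <- elements[[el]]
    # drop taxa absent from every analysed ecoregion for this element
    keep <- rowSums(occ_el$incidence) > 0L
    occ_el <- occurrence_matrix(occ_el$incidence[keep, , drop = FALSE],
                                occ_el$range_flag[keep],
                                if (!is.null(occ_el$range_class))
                                  occ_el$range_class[keep],
                                allow_empty_taxa = TRUE)
    ds <- sorensen_matrix(occ_el)
    # exhaustive search over all 2^18 - 1 climatic subsets is pointless
    # at pipeline level: subsets beyond ~5 variables only ever refine
    # the correlation marginally, so the orchestrated run caps the size
    kc <- if (is.null(max_k)) 5L else max_k
    ka <- if (is.null(max_k)) length(altitudinal_codes) else max_k
    be_c <- bioenv_search(ds, env, climatic_codes, max_k = kc)
    be_a <- bioenv_search(ds, env, altitudinal_codes, max_k = ka)
    preds <- list(
      climatic = euclidean_env_matrix(env, be_c$best_subset),
      altitudinal = euclidean_env_matrix(env, be_a$best_subset),
      geographic = geo)
    if (!is.null(lith_d)) preds$lithological <- lith_d
    fit <- mrm(ds, preds, nperm = nperm, seed = seed)
    part <- variance_partition(ds, preds)
    list(bioenv_climatic = be_c, bioenv_altitudinal = be_a,
         mrm = fit, partition = part, predictors = preds,
         sorensen = ds)
  })
  names(out) <- names(elements)
  structure(out, class = "element_analysis")
}

subset_inputs <- function(ids, occ, env, grid, info, lith = NULL) {
  inc <- occ$incidence[, ids, drop = FALSE]
  keep <- rowSums(inc) > 0L
  occ2 <- occurrence_matrix(inc[keep, , drop = FALSE],
                            occ$range_flag[keep],
                            if (!is.null(occ$range_class))
                              occ$range_class[keep],
                            allow_empty_taxa = TRUE)
  list(occ = occ2,
       env = env[env$ecoregion %in% ids, , drop = FALSE],
       grid = grid[grid$ecoregion %in% ids, , drop = FALSE],
       info = info[info$id %in% ids, , drop = FALSE],
       lith = if (!is.null(lith))
         lith[lith$ecoregion %in% ids, , drop = FALSE])
}

#' Run the full configuration-driven pipeline
#'
#' End-to-end orchestration: load (or simulate) the inputs; summarize
#' the floristic pool; cluster the full flora by UPGMA with
#' multiscale-bootstrap AU support; ordinate by DCA; build the
#' environmental table, its PCA, and the alpha-diversity regressions
#' against the climatic PC1, the altitudinal PC1 and ecoregion area;
#' then run the per-element beta-diversity analysis
#' ([run_beta_analysis()]), optionally restricted to the high-elevation
#' ecoregion subset, and optionally the taxon-resampling robustness
#' check. Every matrix, selection and seed lands in the returned
#' bundle; a results JSON and the intermediate matrices are written to
#' the output directory when one is given. Identical config + seed
#' give identical results.
#'
#' `config` is a named list (or YAML file path, see
#' [read_run_config()]) with entries: either `scenario` (arguments for
#' [scenario_config()]) or `inputs` (paths `occurrence`, `cells`,
#' `grid`, `ecoregions`, optionally `surfaces`); `subset` (`"all"` or
#' `"high-elevation"`); `nperm`; `seed`; `bootstrap` (list `scales`,
#' `B`); optional `resampling` (list `k`, `n_iter`, `nperm`);
#' `out_dir` (optional).
#'
#' @param config named list or path to a YAML config file.
#' @return a `pipeline_result` list with elements `pool_summary`,
#'   `cluster`, `dca`, `pca_climatic`, `pca_altitudinal`,
#'   `alpha_models`, `beta`, `subset_ids`, `resampling`, `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$seed)) stop("config must set a seed")
  seed <- as.integer(config$seed)
  nperm <- if (is.null(config$nperm)) 999L else as.integer(config$nperm)
  if (!is.null(config$scenario)) {
    sc <- config$scenario
    sc$seed <- if (is.null(sc$seed)) seed else sc$seed
    cfg <- do.call(scenario_config, sc)
    land <- generate_landscape(cfg)
    flora <- generate_flora(cfg, land)
    occ <- flora$occ
    cells <- land$cells; grid <- land$grid; info <- land$info
    lith <- build_lithology_table(land$surfaces)
    truth <- flora$truth
  } else if (!is.null(config$inputs)) {
    pp <- config$inputs
    occ <- read_occurrence_matrix(pp$occurrence)
    cells <- read_monthly_cells(pp$cells)
    grid <- read_cell_grid(pp$grid)
    info <- read_ecoregion_info(pp$ecoregions)
    lith <- if (!is.null(pp$surfaces))
      build_lithology_table(utils::read.delim(
        pp$surfaces, check.names = FALSE,
        colClasses = c(ecoregion = "character")))
    truth <- NULL
  } else stop("config needs either 'scenario' or 'inputs'")
  env <- build_env_table(cells)
  pool <- summarize_pool(occ, info)
  boot <- config$bootstrap
  scales <- if (is.null(boot$scales)) seq(0.5, 1.4, by = 0.1)
            else as.numeric(boot$scales)
  B <- if (is.null(boot$B)) 100L else as.integer(boot$B)
  cluster <- multiscale_bootstrap(occ, scales = scales, B = B,
                                  seed = seed)
  ord <- dca(occ)
  pca_c <- pca_env(env, climatic_codes)
  pca_a <- pca_env(env, altitudinal_codes)
  elements <- split_by_endemism(occ)
  alpha_models <- list()
  area <- stats::setNames(info$area_km2, info$id)[occ$ecoregions]
  for (el in names(elements)) {
    inc <- elements[[el]]$incidence
    alpha <- colSums(inc)
    alpha_models[[el]] <- list(
      climatic_pc1 = alpha_regression(
        alpha, stats::setNames(pca_c$site_scores[, 1L],
                               rownames(pca_c$site_scores))),
      altitudinal_pc1 = alpha_regression(
        alpha, stats::setNames(pca_a$site_scores[, 1L],
                               rownames(pca_a$site_scores))),
      area = alpha_regression(alpha, area))
  }
  subset <- if (is.null(config$subset)) "all" else config$subset
  subset_ids <- occ$ecoregions
  inputs <- list(occ = occ, env = env, grid = grid, info = info,
                 lith = lith)
  if (identical(subset, "high-elevation")) {
    subset_ids <- filter_high_elevation(grid)
    sub <- subset_inputs(subset_ids, occ, env, grid, info, lith)
    inputs[names(sub)] <- sub
    inputs$env <- build_env_table(
      cells[cells$ecoregion %in% subset_ids, , drop = FALSE])
  }
  beta <- run_beta_analysis(inputs$occ, inputs$env, inputs$grid,
                            lith = inputs$lith, nperm = nperm,
                            seed = seed)
  resamp <- NULL
  if (!is.null(config$resampling)) {
    rs <- config$resampling
    resamp <- resampling_robustness(
      split_by_endemism(inputs$occ)$nonendemic,
      k = as.integer(rs$k),
      n_iter = if (is.null(rs$n_iter)) 100L else as.integer(rs$n_iter),
      nperm = if (is.null(rs$nperm)) 199L else as.integer(rs$nperm),
      seed = seed)
  }
  res <- structure(
    list(pool_summary = pool, cluster = cluster, dca = ord,
         pca_climatic = pca_c, pca_altitudinal = pca_a,
         alpha_models = alpha_models, beta = beta,
         subset_ids = subset_ids, resampling = resamp,
         truth = truth, config = config),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, inputs,
                                                       config$out_dir)
  res
}

#' @rdname run_pipeline
#' @param path YAML config file path.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

write_pipeline_outputs <- function(res, inputs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (el in names(res$beta)) {
    b <- res$beta[[el]]
    write_distance_matrix(b$sorensen,
                          file.path(dir, paste0("sorensen_", el, ".tsv")))
    for (p in names(b$predictors))
      write_distance_matrix(b$predictors[[p]],
                            file.path(dir, paste0(p, "_", el, ".tsv")))
  }
  write_newick(res$cluster, file.path(dir, "upgma_au.nwk"))
  write_ordination(res$dca, file.path(dir, "dca_scores.tsv"))
  jsonlite::write_json(pipeline_results_list(res),
                       file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# Machine-readable summary of a pipeline run (numbers only, no
# timestamps, so identical config + seed give byte-identical JSON).
pipeline_results_list <- function(res) {
  beta <- lapply(res$beta, function(b) list(
    bioenv_climatic = list(subset = b$bioenv_climatic$best_subset,
                           correlation = b$bioenv_climatic$best_cor),
    bioenv_altitudinal = list(subset = b$bioenv_altitudinal$best_subset,
                              correlation = b$bioenv_altitudinal$best_cor),
    mrm_r2 = b$mrm$r2, mrm_r2_p = b$mrm$r2_p,
    coefficients = b$mrm$coefficients,
    partition = list(unique = as.list(b$partition$unique),
                     joint = b$partition$joint,
                     unexplained = b$partition$unexplained)))
  list(pool_summary = res$pool_summary[
         c("n_taxa", "n_hotspot", "hotspot_pct", "n_endemic",
           "n_nonendemic", "endemic_pct")],
       alpha_models = lapply(res$alpha_models, function(el)
         lapply(el, function(m) m[c("adj_r2", "p_value")])),
       pca = list(climatic_cumvar2 = res$pca_climatic$cumulative_variance[2L],
                  altitudinal_cumvar2 = res$pca_altitudinal$cumulative_variance[2L]),
       beta = beta,
       subset_ids = res$subset_ids,
       resampling = if (!is.null(res$resampling))
         res$resampling[c("mean_adj_r2", "sd_adj_r2", "mean_p")],
       seed = res$config$seed)
}
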