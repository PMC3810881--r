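#' Scenario configuration for the synthetic landscape generator
#'
#' Bundles every knob of the synthetic study system: a rectangular
#' gridded landscape of 1-km2 cells carved into contiguous rectangular
#' ecoregions, with an elevation ridge, elevation-lapsed seasonal
#' temperatures, a westward precipitation gradient with a summer
#' minimum, and a patchy lithology mosaic; and a flora of two guilds —
#' narrow endemics restricted to an elevation window and (with the
#' given fidelity) to a required substrate category, and widespread
#' nonendemics whose occupancy decays with distance from an origin
#' ecoregion and with climate-niche mismatch. The defaults (12
#' ecoregions, 400 species on a 40 x 30 km grid) exercise every
#' pipeline stage in seconds while keeping both guilds' drivers
#' recoverable.
#'
#' @param seed integer seed (mandatory; every stochastic draw flows
#'   from it).
#' @param grid_width,grid_height landscape size in cells (1 km each).
#' @param n_ecoregions number of contiguous rectangular ecoregions.
#' @param n_lithology number of substrate categories (spatial patches).
#' @param n_endemic,n_nonendemic species counts per guild.
#' @param endemic_elev_window half-width (m) of the endemic elevation
#'   niche around its sampled centre.
#' @param climate_sd nonendemic climate-niche breadth (degrees C of
#'   annual mean temperature).
#' @param lithology_fidelity probability that an endemic is excluded
#'   from ecoregions lacking its substrate (1 = strict).
#' @param distance_decay_rate nonendemic occupancy decay per km of
#'   distance from the origin ecoregion.
#' @param occupancy_baseline presence probability when the niche
#'   matches perfectly.
#' @param lapse_rate temperature lapse, degrees C per km of elevation.
#' @param lith_presence_min lithology fraction above which a substrate
#'   counts as present in an ecoregion.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(seed,
                            grid_width = 40L, grid_height = 30L,
                            n_ecoregions = 12L, n_lithology = 6L,
                            n_endemic = 120L, n_nonendemic = 280L,
                            endemic_elev_window = 250,
                            climate_sd = 2,
                            lithology_fidelity = 0.9,
                            distance_decay_rate = 0.03,
                            occupancy_baseline = 0.9,
                            lapse_rate = 6,
                            lith_presence_min = 0.05) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(seed = as.integer(seed), grid_width = as.integer(grid_width),
              grid_height = as.integer(grid_height),
              n_ecoregions = as.integer(n_ecoregions),
              n_lithology = as.integer(n_lithology),
              n_endemic = as.integer(n_endemic),
              n_nonendemic = as.integer(n_nonendemic),
              endemic_elev_window = endemic_elev_window,
              climate_sd = climate_sd,
              lithology_fidelity = lithology_fidelity,
              distance_decay_rate = distance_decay_rate,
              occupancy_baseline = occupancy_baseline,
              lapse_rate = lapse_rate,
              lith_presence_min = lith_presence_min)
  stopifnot(cfg$grid_width > 0, cfg$grid_height > 0,
            cfg$n_ecoregions > 0, cfg$n_lithology > 0,
            cfg$n_endemic > 0, cfg$n_nonendemic > 0,
            cfg$lithology_fidelity >= 0, cfg$lithology_fidelity <= 1,
            cfg$occupancy_baseline >= 0, cfg$occupancy_baseline <= 1,
            cfg$distance_decay_rate >= 0, cfg$climate_sd > 0)
  structure(cfg, class = "scenario_config")
}

#' Preset scenarios with a single known beta-diversity driver
#'
#' `scenario_lithology_endemic`: strict substrate fidelity and a narrow
#' elevation window, so endemic turnover is driven by lithology and
#' elevation. `scenario_distance_decay`: a very broad climate niche and
#' strong distance decay, so nonendemic turnover is driven by geography
#' alone.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [scenario_config()].
#' @return a `scenario_config`.
#' @export
scenario_lithology_endemic <- function(seed, ...) {
  scenario_config(seed, lithology_fidelity = 1,
                  endemic_elev_window = 200, ...)
}

#' @rdname scenario_lithology_endemic
#' @export
scenario_distance_decay <- function(seed, ...) {
  scenario_config(seed, climate_sd = 50, distance_decay_rate = 0.06,
                  ...)
}

# Partition n_eco into vertical strips of near-equal block counts;
# returns an ecoregion index per cell. Blocks are contiguous rectangles
# with seeded-jittered boundaries, so ecoregion areas differ (uses the
# caller's RNG stream).
block_partition <- function(W, H, n_eco) {
  if (n_eco > W * H) stop("more ecoregions than cells")
  ns <- min(W, ceiling(sqrt(n_eco)))
  per <- rep(n_eco %/% ns, ns)
  extra <- n_eco %% ns
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  jitter_breaks <- function(total, k) {
    if (k == 1L) return(c(0, total))
    w <- stats::runif(k, 0.7, 1.3)
    br <- round(cumsum(w) / sum(w) * total)
    br <- pmin(pmax(br, seq_len(k)), total - (k - seq_len(k)))
    c(0, sort(br))
  }
  xb <- jitter_breaks(W, ns)
  yb_list <- lapply(per, function(k) jitter_breaks(H, k))
  assign_cell <- function(x, y) {
    s <- findInterval(x, xb, rightmost.closed = TRUE, all.inside = TRUE)
    b <- findInterval(y, yb_list[[s]], rightmost.closed = TRUE,
                      all.inside = TRUE)
    sum(per[seq_len(s - 1L)]) + b
  }
  assign_cell
}

#' Generate a synthetic landscape
#'
#' Builds the cell grid, per-cell monthly climate table and substrate
#' surface table for a scenario. Elevation is a smooth central ridge
#' (crest rising eastward) plus seeded noise; each monthly mean
#' temperature is a seasonal sea-level value minus `lapse_rate` times
#' elevation in km (maxima/minima offset by +/- 5 degrees C);
#' precipitation follows a winter-peaked seasonal cycle scaled up
#' westward. Lithology categories are nearest-seed (Voronoi) patches.
#' Identical seeds give identical landscapes.
#'
#' @param cfg a `scenario_config`.
#' @return list with `grid` (cell grid data.frame), `cells` (monthly
#'   cell table), `surfaces` (ecoregion x category areas, km2),
#'   `info` (ecoregion info data.frame) and `lith_cell` (per-cell
#'   category).
#' @export
generate_landscape <- function(cfg) {
  W <- cfg$grid_width; H <- cfg$grid_height
  restore <- local_rng(cfg$seed)
  on.exit(restore())
  x <- rep(seq_len(W) - 0.5, times = H)
  y <- rep(seq_len(H) - 0.5, each = W)
  part <- block_partition(W, H, cfg$n_ecoregions)
  eco_idx <- mapply(part, x, y)
  eco_id <- sprintf("E%02d", eco_idx)
  # central ridge, crest height growing eastward; floor at lowland noise
  crest <- 2200 * (0.35 + 0.65 * x / W)
  ridge <- exp(-((y - H / 2)^2) / (2 * (H / 5)^2))
  elev <- pmax(0, 120 + crest * ridge + stats::rnorm(W * H, 0, 40))
  months <- 1:12
  p0 <- 60 + 50 * cos(2 * pi * (months - 1) / 12)  # winter max, Jul min
  # elevation lapse plus elevation-independent structure (continentality
  # gradients in y for both level and seasonal amplitude, cell-level
  # microclimate noise) so climate is correlated with, but not a
  # deterministic function of, elevation; the seasonal amplitude and
  # diurnal range vary in space so the variability codes are informative
  tbar <- 18 - cfg$lapse_rate * elev / 1000 - 0.1 * y +
    stats::rnorm(W * H, 0, 0.5)
  amp <- 8 * (0.8 + 0.4 * y / H + 0.1 * elev / 1000 +
                stats::rnorm(W * H, 0, 0.05))
  season <- cos(2 * pi * (months - 7) / 12)
  tmean <- outer(tbar, rep(1, 12)) + outer(amp, season)
  drange <- 4 + 0.8 * elev / 1000 + stats::rnorm(W * H, 0, 0.2)
  tmax <- tmean + drange
  tmin <- tmean - drange
  west <- 1 + 0.8 * (W - x) / W
  prec <- outer(west, p0, "*") * (1 + 0.2 * elev / 1000) *
    (1 + stats::rnorm(W * H, 0, 0.05))
  cells <- data.frame(ecoregion = eco_id, elev_m = elev)
  colnames(tmean) <- month_cols("tmean")
  colnames(tmax) <- month_cols("tmax")
  colnames(tmin) <- month_cols("tmin")
  colnames(prec) <- month_cols("prec")
  cells <- cbind(cells, tmean, tmax, tmin, prec)
  grid <- data.frame(x_km = x, y_km = y, ecoregion = eco_id,
                     elev_m = elev)
  # lithology mosaic: many small nearest-seed patches, each assigned a
  # random substrate category — patchy like a geological map, and not a
  # simple proxy for geographic position
  n_patch <- max(cfg$n_lithology, 4L * cfg$n_lithology)
  cx <- stats::runif(n_patch, 0, W)
  cy <- stats::runif(n_patch, 0, H)
  patch_cat <- sample(rep_len(seq_len(cfg$n_lithology), n_patch))
  d2 <- outer(x, cx, "-")^2 + outer(y, cy, "-")^2
  lith_cell <- sprintf("L%02d", patch_cat[max.col(-d2)])
  surfaces <- as.data.frame.matrix(table(eco_id, lith_cell))
  surfaces <- data.frame(ecoregion = rownames(surfaces), surfaces,
                         check.names = FALSE)
  ids <- sort(unique(eco_id))
  centro_x <- tapply(x, eco_id, mean)[ids]
  info <- data.frame(
    id = ids,
    name = paste0("ecoregion-", ids),
    region = ifelse(centro_x <= stats::median(centro_x), "West", "East"),
    in_hotspot = TRUE,
    in_baetic = centro_x <= stats::median(centro_x),
    area_km2 = as.vector(table(eco_id)[ids]))
  list(grid = grid, cells = cells, surfaces = surfaces, info = info,
       lith_cell = lith_cell)
}

eco_summaries <- function(landscape) {
  grid <- landscape$grid
  ids <- sort(unique(grid$ecoregion))
  tann <- rowMeans(landscape$cells[month_cols("tmean")])
  lith <- build_lithology_table(landscape$surfaces)
  lith_m <- lithology_values(lith)[ids, , drop = FALSE]
  data.frame(
    id = ids,
    mean_elev = tapply(grid$elev_m, grid$ecoregion, mean)[ids],
    mean_temp = tapply(tann, grid$ecoregion, mean)[ids],
    cx = tapply(grid$x_km, grid$ecoregion, mean)[ids],
    cy = tapply(grid$y_km, grid$ecoregion, mean)[ids],
    row.names = ids) -> sm
  attr(sm, "lith") <- lith_m
  sm
}

#' Generate a synthetic flora over a landscape
#'
#' Nonendemic species draw an origin ecoregion and a climate optimum
#' near the origin's mean annual temperature; their occupancy
#' probability in ecoregion e is `occupancy_baseline` x a Gaussian
#' climate-match kernel (breadth `climate_sd`) x exp(-decay x centroid
#' distance from the origin), with the origin itself always occupied.
#' Endemic species draw an elevation-window centre and a required
#' substrate; they can occur only in ecoregions whose mean elevation
#' falls inside the window, and occurrence in ecoregions lacking the
#' substrate is suppressed with probability `lithology_fidelity`.
#' Species with no feasible ecoregion are re-drawn up to 20 times and
#' then dropped with a warning. The ground truth records which factor
#' dominates each guild under the configuration.
#'
#' @param cfg a `scenario_config`.
#' @param landscape output of [generate_landscape()].
#' @return list with `occ` (an `occurrence_matrix`) and `truth` (guild
#'   driver labels plus per-species niche parameters).
#' @export
generate_flora <- function(cfg, landscape) {
  sm <- eco_summaries(landscape)
  lith_m <- attr(sm, "lith")
  ids <- sm$id
  n_eco <- length(ids)
  dmat <- as.matrix(stats::dist(sm[, c("cx", "cy")]))
  restore <- local_rng((cfg$seed + 1L) %% .Machine$integer.max)
  on.exit(restore())
  rows <- list()
  params <- list()
  dropped <- 0L
  for (s in seq_len(cfg$n_nonendemic)) {
    ok <- FALSE
    for (try in 1:20) {
      origin <- sample.int(n_eco, 1L)
      opt <- sm$mean_temp[origin] + stats::rnorm(1L, 0, 1)
      match_clim <- exp(-(sm$mean_temp - opt)^2 / (2 * cfg$climate_sd^2))
      pocc <- cfg$occupancy_baseline * match_clim *
        exp(-cfg$distance_decay_rate * dmat[origin, ])
      pres <- stats::runif(n_eco) < pocc
      pres[origin] <- TRUE
      if (any(pres)) { ok <- TRUE; break }
    }
    if (!ok) { dropped <- dropped + 1L; next }
    nm <- sprintf("ne%04d", s)
    rows[[nm]] <- pres
    params[[nm]] <- data.frame(taxon = nm, guild = "nonendemic",
                               origin = ids[origin], climate_opt = opt,
                               elev_centre = NA_real_,
                               substrate = NA_character_)
  }
  elev_rng <- range(sm$mean_elev)
  lith_pool <- colnames(lith_m)
  lith_w <- colSums(lith_m)
  for (s in seq_len(cfg$n_endemic)) {
    ok <- FALSE
    for (try in 1:20) {
      centre <- stats::runif(1L, elev_rng[1L], elev_rng[2L])
      cat_s <- sample(lith_pool, 1L, prob = lith_w)
      in_window <- abs(sm$mean_elev - centre) <= cfg$endemic_elev_window
      has_lith <- lith_m[, cat_s] >= cfg$lith_presence_min
      pocc <- ifelse(in_window,
                     cfg$occupancy_baseline *
                       ifelse(has_lith, 1, 1 - cfg$lithology_fidelity),
                     0)
      pres <- stats::runif(n_eco) < pocc
      if (any(pres)) { ok <- TRUE; break }
    }
    if (!ok) { dropped <- dropped + 1L; next }
    nm <- sprintf("en%04d", s)
    rows[[nm]] <- pres
    params[[nm]] <- data.frame(taxon = nm, guild = "endemic",
                               origin = NA_character_,
                               climate_opt = NA_real_,
                               elev_centre = centre, substrate = cat_s)
  }
  if (dropped > 0L)
    warning(dropped, " species had no feasible ecoregion after 20 ",
            "retries and were dropped")
  inc <- do.call(rbind, rows)
  colnames(inc) <- ids
  flags <- ifelse(grepl("^en", rownames(inc)), "endemic", "nonendemic")
  # range classes from realised presences vs the in_baetic flags
  baetic <- landscape$info$in_baetic[match(ids, landscape$info$id)]
  rc <- rep(NA_character_, nrow(inc))
  endem <- flags == "endemic"
  in_b <- inc[, baetic, drop = FALSE]
  in_r <- inc[, !baetic, drop = FALSE]
  rc[endem] <- ifelse(rowSums(in_b[endem, , drop = FALSE]) > 0,
                      ifelse(rowSums(in_r[endem, , drop = FALSE]) > 0,
                             "both", "baetic_only"),
                      "rifan_only")
  occ <- occurrence_matrix(inc, flags, rc)
  truth <- list(
    endemic_driver = if (cfg$lithology_fidelity >= 0.5)
      c("lithology", "elevation") else "elevation",
    nonendemic_driver = if (cfg$distance_decay_rate == 0) "climate"
      else if (cfg$climate_sd >= 10) "geography"
      else "climate+geography",
    species = do.call(rbind, params))
  list(occ = occ, truth = truth)
}

#' Write a full synthetic dataset to delimited-text files
#'
#' Runs [generate_landscape()] and [generate_flora()] and writes the
#' four inputs the analysis readers consume: `occurrence.tsv`,
#' `cells.tsv`, `grid.tsv`, `ecoregions.tsv` plus
#' `lithology_surfaces.tsv`.
#'
#' @param cfg a `scenario_config`.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths.
#' @export
simulate_dataset <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  land <- generate_landscape(cfg)
  flora <- generate_flora(cfg, land)
  paths <- c(
    occurrence = file.path(dir, "occurrence.tsv"),
    cells = file.path(dir, "cells.tsv"),
    grid = file.path(dir, "grid.tsv"),
    ecoregions = file.path(dir, "ecoregions.tsv"),
    surfaces = file.path(dir, "lithology_surfaces.tsv"))
  write_occurrence_matrix(flora$occ, paths["occurrence"])
  utils::write.table(land$cells, paths["cells"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(land$grid, paths["grid"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(land$info, paths["ecoregions"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(land$surfaces, paths["surfaces"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
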