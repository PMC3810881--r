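#' Per-cell monthly climate tables
#'
#' A monthly cell table has one row per 1-km2 cell with its ecoregion
#' id, elevation, and 12-month series of mean, maximum and minimum
#' temperature (degrees C) and total precipitation (mm), in columns
#' `ecoregion, elev_m, tmean_01..tmean_12, tmax_01..tmax_12,
#' tmin_01..tmin_12, prec_01..prec_12`. Per cell and month, max >= mean
#' >= min is enforced.
#'
#' @param path file path.
#' @return a validated data.frame.
#' @export
read_monthly_cells <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(ecoregion = "character"))
  validate_monthly_cells(df)
}

month_cols <- function(prefix) sprintf("%s_%02d", prefix, 1:12)

validate_monthly_cells <- function(df) {
  need <- c("ecoregion", "elev_m", month_cols("tmean"),
            month_cols("tmax"), month_cols("tmin"), month_cols("prec"))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("monthly cell table lacks columns: ",
         paste(miss, collapse = ", "))
  df$ecoregion <- as.character(df$ecoregion)
  if (anyNA(df[need])) stop("monthly cell table has missing values")
  tmx <- as.matrix(df[month_cols("tmax")])
  tmn <- as.matrix(df[month_cols("tmean")])
  tmi <- as.matrix(df[month_cols("tmin")])
  if (any(tmx < tmn - 1e-9) || any(tmn < tmi - 1e-9))
    stop("monthly temperatures violate max >= mean >= min")
  df
}

#' Environmental variable codes
#'
#' The 22 climatic/altitudinal variables: codes 1-18 are temperature and
#' precipitation summaries of the ecoregion's 12-month series, E1-E4 are
#' elevation summaries over its cells.
#'
#' @format character vectors of column names.
#' @export
climatic_codes <- as.character(1:18)

#' @rdname climatic_codes
#' @export
altitudinal_codes <- c("E1", "E2", "E3", "E4")

# Mean over a 3-consecutive-month window (with Dec -> Jan wrap-around)
# chosen to minimise/maximise the window criterion; ties go to the
# earliest starting month.
quarter_stat <- function(series, criterion = series, which = c("min", "max")) {
  which <- match.arg(which)
  idx <- vapply(1:12, function(s) (s + 0:2 - 1L) %% 12L + 1L,
                integer(3L))
  crit <- colSums(matrix(criterion[idx], nrow = 3L))
  s <- if (which == "min") which.min(crit) else which.max(crit)
  mean(series[idx[, s]])
}

#' Build the 22-variable environmental table from per-cell monthly data
#'
#' Per ecoregion, monthly series are first averaged over cells
#' (unweighted: every cell is 1 km2), then summarised into 22 variables:
#' annual mean/SD/range of monthly mean temperature (1-3), annual
#' total/SD/range of monthly precipitation (4-6), mean/SD of monthly
#' maximum (7-8) and minimum (9-10) temperature, precipitation of
#' driest/wettest month (11-12), maximum temperature of the warmest
#' month and minimum of the coldest (13-14), mean precipitation of the
#' driest/wettest annual quarter (15-16), mean temperature of the
#' coldest/warmest quarter (17-18), and mean/max/min/SD of cell
#' elevation (E1-E4). A quarter is any 3 consecutive calendar months
#' with December-to-January wrap-around. All SDs use the n-1
#' denominator; a single-cell ecoregion has E4 = 0.
#'
#' @param cells a monthly cell table (see [read_monthly_cells()]).
#' @return data.frame with an `ecoregion` column and the 22 variables,
#'   one row per ecoregion (first-appearance order).
#' @export
build_env_table <- function(cells) {
  cells <- validate_monthly_cells(cells)
  ids <- unique(cells$ecoregion)
  rows <- lapply(ids, function(id) {
    sub <- cells[cells$ecoregion == id, , drop = FALSE]
    tmean <- colMeans(sub[month_cols("tmean")])
    tmax <- colMeans(sub[month_cols("tmax")])
    tmin <- colMeans(sub[month_cols("tmin")])
    prec <- colMeans(sub[month_cols("prec")])
    elev <- sub$elev_m
    data.frame(
      ecoregion = id,
      `1` = mean(tmean), `2` = stats::sd(tmean),
      `3` = max(tmean) - min(tmean),
      `4` = sum(prec), `5` = stats::sd(prec),
      `6` = max(prec) - min(prec),
      `7` = mean(tmax), `8` = stats::sd(tmax),
      `9` = mean(tmin), `10` = stats::sd(tmin),
      `11` = min(prec), `12` = max(prec),
      `13` = max(tmax), `14` = min(tmin),
      `15` = quarter_stat(prec, prec, "min"),
      `16` = quarter_stat(prec, prec, "max"),
      `17` = quarter_stat(tmean, tmean, "min"),
      `18` = quarter_stat(tmean, tmean, "max"),
      E1 = mean(elev), E2 = max(elev), E3 = min(elev),
      E4 = if (length(elev) > 1L) stats::sd(elev) else 0,
      check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$ecoregion
  out
}

env_values <- function(env, codes) {
  codes <- as.character(codes)
  miss <- setdiff(codes, names(env))
  if (length(miss))
    stop("environmental table lacks variables: ",
         paste(miss, collapse = ", "))
  m <- as.matrix(env[, codes, drop = FALSE])
  rownames(m) <- env$ecoregion
  m
}

#' Build a lithology composition table from substrate surface areas
#'
#' Converts an ecoregion-by-substrate-category table of surface areas
#' (km2) into relative surface fractions: rows are normalised to sum to
#' 1 and the category set is completed to the union over ecoregions
#' (absent categories get fraction 0).
#'
#' @param surfaces data.frame with an `ecoregion` column and one
#'   non-negative area column per substrate category, or a numeric
#'   matrix with ecoregion rownames.
#' @return data.frame with `ecoregion` plus one fraction column per
#'   category; each row sums to 1.
#' @export
build_lithology_table <- function(surfaces) {
  if (is.data.frame(surfaces) && "ecoregion" %in% names(surfaces)) {
    ids <- as.character(surfaces$ecoregion)
    m <- as.matrix(surfaces[, setdiff(names(surfaces), "ecoregion"),
                            drop = FALSE])
    rownames(m) <- ids
  } else {
    m <- as.matrix(surfaces)
    if (is.null(rownames(m))) stop("surfaces need ecoregion labels")
  }
  if (any(m < 0)) stop("negative substrate surface area")
  tot <- rowSums(m)
  if (any(tot <= 0))
    stop("ecoregion with zero total substrate surface: ",
         rownames(m)[tot <= 0][1L])
  frac <- sweep(m, 1L, tot, "/")
  data.frame(ecoregion = rownames(m), frac, check.names = FALSE,
             row.names = rownames(m))
}

#' @rdname build_lithology_table
#' @param path file path for the delimited-text form (categories as
#'   columns, `ecoregion` id column).
#' @export
read_lithology_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = c(ecoregion = "character"))
  frac <- as.matrix(df[, setdiff(names(df), "ecoregion"), drop = FALSE])
  if (any(frac < 0)) stop("negative lithology fraction")
  if (any(abs(rowSums(frac) - 1) > 1e-9))
    stop("lithology fractions do not sum to 1")
  rownames(df) <- df$ecoregion
  df
}

#' @rdname build_lithology_table
#' @param lith a lithology table.
#' @export
write_lithology_table <- function(lith, path) {
  utils::write.table(lith, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

lithology_values <- function(lith) {
  m <- as.matrix(lith[, setdiff(names(lith), "ecoregion"), drop = FALSE])
  rownames(m) <- lith$ecoregion
  m
}
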