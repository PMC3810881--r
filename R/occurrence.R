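#' Taxon-by-ecoregion occurrence matrices
#'
#' The floristic data model: a boolean incidence matrix with taxa as rows
#' and ecoregions as columns, plus a per-taxon `range_flag`
#' (`"endemic"` or `"nonendemic"`) and, for endemic taxa, an optional
#' `range_class` (`"baetic_only"`, `"rifan_only"` or `"both"`) recording
#' which mountain range the taxon is confined to.
#'
#' @param incidence logical (or 0/1) taxon-by-ecoregion matrix with
#'   unique row and column names.
#' @param range_flag character vector, one of `"endemic"`/`"nonendemic"`
#'   per taxon.
#' @param range_class optional character vector; required to be non-NA
#'   for every endemic taxon when supplied.
#' @param allow_empty_taxa keep all-absent taxa (permitted only for raw
#'   input straight from file; validated objects drop them).
#' @return an object of class `occurrence_matrix` with elements
#'   `incidence`, `taxa`, `ecoregions`, `range_flag`, `range_class`.
#' @export
occurrence_matrix <- function(incidence, range_flag, range_class = NULL,
                              allow_empty_taxa = FALSE) {
  incidence <- as.matrix(incidence)
  taxa <- if (nrow(incidence) == 0L) character(0)  # empty element
          else rownames(incidence)
  ecoregions <- colnames(incidence)
  if (is.null(taxa) || is.null(ecoregions))
    stop("incidence must have taxon rownames and ecoregion colnames")
  if (anyDuplicated(taxa))
    stop("duplicate taxon identifier: ", taxa[duplicated(taxa)][1L])
  if (anyDuplicated(ecoregions))
    stop("duplicate ecoregion identifier: ",
         ecoregions[duplicated(ecoregions)][1L])
  if (!is.logical(incidence)) {
    if (!all(incidence %in% c(0, 1))) {
      bad <- which(!(incidence %in% c(0, 1)), arr.ind = TRUE)[1L, ]
      stop(sprintf("non-binary incidence at taxon '%s', ecoregion '%s'",
                   taxa[bad[1L]], ecoregions[bad[2L]]))
    }
    incidence <- incidence == 1
  }
  if (anyNA(incidence)) stop("incidence contains missing values")
  range_flag <- as.character(range_flag)
  if (length(range_flag) != length(taxa))
    stop("range_flag length does not match taxon count")
  if (anyNA(range_flag) || !all(range_flag %in% c("endemic", "nonendemic"))) {
    bad <- taxa[is.na(range_flag) |
                  !range_flag %in% c("endemic", "nonendemic")][1L]
    stop("missing or invalid range_flag for taxon: ", bad)
  }
  names(range_flag) <- taxa
  if (!is.null(range_class)) {
    range_class <- as.character(range_class)
    if (length(range_class) != length(taxa))
      stop("range_class length does not match taxon count")
    names(range_class) <- taxa
    ok <- is.na(range_class) |
      range_class %in% c("baetic_only", "rifan_only", "both")
    if (!all(ok)) stop("invalid range_class for taxon: ", taxa[!ok][1L])
    miss <- range_flag == "endemic" & is.na(range_class)
    if (any(miss))
      stop("endemic taxon lacks a range_class: ", taxa[miss][1L])
  }
  empty <- rowSums(incidence) == 0L
  if (any(empty) && !allow_empty_taxa) {
    warning("dropping ", sum(empty),
            " taxa with no presences after validation")
    incidence <- incidence[!empty, , drop = FALSE]
    range_flag <- range_flag[!empty]
    if (!is.null(range_class)) range_class <- range_class[!empty]
    taxa <- rownames(incidence)
  }
  structure(list(incidence = incidence, taxa = taxa,
                 ecoregions = ecoregions, range_flag = range_flag,
                 range_class = range_class),
            class = "occurrence_matrix")
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat("occurrence_matrix:", length(x$taxa), "taxa x",
      length(x$ecoregions), "ecoregions (",
      sum(x$range_flag == "endemic"), "endemic,",
      sum(x$range_flag == "nonendemic"), "nonendemic )\n")
  invisible(x)
}

#' Read / write an occurrence table as delimited text
#'
#' The file has one row per taxon: a `taxon` identifier column, one 0/1
#' column per ecoregion, a `range_flag` column, and optional
#' `range_class` and `excluded` columns. Rows flagged `excluded` (any
#' truthy value) are dropped on read — upstream curation such as removal
#' of hybrids or doubtful records is represented by that flag, never by
#' taxonomic logic here. Row and column order are preserved.
#'
#' @param path file path.
#' @param sep field separator, tab by default.
#' @param allow_empty_taxa passed through to [occurrence_matrix()].
#' @return an `occurrence_matrix`.
#' @export
read_occurrence_matrix <- function(path, sep = "\t",
                                   allow_empty_taxa = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!"taxon" %in% names(df)) stop("missing 'taxon' column")
  if (!"range_flag" %in% names(df)) stop("missing 'range_flag' column")
  meta_cols <- intersect(c("taxon", "range_flag", "range_class",
                           "excluded"), names(df))
  eco_cols <- setdiff(names(df), meta_cols)
  if (!length(eco_cols)) stop("no ecoregion columns found")
  if ("excluded" %in% names(df)) {
    drop <- df$excluded %in% c("1", "TRUE", "true", "yes")
    df <- df[!drop, , drop = FALSE]
  }
  inc <- as.matrix(df[, eco_cols, drop = FALSE])
  bad <- which(!(inc %in% c("0", "1")))
  if (length(bad)) {
    pos <- arrayInd(bad[1L], dim(inc))
    stop(sprintf("non-binary cell at row %d (taxon '%s'), column '%s'",
                 pos[1L], df$taxon[pos[1L]], eco_cols[pos[2L]]))
  }
  inc <- matrix(inc == "1", nrow(inc), ncol(inc),
                dimnames = list(df$taxon, eco_cols))
  rc <- if ("range_class" %in% names(df)) {
    out <- df$range_class
    out[out %in% c("", "NA")] <- NA_character_
    out
  }
  occurrence_matrix(inc, df$range_flag, rc,
                    allow_empty_taxa = allow_empty_taxa)
}

#' @rdname read_occurrence_matrix
#' @param occ an `occurrence_matrix`.
#' @export
write_occurrence_matrix <- function(occ, path, sep = "\t") {
  df <- data.frame(taxon = occ$taxa,
                   as.data.frame(occ$incidence * 1L),
                   range_flag = occ$range_flag,
                   check.names = FALSE)
  if (!is.null(occ$range_class)) df$range_class <- occ$range_class
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Ecoregion metadata and cell-grid tables
#'
#' `read_ecoregion_info` expects columns
#' `id,name,region,in_hotspot,in_baetic,area_km2`; positive areas are
#' required and membership of the Baetic range implies membership of the
#' hotspot. `read_cell_grid` expects `x_km,y_km,ecoregion,elev_m`:
#' planar cell-centre coordinates in km (the 1-km2 gridding of the study
#' area), an ecoregion id per cell, and the cell elevation in m.
#'
#' @param path file path.
#' @return a validated data.frame.
#' @export
read_ecoregion_info <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(id = "character"))
  validate_ecoregion_info(df)
}

validate_ecoregion_info <- function(df) {
  need <- c("id", "name", "region", "in_hotspot", "in_baetic", "area_km2")
  if (!all(need %in% names(df)))
    stop("ecoregion info lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop("duplicate ecoregion id: ", df$id[duplicated(df$id)][1L])
  df$in_hotspot <- as.logical(df$in_hotspot)
  df$in_baetic <- as.logical(df$in_baetic)
  if (any(df$area_km2 <= 0)) stop("ecoregion area must be positive")
  if (any(df$in_baetic & !df$in_hotspot))
    stop("in_baetic implies in_hotspot; violated for ecoregion ",
         df$id[df$in_baetic & !df$in_hotspot][1L])
  df
}

#' @rdname read_ecoregion_info
#' @export
read_cell_grid <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(ecoregion = "character"))
  validate_cell_grid(df)
}

validate_cell_grid <- function(df) {
  need <- c("x_km", "y_km", "ecoregion", "elev_m")
  if (!all(need %in% names(df)))
    stop("cell grid lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$ecoregion <- as.character(df$ecoregion)
  if (anyNA(df[need])) stop("cell grid contains missing values")
  df
}

#' Merge ecoregions in an occurrence matrix
#'
#' Replaces a set of ecoregion columns by a single column holding their
#' element-wise union, in the position of the first merged column. The
#' analysis-unit analogue of merging small adjacent ecoregions with very
#' similar environments into one unit. Merging a single id acts as a
#' rename. Companion tables are relabelled consistently:
#' `merge_ecoregion_info` sums areas and ORs the flags;
#' `merge_cell_grid` reassigns cell memberships.
#'
#' @param occ an `occurrence_matrix`.
#' @param ids ecoregion ids to merge (all must exist).
#' @param new_id identifier of the merged ecoregion; must not collide
#'   with a remaining ecoregion.
#' @return an `occurrence_matrix` with the merged column.
#' @export
merge_ecoregions <- function(occ, ids, new_id) {
  ids <- as.character(ids)
  missing <- setdiff(ids, occ$ecoregions)
  if (length(missing))
    stop("unknown ecoregion id: ", paste(missing, collapse = ", "))
  keep <- setdiff(occ$ecoregions, ids)
  if (new_id %in% keep)
    stop("new_id '", new_id, "' collides with an existing ecoregion")
  merged <- rowSums(occ$incidence[, ids, drop = FALSE]) > 0L
  first <- match(ids[1L], occ$ecoregions)
  inc <- occ$incidence[, !(occ$ecoregions %in% ids), drop = FALSE]
  before <- sum(!(occ$ecoregions[seq_len(first - 1L)] %in% ids))
  inc <- cbind(inc[, seq_len(before), drop = FALSE],
               merged,
               inc[, setdiff(seq_len(ncol(inc)), seq_len(before)),
                   drop = FALSE])
  colnames(inc)[before + 1L] <- new_id
  occurrence_matrix(inc, occ$range_flag, occ$range_class,
                    allow_empty_taxa = TRUE)
}

#' @rdname merge_ecoregions
#' @param info ecoregion info data.frame (see [read_ecoregion_info()]).
#' @export
merge_ecoregion_info <- function(info, ids, new_id) {
  ids <- as.character(ids)
  if (!all(ids %in% info$id)) stop("unknown ecoregion id in merge")
  sel <- info$id %in% ids
  merged <- info[which(sel)[1L], , drop = FALSE]
  merged$id <- new_id
  merged$name <- paste(info$name[sel], collapse = "+")
  merged$area_km2 <- sum(info$area_km2[sel])
  merged$in_hotspot <- any(info$in_hotspot[sel])
  merged$in_baetic <- any(info$in_baetic[sel])
  out <- rbind(info[!sel, , drop = FALSE], merged)
  validate_ecoregion_info(out[order(match(out$id, c(info$id, new_id))), ,
                              drop = FALSE])
}

#' @rdname merge_ecoregions
#' @param grid cell grid data.frame (see [read_cell_grid()]).
#' @export
merge_cell_grid <- function(grid, ids, new_id) {
  grid$ecoregion[grid$ecoregion %in% as.character(ids)] <- new_id
  grid
}

#' Split a flora into its endemic and nonendemic elements
#'
#' Partitions the taxa by `range_flag` into the endemic element (taxa
#' confined to the hotspot) and the nonendemic element (all other native
#' taxa). Ecoregion order is identical in both outputs and the partition
#' is exhaustive and disjoint.
#'
#' @param occ an `occurrence_matrix`.
#' @return list with `occurrence_matrix` elements `endemic` and
#'   `nonendemic`.
#' @export
split_by_endemism <- function(occ) {
  take <- function(sel) {
    occurrence_matrix(occ$incidence[sel, , drop = FALSE],
                      occ$range_flag[sel],
                      if (!is.null(occ$range_class)) occ$range_class[sel],
                      allow_empty_taxa = TRUE)
  }
  list(endemic = take(occ$range_flag == "endemic"),
       nonendemic = take(occ$range_flag == "nonendemic"))
}

#' Select high-elevation ecoregions from a cell grid
#'
#' Implements the mountain-subset rule: an ecoregion is retained when a
#' non-negligible fraction of its cells lies above `upper_m` AND no more
#' than `max_frac_below` of its cells lies below `lower_m`. The verbal
#' criteria ("no significant fraction above 1500 m", "most of the
#' surface below 500 m") are quantified by the default cutoffs, exposed
#' as parameters.
#'
#' @param grid cell grid data.frame.
#' @param upper_m,lower_m elevation thresholds in m.
#' @param min_frac_above minimum fraction of cells above `upper_m`.
#' @param max_frac_below maximum tolerated fraction below `lower_m`.
#' @return character vector of retained ecoregion ids (input order).
#' @export
filter_high_elevation <- function(grid, upper_m = 1500, lower_m = 500,
                                  min_frac_above = 0.05,
                                  max_frac_below = 0.5) {
  stopifnot(upper_m > 0, lower_m > 0,
            min_frac_above >= 0, min_frac_above <= 1,
            max_frac_below >= 0, max_frac_below <= 1)
  grid <- validate_cell_grid(grid)
  ids <- unique(grid$ecoregion)
  keep <- vapply(ids, function(id) {
    elev <- grid$elev_m[grid$ecoregion == id]
    if (!length(elev)) stop("ecoregion with no cells: ", id)
    mean(elev > upper_m) >= min_frac_above &&
      mean(elev < lower_m) <= max_frac_below
  }, logical(1L))
  ids[keep]
}

#' Summarize a floristic pool
#'
#' Reports, for a flora and its ecoregion metadata: the total taxon
#' count; the count and percentage (nearest integer) of taxa present in
#' at least one hotspot ecoregion; the endemic count and its percentage
#' of the hotspot pool (one decimal); and, when range classes are
#' available, the per-class endemic counts.
#'
#' @param occ an `occurrence_matrix`.
#' @param info ecoregion info data.frame with `in_hotspot` flags.
#' @return list of counts and percentages.
#' @export
summarize_pool <- function(occ, info) {
  info <- validate_ecoregion_info(info)
  hot <- info$id[info$in_hotspot]
  missing <- setdiff(occ$ecoregions, info$id)
  if (length(missing))
    stop("ecoregions missing from info: ",
         paste(missing, collapse = ", "))
  hot_cols <- intersect(occ$ecoregions, hot)
  in_hot <- rowSums(occ$incidence[, hot_cols, drop = FALSE]) > 0L
  n_total <- length(occ$taxa)
  n_hot <- sum(in_hot)
  n_end <- sum(in_hot & occ$range_flag == "endemic")
  out <- list(
    n_taxa = n_total,
    n_hotspot = n_hot,
    hotspot_pct = round(100 * n_hot / n_total),
    n_endemic = n_end,
    n_nonendemic = n_hot - n_end,
    endemic_pct = round(100 * n_end / n_hot, 1L))
  if (!is.null(occ$range_class)) {
    cls <- occ$range_class[in_hot & occ$range_flag == "endemic"]
    out$range_class_counts <- table(factor(
      cls, levels = c("baetic_only", "rifan_only", "both")))
  }
  out
}
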