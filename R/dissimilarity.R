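#' Sorensen dissimilarity between ecoregion assemblages
#'
#' For each pair of ecoregions with a shared taxa and b, c taxa unique
#' to either, the dissimilarity is 1 - 2a / (2a + b + c), i.e. one minus
#' the Sorensen similarity of the two presence/absence assemblages.
#' Values lie in [0, 1]: 0 for identical assemblages, 1 for disjoint
#' ones. Every ecoregion must hold at least one taxon — the index is
#' undefined for empty assemblages.
#'
#' @param occ an `occurrence_matrix` (any floristic element).
#' @return a `distance_matrix` over the ecoregions.
#' @export
sorensen_matrix <- function(occ) {
  inc <- occ$incidence
  empty <- colSums(inc) == 0L
  if (any(empty))
    stop("empty ecoregion assemblage: ",
         paste(colnames(inc)[empty], collapse = ", "))
  x <- inc * 1
  shared <- crossprod(x)                   # a
  rich <- colSums(x)                       # a + b per column
  denom <- outer(rich, rich, "+")          # 2a + b + c
  d <- 1 - 2 * shared / denom
  diag(d) <- 0
  d <- (d + t(d)) / 2
  distance_matrix(d, colnames(inc))
}

#' Bray-Curtis dissimilarity between lithology compositions
#'
#' D(i, j) = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk) over the relative
#' surface fractions of the substrate categories; 0 for identical
#' composition, 1 when no category is shared.
#'
#' @param lith a lithology table (see [build_lithology_table()]).
#' @return a `distance_matrix` over the ecoregions.
#' @export
braycurtis_matrix <- function(lith) {
  m <- lithology_values(lith)
  if (any(m < 0)) stop("negative lithology fraction")
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <-
      sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  }
  distance_matrix(d, rownames(m))
}

#' Standardized Euclidean distance on environmental variable subsets
#'
#' Each selected variable is standardized to zero mean and unit SD
#' (n - 1 denominator) across exactly the ecoregions present in `env` —
#' analyses restricted to a subset of ecoregions therefore standardize
#' over that subset only — and pairwise Euclidean distances are taken on
#' the standardized values. Distances are invariant to affine rescaling
#' of any raw variable.
#'
#' @param env environmental table (see [build_env_table()]).
#' @param subset character vector of variable codes to use.
#' @return a `distance_matrix` over the ecoregions of `env`.
#' @export
euclidean_env_matrix <- function(env, subset) {
  if (!length(subset)) stop("empty variable subset")
  m <- env_values(env, subset)
  if (nrow(m) < 2L) stop("need at least 2 ecoregions")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance variable in subset: ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  z <- scale(m)
  d <- as.matrix(stats::dist(z))
  distance_matrix(d, rownames(m))
}

#' Geographic distance between ecoregions from their cell grids
#'
#' Ecoregions are irregular shapes, so a single point location
#' misrepresents their separation. Instead the distance between two
#' ecoregions is the mean planar Euclidean distance over all pairs of
#' 1-km2 cell centres, one cell from each ecoregion — the mean of the
#' distribution of constituent cell-pair distances (a median summary is
#' available). With many cells the exact mean is O(n m) per pair;
#' `method = "subsample"` instead draws a seeded random subset of cells
#' per ecoregion, trading a documented Monte-Carlo error for speed.
#'
#' @param grid cell grid data.frame (see [read_cell_grid()]).
#' @param method `"exact"` (all cross pairs) or `"subsample"`.
#' @param subsample_size cells drawn per ecoregion when subsampling
#'   (without replacement, capped at the cell count).
#' @param seed integer seed for the subsample draw.
#' @param summary `"mean"` (default) or `"median"` of the cell-pair
#'   distance distribution.
#' @return a `distance_matrix` over the ecoregions (diagonal 0).
#' @export
geographic_distance_matrix <- function(grid,
                                       method = c("exact", "subsample"),
                                       subsample_size = 100L,
                                       seed = NULL,
                                       summary = c("mean", "median")) {
  method <- match.arg(method)
  summary <- match.arg(summary)
  grid <- validate_cell_grid(grid)
  ids <- unique(grid$ecoregion)
  coords <- lapply(ids, function(id)
    as.matrix(grid[grid$ecoregion == id, c("x_km", "y_km")]))
  names(coords) <- ids
  if (method == "subsample") {
    if (subsample_size < 1L) stop("subsample_size must be >= 1")
    rng <- local_rng(seed)
    coords <- lapply(coords, function(xy) {
      if (nrow(xy) <= subsample_size) return(xy)
      xy[sample(nrow(xy), subsample_size), , drop = FALSE]
    })
    rng()
  }
  stat <- if (summary == "mean") mean else stats::median
  n <- length(ids)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- coords[[i]]; b <- coords[[j]]
    dx <- outer(a[, 1L], b[, 1L], "-")
    dy <- outer(a[, 2L], b[, 2L], "-")
    d[i, j] <- d[j, i] <- stat(sqrt(dx * dx + dy * dy))
  }
  distance_matrix(d, ids)
}

# Seed-scoped RNG helper: sets the seed if given and returns a restorer
# for the caller's random state, so seeded package functions never leak
# global RNG changes. With seed = NULL the global stream is used as-is
# and the restorer is a no-op.
local_rng <- function(seed) {
  if (is.null(seed)) return(function() invisible(NULL))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}
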