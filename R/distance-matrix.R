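#' Labelled symmetric distance matrices
#'
#' All dissimilarity constructors in the package return a
#' `distance_matrix`: a square numeric matrix with identical, unique row
#' and column labels, a zero diagonal, non-negative entries, and symmetry
#' enforced to within 1e-12. It is the common currency passed between the
#' dissimilarity, clustering, ordination and matrix-regression stages.
#'
#' @param values square numeric matrix of non-negative dissimilarities.
#' @param labels character vector of unit labels; defaults to the
#'   rownames of `values`.
#' @return an object of class `distance_matrix` (a labelled matrix).
#' @export
distance_matrix <- function(values, labels = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(labels)) stop("distance_matrix requires labels")
  labels <- as.character(labels)
  if (nrow(values) != ncol(values))
    stop("distance_matrix values must be square")
  if (length(labels) != nrow(values))
    stop("label length does not match matrix dimension")
  if (anyDuplicated(labels))
    stop("duplicate labels: ", labels[duplicated(labels)][1L])
  storage.mode(values) <- "double"
  dimnames(values) <- list(labels, labels)
  validate_distance_matrix(values)
  structure(values, class = c("distance_matrix", "matrix", "array"))
}

validate_distance_matrix <- function(values) {
  if (anyNA(values)) stop("distance matrix contains NA/NaN")
  if (any(values < 0)) stop("distance matrix has negative entries")
  if (max(abs(values - t(values))) > 1e-12)
    stop("distance matrix is not symmetric within 1e-12")
  if (any(abs(diag(values)) > 1e-12))
    stop("distance matrix diagonal is not zero")
  invisible(values)
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("distance_matrix over", nrow(x), "units:",
      paste(utils::head(rownames(x), 5L), collapse = ", "),
      if (nrow(x) > 5L) "..." else "", "\n")
  print(unclass(x), ...)
  invisible(x)
}

dm_labels <- function(d) rownames(d)

#' Strictly-upper-triangle vector of a distance matrix
#'
#' Unfolds the n(n-1)/2 off-diagonal entries in column-major order of the
#' upper triangle; the same unfolding is used everywhere (BIO-ENV
#' correlations, matrix regressions), so entries of different matrices
#' with matching labels align pair-for-pair.
#'
#' @param d a `distance_matrix`.
#' @return numeric vector of length n(n-1)/2.
#' @export
upper_vec <- function(d) {
  m <- as.matrix(d)
  m[upper.tri(m)]
}

#' Write / read a distance matrix as labelled square TSV
#'
#' The text form is a square tab-separated table with unit labels as both
#' header and first column. The reader re-validates symmetry, zero
#' diagonal and non-negativity, so files edited by hand cannot smuggle an
#' invalid matrix into an analysis.
#'
#' @param d a `distance_matrix`.
#' @param path file path.
#' @return `read_distance_matrix` returns a `distance_matrix`;
#'   `write_distance_matrix` returns `path` invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(label = rownames(d), as.data.frame(unclass(d)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(label = "character"))
  labs <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!identical(colnames(m), labs))
    stop("distance matrix file has mismatched row and column labels")
  distance_matrix(m, labs)
}

#' Restrict a distance matrix to a subset of its labels
#'
#' @param d a `distance_matrix`.
#' @param labels labels to keep, in the order given.
#' @return the sub-`distance_matrix`.
#' @export
subset_distance_matrix <- function(d, labels) {
  missing <- setdiff(labels, rownames(d))
  if (length(missing))
    stop("labels not in distance matrix: ",
         paste(missing, collapse = ", "))
  distance_matrix(unclass(d)[labels, labels, drop = FALSE], labels)
}
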