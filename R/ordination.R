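#' UPGMA hierarchical clustering of a distance matrix
#'
#' Classic unweighted pair-group average-linkage agglomeration:
#' repeatedly merge the pair of clusters with the smallest average
#' inter-cluster distance, record that average as the merge height, and
#' update distances to the merged cluster as the size-weighted mean of
#' its parts (so the height is always the plain average over all
#' original leaf pairs). The result is an ultrametric rooted dendrogram.
#' Ties are broken deterministically: among minimal pairs, the pair
#' whose (alphabetically smallest-leaf) representatives sort first wins.
#'
#' @param d a `distance_matrix` with at least 2 labels.
#' @return an `upgma_tree`: list with `labels`, hclust-style `merge`
#'   and `height`, and `edges` — one entry per internal node giving its
#'   sorted leaf set (the clade identity used for bootstrap support).
#' @export
upgma <- function(d) {
  if (anyNA(d)) stop("NaN in distance matrix")
  labs <- dm_labels(d)
  n <- length(labs)
  if (n < 2L) stop("need at least 2 labels")
  dm <- unclass(as.matrix(d))
  active <- seq_len(n)                 # current cluster ids
  id <- -seq_len(n)                    # hclust code per cluster
  size <- rep(1L, n)
  rep_leaf <- labs                     # smallest leaf label per cluster
  leafset <- as.list(labs)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  edges <- vector("list", n - 1L)
  cur <- dm
  for (step in seq_len(n - 1L)) {
    m <- length(active)
    best <- NULL
    bestd <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      dij <- cur[i, j]
      if (dij < bestd - 1e-12) {
        bestd <- dij; best <- c(i, j)
      } else if (abs(dij - bestd) <= 1e-12) {
        key_new <- sort(c(rep_leaf[i], rep_leaf[j]))
        key_old <- sort(c(rep_leaf[best[1L]], rep_leaf[best[2L]]))
        if (key_new[1L] < key_old[1L] ||
            (key_new[1L] == key_old[1L] && key_new[2L] < key_old[2L])) {
          bestd <- dij; best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    merge[step, ] <- c(id[i], id[j])
    height[step] <- cur[i, j]
    newset <- sort(c(leafset[[i]], leafset[[j]]))
    edges[[step]] <- newset
    # weighted update = unweighted average over original leaves
    ni <- size[i]; nj <- size[j]
    newrow <- (ni * cur[i, ] + nj * cur[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(m), c(i, j))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], newrow[keep]),
                 c(newrow[keep], 0))
    id <- c(id[keep], step)
    size <- c(size[keep], ni + nj)
    rep_leaf <- c(rep_leaf[keep], min(rep_leaf[c(i, j)]))
    leafset <- c(leafset[keep], list(newset))
    active <- seq_along(id)
  }
  structure(list(labels = labs, merge = merge, height = height,
                 edges = edges),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA dendrogram over", length(x$labels), "leaves; root height",
      format(max(x$height), digits = 4), "\n")
  if (!is.null(x$au))
    cat("with multiscale-bootstrap AU/BP support on",
        length(x$au), "edges\n")
  invisible(x)
}

#' Convert an UPGMA tree to base/ape representations
#'
#' `as.hclust` gives the standard hclust object (merge heights are the
#' UPGMA average distances); `as_phylo` the ape phylogeny, with node
#' labels `"AU|BP"` in percent when bootstrap support is attached.
#'
#' @param x an `upgma_tree`.
#' @param ... unused.
#' @return an `hclust` / `phylo` object.
#' @export
as.hclust.upgma_tree <- function(x, ...) {
  n <- length(x$labels)
  ord <- integer(0)
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(x$merge[node, 1L]), walk(x$merge[node, 2L]))
  }
  ord <- walk(n - 1L)
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = NULL),
            class = "hclust")
}

#' @rdname as.hclust.upgma_tree
#' @export
as_phylo <- function(x) {
  phy <- ape::as.phylo(as.hclust.upgma_tree(x))
  if (!is.null(x$au)) {
    # map internal merge nodes to phylo node numbers via clade leaf sets
    lab <- rep("", phy$Nnode)
    for (k in seq_along(x$edges)) {
      tips <- match(x$edges[[k]], phy$tip.label)
      node <- ape::getMRCA(phy, tips)
      if (!is.null(node))
        lab[node - length(phy$tip.label)] <-
          sprintf("%.0f|%.0f", 100 * x$au[k], 100 * x$bp[k])
    }
    phy$node.label <- lab
  }
  phy
}

#' @rdname as.hclust.upgma_tree
#' @param path file path for the Newick export.
#' @export
write_newick <- function(x, path) {
  ape::write.tree(as_phylo(x), file = path)
  invisible(path)
}

#' Cophenetic distances of an UPGMA tree
#'
#' @param x an `upgma_tree`.
#' @return a `distance_matrix` of cophenetic (merge-height) distances.
#' @export
cophenetic_matrix <- function(x) {
  co <- as.matrix(stats::cophenetic(as.hclust.upgma_tree(x)))
  labs <- x$labels
  distance_matrix(co[labs, labs], labs)
}

# --- correspondence analysis -----------------------------------------

ca_core <- function(inc) {
  N <- inc * 1
  if (any(rowSums(N) == 0) || any(colSums(N) == 0))
    stop("correspondence analysis requires no empty rows or columns")
  if (ncol(N) < 2L)
    stop("degenerate table: need at least 2 ecoregions")
  tot <- sum(N)
  P <- N / tot
  r <- rowSums(P)
  c_ <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, c_)) %*% diag(1 / sqrt(c_))
  sv <- svd(S)
  keep <- which(sv$d > 1e-10)
  keep <- keep[keep <= min(dim(N)) - 1L]  # drop trivial/null axes
  d <- sv$d[keep]
  # standard coordinates for sites (columns) and species (rows)
  site_std <- diag(1 / sqrt(c_)) %*% sv$v[, keep, drop = FALSE]
  sp_std <- diag(1 / sqrt(r)) %*% sv$u[, keep, drop = FALSE]
  rownames(site_std) <- colnames(N)
  rownames(sp_std) <- rownames(N)
  list(eig = d^2, site = site_std, species = sp_std, r = r, c = c_,
       N = N)
}

#' Correspondence analysis of an incidence table
#'
#' Chi-square-standardized singular value decomposition of the
#' taxon-by-ecoregion table. Site (ecoregion) scores are the standard
#' coordinates of the columns; eigenvalues (all <= 1) are the squared
#' singular values and measure the inertia of each axis.
#'
#' @param occ an `occurrence_matrix` without empty rows or columns.
#' @param naxes number of axes to return.
#' @return an `ordination_result`: list with `method`, `site_scores`,
#'   `species_scores`, `eig`.
#' @export
correspondence_analysis <- function(occ, naxes = 4L) {
  ca <- ca_core(occ$incidence)
  k <- min(naxes, length(ca$eig))
  structure(list(method = "CA",
                 site_scores = ca$site[, seq_len(k), drop = FALSE],
                 species_scores = ca$species[, seq_len(k), drop = FALSE],
                 eig = ca$eig[seq_len(k)]),
            class = "ordination_result")
}

# Segment-wise centering of y against the axis-1 ordering x: equal-width
# bins over the range of x, each non-empty bin centred to zero mean.
detrend_segments <- function(y, x, segments) {
  br <- seq(min(x), max(x), length.out = segments + 1L)
  bin <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  for (b in unique(bin)) {
    sel <- bin == b
    y[sel] <- y[sel] - mean(y[sel])
  }
  y
}

#' Detrended correspondence analysis (detrending by segments)
#'
#' Axis 1 is the first correspondence-analysis axis. The second axis is
#' obtained by reciprocal averaging in which, at every iteration, the
#' trial site scores are detrended against axis 1: the axis-1 range is
#' cut into `segments` equal-width bins and the axis-2 scores within
#' each bin are centred to zero mean. This removes the arch artefact of
#' plain CA. Hill's nonlinear rescaling of axis units is deliberately
#' not performed — the detrended configuration is used for qualitative
#' site scatter only, and the omission keeps the axis scores exactly
#' reproducible. `segments = "off"` disables detrending, reducing the
#' result to plain CA.
#'
#' @param occ an `occurrence_matrix`.
#' @param segments number of detrending segments (default 26), or
#'   `"off"`.
#' @param naxes axes to return (detrending applies to axis 2).
#' @param tol,max_iter convergence tolerance and iteration cap of the
#'   reciprocal-averaging loop.
#' @return an `ordination_result` with `method = "DCA"`.
#' @export
dca <- function(occ, segments = 26L, naxes = 2L, tol = 1e-10,
                max_iter = 999L) {
  if (identical(segments, "off")) {
    out <- correspondence_analysis(occ, naxes)
    out$method <- "DCA"
    out$segments <- "off"
    return(out)
  }
  segments <- as.integer(segments)
  if (segments < 2L) stop("segments must be >= 2 (or \"off\")")
  ca <- ca_core(occ$incidence)
  ax1 <- ca$site[, 1L]
  N <- ca$N
  rs <- rowSums(N)
  cs <- colSums(N)
  # reciprocal averaging for axis 2 with in-loop detrending
  x <- if (ncol(ca$site) >= 2L) ca$site[, 2L] else
    stats::rnorm(length(cs))  # unreachable for non-degenerate tables
  x <- detrend_segments(x, ax1, segments)
  ev <- 0
  for (it in seq_len(max_iter)) {
    u <- as.vector(N %*% x) / rs          # species scores
    xnew <- as.vector(crossprod(N, u)) / cs
    xnew <- xnew - sum(cs * xnew) / sum(cs)   # weighted centring
    xnew <- detrend_segments(xnew, ax1, segments)
    ev_new <- sqrt(sum(cs * xnew^2) / sum(cs))  # shrinkage estimate
    if (ev_new < 1e-12) { x <- xnew; ev <- 0; break }
    xnew <- xnew / ev_new
    if (max(abs(xnew - x)) < tol || max(abs(xnew + x)) < tol) {
      x <- xnew; ev <- ev_new; break
    }
    x <- xnew; ev <- ev_new
  }
  site <- cbind(ax1, x)
  colnames(site) <- c("DCA1", "DCA2")
  rownames(site) <- names(cs)
  eig <- c(ca$eig[1L], ev)
  u <- as.vector(N %*% x) / rs
  sp <- cbind(ca$species[, 1L], u)
  dimnames(sp) <- list(names(rs), c("DCA1", "DCA2"))
  structure(list(method = "DCA", site_scores = site,
                 species_scores = sp, eig = eig, segments = segments),
            class = "ordination_result")
}

#' Principal component analysis of environmental variables
#'
#' PCA on the correlation matrix (variables standardized first — the
#' table mixes mm, degrees C and m, so covariance-based axes would be
#' unit-driven). Loadings are unit-norm eigenvectors with the sign
#' convention that the largest-magnitude loading on each axis is
#' positive; scores are the standardized data projected on them.
#'
#' @param env environmental table.
#' @param codes variable codes to include.
#' @return an `ordination_result` with `loadings`, `site_scores`,
#'   `eig`, `variance_fraction`, `cumulative_variance`.
#' @export
pca_env <- function(env, codes) {
  m <- env_values(env, codes)
  if (ncol(m) < 2L) stop("need at least 2 variables")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance variable: ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  z <- scale(m)
  e <- eigen(stats::cor(m), symmetric = TRUE)
  load <- e$vectors
  for (k in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, k])), k] < 0)
      load[, k] <- -load[, k]
  }
  dimnames(load) <- list(colnames(m),
                         paste0("PC", seq_len(ncol(load))))
  scores <- z %*% load
  eig <- pmax(e$values, 0)
  structure(list(method = "PCA", loadings = load, site_scores = scores,
                 eig = eig,
                 variance_fraction = eig / sum(eig),
                 cumulative_variance = cumsum(eig) / sum(eig)),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(x$method, "ordination:", nrow(x$site_scores), "sites,",
      length(x$eig), "axes; eigenvalues",
      paste(format(x$eig, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

#' Write ordination scores and eigenvalues to TSV
#'
#' @param x an `ordination_result`.
#' @param path file path.
#' @export
write_ordination <- function(x, path) {
  df <- data.frame(site = rownames(x$site_scores), x$site_scores,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cat("# eigenvalues:", paste(format(x$eig, digits = 10),
                              collapse = "\t"), "\n",
      file = path, append = TRUE)
  invisible(path)
}
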