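#' Fit AU and BP support from per-scale bootstrap proportions
#'
#' The multiscale-bootstrap model for one dendrogram edge: at sampling
#' ratio r the bootstrap probability BP_r of the edge satisfies
#' qnorm(1 - BP_r) = v*sqrt(r) + c/sqrt(r), where v is the signed
#' distance of the data from the region boundary and c its curvature.
#' (v, c) are fitted by weighted least squares on the probit scale with
#' binomial weights B / (BP_r (1 - BP_r)); the approximately unbiased
#' p-value is then AU = 1 - pnorm(v - c) and the bias-corrected
#' ordinary bootstrap value BP = 1 - pnorm(v + c). Counts are clipped
#' to [0.5, B - 0.5] before the probit transform so edges seen in all
#' or no replicates remain finite.
#'
#' Degenerate cases degrade gracefully: with a single scale the model
#' is not identifiable and AU falls back to the observed BP (with a
#' warning); an edge whose counts are clipped at every scale reports
#' AU = BP = its clipped proportion at the scale closest to 1, flagged.
#'
#' @param counts integer vector: replicates containing the edge, per
#'   scale.
#' @param B integer vector (or scalar) of replicates per scale.
#' @param scales numeric vector of sampling ratios r.
#' @return list with `au`, `bp`, `v`, `c`, `flag` (TRUE when the fit
#'   was degenerate).
#' @export
au_fit <- function(counts, B, scales) {
  stopifnot(length(counts) == length(scales))
  B <- rep_len(B, length(scales))
  clipped <- pmin(pmax(counts, 0.5), B - 0.5)
  all_clipped <- all(counts <= 0 | counts >= B)
  bp_r <- clipped / B
  near1 <- which.min(abs(scales - 1))
  if (length(unique(scales)) < 2L) {
    warning("single bootstrap scale: AU not identifiable, using BP")
    return(list(au = bp_r[near1], bp = bp_r[near1], v = NA_real_,
                c = NA_real_, flag = TRUE))
  }
  if (all_clipped) {
    return(list(au = bp_r[near1], bp = bp_r[near1], v = NA_real_,
                c = NA_real_, flag = TRUE))
  }
  z <- stats::qnorm(1 - bp_r)
  w <- B / (bp_r * (1 - bp_r))
  X <- cbind(sqrt(scales), 1 / sqrt(scales))
  fit <- stats::lm.wfit(X, z, w)
  v <- unname(fit$coefficients[1L])
  cc <- unname(fit$coefficients[2L])
  list(au = 1 - stats::pnorm(v - cc), bp = 1 - stats::pnorm(v + cc),
       v = unname(v), c = unname(cc), flag = FALSE)
}

# Edge-occurrence table of a replicate tree: named logical over the
# reference edges. An edge is supported when some clade of the replicate
# has exactly the same leaf set; reference edges containing leaves
# absent from the replicate (ecoregions emptied by the draw) count as
# unsupported.
match_edges <- function(ref_edges, rep_tree) {
  rep_keys <- vapply(rep_tree$edges, paste, "", collapse = "\r")
  rep_leaves <- rep_tree$labels
  vapply(ref_edges, function(e) {
    if (!all(e %in% rep_leaves)) return(FALSE)
    paste(e, collapse = "\r") %in% rep_keys
  }, logical(1L))
}

#' UPGMA dendrogram with multiscale-bootstrap AU support
#'
#' Builds the reference tree upgma(sorensen_matrix(occ)), then assesses
#' the support of every internal edge (clade) by multiscale bootstrap
#' resampling of the taxa: at each sampling ratio r in `scales`, `B`
#' replicates draw round(r * T) taxa with replacement, the Sorensen
#' matrix and UPGMA tree of the resampled flora are recomputed, and the
#' fraction of replicate trees containing the clade is recorded.
#' [au_fit()] then extrapolates the per-scale proportions to the
#' approximately unbiased support AU of each edge. Ecoregions emptied
#' by a draw are dropped from that replicate's tree; reference clades
#' involving them count as unsupported in that replicate.
#'
#' @param occ an `occurrence_matrix`.
#' @param scales sampling ratios; must straddle 1.0. Default ten scales
#'   0.5..1.4.
#' @param B bootstrap replicates per scale (>= 100).
#' @param seed integer seed; the whole procedure is reproducible from
#'   it.
#' @return the reference `upgma_tree` with per-edge vectors `au`, `bp`,
#'   `bp_raw` (observed proportion at the scale nearest 1), `au_flag`,
#'   and a `bp_table` (edges x scales) of raw counts.
#' @export
multiscale_bootstrap <- function(occ, scales = seq(0.5, 1.4, by = 0.1),
                                 B = 100L, seed = 1L) {
  if (min(scales) >= 1 || max(scales) <= 1)
    if (length(unique(scales)) > 1L)
      stop("scales must straddle 1.0")
  if (B < 100L) stop("B must be >= 100")
  ref <- upgma(sorensen_matrix(occ))
  ref_edges <- ref$edges
  ntax <- length(occ$taxa)
  restore <- local_rng(seed)
  on.exit(restore())
  counts <- matrix(0L, length(ref_edges), length(scales),
                   dimnames = list(NULL, as.character(scales)))
  dropped_any <- FALSE
  for (si in seq_along(scales)) {
    m <- max(2L, round(scales[si] * ntax))
    for (b in seq_len(B)) {
      rows <- sample.int(ntax, m, replace = TRUE)
      inc <- occ$incidence[rows, , drop = FALSE]
      keep <- colSums(inc) > 0L
      if (!all(keep)) dropped_any <- TRUE
      inc <- inc[, keep, drop = FALSE]
      if (ncol(inc) < 2L) next
      rownames(inc) <- sprintf("r%d", seq_len(nrow(inc)))
      rep_occ <- occurrence_matrix(
        inc, rep("nonendemic", nrow(inc)), allow_empty_taxa = TRUE)
      rep_tree <- upgma(sorensen_matrix(rep_occ))
      counts[, si] <- counts[, si] + match_edges(ref_edges, rep_tree)
    }
  }
  if (dropped_any)
    message("some replicates emptied ecoregions; those ecoregions ",
            "were dropped from the affected replicate trees")
  fits <- lapply(seq_len(nrow(counts)),
                 function(i) au_fit(counts[i, ], B, scales))
  ref$au <- vapply(fits, `[[`, 0, "au")
  ref$bp <- vapply(fits, `[[`, 0, "bp")
  near1 <- which.min(abs(scales - 1))
  ref$bp_raw <- counts[, near1] / B
  ref$au_flag <- vapply(fits, `[[`, TRUE, "flag")
  ref$bp_table <- counts
  ref$scales <- scales
  ref$B <- B
  ref$seed <- seed
  ref
}
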