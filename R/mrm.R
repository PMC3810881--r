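#' Ordinary linear regression of alpha diversity on one predictor
#'
#' Simple OLS of per-ecoregion richness against one predictor (a
#' principal-component score, or ecoregion area), reported with the
#' adjusted R2 convention adj = 1 - (1 - R2)(n - 1)/(n - p - 1); pure
#' noise therefore yields values near (possibly below) zero, and the
#' output domain admits negative adjusted R2.
#'
#' @param alpha named numeric vector of per-ecoregion richness.
#' @param x named numeric vector of the predictor (same names).
#' @return an `lm_result`: list with `slope`, `intercept`, `r2`,
#'   `adj_r2`, `p_value` (F test), `n`.
#' @export
alpha_regression <- function(alpha, x) {
  if (!is.null(names(alpha)) && !is.null(names(x)))
    x <- x[names(alpha)]
  if (length(alpha) != length(x) || anyNA(x))
    stop("alpha and predictor must cover the same ecoregions")
  n <- length(alpha)
  if (n < 4L) stop("need at least 4 ecoregions")
  if (stats::sd(x) == 0) stop("constant predictor")
  fit <- stats::lm(alpha ~ x)
  sm <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
  p <- if (sm$r.squared >= 1 - 1e-12) 0 else
    stats::pf(sm$fstatistic[1L], sm$fstatistic[2L], sm$fstatistic[3L],
              lower.tail = FALSE)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
                 p_value = unname(p), n = n),
            class = "lm_result")
}

# Align a named list of distance matrices on common labels and unfold.
unfold_predictors <- function(response, predictors) {
  labs <- dm_labels(response)
  preds <- lapply(predictors, function(p) {
    if (!setequal(dm_labels(p), labs))
      stop("predictor labels do not match the response matrix")
    subset_distance_matrix(p, labs)
  })
  X <- vapply(preds, upper_vec, numeric(length(upper_vec(response))))
  colnames(X) <- names(predictors)
  X
}

r2_of <- function(y, X) {
  fit <- stats::lm.fit(cbind(1, X), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Multiple regression on distance matrices (MRM)
#'
#' Unfolds the strictly upper triangles of the response and predictor
#' distance matrices to vectors and fits OLS of the response
#' dissimilarities on the predictor distances. Because the n(n-1)/2
#' pairwise entries are not independent, no parametric p-values are
#' reported; significance comes from a matrix permutation null: the
#' response matrix's rows and columns are permuted together by a random
#' relabelling, the permuted matrix re-unfolded and the model refitted.
#' Two-sided coefficient p-values and a one-sided R2 p-value use the
#' +1/+1 rule, p = (1 + #(permuted statistic >= observed)) /
#' (nperm + 1), so the smallest attainable p is 1/(nperm + 1).
#'
#' @param response a `distance_matrix`.
#' @param predictors named list of `distance_matrix` objects over the
#'   same labels.
#' @param nperm number of permutations (>= 99).
#' @param seed integer seed.
#' @return an `mrm_result`: list with `coefficients` (data.frame of
#'   coefficient and permutation p per predictor, intercept p = NA),
#'   `r2`, `r2_p`, `nperm`, `seed`, `n` (number of units).
#' @export
mrm <- function(response, predictors, nperm = 999L, seed = 1L) {
  if (is.null(names(predictors)) || any(names(predictors) == ""))
    stop("predictors must be a named list")
  if (nperm < 99L) stop("nperm must be >= 99")
  labs <- dm_labels(response)
  y <- upper_vec(response)
  X <- unfold_predictors(response, predictors)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance predictor vector: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  if (kappa(cbind(1, scale(X)), exact = TRUE) > 1e8)
    stop("predictor distance matrices are (near-)collinear")
  fit <- stats::lm.fit(cbind(1, X), y)
  b_obs <- fit$coefficients
  r2_obs <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  m <- unclass(as.matrix(response))
  n <- length(labs)
  restore <- local_rng(seed)
  on.exit(restore())
  ge_b <- rep(0L, length(b_obs) - 1L)
  ge_r2 <- 0L
  for (k in seq_len(nperm)) {
    pidx <- sample.int(n)
    yp <- m[pidx, pidx][upper.tri(m)]
    pf <- stats::lm.fit(cbind(1, X), yp)
    bp <- pf$coefficients[-1L]
    ge_b <- ge_b + (abs(bp) >= abs(b_obs[-1L]) - 1e-12)
    r2p <- 1 - sum(pf$residuals^2) / sum((yp - mean(yp))^2)
    ge_r2 <- ge_r2 + (r2p >= r2_obs - 1e-12)
  }
  coefs <- data.frame(
    predictor = c("(Intercept)", colnames(X)),
    coefficient = unname(b_obs),
    p_value = c(NA_real_, (ge_b + 1) / (nperm + 1)),
    stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, r2 = r2_obs,
                 r2_p = (ge_r2 + 1) / (nperm + 1),
                 nperm = nperm, seed = seed, n = n),
            class = "mrm_result")
}

#' @export
print.mrm_result <- function(x, ...) {
  cat("MRM over", x$n, "units,", x$nperm, "permutations\n")
  print(x$coefficients, row.names = FALSE)
  cat("R2 =", format(x$r2, digits = 4), " (p =",
      format(x$r2_p, digits = 4), ")\n")
  invisible(x)
}

#' Partition beta-diversity variance among predictor matrices
#'
#' Semi-partial decomposition of the full-model MRM R2: the unique
#' contribution of predictor i is R2(full) - R2(all predictors except
#' i) — the variance only it explains; the joint (covariation) term is
#' what remains of R2(full) after all unique contributions, i.e. the
#' variance shared among correlated predictors; unexplained is
#' 1 - R2(full). The three parts sum to 1 by construction. Shares of
#' the single (unique) contributions are also reported, as unique_i /
#' sum(unique).
#'
#' @param response a `distance_matrix`.
#' @param predictors named list of `distance_matrix` objects.
#' @return a `partition_result`: list with `unique` (named vector),
#'   `joint`, `unexplained`, `r2_full`, `unique_share`.
#' @export
variance_partition <- function(response, predictors) {
  y <- upper_vec(response)
  X <- unfold_predictors(response, predictors)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance predictor vector: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  r2_full <- r2_of(y, X)
  uni <- vapply(seq_len(ncol(X)), function(i) {
    if (ncol(X) == 1L) return(r2_full)
    r2_full - r2_of(y, X[, -i, drop = FALSE])
  }, numeric(1L))
  names(uni) <- colnames(X)
  joint <- if (ncol(X) == 1L) 0 else r2_full - sum(uni)
  structure(list(unique = uni, joint = joint,
                 unexplained = 1 - r2_full, r2_full = r2_full,
                 unique_share = if (sum(uni) > 0) uni / sum(uni)
                                else uni * NA_real_),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat("variance partition (R2 full =",
      format(x$r2_full, digits = 4), ")\n")
  tab <- rbind(unique = x$unique)
  print(tab)
  cat("joint =", format(x$joint, digits = 4),
      " unexplained =", format(x$unexplained, digits = 4), "\n")
  invisible(x)
}

#' Robustness of beta-diversity structure to pool size
#'
#' Tests whether the difference in taxon counts between floristic
#' elements could drive the beta-diversity results: repeatedly draw k
#' taxa with replacement from a pool, rebuild the Sorensen matrix of
#' the resampled assemblage, and regress it (single-predictor MRM,
#' permutation test) on the pool's original Sorensen matrix restricted
#' to the ecoregions surviving the draw. High mean adjusted R2 across
#' iterations means the pairwise structure is stable under heavy
#' subsampling.
#'
#' @param pool an `occurrence_matrix`.
#' @param k taxa drawn per iteration (with replacement).
#' @param n_iter iterations (>= 2).
#' @param nperm permutations per MRM test.
#' @param seed integer seed.
#' @return list with `mean_adj_r2`, `sd_adj_r2`, `mean_p`,
#'   `n_discarded` (iterations with < 3 surviving ecoregions) and the
#'   per-iteration `adj_r2` / `p` vectors.
#' @export
resampling_robustness <- function(pool, k, n_iter = 100L, nperm = 199L,
                                  seed = 1L) {
  if (n_iter < 2L) stop("n_iter must be >= 2")
  full <- sorensen_matrix(pool)
  ntax <- length(pool$taxa)
  npairs_n <- function(n) n * (n - 1L) / 2L
  restore <- local_rng(seed)
  on.exit(restore())
  adj <- p <- numeric(0)
  discarded <- 0L
  dropped_note <- FALSE
  for (it in seq_len(n_iter)) {
    rows <- sample.int(ntax, k, replace = TRUE)
    inc <- pool$incidence[rows, , drop = FALSE]
    keep <- colSums(inc) > 0L
    if (sum(keep) < 3L) { discarded <- discarded + 1L; next }
    if (!all(keep)) dropped_note <- TRUE
    inc <- inc[, keep, drop = FALSE]
    rownames(inc) <- sprintf("r%d", seq_len(nrow(inc)))
    samp <- occurrence_matrix(inc, rep("nonendemic", nrow(inc)),
                              allow_empty_taxa = TRUE)
    ds <- sorensen_matrix(samp)
    dref <- subset_distance_matrix(full, dm_labels(ds))
    if (max(abs(unclass(ds) - unclass(dref))) < 1e-12) {
      # resample reproduced the pool matrix exactly (e.g. a pool of
      # identical taxa); perfect recovery, permutation p undefined
      adj <- c(adj, 1)
      p <- c(p, NA_real_)
      next
    }
    sub_seed <- (seed + it * 1009L) %% .Machine$integer.max
    fit <- mrm(ds, list(reference = dref), nperm = nperm,
               seed = sub_seed)
    n_units <- fit$n
    r2 <- fit$r2
    adj <- c(adj, 1 - (1 - r2) * (npairs_n(n_units) - 1) /
               (npairs_n(n_units) - 2))
    p <- c(p, fit$coefficients$p_value[2L])
  }
  if (dropped_note)
    message("some iterations emptied ecoregions; those ecoregions ",
            "were dropped for the affected iterations")
  if (!length(adj)) stop("all iterations discarded")
  list(mean_adj_r2 = mean(adj), sd_adj_r2 = stats::sd(adj),
       mean_p = mean(p, na.rm = TRUE), n_discarded = discarded,
       adj_r2 = adj, p = p)
}
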