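test_that("UPGMA reproduces the hand-worked three-leaf example", {
  d <- distance_matrix(matrix(c(0, 2, 8,
                                2, 0, 8,
                                8, 8, 0), 3L, 3L),
                       c("A", "B", "C"))
  tr <- upgma(d)
  expect_equal(tr$height, c(2, 8))
  expect_identical(tr$edges[[1L]], c("A", "B"))
  expect_identical(tr$edges[[2L]], c("A", "B", "C"))
})

test_that("equal distances merge at one height with the stated tie-break", {
  labs <- c("D", "B", "C", "A")
  d <- distance_matrix(matrix(3, 4L, 4L) - diag(3, 4L), labs)
  tr <- upgma(d)
  expect_equal(tr$height, rep(3, 3L))
  # lexicographically smallest pair first
  expect_identical(tr$edges[[1L]], c("A", "B"))
})

test_that("cophenetic distances are ultrametric and match hclust", {
  withr::local_seed(14)
  for (rep in 1:4) {
    d <- random_geo_dm(8L)
    tr <- upgma(d)
    co <- unclass(cophenetic_matrix(tr))
    labs <- rownames(co)
    for (i in labs) for (j in labs) for (k in labs)
      expect_lte(co[i, k], max(co[i, j], co[j, k]) + 1e-9)
    # independent oracle: base hclust average linkage
    hc <- stats::hclust(stats::as.dist(unclass(d)), method = "average")
    co_hc <- as.matrix(stats::cophenetic(hc))[labs, labs]
    expect_equal(co, co_hc, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("UPGMA rejects NaN distances", {
  d <- random_geo_dm(4L, seed = 2)
  bad <- unclass(d)
  class(bad) <- c("distance_matrix", "matrix", "array")
  bad[1L, 2L] <- bad[2L, 1L] <- NaN
  expect_error(upgma(bad), "NaN")
})

test_that("correspondence analysis has CA structure", {
  # identical ecoregion columns get identical site scores
  inc <- matrix(c(1, 1, 0,
                  1, 1, 0,
                  0, 0, 1,
                  1, 1, 1), 4L, 3L, byrow = TRUE,
                dimnames = list(sprintf("t%d", 1:4), c("A", "B", "C")))
  occ <- occurrence_matrix(inc, rep("nonendemic", 4L))
  ca <- correspondence_analysis(occ)
  expect_equal(unname(ca$site_scores["A", ]),
               unname(ca$site_scores["B", ]), tolerance = 1e-9)
  expect_true(all(ca$eig <= 1 + 1e-12))
  # block-diagonal table: axis 1 separates the blocks by sign
  inc2 <- rbind(
    cbind(matrix(1, 5L, 3L), matrix(0, 5L, 3L)),
    cbind(matrix(0, 5L, 3L), matrix(1, 5L, 3L)))
  dimnames(inc2) <- list(sprintf("t%d", 1:10), sprintf("e%d", 1:6))
  occ2 <- occurrence_matrix(inc2, rep("nonendemic", 10L))
  ca2 <- correspondence_analysis(occ2)
  s1 <- ca2$site_scores[1:3, 1L]
  s2 <- ca2$site_scores[4:6, 1L]
  expect_true(all(sign(s1) == sign(s1[1L])))
  expect_true(all(sign(s2) == -sign(s1[1L])))
  expect_equal(ca2$eig[1L], 1)  # disconnected blocks: unit eigenvalue
})

test_that("CA eigenvalues match vegan's cca on a random table", {
  skip_if_not_installed("vegan")
  withr::local_seed(9)
  occ <- random_occ(12L, 6L)
  ca <- correspondence_analysis(occ, naxes = 4L)
  vg <- vegan::cca(t(occ$incidence * 1))
  expect_equal(ca$eig, unname(vg$CA$eig[1:4]), tolerance = 1e-8)
})

test_that("DCA with detrending off reduces to plain CA", {
  withr::local_seed(4)
  occ <- random_occ(15L, 7L)
  ca <- correspondence_analysis(occ, naxes = 2L)
  d <- dca(occ, segments = "off")
  expect_equal(d$site_scores, ca$site_scores, tolerance = 1e-12)
  expect_equal(d$eig, ca$eig, tolerance = 1e-12)
})

test_that("DCA recovers a single-gradient coenocline order and detrends", {
  # unimodal bands along one gradient: site i holds species with
  # optima near position i
  n_site <- 12L; n_sp <- 40L
  pos <- seq(0, 1, length.out = n_site)
  opt <- seq(0, 1, length.out = n_sp)
  inc <- outer(opt, pos, function(o, p) abs(o - p) < 0.18)
  dimnames(inc) <- list(sprintf("s%02d", 1:n_sp),
                        sprintf("site%02d", 1:n_site))
  occ <- occurrence_matrix(inc, rep("nonendemic", n_sp))
  res <- dca(occ, segments = 10L)
  ord <- order(res$site_scores[, 1L])
  expect_true(identical(ord, seq_len(n_site)) ||
                identical(ord, rev(seq_len(n_site))))
  # within-segment means of axis 2 are zero by construction
  ax1 <- res$site_scores[, 1L]
  br <- seq(min(ax1), max(ax1), length.out = 11L)
  bin <- findInterval(ax1, br, rightmost.closed = TRUE,
                      all.inside = TRUE)
  for (b in unique(bin))
    expect_equal(mean(res$site_scores[bin == b, 2L]), 0,
                 tolerance = 1e-8)
})

test_that("PCA on the correlation matrix behaves as expected", {
  # two perfectly correlated variables: PC1 carries all variance
  env <- env_fixture(sprintf("e%d", 1:5),
                     `1` = c(1, 2, 3, 4, 5), `2` = c(3, 5, 7, 9, 11))
  p <- pca_env(env, c("1", "2"))
  expect_equal(p$variance_fraction[1L], 1)
  # orthonormal loadings, unit column sums of squares
  withr::local_seed(3)
  env2 <- env_fixture(sprintf("e%d", 1:8),
                      `1` = stats::rnorm(8), `2` = stats::rnorm(8),
                      `3` = stats::rnorm(8))
  p2 <- pca_env(env2, c("1", "2", "3"))
  expect_equal(unname(colSums(p2$loadings^2)), rep(1, 3L))
  expect_equal(sum(p2$variance_fraction), 1)
  expect_true(all(diff(p2$eig) <= 1e-12))
  expect_true(all(abs(p2$loadings) <= 1 + 1e-12))
})

test_that("PCA eigenvalues match a closed-form 3x3 solution", {
  # columns z1 (+/-1 pattern), z2 orthogonal, x3 = z1 + z2 gives the
  # correlation matrix [[1,0,a],[0,1,a],[a,a,1]] with a = 1/sqrt(2);
  # eigenvector (1,-1,0) gives eigenvalue 1 and the symmetric 2x2
  # block gives 1 +/- a*sqrt(2), hence eigenvalues {2, 1, 0}
  env <- env_fixture(sprintf("e%d", 1:4),
                     `1` = c(1, -1, 1, -1), `2` = c(1, 1, -1, -1),
                     `3` = c(2, 0, 0, -2))
  p <- pca_env(env, c("1", "2", "3"))
  expect_equal(p$eig, c(2, 1, 0), tolerance = 1e-12)
  expect_equal(p$cumulative_variance, c(2 / 3, 1, 1),
               tolerance = 1e-12)
})
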