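test_that("alpha regression reports the adjusted R2 convention", {
  # perfectly linear data
  x <- stats::setNames(1:6, sprintf("e%d", 1:6))
  fit <- alpha_regression(2 * x + 3, x)
  expect_equal(fit$adj_r2, 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 3)
  # formula check at n = 20, p = 1, R2 = 0.5
  withr::local_seed(99)
  repeat {
    xx <- stats::rnorm(20)
    yy <- xx + stats::rnorm(20)
    f <- stats::lm(yy ~ xx)
    if (abs(summary(f)$r.squared - 0.5) < 0.2) break
  }
  res <- alpha_regression(stats::setNames(yy, sprintf("e%d", 1:20)),
                          stats::setNames(xx, sprintf("e%d", 1:20)))
  expect_equal(res$adj_r2, 1 - (1 - res$r2) * 19 / 18,
               tolerance = 1e-12)
  expect_lte(res$adj_r2, res$r2)
  # pure-noise predictors may produce negative adjusted R2
  withr::local_seed(2)
  vals <- replicate(40, {
    y <- stats::rnorm(10); x0 <- stats::rnorm(10)
    alpha_regression(stats::setNames(y, letters[1:10]),
                     stats::setNames(x0, letters[1:10]))$adj_r2
  })
  expect_true(any(vals < 0))
  expect_error(alpha_regression(stats::setNames(1:5, letters[1:5]),
                                stats::setNames(rep(1, 5), letters[1:5])),
               "constant")
})

test_that("single-predictor MRM equals OLS on the unfolded vectors", {
  withr::local_seed(41)
  for (rep in 1:4) {
    y_dm <- random_geo_dm(8L)
    x_dm <- random_geo_dm(8L)
    fit <- mrm(y_dm, list(x = x_dm), nperm = 99L, seed = 1L)
    # independent closed-form OLS oracle on the unfolded vectors
    yv <- upper_vec(y_dm); xv <- upper_vec(x_dm)
    b <- sum((xv - mean(xv)) * (yv - mean(yv))) /
      sum((xv - mean(xv))^2)
    expect_equal(fit$coefficients$coefficient[2L], b,
                 tolerance = 1e-10)
    expect_equal(fit$r2, stats::cor(xv, yv)^2, tolerance = 1e-10)
  }
})

test_that("a predictor identical to the response is maximally significant", {
  d <- random_geo_dm(9L, seed = 8)
  fit <- mrm(d, list(self = d), nperm = 199L, seed = 4L)
  expect_equal(fit$coefficients$coefficient[2L], 1, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$coefficients$p_value[2L], 1 / 200)
  expect_equal(fit$r2_p, 1 / 200)
})

test_that("MRM rejects degenerate predictor sets", {
  d <- random_geo_dm(6L, seed = 3)
  flat <- distance_matrix(matrix(1, 6L, 6L) - diag(6L), dm_labels(d))
  expect_error(mrm(d, list(flat = flat), nperm = 99L), "zero-variance")
  expect_error(mrm(d, list(a = d, b = d), nperm = 99L), "collinear")
  expect_error(mrm(d, list(d), nperm = 99L), "named")
})

test_that("variance partition conserves and decomposes correctly", {
  withr::local_seed(55)
  y <- random_geo_dm(8L)
  x1 <- random_geo_dm(8L)
  x2 <- random_geo_dm(8L)
  part <- variance_partition(y, list(a = x1, b = x2))
  expect_equal(sum(part$unique) + part$joint + part$unexplained, 1,
               tolerance = 1e-9)
  # single predictor: unique is the whole R2, no joint term
  p1 <- variance_partition(y, list(a = x1))
  expect_equal(unname(p1$unique["a"]), p1$r2_full)
  expect_equal(p1$joint, 0)
  # two exactly duplicated predictors: all shared variance sits in
  # joint (the duplicate is aliased out of the full fit)
  x1b <- distance_matrix(unclass(x1) * 1.5, dm_labels(x1))
  pdup <- variance_partition(y, list(a = x1, b = x1b))
  expect_equal(max(abs(pdup$unique)), 0, tolerance = 1e-9)
  expect_equal(pdup$joint, pdup$r2_full, tolerance = 1e-9)
})

test_that("orthogonal predictors partition into their marginal R2", {
  # build two predictor vectors orthogonal after centring, fold them
  # back into symmetric matrices
  n <- 5L
  labs <- sprintf("e%d", 1:n)
  npair <- n * (n - 1L) / 2L
  v1 <- c(1, 2, 3, 4, 3, 2, 1, 2, 3, 4)
  v2 <- c(1, -1, 1, -1, 1, -1, 1, -1, 1, -1) + 2
  v1c <- v1 - mean(v1); v2c <- v2 - mean(v2)
  v2c <- v2c - sum(v1c * v2c) / sum(v1c^2) * v1c  # orthogonalise
  stopifnot(abs(sum(v1c * v2c)) < 1e-12)
  fold <- function(v) {
    m <- matrix(0, n, n, dimnames = list(labs, labs))
    m[upper.tri(m)] <- v - min(v) + 1
    m <- m + t(m)
    distance_matrix(m, labs)
  }
  x1 <- fold(v1c); x2 <- fold(v2c)
  yv <- 2 * upper_vec(x1) + 3 * upper_vec(x2)
  y <- fold(yv)
  part <- variance_partition(y, list(a = x1, b = x2))
  r2a <- stats::cor(upper_vec(y), upper_vec(x1))^2
  r2b <- stats::cor(upper_vec(y), upper_vec(x2))^2
  expect_equal(unname(part$unique["a"]), r2a, tolerance = 1e-9)
  expect_equal(unname(part$unique["b"]), r2b, tolerance = 1e-9)
  expect_equal(part$joint, 0, tolerance = 1e-9)
})

test_that("permutation test keeps nominal type-I error under the null", {
  # 200 independent null datasets at nperm = 199: rejection rate at
  # alpha = 0.05 must sit within the binomial 95% band around 0.05
  withr::local_seed(1234)
  x_dm <- random_geo_dm(8L)
  rejections <- 0L
  for (i in 1:200) {
    y_dm <- random_geo_dm(8L)
    fit <- mrm(y_dm, list(x = x_dm), nperm = 199L, seed = 10000L + i)
    if (fit$coefficients$p_value[2L] <= 0.05)
      rejections <- rejections + 1L
  }
  rate <- rejections / 200
  half <- 1.96 * sqrt(0.05 * 0.95 / 200)
  expect_gte(rate, 0.05 - half)
  expect_lte(rate, 0.05 + half)
})

test_that("taxon resampling robustness behaves as specified", {
  withr::local_seed(66)
  # degenerate pool: identical taxa reproduce the matrix exactly
  inc_same <- matrix(TRUE, 10L, 4L,
                     dimnames = list(sprintf("t%d", 1:10),
                                     letters[1:4]))
  pool_same <- occurrence_matrix(inc_same, rep("nonendemic", 10L))
  rs <- resampling_robustness(pool_same, k = 5L, n_iter = 5L,
                              nperm = 99L, seed = 2L)
  expect_equal(rs$mean_adj_r2, 1)
  expect_equal(rs$sd_adj_r2, 0)
  # determinism
  occ <- random_occ(60L, 8L, p = 0.35)
  r1 <- resampling_robustness(occ, k = 30L, n_iter = 10L, nperm = 99L,
                              seed = 7L)
  r2 <- resampling_robustness(occ, k = 30L, n_iter = 10L, nperm = 99L,
                              seed = 7L)
  expect_identical(r1, r2)
  expect_true(all(r1$adj_r2 <= 1))
})

test_that("resampled fidelity grows with the number of taxa drawn", {
  withr::local_seed(505)
  occ <- random_occ(400L, 10L, p = 0.3)
  ks <- c(25L, 100L, 400L)
  means <- vapply(ks, function(k)
    resampling_robustness(occ, k = k, n_iter = 50L, nperm = 99L,
                          seed = 31L)$mean_adj_r2, numeric(1L))
  expect_true(all(diff(means) > 0))
})
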