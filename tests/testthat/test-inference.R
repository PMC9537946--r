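test_that("spearman correlation handles monotone transforms and the null", {
  x <- c(1, 3, 2, 8, 5, 4, 9)
  expect_equal(spearman_corr(x, exp(x))$rho, 1.0)
  set.seed(61)
  big <- spearman_corr(rnorm(10000), rnorm(10000))
  expect_lt(abs(big$rho), 0.03)
  expect_error(spearman_corr(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearman_corr(rnorm(4), rnorm(4)), "at least 5")
})

test_that("partial correlation reduces to plain correlation without covariates", {
  set.seed(62)
  x <- rnorm(30); y <- rnorm(30)
  plain <- cor(x, y)
  expect_equal(partial_corr(x, y)$r, plain, tolerance = 1e-12)
  expect_equal(partial_corr(x, y, data.frame(c1 = rep(2, 30)))$r, plain,
               tolerance = 1e-12)
  z <- rnorm(30)
  pc <- partial_corr(x, y, data.frame(z = z))
  r_xz <- cor(x, z); r_yz <- cor(y, z)
  expect_equal(pc$r, (plain - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2)),
               tolerance = 1e-12)
})

test_that("edge regression matches a normal-equations hand computation", {
  set.seed(63)
  n <- 10
  els <- rnorm(n); cov1 <- rnorm(n)
  edge <- 0.3 * els - 0.2 * cov1 + rnorm(n)
  rec <- edge_regression(edge, els, data.frame(cov1 = cov1))
  X <- cbind(1, els, cov1)
  beta <- solve(t(X) %*% X, t(X) %*% edge)
  resid <- edge - X %*% beta
  df <- n - ncol(X)
  se <- sqrt(drop(t(resid) %*% resid) / df * solve(t(X) %*% X)[2, 2])
  t_hand <- beta[2] / se
  expect_equal(rec$t_statistic, t_hand, tolerance = 1e-10)
  expect_equal(rec$p_value, 2 * pt(-abs(t_hand), df), tolerance = 1e-12)
  expect_equal(rec$df_residual, df)
  expect_equal(rec$df_label, n)
})

test_that("Cohen's d uses the t/sqrt(n) convention", {
  # reconstruct a design that yields t very close to 3.00 at n = 86, then
  # check the conversion directly on the record
  set.seed(64)
  n <- 86
  els <- rnorm(n)
  edge <- 0.3 * els + rnorm(n)
  rec <- edge_regression(edge, els)
  expect_equal(rec$cohen_d, rec$t_statistic / sqrt(n), tolerance = 1e-12)
  expect_equal(round(3.00 / sqrt(86), 2), 0.32)   # the published conversion
})

test_that("edge regression p-values are uniform under the null", {
  set.seed(65)
  ps <- sapply(1:200, function(i) {
    n <- 40
    covs <- data.frame(sex = rbinom(n, 1, 0.5), age = rnorm(n))
    edge_regression(rnorm(n), rnorm(n), covs)$p_value
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Steiger's test matches the frozen oracle and is antisymmetric", {
  st <- steiger_test(0.5, 0.3, 0.2, 100)
  expect_equal(st$z, 1.7803242299204265, tolerance = 1e-8)
  expect_equal(steiger_test(0.3, 0.5, 0.2, 100)$z, -st$z, tolerance = 1e-12)
  eq <- steiger_test(0.4, 0.4, 0.1, 50)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
  expect_error(steiger_test(0.5, 0.3, 1, 100), "r23")
  expect_error(steiger_test(1, 0.3, 0.2, 100), "correlations")
})

test_that("Steiger's test keeps nominal type-I error under a trivariate normal null", {
  set.seed(66)
  sigma <- matrix(c(1, .3, .3, .3, 1, .2, .3, .2, 1), 3)
  rejections <- sum(replicate(500, {
    x <- MASS::mvrnorm(100, rep(0, 3), sigma)
    r <- cor(x)
    steiger_test(r[1, 2], r[1, 3], r[2, 3], 100)$p_value < 0.05
  }))
  expect_binomial_coverage(rejections, 500)
})

test_that("BH adjustment reproduces the 16-test worked example and is order-invariant", {
  p <- c(0.004, 0.014, 0.015, rep(0.2, 13))
  q <- bh_fdr(p)
  expect_equal(q[1:3], c(0.064, 0.08, 0.08), tolerance = 1e-12)
  expect_equal(round(q[1:3], 2), c(0.06, 0.08, 0.08))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(67)
  perm <- sample(16)
  expect_equal(bh_fdr(p[perm]), q[perm], tolerance = 1e-15)
  expect_true(all(diff(sort(bh_fdr(runif(50)))) >= -1e-15))
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
})

test_that("extreme groups take floor(fraction * N) per tail, ties included", {
  s <- setNames(1:9, letters[1:9])
  g <- extreme_groups(s, 1 / 3)
  expect_equal(g$low_ids, c("a", "b", "c"))
  expect_equal(g$high_ids, c("g", "h", "i"))
  s2 <- setNames(c(1, 2, 3, 4, 5, 5, 5, 9, 10), letters[1:9])
  g2 <- extreme_groups(s2, 1 / 3)               # boundary value 5 is tied
  expect_equal(sort(g2$high_ids), c("e", "f", "g", "h", "i"))
  s3 <- setNames(1:10, letters[1:10])
  g3 <- extreme_groups(s3, 0.5)
  expect_length(intersect(g3$low_ids, g3$high_ids), 0)
  expect_error(extreme_groups(setNames(rep(1, 10), letters[1:10]), 0.5), "overlap")
  expect_error(extreme_groups(s, 0.6), "target_fraction")
})

test_that("edge contrast is antisymmetric and finds a planted shifted edge", {
  set.seed(68)
  hi <- matrix(rnorm(30 * 10), 30, 10, dimnames = list(NULL, paste0("e", 1:10)))
  lo <- matrix(rnorm(30 * 10), 30, 10, dimnames = list(NULL, paste0("e", 1:10)))
  a <- edge_contrast(hi, lo)
  b <- edge_contrast(lo, hi)
  expect_equal(a$mean_diff, -b$mean_diff, tolerance = 1e-12)
  expect_equal(a$t_statistic, -b$t_statistic, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)

  hits <- sapply(1:25, function(s) {
    set.seed(700 + s)
    hi <- matrix(rnorm(30 * 66), 30, 66)
    lo <- matrix(rnorm(30 * 66), 30, 66)
    hi[, 7] <- hi[, 7] + 3
    tab <- edge_contrast(hi, lo)
    tab$rank[7] == 1
  })
  expect_gte(sum(hits), 24)

  same <- matrix(rnorm(5 * 4), 5, 4)
  expect_equal(edge_contrast(same, same)$mean_diff, rep(0, 4))
})

test_that("contrast p-values are uniform under the null", {
  set.seed(69)
  ps <- sapply(1:200, function(i) {
    hi <- matrix(rnorm(20 * 5), 20, 5)
    lo <- matrix(rnorm(20 * 5), 20, 5)
    edge_contrast(hi, lo)$p_value[1]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
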