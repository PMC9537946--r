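test_that("connectivity RDM is one minus profile correlation, with exact anchors", {
  p <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = -c(1, 2, 3, 4))
  d <- connectivity_rdm(p)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 2)
  expect_equal(unname(diag(unclass(d))), rep(0, 3))

  set.seed(41)
  hand <- rbind(x = rnorm(4), y = rnorm(4), z = rnorm(4))
  dh <- connectivity_rdm(hand)
  for (pair in list(c("x", "y"), c("x", "z"), c("y", "z"))) {
    expect_equal(dh[pair[1], pair[2]],
                 1 - cor(hand[pair[1], ], hand[pair[2], ]), tolerance = 1e-14)
  }
  expect_error(connectivity_rdm(rbind(a = rep(1, 4), b = rnorm(4), c = rnorm(4))),
               "constant")
})

test_that("model RDM is the absolute score difference and translation-invariant", {
  s <- c(a = 1, b = 2, c = 4)
  d <- model_rdm(s)
  expect_equal(unname(d[upper.tri(d)]), c(1, 3, 2))
  expect_equal(unclass(model_rdm(s + 100)), unclass(d))
  expect_equal(max(abs(unclass(model_rdm(c(a = 5, b = 5, c = 5))))), 0)
  expect_error(model_rdm(c(a = 1, b = NA, c = 2)), "missing")
})

test_that("RDM construction commutes with participant reordering", {
  set.seed(42)
  prof <- random_profiles(8)
  scores <- setNames(rnorm(8), rownames(prof))
  perm <- sample(8)
  d1 <- unclass(connectivity_rdm(prof))[perm, perm]
  d2 <- unclass(connectivity_rdm(prof[perm, ]))
  expect_equal(d1, d2, tolerance = 1e-14, ignore_attr = TRUE)
  m1 <- unclass(model_rdm(scores))[perm, perm]
  m2 <- unclass(model_rdm(scores[perm]))
  expect_equal(m1, m2, ignore_attr = TRUE)
})

test_that("the 2-SD outlier rule flags by a single mean/SD pass", {
  v <- c(rep(0, 19), 10)
  names(v) <- sprintf("s%02d", 1:20)
  expect_equal(flag_outliers(v), "s20")
  expect_warning(out0 <- flag_outliers(setNames(rep(1, 5), letters[1:5])),
                 "zero variance")
  expect_length(out0, 0)
  set.seed(43)
  expect_length(flag_outliers(setNames(rnorm(30), 1:30), k = 1e6), 0)
})

test_that("self-correlation gives partial_r 1 and the minimal permutation p", {
  set.seed(44)
  d <- connectivity_rdm(random_profiles(10))
  fit <- partial_rdm_correlation(d, d, n_perm = 199, seed = 1)
  expect_equal(fit$partial_r, 1, tolerance = 1e-12)
  expect_equal(fit$p_value, 1 / 200)
})

test_that("unranked partial correlation matches the textbook closed form at N = 6", {
  set.seed(45)
  target <- connectivity_rdm(random_profiles(6, seed = 45))
  model <- model_rdm(setNames(rnorm(6), rownames(target)))
  covar <- model_rdm(setNames(rnorm(6), rownames(target)))
  fit <- partial_rdm_correlation(target, model, list(covar),
                                 method = "pearson", n_perm = 99, seed = 2)
  x <- model[upper.tri(model)]; y <- target[upper.tri(target)]
  z <- covar[upper.tri(covar)]
  r_xy <- cor(x, y); r_xz <- cor(x, z); r_yz <- cor(y, z)
  expect_equal(fit$partial_r,
               (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2)),
               tolerance = 1e-12)
})

test_that("the spearman statistic with no covariates equals a rank Mantel statistic", {
  skip_if_not_installed("vegan")
  set.seed(46)
  target <- connectivity_rdm(random_profiles(12, seed = 46))
  model <- model_rdm(setNames(rnorm(12), rownames(target)))
  fit <- partial_rdm_correlation(target, model, n_perm = 99, seed = 3)
  vg <- vegan::mantel(as.dist(unclass(model)), as.dist(unclass(target)),
                      method = "spearman", permutations = 0)
  expect_equal(fit$partial_r, unname(vg$statistic), tolerance = 1e-10)
})

test_that("the statistic is invariant to a consistent participant reordering", {
  set.seed(47)
  prof <- random_profiles(15, seed = 47)
  scores <- setNames(rnorm(15), rownames(prof))
  cov_sc <- setNames(rnorm(15), rownames(prof))
  perm <- sample(15)
  f1 <- partial_rdm_correlation(connectivity_rdm(prof), model_rdm(scores),
                                list(model_rdm(cov_sc)), n_perm = 99, seed = 5)
  f2 <- partial_rdm_correlation(connectivity_rdm(prof[perm, ]), model_rdm(scores[perm]),
                                list(model_rdm(cov_sc[perm])), n_perm = 99, seed = 5)
  expect_equal(f1$partial_r, f2$partial_r, tolerance = 1e-12)
})

test_that("mismatched ids and collinear covariates are rejected", {
  set.seed(48)
  prof <- random_profiles(6, seed = 48)
  target <- connectivity_rdm(prof)
  scores <- setNames(rnorm(6), rownames(prof))
  model <- model_rdm(scores)
  shuffled <- model_rdm(scores[c(2, 1, 3:6)])
  expect_error(partial_rdm_correlation(target, shuffled, n_perm = 99, seed = 1),
               "aligned")
  expect_error(partial_rdm_correlation(target, model, list(model_rdm(scores * 2)),
                                       n_perm = 99, seed = 1), "collinear")
  expect_error(partial_rdm_correlation(target, model, n_perm = 50, seed = 1), "99")
  expect_error(partial_rdm_correlation(target, model, n_perm = 99), "seed")
})

test_that("partial_r increases with the planted pattern effect", {
  grid <- c(0, 0.03, 0.08)
  mean_r <- sapply(grid, function(b) {
    mean(sapply(1:12, function(s) {
      coh <- simulate_cohort(sim_config(40, n_volumes = 80, beta_pattern = b,
                                        seed = 500 + s))
      prof <- connectivity_profiles(coh$timeseries)
      target <- connectivity_rdm(prof)
      m <- model_rdm(coh$truth$latent_prospective)
      fit <- partial_rdm_correlation(target, m, n_perm = 99, seed = 600 + s)
      fit$partial_r
    }))
  })
  expect_true(all(diff(mean_r) > 0))
})
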