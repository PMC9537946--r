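test_that("EM returns the input untouched when nothing is missing", {
  y <- complete_battery(n = 25, seed = 4)
  res <- em_impute(y)
  expect_identical(res$completed, y)
  expect_equal(res$em_iterations, 0L)
  expect_equal(res$n_imputed_cells, 0L)
  expect_true(res$em_converged)
})

test_that("EM recovers the closed-form conditional mean on bivariate normal data", {
  set.seed(10)
  n <- 4000
  x <- rnorm(n)
  y <- 0.8 * x + sqrt(1 - 0.8^2) * rnorm(n)
  m <- cbind(a = x, b = y)
  # standardize to exact sample moments so the conditional mean is exactly
  # rho * partner value
  m <- apply(m, 2, function(col) (col - mean(col)) / sd(col))
  rho <- cor(m[, 1], m[, 2])
  hold <- m[1, 1]                        # partner value for the missing cell
  m[1, 1] <- hold                         # keep column 1 observed
  m[1, 2] <- NA                           # one missing cell in column 2
  res <- em_impute(m, max_missing = 1)
  expect_lt(abs(res$completed[1, 2] - rho * hold), 1e-3)
})

test_that("EM beats column-mean imputation under 10% MCAR", {
  ## n chosen so the 20 x 20 ML covariance is stable (n >> p); the design
  ## this emulates likewise estimated EM parameters from a large cohort
  wins <- sapply(1:20, function(s) {
    y <- complete_battery(n = 300, seed = 100 + s)
    set.seed(200 + s)
    mask <- matrix(runif(length(y)) < 0.10, nrow(y), ncol(y))
    # keep every participant eligible and every column estimable
    mask[rowSums(mask) > 8, ] <- FALSE
    ymiss <- y; ymiss[mask] <- NA
    em <- em_impute(ymiss)
    colmean <- ymiss
    for (j in seq_len(ncol(ymiss))) {
      colmean[is.na(ymiss[, j]), j] <- mean(ymiss[, j], na.rm = TRUE)
    }
    rmse <- function(imp) sqrt(mean((imp[mask] - y[mask])^2))
    rmse(em$completed) < rmse(colmean)
  })
  expect_true(all(wins))
})

test_that("EM is a projection: a second pass changes nothing", {
  y <- complete_battery(n = 30, seed = 8)
  y[cbind(c(1, 5, 9), c(2, 7, 20))] <- NA
  first <- em_impute(y)
  second <- em_impute(first$completed)
  expect_identical(second$completed, first$completed)
  expect_equal(second$em_iterations, 0L)
})

test_that("participants over the missing-variable cap are excluded with a warning", {
  y <- complete_battery(n = 10, seed = 3)
  y[2, 1:9] <- NA                         # 9 of 20 missing: ineligible
  y[4, 1:3] <- NA                         # eligible
  expect_warning(res <- em_impute(y), "sub-002")
  expect_false("sub-002" %in% rownames(res$completed))
  expect_true("sub-004" %in% rownames(res$completed))
})

test_that("composite averages instruments after time/parent averaging and is centered", {
  y <- complete_battery(n = 50, seed = 5)
  res <- prospective_risk_index(y)
  expect_lt(abs(mean(res$composite)), 1e-10)

  # all four instruments identical columns -> composite is that column's z-score
  z <- rnorm(20)
  y2 <- matrix(rep(z, 20), nrow = 20, dimnames = list(NULL, battery_variables()$variable))
  res2 <- prospective_risk_index(y2)
  expect_equal(unname(res2$composite), as.vector(scale(z)), tolerance = 1e-12)
})

test_that("two-participant (a, -a) pattern standardizes to +/- 1/sqrt(2) under sample SD", {
  a <- 3.7
  y <- matrix(rep(c(a, -a), 20), nrow = 2,
              dimnames = list(c("p1", "p2"), battery_variables()$variable))
  res <- prospective_risk_index(y)
  expect_equal(unname(res$composite), c(1, -1) / sqrt(2), tolerance = 1e-12)
})

test_that("composite is invariant to affine rescaling of a raw instrument", {
  y <- complete_battery(n = 40, seed = 6)
  base <- prospective_risk_index(y)$composite
  y2 <- y
  bdi_cols <- battery_variables()$variable[battery_variables()$instrument == "BDI"]
  y2[, bdi_cols] <- 100 + 7 * y2[, bdi_cols]
  expect_equal(prospective_risk_index(y2)$composite, base, tolerance = 1e-10)
})

test_that("retrospective scoring follows the domain rules and bounds", {
  rdict <- retro_item_dictionary()
  mk <- function(vals) as.data.frame(as.list(setNames(vals, rdict$item)))
  expect_equal(unname(retrospective_els_score(mk(rep(0, 17)))), 0)
  expect_equal(unname(retrospective_els_score(mk(c(rep(2, 10), rep(2, 7))))), 24)
  # worked domain arithmetic: pairs (2,1),(0,0),(1,1),(0,1),(2,2); binaries y,n,y,n,y,n,n
  vals <- c(2, 1, 0, 0, 1, 1, 0, 1, 2, 2, 2, 0, 2, 0, 2, 0, 0)
  expect_equal(unname(retrospective_els_score(mk(vals))), 11.0)
  expect_error(retrospective_els_score(mk(c(3, rep(0, 16)))), "illegal value")
  expect_error(retrospective_els_score(mk(c(rep(0, 10), 1, rep(0, 6)))), "illegal value")
})

test_that("retrospective score is monotone nondecreasing in every item", {
  rdict <- retro_item_dictionary()
  set.seed(9)
  base_items <- as.data.frame(sapply(seq_len(nrow(rdict)), function(k) {
    if (rdict$type[k] == "ordinal") sample(0:2, 30, TRUE) else sample(c(0, 2), 30, TRUE)
  }))
  names(base_items) <- rdict$item
  base <- retrospective_els_score(base_items)
  for (k in seq_len(nrow(rdict))) {
    bumped <- base_items
    lo <- bumped[[k]] < 2
    bumped[[k]][lo] <- ifelse(rdict$type[k] == "ordinal", bumped[[k]][lo] + 1, 2)
    expect_true(all(retrospective_els_score(bumped) >= base))
  }
})

test_that("Cronbach's alpha matches closed forms and the independence null", {
  expect_equal(cronbach_alpha(matrix(rep(rnorm(10), 4), ncol = 4)), 1.0)
  set.seed(12)
  pair <- exact_corr_pair(n = 30, rho = 0.5)
  expect_equal(cronbach_alpha(pair), 2 * 0.5 / (1 + 0.5), tolerance = 1e-3)
  set.seed(13)
  noise <- matrix(rnorm(10000 * 8), ncol = 8)
  expect_lt(abs(cronbach_alpha(noise)), 0.05)
  expect_error(cronbach_alpha(matrix(1, 5, 3)), "zero total-score variance")
})
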