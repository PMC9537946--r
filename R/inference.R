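#' Spearman correlation with t-approximation p-value
#'
#' Rank-transforms both vectors and applies the Pearson machinery; the
#' two-tailed p-value uses the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of freedom.
#'
#' @param x,y Numeric vectors (n >= 5).
#' @return List: `rho`, `p_value`, `n`.
#' @export
spearman_corr <- function(x, y) {
  check_corr_input(x, y)
  rho <- stats::cor(rank(x), rank(y))
  list(rho = rho, p_value = corr_t_p(rho, length(x), k = 0), n = length(x))
}

#' Partial correlation via residualization
#'
#' Correlates the least-squares residuals of `x` and `y` after regressing
#' each on the covariate columns (plus intercept).  With no covariates this
#' reduces exactly to the plain correlation.  Two-tailed p from the t
#' approximation on `n - 2 - k` degrees of freedom (k covariates).
#'
#' @param x,y Numeric vectors.
#' @param covariates data.frame/matrix of covariate columns (may be empty).
#' @param method `"pearson"` (default) or `"spearman"` (ranks first).
#' @return List: `r`, `p_value`, `n`, `n_covariates`.
#' @export
partial_corr <- function(x, y, covariates = NULL, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  check_corr_input(x, y)
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  k <- 0L
  if (!is.null(covariates) && NCOL(covariates) > 0 && NROW(covariates) > 0) {
    z <- as.matrix(as.data.frame(covariates))
    if (method == "spearman") z <- apply(z, 2, rank)
    if (nrow(z) != length(x)) stop_("covariate rows must match x/y length")
    keep <- apply(z, 2, function(col) stats::var(col) > 0)
    z <- z[, keep, drop = FALSE]
    k <- ncol(z)
    if (k > 0) {
      qz <- qr(cbind(1, z))
      x <- qr.resid(qz, x); y <- qr.resid(qz, y)
    }
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop_("constant input after residualization")
  r <- sum(scale(x, scale = FALSE) * scale(y, scale = FALSE)) /
    sqrt(sum(scale(x, scale = FALSE)^2) * sum(scale(y, scale = FALSE)^2))
  list(r = r, p_value = corr_t_p(r, length(x), k), n = length(x),
       n_covariates = k)
}

check_corr_input <- function(x, y) {
  if (length(x) != length(y)) stop_("x and y must have equal length")
  if (length(x) < 5) stop_("need at least 5 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop_("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop_("constant input")
  invisible(TRUE)
}

corr_t_p <- function(r, n, k = 0) {
  df <- n - 2 - k
  if (abs(r) >= 1) return(if (df > 0) 0 else NA_real_)
  tt <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(tt), df)
}

#' Covariate-adjusted edge regression
#'
#' Ordinary least squares of one connectivity edge on an ELS score plus
#' background covariates.  Reports the ELS coefficient's t statistic,
#' two-tailed p, and Cohen's d converted as `d = t / sqrt(n)` (the
#' n-denominator convention; see the package vignette for why).  `df_label`
#' follows the common applied reporting style of printing n alongside t,
#' while the p-value uses the regression's residual degrees of freedom.
#'
#' @param edge Numeric vector of edge values.
#' @param els Numeric ELS scores.
#' @param covariates data.frame of covariates (may be NULL).
#' @param edge_label,predictor_label Labels carried into the record.
#' @return One-row data.frame: edge, predictor, estimate, t_statistic,
#'   df_label, df_residual, p_value, cohen_d, n.
#' @export
edge_regression <- function(edge, els, covariates = NULL,
                            edge_label = "edge", predictor_label = "els") {
  n <- length(edge)
  dat <- data.frame(.edge = edge, .els = els)
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    dat <- cbind(dat, as.data.frame(covariates))
  }
  if (n <= ncol(dat) + 1) stop_("too few observations for this design")
  fit <- stats::lm(.edge ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) {
    stop_("rank-deficient design: %s",
          paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  tt <- sm[".els", "t value"]
  data.frame(edge = edge_label, predictor = predictor_label,
             estimate = sm[".els", "Estimate"],
             t_statistic = tt,
             df_label = n,
             df_residual = fit$df.residual,
             p_value = sm[".els", "Pr(>|t|)"],
             cohen_d = tt / sqrt(n),
             n = n, stringsAsFactors = FALSE)
}

#' Steiger's test for two dependent correlations sharing one variable
#'
#' Compares r12 and r13 measured on the same sample (variable 1 common to
#' both).  Both correlations are Fisher z-transformed; their difference is
#' scaled by the asymptotic covariance of the two estimates, computed with
#' the pooled correlation `rbar = (r12 + r13) / 2`:
#' `s = (r23 (1 - 2 rbar^2) - rbar^2 (1 - 2 rbar^2 - r23^2) / 2) / (1 - rbar^2)^2`,
#' `z = (z12 - z13) sqrt((n - 3) / (2 (1 - s)))`, two-tailed p from the
#' standard normal.
#'
#' @param r12,r13 The two correlations being compared (share variable 1).
#' @param r23 Correlation between variables 2 and 3.
#' @param n Sample size (>= 10).
#' @return List: `z`, `p_value`.
#' @export
steiger_test <- function(r12, r13, r23, n) {
  for (r in c(r12, r13)) if (abs(r) >= 1) stop_("correlations must lie in (-1, 1)")
  if (abs(r23) >= 1) stop_("|r23| must be < 1")
  if (n < 10) stop_("n must be at least 10")
  rbar <- (r12 + r13) / 2
  s <- (r23 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)) /
    (1 - rbar^2)^2
  z <- (atanh(r12) - atanh(r13)) * sqrt((n - 3) / (2 * (1 - s)))
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted values `q(k) = min_(j>=k) p(j) m / j` (sorted scale),
#' capped at 1 and returned in the input order.  Thin wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Adjusted q-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) stop_("empty p-value vector")
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop_("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Split a cohort into extreme low/high score groups
#'
#' Takes `floor(target_fraction * N)` participants from each tail of the
#' score distribution.  Ties straddling a boundary are all included, so the
#' groups may be unequal (e.g. 27 vs 22 from nominal 30/30).
#'
#' @param scores Named numeric vector.
#' @param target_fraction Fraction per tail, in (0, 0.5].
#' @return List: `low_ids`, `high_ids`.
#' @export
extreme_groups <- function(scores, target_fraction) {
  if (!(target_fraction > 0 && target_fraction <= 0.5)) {
    stop_("target_fraction must lie in (0, 0.5]")
  }
  n <- length(scores)
  k <- floor(target_fraction * n)
  if (k < 1) stop_("target_fraction too small: empty groups")
  ids <- names(scores) %||% as.character(seq_len(n))
  srt <- sort(scores)
  low_cut <- srt[k]         # include all ties at the boundary value
  high_cut <- srt[n - k + 1]
  low <- ids[scores <= low_cut]
  high <- ids[scores >= high_cut]
  if (length(intersect(low, high))) {
    stop_("low and high groups overlap (fraction too large given ties)")
  }
  list(low_ids = low, high_ids = high)
}

#' Edge-wise extreme-group contrast
#'
#' Welch two-sample t test of every edge between the high- and low-ELS
#' groups, with the mean difference reported as high minus low,
#' Benjamini-Hochberg adjustment across the edges, and edges ranked by raw
#' p (rank 1 = smallest).  The top-ranked edges are the circulograph table.
#'
#' @param profiles_high,profiles_low participants x edges matrices with a
#'   shared edge order (colnames).
#' @param top_k How many edges to flag in the `top` column (default 10).
#' @return data.frame, one row per edge: edge, mean_diff, t_statistic,
#'   p_value, q_value, rank, top, n_high, n_low.
#' @export
edge_contrast <- function(profiles_high, profiles_low, top_k = 10) {
  ph <- as.matrix(profiles_high); pl <- as.matrix(profiles_low)
  if (ncol(ph) != ncol(pl)) stop_("edge sets differ between groups")
  if (!is.null(colnames(ph)) && !is.null(colnames(pl)) &&
      !identical(colnames(ph), colnames(pl))) {
    stop_("edge order differs between groups")
  }
  if (nrow(ph) < 3 || nrow(pl) < 3) stop_("need at least 3 participants per group")
  res <- lapply(seq_len(ncol(ph)), function(e) {
    hi <- ph[, e]; lo <- pl[, e]
    if (stats::var(hi) == 0 && stats::var(lo) == 0) {
      warn_("edge %d has zero variance in both groups; p set to 1", e)
      return(c(mean(hi) - mean(lo), 0, 1))
    }
    tt <- stats::t.test(hi, lo)    # Welch by default
    c(mean(hi) - mean(lo), unname(tt$statistic), tt$p.value)
  })
  res <- do.call(rbind, res)
  out <- data.frame(
    edge = colnames(ph) %||% paste0("edge", seq_len(ncol(ph))),
    mean_diff = res[, 1], t_statistic = res[, 2], p_value = res[, 3],
    q_value = bh_fdr(res[, 3]),
    stringsAsFactors = FALSE)
  out$rank <- rank(out$p_value, ties.method = "first")
  out$top <- out$rank <= top_k
  out$n_high <- nrow(ph); out$n_low <- nrow(pl)
  out
}
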