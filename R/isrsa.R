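#' Connectivity representational dissimilarity matrix
#'
#' Dissimilarity between two participants' connectivity profiles is one
#' minus the Pearson correlation of their 66-edge vectors, giving an N x N
#' symmetric matrix with zero diagonal and entries in \[0, 2\].
#'
#' @param profiles participants x edges matrix, rownames = participant ids.
#' @return Matrix of class `els_rdm` with attribute `provenance =
#'   "connectivity"`.
#' @export
connectivity_rdm <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 3) stop_("need at least 3 participants")
  v <- apply(profiles, 1, stats::var)
  if (any(v == 0)) {
    stop_("constant connectivity profile for participant(s): %s",
          paste(rownames(profiles)[v == 0], collapse = ", "))
  }
  d <- 1 - stats::cor(t(profiles))
  diag(d) <- 0
  new_rdm(d, rownames(profiles), "connectivity")
}

#' Model representational dissimilarity matrix from a score
#'
#' Entry (a, b) is the absolute difference of the participants' scores; it
#' is translation-invariant in the score.
#'
#' @param scores Named numeric vector (names = participant ids).
#' @return Matrix of class `els_rdm` with attribute `provenance = "model"`.
#' @export
model_rdm <- function(scores) {
  if (anyNA(scores)) {
    stop_("missing score for participant(s): %s",
          paste(names(scores)[is.na(scores)] %||% which(is.na(scores)),
                collapse = ", "))
  }
  d <- abs(outer(scores, scores, `-`))
  new_rdm(d, names(scores), "model")
}

new_rdm <- function(d, ids, provenance) {
  if (!is.null(ids)) dimnames(d) <- list(ids, ids)
  attr(d, "provenance") <- provenance
  class(d) <- c("els_rdm", class(d))
  d
}

check_rdm <- function(d, what = "RDM") {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop_("%s must be a square matrix", what)
  if (max(abs(d - t(d))) > 1e-8) stop_("%s must be symmetric", what)
  if (max(abs(diag(d))) > 1e-10) stop_("%s must have a zero diagonal", what)
  if (min(d) < -1e-10) stop_("%s must be nonnegative", what)
  invisible(d)
}

#' Flag outliers by the two-standard-deviation rule
#'
#' Single-pass rule: participants whose value lies more than `k` standard
#' deviations from the mean (mean and SD computed once, over all values)
#' are flagged for exclusion.
#'
#' @param values Named numeric vector.
#' @param k SD multiplier (default 2).
#' @return Character vector (or integer indices if unnamed) of flagged ids.
#' @export
flag_outliers <- function(values, k = 2) {
  if (length(values) < 3) stop_("need at least 3 values")
  s <- stats::sd(values)
  if (s == 0) {
    warn_("zero variance; no outliers flagged")
    return(character(0))
  }
  out <- abs(values - mean(values)) > k * s
  if (is.null(names(values))) which(out) else names(values)[out]
}

## upper-triangle vectorization shared by the RDM statistics
rdm_upper <- function(d) d[upper.tri(d)]

#' Partial correlation of two RDMs with Mantel-style permutation inference
#'
#' The inter-subject representational similarity statistic: upper triangles
#' of the target (connectivity) and model RDMs are vectorized,
#' rank-transformed if `method = "spearman"` (the default, standard in RSA
#' practice), both residualized on the covariate RDM vectors by least
#' squares, and the residuals correlated.  Significance comes from a
#' Mantel-style permutation null: participant labels of the model RDM are
#' permuted (rows and columns jointly — equivalent to permuting the
#' underlying scores and rebuilding the RDM), the partial statistic is
#' recomputed, and the two-tailed p-value is
#' `(1 + #{|r_perm| >= |r_obs|}) / (1 + n_perm)`.  Covariate RDMs are not
#' permuted, preserving their structure under the null.
#'
#' @param target Connectivity RDM (N x N).
#' @param model Model RDM, same participant order.
#' @param covariates List of covariate RDMs to partial out (may be empty).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm Number of permutations (default 10000, minimum 99).
#' @param seed Integer seed (required).
#' @return List of class `els_isrsa`: `partial_r`, `p_value`, `n_perm`,
#'   `method`, `n`, `seed`.
#' @export
partial_rdm_correlation <- function(target, model, covariates = list(),
                                    method = c("spearman", "pearson"),
                                    n_perm = 10000, seed = NULL) {
  method <- match.arg(method)
  if (is.null(seed)) stop_("seed is required")
  if (n_perm < 99) stop_("n_perm must be at least 99")
  check_rdm(target, "target RDM"); check_rdm(model, "model RDM")
  n <- nrow(target)
  ids <- rownames(target)
  for (d in c(list(model), covariates)) {
    if (nrow(d) != n) stop_("all RDMs must share the same participants")
    if (!is.null(ids) && !is.null(rownames(d)) && !identical(rownames(d), ids)) {
      stop_("RDM participant ids are not aligned")
    }
  }

  xform <- if (method == "spearman") rank else identity
  y <- xform(rdm_upper(target))
  z <- if (length(covariates)) {
    sapply(covariates, function(d) xform(rdm_upper(d)))
  } else NULL
  x_obs <- xform(rdm_upper(model))
  for (k in seq_along(covariates)) {
    if (abs(stats::cor(x_obs, z[, k])) > 0.999) {
      stop_("covariate RDM %d is collinear with the model RDM", k)
    }
  }

  ## residualize once on covariates; the covariate block is fixed under the
  ## permutation scheme, so y's residuals are reusable across permutations
  if (!is.null(z)) {
    qz <- qr(cbind(1, z))
    y_res <- qr.resid(qz, y)
  } else {
    qz <- NULL
    y_res <- y - mean(y)
  }
  partial_stat <- function(x) {
    x_res <- if (is.null(qz)) x - mean(x) else qr.resid(qz, x)
    sum(x_res * y_res) / sqrt(sum(x_res^2) * sum(y_res^2))
  }
  r_obs <- partial_stat(x_obs)

  ut <- upper.tri(model)
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      pi_b <- sample.int(n)
      mp <- model[pi_b, pi_b]
      partial_stat(xform(mp[ut]))
    }, numeric(1))
  })
  p <- (1 + sum(abs(r_perm) >= abs(r_obs))) / (1 + n_perm)
  structure(list(partial_r = r_obs, p_value = p, n_perm = as.integer(n_perm),
                 method = method, n = n, n_covariates = length(covariates),
                 seed = as.integer(seed)),
            class = "els_isrsa")
}

#' @export
print.els_isrsa <- function(x, ...) {
  cat(sprintf("IS-RSA partial RDM correlation (%s): r = %.4f, p = %.4g (%d permutations, n = %d)\n",
              x$method, x$partial_r, x$p_value, x$n_perm, x$n))
  invisible(x)
}
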