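#' Gower centering of a dissimilarity matrix
#'
#' The classical multidimensional-scaling transform: with
#' `A = -1/2 * D^2` (elementwise square) and the centering projector
#' `J = I - 11'/N`, returns `G = J A J`.  Rows and columns of `G` sum to
#' zero, and when `D` holds Euclidean distances of a point configuration
#' `X`, `G` equals the centered Gram matrix `Xc Xc'`.
#'
#' @param d N x N symmetric dissimilarity matrix.
#' @return Centered inner-product matrix `G`.
#' @export
gower_center <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop_("D must be square")
  if (max(abs(d - t(d))) > 1e-8) stop_("D must be symmetric")
  a <- -0.5 * d^2
  n <- nrow(d)
  rm_ <- rowMeans(a); gm <- mean(a)
  g <- a - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
  dimnames(g) <- dimnames(d)
  g
}

#' Multivariate distance matrix regression
#'
#' Regresses a Gower-centered participant dissimilarity matrix on a design
#' of predictors and covariates.  With `H` the hat matrix of the full
#' design (always including an intercept) and `H_j = H - H_(-j)` the
#' increment of term j over the design without it, each term is summarized
#' by
#' \describe{
#'   \item{statistic}{`tr(H_j G) / tr((I - H) G)` — explained-to-residual
#'     trace ratio;}
#'   \item{pseudo R-squared}{`tr(H_j G) / tr(G)` — the share of the total
#'     centered dissimilarity attributable to the term.}
#' }
#' The omnibus row uses `H_omni = H - H_0` with `H_0` the intercept-only
#' hat matrix.  These definitions satisfy the identity
#' `pseudo_R2 / statistic = 1 - omnibus pseudo_R2` for every term.
#'
#' p-values come from Freedman-Lane residual permutation: for term j the
#' dissimilarity information is residualized on the reduced design
#' (`R_j = (I - H_(-j)) G (I - H_(-j))`), rows and columns of `R_j` are
#' permuted jointly, and the term statistic is recomputed `n_perm` times;
#' `p = (1 + #{stat_perm >= stat_obs}) / (1 + n_perm)`.  The omnibus test
#' permutes the intercept-residualized `G`.
#'
#' @param d N x N dissimilarity matrix (e.g. a connectivity RDM).
#' @param design data.frame/matrix of predictors and covariates, one row
#'   per participant in `d`'s order; every column is tested as a term.  An
#'   intercept is added automatically.
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed (required).
#' @return List of class `els_mdmr` with a tidy `table` (data.frame: term,
#'   statistic, df, pseudo_r2, p_value; first row `(Omnibus)`), plus
#'   `n_perm`, `seed`, `n`.
#' @export
mdmr_fit <- function(d, design, n_perm = 5000, seed = NULL) {
  if (is.null(seed)) stop_("seed is required")
  check_rdm(unclass(d), "distance matrix")
  n <- nrow(d)
  x <- stats::model.matrix(~ ., data = as.data.frame(design))
  terms <- colnames(x)[-1]
  if (nrow(x) != n) stop_("design rows must match the distance matrix")
  if (n <= ncol(x) + 2) stop_("too few participants for this design")
  if (qr(x)$rank < ncol(x)) {
    qx <- qr(x)
    dropped <- colnames(x)[qx$pivot[seq(qx$rank + 1, ncol(x))]]
    stop_("design is rank deficient; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }

  g <- gower_center(unclass(d))
  tr_g <- sum(diag(g))
  if (tr_g <= 0) stop_("degenerate distance matrix: tr(G) <= 0")

  hat_of <- function(xm) {
    q <- qr.Q(qr(xm))
    tcrossprod(q)
  }
  h_full <- hat_of(x)
  h0 <- hat_of(x[, 1, drop = FALSE])
  i_n <- diag(n)
  res_tr <- sum((i_n - h_full) * g)  # tr((I-H)G), by symmetry of both factors

  fit_term <- function(h_red, df) {
    h_j <- h_full - h_red
    stat <- sum(h_j * g) / res_tr
    r2 <- sum(h_j * g) / tr_g
    list(h_red = h_red, h_j = h_j, stat = stat, r2 = r2, df = df)
  }
  omni <- fit_term(h0, ncol(x) - 1L)
  per_term <- lapply(seq_along(terms), function(k) {
    fit_term(hat_of(x[, -(k + 1L), drop = FALSE]), 1L)
  })

  perm_p <- function(tm) {
    m <- i_n - tm$h_red
    r_g <- m %*% g %*% m                  # reduced-model residualized G
    h_j <- tm$h_j
    res_mat <- i_n - h_full
    stats_perm <- vapply(seq_len(n_perm), function(b) {
      pi_b <- sample.int(n)
      gp <- r_g[pi_b, pi_b]
      sum(h_j * gp) / sum(res_mat * gp)
    }, numeric(1))
    (1 + sum(stats_perm >= tm$stat)) / (1 + n_perm)
  }
  seeds <- vapply(c("omnibus", terms), function(s) derive_seed(seed, s), 0L)
  p_omni <- with_seed(seeds[["omnibus"]], perm_p(omni))
  p_terms <- vapply(seq_along(terms), function(k) {
    with_seed(seeds[[terms[k]]], perm_p(per_term[[k]]))
  }, numeric(1))

  tab <- data.frame(
    term = c("(Omnibus)", terms),
    statistic = c(omni$stat, vapply(per_term, `[[`, 0, "stat")),
    df = c(omni$df, vapply(per_term, `[[`, 0L, "df")),
    pseudo_r2 = c(omni$r2, vapply(per_term, `[[`, 0, "r2")),
    p_value = c(p_omni, p_terms),
    stringsAsFactors = FALSE)
  structure(list(table = tab, n = n, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "els_mdmr")
}

#' @export
print.els_mdmr <- function(x, ...) {
  cat(sprintf("MDMR (n = %d, %d permutations)\n", x$n, x$n_perm))
  tab <- x$table
  tab$statistic <- sprintf("%.4f", tab$statistic)
  tab$pseudo_r2 <- sprintf("%.5f", tab$pseudo_r2)
  tab$p_value <- ifelse(x$table$p_value < 1 / x$n_perm,
                        sprintf("<%.4g", 1 / x$n_perm),
                        sprintf("%.4g", x$table$p_value))
  print(tab, row.names = FALSE)
  invisible(x)
}
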