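#' Variable dictionary for the prospective ELS battery
#'
#' The prospective battery holds 20 variables: two mental-health instruments
#' (BDI, GHQ) filled by both parents at all three timepoints (pregnancy, T1;
#' child age 2 months, T2; child age 12 months, T3), and two relationship
#' instruments (DAS, PSI) filled by both parents at T2 and T3 only.
#'
#' @return data.frame with columns `variable`, `instrument`, `reporter`,
#'   `timepoint` (20 rows, in canonical column order).
#' @export
battery_variables <- function() {
  rows <- list()
  for (inst in c("BDI", "GHQ")) {
    for (rep in c("mother", "father")) {
      for (tp in c("T1", "T2", "T3")) rows[[length(rows) + 1]] <- c(inst, rep, tp)
    }
  }
  for (inst in c("DAS", "PSI")) {
    for (rep in c("mother", "father")) {
      for (tp in c("T2", "T3")) rows[[length(rows) + 1]] <- c(inst, rep, tp)
    }
  }
  d <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(d) <- c("instrument", "reporter", "timepoint")
  d$variable <- paste(d$instrument, d$reporter, d$timepoint, sep = "_")
  d[c("variable", "instrument", "reporter", "timepoint")]
}

check_battery <- function(battery) {
  battery <- as.matrix(battery)
  vars <- battery_variables()$variable
  if (is.null(colnames(battery))) {
    if (ncol(battery) != 20) stop_("battery must have the 20 canonical columns")
    colnames(battery) <- vars
  }
  missing_cols <- setdiff(vars, colnames(battery))
  if (length(missing_cols)) {
    stop_("battery missing variable(s): %s", paste(missing_cols, collapse = ", "))
  }
  battery[, vars, drop = FALSE]
}

#' Expectation-maximization imputation for the prospective battery
#'
#' Single-imputation EM under a multivariate normal model for the 20
#' battery variables.  The E-step fills the conditional expectations (and
#' conditional second moments) of each participant's missing cells given
#' their observed cells and the current mean/covariance; the M-step
#' re-estimates mean and covariance from the completed sufficient
#' statistics; iteration stops when the largest absolute change in any mean
#' or covariance entry falls below `tol`.  Missing cells are finally
#' replaced by their conditional means.
#'
#' Participants missing more than `max_missing` of the 20 variables are
#' excluded with a warning before fitting (the eligibility rule for this
#' battery); the model parameters are estimated from the analysis sample
#' itself.
#'
#' @param battery participants x variables numeric matrix (NAs = missing);
#'   for the canonical battery, columns as in [battery_variables()] and
#'   rownames = participant ids.  Any numeric matrix with >= 2 columns is
#'   accepted — the EM is not specific to the 20-variable battery.
#' @param tol Convergence threshold on the maximum absolute parameter
#'   change (default 1e-6).
#' @param max_iter Maximum EM iterations (default 500).
#' @param ridge Variance floor added to the covariance diagonal each M-step
#'   for numerical stability (default 1e-8).
#' @param max_missing Per-participant missing-variable cap (default 8).
#' @return List: `completed` (imputed matrix, excluded rows dropped),
#'   `n_imputed_cells`, `em_iterations`, `em_converged`, `excluded_ids`,
#'   `imputed_mask` (logical matrix of imputed cells).
#' @export
em_impute <- function(battery, tol = 1e-6, max_iter = 500, ridge = 1e-8,
                      max_missing = 8) {
  y <- as.matrix(battery)
  if (ncol(y) < 2) stop_("need at least 2 variables")
  storage.mode(y) <- "double"
  n_miss_row <- rowSums(is.na(y))
  drop <- n_miss_row > max_missing
  if (any(drop)) {
    ids <- rownames(y)[drop] %||% which(drop)
    warn_("excluding %d participant(s) with > %d of %d variables missing: %s",
          sum(drop), max_missing, ncol(y), paste(ids, collapse = ", "))
    y <- y[!drop, , drop = FALSE]
  }
  n_obs_col <- colSums(!is.na(y))
  if (any(n_obs_col < 2)) {
    stop_("variable(s) observed for fewer than 2 participants: %s",
          paste(colnames(y)[n_obs_col < 2], collapse = ", "))
  }
  miss <- is.na(y)
  n <- nrow(y); p <- ncol(y)
  if (!any(miss)) {
    return(list(completed = y, n_imputed_cells = 0L, em_iterations = 0L,
                em_converged = TRUE, excluded_ids = rownames(battery)[drop],
                imputed_mask = miss))
  }

  ## start values: observed means; covariance of mean-filled data
  mu <- colMeans(y, na.rm = TRUE)
  y0 <- y
  for (j in seq_len(p)) y0[miss[, j], j] <- mu[j]
  sigma <- stats::cov(y0) * (n - 1) / n
  diag(sigma) <- diag(sigma) + ridge

  patterns <- apply(miss, 1, function(m) paste(which(m), collapse = ","))
  converged <- FALSE
  iter <- 0L
  yhat <- y
  for (iter in seq_len(max_iter)) {
    cross_extra <- matrix(0, p, p)  # conditional covariance contributions
    for (pat in unique(patterns)) {
      rows <- which(patterns == pat)
      if (pat == "") { next }
      m_idx <- as.integer(strsplit(pat, ",")[[1]])
      o_idx <- setdiff(seq_len(p), m_idx)
      s_oo <- sigma[o_idx, o_idx, drop = FALSE]
      s_mo <- sigma[m_idx, o_idx, drop = FALSE]
      reg <- tryCatch(s_mo %*% solve(s_oo),
                      error = function(e) stop_("covariance singular during EM (ridge %g too small)", ridge))
      cond_cov <- sigma[m_idx, m_idx, drop = FALSE] - reg %*% t(s_mo)
      for (i in rows) {
        yhat[i, m_idx] <- mu[m_idx] + reg %*% (y[i, o_idx] - mu[o_idx])
      }
      cross_extra[m_idx, m_idx] <- cross_extra[m_idx, m_idx] +
        length(rows) * cond_cov
    }
    mu_new <- colMeans(yhat)
    centered <- sweep(yhat, 2, mu_new)
    sigma_new <- (crossprod(centered) + cross_extra) / n
    diag(sigma_new) <- diag(sigma_new) + ridge
    delta <- max(abs(mu_new - mu), abs(sigma_new - sigma))
    mu <- mu_new; sigma <- sigma_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(completed = yhat,
       n_imputed_cells = sum(miss),
       em_iterations = iter,
       em_converged = converged,
       excluded_ids = rownames(battery)[drop],
       imputed_mask = miss)
}

#' Prospective cumulative risk index
#'
#' Collapses the completed 20-variable battery into one z-scored composite:
#' each instrument's scores are averaged over timepoints, then over the two
#' parents, z-standardized across participants (sample SD, n-1 denominator),
#' and the four standardized instrument scores are averaged.  The composite
#' mean is exactly 0 by construction.  Cronbach's alpha of the 20 raw
#' variables is reported as the battery's internal-consistency diagnostic.
#'
#' @param battery Completed (no missing cells) participants x 20 matrix.
#' @return List of class `els_risk_index`: `composite` (named vector,
#'   z-units), `instrument_scores` (participants x 4, standardized),
#'   `alpha_20`.
#' @export
prospective_risk_index <- function(battery) {
  y <- check_battery(battery)
  if (anyNA(y)) stop_("battery has missing cells; run em_impute() first")
  dict <- battery_variables()
  insts <- unique(dict$instrument)
  inst_scores <- sapply(insts, function(inst) {
    per_reporter <- sapply(c("mother", "father"), function(rep) {
      v <- dict$variable[dict$instrument == inst & dict$reporter == rep]
      rowMeans(y[, v, drop = FALSE])          # mean over timepoints
    })
    rowMeans(per_reporter)                    # mean over parents
  })
  inst_z <- apply(inst_scores, 2, zscore)
  if (nrow(y) == 1) inst_z <- matrix(inst_z, nrow = 1, dimnames = list(rownames(y), insts))
  composite <- rowMeans(inst_z)
  names(composite) <- rownames(y)
  structure(list(composite = composite,
                 instrument_scores = inst_z,
                 alpha_20 = if (nrow(y) >= 3) cronbach_alpha(y) else NA_real_),
            class = "els_risk_index")
}

#' Item dictionary for the retrospective ELS questionnaire
#'
#' Twelve adverse-childhood-experience domains: five assessed by two items
#' each on a 0/1/2 scale (0 = never, 1 = sometimes, 2 = often) and seven by
#' one binary item scored 0 = no, 2 = yes.
#'
#' @return data.frame with `item`, `domain`, `type` (`ordinal`/`binary`).
#' @export
retro_item_dictionary <- function() {
  two <- c("emotional_abuse", "physical_abuse", "emotional_neglect",
           "parent_treated_violently", "interparental_psych_violence")
  one <- c("family_alcohol_drug", "peer_victimization", "parents_divorce",
           "family_mental_illness", "death_of_close_person",
           "family_somatic_illness", "other_adversity")
  rbind(
    data.frame(item = paste0(rep(two, each = 2), "_", 1:2),
               domain = rep(two, each = 2), type = "ordinal",
               stringsAsFactors = FALSE),
    data.frame(item = one, domain = one, type = "binary",
               stringsAsFactors = FALSE))
}

#' Retrospective ELS domain-sum score
#'
#' Each two-item domain is scored as the mean of its two items; each binary
#' domain as its single item (0 or 2); the total is the sum of the 12 domain
#' scores, ranging 0-24.
#'
#' @param items participants x 17 matrix/data.frame with columns named as in
#'   [retro_item_dictionary()]; ordinal items in \{0, 1, 2\}, binary items in
#'   \{0, 2\}.
#' @return Named numeric vector of totals in \[0, 24\].
#' @export
retrospective_els_score <- function(items) {
  dict <- retro_item_dictionary()
  items <- as.data.frame(items)
  missing_cols <- setdiff(dict$item, names(items))
  if (length(missing_cols)) {
    stop_("items table missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  ids <- rownames(items) %||% seq_len(nrow(items))
  for (k in seq_len(nrow(dict))) {
    legal <- if (dict$type[k] == "ordinal") c(0, 1, 2) else c(0, 2)
    v <- items[[dict$item[k]]]
    bad <- is.na(v) | !v %in% legal
    if (any(bad)) {
      stop_("illegal value for item '%s', participant(s) %s (allowed: %s)",
            dict$item[k], paste(ids[bad], collapse = ", "),
            paste(legal, collapse = "/"))
    }
  }
  domains <- unique(dict$domain)
  dom_scores <- sapply(domains, function(d) {
    cols <- dict$item[dict$domain == d]
    rowMeans(as.matrix(items[cols]))
  })
  if (nrow(items) == 1) dom_scores <- matrix(dom_scores, nrow = 1)
  total <- rowSums(dom_scores)
  names(total) <- ids
  total
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient `alpha = k/(k-1) * (1 - sum(item
#' variances) / variance(item sum))`, sample variances.
#'
#' @param item_matrix participants x items numeric matrix, no missing cells.
#' @export
cronbach_alpha <- function(item_matrix) {
  y <- as.matrix(item_matrix)
  if (ncol(y) < 2) stop_("need at least 2 items")
  if (nrow(y) < 3) stop_("need at least 3 participants")
  if (anyNA(y)) stop_("missing cells not allowed; impute first")
  total_var <- stats::var(rowSums(y))
  if (total_var == 0) stop_("zero total-score variance; alpha undefined")
  k <- ncol(y)
  k / (k - 1) * (1 - sum(apply(y, 2, stats::var)) / total_var)
}
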