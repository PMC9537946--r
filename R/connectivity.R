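#' Motion quality control: exclude high-motion participants
#'
#' Retains participants whose mean framewise displacement (FD) does not
#' exceed the threshold; the rule is a strict inequality, so a participant at
#' exactly the threshold is retained.  The 0.2 mm default is the conventional
#' cut-off for resting-state cohorts of this kind.
#'
#' @param cohort data.frame with columns `participant_id` and `mean_fd` (mm).
#' @param fd_threshold Exclusion threshold in mm; participants with
#'   `mean_fd > fd_threshold` are dropped.
#' @return List with `retained_ids`, `excluded_ids`, and `log` (data.frame of
#'   excluded participants with their mean FD).
#' @export
qc_filter <- function(cohort, fd_threshold = 0.2) {
  if (!all(c("participant_id", "mean_fd") %in% names(cohort))) {
    stop_("cohort table must have participant_id and mean_fd columns")
  }
  if (anyNA(cohort$mean_fd)) {
    stop_("mean_fd missing for participant(s): %s",
          paste(cohort$participant_id[is.na(cohort$mean_fd)], collapse = ", "))
  }
  drop <- cohort$mean_fd > fd_threshold
  list(retained_ids = cohort$participant_id[!drop],
       excluded_ids = cohort$participant_id[drop],
       log = data.frame(participant_id = cohort$participant_id[drop],
                        mean_fd = cohort$mean_fd[drop],
                        reason = rep(sprintf("mean FD > %g mm", fd_threshold),
                                     sum(drop)),
                        stringsAsFactors = FALSE))
}

#' Pearson connectivity matrix from ROI time series
#'
#' Correlates every pair of ROI signal columns, giving the participant's
#' R x R functional connectivity matrix (12 x 12 for the packaged networks).
#' Inputs are assumed fully preprocessed ROI means; no detrending or
#' filtering is applied here.
#'
#' @param ts Numeric matrix, volumes x ROIs, with ROI labels as column names
#'   (or supplied via `roi_labels`).
#' @param roi_labels Optional ROI labels overriding column names.
#' @return Symmetric correlation matrix with unit diagonal, dimnames set to
#'   the ROI labels, class `els_connectivity`.
#' @export
connectivity_matrix <- function(ts, roi_labels = NULL) {
  ts <- as.matrix(ts)
  if (!is.null(roi_labels)) colnames(ts) <- roi_labels
  if (is.null(colnames(ts))) stop_("ROI labels required (column names)")
  if (anyDuplicated(colnames(ts))) stop_("ROI labels must be unique")
  if (nrow(ts) < 3) stop_("need at least 3 volumes")
  v <- apply(ts, 2, stats::var)
  if (any(v == 0)) {
    stop_("constant signal in ROI(s): %s",
          paste(colnames(ts)[v == 0], collapse = ", "))
  }
  cm <- stats::cor(ts)
  diag(cm) <- 1
  class(cm) <- c("els_connectivity", class(cm))
  cm
}

#' Vectorize a connectivity matrix into a fixed-order edge profile
#'
#' Takes the row-major upper triangle (excluding the diagonal) of a symmetric
#' connectivity matrix, yielding the participant's connectivity profile:
#' R(R-1)/2 values (66 for 12 ROIs) in an order that is identical for every
#' participant sharing the ROI label order, as inter-subject analyses
#' require.  [devectorize_profile()] is the exact inverse.
#'
#' @param cm Symmetric matrix with ROI labels as dimnames.
#' @return Named numeric vector (names `"A--B"`), attribute `roi_labels`.
#' @seealso [edge_index()] for the edge order contract.
#' @export
vectorize_profile <- function(cm) {
  cm <- unclass(cm)
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) stop_("cm must be square")
  if (max(abs(cm - t(cm))) > 1e-8) stop_("cm must be symmetric")
  labs <- rownames(cm)
  if (is.null(labs)) stop_("cm must carry ROI labels as dimnames")
  idx <- edge_index(labs)
  prof <- cm[cbind(idx$i, idx$j)]
  names(prof) <- idx$edge_label
  attr(prof, "roi_labels") <- labs
  prof
}

#' @rdname vectorize_profile
#' @param profile Numeric vector of length R(R-1)/2.
#' @param roi_labels ROI labels of the target matrix; defaults to the
#'   `roi_labels` attribute of `profile`.
#' @export
devectorize_profile <- function(profile, roi_labels = attr(profile, "roi_labels")) {
  if (is.null(roi_labels)) stop_("roi_labels required")
  r <- length(roi_labels)
  if (length(profile) != r * (r - 1) / 2) {
    stop_("profile length %d does not match %d ROIs (expected %d)",
          length(profile), r, r * (r - 1) / 2)
  }
  idx <- edge_index(roi_labels)
  cm <- diag(1, r)
  cm[cbind(idx$i, idx$j)] <- profile
  cm[cbind(idx$j, idx$i)] <- profile
  dimnames(cm) <- list(roi_labels, roi_labels)
  cm
}

#' Mean connectivity of a profile
#'
#' Arithmetic mean of the edge correlations — the network's mean correlation
#' strength.  By default raw r values are averaged; `fisher = TRUE` averages
#' Fisher z-transformed values and back-transforms the mean.
#'
#' @param profile Edge vector from [vectorize_profile()].
#' @param fisher Average in Fisher z space (default FALSE, raw r).
#' @export
mean_connectivity <- function(profile, fisher = FALSE) {
  if (length(profile) == 0) stop_("empty profile")
  if (fisher) tanh(mean(atanh(profile))) else mean(profile)
}

#' Look up a named edge in a connectivity matrix
#'
#' Label order is irrelevant: `edge_value(cm, "L_OFC", "L_AMG")` equals
#' `edge_value(cm, "L_AMG", "L_OFC")`.
#'
#' @param cm Connectivity matrix with ROI dimnames.
#' @param label_a,label_b ROI labels.
#' @export
edge_value <- function(cm, label_a, label_b) {
  labs <- rownames(cm)
  for (l in c(label_a, label_b)) {
    if (!l %in% labs) {
      stop_("unknown ROI label '%s'; valid labels: %s",
            l, paste(labs, collapse = ", "))
    }
  }
  unname(cm[label_a, label_b])
}

#' Connectivity profiles for a set of participants
#'
#' Convenience wrapper: computes each participant's correlation matrix and
#' stacks the fixed-order edge profiles into a participants x edges matrix.
#'
#' @param timeseries Named list of volumes x ROIs matrices (names =
#'   participant ids).
#' @param roi_labels Optional ROI order to enforce across participants.
#' @return Matrix participants x edges, rownames = participant ids, colnames
#'   = edge labels.
#' @export
connectivity_profiles <- function(timeseries, roi_labels = NULL) {
  stopifnot(is.list(timeseries), !is.null(names(timeseries)))
  profs <- lapply(names(timeseries), function(id) {
    ts <- timeseries[[id]]
    if (!is.null(roi_labels)) {
      missing_cols <- setdiff(roi_labels, colnames(ts))
      if (length(missing_cols)) {
        stop_("participant %s: time series missing ROI column(s): %s",
              id, paste(missing_cols, collapse = ", "))
      }
      ts <- ts[, roi_labels, drop = FALSE]
    }
    vectorize_profile(connectivity_matrix(ts))
  })
  out <- do.call(rbind, profs)
  rownames(out) <- names(timeseries)
  out
}
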