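#' Simulation configuration for a synthetic ELS cohort
#'
#' Bundles and validates every knob of the synthetic-cohort generator.  The
#' generator emulates the data structure of a prospective birth-cohort
#' neuroimaging study: a 20-variable prospective questionnaire battery with
#' realistic block and item missingness, 12 retrospective
#' adverse-childhood-experience domains, background covariates, motion
#' summaries, and 12-ROI BOLD-like time series whose covariance carries
#' plantable ELS effects.
#'
#' Two latent ELS variables (prospective, retrospective) are drawn jointly
#' with correlation `retro_prospective_corr` (default 0.2: the two
#' operationalizations of early-life stress typically show poor
#' convergence).  Two effects can be planted in the time-series covariance
#' of participant i:
#' \describe{
#'   \item{`beta_mean`}{mean-level effect: the retrospective latent (in z
#'     units) shifts every off-diagonal covariance entry by
#'     `beta_mean * z_retro_i`, raising or lowering mean connectivity.}
#'   \item{`beta_pattern`}{pattern-level effect: the prospective latent
#'     scales a fixed zero-trace symmetric pattern matrix `P` (unit
#'     root-mean-square off-diagonal, zero mean, so it reshapes the
#'     connectivity profile with little effect on its mean), coupling ELS
#'     similarity to profile similarity.}
#' }
#' Each participant's covariance is eigenvalue-clipped at 1e-6 to restore
#' positive definiteness after perturbation.
#'
#' @param n_participants Number of participants.
#' @param n_rois Number of ROIs (default 12).
#' @param n_volumes Time-series length in volumes (default 150).
#' @param sampling_interval Repetition time in seconds (default 2.5).
#' @param beta_mean Mean-level connectivity effect of the standardized
#'   retrospective latent (default 0, null).
#' @param beta_pattern Pattern-level effect of the standardized prospective
#'   latent (default 0, null).
#' @param retro_prospective_corr Correlation of the two latents (default 0.2).
#' @param missing_block_rate Probability a participant is missing one whole
#'   instrument (all its reporter x timepoint variables; default 8/92).
#' @param missing_item_rate MCAR per-cell missingness rate applied on top
#'   (default 0.004, so roughly 7 in 92 participants have scattered gaps).
#' @param fd_exceed_fraction Fraction of participants whose mean framewise
#'   displacement is scaled to exceed 0.2 mm (default 6/92).
#' @param loading Common standardized loading of the 20 battery variables on
#'   the prospective latent, in (0, 1] (default 0.574, tuned so the battery's
#'   Cronbach's alpha is close to 0.88).
#' @param ar1 Optional AR(1) coefficient for temporally autocorrelated
#'   time-series noise (default 0, white).
#' @param roi_labels ROI label order for the time series (default the
#'   packaged DMN's 12 labels).
#' @param seed Integer seed; required — the generator refuses to run
#'   unseeded.
#' @return Validated list of class `els_sim_config`.
#' @export
sim_config <- function(n_participants,
                       n_rois = 12,
                       n_volumes = 150,
                       sampling_interval = 2.5,
                       beta_mean = 0,
                       beta_pattern = 0,
                       retro_prospective_corr = 0.2,
                       missing_block_rate = 8 / 92,
                       missing_item_rate = 0.004,
                       fd_exceed_fraction = 6 / 92,
                       loading = 0.574,
                       ar1 = 0,
                       roi_labels = NULL,
                       seed = NULL) {
  if (is.null(seed)) stop_("seed is required (reproducibility contract)")
  for (nm in c("n_participants", "n_rois", "n_volumes")) {
    if (!is_count(get(nm))) stop_("%s must be a positive integer", nm)
  }
  if (n_volumes < 3) stop_("n_volumes must be at least 3")
  if (!is_prob(missing_block_rate) || !is_prob(missing_item_rate) ||
      !is_prob(fd_exceed_fraction)) {
    stop_("missingness/FD rates must lie in [0, 1]")
  }
  if (abs(retro_prospective_corr) > 1) stop_("|retro_prospective_corr| must be <= 1")
  if (!(loading > 0 && loading <= 1)) stop_("loading must lie in (0, 1]")
  if (abs(ar1) >= 1) stop_("|ar1| must be < 1")
  if (is.null(roi_labels)) {
    roi_labels <- if (n_rois == 12) network_definition("dmn")$roi_labels
                  else paste0("ROI", seq_len(n_rois))
  }
  if (length(roi_labels) != n_rois) stop_("roi_labels length must equal n_rois")
  structure(list(n_participants = as.integer(n_participants),
                 n_rois = as.integer(n_rois),
                 n_volumes = as.integer(n_volumes),
                 sampling_interval = sampling_interval,
                 beta_mean = beta_mean, beta_pattern = beta_pattern,
                 retro_prospective_corr = retro_prospective_corr,
                 missing_block_rate = missing_block_rate,
                 missing_item_rate = missing_item_rate,
                 fd_exceed_fraction = fd_exceed_fraction,
                 loading = loading, ar1 = ar1,
                 roi_labels = roi_labels,
                 seed = as.integer(seed)),
            class = "els_sim_config")
}

## Block-structured base covariance: unit diagonal, homologous left/right
## pairs at 0.45, pairs within the first three (densely coupled) regions at
## 0.25, all remaining pairs at 0.10.  Mirrors the qualitative structure of
## empirical within-network ROI correlation matrices.
base_covariance <- function(n_rois) {
  s <- matrix(0.10, n_rois, n_rois)
  region <- (seq_len(n_rois) + 1L) %/% 2L      # ROIs 2k-1, 2k share region k
  for (i in seq_len(n_rois)) {
    for (j in seq_len(n_rois)) {
      if (i != j && region[i] == region[j]) s[i, j] <- 0.45
      else if (i != j && region[i] <= 3 && region[j] <= 3) s[i, j] <- 0.25
    }
  }
  diag(s) <- 1
  if (min(eigen(s, symmetric = TRUE, only.values = TRUE)$values) < 1e-6) {
    stop_("base covariance is not positive definite")
  }
  s
}

## Fixed zero-trace symmetric perturbation pattern: zero diagonal,
## off-diagonal entries centered to mean 0 and scaled to unit RMS.  Built
## from an internal constant seed so it is identical across runs and
## independent of the user's seed.
pattern_matrix <- function(n_rois) {
  with_seed(104729L, {
    p <- matrix(0, n_rois, n_rois)
    ut <- upper.tri(p)
    v <- stats::rnorm(sum(ut))
    v <- v - mean(v)
    v <- v / sqrt(mean(v^2))
    p[ut] <- v
    p + t(p)
  })
}

## Eigenvalue clipping: smallest PD repair that preserves the perturbation
## direction.  Floor defaults to 1e-6.
clip_pd <- function(s, floor = 1e-6) {
  e <- eigen(s, symmetric = TRUE)
  if (any(!is.finite(e$values))) stop_("covariance not repairable: non-finite eigenvalues")
  vals <- pmax(e$values, floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  (out + t(out)) / 2
}

#' Simulate questionnaire data from latent ELS values
#'
#' Generates the 20-variable prospective battery and the 17 retrospective
#' items for given latent ELS values.  Each battery variable is
#' `loading * z_prospective + noise` on a standardized scale, then shifted
#' and scaled to an instrument-realistic range (all instruments are
#' problem-scored: higher = more family adversity).  The common loading is
#' tuned so that the 20 variables' Cronbach's alpha is about 0.88.
#' Retrospective items follow ordered-logit (0/1/2 ordinal domains) or
#' logit (0/2 binary domains) models whose endorsement probability
#' increases with the retrospective latent; domain intercepts are set so
#' the domain-sum total averages about 4.5 with SD about 2.6 in an
#' unselected cohort.  Block missingness (one whole instrument) and MCAR
#' item missingness are applied to the battery afterwards.
#'
#' @param config An `els_sim_config`.
#' @param latent_els data.frame/matrix with columns `prospective` and
#'   `retrospective` (z-scaled latents, one row per participant).
#' @return List: `battery` (participants x 20 matrix, NAs where missing),
#'   `retro_items` (participants x 17 data.frame).
#' @export
simulate_questionnaires <- function(config, latent_els) {
  stopifnot(inherits(config, "els_sim_config"))
  latent_els <- as.data.frame(latent_els)
  if (!all(c("prospective", "retrospective") %in% names(latent_els))) {
    stop_("latent_els needs columns 'prospective' and 'retrospective'")
  }
  if (!all(is.finite(latent_els$prospective)) ||
      !all(is.finite(latent_els$retrospective))) {
    stop_("latent ELS values must be finite")
  }
  n <- nrow(latent_els)
  lam <- config$loading
  dict <- battery_variables()
  scale_of <- c(BDI = 4, GHQ = 9, DAS = 15, PSI = 15)
  mean_of <- c(BDI = 5, GHQ = 20, DAS = 35, PSI = 70)

  z <- latent_els$prospective
  battery <- sapply(seq_len(nrow(dict)), function(k) {
    inst <- dict$instrument[k]
    std <- lam * z + sqrt(1 - lam^2) * stats::rnorm(n)
    mean_of[[inst]] + scale_of[[inst]] * std
  })
  colnames(battery) <- dict$variable
  rownames(battery) <- rownames(latent_els)

  ## block missingness: one whole instrument (all reporters x timepoints)
  blocked <- stats::runif(n) < config$missing_block_rate
  which_inst <- sample(unique(dict$instrument), n, replace = TRUE)
  for (i in which(blocked)) {
    battery[i, dict$variable[dict$instrument == which_inst[i]]] <- NA
  }
  ## MCAR item missingness
  mcar <- matrix(stats::runif(n * 20) < config$missing_item_rate, n, 20)
  battery[mcar] <- NA

  ## retrospective items: ordered-logit / logit with latent-linked slopes
  zr <- latent_els$retrospective
  rdict <- retro_item_dictionary()
  slope <- 0.5                       # latent slope on the logit scale
  tau <- c(1.3, 2.7)                 # ordinal thresholds (item >= 1, item == 2)
  bin_icpt <- c(family_alcohol_drug = -2.3, peer_victimization = -1.3,
                parents_divorce = -1.5, family_mental_illness = -2.1,
                death_of_close_person = -0.1, family_somatic_illness = -1.1,
                other_adversity = -2.7)
  retro_items <- as.data.frame(sapply(seq_len(nrow(rdict)), function(k) {
    w <- slope * zr + stats::rlogis(n)
    if (rdict$type[k] == "ordinal") {
      (w > tau[1]) + (w > tau[2])
    } else {
      2 * (w > -bin_icpt[[rdict$item[k]]])
    }
  }))
  names(retro_items) <- rdict$item
  rownames(retro_items) <- rownames(latent_els)
  list(battery = battery, retro_items = retro_items)
}

#' Simulate a complete synthetic cohort
#'
#' Draws latent ELS values, covariates, motion summaries, questionnaires and
#' per-participant ROI time series in one seeded pass.  Participant-level
#' draws and time-series draws use separate substreams derived from
#' `config$seed`, so cohorts simulated with the same seed but different ROI
#' sets share identical participants.
#'
#' Time series for participant i are multivariate normal with covariance
#' `clip_pd(S0 + beta_mean * z_retro_i * U + beta_pattern * z_prosp_i * P)`
#' where `S0` is the fixed block-structured base covariance, `U` the
#' all-off-diagonal unit pattern and `P` the fixed zero-trace pattern (see
#' [sim_config()]).  Mean framewise displacement is lognormal, rescaled so
#' that `round(fd_exceed_fraction * n)` participants exceed the 0.2 mm
#' motion cut-off exactly.
#'
#' @param config An `els_sim_config` (seed required).
#' @return List of class `els_cohort`: `cohort_table` (data.frame:
#'   participant_id, sex, art, mother_age, mother_ses, mean_fd), `battery`,
#'   `retro_items`, `timeseries` (named list of n_volumes x n_rois matrices),
#'   `truth` (latents and planted effect sizes), `config`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_participants = 8, n_volumes = 60, seed = 1))
#' dim(coh$timeseries[[1]])
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "els_sim_config"))
  n <- config$n_participants
  ids <- sprintf("sub-%03d", seq_len(n))

  part <- with_seed(derive_seed(config$seed, "participants"), {
    ## latents: bivariate standard normal with target correlation
    rho <- config$retro_prospective_corr
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    latent <- data.frame(prospective = z1, retrospective = z2,
                         row.names = ids)
    covars <- data.frame(
      participant_id = ids,
      sex = stats::rbinom(n, 1, 0.5),
      art = stats::rbinom(n, 1, 0.5),
      mother_age = stats::rnorm(n, 48, 4),
      mother_ses = sample(0:4, n, replace = TRUE),
      stringsAsFactors = FALSE)
    fd <- stats::rlnorm(n, meanlog = -2.1, sdlog = 0.35)
    k <- round(config$fd_exceed_fraction * n)
    if (k > 0 && k < n) {
      srt <- sort(fd)
      cut <- sqrt(srt[n - k] * srt[n - k + 1])  # geometric midpoint
      fd <- fd * (0.2 / cut)
    } else if (k == 0 && max(fd) > 0.2) {
      fd <- fd * (0.19 / max(fd))
    } else if (k == n) {
      fd <- fd * (0.21 / min(fd)) * 1.01
    }
    covars$mean_fd <- fd
    q <- simulate_questionnaires(config, latent)
    list(latent = latent, covars = covars, q = q)
  })

  s0 <- base_covariance(config$n_rois)
  u <- matrix(1, config$n_rois, config$n_rois); diag(u) <- 0
  p <- pattern_matrix(config$n_rois)
  ts_seed <- derive_seed(config$seed,
                         paste0("timeseries:", paste(config$roi_labels, collapse = ",")))
  timeseries <- with_seed(ts_seed, {
    lapply(seq_len(n), function(i) {
      s_i <- clip_pd(s0 +
                       config$beta_mean * part$latent$retrospective[i] * u +
                       config$beta_pattern * part$latent$prospective[i] * p)
      x <- MASS::mvrnorm(config$n_volumes, mu = rep(0, config$n_rois),
                         Sigma = s_i)
      if (config$ar1 != 0) {
        x <- apply(x, 2, function(col) {
          as.numeric(stats::filter(col, config$ar1, method = "recursive")) *
            sqrt(1 - config$ar1^2)
        })
      }
      colnames(x) <- config$roi_labels
      x
    })
  })
  names(timeseries) <- ids

  structure(list(
    cohort_table = part$covars,
    battery = part$q$battery,
    retro_items = part$q$retro_items,
    timeseries = timeseries,
    truth = list(latent_prospective = stats::setNames(part$latent$prospective, ids),
                 latent_retrospective = stats::setNames(part$latent$retrospective, ids),
                 beta_mean = config$beta_mean,
                 beta_pattern = config$beta_pattern),
    config = config), class = "els_cohort")
}

#' @export
print.els_cohort <- function(x, ...) {
  cat(sprintf("<els_cohort> %d participants, %d x %d time series, seed %d\n",
              nrow(x$cohort_table), x$config$n_volumes, x$config$n_rois,
              x$config$seed))
  cat(sprintf("  planted effects: beta_mean = %g, beta_pattern = %g\n",
              x$truth$beta_mean, x$truth$beta_pattern))
  invisible(x)
}
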