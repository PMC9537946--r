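#' Assemble and validate a pipeline run configuration
#'
#' A run either simulates its cohort (`simulation` = list of [sim_config()]
#' arguments, seed excluded) or reads one from disk (`input` = list with
#' `dir`, the cohort directory written by [write_cohort()]).  All
#' randomness in the run — simulation, IS-RSA and MDMR permutations — is
#' derived from the single master `seed` through named substreams, so
#' switching one analysis off does not shift another's random numbers.
#'
#' @param seed Master integer seed (required).
#' @param simulation List of arguments for [sim_config()] (or NULL).
#' @param input List with `dir` pointing at a cohort directory (or NULL).
#' @param network `"dmn"`, `"fln"`, or an `els_network`.
#' @param analyses Subset of `c("univariate", "isrsa", "mdmr", "contrast")`.
#' @param covariates Covariate column names in the participant table.
#' @param n_perm Permutations for IS-RSA and MDMR (default 5000).
#' @param isrsa_method `"spearman"` (default) or `"pearson"`.
#' @param outlier_k SD multiplier for outlier screening (default 2).
#' @param contrast_fraction Tail fraction for extreme-group contrasts
#'   (default 0.35, i.e. about 30 of 86).
#' @param fd_threshold Motion exclusion threshold in mm (default 0.2).
#' @param out_dir Optional output directory; when given, every stage's
#'   artifact is written there.
#' @return Validated list of class `els_run_config`.
#' @export
run_config <- function(seed, simulation = NULL, input = NULL,
                       network = "dmn",
                       analyses = c("univariate", "isrsa", "mdmr", "contrast"),
                       covariates = c("sex", "art", "mother_age", "mother_ses"),
                       n_perm = 5000, isrsa_method = "spearman",
                       outlier_k = 2, contrast_fraction = 0.35,
                       fd_threshold = 0.2, out_dir = NULL) {
  if (missing(seed) || is.null(seed)) stop_("seed is required")
  if (is.null(simulation) && is.null(input)) {
    stop_("config needs either a simulation block or an input block")
  }
  if (!is.null(simulation) && !is.null(input)) {
    stop_("config cannot have both simulation and input blocks")
  }
  analyses <- match.arg(analyses, several.ok = TRUE)
  net <- if (inherits(network, "els_network")) network else network_definition(network)
  structure(list(seed = as.integer(seed), simulation = simulation,
                 input = input, network = net, analyses = analyses,
                 covariates = covariates, n_perm = n_perm,
                 isrsa_method = isrsa_method, outlier_k = outlier_k,
                 contrast_fraction = contrast_fraction,
                 fd_threshold = fd_threshold, out_dir = out_dir),
            class = "els_run_config")
}

config_hash <- function(config) {
  js <- jsonlite::toJSON(config[setdiff(names(config), "network")],
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 0
  for (ch in utf8ToInt(as.character(js))) h <- (h * 131 + ch) %% 2147483587
  sprintf("%s-%08x", config$network$name, h)
}

#' Run the full ELS-connectivity analysis pipeline
#'
#' Executes, in order: cohort acquisition (simulate or read), motion QC,
#' risk scoring (EM imputation, prospective composite, retrospective domain
#' sum), connectivity profiling, and the requested analyses:
#' \describe{
#'   \item{univariate}{Spearman correlation of each ELS score with the
#'     network's mean connectivity, a partial correlation controlling for
#'     the background covariates, and Steiger's test comparing the two ELS
#'     correlations; participants outlying in mean connectivity (by the
#'     `outlier_k`-SD rule) are excluded listwise first.}
#'   \item{isrsa}{Connectivity RDM vs each ELS model RDM, partialling out
#'     the covariate model RDMs, permutation p-values; participants
#'     outlying in mean RDM row dissimilarity excluded listwise first.}
#'   \item{mdmr}{MDMR of the connectivity RDM on both ELS scores plus
#'     covariates (no outlier screening; the trace statistic pools all
#'     participants, as distance-matrix regression conventionally does).}
#'   \item{contrast}{Edge-wise Welch contrasts between extreme high/low
#'     groups on each ELS score.}
#' }
#'
#' @param config An `els_run_config` from [run_config()].
#' @return List of class `els_run_report`: per-stage tables, provenance
#'   (config hash, seed, package version, timestamp) and a warnings log.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "els_run_config"))
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))
  in_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(config$out_dir)) {
        dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
        writeLines(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
                   file.path(config$out_dir, "FAILED"))
      }
      stop_("stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }
  net <- config$network

  ## --- cohort -----------------------------------------------------------
  cohort <- in_stage("cohort", {
    if (!is.null(config$simulation)) {
      sim_args <- config$simulation
      sim_args$seed <- derive_seed(config$seed, "simulate")
      sim_args$roi_labels <- sim_args$roi_labels %||% net$roi_labels
      sim_args$n_rois <- length(sim_args$roi_labels)
      simulate_cohort(do.call(sim_config, sim_args))
    } else {
      read_cohort_dir(config$input$dir, roi_labels = net$roi_labels)
    }
  })
  ct <- cohort$cohort_table
  missing_cov <- setdiff(config$covariates, names(ct))
  if (length(missing_cov)) {
    stop_("validation: covariate column(s) not in participant table: %s",
          paste(missing_cov, collapse = ", "))
  }

  ## --- motion QC --------------------------------------------------------
  qc <- in_stage("qc_filter", qc_filter(ct, config$fd_threshold))
  keep <- qc$retained_ids
  if (length(qc$excluded_ids)) {
    note("motion QC excluded %d participant(s): %s", length(qc$excluded_ids),
         paste(qc$excluded_ids, collapse = ", "))
  }
  ct <- ct[ct$participant_id %in% keep, , drop = FALSE]

  ## --- risk scores ------------------------------------------------------
  em <- in_stage("risk_scores", withCallingHandlers(
    em_impute(cohort$battery[keep, , drop = FALSE]),
    warning = function(w) { note("%s", conditionMessage(w)); invokeRestart("muffleWarning") }))
  if (length(em$excluded_ids)) {
    keep <- setdiff(keep, em$excluded_ids)
    ct <- ct[ct$participant_id %in% keep, , drop = FALSE]
  }
  risk <- in_stage("risk_scores",
                   prospective_risk_index(em$completed[keep, , drop = FALSE]))
  retro <- in_stage("risk_scores",
                    retrospective_els_score(cohort$retro_items[keep, , drop = FALSE]))
  scores <- data.frame(participant_id = keep,
                       prospective_els = unname(risk$composite[keep]),
                       retrospective_els = unname(retro[keep]),
                       stringsAsFactors = FALSE)

  ## --- connectivity -----------------------------------------------------
  profiles <- in_stage("connectivity",
                       connectivity_profiles(cohort$timeseries[keep],
                                             roi_labels = net$roi_labels))
  mean_conn <- apply(profiles, 1, mean_connectivity)
  covars <- ct[match(keep, ct$participant_id), config$covariates, drop = FALSE]
  rownames(covars) <- keep

  results <- list()

  ## --- univariate -------------------------------------------------------
  if ("univariate" %in% config$analyses) in_stage("univariate", {
    out_ids <- flag_outliers(mean_conn, config$outlier_k)
    if (length(out_ids)) note("univariate: excluded %d mean-connectivity outlier(s)",
                              length(out_ids))
    ok <- setdiff(keep, out_ids)
    rows <- lapply(c("prospective_els", "retrospective_els"), function(sc) {
      x <- scores[[sc]][match(ok, scores$participant_id)]
      sp <- spearman_corr(x, mean_conn[ok])
      pc <- partial_corr(x, mean_conn[ok], covars[ok, , drop = FALSE],
                         method = "spearman")
      data.frame(network = net$name, score = sc, n = length(ok),
                 rho = sp$rho, p_value = sp$p_value,
                 partial_r = pc$r, partial_p = pc$p_value,
                 stringsAsFactors = FALSE)
    })
    uni <- do.call(rbind, rows)
    xp <- scores$prospective_els[match(ok, scores$participant_id)]
    xr <- scores$retrospective_els[match(ok, scores$participant_id)]
    st <- steiger_test(stats::cor(rank(xp), rank(mean_conn[ok])),
                       stats::cor(rank(xr), rank(mean_conn[ok])),
                       stats::cor(rank(xp), rank(xr)), length(ok))
    results$univariate <- uni
    results$steiger <- data.frame(network = net$name, z = st$z,
                                  p_value = st$p_value, n = length(ok))
  })

  ## --- IS-RSA -----------------------------------------------------------
  if ("isrsa" %in% config$analyses) in_stage("isrsa", {
    rdm_full <- connectivity_rdm(profiles)
    row_dis <- rowSums(rdm_full) / (nrow(rdm_full) - 1)
    out_ids <- flag_outliers(row_dis, config$outlier_k)
    if (length(out_ids)) note("isrsa: excluded %d RDM-row outlier(s)", length(out_ids))
    ok <- setdiff(keep, out_ids)
    target <- connectivity_rdm(profiles[ok, , drop = FALSE])
    cov_rdms <- lapply(config$covariates, function(cv) {
      model_rdm(stats::setNames(covars[ok, cv], ok))
    })
    rows <- lapply(c("prospective_els", "retrospective_els"), function(sc) {
      m <- model_rdm(stats::setNames(scores[[sc]][match(ok, scores$participant_id)], ok))
      fit <- partial_rdm_correlation(
        target, m, cov_rdms, method = config$isrsa_method,
        n_perm = config$n_perm,
        seed = derive_seed(config$seed, paste0("isrsa:", sc)))
      data.frame(network = net$name, model = sc, n = fit$n,
                 partial_r = fit$partial_r, p_value = fit$p_value,
                 n_perm = fit$n_perm, method = fit$method,
                 stringsAsFactors = FALSE)
    })
    results$isrsa <- do.call(rbind, rows)
    results$isrsa_rdm <- target
  })

  ## --- MDMR -------------------------------------------------------------
  if ("mdmr" %in% config$analyses) in_stage("mdmr", {
    target <- connectivity_rdm(profiles)
    design <- cbind(scores[c("prospective_els", "retrospective_els")], covars)
    fit <- mdmr_fit(target, design, n_perm = config$n_perm,
                    seed = derive_seed(config$seed, "mdmr"))
    results$mdmr <- cbind(network = net$name, fit$table)
  })

  ## --- extreme-group contrasts -----------------------------------------
  if ("contrast" %in% config$analyses) in_stage("contrast", {
    rows <- lapply(c("prospective_els", "retrospective_els"), function(sc) {
      grp <- extreme_groups(stats::setNames(scores[[sc]], scores$participant_id),
                            config$contrast_fraction)
      tab <- withCallingHandlers(
        edge_contrast(profiles[grp$high_ids, , drop = FALSE],
                      profiles[grp$low_ids, , drop = FALSE]),
        warning = function(w) { note("%s", conditionMessage(w)); invokeRestart("muffleWarning") })
      cbind(network = net$name, score = sc, tab)
    })
    results$contrast <- do.call(rbind, rows)
  })

  report <- structure(list(
    results = results,
    scores = scores,
    mean_connectivity = mean_conn,
    qc = qc,
    risk_diagnostics = list(n_imputed_cells = em$n_imputed_cells,
                            em_iterations = em$em_iterations,
                            em_converged = em$em_converged,
                            alpha_20 = risk$alpha_20,
                            imputed_cells = imputed_cell_table(em$imputed_mask)),
    provenance = list(config_hash = config_hash(config),
                      seed = config$seed,
                      n_analyzed = length(keep),
                      package_version = as.character(utils::packageVersion("elsconn")),
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    warnings = warnings_log), class = "els_run_report")

  if (!is.null(config$out_dir)) write_report(report, config, profiles)
  report
}

## per-cell imputation provenance: which participant x variable cells were
## filled by EM rather than observed
imputed_cell_table <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  data.frame(participant_id = rownames(mask)[idx[, "row"]],
             variable = colnames(mask)[idx[, "col"]],
             stringsAsFactors = FALSE)
}

write_report <- function(report, config, profiles) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(f) file.path(config$out_dir, f)
  write_results_table(report$scores, outp("risk_scores.csv"))
  write_profiles(profiles, outp("profiles.tsv"))
  write_results_table(edge_index(config$network$roi_labels), outp("edge_dictionary.tsv"))
  res <- report$results
  if (!is.null(res$univariate)) write_results_table(res$univariate, outp("univariate_results.tsv"))
  if (!is.null(res$steiger)) write_results_table(res$steiger, outp("steiger.tsv"))
  if (!is.null(res$isrsa)) {
    write_results_table(res$isrsa, outp("isrsa_results.tsv"))
    write_rdm(res$isrsa_rdm, outp(sprintf("rdm_%s.csv", tolower(config$network$name))))
    write_results_table(rdm_to_long(res$isrsa_rdm),
                        outp(sprintf("rdm_%s_long.tsv", tolower(config$network$name))))
  }
  if (!is.null(res$mdmr)) write_results_table(res$mdmr, outp("mdmr_results.tsv"))
  if (!is.null(res$contrast)) write_results_table(res$contrast, outp("contrast_results.tsv"))
  jsonlite::write_json(report$risk_diagnostics, outp("imputation_report.json"),
                       auto_unbox = TRUE, digits = NA)
  prov <- c(report$provenance,
            list(warnings = report$warnings,
                 risk_diagnostics = report$risk_diagnostics[
                   c("n_imputed_cells", "em_iterations", "em_converged", "alpha_20")]))
  jsonlite::write_json(prov, outp("run_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}

#' @export
print.els_run_report <- function(x, ...) {
  cat(sprintf("<els_run_report> %s | n = %d analyzed | seed %d\n",
              x$provenance$config_hash, x$provenance$n_analyzed,
              x$provenance$seed))
  for (nm in names(x$results)) {
    if (is.data.frame(x$results[[nm]])) {
      cat(sprintf("  $results$%s: %d row(s)\n", nm, nrow(x$results[[nm]])))
    }
  }
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
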