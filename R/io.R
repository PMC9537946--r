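## File contracts for every pipeline artifact.  Matrices that must
## round-trip exactly (time series, profiles, RDMs) are written with 17
## significant digits; result tables with 10.

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "g"), x))
}

write_delim_ <- function(df, path, sep, digits = 10) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- fmt_num(df[[j]], digits)
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_table_ <- function(path, sep) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Readers and writers for pipeline artifacts
#'
#' Plain-text, UTF-8 contracts for every artifact the pipeline exchanges:
#' participant tables (CSV), long-format questionnaire items (CSV),
#' per-participant ROI time series (TSV, header row = ROI labels, one row
#' per volume, named `sub-<id>_ts.tsv`), connectivity profiles (one wide
#' TSV, participants x edges, with an edge-dictionary sidecar), RDMs (CSV
#' with ids in the first column), and result tables (TSV).  Writing then
#' reading reproduces values to full double precision.
#'
#' @param path,dir File or directory path.
#' @param cohort,df,rdm,mat,ids Objects to write; see individual functions.
#' @name els_io
NULL

#' @rdname els_io
#' @export
write_participants <- function(df, path) write_delim_(df, path, ",", digits = 17)

#' @rdname els_io
#' @export
read_participants <- function(path) {
  df <- read_table_(path, ",")
  if (!"participant_id" %in% names(df)) {
    stop_("participants file %s lacks a participant_id column", path)
  }
  df
}

#' @rdname els_io
#' @param ts volumes x ROIs matrix with ROI labels as colnames.
#' @export
write_roi_timeseries <- function(ts, path) {
  write_delim_(as.data.frame(ts), path, "\t", digits = 17)
}

#' @rdname els_io
#' @param roi_labels If given, validated against (and used to reorder) the
#'   file's header.
#' @export
read_roi_timeseries <- function(path, roi_labels = NULL) {
  df <- read_table_(path, "\t")
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      stop_("%s: non-numeric values in ROI column '%s'", path, names(df)[j])
    }
  }
  m <- as.matrix(df)
  if (!is.null(roi_labels)) {
    missing_cols <- setdiff(roi_labels, colnames(m))
    if (length(missing_cols)) {
      stop_("%s: missing ROI column(s): %s", path,
            paste(missing_cols, collapse = ", "))
    }
    m <- m[, roi_labels, drop = FALSE]
  }
  m
}

#' @rdname els_io
#' @export
write_profiles <- function(mat, path) {
  df <- data.frame(participant_id = rownames(mat), as.data.frame(mat),
                   check.names = FALSE)
  write_delim_(df, path, "\t", digits = 17)
}

#' @rdname els_io
#' @export
read_profiles <- function(path) {
  df <- read_table_(path, "\t")
  m <- as.matrix(df[-1])
  rownames(m) <- df$participant_id
  m
}

#' @rdname els_io
#' @export
write_rdm <- function(rdm, path) {
  df <- data.frame(participant_id = rownames(rdm) %||% seq_len(nrow(rdm)),
                   as.data.frame(unclass(rdm)), check.names = FALSE)
  write_delim_(df, path, ",", digits = 17)
}

#' @rdname els_io
#' @export
read_rdm <- function(path) {
  df <- read_table_(path, ",")
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  colnames(m) <- df[[1]]
  new_rdm(m, rownames(m), "file")
}

#' @rdname els_io
#' @export
write_results_table <- function(df, path) write_delim_(df, path, "\t", digits = 10)

#' Long-format questionnaire item table
#'
#' Converts between the wide battery/items objects and the long on-disk
#' format (columns: participant_id, measure, instrument, reporter,
#' timepoint, item, value).  Missing battery cells are kept as NA rows so
#' the missingness mask round-trips.
#'
#' @param battery participants x 20 matrix.
#' @param retro_items participants x 17 data.frame.
#' @export
items_to_long <- function(battery, retro_items) {
  dict <- battery_variables()
  ids <- rownames(battery) %||% sprintf("sub-%03d", seq_len(nrow(battery)))
  pros <- do.call(rbind, lapply(seq_len(nrow(dict)), function(k) {
    data.frame(participant_id = ids, measure = "prospective",
               instrument = dict$instrument[k], reporter = dict$reporter[k],
               timepoint = dict$timepoint[k], item = dict$variable[k],
               value = battery[, dict$variable[k]], stringsAsFactors = FALSE)
  }))
  rdict <- retro_item_dictionary()
  retro <- do.call(rbind, lapply(seq_len(nrow(rdict)), function(k) {
    data.frame(participant_id = ids, measure = "retrospective",
               instrument = "ACE", reporter = "self", timepoint = "T4",
               item = rdict$item[k], value = retro_items[[rdict$item[k]]],
               stringsAsFactors = FALSE)
  }))
  out <- rbind(pros, retro)
  rownames(out) <- NULL
  out
}

#' @rdname items_to_long
#' @param long Long-format item data.frame.
#' @export
items_from_long <- function(long) {
  need <- c("participant_id", "measure", "item", "value")
  missing_cols <- setdiff(need, names(long))
  if (length(missing_cols)) {
    stop_("items table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  ids <- unique(long$participant_id)
  pros <- long[long$measure == "prospective", ]
  dict <- battery_variables()
  battery <- matrix(NA_real_, length(ids), nrow(dict),
                    dimnames = list(ids, dict$variable))
  battery[cbind(match(pros$participant_id, ids), match(pros$item, dict$variable))] <-
    pros$value
  retro <- long[long$measure == "retrospective", ]
  rdict <- retro_item_dictionary()
  ritems <- matrix(NA_real_, length(ids), nrow(rdict),
                   dimnames = list(ids, rdict$item))
  ritems[cbind(match(retro$participant_id, ids), match(retro$item, rdict$item))] <-
    retro$value
  list(battery = battery, retro_items = as.data.frame(ritems))
}

#' Write a synthetic cohort to disk
#'
#' Emits the full file contract of a cohort: `participants.csv`,
#' `items.csv` (long format), one `sub-<id>_ts.tsv` per participant, and
#' `truth.json` holding the latent ELS values and planted effect sizes.
#'
#' @param cohort An `els_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "els_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_participants(cohort$cohort_table, file.path(dir, "participants.csv"))
  write_delim_(items_to_long(cohort$battery, cohort$retro_items),
               file.path(dir, "items.csv"), ",", digits = 17)
  for (id in names(cohort$timeseries)) {
    write_roi_timeseries(cohort$timeseries[[id]],
                         file.path(dir, sprintf("%s_ts.tsv", id)))
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @param roi_labels ROI order for the time-series files.
#' @export
read_cohort_dir <- function(dir, roi_labels = NULL) {
  ct <- read_participants(file.path(dir, "participants.csv"))
  items <- items_from_long(read_table_(file.path(dir, "items.csv"), ","))
  ts_files <- file.path(dir, sprintf("%s_ts.tsv", ct$participant_id))
  missing_f <- !file.exists(ts_files)
  if (any(missing_f)) {
    stop_("missing time-series file(s): %s",
          paste(basename(ts_files[missing_f]), collapse = ", "))
  }
  timeseries <- lapply(ts_files, read_roi_timeseries, roi_labels = roi_labels)
  names(timeseries) <- ct$participant_id
  list(cohort_table = ct, battery = items$battery,
       retro_items = items$retro_items, timeseries = timeseries)
}

#' Long-format RDM export
#'
#' One row per unordered participant pair — the heatmap-ready form of an
#' RDM.
#'
#' @param rdm N x N dissimilarity matrix with participant dimnames.
#' @return data.frame: `id_a`, `id_b`, `dissimilarity`.
#' @export
rdm_to_long <- function(rdm) {
  ids <- rownames(rdm) %||% as.character(seq_len(nrow(rdm)))
  ut <- which(upper.tri(rdm), arr.ind = TRUE)
  ut <- ut[order(ut[, "row"], ut[, "col"]), , drop = FALSE]
  data.frame(id_a = ids[ut[, "row"]], id_b = ids[ut[, "col"]],
             dissimilarity = rdm[ut], stringsAsFactors = FALSE)
}
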