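#' Packaged resting-state network definitions
#'
#' The package ships two 12-ROI bilateral network definitions commonly used
#' in developmental resting-state work: a default mode network (DMN: posterior
#' cingulate cortex, medial prefrontal cortex, inferior parietal cortex,
#' middle temporal gyrus, dorsolateral prefrontal cortex, hippocampus) and a
#' fronto-limbic network (FLN: orbitofrontal cortex, medial prefrontal
#' cortex, anterior cingulate cortex, amygdala, nucleus accumbens,
#' hippocampus).  Each region appears once per hemisphere, the left
#' hemisphere ROI ordered before the right within each region, regions in
#' their canonical column order.  ROI order is the cross-participant edge
#' alignment contract: every connectivity profile in a cohort is vectorized
#' over the same ordered label list.
#'
#' Definitions are read from a YAML file; the packaged file also carries the
#' cortical atlas parcel lists as metadata (this package never touches voxel
#' or surface data — parcellation is assumed done upstream).
#'
#' @param name Network name, `"dmn"` or `"fln"` (case-insensitive), or the
#'   path to a YAML network definition file with fields `name`, `regions`.
#' @return An object of class `els_network`: list with `name`, `regions`
#'   (region short codes), `roi_labels` (length 12, `L_`/`R_` prefixed) and
#'   `parcels` metadata.
#' @examples
#' dmn <- network_definition("dmn")
#' dmn$roi_labels
#' @export
network_definition <- function(name = c("dmn", "fln")) {
  if (length(name) == 1 && file.exists(name)) {
    def <- yaml::read_yaml(name)
  } else {
    name <- tolower(match.arg(name))
    path <- system.file("extdata", "networks.yaml", package = "elsconn",
                        mustWork = TRUE)
    all_defs <- yaml::read_yaml(path)
    if (!name %in% names(all_defs)) {
      stop_("unknown network '%s'; packaged networks: %s",
            name, paste(names(all_defs), collapse = ", "))
    }
    def <- all_defs[[name]]
  }
  regions <- vapply(def$regions, function(r) r$code, character(1))
  if (anyDuplicated(regions)) stop_("duplicate region codes in network definition")
  roi_labels <- as.vector(t(outer(regions, c("L", "R"),
                                  function(r, h) paste0(h, "_", r))))
  structure(
    list(name = def$name,
         regions = regions,
         roi_labels = roi_labels,
         parcels = lapply(def$regions, function(r) r$parcels)),
    class = "els_network")
}

#' @export
print.els_network <- function(x, ...) {
  cat(sprintf("<els_network> %s: %d ROIs (%d bilateral regions)\n",
              x$name, length(x$roi_labels), length(x$regions)))
  cat("  ", paste(x$roi_labels, collapse = " "), "\n")
  invisible(x)
}

#' Edge index table for an ordered ROI label list
#'
#' Enumerates the row-major upper-triangle edge order used by
#' [vectorize_profile()]: edge (i, j) with i < j, i advancing slowest.  For
#' 12 ROIs this yields the fixed 66-edge order shared by every participant.
#'
#' @param roi_labels Character vector of unique ROI labels.
#' @return data.frame with columns `edge` (1-based index), `i`, `j`,
#'   `label_i`, `label_j`, `edge_label` (`"A--B"`).
#' @export
edge_index <- function(roi_labels) {
  r <- length(roi_labels)
  if (anyDuplicated(roi_labels)) stop_("ROI labels must be unique")
  if (r < 2) stop_("need at least 2 ROIs")
  ij <- which(upper.tri(matrix(0, r, r)), arr.ind = TRUE)
  ij <- ij[order(ij[, "row"], ij[, "col"]), , drop = FALSE]
  data.frame(
    edge = seq_len(nrow(ij)),
    i = unname(ij[, "row"]), j = unname(ij[, "col"]),
    label_i = roi_labels[ij[, "row"]], label_j = roi_labels[ij[, "col"]],
    edge_label = paste0(roi_labels[ij[, "row"]], "--", roi_labels[ij[, "col"]]),
    stringsAsFactors = FALSE)
}
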