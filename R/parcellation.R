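#' Parcellation schemes: ROIs grouped into resting-state networks
#'
#' A parcellation is a tibble with columns `roi` (character, unique) and
#' `network` (factor). ROI row order is the canonical axis order of every
#' functional-connectivity matrix produced downstream. Each network must
#' contain at least two ROIs so that within-network connectivity is defined.
#'
#' @param roi Character vector of ROI names (unique, non-empty).
#' @param network Vector of network labels, one per ROI.
#' @param network_levels Optional ordering of the network labels; defaults to
#'   order of first appearance.
#' @return A tibble of class `dfc_parcellation` with columns `roi`, `network`.
#' @examples
#' p <- parcellation(c("A1", "A2", "B1", "B2"), c("A", "A", "B", "B"))
#' network_sizes(p)
#' @export
parcellation <- function(roi, network, network_levels = NULL) {
  roi <- as.character(roi)
  network <- as.character(network)
  if (length(roi) != length(network)) {
    abort("`roi` and `network` must have the same length.")
  }
  if (anyDuplicated(roi)) abort("ROI names must be unique.")
  if (is.null(network_levels)) network_levels <- unique(network)
  if (!all(network %in% network_levels)) {
    abort("All network labels must appear in `network_levels`.")
  }
  sizes <- table(factor(network, levels = network_levels))
  if (any(sizes < 2)) {
    abort(paste0(
      "Every network needs >= 2 ROIs; too small: ",
      paste(names(sizes)[sizes < 2], collapse = ", ")
    ))
  }
  out <- tibble(roi = roi, network = factor(network, levels = network_levels))
  class(out) <- c("dfc_parcellation", class(out))
  out
}

#' @export
print.dfc_parcellation <- function(x, ...) {
  cat(
    "<dfc_parcellation> ", nrow(x), " ROIs in ",
    nlevels(x$network), " networks\n",
    sep = ""
  )
  NextMethod()
}

#' Number of ROIs per network
#' @param parcellation A [parcellation()] tibble.
#' @return Named integer vector, one entry per network in canonical order.
#' @export
network_sizes <- function(parcellation) {
  stopifnot(inherits(parcellation, "dfc_parcellation"))
  tab <- table(parcellation$network)
  stats::setNames(as.integer(tab), names(tab))
}

# 30 ROIs in 7 networks, modeled on the ICA-derived network parcellation used
# in resting-state dFC work (bilateral association-network nodes, a 3-node
# sensorimotor strip, and a 7-node cingulo-opercular set).
.default_rois <- list(
  VN  = c("VN_medial", "VN_occipital", "VN_lateral_L", "VN_lateral_R"),
  DAN = c("DAN_FEF_L", "DAN_FEF_R", "DAN_IPS_L", "DAN_IPS_R"),
  SMN = c("SMN_lateral_L", "SMN_lateral_R", "SMN_superior"),
  CON = c(
    "CON_ACC", "CON_aInsula_L", "CON_aInsula_R",
    "CON_rPFC_L", "CON_rPFC_R", "CON_SMG_L", "CON_SMG_R"
  ),
  LN  = c("LN_IFG_L", "LN_IFG_R", "LN_pSTG_L", "LN_pSTG_R"),
  FPN = c("FPN_lPFC_L", "FPN_lPFC_R", "FPN_PPC_L", "FPN_PPC_R"),
  DMN = c("DMN_MPFC", "DMN_PCC", "DMN_LP_L", "DMN_LP_R")
)

#' Default 30-ROI, 7-network parcellation
#'
#' Thirty ROIs assigned to the seven canonical resting-state networks:
#' visual (VN), dorsal attention (DAN), sensorimotor (SMN), cingulo-opercular
#' (CON), language (LN), fronto-parietal (FPN) and default mode (DMN).
#'
#' @return A `dfc_parcellation` tibble with 30 rows.
#' @export
default_parcellation <- function() {
  parcellation(
    roi = unlist(.default_rois, use.names = FALSE),
    network = rep(names(.default_rois), lengths(.default_rois)),
    network_levels = names(.default_rois)
  )
}

#' Read a parcellation table from TSV
#'
#' Expects columns `roi` and `network` (extra columns are ignored). Network
#' order is order of first appearance.
#'
#' @param path Path to a tab-separated file.
#' @return A `dfc_parcellation` tibble.
#' @export
read_parcellation <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("roi", "network") %in% names(tab))) {
    abort("Parcellation file needs columns `roi` and `network`.")
  }
  parcellation(tab$roi, tab$network)
}

#' Write a parcellation table to TSV
#' @param parcellation A `dfc_parcellation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parcellation <- function(parcellation, path) {
  readr::write_tsv(
    tibble(
      roi = parcellation$roi,
      network = as.character(parcellation$network)
    ),
    path
  )
  invisible(path)
}

#' Read one subject's ROI time series from TSV
#'
#' The file must have a header of ROI names and one row per volume. Columns
#' are reordered to the parcellation's canonical ROI order; missing or extra
#' ROI columns and non-numeric cells are errors.
#'
#' @param path Path to a tab-separated time-series file.
#' @param parcellation A [parcellation()] defining the canonical ROI order.
#' @param subject Subject identifier; defaults to the file name sans extension.
#' @param run Run index (integer, default 1).
#' @param tr_seconds Repetition time in seconds (metadata only here).
#' @return A tibble with columns `subject`, `run`, `volume`, then one numeric
#'   column per ROI in canonical order.
#' @export
read_roi_timeseries <- function(path, parcellation, subject = NULL, run = 1L,
                                tr_seconds = NULL) {
  if (is.null(subject)) {
    subject <- sub("\\.[^.]+$", "", basename(path))
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "d"))
  rois <- parcellation$roi
  missing_cols <- setdiff(rois, names(tab))
  extra_cols <- setdiff(names(tab), rois)
  if (length(missing_cols) || length(extra_cols)) {
    abort(paste0(
      "Time-series columns do not match the parcellation.",
      if (length(missing_cols)) {
        paste0(" Missing: ", paste(missing_cols, collapse = ", "), ".")
      },
      if (length(extra_cols)) {
        paste0(" Unexpected: ", paste(extra_cols, collapse = ", "), ".")
      }
    ))
  }
  tab <- tab[rois]
  if (!all(vapply(tab, is.numeric, logical(1))) || anyNA(tab) ||
      !all(vapply(tab, function(x) all(is.finite(x)), logical(1)))) {
    abort("Time series contains non-numeric or non-finite values.")
  }
  dplyr::bind_cols(
    tibble(
      subject = subject,
      run = as.integer(run),
      volume = seq_len(nrow(tab))
    ),
    tab
  )
}

#' Write one subject's ROI time series to TSV
#'
#' Writes only the ROI columns (header = ROI names, one row per volume), the
#' on-disk layout that [read_roi_timeseries()] expects.
#'
#' @param ts A cohort time-series tibble (single subject/run).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_timeseries <- function(ts, path) {
  stopifnot(length(unique(ts$subject)) == 1, length(unique(ts$run)) == 1)
  readr::write_tsv(ts[setdiff(names(ts), c("subject", "run", "volume"))], path)
  invisible(path)
}

#' Read a behavior table from TSV
#'
#' Expects columns `subject`, `coc_bells`, `coc_letter` and `group`; optional
#' `nihss`, `lesion_cm3`, `outliers` are kept when present. Group labels must
#' take exactly two values.
#'
#' @param path Path to a tab-separated behavior file.
#' @return A tibble.
#' @export
read_behavior <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("subject", "coc_bells", "coc_letter", "group")
  if (!all(need %in% names(tab))) {
    abort(paste0(
      "Behavior file needs columns ",
      paste(need, collapse = ", "), "."
    ))
  }
  if (!all(is.finite(tab$coc_bells)) || !all(is.finite(tab$coc_letter))) {
    abort("CoC scores must be finite.")
  }
  if (length(unique(tab$group)) != 2) {
    abort("`group` must take exactly two values.")
  }
  tab$subject <- as.character(tab$subject)
  tab
}

# ROI columns of a cohort time-series tibble, in stored order.
roi_columns <- function(ts) {
  setdiff(names(ts), c("subject", "run", "volume"))
}

# Extract a T x N matrix for a single subject/run block (rows assumed in
# acquisition order).
ts_matrix <- function(ts) {
  as.matrix(ts[roi_columns(ts)])
}
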