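#' Electrode layout descriptor
#'
#' Describes the physical geometry of a microelectrode array: electrode
#' identifiers, planar positions in micrometres, and which electrodes are
#' reference (ground) electrodes excluded from every analysis stage.
#'
#' @param electrode_ids character vector of unique electrode identifiers.
#' @param positions numeric matrix with one row per electrode and columns
#'   \code{x}, \code{y} (micrometres).
#' @param reference_ids identifiers of reference electrodes; must be a subset
#'   of \code{electrode_ids}.
#'
#' @return An object of class \code{"mea_layout"}: a list with elements
#'   \code{electrode_ids}, \code{positions}, \code{reference_ids}.
#' @seealso [standard_mea_layout()] for the default 60-electrode grid.
#' @export
mea_layout <- function(electrode_ids, positions, reference_ids = character()) {
  electrode_ids <- as.character(electrode_ids)
  if (anyDuplicated(electrode_ids))
    stop("electrode ids must be unique")
  positions <- as.matrix(positions)
  if (nrow(positions) != length(electrode_ids) || ncol(positions) != 2)
    stop("positions must be a (n_electrodes x 2) matrix")
  if (anyDuplicated(positions))
    stop("electrode positions must be unique")
  colnames(positions) <- c("x", "y")
  rownames(positions) <- electrode_ids
  reference_ids <- as.character(reference_ids)
  if (!all(reference_ids %in% electrode_ids))
    stop("reference_ids must be a subset of electrode_ids")
  structure(
    list(electrode_ids = electrode_ids, positions = positions,
         reference_ids = reference_ids),
    class = "mea_layout")
}

#' Standard 60-electrode MEA layout
#'
#' The conventional in vitro layout: an 8 x 8 grid with the four corners
#' absent (60 electrodes) at 200 um inter-electrode pitch, one of which is a
#' reference electrode, leaving 59 analysis electrodes. Identifiers follow the
#' column-row convention (e.g. "12" is column 1, row 2).
#'
#' @param pitch_um inter-electrode spacing in micrometres (default 200).
#' @param reference_id identifier of the reference electrode (default "15").
#' @return An [mea_layout()] with 59 analysis electrodes.
#' @export
standard_mea_layout <- function(pitch_um = 200, reference_id = "15") {
  ids <- character(0); xs <- numeric(0); ys <- numeric(0)
  for (col in 1:8) for (row in 1:8) {
    if ((col %in% c(1, 8)) && (row %in% c(1, 8))) next  # corners absent
    ids <- c(ids, paste0(col, row))
    xs <- c(xs, (col - 1) * pitch_um)
    ys <- c(ys, (row - 1) * pitch_um)
  }
  mea_layout(ids, cbind(xs, ys), reference_ids = reference_id)
}

#' Analysis electrodes of a layout
#'
#' Electrode identifiers retained for analysis: all electrodes except the
#' reference electrodes and any explicitly excluded identifiers.
#'
#' @param layout an [mea_layout()].
#' @param excluded additional identifiers to drop (e.g. noisy electrodes).
#' @return character vector of analysis electrode ids.
#' @export
analysis_electrodes <- function(layout, excluded = character()) {
  setdiff(layout$electrode_ids, union(layout$reference_ids, excluded))
}

#' @export
print.mea_layout <- function(x, ...) {
  cat(sprintf("MEA layout: %d electrodes (%d reference)\n",
              length(x$electrode_ids), length(x$reference_ids)))
  invisible(x)
}
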