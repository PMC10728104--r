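#' Recording session container
#'
#' The unit every analysis stage consumes: per-electrode spike times on a
#' layout, with duration, sampling rate and a condition label. Spike times are
#' seconds from recording onset, strictly increasing per electrode.
#'
#' @param spike_times named list of numeric vectors (seconds), one per
#'   electrode; names must be electrode ids present in \code{layout}.
#'   Electrodes absent from the list are treated as silent.
#' @param layout an [mea_layout()].
#' @param duration recording duration in seconds (> 0).
#' @param sampling_rate acquisition rate in Hz (default 20000).
#' @param label free-form condition/timepoint tag.
#' @param excluded_electrodes ids flagged as noisy; retained in the object but
#'   dropped from analysis.
#'
#' @return An object of class \code{"recording_session"}.
#' @export
recording_session <- function(spike_times, layout, duration,
                              sampling_rate = 20000, label = "",
                              excluded_electrodes = character()) {
  stopifnot(inherits(layout, "mea_layout"))
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0)
    stop("duration must be a positive scalar (seconds)")
  if (is.null(names(spike_times)) && length(spike_times) > 0)
    stop("spike_times must be a named list keyed by electrode id")
  unknown <- setdiff(names(spike_times), layout$electrode_ids)
  if (length(unknown))
    stop("spike_times contains unknown electrode ids: ",
         paste(unknown, collapse = ", "))
  for (id in names(spike_times)) {
    st <- spike_times[[id]]
    if (length(st)) {
      if (is.unsorted(st, strictly = TRUE))
        stop("spike times not strictly increasing on electrode ", id)
      if (st[1] < 0 || st[length(st)] > duration)
        stop("spike times outside [0, duration] on electrode ", id)
    }
  }
  # fill silent electrodes so every layout electrode has a train
  full <- setNames(vector("list", length(layout$electrode_ids)),
                   layout$electrode_ids)
  for (id in layout$electrode_ids)
    full[[id]] <- if (id %in% names(spike_times))
      as.numeric(spike_times[[id]]) else numeric(0)
  structure(
    list(layout = layout, spike_times = full, duration = duration,
         sampling_rate = sampling_rate, label = label,
         excluded_electrodes = as.character(excluded_electrodes)),
    class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  n <- sum(vapply(x$spike_times, length, integer(1)))
  cat(sprintf("Recording session '%s': %.0f s, %d electrodes, %d spikes\n",
              x$label, x$duration, length(x$spike_times), n))
  invisible(x)
}

#' Spike trains of the analysis electrodes
#'
#' @param session a [recording_session()].
#' @return named list of spike-time vectors restricted to analysis electrodes
#'   (reference and excluded electrodes removed).
#' @export
session_trains <- function(session) {
  ids <- analysis_electrodes(session$layout, session$excluded_electrodes)
  session$spike_times[ids]
}

#' Load a recording session from a long-format CSV spike table
#'
#' The on-disk schema is long format with columns \code{electrode_id} and
#' \code{time_s}, one row per spike. Session metadata (duration, sampling
#' rate, label, exclusions) is supplied by the caller or by a JSON sidecar
#' written by [save_session_csv()]. Rows naming electrodes absent from the
#' layout are reported in an error, never silently dropped.
#'
#' @param path CSV file path.
#' @param layout an [mea_layout()]; default [standard_mea_layout()].
#' @param duration recording duration in seconds; if \code{NULL}, read from
#'   the \code{<path>.meta.json} sidecar.
#' @param ... passed to [recording_session()].
#' @return a [recording_session()].
#' @export
load_session_csv <- function(path, layout = standard_mea_layout(),
                             duration = NULL, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("electrode_id", "time_s")
  if (!all(need %in% names(tab)))
    stop("schema error: spike table must have columns ",
         paste(need, collapse = ", "))
  meta <- list()
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(duration)) duration <- meta$duration
  if (is.null(duration)) stop("duration not given and no metadata sidecar")
  tab$electrode_id <- as.character(tab$electrode_id)
  unknown <- setdiff(unique(tab$electrode_id), layout$electrode_ids)
  if (length(unknown))
    stop("spike table names electrodes not in the layout: ",
         paste(unknown, collapse = ", "))
  spikes <- split(tab$time_s, tab$electrode_id)
  spikes <- lapply(spikes, function(v) sort(unique(as.numeric(v))))
  args <- list(spike_times = spikes, layout = layout, duration = duration)
  extra <- list(...)
  for (nm in c("sampling_rate", "label", "excluded_electrodes"))
    if (!is.null(meta[[nm]]) && is.null(extra[[nm]])) extra[[nm]] <- meta[[nm]]
  do.call(recording_session, c(args, extra))
}

#' Save a recording session as a long-format CSV spike table
#'
#' Writes \code{<path>} (columns \code{electrode_id}, \code{time_s}) plus a
#' \code{<path>.meta.json} sidecar holding duration, sampling rate, label and
#' exclusions, so that [load_session_csv()] round-trips losslessly.
#'
#' @param session a [recording_session()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
save_session_csv <- function(session, path) {
  ids <- rep(names(session$spike_times),
             vapply(session$spike_times, length, integer(1)))
  times <- unlist(session$spike_times, use.names = FALSE)
  tab <- data.frame(electrode_id = ids,
                    time_s = if (length(times)) times else numeric(0))
  write.csv(tab, path, row.names = FALSE)
  meta <- list(duration = session$duration,
               sampling_rate = session$sampling_rate,
               label = session$label,
               excluded_electrodes = session$excluded_electrodes)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Minimum-activity gate
#'
#' Recordings with too little activity are excluded from analysis. The default
#' threshold is 2000 spikes per 5-minute recording, scaled linearly to the
#' session's duration; a session exactly at the threshold passes. Counts are
#' taken over analysis electrodes only (after noise exclusion).
#'
#' @param session a [recording_session()].
#' @param min_spikes threshold count per \code{ref_duration} seconds.
#' @param ref_duration duration the threshold refers to (default 300 s).
#' @return \code{TRUE} if the session passes the gate.
#' @export
activity_gate <- function(session, min_spikes = 2000, ref_duration = 300) {
  total <- sum(vapply(session_trains(session), length, integer(1)))
  total >= min_spikes * session$duration / ref_duration
}
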