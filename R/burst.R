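#' Burstlet detection on a single-electrode spike train
#'
#' A burstlet is a core group of at least \code{min_spikes} (default 4)
#' closely spaced spikes plus looser peripheral spikes. The core ISI bound is
#' the smaller of 100 ms and the ISI of a train firing at 4x the electrode's
#' mean rate, i.e. \code{min(100 ms, 1/(4 rate))}; the peripheral bound is
#' \code{min(200 ms, 1/(3 rate))}. Cores are maximal runs of consecutive ISIs
#' within the core bound, built greedily left to right; peripheral spikes are
#' appended on both sides while their ISI to the burstlet edge stays within
#' the peripheral bound. A spike belongs to at most one burstlet. Detection
#' runs over the whole train, so a spike run crossing a processing-chunk
#' boundary forms a single burstlet directly (equivalent to per-chunk
#' detection followed by merging of boundary-overlapping burstlets).
#'
#' @param spikes sorted spike times (seconds) of one electrode.
#' @param rate the electrode's mean firing rate over the recording (Hz); used
#'   to adapt the ISI bounds. If \code{NULL}, computed as
#'   \code{length(spikes)/duration}.
#' @param duration recording duration in seconds (needed when
#'   \code{rate = NULL}).
#' @param config a [pipeline_config()].
#' @return data.frame with one row per burstlet: \code{start}, \code{end}
#'   (seconds), \code{n_spikes}, \code{core_size}, and a list column
#'   \code{spike_idx} of member-spike indices into \code{spikes}.
#' @export
detect_burstlets <- function(spikes, rate = NULL, duration = NULL,
                             config = pipeline_config()) {
  n <- length(spikes)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0), core_size = integer(0))
  empty$spike_idx <- list()
  if (n < config$burstlet_min_spikes) return(empty)
  if (is.null(rate)) {
    if (is.null(duration)) stop("need duration when rate is not given")
    rate <- n / duration
  }
  th_core <- config$core_isi_ms / 1000
  th_peri <- config$periph_isi_ms / 1000
  if (rate > 0) {
    th_core <- min(th_core, 1 / (config$core_rate_factor * rate))
    th_peri <- min(th_peri, 1 / (config$periph_rate_factor * rate))
  }
  isi <- diff(spikes)
  # maximal runs of consecutive ISIs <= th_core, kept if >= min_spikes spikes
  in_run <- isi <= th_core
  r <- rle(in_run)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1
  taken <- logical(n)
  rows <- list()
  for (j in which(r$values)) {
    i0 <- begs[j]            # run spans spikes i0 .. ends[j]+1
    i1 <- ends[j] + 1
    if (i1 - i0 + 1 < config$burstlet_min_spikes) next
    core0 <- i0; core1 <- i1
    # peripheral extension on both sides, skipping spikes already claimed
    while (i0 > 1 && !taken[i0 - 1] &&
           spikes[i0] - spikes[i0 - 1] <= th_peri) i0 <- i0 - 1
    while (i1 < n && !taken[i1 + 1] &&
           spikes[i1 + 1] - spikes[i1] <= th_peri) i1 <- i1 + 1
    taken[i0:i1] <- TRUE
    rows[[length(rows) + 1]] <-
      list(start = spikes[i0], end = spikes[i1],
           n_spikes = as.integer(i1 - i0 + 1), core_size = as.integer(core1 - core0 + 1),
           spike_idx = i0:i1)
  }
  if (!length(rows)) return(empty)
  out <- data.frame(start = vapply(rows, `[[`, numeric(1), "start"),
                    end = vapply(rows, `[[`, numeric(1), "end"),
                    n_spikes = vapply(rows, `[[`, integer(1), "n_spikes"),
                    core_size = vapply(rows, `[[`, integer(1), "core_size"))
  out$spike_idx <- lapply(rows, `[[`, "spike_idx")
  out[order(out$start), , drop = FALSE]
}

#' Burstlets for every analysis electrode of a session
#'
#' @param session a [recording_session()].
#' @param config a [pipeline_config()].
#' @return data.frame of burstlets across electrodes with an
#'   \code{electrode} column.
#' @export
session_burstlets <- function(session, config = pipeline_config()) {
  trains <- session_trains(session)
  out <- lapply(names(trains), function(id) {
    b <- detect_burstlets(trains[[id]], duration = session$duration,
                          config = config)
    if (nrow(b)) b$electrode <- id
    b
  })
  out <- out[vapply(out, nrow, integer(1)) > 0]
  if (!length(out))
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0), core_size = integer(0),
                      electrode = character(0)))
  do.call(rbind, out)
}

#' Global burst detection
#'
#' A global (network-wide) burst is a maximal overlap-connected component of
#' burstlet intervals involving at least \code{min_electrodes} (default 3)
#' distinct electrodes. Overlap means non-empty intersection of closed
#' intervals; components are found by a start-ordered sweep, so the result is
#' invariant to electrode ordering.
#'
#' @param burstlets data.frame as returned by [session_burstlets()] (needs
#'   \code{start}, \code{end}, \code{electrode}).
#' @param min_electrodes minimum distinct electrodes per global burst.
#' @return data.frame with \code{start}, \code{end} (envelope of members),
#'   \code{n_burstlets}, \code{n_electrodes}, and list column \code{members}
#'   of row indices into \code{burstlets}.
#' @export
detect_global_bursts <- function(burstlets, min_electrodes = 3) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_burstlets = integer(0), n_electrodes = integer(0))
  empty$members <- list()
  if (!nrow(burstlets)) return(empty)
  o <- order(burstlets$start)
  comp <- integer(nrow(burstlets))
  cur <- 0L; cur_end <- -Inf
  for (i in o) {
    if (burstlets$start[i] > cur_end) { cur <- cur + 1L; cur_end <- -Inf }
    comp[i] <- cur
    cur_end <- max(cur_end, burstlets$end[i])
  }
  rows <- list()
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    ne <- length(unique(burstlets$electrode[idx]))
    if (ne < min_electrodes) next
    rows[[length(rows) + 1]] <-
      list(start = min(burstlets$start[idx]), end = max(burstlets$end[idx]),
           n_burstlets = length(idx), n_electrodes = ne, members = idx)
  }
  if (!length(rows)) return(empty)
  out <- data.frame(start = vapply(rows, `[[`, numeric(1), "start"),
                    end = vapply(rows, `[[`, numeric(1), "end"),
                    n_burstlets = vapply(rows, `[[`, integer(1), "n_burstlets"),
                    n_electrodes = vapply(rows, `[[`, integer(1),
                                          "n_electrodes"))
  out$members <- lapply(rows, `[[`, "members")
  out[order(out$start), , drop = FALSE]
}

#' Binary burstlet train of one spike train
#'
#' Bins spike times at 300 ms resolution and assigns bins containing at least
#' four spikes the value 1, 0 otherwise. The final partial bin is discarded.
#'
#' @param spikes sorted spike times in seconds.
#' @param duration recording duration in seconds.
#' @param bin_ms bin width in milliseconds (default 300).
#' @param threshold minimum spikes for a 1 (default 4).
#' @return integer 0/1 vector of length \code{floor(duration/bin)}.
#' @export
binarize_burstlets <- function(spikes, duration, bin_ms = 300, threshold = 4) {
  w <- bin_ms / 1000
  nb <- floor(duration / w)
  if (nb < 1) stop("duration shorter than one bin")
  counts <- tabulate(pmin(floor(spikes / w) + 1L, nb + 1L), nbins = nb + 1L)
  as.integer(counts[seq_len(nb)] >= threshold)
}

#' Binary burstlet trains for a whole session
#'
#' @param session a [recording_session()].
#' @param config a [pipeline_config()].
#' @return integer matrix (analysis electrodes x bins) of 0/1 values, with
#'   attribute \code{bin_width_ms}.
#' @export
session_burstlet_trains <- function(session, config = pipeline_config()) {
  trains <- session_trains(session)
  m <- t(vapply(trains, binarize_burstlets, duration = session$duration,
                bin_ms = config$train_bin_ms,
                threshold = config$train_bin_threshold,
                FUN.VALUE = integer(floor(session$duration /
                                            (config$train_bin_ms / 1000)))))
  attr(m, "bin_width_ms") <- config$train_bin_ms
  m
}
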