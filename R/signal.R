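#' Voltage trace container
#'
#' Raw or conditioned extracellular voltage, one equal-length sample vector
#' per electrode, in microvolts.
#'
#' @param samples named list of numeric vectors (uV), all the same length.
#' @param sampling_rate acquisition rate in Hz (default 20000).
#' @param chunk_s processing chunk length in seconds (default 10).
#' @return an object of class \code{"voltage_trace"}.
#' @export
voltage_trace <- function(samples, sampling_rate = 20000, chunk_s = 10) {
  lens <- vapply(samples, length, integer(1))
  if (length(unique(lens)) > 1)
    stop("all electrodes must have the same number of samples")
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 chunk_s = chunk_s),
            class = "voltage_trace")
}

# Zero-phase Butterworth bandpass + notch applied to one numeric vector.
# filtfilt runs forward and reverse, so no phase shift is introduced.
.condition_vector <- function(x, fs, band, order, notch) {
  nyq <- fs / 2
  bp <- signal::butter(order, band / nyq, type = "pass")
  ns <- signal::butter(2, c(notch - 2, notch + 2) / nyq, type = "stop")
  y <- signal::filtfilt(bp, x)
  signal::filtfilt(ns, y)
}

#' Condition a raw voltage trace
#'
#' Band-limits each electrode to the spike band with a zero-phase
#' fourth-order Butterworth bandpass (default 20-2000 Hz) and a 60 Hz notch,
#' processed in chunks (default 10 s) with symmetric context padding so
#' chunked output matches whole-trace filtering away from the trace ends.
#'
#' @param trace a [voltage_trace()].
#' @param config a [pipeline_config()].
#' @param pad_s context padding per chunk side in seconds (default 1).
#' @return a conditioned [voltage_trace()].
#' @export
condition_signal <- function(trace, config = pipeline_config(), pad_s = 1) {
  fs <- trace$sampling_rate
  band <- config$filter_band_hz
  if (fs < 2 * band[2])
    stop("sampling rate must exceed twice the upper filter band")
  n <- length(trace$samples[[1]])
  # filtfilt needs > 3x the filter length to initialize its edge transients
  warmup <- 3 * (2 * config$filter_order + 1)
  if (n <= warmup)
    stop("trace too short for filter warm-up (needs > ", warmup, " samples)")
  chunk_n <- round(trace$chunk_s * fs)
  pad_n <- round(pad_s * fs)
  out <- lapply(trace$samples, function(x) {
    if (length(x) <= chunk_n)
      return(.condition_vector(x, fs, band, config$filter_order,
                               config$notch_hz))
    starts <- seq(1, length(x), by = chunk_n)
    y <- numeric(length(x))
    for (s in starts) {
      e <- min(s + chunk_n - 1, length(x))
      ps <- max(1, s - pad_n); pe <- min(length(x), e + pad_n)
      seg <- .condition_vector(x[ps:pe], fs, band, config$filter_order,
                               config$notch_hz)
      y[s:e] <- seg[(s - ps + 1):(s - ps + 1 + (e - s))]
    }
    y
  })
  voltage_trace(out, fs, trace$chunk_s)
}

#' Adaptive threshold spike detection
#'
#' Detects spikes as excursions beyond +/- k x SD of the conditioned signal,
#' with the threshold recomputed per electrode for every chunk (default 10 s)
#' so slow drifts in background noise are tracked. Each contiguous
#' supra-threshold excursion yields one event timed at its maximum absolute
#' value; events closer than the refractory interval (default 2 ms) to the
#' previously accepted event are discarded so no spike is counted twice.
#'
#' @param trace a conditioned [voltage_trace()].
#' @param config a [pipeline_config()]; uses \code{spike_threshold_sd},
#'   \code{refractory_ms}, \code{chunk_s}.
#' @return named list of spike-time vectors (seconds), one per electrode.
#' @export
detect_spikes <- function(trace, config = pipeline_config()) {
  fs <- trace$sampling_rate
  chunk_n <- round(config$chunk_s * fs)
  refr_s <- config$refractory_ms / 1000
  k <- config$spike_threshold_sd
  lapply(trace$samples, function(x) {
    n <- length(x)
    starts <- seq(1, n, by = chunk_n)
    times <- numeric(0)
    for (s in starts) {
      e <- min(s + chunk_n - 1, n)
      seg <- x[s:e]
      thr <- k * sd(seg)
      if (!is.finite(thr) || thr == 0) next
      over <- abs(seg) > thr
      if (!any(over)) next
      # contiguous supra-threshold runs -> one candidate each, at peak |v|
      r <- rle(over)
      ends <- cumsum(r$lengths)
      begs <- ends - r$lengths + 1
      for (j in which(r$values)) {
        idx <- begs[j]:ends[j]
        peak <- idx[which.max(abs(seg[idx]))]
        times <- c(times, (s + peak - 2) / fs)
      }
    }
    if (!length(times)) return(numeric(0))
    times <- sort(times)
    keep <- times[1]
    for (t in times[-1]) if (t - keep[length(keep)] >= refr_s)
      keep <- c(keep, t)
    keep
  })
}
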