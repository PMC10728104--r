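#' Per-electrode and network activity rates
#'
#' Spike rate and burstlet rate per analysis electrode, and the network-wide
#' global burst rate, all as count/duration in Hz.
#'
#' @param session a [recording_session()].
#' @param burstlets output of [session_burstlets()]; computed if \code{NULL}.
#' @param global_bursts output of [detect_global_bursts()]; computed if
#'   \code{NULL}.
#' @param config a [pipeline_config()].
#' @return list with \code{spike_rate}, \code{burstlet_rate} (named numeric
#'   vectors, Hz) and scalar \code{global_burst_rate} (Hz).
#' @export
activity_rates <- function(session, burstlets = NULL, global_bursts = NULL,
                           config = pipeline_config()) {
  if (is.null(burstlets)) burstlets <- session_burstlets(session, config)
  if (is.null(global_bursts))
    global_bursts <- detect_global_bursts(burstlets,
                                          config$global_min_electrodes)
  trains <- session_trains(session)
  d <- session$duration
  sr <- vapply(trains, length, integer(1)) / d
  br <- setNames(numeric(length(trains)), names(trains))
  if (nrow(burstlets)) {
    tb <- table(burstlets$electrode)
    br[names(tb)] <- as.numeric(tb) / d
  }
  list(spike_rate = sr, burstlet_rate = br,
       global_burst_rate = nrow(global_bursts) / d)
}

#' Fano factor of windowed spike counts
#'
#' Counts spikes in non-overlapping windows of width \code{w} (default
#' 100 ms) anchored at t = 0 and returns the variance-to-mean ratio of the
#' counts. The sample variance (n - 1 denominator) is used. The Fano factor
#' is 1 for Poisson firing and tends to 0 for regularly spaced spikes; it is
#' undefined (\code{NA}, flagged) when the mean count is zero.
#'
#' @param spikes sorted spike times in seconds.
#' @param duration recording duration in seconds (>= one window).
#' @param window_ms window width in milliseconds.
#' @return list with \code{ff}, \code{counts}, \code{defined}.
#' @export
fano_factor <- function(spikes, duration, window_ms = 100) {
  w <- window_ms / 1000
  nw <- floor(duration / w)
  if (nw < 2) stop("duration must cover at least two windows")
  counts <- tabulate(pmin(floor(spikes / w) + 1L, nw + 1L), nbins = nw + 1L)
  counts <- counts[seq_len(nw)]
  mu <- mean(counts)
  if (mu == 0)
    return(list(ff = NA_real_, counts = counts, defined = FALSE))
  list(ff = var(counts) / mu, counts = counts, defined = TRUE)
}

#' Pairwise synchrony of firing
#'
#' SF between electrodes x and y is the number of times the two electrodes
#' burst together divided by the maximum of their individual burstlet counts.
#' "Bursting together" is counted as the number of burstlets of the
#' less-bursting electrode that temporally overlap at least one burstlet of
#' the other (closed-interval overlap), which bounds SF by 1 under this
#' denominator. SF is 0 when neither electrode bursts.
#'
#' @param bx,by data.frames of burstlets (columns \code{start}, \code{end})
#'   for the two electrodes, from the same recording.
#' @return list with \code{sf}, \code{b_joint}, \code{b_max} and
#'   \code{category} (\code{"sub-threshold"}, \code{"weak"}, \code{"medium"},
#'   \code{"strong"}).
#' @export
synchrony_of_firing <- function(bx, by) {
  nx <- nrow(bx); ny <- nrow(by)
  b_max <- max(nx, ny)
  if (b_max == 0)
    return(list(sf = 0, b_joint = 0L, b_max = 0L,
                category = "sub-threshold"))
  # count overlapping burstlets of the less-bursting electrode
  if (nx <= ny) { a <- bx; b <- by } else { a <- by; b <- bx }
  joint <- 0L
  if (nrow(a) && nrow(b)) {
    for (i in seq_len(nrow(a)))
      if (any(a$start[i] <= b$end & b$start <= a$end[i])) joint <- joint + 1L
  }
  sf <- joint / b_max
  category <- if (sf < 0.1) "sub-threshold"
  else if (sf < 0.4) "weak" else if (sf < 0.7) "medium" else "strong"
  list(sf = sf, b_joint = joint, b_max = as.integer(b_max),
       category = category)
}

#' Synchrony-of-firing matrix for a session
#'
#' @param session a [recording_session()].
#' @param burstlets output of [session_burstlets()]; computed if \code{NULL}.
#' @param config a [pipeline_config()].
#' @return symmetric numeric matrix of SF values over analysis electrodes,
#'   zero diagonal.
#' @export
sf_matrix <- function(session, burstlets = NULL,
                      config = pipeline_config()) {
  if (is.null(burstlets)) burstlets <- session_burstlets(session, config)
  ids <- analysis_electrodes(session$layout, session$excluded_electrodes)
  per <- lapply(ids, function(id)
    burstlets[burstlets$electrode == id, c("start", "end"), drop = FALSE])
  names(per) <- ids
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (length(ids) >= 2)
    for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids)) {
      s <- synchrony_of_firing(per[[i]], per[[j]])$sf
      m[i, j] <- s; m[j, i] <- s
    }
  m
}

#' Track per-electrode metrics over timepoints as percent change
#'
#' Electrodes (or pairs) are tracked only if present and at or above the
#' metric's floor at every timepoint, preventing artificial inflation of
#' percent-change values. Percent change at each post timepoint is
#' \code{100 (v_post - v_baseline)/v_baseline}. For synchronization, the
#' category of each unit is fixed by its baseline value.
#'
#' @param values numeric matrix, rows = units (electrodes or pairs), columns
#'   = timepoints in chronological order; first column is baseline. Rows
#'   must be named.
#' @param floor per-metric lower bound applied at every timepoint.
#' @return data.frame with unit id, validity flag, baseline value, and one
#'   \code{pct_change_<timepoint>} column per post timepoint (NA when not
#'   valid).
#' @export
track_metric <- function(values, floor = 0) {
  if (is.null(rownames(values))) stop("rows of values must be named")
  if (ncol(values) < 2) stop("need a baseline and at least one post timepoint")
  valid <- apply(values, 1, function(v) all(is.finite(v)) && all(v >= floor))
  out <- data.frame(unit = rownames(values), valid = valid,
                    baseline = values[, 1])
  cn <- colnames(values)
  if (is.null(cn)) cn <- paste0("t", seq_len(ncol(values)))
  for (j in 2:ncol(values)) {
    pc <- ifelse(valid, 100 * (values[, j] - values[, 1]) / values[, 1],
                 NA_real_)
    out[[paste0("pct_change_", cn[j])]] <- pc
  }
  rownames(out) <- NULL
  out
}

#' Median-absolute-deviation outlier filter
#'
#' Drops values farther than \code{k} x MAD from the median, where MAD is the
#' (unscaled) median of absolute deviations from the median. When MAD is 0
#' nothing is removed and a warning is emitted.
#'
#' @param values numeric vector (>= 3 values).
#' @param k scale factor (2 or 3 in typical use).
#' @return list with \code{kept}, \code{removed}, and logical \code{keep}
#'   mask aligned with the input.
#' @export
mad_filter <- function(values, k = 3) {
  if (length(values) < 3) stop("need at least 3 values")
  med <- median(values)
  madv <- median(abs(values - med))
  if (madv == 0) {
    warning("MAD is zero; no values excluded")
    return(list(kept = values, removed = values[0],
                keep = rep(TRUE, length(values))))
  }
  keep <- abs(values - med) <= k * madv
  list(kept = values[keep], removed = values[!keep], keep = keep)
}

#' Bootstrap estimation statistics for a difference of group means
#'
#' Resamples each group with replacement (\code{n_iter} iterations, default
#' 500), forms the bootstrap distribution of the difference of means
#' (A - B), and reports the 95 percent percentile confidence interval. The
#' p-value is derived from the CI by treating the bootstrap distribution as
#' approximately normal: \code{p = 2 (1 - pnorm(|mean difference| / SE))}
#' with SE the bootstrap standard deviation.
#'
#' @param deltas_a,deltas_b numeric vectors of per-unit changes in the two
#'   groups (both non-empty).
#' @param n_iter bootstrap iterations.
#' @param conf confidence level for the percentile interval.
#' @param seed optional integer seed for reproducibility.
#' @return list with \code{mean_diff}, \code{ci} (length 2), \code{p},
#'   \code{boot} (the bootstrap draws).
#' @export
estimation_difference <- function(deltas_a, deltas_b, n_iter = 500,
                                  conf = 0.95, seed = NULL) {
  if (!length(deltas_a) || !length(deltas_b)) stop("both groups must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  boot <- replicate(n_iter,
    mean(sample(deltas_a, replace = TRUE)) -
    mean(sample(deltas_b, replace = TRUE)))
  md <- mean(deltas_a) - mean(deltas_b)
  alpha <- 1 - conf
  ci <- unname(quantile(boot, c(alpha / 2, 1 - alpha / 2)))
  se <- sd(boot)
  p <- if (se == 0) as.numeric(md == 0) else 2 * (1 - pnorm(abs(md) / se))
  list(mean_diff = md, ci = ci, p = min(1, p), boot = boot)
}
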