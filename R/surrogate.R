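#' Homogeneous Poisson spike trains
#'
#' @param rate firing rate in Hz (> 0).
#' @param duration seconds.
#' @param n number of independent trains.
#' @param seed optional integer seed.
#' @return named list of sorted spike-time vectors.
#' @export
poisson_trains <- function(rate, duration, n = 1, seed = NULL) {
  stopifnot(rate > 0)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(n), function(i) {
    k <- rpois(1, rate * duration)
    sort(runif(k, 0, duration))
  })
  names(out) <- paste0("e", seq_len(n))
  out
}

#' Perfectly periodic spike trains
#'
#' @param period inter-spike interval in seconds.
#' @param duration seconds.
#' @param n number of trains.
#' @param phase common phase offset in seconds.
#' @return named list of spike-time vectors.
#' @export
periodic_trains <- function(period, duration, n = 1, phase = period / 2) {
  out <- lapply(seq_len(n), function(i) seq(phase, duration, by = period))
  names(out) <- paste0("e", seq_len(n))
  out
}

#' Coupled binary burstlet trains from the generative logistic model
#'
#' Samples C binary trains sequentially: the per-bin burst probability of
#' each train is the logistic function of a baseline plus weighted recent
#' history of all trains, i.e. the generative twin of the point-process GC
#' model. Returns the trains together with the true directed coupling graph.
#'
#' @param omega list with \code{baseline} (length C) and \code{kernel}
#'   (C x C x M array; \code{kernel[c, j, l]} is the effect of train j's lag
#'   l on train c).
#' @param T number of bins.
#' @param seed optional integer seed.
#' @return list with \code{trains} (C x T 0/1 matrix, rows named),
#'   \code{edges} (data.frame source, target of true nonzero couplings).
#' @export
coupled_glm_trains <- function(omega, T, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- length(omega$baseline)
  M <- dim(omega$kernel)[3]
  trains <- matrix(0L, C, T)
  rownames(trains) <- paste0("e", seq_len(C))
  for (t in seq_len(T)) {
    for (c in seq_len(C)) {
      eta <- omega$baseline[c]
      for (l in seq_len(min(M, t - 1)))
        eta <- eta + sum(omega$kernel[c, , l] * trains[, t - l])
      trains[c, t] <- rbinom(1, 1, 1 / (1 + exp(-eta)))
    }
  }
  nz <- which(apply(abs(omega$kernel), c(1, 2), sum) > 0, arr.ind = TRUE)
  nz <- nz[nz[, 1] != nz[, 2], , drop = FALSE]
  edges <- data.frame(source = paste0("e", nz[, 2]),
                      target = paste0("e", nz[, 1]))
  list(trains = trains, edges = edges)
}

#' Binary trains with planted r-wise synchrony
#'
#' Independent Bernoulli background on every electrode, plus simultaneous
#' burst events injected across a fixed set of r electrodes at an excess
#' per-bin rate. With \code{excess_rate = 0} this is a pure independence
#' null for calibrating the synchrony tests.
#'
#' @param C number of electrodes; \code{r} planted synchrony order;
#'   \code{base_p} background per-bin burst probability;
#'   \code{excess_rate} per-bin probability of an injected r-wise event;
#'   \code{T} bins; \code{seed} optional seed.
#' @return list with \code{trains} (C x T matrix) and \code{members} (the
#'   planted electrode set).
#' @export
planted_synchrony_marks <- function(C, r, base_p, excess_rate, T,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(r <= C)
  trains <- matrix(rbinom(C * T, 1, base_p), C, T)
  members <- seq_len(r)
  if (excess_rate > 0) {
    ev <- which(runif(T) < excess_rate)
    trains[members, ev] <- 1L
  }
  rownames(trains) <- paste0("e", seq_len(C))
  list(trains = trains, members = paste0("e", members))
}

#' Assemble surrogate spike trains into a full recording session
#'
#' Places surrogate trains on the standard 59-electrode layout so the whole
#' pipeline (gating, burst detection, metrics, connectivity, GC, synchrony)
#' can run end to end on data with known structure.
#'
#' @param trains named list of spike-time vectors (at most 59); names are
#'   ignored and trains are assigned to analysis electrodes in layout order.
#' @param duration seconds.
#' @param label session tag.
#' @return a [recording_session()] on [standard_mea_layout()].
#' @export
toy_session <- function(trains, duration, label = "surrogate") {
  layout <- standard_mea_layout()
  ids <- analysis_electrodes(layout)
  if (length(trains) > length(ids))
    stop("at most ", length(ids), " trains fit on the layout")
  st <- setNames(trains, ids[seq_along(trains)])
  recording_session(st, layout, duration, label = label)
}
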