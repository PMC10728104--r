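#' Pipeline configuration with documented defaults
#'
#' Collects every tunable of the analysis pipeline in one list. Values can be
#' overridden by name; unknown names are an error. Units: time thresholds in
#' milliseconds unless suffixed \code{_s}, coordinates in micrometres.
#'
#' Defaults: 20-2000 Hz fourth-order Butterworth band with a 60 Hz notch,
#' 10 s filter chunks, spike threshold 4.5 x the chunk noise SD with a 2 ms
#' refractory merge; burstlet core ISI min(100 ms, 1/(4 rate)) for >= 4 spikes
#' with peripheral ISI min(200 ms, 1/(3 rate)); global bursts >= 3 overlapping
#' burstlets on distinct electrodes; 300 ms burstlet-train bins with a
#' 4-spike threshold; 100 ms Fano windows; connectivity bins 10 ms in vitro /
#' 1 ms in silico with a 0.005 weight floor; GC history M = 3 bins, 5-fold
#' blocked CV, BH FDR level 0.01; synchrony activity threshold 30 burstlets,
#' order classes 2-8 / 9-15 / 16+; per-electrode tracking floors 0.2 Hz spike
#' rate, 0.02 Hz burstlet rate, 0.01 Hz global burst rate, 0.005 AU local
#' efficiency.
#'
#' @param ... name = value overrides.
#' @return a named list of class \code{"burstnet_config"}.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # signal conditioning / spike detection
    filter_band_hz      = c(20, 2000),
    filter_order        = 4,
    notch_hz            = 60,
    chunk_s             = 10,
    spike_threshold_sd  = 4.5,
    refractory_ms       = 2,
    # burstlet / global burst detection
    burstlet_min_spikes = 4,
    core_isi_ms         = 100,
    core_rate_factor    = 4,
    periph_isi_ms       = 200,
    periph_rate_factor  = 3,
    global_min_electrodes = 3,
    # binary burstlet trains
    train_bin_ms        = 300,
    train_bin_threshold = 4,
    # activity metrics
    fano_window_ms      = 100,
    sync_bins           = c(weak = 0.1, medium = 0.4, strong = 0.7),
    activity_min_spikes = 2000,
    # connectivity
    conn_bin_ms_vitro   = 10,
    conn_bin_ms_silico  = 1,
    conn_weight_floor   = 0.005,
    # tracking floors (per-electrode lower bounds before percent change)
    floor_spike_rate_hz  = 0.2,
    floor_burstlet_rate_hz = 0.02,
    floor_global_burst_rate_hz = 0.01,
    floor_local_efficiency = 0.005,
    # Granger causality
    gc_history_bins     = 3,
    gc_max_support      = 12,
    gc_cv_folds         = 5,
    gc_fdr_level        = 0.01,
    gc_ridge            = 1e-6,
    gc_newton_tol       = 1e-8,
    gc_newton_maxit     = 100,
    # higher-order synchrony
    sync_min_burstlets  = 30,
    order_classes       = list(low = c(2, 8), intermediate = c(9, 15),
                               high = c(16, Inf)),
    sync_alpha          = 0.05,
    sync_n_null         = 200,
    # Tokeshi
    tokeshi_bin_width   = 3,
    # estimation statistics
    boot_iterations     = 500
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- c("burstnet_config", "list")
  cfg
}
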