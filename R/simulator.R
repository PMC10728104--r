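#' Default dynamics constants for the LIF network
#'
#' Membrane, synaptic, after-hyperpolarization, noise and STDP constants, in
#' SI units (F, S, V, A, s). These are documented package defaults chosen to
#' produce irregular spiking with recurrent network-wide bursting in the
#' control condition; every value can be overridden.
#'
#' @param ... name = value overrides.
#' @return named list of dynamics constants.
#' @export
lif_params <- function(...) {
  par <- list(
    dt        = 1e-4,     # integration step, 0.1 ms
    C_m       = 200e-12,  # membrane capacitance
    g_m       = 10e-9,    # leak conductance (tau_m = 20 ms)
    V_L       = -70e-3,   # resting potential
    V_th      = -50e-3,   # spike threshold
    V_reset   = -65e-3,   # post-spike reset
    t_ref     = 2e-3,     # absolute refractory period
    E_ampa    = 0,        tau_ampa = 2e-3,
    E_nmda    = 0,        tau_nmda = 100e-3,
    E_gaba    = -80e-3,   tau_gaba = 10e-3,
    g_ampa_unit = 2.5e-9,   # conductance per weight AU
    g_nmda_unit = 0.03e-9,
    g_gaba_unit = 3e-9,
    E_ahp     = -90e-3,   tau_ahp = 2.0, dg_ahp = 60e-9,
    noise_sd  = 12e-12,   # white-noise current amplitude (A sqrt(s))
    drive_mean = 70e-12,  # tonic drive mean (rheobase is 200 pA)
    drive_sd   = 10e-12,  # Gaussian heterogeneity across neurons
    stdp_on   = TRUE,
    A_plus    = 0.05, A_minus = 0.055,   # additive STDP amplitudes (AU)
    tau_plus  = 20e-3, tau_minus = 20e-3,
    w_min     = 0, w_max = 16,
    w_init_ee = 8
  )
  over <- list(...)
  bad <- setdiff(names(over), names(par))
  if (length(bad)) stop("unknown dynamics constants: ",
                        paste(bad, collapse = ", "))
  par[names(over)] <- over
  par
}

# deterministic sub-seeds for the named RNG streams
.stream_seed <- function(seed, stream) {
  (seed * 16L + match(stream, c("wiring", "dynamics", "injury", "bdnf"))) %%
    2147483647L
}

#' Generate the simulated culture connectome
#'
#' Places 500 neurons (440 excitatory, 60 inhibitory) uniformly at random in
#' a square culture whose area matches a plating density of 3.5e3 cells/mm2,
#' then wires them probabilistically with a distance-decaying Gaussian kernel
#' per connection class (excitatory vs inhibitory presynaptic). The
#' inhibitory kernel amplitude is calibrated in closed form from the realized
#' positions so that, in expectation, the target fraction (default 65
#' percent) of synapses has an excitatory presynaptic neuron. At most one
#' synapse exists per ordered neuron pair. Excitatory-excitatory weights
#' start at 8 AU (plastic, capped at 16); all other synapses have fixed
#' weight 1.
#'
#' @param seed integer seed (wiring stream).
#' @param n_exc,n_inh neuron counts (defaults 440 / 60).
#' @param density_mm2 plating density in cells/mm2 (default 3500).
#' @param sigma_e_mm,sigma_i_mm Gaussian kernel length constants for
#'   excitatory / inhibitory presynaptic neurons (mm).
#' @param amp_e excitatory kernel amplitude (connection probability at zero
#'   distance).
#' @param target_exc_fraction calibration target for the fraction of
#'   synapses with excitatory presynaptic neurons.
#' @param params a [lif_params()] list (for the initial e-e weight).
#' @return object of class \code{"network_model"}: list with
#'   \code{positions} (mm), \code{type} ("E"/"I"), \code{alive},
#'   \code{synapses} (data.frame pre, post, weight, ee, status),
#'   \code{side_mm}, \code{seed}, \code{amp_i}.
#' @export
generate_network <- function(seed = 1, n_exc = 440, n_inh = 60,
                             density_mm2 = 3500,
                             sigma_e_mm = 0.15, sigma_i_mm = 0.10,
                             amp_e = 0.08, target_exc_fraction = 0.65,
                             params = lif_params()) {
  set.seed(.stream_seed(seed, "wiring"))
  n <- n_exc + n_inh
  side <- sqrt(n / density_mm2)
  pos <- cbind(x = runif(n, 0, side), y = runif(n, 0, side))
  type <- sample(rep(c("E", "I"), c(n_exc, n_inh)))
  d2 <- as.matrix(dist(pos))^2
  kern_e <- exp(-d2 / (2 * sigma_e_mm^2))
  kern_i <- exp(-d2 / (2 * sigma_i_mm^2))
  diag(kern_e) <- 0; diag(kern_i) <- 0
  is_e <- type == "E"
  # closed-form calibration of the inhibitory amplitude to the target
  # excitatory-synapse fraction, from the realized kernel mass
  K_e <- sum(kern_e[is_e, ])
  K_i <- sum(kern_i[!is_e, ])
  amp_i <- amp_e * K_e * (1 - target_exc_fraction) /
    (target_exc_fraction * K_i)
  p <- matrix(0, n, n)
  p[is_e, ] <- amp_e * kern_e[is_e, ]
  p[!is_e, ] <- amp_i * kern_i[!is_e, ]
  if (max(p) > 1)
    warning("connection probabilities clipped at 1; lower amp_e")
  p <- pmin(p, 1)
  diag(p) <- 0
  conn <- which(matrix(runif(n * n), n, n) < p, arr.ind = TRUE)
  ee <- is_e[conn[, 1]] & is_e[conn[, 2]]
  synapses <- data.frame(pre = conn[, 1], post = conn[, 2],
                         weight = ifelse(ee, params$w_init_ee, 1),
                         ee = ee, status = "active",
                         stringsAsFactors = FALSE)
  structure(list(positions = pos, type = type, alive = rep(TRUE, n),
                 synapses = synapses, side_mm = side, seed = seed,
                 amp_i = amp_i),
            class = "network_model")
}

#' Apply the simulated glutamate injury
#'
#' Silences 30 percent of excitatory neurons and 25 percent of inhibitory
#' neurons, chosen uniformly at random, removing all synapses with a dead
#' endpoint; then deletes 75 percent of the surviving inhibitory-presynaptic
#' synapses uniformly at random. Removed synapses keep a status record
#' (\code{"dead_endpoint"} or \code{"deleted_inh"}) so a later BDNF revival
#' can restore exactly the right ones.
#'
#' @param network a [generate_network()] result.
#' @param seed integer seed (injury stream).
#' @param frac_exc,frac_inh,frac_inh_syn deletion fractions (defaults 0.30,
#'   0.25, 0.75).
#' @return the perturbed \code{"network_model"} with \code{injured_inh}
#'   recording the silenced inhibitory neurons.
#' @export
apply_injury <- function(network, seed = 1, frac_exc = 0.30,
                         frac_inh = 0.25, frac_inh_syn = 0.75) {
  set.seed(.stream_seed(seed, "injury"))
  exc <- which(network$type == "E" & network$alive)
  inh <- which(network$type == "I" & network$alive)
  kill_e <- sample(exc, round(frac_exc * length(exc)))
  kill_i <- sample(inh, round(frac_inh * length(inh)))
  dead <- c(kill_e, kill_i)
  network$alive[dead] <- FALSE
  syn <- network$synapses
  hit <- syn$status == "active" & (syn$pre %in% dead | syn$post %in% dead)
  syn$status[hit] <- "dead_endpoint"
  surv_inh <- which(syn$status == "active" &
                      network$type[syn$pre] == "I")
  del <- sample(surv_inh, round(frac_inh_syn * length(surv_inh)))
  syn$status[del] <- "deleted_inh"
  network$synapses <- syn
  network$injured_inh <- kill_i
  network$injured_exc <- kill_e
  network
}

#' Apply the simulated BDNF treatment
#'
#' Revives half (floor) of the inhibitory neurons silenced by the injury.
#' Reintroduced neurons regain their pre-injury synapses except those whose
#' partner is still dead or that were removed by the targeted
#' inhibitory-synapse deletion.
#'
#' @param network an injured \code{"network_model"}.
#' @param seed integer seed (revival stream).
#' @param frac_revive fraction of injured inhibitory neurons revived
#'   (default 0.5, floored).
#' @return the treated \code{"network_model"} with \code{revived_inh}.
#' @export
apply_bdnf <- function(network, seed = 1, frac_revive = 0.5) {
  if (is.null(network$injured_inh))
    stop("BDNF revival requires a previously injured network")
  set.seed(.stream_seed(seed, "bdnf"))
  n_rev <- floor(frac_revive * length(network$injured_inh))
  revived <- sample(network$injured_inh, n_rev)
  network$alive[revived] <- TRUE
  syn <- network$synapses
  restore <- syn$status == "dead_endpoint" &
    network$alive[syn$pre] & network$alive[syn$post]
  syn$status[restore] <- "active"
  network$synapses <- syn
  network$revived_inh <- revived
  network
}

# active synapse table and CSR index structures for the C++ core
.active_csr <- function(network) {
  syn <- network$synapses[network$synapses$status == "active", , drop = FALSE]
  n <- length(network$alive)
  # 0-based synapse row indices grouped by pre (out) / post (in) neuron
  out_idx <- as.integer(order(syn$pre) - 1L)
  out_ptr <- c(0L, cumsum(tabulate(syn$pre, nbins = n)))
  in_idx <- as.integer(order(syn$post) - 1L)
  in_ptr <- c(0L, cumsum(tabulate(syn$post, nbins = n)))
  list(syn = syn, out_ptr = as.integer(out_ptr), out_idx = out_idx,
       in_ptr = as.integer(in_ptr), in_idx = in_idx)
}

#' Integrate the network dynamics
#'
#' Euler-Maruyama integration of the conductance-based LIF equations with
#' threshold-reset spiking, exponential AMPA/NMDA/GABA conductances, an
#' after-hyperpolarization conductance, per-neuron Gaussian tonic drive, and
#' additive pair-based STDP on excitatory-excitatory weights (clipped to
#' [0, 16]). State (potentials, conductances, traces) can be carried across
#' calls so perturbations can be applied between epochs.
#'
#' @param network a \code{"network_model"}.
#' @param duration seconds to integrate.
#' @param params a [lif_params()].
#' @param state \code{NULL} to start at rest, or the \code{state} element of
#'   a previous result.
#' @param t0 start time in seconds (for spike timestamps).
#' @param I_ext optional per-neuron tonic drive vector; drawn from the
#'   configured Gaussian if missing and not in \code{state}.
#' @return list with \code{spikes} (data.frame neuron, time), \code{network}
#'   (weights updated), \code{state}, \code{I_ext}.
#' @export
simulate_network <- function(network, duration, params = lif_params(),
                             state = NULL, t0 = 0, I_ext = NULL) {
  n <- length(network$alive)
  if (is.null(I_ext))
    I_ext <- rnorm(n, params$drive_mean, params$drive_sd)
  if (is.null(state))
    state <- list(V = rep(params$V_L, n), g_ampa = numeric(n),
                  g_nmda = numeric(n), g_gaba = numeric(n),
                  g_ahp = numeric(n), x_trace = numeric(n),
                  y_trace = numeric(n), last_spike = rep(-Inf, n))
  csr <- .active_csr(network)
  par <- params; par$I_ext <- I_ext
  res <- cpp_simulate_lif(n, as.integer(network$alive),
                          as.integer(network$type == "E"),
                          as.integer(csr$syn$pre - 1L),
                          as.integer(csr$syn$post - 1L),
                          csr$syn$weight, as.integer(csr$syn$ee),
                          csr$out_ptr, csr$out_idx, csr$in_ptr, csr$in_idx,
                          par, state, t0, duration)
  network$synapses$weight[network$synapses$status == "active"] <- res$weights
  list(spikes = data.frame(neuron = res$spike_i, time = res$spike_t),
       network = network, state = res$state, I_ext = I_ext)
}

#' Run the full perturbation schedule
#'
#' Epochs: settle 0-120 s, pre 120-240 s, treatment-1 240-360 s, treatment-2
#' 360-480 s, post 480-600 s. Glutamate injury (if any) is applied at 240 s
#' and BDNF revival (if any) at 360 s. Conditions sharing a seed have
#' identical dynamics up to 240 s because the injury and revival draw from
#' their own RNG streams.
#'
#' @param network a freshly generated \code{"network_model"}.
#' @param condition \code{"control"}, \code{"injury"}, or
#'   \code{"injury_bdnf"}.
#' @param seed integer seed (dynamics stream; also used for the perturbation
#'   streams).
#' @param params a [lif_params()].
#' @param epoch_s epoch length in seconds (default 120; smaller values give
#'   a proportionally compressed schedule for quick studies).
#' @return list with \code{spikes} (all epochs pooled), \code{epochs}
#'   (per-epoch spike data.frames), \code{network} (final), \code{weights_pre},
#'   \code{weights_post} (e-e weights at the ends of the pre and post
#'   epochs), \code{condition}, \code{epoch_s}.
#' @export
run_schedule <- function(network, condition = c("control", "injury",
                                                "injury_bdnf"),
                         seed = 1, params = lif_params(), epoch_s = 120) {
  condition <- match.arg(condition)
  set.seed(.stream_seed(seed, "dynamics"))
  I_ext <- rnorm(length(network$alive), params$drive_mean, params$drive_sd)
  epochs <- list(); state <- NULL; t0 <- 0
  weights_pre <- NULL; weights_post <- NULL
  for (ep in c("settle", "pre", "treat1", "treat2", "post")) {
    if (ep == "treat1" && condition != "control")
      network <- apply_injury(network, seed)
    if (ep == "treat2" && condition == "injury_bdnf")
      network <- apply_bdnf(network, seed)
    run <- simulate_network(network, epoch_s, params, state, t0, I_ext)
    network <- run$network; state <- run$state; t0 <- t0 + epoch_s
    epochs[[ep]] <- run$spikes
    if (ep == "pre")
      weights_pre <- network$synapses$weight[network$synapses$ee &
                                               network$synapses$status ==
                                                 "active"]
    if (ep == "post")
      weights_post <- network$synapses$weight[network$synapses$ee &
                                                network$synapses$status ==
                                                  "active"]
  }
  list(spikes = do.call(rbind, epochs), epochs = epochs, network = network,
       weights_pre = weights_pre, weights_post = weights_post,
       condition = condition, epoch_s = epoch_s)
}

#' Convert simulated spikes to a pseudo-MEA recording session
#'
#' Partitions the culture into an 8 x 8 spatial grid, removes 5 reference
#' cells (the four corners plus a central cell by default), and merges the
#' member neurons' spikes per remaining cell into one electrode train
#' (sorted, deduplicated at identical timestamps), yielding a 59-electrode
#' session analyzable by every pipeline stage.
#'
#' @param network a \code{"network_model"}.
#' @param spikes data.frame \code{neuron}, \code{time} from
#'   [simulate_network()] or [run_schedule()].
#' @param duration session duration in seconds; spike times are shifted by
#'   \code{t_offset} first.
#' @param t_offset subtracted from spike times (e.g. the start of the
#'   analysis epoch).
#' @param reference_cells integer vector of 5 grid-cell indices (1..64,
#'   column-major) to remove; default corners plus the 28th cell (central).
#' @return a [recording_session()] with a 59-electrode grid layout; the
#'   neuron-to-electrode assignment is attached as attribute
#'   \code{"assignment"}.
#' @export
to_pseudo_mea <- function(network, spikes, duration,
                          t_offset = 0,
                          reference_cells = c(1, 8, 57, 64, 28)) {
  side <- network$side_mm
  gx <- pmin(floor(network$positions[, "x"] / side * 8), 7)
  gy <- pmin(floor(network$positions[, "y"] / side * 8), 7)
  cell <- gx * 8 + gy + 1   # column-major 1..64
  ids <- paste0("g", cell)
  cell_ids <- paste0("g", 1:64)
  cx <- ((0:63) %/% 8 + 0.5) * side / 8 * 1000   # um
  cy <- ((0:63) %% 8 + 0.5) * side / 8 * 1000
  layout <- mea_layout(cell_ids, cbind(cx, cy),
                       reference_ids = paste0("g", reference_cells))
  st <- list()
  times <- spikes$time - t_offset
  keep <- times >= 0 & times <= duration
  nrn <- spikes$neuron[keep]; times <- times[keep]
  for (cc in 1:64) {
    members <- which(cell == cc & network$alive)
    tt <- sort(unique(times[nrn %in% members]))
    if (length(tt)) st[[paste0("g", cc)]] <- tt
  }
  sess <- recording_session(st, layout, duration,
                            label = "pseudo-MEA")
  attr(sess, "assignment") <- cell
  sess
}

#' Neurons recorded per pseudo-MEA electrode
#'
#' @param network a \code{"network_model"}.
#' @param reference_cells as in [to_pseudo_mea()].
#' @return list with \code{per_electrode} (named counts over the 59
#'   recording cells, live neurons only) and \code{mean}.
#' @export
pseudo_mea_occupancy <- function(network,
                                 reference_cells = c(1, 8, 57, 64, 28)) {
  side <- network$side_mm
  gx <- pmin(floor(network$positions[, "x"] / side * 8), 7)
  gy <- pmin(floor(network$positions[, "y"] / side * 8), 7)
  cell <- gx * 8 + gy + 1
  rec <- setdiff(1:64, reference_cells)
  counts <- vapply(rec, function(cc) sum(cell == cc & network$alive),
                   integer(1))
  names(counts) <- paste0("g", rec)
  list(per_electrode = counts, mean = mean(counts))
}

#' Summaries of excitatory-excitatory synaptic weights
#'
#' @param weights_pre,weights_post e-e weight vectors at the pre and post
#'   epochs (aligned; same synapses).
#' @param window moving-average window (synapses) for the change-vs-initial
#'   curve.
#' @return list with \code{mean_pre}, \code{mean_post}, \code{ecdf_post},
#'   and \code{change_curve} (data.frame initial, change, smoothed).
#' @export
weight_summary <- function(weights_pre, weights_post, window = 250) {
  stopifnot(length(weights_pre) == length(weights_post))
  o <- order(weights_pre)
  init <- weights_pre[o]
  change <- (weights_post - weights_pre)[o]
  sm <- if (length(init) >= window)
    stats::filter(change, rep(1 / window, window), sides = 2)
  else rep(NA_real_, length(init))
  list(mean_pre = mean(weights_pre), mean_post = mean(weights_post),
       ecdf_post = stats::ecdf(weights_post),
       change_curve = data.frame(initial = init, change = change,
                                 smoothed = as.numeric(sm)))
}
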