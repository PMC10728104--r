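# single isolated neuron embedded in the network container
single_neuron_net <- function() {
  structure(list(positions = cbind(x = 0.1, y = 0.1), type = "E",
                 alive = TRUE,
                 synapses = data.frame(pre = integer(0), post = integer(0),
                                       weight = numeric(0), ee = logical(0),
                                       status = character(0)),
                 side_mm = 0.38, seed = 1),
            class = "network_model")
}

test_that("generated connectomes have the specified composition", {
  net <- generate_network(seed = 3)
  expect_equal(sum(net$type == "E"), 440)
  expect_equal(sum(net$type == "I"), 60)
  expect_equal(length(net$alive), 500)
  expect_true(all(net$alive))
  # density fixes the culture area
  expect_equal(net$side_mm^2 * 3500, 500, tolerance = 1e-9)
  # at most one synapse per ordered pair, no self-synapses
  key <- paste(net$synapses$pre, net$synapses$post)
  expect_false(any(duplicated(key)))
  expect_false(any(net$synapses$pre == net$synapses$post))
  # e-e weights start at 8, others at 1
  expect_true(all(net$synapses$weight[net$synapses$ee] == 8))
  expect_true(all(net$synapses$weight[!net$synapses$ee] == 1))
})

test_that("connection probability decays with distance for both types", {
  net <- generate_network(seed = 4)
  syn <- net$synapses
  d <- sqrt(rowSums((net$positions[syn$pre, ] -
                       net$positions[syn$post, ])^2))
  # connected pairs are closer on average than arbitrary pairs
  set.seed(4)
  i <- sample(500, 2000, TRUE); j <- sample(500, 2000, TRUE)
  d_all <- sqrt(rowSums((net$positions[i, ] - net$positions[j, ])^2))
  expect_lt(mean(d), mean(d_all[i != j]))
})

test_that("excitatory synapse fraction calibrates to the 65/35 balance", {
  fr <- vapply(1:6, function(s) {
    net <- generate_network(seed = s)
    mean(net$type[net$synapses$pre] == "E")
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.65), 0.02)
})

test_that("injury removes the stated fractions and only via endpoints for
           excitatory synapses", {
  net <- generate_network(seed = 6)
  inj <- apply_injury(net, seed = 6)
  expect_equal(sum(inj$alive & inj$type == "E"), 308)
  expect_equal(sum(inj$alive & inj$type == "I"), 45)
  expect_equal(length(inj$alive), 500)   # neurons are flagged, not removed
  syn <- inj$synapses
  # every removed excitatory synapse lost an endpoint (no extra deletion)
  pre_e <- inj$type[syn$pre] == "E"
  gone_e <- pre_e & syn$status != "active"
  expect_true(all(syn$status[gone_e] == "dead_endpoint"))
  expect_true(all(!inj$alive[syn$pre[gone_e]] |
                    !inj$alive[syn$post[gone_e]]))
  # inhibitory reduction equals the direct count from the realized connectome
  pre_i <- inj$type[syn$pre] == "I"
  both_alive <- sum(pre_i & inj$alive[syn$pre] & inj$alive[syn$post])
  expected_surv <- both_alive - round(0.75 * both_alive)
  expect_equal(sum(pre_i & syn$status == "active"), expected_surv)
  frac_lost <- 1 - expected_surv / sum(pre_i)
  expect_lt(abs(frac_lost - 0.86), 0.04)
})

test_that("BDNF revives 7 inhibitory neurons with their surviving synapses", {
  net <- generate_network(seed = 7)
  inj <- apply_injury(net, seed = 7)
  bd <- apply_bdnf(inj, seed = 7)
  expect_equal(length(bd$revived_inh), 7)
  expect_true(all(bd$type[bd$revived_inh] == "I"))   # no excitatory revival
  expect_equal(sum(bd$alive & bd$type == "I"), 52)
  expect_equal(sum(bd$alive & bd$type == "E"), 308)
  syn <- bd$synapses
  # restored synapses never connect to a dead partner
  act <- syn[syn$status == "active", ]
  expect_true(all(bd$alive[act$pre] & bd$alive[act$post]))
  # targeted deletions stay deleted even when both endpoints are alive again
  del_restorable <- syn$status == "deleted_inh" &
    bd$alive[syn$pre] & bd$alive[syn$post]
  expect_true(any(del_restorable))
  expect_true(all(syn$status[del_restorable] == "deleted_inh"))
  expect_error(apply_bdnf(net, 1), "injured")
})

test_that("pseudo-MEA occupancy and session conversion behave", {
  occ <- vapply(1:8, function(s)
    pseudo_mea_occupancy(generate_network(seed = s))$mean, numeric(1))
  expect_lt(abs(mean(occ) - 7.8), 0.15)
  # silenced neurons contribute no spikes
  net <- generate_network(seed = 8)
  inj <- apply_injury(net, seed = 8)
  dead <- which(!inj$alive)
  fake <- data.frame(neuron = c(dead[1], which(inj$alive)[1]),
                     time = c(0.5, 0.6))
  sess <- to_pseudo_mea(inj, fake, 1)
  expect_equal(sum(vapply(sess$spike_times, length, integer(1))), 1L)
  expect_length(analysis_electrodes(sess$layout), 59)
  # merged trains are sorted and deduplicated
  alive2 <- which(inj$alive)[1:2]
  fake2 <- data.frame(neuron = c(alive2, alive2[1]),
                      time = c(0.5, 0.5, 0.2))
  sess2 <- to_pseudo_mea(inj, fake2, 1)
  ok <- vapply(sess2$spike_times, function(v)
    length(v) < 2 || !is.unsorted(v, strictly = TRUE), logical(1))
  expect_true(all(ok))
})

test_that("isolated noise-free neuron matches the LIF closed form", {
  p <- lif_params(noise_sd = 0, stdp_on = FALSE, dt = 1e-5, dg_ahp = 0)
  net <- single_neuron_net()
  I <- 250e-12
  res <- simulate_network(net, 2, p, I_ext = I)
  isi <- diff(res$spikes$time)
  tau <- p$C_m / p$g_m
  Vinf <- p$V_L + I / p$g_m
  isi_theory <- p$t_ref + tau * log((Vinf - p$V_reset) / (Vinf - p$V_th))
  expect_equal(mean(isi), isi_theory, tolerance = 2e-3)
  # sub-threshold fixed point: no input, no noise -> V stays at V_L
  res0 <- simulate_network(net, 0.5, lif_params(noise_sd = 0,
                                                stdp_on = FALSE),
                           I_ext = 0)
  expect_equal(res0$state$V[1], p$V_L, tolerance = 1e-12)
  expect_equal(nrow(res0$spikes), 0)
})

test_that("STDP potentiates pre-before-post and depresses the reverse", {
  # two neurons, one e-e synapse, zero synaptic conductance so spike timing
  # is set purely by the drives; phases set via initial V
  mk2 <- function() structure(
    list(positions = cbind(x = c(0.1, 0.2), y = c(0.1, 0.1)),
         type = c("E", "E"), alive = c(TRUE, TRUE),
         synapses = data.frame(pre = 1L, post = 2L, weight = 8,
                               ee = TRUE, status = "active"),
         side_mm = 0.38, seed = 1),
    class = "network_model")
  p <- lif_params(noise_sd = 0, dt = 1e-5, dg_ahp = 0,
                  g_ampa_unit = 0, g_nmda_unit = 0)
  st <- function(v2) list(V = c(p$V_L, v2), g_ampa = numeric(2),
                          g_nmda = numeric(2), g_gaba = numeric(2),
                          g_ahp = numeric(2), x_trace = numeric(2),
                          y_trace = numeric(2), last_spike = rep(-Inf, 2))
  I <- rep(250e-12, 2)
  # post starts closer to threshold -> fires ~5 ms after... tune by offset:
  # pre at V_L fires first when post starts lower
  lead <- simulate_network(mk2(), 1, p, state = st(p$V_L - 4e-3), I_ext = I)
  expect_gt(lead$network$synapses$weight, 8)     # pre fires before post
  lag <- simulate_network(mk2(), 1, p, state = st(p$V_L + 4e-3), I_ext = I)
  expect_lt(lag$network$synapses$weight, 8)      # post fires before pre
})

test_that("weights stay within bounds and plasticity-off means no change", {
  net <- generate_network(seed = 9)
  set.seed(9)
  run <- simulate_network(net, 3, lif_params())
  w <- run$network$synapses$weight[run$network$synapses$ee]
  expect_true(all(w >= 0 & w <= 16))
  set.seed(9)
  frozen <- simulate_network(net, 3, lif_params(stdp_on = FALSE))
  expect_true(all(frozen$network$synapses$weight ==
                    net$synapses$weight))
  expect_gt(nrow(frozen$spikes), 0)
})

test_that("conditions sharing a seed have identical dynamics up to the
           injury and conserve structure", {
  ctrl <- run_schedule(generate_network(seed = 11), "control", seed = 11,
                       epoch_s = 2)
  inj <- run_schedule(generate_network(seed = 11), "injury", seed = 11,
                      epoch_s = 2)
  bdnf <- run_schedule(generate_network(seed = 11), "injury_bdnf",
                       seed = 11, epoch_s = 2)
  expect_identical(ctrl$epochs$settle, inj$epochs$settle)
  expect_identical(ctrl$epochs$pre, inj$epochs$pre)
  expect_identical(ctrl$epochs$pre, bdnf$epochs$pre)
  # alive counts change only at perturbation events, by the stated amounts
  expect_equal(sum(ctrl$network$alive), 500)
  expect_equal(sum(inj$network$alive), 353)            # 308 E + 45 I
  expect_equal(sum(bdnf$network$alive), 360)           # + 7 revived
  expect_equal(length(inj$network$alive), 500)
})
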