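// Conductance-based leaky integrate-and-fire network with AMPA/NMDA/GABA
// exponential synapses, an after-hyperpolarization conductance, Gaussian
// presynaptic noise current, and additive pair-based STDP on
// excitatory-excitatory synapses. Fixed-step Euler-Maruyama integration;
// spikes are processed once per step in ascending neuron index. Uses R's RNG
// so set.seed() controls the noise stream.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_simulate_lif(int n,
                      const IntegerVector& alive,
                      const IntegerVector& is_exc,
                      const IntegerVector& syn_pre,   // 0-based
                      const IntegerVector& syn_post,  // 0-based
                      const NumericVector& syn_w_in,
                      const IntegerVector& syn_ee,    // 1 if exc->exc
                      const IntegerVector& out_ptr,   // CSR over presyn
                      const IntegerVector& out_idx,   // synapse indices
                      const IntegerVector& in_ptr,    // CSR over postsyn
                      const IntegerVector& in_idx,
                      const List& par,
                      List state,
                      double t0, double duration) {
  const double dt       = par["dt"];
  const double Cm       = par["C_m"];
  const double gm       = par["g_m"];
  const double VL       = par["V_L"];
  const double Vth      = par["V_th"];
  const double Vreset   = par["V_reset"];
  const double tref     = par["t_ref"];
  const double E_ampa   = par["E_ampa"],  tau_ampa = par["tau_ampa"];
  const double E_nmda   = par["E_nmda"],  tau_nmda = par["tau_nmda"];
  const double E_gaba   = par["E_gaba"],  tau_gaba = par["tau_gaba"];
  const double g_ampa_u = par["g_ampa_unit"];
  const double g_nmda_u = par["g_nmda_unit"];
  const double g_gaba_u = par["g_gaba_unit"];
  const double E_ahp    = par["E_ahp"],   tau_ahp  = par["tau_ahp"];
  const double dg_ahp   = par["dg_ahp"];
  const double noise_sd = par["noise_sd"];
  const bool   stdp_on  = par["stdp_on"];
  const double A_plus   = par["A_plus"],  A_minus = par["A_minus"];
  const double tau_plus = par["tau_plus"], tau_minus = par["tau_minus"];
  const double w_min    = par["w_min"],   w_max = par["w_max"];
  NumericVector I_ext   = par["I_ext"];   // per-neuron tonic drive
  NumericVector syn_w   = clone(syn_w_in);

  arma::vec V   = as<arma::vec>(state["V"]);
  arma::vec gA  = as<arma::vec>(state["g_ampa"]);
  arma::vec gN  = as<arma::vec>(state["g_nmda"]);
  arma::vec gG  = as<arma::vec>(state["g_gaba"]);
  arma::vec gH  = as<arma::vec>(state["g_ahp"]);
  arma::vec xtr = as<arma::vec>(state["x_trace"]);
  arma::vec ytr = as<arma::vec>(state["y_trace"]);
  arma::vec last = as<arma::vec>(state["last_spike"]);

  const double dA = std::exp(-dt / tau_ampa);
  const double dN = std::exp(-dt / tau_nmda);
  const double dG = std::exp(-dt / tau_gaba);
  const double dH = std::exp(-dt / tau_ahp);
  const double dP = std::exp(-dt / tau_plus);
  const double dM = std::exp(-dt / tau_minus);
  const double sq = noise_sd * std::sqrt(dt) / Cm;

  long n_steps = (long)std::llround(duration / dt);
  std::vector<double> sp_t; std::vector<int> sp_i;
  RNGScope rng;

  for (long step = 0; step < n_steps; ++step) {
    double t = t0 + (step + 1) * dt;
    gA *= dA; gN *= dN; gG *= dG; gH *= dH;
    if (stdp_on) { xtr *= dP; ytr *= dM; }
    for (int i = 0; i < n; ++i) {
      if (!alive[i]) continue;
      if (t - last[i] < tref) { V[i] = Vreset; continue; }
      double Isyn = gA[i] * (V[i] - E_ampa) + gN[i] * (V[i] - E_nmda) +
                    gG[i] * (V[i] - E_gaba);
      double Iahp = -gH[i] * (V[i] - E_ahp);
      double dV = (-gm * (V[i] - VL) - Isyn + Iahp + I_ext[i]) * dt / Cm;
      if (noise_sd > 0) dV += sq * R::norm_rand();
      V[i] += dV;
      if (!std::isfinite(V[i]))
        stop("membrane potential diverged (neuron %d, t = %.4f s)", i + 1, t);
    }
    // threshold crossing: process spikes once per step, ascending index
    for (int i = 0; i < n; ++i) {
      if (!alive[i] || V[i] < Vth) continue;
      V[i] = Vreset;
      last[i] = t;
      gH[i] += dg_ahp;
      sp_t.push_back(t); sp_i.push_back(i + 1);
      if (stdp_on) {
        // potentiation of incoming e-e synapses (pre fired before this post)
        for (int k = in_ptr[i]; k < in_ptr[i + 1]; ++k) {
          int s = in_idx[k];
          if (syn_ee[s] && alive[syn_pre[s]]) {
            double w = syn_w[s] + A_plus * xtr[syn_pre[s]];
            syn_w[s] = std::min(w_max, std::max(w_min, w));
          }
        }
      }
      // propagate to targets and apply depression on outgoing e-e synapses
      for (int k = out_ptr[i]; k < out_ptr[i + 1]; ++k) {
        int s = out_idx[k];
        int j = syn_post[s];
        if (!alive[j]) continue;
        if (is_exc[i]) {
          gA[j] += syn_w[s] * g_ampa_u;
          gN[j] += syn_w[s] * g_nmda_u;
          if (stdp_on && syn_ee[s]) {
            double w = syn_w[s] - A_minus * ytr[j];
            syn_w[s] = std::min(w_max, std::max(w_min, w));
          }
        } else {
          gG[j] += syn_w[s] * g_gaba_u;
        }
      }
      if (stdp_on) { xtr[i] += 1.0; ytr[i] += 1.0; }
    }
  }

  List new_state = List::create(
    _["V"] = V, _["g_ampa"] = gA, _["g_nmda"] = gN, _["g_gaba"] = gG,
    _["g_ahp"] = gH, _["x_trace"] = xtr, _["y_trace"] = ytr,
    _["last_spike"] = last);
  return List::create(_["spike_t"] = wrap(sp_t), _["spike_i"] = wrap(sp_i),
                      _["weights"] = syn_w, _["state"] = new_state);
}
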