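---
title: "Burst-level network analysis and the simulated injury model"
author: "burstnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burst-level network analysis and the simulated injury model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstnet)
```

`burstnet` characterizes homeostasis in cultured neuronal networks recorded
on microelectrode arrays (MEAs): how spontaneous burst-level activity,
functional connectivity, directed interactions, and higher-order synchrony
change through development, excitotoxic injury, and neurotrophin-driven
recovery. This vignette is the package's account of its models and numerical
choices.

## From voltage to burstlet trains

Raw extracellular signals (20 kHz) are conditioned in 10 s chunks with a
zero-phase fourth-order Butterworth bandpass (20--2000 Hz) plus a 60 Hz
notch; zero-phase forward--reverse filtering keeps spike timing undistorted.
Spikes are threshold crossings at 4.5 times the per-chunk, per-electrode
signal SD, timed at the maximum absolute excursion, with a 2 ms refractory
merge so a single waveform is never counted twice. The chunk SD is computed
without spike-masking, which at the sparse firing typical of these cultures
is an adequate estimate of background noise.

Burstlets are cores of at least four spikes whose inter-spike intervals stay
within `min(100 ms, 1/(4 * rate))`, extended on both sides by peripheral
spikes within `min(200 ms, 1/(3 * rate))`, where `rate` is the electrode's
mean firing rate over the whole recording. The rate-adaptive reading of the
"4 times the firing rate" bound -- the ISI of a train firing at four times
the electrode's mean rate -- gives faster electrodes tighter criteria, which
matches the adaptive intent and is stated explicitly so results are
reproducible. Detection runs on the whole
train, so a spike run that crosses a 10 s chunk boundary forms one burstlet
directly; this is the same result as per-chunk detection followed by merging
of boundary-overlapping burstlets, and it additionally handles the edge case
where neither fragment alone reaches four spikes. Burstlets on one electrode
never overlap: the greedy left-to-right core construction assigns each spike
to at most one burstlet.

Global bursts are overlap-connected components of burstlet intervals
(closed-interval intersection) touching at least three distinct electrodes.
For the statistical stages, each electrode's spike train is reduced to a
binary burstlet train: 300 ms bins, 1 where at least four spikes fall in the
bin, final partial bin discarded.

## Activity metrics

The Fano factor is the variance-to-mean ratio of spike counts in
non-overlapping 100 ms windows anchored at zero; we use the sample variance
(n - 1), under which a homogeneous Poisson train calibrates to 1 at the
3000-window count of a 5-minute recording and a perfectly periodic train to
0. Zero-mean electrodes have an undefined Fano factor and are flagged and
excluded rather than forced to zero.

Synchrony of firing between two electrodes is the co-bursting count divided
by the larger of the two electrodes' burstlet counts. Co-bursting is counted
as the number of burstlets of the less-bursting electrode overlapping at
least one burstlet of the other; this convention bounds the ratio by 1 under
the stated denominator, which is why we chose it among the readings
consistent with the definition. Pairs are categorized at baseline (weak
0.1--0.4, medium 0.4--0.7, strong 0.7--1.0) and keep their baseline category
in longitudinal tracking; pairs below 0.1 are excluded to avoid inflated
percent changes.

Longitudinal tracking reports percent change against baseline only for
units valid at every timepoint and above per-metric floors: 0.2 Hz spike
rate, 0.02 Hz burstlet rate, 0.01 Hz global burst rate, 0.005 AU local
efficiency. Outliers are removed, rarely, by a median-absolute-deviation
filter (unscaled MAD; k = 2 for wet-lab summaries, k = 3 for normalized
simulation outputs); when the MAD is zero nothing is removed and a warning
is raised. Group contrasts use estimation statistics: a 500-iteration
bootstrap of the difference of group means, a 95% percentile interval, and a
p-value from the interval via a normal approximation
(`p = 2 * (1 - pnorm(|mean| / SE_boot))`).

## Functional connectivity and efficiency

Connectivity matrices are zero-lag Pearson correlations of binned spike
counts (10 ms bins in vitro, 1 ms in silico -- simulated activity is
burstier and less chattery), negatives clipped to zero, weights under 0.005
floored, diagonal zeroed. Zero lag is the declared default; a maximum-over-
lags variant is available but off. Graph efficiency uses lengths = 1/weight:
global efficiency is the mean inverse shortest-path length over node pairs,
and local efficiency is the cube-root weighted neighborhood form
\[
E_{loc}(u) = \frac{1}{k_u (k_u - 1)} \sum_{j \neq k \in N(u)}
  \bigl(w_{uj}\, w_{uk}\, d_{jk}(N_u)^{-1}\bigr)^{1/3},
\]
with `d` computed inside the neighborhood subgraph. Both are validated
against exhaustive path enumeration on small graphs.

## Sparse point-process Granger causality

Each electrode's binary burstlet train is modeled as Bernoulli draws whose
per-bin probability is a logistic function of a baseline plus the recent
history of every electrode (self-history included). The history depth defaults to
M = 3 bins (900 ms): three bins cover the burst-interaction timescales
while keeping 1 + 3C parameters tractable at C = 59; it is configurable. The log-likelihood is
accumulated overflow-safely.

Estimation is by generalized orthogonal matching pursuit: starting from the
baseline (which is never dropped), the covariate with the largest absolute
partial gradient enters, and the likelihood is re-maximized over the support
by damped Newton iterations (gradient tolerance 1e-8, at most 100 steps, a
1e-6 ridge guarding perfect separation). Support size is chosen by 5-fold
blocked cross-validation -- contiguous folds, respecting the time-series
structure -- maximizing held-out log-likelihood with ties resolved toward
the smaller support. The reduced model for a candidate source re-runs OMP on
the design without that source's columns at the full model's selected size;
if the greedy full fit ever lands below the reduced fit, the full model is
re-refined from the union of supports, so the deviance difference
`D = 2 [L(full) - L(reduced)]` is non-negative by construction.

Deviances are converted to p-values with a chi-square null whose degrees of
freedom equal the number of removed history covariates (M); a parametric
bootstrap from the fitted reduced model is available for calibration
checks. Exact characterizations of this deviance under greedy selection
exist but are substantially more involved; under OMP sparsity the chi-square route is conservative, and the
empirical false-discovery proportion on independent trains sits well below
the Benjamini--Hochberg level of 0.01 used across all C(C-1) ordered pairs.
Self-links are never tested; degenerate (all-zero/all-one) trains are
dropped with a warning.

## Higher-order synchrony

For C active electrodes (at least 30 burstlets each; quieter electrodes are
dropped for numerical tractability) every 300 ms bin carries one of the
2^C ensemble states. The saturated mark model assigns each state its
empirical frequency in closed form. To test order r, the reduced model fixes
the rate parameter of every r-order mark at its independence value -- the
sum of the member electrodes' marginal log-odds -- and re-maximizes the
rest, which is again closed-form: the fixed marks enter only through the sum
of their exponentiated rates, an elementary symmetric polynomial of the
marginal odds computed by the standard O(Cr) recurrence. Only observed
patterns are ever materialized, so no 2^C table exists even at C near 59.

Detection is one-sided on excess r-wise simultaneity: if the observed count
of r-order bins does not exceed its independence expectation the p-value is
1; otherwise the deviance difference is referred to a parametric Monte Carlo
null (independent Bernoulli trains at the plug-in marginals, 200 draws by
default). A per-order chi-square reference would need the number of
constrained cells -- binomial(C, r), mostly unobserved -- and is poorly
behaved in that sparse regime, which is why the Monte Carlo null is the
default. Orders r = 2..C are tested with Benjamini--Hochberg correction at
0.05 with BH across orders (the package's choice of level for this stage). For each significant order, detected
groups are the r-order patterns whose empirical count exceeds their
independence expectation; this attribution rule is one of several
defensible choices and is therefore configurable.

Spatial dispersion subtracts each group's centroid -- the arithmetic mean
of member positions -- and pools relative positions by order class (low 2--8, intermediate
9--15, high 16+). Classes and timepoints are compared by two-sample KS tests
on radial distances.

## Tokeshi's test of bimodality

Order-class frequency histograms are classified by Tokeshi's test: candidate
modes are the peaks among the lower and upper halves of the classes; under
uniform assignment of N samples to 1/h classes, the marginal binomial tails
P_l and P_r and the joint trinomial tail P_c are computed exactly. P_c is
implemented as the complete double tail over `i >= n_l, j >= n_r,
i + j <= N` -- the event the test describes -- and is checked against full
trinomial enumeration. The weaker peak can be rescued as locally significant
when t consecutive adjacent classes fall below it and
`rho(t) = (1 - max(P_l, P_r))^t < 0.1`. Classification follows the decision
table top-to-bottom (Uniform; Unimodal; Strongly bimodal; Bimodal; Weakly
bimodal, including the one-sided rho rows); combinations outside the table
(one tail moderate, the other large) default to Unimodal, since they show a
single departure from uniformity without a second local peak. The number of
order classes merged per bin before testing defaults to 3 and is
configurable; the test itself always receives explicit class counts, so this
choice is isolated from the inference.

## The simulated culture

The in silico model is the package's primary synthetic-data engine. Five
hundred neurons (440 excitatory, 60 inhibitory -- an 88/12 neuronal balance)
are placed uniformly in a square whose area matches a plating density of
3.5e3 cells/mm^2 (side ~378 um, computed from count/density at run time).
Connections are sampled per ordered pair from Gaussian distance kernels,
sigma = 150 um for excitatory and 100 um for inhibitory presynaptic neurons
(inhibition more local, following the spatial-connectivity scheme the model
family uses); the inhibitory amplitude is calibrated in closed form from the
realized kernel mass so that 65% of synapses have excitatory presynaptic
neurons in expectation. At most one synapse exists per ordered pair.
Excitatory-excitatory weights start at 8 AU, are plastic, and are clipped to
[0, 16]; all other weights are fixed at 1.

Membrane dynamics are conductance-based leaky integrate-and-fire with
exponential AMPA (tau 2 ms), NMDA (100 ms) and GABA (10 ms) conductances, an
after-hyperpolarization conductance (tau 2 s) incremented at each spike, a
per-neuron Gaussian tonic drive, and white-noise current, integrated by
Euler--Maruyama at 0.1 ms with threshold-reset spiking and a 2 ms refractory
period. The dynamics constants are package defaults, documented here -- C_m 200 pF, g_m 10 nS, V_L -70 mV, threshold -50 mV, reset
-65 mV, AMPA 2.5 nS/AU, GABA 3 nS, AHP increment 60 nS, drive 70 +/- 10 pA,
noise 12 pA sqrt(s) -- chosen once to produce near-silence punctuated by
recurring network-wide bursts at roughly 0.1/s in the control condition,
the regime these cultures show. Every constant is overridable, and the
isolated noise-free neuron reproduces the closed-form LIF period to a
fraction of a percent. Excitatory-excitatory synapses follow additive
pair-based STDP (A+ 0.05, A- 0.055, tau 20 ms) with hard weight bounds.

The perturbation schedule is settle 0--120 s, pre 120--240 s, two treatment
epochs, and post 480--600 s. Glutamate injury at 240 s silences 30% of
excitatory and 25% of inhibitory neurons (flagged dead with all their
synapses) and then deletes 75% of the surviving inhibitory synapses; the
compounding of endpoint loss and targeted deletion yields the ~86% net
inhibitory-synapse reduction the structural acceptance checks verify. BDNF
at 360 s revives floor(50%) = 7 of the silenced inhibitory neurons with
their pre-injury synapses, except synapses whose partner is still dead or
that were specifically deleted. Silenced neurons are removed from the
dynamics together with their synapses (rather than clamped), consistent
with deletion "along with all their synapses". Wiring, dynamics noise,
injury and revival draw from separate derived RNG streams, so conditions
sharing a seed have bit-identical dynamics through the pre epoch and each
perturbation is independently reproducible.

For analysis, the culture is partitioned into an 8 x 8 spatial grid and 5
reference cells are removed to match the 59 recording electrodes; which
five cells are references is a free choice; the default takes the four
corners plus a central cell (configurable).
Member neurons' spikes are merged, sorted, and deduplicated per electrode.
An uninjured network averages ~7.8 live neurons per electrode. Because
simulated effect sizes depend on the dynamics constants, the ordering of
post-epoch mean excitatory weights across conditions is treated as a
reported qualitative property only.

## Surrogates and what passing tests show

Calibration generators bypass the simulator: homogeneous Poisson and
periodic spike trains (Fano and connectivity limits), sequentially sampled
coupled Bernoulli trains from the generative logistic model (GC ground
truth), planted r-wise synchrony (independent background plus simultaneous
events on a fixed electrode set), and full 59-electrode toy sessions. They
operate at the burstlet-train level where the statistics do and at the
spike level where the signal pipeline does. Surrogates have exact known
structure; real MEA data add electrode noise, spike-sorting ambiguity,
nonstationarity across a recording, and refractory/latency structure that
none of these generators emulate, so passing calibration bounds the
method's behavior under its own assumptions rather than guaranteeing field
performance.

Problem sizes in the test-suite were chosen so the full statistical suite
runs in minutes on one CPU: GC null calibration uses C = 10, T = 1000 over
50 replicates; planted-edge recovery C = 5, T = 5000; synchrony power
r = 4, T = 2000 with ~80-draw Monte Carlo nulls; dynamics checks use
compressed 2 s epochs, which exercise the identical code path as the full
120 s schedule.

## Known limitations

Spike sorting and waveform clustering are out of scope: an electrode is the
unit of analysis. The GC null is an approximation under greedy model
selection (conservative in our calibrations). The marked point-process model
is static; history-dependent synchrony is not modeled. The dynamics
constants are package defaults, not published values, so simulated effect
sizes are qualitative. HDF5 session I/O is not provided; the documented
long-format CSV schema plus JSON sidecar is the interchange format, and the
acquisition vendors' proprietary formats require external conversion.
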