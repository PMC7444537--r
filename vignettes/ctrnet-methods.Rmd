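---
title: "ctrnet: model, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ctrnet: model, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Cortex is modular: activity generated in one local network must traverse
sparse, weak projections to reach the next. One proposed solution is to send
*pulse packets* -- volleys of near-synchronous spikes -- and to exploit the
*resonance* of the receiving excitatory-inhibitory (EI) module: an EI network
in the asynchronous-irregular regime, perturbed by a transient input, responds
with a damped population oscillation at its natural frequency. Periodic input
at that frequency is amplified over successive cycles (communication through
resonance), and a pair of bidirectionally coupled modules whose loop delay
(forward plus feedback transmission delay) matches the resonance period can
amplify even a single packet into a packet train that the remaining layers
relay.

`ctrnet` implements this full simulation study: the spiking network model,
the stimulus generators, the propagation statistics, and the parameter sweeps
that map where propagation succeeds.

## Neuron and synapse model

Neurons are conductance-based leaky integrate-and-fire units,

$$C_m \dot V = -G_{leak}\,[V - V_{rest}] - g_e(t)\,[V - E_{exc}]
  - g_i(t)\,[V - E_{inh}] + I_{ext},$$

with $C_m = 250$ pF, $G_{leak} = 16.67$ nS (15 ms membrane time constant),
threshold $-54$ mV, reset and resting potential $-70$ mV, and a 2 ms absolute
refractory period during which $V$ is clamped to the reset while the synaptic
conductances keep evolving. Each synaptic event contributes an alpha-function
conductance transient $(t/\tau)\,e^{-t/\tau}$ with $\tau = 1$ ms, scaled so
its **peak equals the synapse's peak conductance**; excitatory and inhibitory
events drive separate conductances with reversals $0$ and $-80$ mV. Initial
potentials are drawn from $\mathcal N(-70, 3^2)$ mV to avoid a start-up
synchrony artifact.

Integration is classical fixed-step 4th-order Runge-Kutta at $dt = 0.1$ ms on
the coupled voltage/conductance system, with spike detection at step
boundaries and delayed delivery through per-step ring buffers (the compiled
core in `src/sim.cpp`). Unit tests pin the integrator against closed forms:
the analytic alpha-PSP convolution (relative error $< 10^{-4}$), the
closed-form LIF firing period under constant current ($< 2\,dt$), and
step-halving stability of spike times.

### Coupling strengths: conductance vs amplitude semantics

Coupling strengths are stated as one number per connection class
(`J_ee = 0.33`, `J_ei = 1.5`, `J_ie = -6.2`, `J_ii = -12`, background
`J_pe = 0.25`, `J_pi = 0.4`, packet `J_pp = 0.33`). Two readings of such
numbers circulate for this model family: alpha-synapse **peak conductances in
nS** (the native weight unit of conductance-based simulators) or **PSP
amplitudes in mV** at a measurement potential ($-70$ mV for excitation,
$-54$ mV for inhibition). `ctrnet` implements both
(`synapse_params(units = "nS")`, the default, or `"mV"`); the amplitude
reading converts each value to a conductance with
`calibrate_peak_conductance()`, a root search against the package's own
single-neuron integrator.

The default is the nS reading because only it reproduces the study's stated
operating regime: with it, a default module sits in the asynchronous-irregular
state (excitatory rates ~6 spikes/s, population Fano factor below 2,
spectral entropy above 0.9, irregular intervals) and responds to a packet
with a damped oscillation in the low-gamma range, with the large-layer
variant resonating near 30 Hz; with the mV reading the same module fires at
~16 spikes/s with strong baseline synchrony and a much faster evoked
oscillation. The choice is a semantic reconstruction, made once, and both
paths are exported and tested.

## Network architecture

A layer is an EI module of 200 excitatory and 50 inhibitory neurons (large
variant: 2000/500), connected by independent Bernoulli draws with probability
0.2 over every ordered pair, no self-synapses, delay 1.5 ms. Ten layers form
a feedforward network (FFN): 70 randomly chosen excitatory "projecting"
neurons per layer each connect with probability 0.2 to the next layer's
excitatory neurons (mean forward in-degree 14) at the excitatory-to-excitatory
strength, delay `d_ff`. The resonance-pair network (RPN) adds feedback: 70
layer-2 excitatory neurons -- disjoint from layer 2's forward projectors --
connect with the same probability and strength to 70 randomly chosen layer-1
excitatory neurons, delay `d_fb`. Feedback records that would make a single
neuron pair bidirectional are re-targeted by rejection resampling, which
leaves the binomial in-degree marginals intact (verified over 1000 seeds).
Construction is deterministic given the spec seed, and an FFN and RPN sharing
a seed differ only by the feedback block, so topology contrasts are paired.

Optional Gaussian delay heterogeneity (`delay_cv`) perturbs every delay with
standard deviation `cv * base`, truncated at one integration step.

## Stimuli

*Background*: each excitatory neuron receives an aggregate 8000 spikes/s of
independent excitatory Poisson drive (6400 spikes/s for inhibitory neurons);
by the superposition property these are generated as one lumped Poisson
process per neuron through a single background synapse. When the excitatory
rate is swept, the inhibitory rate follows so their difference stays at
1600 spikes/s. *Pulse packets*: volleys of `alpha = 20` spikes drawn i.i.d.
from $\mathcal N(t_{center}, \sigma^2)$, $\sigma = 2$ ms, each spike
delivered to **every** layer-1 projecting neuron (a shared population
stimulus; with the alternative one-spike-per-neuron reading no neuron could
respond at these weak weights). *Trains*: packet centers on a periodic grid
(default 25 ms) with optional uniform jitter on $(-j, +j)$; packet times
falling before time zero are discarded.

## Statistics

All statistics operate on spike-count vectors in half-open bins (default
5 ms):

- **Pairwise correlation**: Pearson coefficients between per-neuron count
  vectors, averaged over within-layer pairs; zero-variance rows are excluded
  and counted.
- **Population Fano factor (pFF)**: variance/mean of the layer-summed count
  vector; ~1 in the asynchronous-irregular state, large under population
  synchrony.
- **Spectrum, network frequency, spectral entropy**: Fourier power of the
  mean-subtracted count vector (rectangular window); the network frequency is
  the spectral argmax restricted to 5-100 Hz (clear of the DC-adjacent
  bins); the spectral entropy is the Shannon entropy of the unit-normalized
  power, divided by $\log_2$ of the number of frequency points -- 0 for a
  pure oscillation, 1 for white noise.
- **SNR**: variance of a layer's summed excitatory counts in the stimulation
  window divided by the variance in an ongoing window before the stimulus.
  The windows are not fixed by the phenomenon itself, so they are explicit
  parameters with these defaults: ongoing = 1000 ms ending 100 ms before
  injection; stimulation = 300 ms from injection for a single packet and the
  full train span for a train (a 300 ms window would end before a slowly
  building train response appears). SNR $\ge 4$ is used throughout as the
  success threshold for propagation.
- **Oscillation duration**: the layer's 1 ms population rate is band-passed
  at 20-60 Hz (2nd-order Butterworth, zero-phase), peak-to-trough amplitudes
  are measured in consecutive cycles of the resonance period from the
  injection time, and cycles are counted while the amplitude exceeds the
  99th percentile of per-cycle amplitudes during ongoing activity. Pure
  noise yields 0 by construction; a synthetic damped cosine with known
  envelope recovers its analytic cycle count.
- **Propagation latency**: first bin (center reported) in which the layer's
  summed count exceeds the ongoing mean plus 5 standard deviations; `NA`
  when no crossing occurs.
- **CV of inter-spike intervals, firing rates**: per neuron; neurons with
  fewer than two intervals are excluded and counted.

Each formula-defined statistic is tested against a brute-force evaluation of
its defining expression to machine precision, plus analytic limit cases
(anti-phase correlation $-1$, Parseval's identity, entropy 0/1 endpoints,
all-or-none burst Fano factor, dead-time-process CV).

## Experiments

`run_scenario()` assembles one condition (topology x stimulus) and returns
spikes, traces and window metadata; `trial_snr()` averages the layer-10 SNR
over independently re-drawn networks and noise. On top of these sit the
sweeps: equal-delay and fixed-forward delay/strength grids
(`sweep_delay_strength()`), the independent forward x feedback delay grid
(`sweep_ff_fb()`), background-regime maps of pFF over strength x rate and
delay x strength (`sweep_background_rates()`, `sweep_background_delays()`),
two-layer resonance-condition maps (`sweep_resonance_conditions()`),
threshold and speed comparisons (`threshold_curves()`,
`speed_comparison()`), jittered-train and heterogeneous-delay robustness
(`sweep_train_jitter()`, `run_delay_cv()`), the large-network variant
(`large_network_snr()`), and the evoked-oscillation duration distribution
(`duration_distribution()`). Every sweep derives per-grid-point, per-trial
seeds deterministically from one base seed (`derive_seed()`), so any cell of
any result table can be regenerated in isolation.

The evoked resonance frequency of an isolated module
(`module_resonance_frequency()`) averages injection-aligned count vectors
across trials *before* taking the spectrum: the phase-locked damped
oscillation survives the average while asynchronous background activity is
suppressed by $1/\sqrt{n}$. Single-trial spectra of a one-or-two-cycle
transient are dominated by background power and their argmax is unstable.

## Problem sizes

Default problem sizes were chosen once for desk-scale runs: 10 trials for
SNR-level estimates, 50 trials for the duration median (the distribution is
broad), 40 injection-aligned trials for the module resonance spectrum,
5-point delay grids with 6-10 trials per point, and ~1.6 s of simulated time
per propagation trial (1.25 s of settling and ongoing baseline before
injection). Background-regime maps default to a few seconds per cell rather
than the 20 s used for publication-grade correlation estimates; the
correlation and pFF tests use 8 s windows.

## What reproduces and what does not

Two headline aspects of the study reproduce robustly under the faithful
default configuration:

- the **baseline regime**: every layer in the asynchronous-irregular state
  (pFF < 2, near-zero pairwise correlations, high spectral entropy,
  CV$_{ISI}$ broad around ~0.8, excitatory rates of a few spikes/s), stable
  over the whole simulated range; and
- the **module resonance**: a packet evokes a damped population oscillation
  in the low-gamma band, slower in the large-layer variant, with the loop
  statistics (SNR, entropy, frequency) behaving consistently.

The headline **propagation** phenomena do not reproduce at the default
coupling: volleys attenuate from layer to layer (the per-hop gain of a
70-projector volley is well below 1), so single packets die in the FFN (as
stated) but also fail to be amplified by the resonance pair, and periodic
trains entrain layer 2 (~3x phase modulation of its spiking, growing
mean-potential oscillation) without recruiting deeper layers. An independent
dense-matrix reference implementation of one module reproduces the compiled
core's rates and packet response, so this is a property of the model
configuration as specified here, not of the integrator. Reproducing the
propagation results would require roughly 2-3x stronger coincident-volley
efficacy than the default connectivity and strengths provide; the package
exposes every relevant dial (`J_ff`, `eps_fb`, `J_fb`, layer sizes, rates) so
this gap can be explored, but the defaults are not tuned away from the stated
values. The acceptance suite reports the propagation-dependent quantities
honestly from the default configuration and they fall short of the published
levels; tests assert them at their stated tolerances and fail where the model
falls short.

## Known limitations

- The generator emulates stationary background and isolated packet programs;
  it does not model distance-dependent connectivity, synaptic plasticity,
  inhomogeneous backgrounds, or information content of packets.
- Spike times are quantized to the integration step (no within-step
  threshold interpolation); the step-halving test bounds the effect.
- SNR windows, spectral windows and the oscillation-duration threshold are
  operational choices exposed as parameters; published values of
  window-dependent quantities can only be compared against the window
  conventions documented above.
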