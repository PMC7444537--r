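#' Leaky integrate-and-fire neuron parameters
#'
#' Membrane parameters of the conductance-based LIF neuron. The defaults are
#' the values used throughout the study: a 250 pF membrane with 16.67 nS leak
#' (15 ms membrane time constant), firing threshold -54 mV and reset -70 mV.
#' The leak reversal equals the reset potential, so -70 mV is also the resting
#' potential of an unstimulated neuron.
#'
#' @param C_m membrane capacitance (pF)
#' @param G_leak leak conductance (nS)
#' @param V_th spike threshold (mV)
#' @param V_reset reset (and leak reversal) potential (mV)
#' @param tau_ref absolute refractory period (ms)
#' @return an object of class `neuron_params`
#' @export
#' @examples
#' neuron_params()
neuron_params <- function(C_m = 250, G_leak = 16.67, V_th = -54,
                          V_reset = -70, tau_ref = 2) {
  stopifnot(C_m > 0, G_leak > 0, tau_ref > 0)
  if (!(V_reset < V_th)) stop("V_reset must be below V_th", call. = FALSE)
  structure(list(C_m = C_m, G_leak = G_leak, V_th = V_th,
                 V_reset = V_reset, tau_ref = tau_ref),
            class = "neuron_params")
}

#' Synapse parameters
#'
#' Alpha-conductance synapse parameters and the coupling strengths of every
#' connection class. By default (`units = "nS"`) the `J` values are the peak
#' conductances of the alpha conductance transient, the convention under
#' which the default numbers place each module in the asynchronous-irregular
#' state with a 40 Hz resonance. With `units = "mV"` the `J` values are read
#' as postsynaptic-potential amplitudes at the stated measurement potential
#' (excitatory at -70 mV, inhibitory at -54 mV) and converted to peak
#' conductances by [calibrate_peak_conductance()].
#'
#' @param tau_exc,tau_inh rise time of excitatory/inhibitory conductance (ms)
#' @param E_exc,E_inh synaptic reversal potentials (mV)
#' @param J_ee,J_ei excitatory strengths onto E and I neurons (>= 0)
#' @param J_ie,J_ii inhibitory strengths onto E and I neurons (<= 0; the
#'   magnitude is the peak conductance when `units = "nS"`)
#' @param J_pe,J_pi strength of one background (Poisson) input event onto E
#'   and I neurons
#' @param J_pp strength of one pulse-packet spike onto a layer-1 projecting
#'   neuron
#' @param V_meas_exc,V_meas_inh measurement potentials used when
#'   `units = "mV"` (mV)
#' @param d_within within-layer transmission delay (ms)
#' @param units `"nS"` (peak conductances) or `"mV"` (PSP amplitudes)
#' @return an object of class `synapse_params`
#' @export
#' @examples
#' synapse_params()
#' # large-network variant
#' synapse_params(J_ee = 0.25, J_pp = 0.25)
synapse_params <- function(tau_exc = 1, tau_inh = 1, E_exc = 0, E_inh = -80,
                           J_ee = 0.33, J_ei = 1.5, J_ie = -6.2, J_ii = -12,
                           J_pe = 0.25, J_pi = 0.4, J_pp = 0.33,
                           V_meas_exc = -70, V_meas_inh = -54,
                           d_within = 1.5, units = c("nS", "mV")) {
  units <- match.arg(units)
  stopifnot(tau_exc > 0, tau_inh > 0, d_within > 0)
  if (any(c(J_ee, J_ei, J_pe, J_pi, J_pp) < 0))
    stop("excitatory strengths must be >= 0", call. = FALSE)
  if (any(c(J_ie, J_ii) > 0))
    stop("inhibitory strengths must be <= 0", call. = FALSE)
  structure(list(tau_exc = tau_exc, tau_inh = tau_inh,
                 E_exc = E_exc, E_inh = E_inh,
                 J_ee = J_ee, J_ei = J_ei, J_ie = J_ie, J_ii = J_ii,
                 J_pe = J_pe, J_pi = J_pi, J_pp = J_pp,
                 V_meas_exc = V_meas_exc, V_meas_inh = V_meas_inh,
                 d_within = d_within, units = units),
            class = "synapse_params")
}

#' Layer composition
#'
#' Size and internal connectivity of one excitatory-inhibitory module
#' ("layer"): `N_exc` excitatory and `N_inh` inhibitory neurons, of which
#' `N_proj` excitatory neurons project to the next layer, with a uniform
#' within-layer connection probability.
#'
#' @param N_exc,N_inh,N_proj population sizes (counts)
#' @param eps_within within-layer connection probability
#' @return an object of class `layer_spec`
#' @export
#' @examples
#' layer_spec()                      # 200 E + 50 I, 70 projecting
#' layer_spec(2000, 500, 680)        # large-network variant
layer_spec <- function(N_exc = 200, N_inh = 50, N_proj = 70,
                       eps_within = 0.2) {
  stopifnot(N_exc >= 1, N_inh >= 0)
  if (N_proj > N_exc) stop("N_proj must not exceed N_exc", call. = FALSE)
  if (eps_within < 0 || eps_within > 1)
    stop("eps_within must lie in [0, 1]", call. = FALSE)
  structure(list(N_exc = as.integer(N_exc), N_inh = as.integer(N_inh),
                 N_proj = as.integer(N_proj), eps_within = eps_within),
            class = "layer_spec")
}

#' Network specification
#'
#' Declarative description of a layered modular network. `topology = "FFN"`
#' couples consecutive layers only by forward projections; `topology = "RPN"`
#' additionally adds sparse excitatory feedback from layer 2 to layer 1 (the
#' "resonance pair"). Feedback probability and strength default to the forward
#' values but can be set independently (used when mapping the conditions for
#' resonance).
#'
#' @param n_layers number of layers
#' @param layer a [layer_spec()]
#' @param eps_inter inter-layer (forward) connection probability
#' @param topology `"FFN"` or `"RPN"`
#' @param d_ff forward inter-layer delay (ms)
#' @param d_fb feedback delay, layer 2 to layer 1 (ms; required for RPN)
#' @param J_ff forward (and, by default, feedback) inter-layer PSP amplitude
#'   (mV); `NULL` uses the within-layer `J_ee`
#' @param eps_fb feedback connection probability; `NULL` uses `eps_inter`
#' @param J_fb feedback PSP amplitude (mV); `NULL` uses `J_ff`
#' @param delay_cv fractional standard deviation of Gaussian delay
#'   heterogeneity applied to all within- and inter-layer delays (0 = fixed
#'   delays)
#' @param seed integer seed for the stochastic construction
#' @return an object of class `network_spec`
#' @export
#' @examples
#' network_spec(topology = "FFN", d_ff = 12.5)
#' network_spec(topology = "RPN", d_ff = 12.5, d_fb = 12.5)
network_spec <- function(n_layers = 10, layer = layer_spec(),
                         eps_inter = 0.2,
                         topology = c("FFN", "RPN"),
                         d_ff = 12.5, d_fb = NULL,
                         J_ff = NULL, eps_fb = NULL, J_fb = NULL,
                         delay_cv = 0, seed = 1) {
  topology <- match.arg(topology)
  stopifnot(n_layers >= 1, eps_inter >= 0, eps_inter <= 1,
            d_ff > 0, delay_cv >= 0)
  if (!inherits(layer, "layer_spec")) stop("layer must be a layer_spec", call. = FALSE)
  if (topology == "RPN") {
    if (is.null(d_fb)) stop("d_fb must be given for an RPN", call. = FALSE)
    stopifnot(d_fb > 0)
    if (n_layers < 2) stop("an RPN needs at least 2 layers", call. = FALSE)
  }
  if (!is.null(eps_fb) && (eps_fb < 0 || eps_fb > 1))
    stop("eps_fb must lie in [0, 1]", call. = FALSE)
  structure(list(n_layers = as.integer(n_layers), layer = layer,
                 eps_inter = eps_inter, topology = topology,
                 d_ff = d_ff, d_fb = d_fb,
                 J_ff = J_ff, eps_fb = eps_fb, J_fb = J_fb,
                 delay_cv = delay_cv, seed = as.integer(seed)),
            class = "network_spec")
}

#' Large-network layer and spec presets
#'
#' Convenience constructors for the up-scaled network variant: layers of
#' 2000 E + 500 I neurons with 680 projecting neurons, inter-layer
#' probability 0.1, and weakened recurrent excitation (`J_ee` = `J_pp` =
#' 0.25 mV), for which the module resonance sits near 33 Hz.
#'
#' @param topology,d_ff,d_fb,seed,... passed to [network_spec()]
#' @return a `network_spec` (or, for `large_synapse_params()`, a
#'   `synapse_params`)
#' @export
large_network_spec <- function(topology = "RPN", d_ff = 15, d_fb = 15,
                               seed = 1, ...) {
  network_spec(n_layers = 10, layer = layer_spec(2000, 500, 680, 0.2),
               eps_inter = 0.1, topology = topology,
               d_ff = d_ff, d_fb = if (topology == "RPN") d_fb else NULL,
               seed = seed, ...)
}

#' @rdname large_network_spec
#' @export
large_synapse_params <- function() synapse_params(J_ee = 0.25, J_pp = 0.25)

#' Simulation configuration
#'
#' @param dt integration step (ms)
#' @param duration simulated time (ms)
#' @param seed integer seed covering initial conditions, background noise and
#'   stimulus realization
#' @param v_init_mean,v_init_sd mean and sd (mV) of the Gaussian initial
#'   membrane potentials (dispersed to avoid a start-up synchrony transient)
#' @param record_vm record membrane potentials?
#' @param record_ids 0-based global neuron ids to record (`NULL` = all)
#' @param vm_decimation record every `vm_decimation`-th step
#' @return an object of class `sim_config`
#' @export
sim_config <- function(duration, dt = 0.1, seed = 1,
                       v_init_mean = -70, v_init_sd = 3,
                       record_vm = FALSE, record_ids = NULL,
                       vm_decimation = 10L) {
  stopifnot(dt > 0, duration >= 0, v_init_sd >= 0, vm_decimation >= 1)
  structure(list(duration = duration, dt = dt, seed = as.integer(seed),
                 v_init_mean = v_init_mean, v_init_sd = v_init_sd,
                 record_vm = isTRUE(record_vm), record_ids = record_ids,
                 vm_decimation = as.integer(vm_decimation)),
            class = "sim_config")
}
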