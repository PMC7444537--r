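# Synaptic strengths are specified as PSP amplitudes (mV) at a measurement
# potential; the simulator needs peak conductances (nS). The mapping depends
# on the driving force and membrane filtering, so it is obtained numerically
# with the same integrator that runs the network.

.calib_cache <- new.env(parent = emptyenv())

# Peak PSP deflection (mV) of a single neuron resting at v_meas receiving one
# synaptic event of peak conductance g toward `reversal`. The leak reversal is
# set to v_meas so the deflection is purely synaptic.
psp_peak <- function(g, reversal, v_meas, tau, neuron, dt = 0.1, t_max = 80) {
  n_steps <- as.integer(ceiling(t_max / dt))
  out <- sim_core(v_init = v_meas,
                  c_m = neuron$C_m, g_leak = neuron$G_leak, e_leak = v_meas,
                  v_th = 1e6, v_reset = v_meas, tau_ref = neuron$tau_ref,
                  e_exc = reversal, e_inh = -80, tau_exc = tau, tau_inh = tau,
                  syn_ptr = c(0L, 0L), syn_post = integer(0),
                  syn_g = numeric(0), syn_inh = integer(0),
                  syn_dstep = integer(0),
                  bg_lambda = 0, bg_g = 0,
                  ext_step = 5L, ext_target = 0L, ext_g = g,
                  i_ext = 0,
                  dt = dt, n_steps = n_steps,
                  record_idx = 0L, record_every = 1L)
  max(abs(out$vm[, 1] - v_meas))
}

#' Calibrate the peak conductance that yields a given PSP amplitude
#'
#' Finds the alpha-synapse peak conductance (nS) for which a single synaptic
#' event, delivered to an otherwise unperturbed neuron resting at the
#' measurement potential `V_meas`, produces a postsynaptic potential whose
#' peak deflection equals `J` (mV). The root is found against the package's
#' own single-neuron integrator and is accurate to 0.1% relative tolerance.
#' Results are cached per parameter tuple.
#'
#' @param J PSP amplitude (mV); sign must agree with `reversal - V_meas`
#' @param reversal synaptic reversal potential (mV)
#' @param V_meas membrane potential at which the amplitude is measured (mV)
#' @param tau synaptic rise time (ms)
#' @param neuron a [neuron_params()]
#' @return peak conductance (nS, non-negative scalar)
#' @export
#' @examples
#' calibrate_peak_conductance(0.33, 0, -70, 1, neuron_params())
calibrate_peak_conductance <- function(J, reversal, V_meas, tau,
                                       neuron = neuron_params()) {
  if (J == 0) return(0)
  df <- reversal - V_meas
  if (sign(J) != sign(df))
    stop("sign of J inconsistent with driving force reversal - V_meas",
         call. = FALSE)
  key <- paste(J, reversal, V_meas, tau, neuron$C_m, neuron$G_leak, sep = "|")
  hit <- .calib_cache[[key]]
  if (!is.null(hit)) return(hit)

  target <- abs(J)
  # charge-based linear estimate: deflection ~ g * e * tau * |df| / C_m
  g0 <- target * neuron$C_m / (exp(1) * tau * abs(df))
  lo <- 0
  hi <- 2 * g0
  it <- 0
  while (psp_peak(hi, reversal, V_meas, tau, neuron) < target) {
    hi <- hi * 2
    it <- it + 1
    if (it > 60) stop("peak-conductance calibration failed to bracket the root",
                      call. = FALSE)
  }
  root <- stats::uniroot(function(g)
    psp_peak(g, reversal, V_meas, tau, neuron) - target,
    lower = lo, upper = hi, tol = g0 * 1e-4)$root
  .calib_cache[[key]] <- root
  root
}

# Peak conductances for every connection class of a (neuron, synapse) pair.
# With units = "nS" the strengths already are peak conductances; with "mV"
# they are PSP amplitudes converted through the calibration.
class_conductances <- function(neuron, synapse, J_ff = NULL, J_fb = NULL) {
  if (is.null(J_ff)) J_ff <- synapse$J_ee
  if (is.null(J_fb)) J_fb <- J_ff
  if (identical(synapse$units, "mV")) {
    cal_e <- function(J) calibrate_peak_conductance(J, synapse$E_exc,
                                                    synapse$V_meas_exc,
                                                    synapse$tau_exc, neuron)
    cal_i <- function(J) calibrate_peak_conductance(J, synapse$E_inh,
                                                    synapse$V_meas_inh,
                                                    synapse$tau_inh, neuron)
  } else {
    cal_e <- abs
    cal_i <- abs
  }
  list(g_ee = cal_e(synapse$J_ee), g_ei = cal_e(synapse$J_ei),
       g_ie = cal_i(synapse$J_ie), g_ii = cal_i(synapse$J_ii),
       g_pe = cal_e(synapse$J_pe), g_pi = cal_e(synapse$J_pi),
       g_pp = cal_e(synapse$J_pp),
       g_ff = cal_e(J_ff), g_fb = cal_e(J_fb))
}
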