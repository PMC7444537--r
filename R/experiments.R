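# Experiment drivers: scenario runner, parameter sweeps, and the derived
# comparisons (threshold, speed, robustness). Every sweep is reproducible
# from its base seed; per-trial and per-grid-point seeds are derived
# deterministically.

#' Deterministic seed derivation
#'
#' Folds a base seed and any number of integer indices into a new seed in
#' `[1, 2^31 - 2]`, so that sweeps assign distinct, reproducible seeds to
#' every grid point and trial.
#'
#' @param base base seed
#' @param ... integer indices (grid point, trial, stage, ...)
#' @return an integer seed
#' @export
derive_seed <- function(base, ...) {
  x <- as.double(base) %% 2147483647
  for (k in c(...)) {
    x <- (x * 69069 + as.double(k) * 1234567 + 1) %% 2147483647
  }
  as.integer(x) + 1L
}

#' Run one simulation scenario
#'
#' Builds a network and stimulus program for one of the study's standard
#' conditions and simulates it. Stimuli: `"packet"` (a single pulse packet at
#' `t_inject`), `"train"` (a periodic, optionally jittered packet train
#' starting at `t_inject`), or `"none"` (background only). The stimulation
#' window used for SNR is 300 ms for a single packet and the full train span
#' for a train; it is returned as `stim_len`.
#'
#' @param topology `"FFN"` or `"RPN"`
#' @param stimulus `"packet"`, `"train"`, or `"none"`
#' @param seed base seed for this trial (network construction, stimulus
#'   realization and noise derive from it)
#' @param d_ff,d_fb,J_ff,eps_fb,J_fb,delay_cv,n_layers,eps_inter see
#'   [network_spec()]
#' @param layer_def a [layer_spec()] giving the layer composition
#' @param neuron,synapse parameter sets
#' @param background a [background_spec()]
#' @param alpha,sigma packet strength and dispersion
#' @param n_pulses,interval,jitter train parameters
#' @param t_inject injection time of the (first) packet (ms)
#' @param post_len simulated time after the stimulation window (ms)
#' @param duration total simulated time (ms); `NULL` derives it from
#'   `t_inject`, the stimulation span and `post_len`
#' @param record_vm record membrane potentials?
#' @param dt integration step (ms)
#' @return list with `spikes`, `traces`, `network`, `t_inject`, `stim_len`,
#'   and the packet centers
#' @export
#' @examples
#' \donttest{
#' run <- run_scenario("RPN", "packet", seed = 1, d_ff = 12.5, d_fb = 12.5)
#' snr(run$spikes, layer = 10, t_inject = run$t_inject,
#'     stim_len = run$stim_len)
#' }
run_scenario <- function(topology = c("FFN", "RPN"),
                         stimulus = c("packet", "train", "none"),
                         seed = 1,
                         d_ff = 12.5, d_fb = 12.5, J_ff = NULL,
                         eps_fb = NULL, J_fb = NULL, delay_cv = 0,
                         n_layers = 10, eps_inter = 0.2,
                         layer_def = layer_spec(),
                         neuron = neuron_params(), synapse = synapse_params(),
                         background = background_spec(),
                         alpha = 20, sigma = 2,
                         n_pulses = 20, interval = 25, jitter = 0,
                         t_inject = 1250, post_len = 50, duration = NULL,
                         record_vm = FALSE, dt = 0.1) {
  topology <- match.arg(topology)
  stimulus <- match.arg(stimulus)

  spec <- network_spec(n_layers = n_layers, layer = layer_def,
                       eps_inter = eps_inter, topology = topology,
                       d_ff = d_ff,
                       d_fb = if (topology == "RPN") d_fb else NULL,
                       J_ff = J_ff, eps_fb = eps_fb, J_fb = J_fb,
                       delay_cv = delay_cv, seed = derive_seed(seed, 1))
  network <- build_network(spec, neuron, synapse)

  centers <- switch(stimulus,
    packet = t_inject,
    train = make_train(n_pulses, interval, jitter, t_first = t_inject,
                       seed = derive_seed(seed, 2)),
    none = numeric(0))
  packets <- lapply(centers, pulse_packet_spec, alpha = alpha, sigma = sigma)
  program <- stimulus_program(network, background = background,
                              packets = packets)

  stim_len <- switch(stimulus,
    packet = 300,
    train = n_pulses * interval,
    none = 0)
  if (is.null(duration)) duration <- t_inject + stim_len + post_len
  config <- sim_config(duration = duration, dt = dt,
                       seed = derive_seed(seed, 3),
                       record_vm = record_vm)
  run <- simulate_network(network, program, config)
  list(spikes = run$spikes, traces = run$traces, network = network,
       t_inject = t_inject, stim_len = stim_len,
       packet_centers = centers)
}

# layer-10 (or other layer) SNR of one scenario run
scenario_snr <- function(run, layer = 10, ...) {
  snr(run$spikes, layer = layer, t_inject = run$t_inject,
      stim_len = run$stim_len, ...)
}

#' Trial-averaged SNR of a scenario
#'
#' Repeats [run_scenario()] with derived per-trial seeds and averages the
#' SNR of `layer`.
#'
#' @param n_trials number of independent trials (network and noise both
#'   re-drawn)
#' @param seed base seed
#' @param layer measured layer
#' @param ... passed to [run_scenario()]
#' @return list with `mean`, `sd`, and the per-trial `values`
#' @export
trial_snr <- function(n_trials, seed, layer = 10, ...) {
  vals <- vapply(seq_len(n_trials), function(k) {
    run <- run_scenario(seed = derive_seed(seed, 100, k), ...)
    scenario_snr(run, layer = layer)
  }, 0)
  list(mean = mean(vals), sd = stats::sd(vals), values = vals)
}

#' The four standard propagation scenarios
#'
#' Runs the study's headline comparison: (1) FFN with a single packet
#' (propagation fails), (2) FFN with a 25 ms periodic train (slow,
#' resonance-based propagation), (3) RPN with a single packet and equal
#' 12.5 ms forward/feedback delays (fast propagation), (4) as (3) with extra
#' Poisson drive to the inhibitory populations (shortened oscillations).
#'
#' @param n_trials trials per scenario
#' @param seed base seed
#' @param layers layers at which SNR is reported
#' @param rate_inh_extra extra inhibitory-population input rate for scenario
#'   4 (spikes/s; the study does not print its value)
#' @param ... passed to [run_scenario()]
#' @return data frame with scenario, layer, SNR mean/sd
#' @export
run_scenarios_fig2 <- function(n_trials = 10, seed = 1, layers = c(1, 10),
                               rate_inh_extra = 800, ...) {
  cases <- list(
    ffn_packet = list(topology = "FFN", stimulus = "packet"),
    ffn_train = list(topology = "FFN", stimulus = "train"),
    rpn_packet = list(topology = "RPN", stimulus = "packet"),
    rpn_packet_inh = list(topology = "RPN", stimulus = "packet",
                          background = background_spec(rate_inh_extra = rate_inh_extra)))
  out <- list()
  for (nm in names(cases)) {
    runs <- lapply(seq_len(n_trials), function(k) {
      do.call(run_scenario, c(cases[[nm]],
                              list(seed = derive_seed(seed, match(nm, names(cases)), k)),
                              list(...)))
    })
    for (l in layers) {
      v <- vapply(runs, scenario_snr, 0, layer = l)
      out[[length(out) + 1L]] <- data.frame(
        scenario = nm, layer = l, snr_mean = mean(v), snr_sd = stats::sd(v),
        n_trials = n_trials)
    }
  }
  do.call(rbind, out)
}

#' Delay/strength sweep of the resonance pair
#'
#' Layer-10 SNR of the RPN after a single packet, over a grid of inter-layer
#' delays and forward/feedback strengths. In `"equal"` mode the forward and
#' feedback delays are both set to the swept delay (loop delay = 2 x delay);
#' in `"fixed-ff"` mode the forward delay is fixed (5 ms) and the feedback
#' delay is swept.
#'
#' @param delays delay grid (ms)
#' @param strengths inter-layer PSP amplitudes `J_ff` (mV); default: the
#'   within-layer `J_ee` only
#' @param mode `"equal"` or `"fixed-ff"`
#' @param d_ff_fixed forward delay in `"fixed-ff"` mode (ms)
#' @param n_trials trials per grid point
#' @param seed base seed
#' @param layer measured layer
#' @param ... passed to [run_scenario()]
#' @return data frame over the grid with `snr_mean`, `snr_sd`
#' @export
sweep_delay_strength <- function(delays, strengths = NULL,
                                 mode = c("equal", "fixed-ff"),
                                 d_ff_fixed = 5, n_trials = 10, seed = 1,
                                 layer = 10, ...) {
  mode <- match.arg(mode)
  if (is.null(strengths)) strengths <- synapse_params()$J_ee
  grid <- expand.grid(delay = delays, J_ff = strengths)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    d <- grid$delay[i]; J <- grid$J_ff[i]
    s <- trial_snr(n_trials, derive_seed(seed, 10, i), layer = layer,
                   topology = "RPN", stimulus = "packet",
                   d_ff = if (mode == "equal") d else d_ff_fixed,
                   d_fb = d, J_ff = J, ...)
    data.frame(delay = d, J_ff = J, snr_mean = s$mean, snr_sd = s$sd,
               n_trials = n_trials)
  })
  out <- do.call(rbind, rows)
  attr(out, "mode") <- mode
  out
}

#' Independent forward/feedback delay sweep
#'
#' Layer-10 SNR of the RPN after a single packet over the
#' (`d_ff`, `d_fb`) grid at fixed default strength; propagation is expected
#' along the ridge where the loop delay `d_ff + d_fb` matches the module
#' resonance period.
#'
#' @param d_ff_grid,d_fb_grid delay grids (ms)
#' @inheritParams sweep_delay_strength
#' @return data frame over the grid
#' @export
sweep_ff_fb <- function(d_ff_grid, d_fb_grid, n_trials = 10, seed = 1,
                        layer = 10, ...) {
  grid <- expand.grid(d_ff = d_ff_grid, d_fb = d_fb_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- trial_snr(n_trials, derive_seed(seed, 20, i), layer = layer,
                   topology = "RPN", stimulus = "packet",
                   d_ff = grid$d_ff[i], d_fb = grid$d_fb[i], ...)
    data.frame(d_ff = grid$d_ff[i], d_fb = grid$d_fb[i],
               snr_mean = s$mean, snr_sd = s$sd, n_trials = n_trials)
  })
  do.call(rbind, rows)
}

#' Propagation threshold and speed comparison
#'
#' `threshold_curves()` measures layer-10 SNR as a function of packet
#' strength `alpha` for the RPN (single packet) and the FFN (periodic train),
#' both with 5 ms forward delays and the RPN feedback delay completing the
#' resonance loop (20 ms). `speed_comparison()` measures the mean layer-10
#' propagation latency of the two networks under the same matched conditions
#' and reports the FFN/RPN latency ratio.
#'
#' @param alphas packet strengths
#' @inheritParams sweep_delay_strength
#' @param interval train interval for the FFN (ms)
#' @return `threshold_curves()`: data frame (topology, alpha, snr);
#'   `speed_comparison()`: list with per-trial latencies, means and `ratio`
#' @export
threshold_curves <- function(alphas, n_trials = 10, seed = 1, layer = 10,
                             interval = 25, ...) {
  rows <- list()
  for (i in seq_along(alphas)) {
    a <- alphas[i]
    rpn <- trial_snr(n_trials, derive_seed(seed, 30, i), layer = layer,
                     topology = "RPN", stimulus = "packet",
                     d_ff = 5, d_fb = 20, alpha = a, ...)
    ffn <- trial_snr(n_trials, derive_seed(seed, 31, i), layer = layer,
                     topology = "FFN", stimulus = "train",
                     d_ff = 5, alpha = a, interval = interval, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      topology = c("RPN", "FFN"), alpha = a,
      snr_mean = c(rpn$mean, ffn$mean), snr_sd = c(rpn$sd, ffn$sd))
  }
  do.call(rbind, rows)
}

#' @rdname threshold_curves
#' @export
speed_comparison <- function(n_trials = 10, seed = 1, layer = 10,
                             interval = 25, ...) {
  lat <- function(topology, stimulus, k, ...) {
    run <- run_scenario(topology = topology, stimulus = stimulus,
                        seed = derive_seed(seed, 40, k),
                        d_ff = 5,
                        d_fb = if (topology == "RPN") 20 else 12.5, ...)
    propagation_latency(run$spikes, layer = layer, t_inject = run$t_inject)
  }
  lat_ffn <- vapply(seq_len(n_trials), function(k)
    lat("FFN", "train", k, interval = interval, ...), 0)
  lat_rpn <- vapply(seq_len(n_trials), function(k)
    lat("RPN", "packet", k, post_len = 400, ...), 0)
  list(latency_ffn = lat_ffn, latency_rpn = lat_rpn,
       mean_ffn = mean(lat_ffn, na.rm = TRUE),
       mean_rpn = mean(lat_rpn, na.rm = TRUE),
       ratio = mean(lat_ffn, na.rm = TRUE) / mean(lat_rpn, na.rm = TRUE))
}

#' Background-activity regime sweeps
#'
#' Population Fano factor of the layer-10 excitatory population under
#' background drive only (no packets). `sweep_background_rates()` varies the
#' inter-layer strength and the excitatory input rate (the inhibitory rate
#' follows, keeping the 1600 spikes/s difference); `sweep_background_delays()`
#' varies the inter-layer delay and strength at a fixed 8 kHz input rate.
#'
#' @param J_grid inter-layer strengths (mV)
#' @param rate_grid excitatory input rates (spikes/s)
#' @param delay_grid inter-layer delays (ms)
#' @param topology `"RPN"` or `"FFN"`
#' @param duration simulated time per trial (ms)
#' @param t_skip initial transient excluded from the analysis (ms)
#' @inheritParams sweep_delay_strength
#' @return data frame over the grid with `pFF` mean/sd
#' @export
sweep_background_rates <- function(J_grid, rate_grid, topology = "RPN",
                                   n_trials = 3, seed = 1, duration = 5000,
                                   t_skip = 500, layer = 10, ...) {
  grid <- expand.grid(J_ff = J_grid, rate_exc = rate_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    v <- vapply(seq_len(n_trials), function(k) {
      run <- run_scenario(topology = topology, stimulus = "none",
                          seed = derive_seed(seed, 50, i, k),
                          d_ff = 5, d_fb = 5, J_ff = grid$J_ff[i],
                          background = background_spec(rate_exc = grid$rate_exc[i]),
                          duration = duration, ...)
      population_fano(layer_counts(run$spikes, layer, c(t_skip, duration)))
    }, 0)
    data.frame(J_ff = grid$J_ff[i], rate_exc = grid$rate_exc[i],
               pFF_mean = mean(v), pFF_sd = stats::sd(v), n_trials = n_trials)
  })
  do.call(rbind, rows)
}

#' @rdname sweep_background_rates
#' @export
sweep_background_delays <- function(delay_grid, J_grid, topology = "RPN",
                                    n_trials = 3, seed = 1, duration = 5000,
                                    t_skip = 500, layer = 10, ...) {
  grid <- expand.grid(delay = delay_grid, J_ff = J_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    v <- vapply(seq_len(n_trials), function(k) {
      run <- run_scenario(topology = topology, stimulus = "none",
                          seed = derive_seed(seed, 51, i, k),
                          d_ff = grid$delay[i], d_fb = grid$delay[i],
                          J_ff = grid$J_ff[i], duration = duration, ...)
      population_fano(layer_counts(run$spikes, layer, c(t_skip, duration)))
    }, 0)
    data.frame(delay = grid$delay[i], J_ff = grid$J_ff[i],
               pFF_mean = mean(v), pFF_sd = stats::sd(v), n_trials = n_trials)
  })
  do.call(rbind, rows)
}

#' Conditions for resonance in a two-layer pair
#'
#' For a two-layer RPN under background drive (plus an optional probe
#' packet), sweeps the feedback connection probability against either the
#' forward probability or the feedback strength and reports the layer-1
#' network frequency, spectral entropy and population Fano factor --
#' distinguishing the asynchronous, resonant and sustained-oscillation
#' regimes.
#'
#' @param eps_fb_grid feedback connection probabilities
#' @param eps_ff_grid forward probabilities (axis 2, option A)
#' @param J_fb_grid feedback strengths in mV (axis 2, option B)
#' @param probe_packet inject a single packet (probes the evoked response)?
#' @inheritParams sweep_background_rates
#' @return data frame over the grid with `f_peak`, `H`, `pFF`
#' @export
sweep_resonance_conditions <- function(eps_fb_grid, eps_ff_grid = NULL,
                                       J_fb_grid = NULL, probe_packet = FALSE,
                                       n_trials = 3, seed = 1,
                                       duration = 4000, t_skip = 500, ...) {
  if (is.null(eps_ff_grid) == is.null(J_fb_grid))
    stop("give exactly one of eps_ff_grid or J_fb_grid", call. = FALSE)
  axis2 <- if (is.null(J_fb_grid)) eps_ff_grid else J_fb_grid
  axis2_name <- if (is.null(J_fb_grid)) "eps_inter" else "J_fb"
  grid <- expand.grid(eps_fb = eps_fb_grid, axis2 = axis2)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    v <- lapply(seq_len(n_trials), function(k) {
      args <- list(topology = "RPN",
                   stimulus = if (probe_packet) "packet" else "none",
                   seed = derive_seed(seed, 60, i, k),
                   n_layers = 2, d_ff = 12.5, d_fb = 12.5,
                   eps_fb = grid$eps_fb[i], duration = duration,
                   t_inject = min(1250, duration / 2))
      args[[axis2_name]] <- grid$axis2[i]
      run <- do.call(run_scenario, c(args, list(...)))
      y <- layer_counts(run$spikes, 1, c(t_skip, duration))
      c(f = network_frequency(y), H = spectral_entropy(y),
        pFF = population_fano(y))
    })
    v <- do.call(rbind, v)
    out <- data.frame(eps_fb = grid$eps_fb[i], axis2 = grid$axis2[i],
                      f_peak = mean(v[, "f"], na.rm = TRUE),
                      H = mean(v[, "H"]), pFF = mean(v[, "pFF"]),
                      n_trials = n_trials)
    names(out)[2] <- axis2_name
    out
  })
  do.call(rbind, rows)
}

#' Evoked-oscillation duration distribution
#'
#' Repeats the single-packet RPN scenario and measures the duration (in
#' resonance cycles) of the evoked layer-1 oscillation in every trial.
#'
#' @inheritParams sweep_delay_strength
#' @param f0 resonance frequency defining the cycle length (Hz)
#' @param post_len simulated time after the stimulation window (ms)
#' @return list with the per-trial `cycles` and their `median`
#' @export
duration_distribution <- function(n_trials = 50, seed = 1, f0 = 40,
                                  post_len = 500, ...) {
  cyc <- vapply(seq_len(n_trials), function(k) {
    run <- run_scenario(topology = "RPN", stimulus = "packet",
                        seed = derive_seed(seed, 70, k),
                        d_ff = 12.5, d_fb = 12.5, post_len = post_len, ...)
    as.numeric(oscillation_duration(run$spikes, layer = 1,
                                    t_inject = run$t_inject, f0 = f0))
  }, 0)
  list(cycles = cyc, median = stats::median(cyc))
}

#' Evoked resonance frequency of a single layer module
#'
#' Perturbs one isolated layer (background drive plus a single pulse packet
#' into its projecting neurons) and measures the frequency of the evoked
#' damped oscillation: the population count vectors of the evoked epoch are
#' averaged across trials aligned on the injection time (so the phase-locked
#' transient survives while asynchronous background activity averages out),
#' and the peak of that average's power spectrum is returned.
#'
#' @inheritParams sweep_delay_strength
#' @param large use the large-network layer (2000 E + 500 I, up-scaled
#'   parameters)?
#' @param evoked_len evoked epoch length (ms)
#' @param dt_bin count bin width (ms)
#' @return list with `f_peak` (Hz), the trial-averaged `psth`, and its
#'   `spectrum`
#' @export
module_resonance_frequency <- function(n_trials = 20, seed = 1, large = FALSE,
                                       evoked_len = 150, dt_bin = 2.5, ...) {
  lay <- if (large) layer_spec(2000, 500, 680, 0.2) else layer_spec()
  syn <- if (large) large_synapse_params() else synapse_params()
  acc <- 0
  for (k in seq_len(n_trials)) {
    run <- run_scenario(topology = "FFN", stimulus = "packet",
                        seed = derive_seed(seed, 80, k),
                        n_layers = 1, layer_def = lay, synapse = syn,
                        t_inject = 400, post_len = 20,
                        duration = 400 + evoked_len + 20, ...)
    acc <- acc + layer_counts(run$spikes, 1,
                              c(run$t_inject, run$t_inject + evoked_len),
                              dt_bin)
  }
  psth <- acc / n_trials
  list(f_peak = network_frequency(psth, dt_bin),
       psth = psth,
       spectrum = spike_spectrum(psth, dt_bin))
}

#' Robustness suite: jittered trains, heterogeneous delays, large network
#'
#' `sweep_train_jitter()` drives the RPN with jittered periodic trains and
#' reports layer-10 SNR versus jitter; `run_delay_cv()` measures single-packet
#' RPN propagation with Gaussian-dispersed delays; `large_network_snr()`
#' measures single-packet propagation in the large-network variant.
#'
#' @param jitters maximal jitter amplitudes (ms)
#' @inheritParams sweep_delay_strength
#' @param interval,n_pulses train parameters
#' @return data frames / lists of SNR summaries
#' @export
sweep_train_jitter <- function(jitters, n_trials = 10, seed = 1,
                               interval = 25, n_pulses = 10, layer = 10, ...) {
  rows <- lapply(seq_along(jitters), function(i) {
    s <- trial_snr(n_trials, derive_seed(seed, 90, i), layer = layer,
                   topology = "RPN", stimulus = "train",
                   d_ff = 12.5, d_fb = 12.5,
                   interval = interval, n_pulses = n_pulses,
                   jitter = jitters[i], ...)
    data.frame(jitter = jitters[i], snr_mean = s$mean, snr_sd = s$sd,
               n_trials = n_trials)
  })
  do.call(rbind, rows)
}

#' @rdname sweep_train_jitter
#' @param cv fractional delay standard deviation
#' @export
run_delay_cv <- function(cv, n_trials = 10, seed = 1, layer = 10, ...) {
  s <- trial_snr(n_trials, derive_seed(seed, 91, round(100 * cv)),
                 layer = layer, topology = "RPN", stimulus = "packet",
                 d_ff = 12.5, d_fb = 12.5, delay_cv = cv, ...)
  data.frame(delay_cv = cv, snr_mean = s$mean, snr_sd = s$sd,
             n_trials = n_trials)
}

#' @rdname sweep_train_jitter
#' @param d_inter equal forward/feedback delay of the large network (ms)
#' @export
large_network_snr <- function(n_trials = 5, seed = 1, d_inter = 15,
                              layer = 10, ...) {
  s <- trial_snr(n_trials, derive_seed(seed, 92), layer = layer,
                 topology = "RPN", stimulus = "packet",
                 d_ff = d_inter, d_fb = d_inter,
                 layer_def = layer_spec(2000, 500, 680, 0.2),
                 eps_inter = 0.1, synapse = large_synapse_params(), ...)
  data.frame(d_inter = d_inter, snr_mean = s$mean, snr_sd = s$sd,
             n_trials = n_trials)
}
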