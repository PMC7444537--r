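#' Alpha-function synaptic kernel
#'
#' The unit conductance time course `(t/tau) * exp(-t/tau)` for `t >= 0` and
#' 0 for `t < 0`. It peaks at `1/e` at `t = tau` and integrates to `tau`.
#' Within the simulator each synaptic event contributes this kernel scaled so
#' that its peak equals the synapse's calibrated peak conductance.
#'
#' @param t time since the event (ms); vectorized
#' @param tau synaptic rise time (ms, > 0)
#' @return unitless kernel values
#' @export
#' @examples
#' alpha_kernel(1, 1)   # 1/e
alpha_kernel <- function(t, tau) {
  stopifnot(tau > 0)
  ifelse(t < 0, 0, (t / tau) * exp(-t / tau))
}

new_spike_data <- function(id, time, t_start, t_end, membership) {
  structure(list(id = as.integer(id), time = as.numeric(time),
                 t_start = t_start, t_end = t_end, membership = membership),
            class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf("<spike_data> %d spikes from %d neurons on [%g, %g] ms\n",
              length(x$time), length(unique(x$id)), x$t_start, x$t_end))
  invisible(x)
}

#' Simulate a network under a stimulus program
#'
#' Clock-driven integration of the network: every neuron's membrane potential
#' advances by classical 4th-order Runge-Kutta at a fixed step, synaptic
#' conductances are sums of alpha kernels driven by delayed presynaptic
#' spikes, threshold crossings are detected at step boundaries, and spiking
#' neurons are reset and clamped for the refractory period (their synaptic
#' conductances keep evolving during the clamp). The lumped Poisson
#' background and the pulse packets of `program` drive the layer populations.
#' The run is fully reproducible from (`network$spec$seed`, `config$seed`).
#'
#' @param network a `ctr_network` from [build_network()]
#' @param program a [stimulus_program()]
#' @param config a [sim_config()]
#' @param i_ext optional constant injected current per neuron (pA; scalar or
#'   vector of length `n_neurons`)
#' @return list with `spikes` (a `spike_data`) and, when
#'   `config$record_vm` is `TRUE`, `traces` (a `trace_data`: sample times,
#'   voltage matrix, recorded ids)
#' @export
#' @examples
#' net <- build_network(network_spec(n_layers = 1, topology = "FFN", seed = 1))
#' prog <- stimulus_program(net)
#' run <- simulate_network(net, prog, sim_config(duration = 200, seed = 1))
#' run$spikes
simulate_network <- function(network, program, config, i_ext = 0) {
  stopifnot(inherits(network, "ctr_network"),
            inherits(program, "stimulus_program"),
            inherits(config, "sim_config"))
  n <- network$n_neurons
  dt <- config$dt
  n_steps <- as.integer(round(config$duration / dt))
  con <- network$connections
  if (nrow(con) > 0 && any(con$delay < dt - 1e-9))
    stop("all transmission delays must be >= the integration step dt",
         call. = FALSE)

  set.seed(config$seed)
  v_init <- stats::rnorm(n, config$v_init_mean, config$v_init_sd)

  # pulse packets: every packet spike reaches every target neuron
  ext_step <- integer(0); ext_target <- integer(0)
  n_targets <- length(program$targets)
  packet_times <- lapply(program$packets, function(p) {
    t <- draw_pulse_packet(p)
    t[t < n_steps * dt]
  })
  if (n_targets > 0 && length(packet_times) > 0) {
    all_t <- unlist(packet_times)
    if (length(all_t) > 0) {
      steps <- pmax(0L, as.integer(round(all_t / dt)))
      ext_step <- rep(steps, each = n_targets)
      ext_target <- rep(program$targets, times = length(steps))
      ord <- order(ext_step)
      ext_step <- ext_step[ord]
      ext_target <- ext_target[ord]
    }
  }
  ext_g <- rep(network$g$g_pp, length(ext_step))

  # lumped background
  bg <- program$background
  is_e <- network$membership$pop == "E"
  bg_lambda <- ifelse(is_e, bg$rate_exc, bg$rate_inh) * dt / 1000
  bg_g <- ifelse(is_e, network$g$g_pe, network$g$g_pi)

  # synapse table in CSR order by presynaptic id
  ord <- order(con$pre)
  pre_counts <- tabulate(con$pre + 1L, nbins = n)
  syn_ptr <- c(0L, cumsum(pre_counts))
  syn_dstep <- as.integer(round(con$delay[ord] / dt))

  record_ids <- integer(0); record_every <- 0L
  if (config$record_vm) {
    record_ids <- if (is.null(config$record_ids)) 0:(n - 1L)
                  else as.integer(config$record_ids)
    record_every <- config$vm_decimation
  }
  if (length(i_ext) == 1) i_ext <- rep(i_ext, n)

  out <- sim_core(v_init = v_init,
                  c_m = network$neuron$C_m, g_leak = network$neuron$G_leak,
                  e_leak = network$neuron$V_reset,
                  v_th = network$neuron$V_th,
                  v_reset = network$neuron$V_reset,
                  tau_ref = network$neuron$tau_ref,
                  e_exc = network$synapse$E_exc, e_inh = network$synapse$E_inh,
                  tau_exc = network$synapse$tau_exc,
                  tau_inh = network$synapse$tau_inh,
                  syn_ptr = syn_ptr,
                  syn_post = as.integer(con$post[ord]),
                  syn_g = as.numeric(con$g_peak[ord]),
                  syn_inh = as.integer(con$reversal_class[ord] == "inh"),
                  syn_dstep = syn_dstep,
                  bg_lambda = bg_lambda, bg_g = bg_g,
                  ext_step = ext_step, ext_target = ext_target, ext_g = ext_g,
                  i_ext = as.numeric(i_ext),
                  dt = dt, n_steps = n_steps,
                  record_idx = record_ids, record_every = record_every)

  spikes <- new_spike_data(out$spike_id, out$spike_time,
                           t_start = 0, t_end = n_steps * dt,
                           membership = network$membership)
  traces <- NULL
  if (config$record_vm) {
    traces <- structure(list(time = out$vm_time, vm = out$vm,
                             ids = record_ids),
                        class = "trace_data")
  }
  list(spikes = spikes, traces = traces,
       packet_times = packet_times)
}

#' Layer-averaged membrane potential
#'
#' Arithmetic mean of the recorded membrane potentials over each layer's
#' excitatory neurons, per sample time.
#'
#' @param traces a `trace_data` from [simulate_network()]
#' @param network the simulated `ctr_network`
#' @param layers layer indices (default: all)
#' @return data frame with `time` and one `layer<k>` column per layer
#' @export
mean_vm_by_layer <- function(traces, network, layers = NULL) {
  if (is.null(traces)) stop("membrane potentials were not recorded", call. = FALSE)
  if (is.null(layers)) layers <- seq_len(network$spec$n_layers)
  out <- data.frame(time = traces$time)
  for (l in layers) {
    ids <- layer_members(network, l, "E")
    cols <- which(traces$ids %in% ids)
    if (length(cols) == 0)
      stop(sprintf("no excitatory neurons of layer %d were recorded", l),
           call. = FALSE)
    out[[paste0("layer", l)]] <- rowMeans(traces$vm[, cols, drop = FALSE])
  }
  out
}

fmt_full <- function(x) sprintf("%.17g", x)  # lossless double round-trip

#' Spike and trace file I/O
#'
#' Spikes are written as a two-column tab-separated event table
#' (`neuron_id`, `time_ms`) with a `<path>.membership` sidecar carrying the
#' per-neuron layer/population map; traces as a dense matrix with a leading
#' time column. Numeric values round-trip bit-exactly.
#'
#' @param spikes a `spike_data`
#' @param path output path (sidecar written next to it)
#' @return readers return the reconstructed object; writers their input,
#'   invisibly
#' @export
write_spikes <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_data"))
  header <- sprintf("# t_start=%s t_end=%s", fmt_full(spikes$t_start),
                    fmt_full(spikes$t_end))
  lines <- c(header, "neuron_id\ttime_ms",
             paste(spikes$id, fmt_full(spikes$time), sep = "\t"))
  writeLines(lines, path)
  m <- spikes$membership
  writeLines(c("id\tlayer\tpop", paste(m$id, m$layer, m$pop, sep = "\t")),
             paste0(path, ".membership"))
  invisible(spikes)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# ", "", lines[1]), " ")[[1]]
  t_start <- as.numeric(sub("t_start=", "", hdr[1]))
  t_end <- as.numeric(sub("t_end=", "", hdr[2]))
  body <- lines[-(1:2)]
  id <- integer(0); time <- numeric(0)
  if (length(body) > 0) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    id <- as.integer(vapply(parts, `[[`, "", 1))
    time <- as.numeric(vapply(parts, `[[`, "", 2))
  }
  mpath <- paste0(path, ".membership")
  membership <- NULL
  if (file.exists(mpath)) {
    membership <- utils::read.table(mpath, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE)
  }
  new_spike_data(id, time, t_start, t_end, membership)
}

#' @rdname write_spikes
#' @param traces a `trace_data`
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, "trace_data"))
  header <- paste(c("time_ms", paste0("n", traces$ids)), collapse = "\t")
  rows <- apply(cbind(traces$time, traces$vm), 1,
                function(r) paste(fmt_full(r), collapse = "\t"))
  writeLines(c(header, rows), path)
  invisible(traces)
}

#' @rdname write_spikes
#' @export
read_traces <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  vm <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(vm) <- "double"
  structure(list(time = as.numeric(d[[1]]),
                 vm = vm,
                 ids = as.integer(sub("^n", "", colnames(d)[-1]))),
            class = "trace_data")
}
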