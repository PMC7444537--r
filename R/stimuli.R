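# Synthetic inputs: the study's "data". Each excitatory neuron receives 8,000
# independent 1 spike/s Poisson trains and each inhibitory neuron 6,400; by
# the superposition property of Poisson processes these are generated as one
# lumped process per neuron at the aggregate rate through a single synapse.
# Pulse packets are volleys of `alpha` spikes with Gaussian temporal
# dispersion `sigma`, shared by all layer-1 projecting neurons.

#' Background drive specification
#'
#' Aggregate Poisson input rates per excitatory and inhibitory neuron
#' (spikes/s). When sweeping the excitatory rate, the inhibitory rate follows
#' as `rate_exc - 1600` so the difference between the mean input rates to E-
#' and I-neurons stays constant.
#'
#' @param rate_exc aggregate rate onto each E neuron (spikes/s)
#' @param rate_inh aggregate rate onto each I neuron (spikes/s); `NULL` keeps
#'   the 1600 spikes/s difference below `rate_exc`
#' @param rate_inh_extra additional drive to I neurons (spikes/s), used to
#'   shorten evoked oscillations by raising mean inhibition
#' @return an object of class `background_spec`
#' @export
#' @examples
#' background_spec()                  # 8000 / 6400 spikes/s
#' background_spec(rate_exc = 10000)  # inhibitory rate follows: 8400
background_spec <- function(rate_exc = 8000, rate_inh = NULL,
                            rate_inh_extra = 0) {
  if (is.null(rate_inh)) rate_inh <- rate_exc - 1600
  rate_inh <- rate_inh + rate_inh_extra
  stopifnot(rate_exc >= 0, rate_inh >= 0)
  structure(list(rate_exc = rate_exc, rate_inh = rate_inh),
            class = "background_spec")
}

#' Pulse packet specification
#'
#' A volley of `alpha` spikes whose times are drawn independently from a
#' Gaussian centered on `t_center` with standard deviation `sigma`. Every
#' spike of the packet is delivered to every target (the packet is a shared
#' population stimulus to the layer-1 projecting neurons).
#'
#' @param t_center packet arrival time (ms)
#' @param alpha number of spikes in the volley (integer >= 0)
#' @param sigma temporal dispersion (ms, >= 0)
#' @return an object of class `pulse_packet_spec`
#' @export
pulse_packet_spec <- function(t_center, alpha = 20, sigma = 2) {
  stopifnot(alpha >= 0, alpha == round(alpha), sigma >= 0, t_center >= 0)
  structure(list(t_center = t_center, alpha = as.integer(alpha),
                 sigma = sigma), class = "pulse_packet_spec")
}

#' Draw the spike times of one pulse packet
#'
#' @param spec a [pulse_packet_spec()]
#' @param seed optional integer seed
#' @return sorted spike times (ms); times falling below 0 are discarded
#' @export
#' @examples
#' draw_pulse_packet(pulse_packet_spec(t_center = 100), seed = 1)
draw_pulse_packet <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "pulse_packet_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (spec$alpha == 0) return(numeric(0))
  t <- stats::rnorm(spec$alpha, mean = spec$t_center, sd = spec$sigma)
  sort(t[t >= 0])
}

#' Train of pulse-packet centers
#'
#' Packet centers on a periodic grid `t_first + k * interval`, optionally
#' jittered by independent uniform offsets on `(-jitter, +jitter)`. The mean
#' inter-center interval equals `interval` in expectation.
#'
#' @param n_pulses number of packets
#' @param interval inter-packet interval (ms, > 0)
#' @param jitter maximal deviation from the periodic grid (ms, in
#'   `[0, interval/2]`)
#' @param t_first center of the first packet (ms)
#' @param seed optional integer seed
#' @return packet center times (ms)
#' @export
#' @examples
#' make_train(3, interval = 25, t_first = 100)   # 100 125 150
make_train <- function(n_pulses, interval = 25, jitter = 0, t_first = 0,
                       seed = NULL) {
  stopifnot(n_pulses >= 1, interval > 0, jitter >= 0, jitter <= interval / 2)
  if (!is.null(seed)) set.seed(seed)
  centers <- t_first + (seq_len(n_pulses) - 1) * interval
  if (jitter > 0)
    centers <- centers + stats::runif(n_pulses, -jitter, jitter)
  centers
}

#' Homogeneous Poisson event stream
#'
#' @param rate rate (spikes/s, >= 0)
#' @param duration stream length (ms)
#' @param seed optional integer seed
#' @return sorted event times (ms)
#' @export
poisson_drive <- function(rate, duration, seed = NULL) {
  stopifnot(rate >= 0, duration >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, rate * duration / 1000)
  sort(stats::runif(n, 0, duration))
}

#' Stimulus program
#'
#' Combines the background drive with a schedule of pulse packets aimed at
#' the layer-1 projecting neurons.
#'
#' @param network a `ctr_network`
#' @param background a [background_spec()]
#' @param packets list of [pulse_packet_spec()] (possibly empty)
#' @param targets 0-based ids receiving the packets; defaults to the layer-1
#'   forward projectors and must be a subset of them
#' @return an object of class `stimulus_program`
#' @export
#' @examples
#' net <- build_network(network_spec(n_layers = 2, topology = "FFN", seed = 1))
#' prog <- stimulus_program(net, packets = list(pulse_packet_spec(500)))
stimulus_program <- function(network, background = background_spec(),
                             packets = list(), targets = NULL) {
  stopifnot(inherits(network, "ctr_network"),
            inherits(background, "background_spec"))
  if (inherits(packets, "pulse_packet_spec")) packets <- list(packets)
  proj1 <- network$forward_projectors[[1L]]
  if (is.null(targets)) targets <- proj1
  if (!all(targets %in% proj1))
    stop("packet targets must be layer-1 projecting neurons", call. = FALSE)
  structure(list(background = background, packets = packets,
                 targets = as.integer(targets)),
            class = "stimulus_program")
}

#' Periodic or jittered packet-train program
#'
#' Convenience wrapper building a [stimulus_program()] whose packets form a
#' (possibly jittered) periodic train.
#'
#' @inheritParams stimulus_program
#' @inheritParams make_train
#' @param alpha,sigma packet strength and dispersion, see
#'   [pulse_packet_spec()]
#' @return a `stimulus_program`
#' @export
train_program <- function(network, n_pulses, interval = 25, jitter = 0,
                          t_first = 0, alpha = 20, sigma = 2,
                          background = background_spec(), seed = NULL) {
  centers <- make_train(n_pulses, interval, jitter, t_first, seed)
  packets <- lapply(centers, pulse_packet_spec, alpha = alpha, sigma = sigma)
  stimulus_program(network, background = background, packets = packets)
}

#' Read and write stimulus programs
#'
#' Serializes a [stimulus_program()] to a flat `key = value` text file:
#' background rates, packet schedule (one `packet` line per pulse, as
#' `t_center:alpha:sigma`), and target ids.
#'
#' @param program a `stimulus_program`
#' @param path file path
#' @return `read_stimulus_program()` returns the parsed fields as a list
#'   (attach to a network with [stimulus_program()]); the writer returns its
#'   input invisibly
#' @export
write_stimulus_program <- function(program, path) {
  stopifnot(inherits(program, "stimulus_program"))
  lines <- c(
    paste("rate_exc =", program$background$rate_exc),
    paste("rate_inh =", program$background$rate_inh),
    paste("targets =", paste(program$targets, collapse = ",")),
    vapply(program$packets, function(p)
      sprintf("packet = %.17g:%d:%.17g", p$t_center, p$alpha, p$sigma), ""))
  writeLines(lines, path)
  invisible(program)
}

#' @rdname write_stimulus_program
#' @export
read_stimulus_program <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines[nzchar(lines)], "=", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[[1]]), "")
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = "=")), "")
  packets <- lapply(vals[keys == "packet"], function(v) {
    f <- as.numeric(strsplit(v, ":", fixed = TRUE)[[1]])
    pulse_packet_spec(t_center = f[1], alpha = f[2], sigma = f[3])
  })
  list(background = background_spec(
         rate_exc = as.numeric(vals[keys == "rate_exc"][1]),
         rate_inh = as.numeric(vals[keys == "rate_inh"][1])),
       packets = packets,
       targets = as.integer(strsplit(vals[keys == "targets"][1], ",")[[1]]))
}
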