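# Shared fixtures: everything is generated in code at test time.

# a small, fast network for plumbing tests
tiny_spec <- function(topology = "FFN", seed = 1, ...) {
  network_spec(n_layers = 2, layer = layer_spec(40, 10, 14, 0.2),
               topology = topology,
               d_ff = 5, d_fb = if (topology == "RPN") 5 else NULL,
               seed = seed, ...)
}

# single isolated neuron wrapped as a 1-layer "network" so the public
# simulate_network() interface can drive it
one_neuron_net <- function(neuron = neuron_params(), synapse = synapse_params()) {
  build_network(network_spec(n_layers = 1,
                             layer = layer_spec(1, 0, 1, 0),
                             eps_inter = 0, topology = "FFN", seed = 1),
                neuron, synapse)
}

quiet_background <- function() background_spec(rate_exc = 0, rate_inh = 0)

# synthetic spike_data from explicit events
fake_spikes <- function(id, time, t_end, n_neurons = max(id) + 1L,
                        layer = rep(1L, n_neurons)) {
  ctrnet:::new_spike_data(id, time, 0, t_end,
    membership = data.frame(id = 0:(n_neurons - 1L), layer = layer,
                            pop = rep("E", n_neurons),
                            stringsAsFactors = FALSE))
}
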