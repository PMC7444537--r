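test_that("alpha kernel satisfies its analytic identities", {
  expect_identical(alpha_kernel(0, 1), 0)
  expect_identical(alpha_kernel(-3, 2), 0)
  expect_equal(alpha_kernel(1, 1), exp(-1))
  expect_equal(alpha_kernel(2.5, 2.5), exp(-1))   # maximum at t = tau
  for (tau in c(0.5, 1, 2)) {
    expect_equal(stats::integrate(alpha_kernel, 0, Inf, tau = tau)$value,
                 tau, tolerance = 1e-6)
  }
})

test_that("an unstimulated network at rest stays silent at -70 mV", {
  net <- one_neuron_net()
  prog <- stimulus_program(net, background = quiet_background())
  run <- simulate_network(net, prog,
                          sim_config(duration = 100, seed = 1,
                                     v_init_sd = 0, record_vm = TRUE,
                                     vm_decimation = 1L))
  expect_length(run$spikes$time, 0)
  expect_true(all(abs(run$traces$vm - (-70)) < 1e-9))
})

test_that("constant-current firing matches the closed-form LIF period", {
  np <- neuron_params()
  net <- one_neuron_net(np)
  prog <- stimulus_program(net, background = quiet_background())
  for (I0 in c(350, 500, 800)) {
    run <- simulate_network(net, prog,
                            sim_config(duration = 500, seed = 1, v_init_sd = 0),
                            i_ext = I0)
    isi <- diff(run$spikes$time)
    tau_m <- np$C_m / np$G_leak
    drive <- I0 / np$G_leak
    period <- tau_m * log(drive / (drive - (np$V_th - np$V_reset))) + np$tau_ref
    expect_true(all(abs(isi - period) < 2 * 0.1))
  }
})

test_that("no neuron fires twice within the refractory period", {
  net <- build_network(tiny_spec(seed = 4))
  run <- simulate_network(net, stimulus_program(net),
                          sim_config(duration = 1000, seed = 2))
  by_id <- split(run$spikes$time, run$spikes$id)
  min_isi <- vapply(by_id, function(tt)
    if (length(tt) > 1) min(diff(tt)) else Inf, 0)
  expect_true(all(min_isi >= net$neuron$tau_ref - 1e-9))
})

test_that("a single synaptic event follows the analytic PSP time course", {
  # tiny conductance so the driving force is effectively constant, making the
  # alpha-kernel/membrane convolution exactly solvable
  np <- neuron_params()
  g <- 1e-3
  net <- one_neuron_net(np, synapse_params(J_pp = g))
  prog <- stimulus_program(net, background = quiet_background(),
                           packets = list(pulse_packet_spec(5, alpha = 1,
                                                            sigma = 0)))
  run <- simulate_network(net, prog,
                          sim_config(duration = 60, seed = 1, v_init_sd = 0,
                                     record_vm = TRUE, vm_decimation = 1L))
  vm <- run$traces$vm[, 1]
  tt <- run$traces$time
  tau <- 1
  tau_m <- np$C_m / np$G_leak
  a <- 1 / tau - 1 / tau_m
  t_rel <- tt - 5
  analytic <- ifelse(t_rel <= 0, 0,
    (70 * exp(1) * g / (np$C_m * tau)) * exp(-t_rel / tau_m) *
      (1 - exp(-a * t_rel) * (1 + a * t_rel)) / a^2)
  err <- max(abs((vm + 70) - analytic)) / max(analytic)
  expect_lt(err, 1e-4)
})

test_that("halving the integration step leaves spike times nearly unchanged", {
  np <- neuron_params()
  net <- one_neuron_net(np)
  prog <- stimulus_program(net, background = quiet_background())
  t1 <- simulate_network(net, prog, sim_config(200, dt = 0.1, seed = 1,
                                               v_init_sd = 0),
                         i_ext = 420)$spikes$time
  t2 <- simulate_network(net, prog, sim_config(200, dt = 0.05, seed = 1,
                                               v_init_sd = 0),
                         i_ext = 420)$spikes$time
  # the onset and every interval agree to within the coarser step; only the
  # step-quantization of threshold detection can accumulate beyond that
  expect_lt(abs(t1[1] - t2[1]), 0.1)
  expect_true(all(abs(diff(t1) - diff(t2)) < 0.1))
})

test_that("membrane potentials stay between the reversal bounds", {
  net <- build_network(tiny_spec(topology = "RPN", seed = 9))
  run <- simulate_network(net, stimulus_program(net),
                          sim_config(duration = 500, seed = 3,
                                     record_vm = TRUE))
  expect_true(all(run$traces$vm >= net$synapse$E_inh - 1e-6))
  expect_true(all(run$traces$vm <= net$neuron$V_th + 1))
})

test_that("simulations are exactly reproducible from their seeds", {
  net <- build_network(tiny_spec(seed = 11))
  prog <- stimulus_program(net, packets = list(pulse_packet_spec(300)))
  r1 <- simulate_network(net, prog, sim_config(400, seed = 5))
  r2 <- simulate_network(net, prog, sim_config(400, seed = 5))
  expect_identical(r1$spikes$id, r2$spikes$id)
  expect_identical(r1$spikes$time, r2$spikes$time)
  r3 <- simulate_network(net, prog, sim_config(400, seed = 6))
  expect_false(identical(r1$spikes$time, r3$spikes$time))
})

test_that("delays shorter than the step are rejected", {
  net <- build_network(tiny_spec(seed = 2))
  net$connections$delay[1] <- 0.01
  expect_error(simulate_network(net, stimulus_program(net),
                                sim_config(100, seed = 1)), "delays")
})

test_that("layer-mean membrane potential averages the recorded traces", {
  net <- build_network(tiny_spec(seed = 3))
  run <- simulate_network(net, stimulus_program(net),
                          sim_config(200, seed = 1, record_vm = TRUE))
  mv <- mean_vm_by_layer(run$traces, net, layers = 1)
  ids1 <- layer_members(net, 1, "E")
  manual <- rowMeans(run$traces$vm[, run$traces$ids %in% ids1])
  expect_equal(mv$layer1, manual)
  # a single recorded neuron's "mean" is its own trace
  one <- simulate_network(net, stimulus_program(net),
                          sim_config(100, seed = 1, record_vm = TRUE,
                                     record_ids = ids1[1]))
  mv1 <- mean_vm_by_layer(one$traces, net, layers = 1)
  expect_equal(mv1$layer1, one$traces$vm[, 1])
  expect_error(mean_vm_by_layer(NULL, net), "not recorded")
})

test_that("spike and trace files round-trip bit-exactly", {
  net <- build_network(tiny_spec(seed = 7))
  run <- simulate_network(net, stimulus_program(net),
                          sim_config(300, seed = 2, record_vm = TRUE))
  sp_path <- withr::local_tempfile(fileext = ".tsv")
  write_spikes(run$spikes, sp_path)
  back <- read_spikes(sp_path)
  expect_identical(back$id, run$spikes$id)
  expect_identical(back$time, run$spikes$time)
  expect_identical(back$t_end, run$spikes$t_end)
  expect_equal(back$membership, run$spikes$membership)
  tr_path <- withr::local_tempfile(fileext = ".tsv")
  write_traces(run$traces, tr_path)
  tr <- read_traces(tr_path)
  expect_identical(tr$time, run$traces$time)
  expect_identical(unname(tr$vm), unname(run$traces$vm))
  expect_identical(tr$ids, run$traces$ids)
})
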