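# Brute-force oracles: each statistic is recomputed here from its defining
# formula, element by element, and compared to the package implementation.

test_that("spike binning counts events in half-open bins and conserves totals", {
  sp <- fake_spikes(id = 0L, time = 7, t_end = 20)
  cm <- bin_spikes(sp, c(0, 20), 5, grouping = "neuron", pop = "all")
  expect_identical(as.integer(cm$counts[1, ]), c(0L, 1L, 0L, 0L))
  # no spikes -> all zero
  empty <- fake_spikes(integer(0), numeric(0), 20, n_neurons = 3L)
  expect_true(all(bin_spikes(empty, c(0, 20), 5, "neuron", pop = "all")$counts == 0L))
  # conservation and trailing-bin dropping on random data
  set.seed(8)
  sp2 <- fake_spikes(sample(0:4, 300, TRUE), runif(300, 0, 103), 103,
                     n_neurons = 5L)
  cm2 <- bin_spikes(sp2, c(0, 103), 5, "neuron", pop = "all")
  expect_identical(ncol(cm2$counts), 20L)
  expect_identical(sum(cm2$counts), sum(sp2$time < 100))
  # layer grouping sums neurons
  cml <- bin_spikes(sp2, c(0, 103), 5, "layer", pop = "all")
  expect_equal(unname(cml$counts[1, ]), unname(as.integer(colSums(cm2$counts))))
  expect_error(bin_spikes(sp2, c(50, 50), 5), "window")
})

test_that("pairwise correlation matches the defining formula and its limits", {
  set.seed(21)
  x <- matrix(rpois(10 * 200, 3), nrow = 10)
  res <- pairwise_correlation(x)
  # brute force: explicit expectation formula per pair
  brute <- function(a, b) {
    mean((a - mean(a)) * (b - mean(b))) /
      (sqrt(mean((a - mean(a))^2)) * sqrt(mean((b - mean(b))^2)))
  }
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(res$r_matrix[i, j], brute(x[i, ], x[j, ]), tolerance = 1e-12)
  }
  expect_equal(res$r_mean, mean(res$r_matrix[upper.tri(res$r_matrix)]),
               tolerance = 1e-12)
  # perfectly identical and perfectly anti-phase rows
  y <- rpois(100, 5)
  expect_equal(pairwise_correlation(rbind(y, y))$r_mean, 1)
  expect_equal(pairwise_correlation(rbind(y, 10 - y))$r_mean, -1)
  # zero-variance rows are excluded and reported
  z <- rbind(y, rep(2, 100), y + rpois(100, 1))
  rz <- pairwise_correlation(z)
  expect_identical(rz$n_excluded, 1L)
  expect_identical(dim(rz$r_matrix), c(2L, 2L))
  # independent rows decorrelate at the sampling-error scale
  set.seed(9)
  big <- matrix(rpois(20 * 4000, 2), nrow = 20)
  expect_lt(abs(pairwise_correlation(big)$r_mean), 0.02)
})

test_that("population Fano factor matches VAR/MEAN and its limit cases", {
  expect_equal(population_fano(rep(7, 50)), 0)
  expect_true(is.na(population_fano(rep(0, 50))))
  set.seed(3)
  y <- rpois(2000, 9)
  expect_equal(population_fano(y), var(y) / mean(y), tolerance = 1e-12)
  expect_lt(abs(population_fano(y) - 1), 0.1)
  # all-or-none synchronized bursts of k spikes give pFF near k
  k <- 25
  bursts <- rep(c(k, rep(0, 9)), 40)
  expect_equal(population_fano(bursts), var(bursts) / mean(bursts))
  expect_gt(population_fano(bursts), k / 2)
})

test_that("the spectrum is the mean-subtracted Fourier power", {
  expect_true(all(spike_spectrum(rep(4, 64), 5)$power < 1e-20))
  # pure sinusoidal rate: single dominant line at the generating frequency
  tt <- seq(0, by = 5e-3, length.out = 200)      # 5 ms bins, seconds
  y <- 10 + 8 * sin(2 * pi * 40 * tt)
  sp <- spike_spectrum(y, 5)
  expect_equal(sp$freq[which.max(sp$power)], 40)
  # Parseval: total power equals total squared deviation (odd length)
  set.seed(5)
  z <- rpois(201, 6)
  sp2 <- spike_spectrum(z, 5)
  expect_equal(2 * sum(sp2$power) / 201, sum((z - mean(z))^2),
               tolerance = 1e-9)
})

test_that("network frequency recovers generating frequencies across the band", {
  set.seed(14)
  for (f in c(20, 32, 44, 56)) {
    tt <- seq(0, by = 5e-3, length.out = 400)
    lam <- pmax(0, 10 + 7 * sin(2 * pi * f * tt))
    y <- rpois(400, lam)
    df <- 1 / (400 * 5e-3)
    expect_lt(abs(network_frequency(y, 5) - f), df + 1e-9)
  }
  expect_true(is.na(network_frequency(rep(3, 256), 5)))
})

test_that("spectral entropy is normalized, bounded and concentration-sensitive", {
  n <- 200
  tt <- seq_len(n)
  # exact single line (integer number of periods, no leakage) -> 0
  one <- 10 + cos(2 * pi * 20 * tt / n)
  expect_lt(spectral_entropy(one, 5), 1e-6)
  # impulse: perfectly flat spectrum -> 1
  imp <- c(1, rep(0, n - 1))
  expect_equal(spectral_entropy(imp, 5), 1, tolerance = 1e-9)
  # entropy grows as fixed total power spreads over more lines
  two <- 10 + cos(2 * pi * 20 * tt / n) + cos(2 * pi * 30 * tt / n)
  four <- 10 + cos(2 * pi * 20 * tt / n) + cos(2 * pi * 30 * tt / n) +
    cos(2 * pi * 40 * tt / n) + cos(2 * pi * 50 * tt / n)
  h <- c(spectral_entropy(one, 5), spectral_entropy(two, 5),
         spectral_entropy(four, 5))
  expect_true(all(diff(h) > 0))
  # brute-force Shannon formula on a random vector
  set.seed(2)
  y <- rpois(256, 5)
  sp <- spike_spectrum(y, 5)
  p <- sp$power / sum(sp$power)
  expect_equal(spectral_entropy(y, 5),
               -sum(p[p > 0] * log2(p[p > 0])) / log2(nrow(sp)),
               tolerance = 1e-12)
  expect_gte(spectral_entropy(y, 5), 0)
  expect_lte(spectral_entropy(y, 5), 1)
})

test_that("SNR is the variance ratio of stimulation to ongoing counts", {
  set.seed(31)
  # build spikes with known per-bin counts: ongoing Poisson, stimulated burst
  ong <- rpois(260, 6)     # 1300 ms of 5 ms bins
  stim <- rpois(60, 6) + c(rep(0, 20), 30, 28, 0, 22, rep(0, 36))
  mk <- function(counts, t0) {
    unlist(lapply(seq_along(counts), function(b)
      if (counts[b] > 0) t0 + (b - 1) * 5 + runif(counts[b], 0, 5) else numeric(0)))
  }
  times <- c(mk(ong, 0), mk(stim, 1300))
  sp <- fake_spikes(rep(0L, length(times)), times, 1600)
  got <- snr(sp, layer = 1, t_inject = 1300, stim_len = 300,
             ongoing_len = 1000, gap = 100)
  y_ong <- tabulate(floor((times[times >= 200 & times < 1200] - 200) / 5) + 1, 200)
  y_st <- tabulate(floor((times[times >= 1300] - 1300) / 5) + 1, 60)
  expect_equal(got, var(y_st) / var(y_ong), tolerance = 1e-12)
  expect_gt(got, 4)
  # statistically identical windows give SNR near 1
  sp0 <- fake_spikes(rep(0L, sum(ong)), mk(ong, 0)[seq_len(sum(ong))], 1600)
  flat <- snr(fake_spikes(0L, numeric(0), 1600), layer = 1, t_inject = 1300)
  expect_true(is.na(flat))                      # zero ongoing variance
  set.seed(4)
  tt <- runif(3000, 0, 1600)
  same <- snr(fake_spikes(rep(0L, 3000), tt, 1600), 1, 1300)
  expect_gt(same, 0.5); expect_lt(same, 2)
  # invariance under adding a constant count to every bin of both windows
  plus <- c(tt, rep(seq(2.5, 1597.5, by = 5), each = 2))
  shifted <- snr(fake_spikes(rep(0L, length(plus)), plus, 1600), 1, 1300)
  expect_equal(shifted, same, tolerance = 1e-9)
})

test_that("oscillation duration counts threshold-exceeding resonance cycles", {
  set.seed(77)
  # flat Poisson activity: first post-injection cycle fails, duration 0
  tt <- runif(16000, 0, 2000)
  flat <- fake_spikes(rep(0L, length(tt)), tt, 2000)
  expect_identical(oscillation_duration(flat, 1, t_inject = 1300, f0 = 40), 0L)
  # constructed rate with a small ongoing ripple and an evoked decaying
  # envelope: the number of supra-threshold cycles is known analytically
  f0 <- 40; dt <- 1
  t_grid <- seq(0.5, 2499.5, by = dt)
  a0 <- 3                                   # ongoing ripple amplitude
  A0 <- a0 * exp(2)                         # evoked envelope starts at e^2 * a0
  tau_d <- 5 * 25                           # decay: 1/5 per cycle in log units
  lam <- 20 + a0 * cos(2 * pi * f0 * t_grid / 1000) +
    ifelse(t_grid >= 1300,
           A0 * exp(-(t_grid - 1300) / tau_d) * cos(2 * pi * f0 * (t_grid - 1300) / 1000),
           0)
  counts <- rpois(length(lam), pmax(lam, 0))
  times <- rep(t_grid, counts) + runif(sum(counts), -0.5, 0.5)
  spk <- fake_spikes(rep(0L, length(times)), times, 2500)
  dur <- oscillation_duration(spk, 1, t_inject = 1300, f0 = 40)
  # envelope crosses the ongoing amplitude after tau_d * ln(A0/a0) = 10 cycles
  expect_gte(dur, 8)
  expect_lte(dur, 12)
})

test_that("propagation latency finds the first supra-threshold bin", {
  set.seed(55)
  # no stimulus: never exceeds mean + 5 sd
  tt <- runif(8000, 0, 1600)
  expect_true(is.na(propagation_latency(fake_spikes(rep(0L, 8000), tt, 1600),
                                        1, t_inject = 1300)))
  # deterministic relay: strong burst 45 ms after injection (9 hops x 5 ms)
  burst <- 1345 + runif(120, 0, 5)
  spk <- fake_spikes(rep(0L, 8120), c(tt, burst), 1600)
  lat <- propagation_latency(spk, 1, t_inject = 1300)
  expect_equal(lat, 47.5)                       # center of the 45-50 ms bin
})

test_that("interval statistics match their process oracles", {
  # perfectly periodic train
  per <- fake_spikes(rep(0L, 100), seq(10, by = 20, length.out = 100), 2100)
  expect_equal(cv_isi(per, ids = 0L)$cv, 0)
  # Poisson train: CV near 1
  set.seed(12)
  tt <- cumsum(rexp(4000, 1 / 50))
  pois <- fake_spikes(rep(0L, length(tt)), tt, max(tt) + 1)
  expect_lt(abs(cv_isi(pois, ids = 0L)$cv - 1), 0.05)
  # dead-time process: tau_ref = 2 ms at 5 spikes/s -> CV = 198/200
  isi <- 2 + rexp(4000, 1 / 198)
  dead <- fake_spikes(rep(0L, 4001), cumsum(c(1, isi)), sum(isi) + 10)
  cv <- cv_isi(dead, ids = 0L)$cv
  expect_lt(cv, 1)
  expect_lt(abs(cv - 198 / 200), 0.04)
  # neurons with too few intervals are excluded and counted
  few <- fake_spikes(c(0L, 0L, 1L), c(10, 20, 30), 100, n_neurons = 2L)
  res <- cv_isi(few, ids = c(0L, 1L))
  expect_identical(attr(res, "n_excluded"), 2L)
  # firing rates: count / window
  fr <- firing_rates(per, ids = 0L, window = c(0, 2000))
  expect_equal(fr$rate, 100 / 2)
})

test_that("the layer report gathers the per-layer statistics", {
  net <- build_network(tiny_spec(seed = 17))
  run <- simulate_network(net, stimulus_program(net),
                          sim_config(1500, seed = 4))
  rep <- summarize_layers(run$spikes, c(250, 1250))
  expect_identical(rep$layer, c(1L, 2L))
  expect_true(all(c("rate", "pFF", "H", "f_peak", "r_mean") %in% names(rep)))
  expect_true(all(rep$rate > 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stat_report(rep, path)
  expect_equal(read.delim(path)$pFF, rep$pFF, tolerance = 1e-6)
})
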