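# Spike-train statistics: binned counts, pairwise correlation, population
# Fano factor, spectra / spectral entropy / network frequency, propagation
# SNR, evoked-oscillation duration and propagation latency.

#' Bin spikes into count vectors
#'
#' Counts events per contiguous half-open bin `[edge, edge + dt_bin)`,
#' grouped per neuron or summed per layer. A trailing partial bin is dropped.
#'
#' @param spikes a `spike_data`
#' @param window `c(t0, t1)` analysis window (ms)
#' @param dt_bin bin width (ms)
#' @param grouping `"layer"` (one summed row per layer) or `"neuron"` (one
#'   row per neuron)
#' @param pop population filter: `"E"`, `"I"`, or `"all"`
#' @param layers optional layer subset
#' @return object of class `count_matrix`: list with integer matrix `counts`
#'   (groups x bins), bin `edges`, `dt_bin`, and group labels
#' @export
bin_spikes <- function(spikes, window, dt_bin = 5,
                       grouping = c("layer", "neuron"),
                       pop = "E", layers = NULL) {
  grouping <- match.arg(grouping)
  stopifnot(inherits(spikes, "spike_data"), length(window) == 2)
  t0 <- window[1]; t1 <- window[2]
  if (!(t1 > t0)) stop("empty analysis window", call. = FALSE)
  n_bins <- floor((t1 - t0) / dt_bin + 1e-9)
  if (n_bins < 1) stop("window shorter than one bin", call. = FALSE)

  m <- spikes$membership
  if (is.null(m)) stop("spike data carries no membership map", call. = FALSE)
  keep_ids <- m$id
  if (pop != "all") keep_ids <- m$id[m$pop == pop]
  if (!is.null(layers)) keep_ids <- intersect(keep_ids, m$id[m$layer %in% layers])

  sel <- spikes$id %in% keep_ids & spikes$time >= t0 &
    spikes$time < t0 + n_bins * dt_bin
  id <- spikes$id[sel]
  b <- floor((spikes$time[sel] - t0) / dt_bin)

  if (grouping == "layer") {
    lay_of <- m$layer[match(id, m$id)]
    groups <- if (is.null(layers)) sort(unique(m$layer)) else sort(layers)
    counts <- matrix(0L, nrow = length(groups), ncol = n_bins)
    if (length(id) > 0) {
      tab <- table(factor(lay_of, levels = groups), factor(b, levels = 0:(n_bins - 1)))
      counts <- matrix(as.integer(tab), nrow = length(groups))
    }
    rownames(counts) <- paste0("layer", groups)
  } else {
    groups <- sort(keep_ids)
    counts <- matrix(0L, nrow = length(groups), ncol = n_bins)
    if (length(id) > 0) {
      tab <- table(factor(id, levels = groups), factor(b, levels = 0:(n_bins - 1)))
      counts <- matrix(as.integer(tab), nrow = length(groups))
    }
    rownames(counts) <- paste0("n", groups)
  }
  structure(list(counts = counts, edges = t0 + dt_bin * 0:n_bins,
                 dt_bin = dt_bin, groups = groups, grouping = grouping),
            class = "count_matrix")
}

# summed excitatory count vector of one layer
layer_counts <- function(spikes, layer, window, dt_bin = 5, pop = "E") {
  cm <- bin_spikes(spikes, window, dt_bin, grouping = "layer",
                   pop = pop, layers = layer)
  as.numeric(cm$counts[1, ])
}

#' Mean pairwise Pearson correlation of binned spike counts
#'
#' Pearson correlation between every pair of count-vector rows; the average
#' over distinct pairs quantifies within-layer synchrony. Zero-variance rows
#' are excluded (and counted).
#'
#' @param counts a `count_matrix` (typically `grouping = "neuron"`) or a
#'   numeric matrix with one unit per row
#' @return list with `r_mean`, the full `r_matrix`, and `n_excluded`;
#'   `r_mean` is `NA` when fewer than two rows have variance
#' @export
pairwise_correlation <- function(counts) {
  x <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need at least 2 units and 2 bins", call. = FALSE)
  v <- apply(x, 1, stats::var)
  ok <- v > 0
  n_excluded <- sum(!ok)
  if (sum(ok) < 2)
    return(list(r_mean = NA_real_, r_matrix = NULL, n_excluded = n_excluded))
  r <- stats::cor(t(x[ok, , drop = FALSE]))
  list(r_mean = mean(r[upper.tri(r)]), r_matrix = r, n_excluded = n_excluded)
}

#' Population Fano factor
#'
#' Variance-to-mean ratio of a layer-summed spike count vector; ~1 for an
#' asynchronous-irregular population, much larger under population synchrony.
#'
#' @param y summed count vector (or a single-row `count_matrix`)
#' @return the Fano factor; `NA` when the mean count is zero
#' @export
population_fano <- function(y) {
  if (inherits(y, "count_matrix")) {
    if (nrow(y$counts) != 1)
      stop("population_fano expects one summed count vector", call. = FALSE)
    y <- as.numeric(y$counts[1, ])
  }
  m <- mean(y)
  if (m == 0) return(NA_real_)
  stats::var(y) / m
}

#' Power spectrum of a count vector
#'
#' Discrete Fourier power `|Y(f)|^2` of the mean-subtracted count vector
#' (rectangular window), returned for the positive frequencies up to Nyquist.
#' Frequency resolution is the inverse window length.
#'
#' @param y count vector
#' @param dt_bin bin width used to form `y` (ms)
#' @return data frame with `freq` (Hz) and `power`
#' @export
spike_spectrum <- function(y, dt_bin = 5) {
  n <- length(y)
  if (n < 8) stop("count vector too short for a spectrum", call. = FALSE)
  z <- y - mean(y)
  Y <- stats::fft(z)
  half <- floor(n / 2)
  data.frame(freq = (1:half) / (n * dt_bin / 1000),
             power = Mod(Y[2:(half + 1)])^2)
}

#' Network frequency (spectral peak)
#'
#' Frequency of maximal power of the count-vector spectrum within `band`
#' (default 5-100 Hz, keeping clear of the DC-adjacent bins).
#'
#' @inheritParams spike_spectrum
#' @param band frequency band searched (Hz)
#' @return peak frequency (Hz); `NA` for a flat (zero-power) spectrum
#' @export
network_frequency <- function(y, dt_bin = 5, band = c(5, 100)) {
  sp <- spike_spectrum(y, dt_bin)
  sel <- sp$freq >= band[1] & sp$freq <= band[2]
  if (!any(sel) || max(sp$power[sel]) <= 0) return(NA_real_)
  sp$freq[sel][which.max(sp$power[sel])]
}

#' Normalized spectral entropy
#'
#' The power spectrum is normalized to unit sum and treated as a probability
#' distribution over frequency; its Shannon entropy, divided by `log2` of the
#' number of frequency points, gives a value in `[0, 1]`: 0 for a pure
#' oscillation (single spectral line), 1 for white noise (flat spectrum).
#'
#' @inheritParams spike_spectrum
#' @return entropy in `[0, 1]`; `NA` when total power is zero
#' @export
spectral_entropy <- function(y, dt_bin = 5) {
  sp <- spike_spectrum(y, dt_bin)
  tot <- sum(sp$power)
  if (tot <= 0) return(NA_real_)
  p <- sp$power / tot
  p <- p[p > 0]
  -sum(p * log2(p)) / log2(nrow(sp))
}

#' Propagation signal-to-noise ratio
#'
#' Variance of a layer's summed excitatory count vector in the stimulation
#' window divided by its variance during ongoing activity before the
#' stimulus. An SNR of about 1 means the stimulus left no trace; values
#' >= 4 mark successful propagation.
#'
#' @param spikes a `spike_data`
#' @param layer layer index
#' @param t_inject packet injection time (ms)
#' @param stim_len stimulation window length (ms), starting at `t_inject`
#' @param ongoing_len,gap the ongoing window is
#'   `[t_inject - gap - ongoing_len, t_inject - gap)`
#' @param dt_bin bin width (ms)
#' @return the SNR; `NA` if the ongoing variance is zero
#' @export
snr <- function(spikes, layer, t_inject, stim_len = 300,
                ongoing_len = 1000, gap = 100, dt_bin = 5) {
  t0 <- t_inject - gap - ongoing_len
  if (t0 < spikes$t_start)
    stop("ongoing window starts before the recording", call. = FALSE)
  if (t_inject + stim_len > spikes$t_end + 1e-9)
    stop("stimulation window exceeds the recording", call. = FALSE)
  y_ong <- layer_counts(spikes, layer, c(t0, t_inject - gap), dt_bin)
  y_stim <- layer_counts(spikes, layer, c(t_inject, t_inject + stim_len), dt_bin)
  v <- stats::var(y_ong)
  if (v == 0) return(NA_real_)
  stats::var(y_stim) / v
}

#' Duration of the evoked oscillation, in cycles
#'
#' Operationalizes "how long the stimulus-evoked oscillation lasts": the
#' layer's population rate (1 ms bins) is band-pass filtered around the
#' resonance (2nd-order Butterworth, zero-phase), the peak-to-trough
#' amplitude is measured in consecutive cycles of length `1/f0` starting at
#' the injection time, and cycles are counted while the amplitude stays above
#' a baseline threshold (the `q`-quantile of per-cycle amplitudes during
#' ongoing activity). Returns 0 when the first cycle already fails, so pure
#' background noise yields 0 by construction.
#'
#' @inheritParams snr
#' @param f0 oscillation frequency defining the cycle length (Hz)
#' @param band band-pass edges (Hz)
#' @param q baseline quantile defining the amplitude threshold
#' @param dt_bin rate bin width (ms; 1 ms recommended)
#' @return number of complete cycles (integer >= 0)
#' @export
oscillation_duration <- function(spikes, layer, t_inject, f0 = 40,
                                 band = c(20, 60), q = 0.99,
                                 ongoing_len = 1000, gap = 100, dt_bin = 1) {
  stopifnot(f0 > 0)
  cyc <- 1000 / f0                       # cycle length, ms
  t0 <- max(spikes$t_start, t_inject - gap - ongoing_len)
  y <- layer_counts(spikes, layer, c(t0, spikes$t_end), dt_bin)
  fs <- 1000 / dt_bin
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  yf <- signal::filtfilt(bf, y - mean(y))
  tt <- t0 + dt_bin * (seq_along(yf) - 0.5)

  cycle_amp <- function(from) {
    sel <- tt >= from & tt < from + cyc
    if (sum(sel) < 2) return(NA_real_)
    max(yf[sel]) - min(yf[sel])
  }
  ong_starts <- seq(t0, t_inject - gap - cyc, by = cyc)
  amps <- vapply(ong_starts, cycle_amp, 0)
  thr <- stats::quantile(amps[!is.na(amps)], q, names = FALSE)

  n_cycles <- 0L
  from <- t_inject
  repeat {
    a <- cycle_amp(from)
    if (is.na(a) || a <= thr) break
    n_cycles <- n_cycles + 1L
    from <- from + cyc
  }
  n_cycles
}

#' Propagation latency
#'
#' Time after injection at which a layer's summed excitatory count first
#' exceeds `mean + k * sd` of its ongoing count distribution (bin centers are
#' reported). `NA` signals that the layer never responded.
#'
#' @inheritParams snr
#' @param k threshold in ongoing standard deviations
#' @return latency (ms) or `NA`
#' @export
propagation_latency <- function(spikes, layer, t_inject, k = 5,
                                ongoing_len = 1000, gap = 100, dt_bin = 5) {
  t0 <- max(spikes$t_start, t_inject - gap - ongoing_len)
  y_ong <- layer_counts(spikes, layer, c(t0, t_inject - gap), dt_bin)
  thr <- mean(y_ong) + k * stats::sd(y_ong)
  y_post <- layer_counts(spikes, layer, c(t_inject, spikes$t_end), dt_bin)
  hit <- which(y_post > thr)
  if (length(hit) == 0) return(NA_real_)
  (hit[1] - 0.5) * dt_bin
}

#' Inter-spike-interval variability and firing rates
#'
#' `cv_isi()` returns the coefficient of variation (sd/mean) of each
#' neuron's inter-spike intervals; neurons with fewer than two intervals are
#' excluded and counted. `firing_rates()` returns each neuron's spike count
#' divided by the window length.
#'
#' @param spikes a `spike_data`
#' @param ids 0-based neuron ids (default: all with membership of `pop`)
#' @param pop population filter when `ids` is `NULL`
#' @param window `c(t0, t1)` (ms); default: the whole recording
#' @return `cv_isi()`: data frame (`id`, `cv`) with attribute `n_excluded`;
#'   `firing_rates()`: data frame (`id`, `rate`) in spikes/s
#' @export
cv_isi <- function(spikes, ids = NULL, pop = "E", window = NULL) {
  if (is.null(ids)) {
    m <- spikes$membership
    ids <- if (pop == "all") m$id else m$id[m$pop == pop]
  }
  if (is.null(window)) window <- c(spikes$t_start, spikes$t_end)
  sel <- spikes$id %in% ids & spikes$time >= window[1] & spikes$time < window[2]
  by_id <- split(spikes$time[sel], spikes$id[sel])
  cvs <- vapply(by_id, function(tt) {
    if (length(tt) < 3) return(NA_real_)
    isi <- diff(sort(tt))
    stats::sd(isi) / mean(isi)
  }, 0)
  ok <- !is.na(cvs)
  out <- data.frame(id = as.integer(names(by_id))[ok], cv = unname(cvs[ok]))
  attr(out, "n_excluded") <- length(ids) - sum(ok)
  out
}

#' @rdname cv_isi
#' @export
firing_rates <- function(spikes, ids = NULL, pop = "E", window = NULL) {
  if (is.null(ids)) {
    m <- spikes$membership
    ids <- if (pop == "all") m$id else m$id[m$pop == pop]
  }
  if (is.null(window)) window <- c(spikes$t_start, spikes$t_end)
  sel <- spikes$id %in% ids & spikes$time >= window[1] & spikes$time < window[2]
  n <- tabulate(match(spikes$id[sel], ids), nbins = length(ids))
  data.frame(id = ids, rate = n / (window[2] - window[1]) * 1000)
}

#' Per-layer statistics report
#'
#' Computes, for each layer's excitatory population over one window: mean
#' firing rate, population Fano factor, spectral entropy, network frequency,
#' and the mean pairwise count correlation.
#'
#' @inheritParams bin_spikes
#' @param corr_sample number of neurons used for the pairwise-correlation
#'   estimate (pairs grow quadratically; a subsample keeps the cost bounded)
#' @return data frame with one row per layer
#' @export
summarize_layers <- function(spikes, window, dt_bin = 5, layers = NULL,
                             corr_sample = 100) {
  m <- spikes$membership
  if (is.null(layers)) layers <- sort(unique(m$layer))
  rows <- lapply(layers, function(l) {
    ids <- m$id[m$layer == l & m$pop == "E"]
    y <- layer_counts(spikes, l, window, dt_bin)
    rate <- mean(firing_rates(spikes, ids = ids, window = window)$rate)
    sub <- if (length(ids) > corr_sample) sort(sample(ids, corr_sample)) else ids
    cmn <- bin_spikes(spikes, window, dt_bin, grouping = "neuron",
                      layers = l, pop = "E")
    cmn$counts <- cmn$counts[cmn$groups %in% sub, , drop = FALSE]
    data.frame(layer = l, rate = rate, pFF = population_fano(y),
               H = spectral_entropy(y, dt_bin),
               f_peak = network_frequency(y, dt_bin),
               r_mean = pairwise_correlation(cmn$counts)$r_mean)
  })
  do.call(rbind, rows)
}

#' Export a statistics report
#'
#' Writes a per-layer statistics table (as returned by [summarize_layers()],
#' possibly with extra keying columns) as a tab-separated file.
#'
#' @param report a data frame
#' @param path output path
#' @export
write_stat_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}
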