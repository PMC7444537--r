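# Stochastic construction of the layered EI network.
#
# Global neuron ids are 0-based and layer-major, excitatory before inhibitory
# within each layer: layer l (1-based) occupies ids
# (l-1)*(N_exc+N_inh) ... l*(N_exc+N_inh)-1.

#' Gaussian delay heterogeneity
#'
#' Draws `n` transmission delays from a Gaussian with mean `base` and standard
#' deviation `cv * base`, truncated below at the integration step so no delay
#' can fall under one step. `cv = 0` returns constant delays.
#'
#' @param base mean delay (ms, > 0)
#' @param cv fractional standard deviation (>= 0)
#' @param n number of draws
#' @param floor lower truncation (ms; the integration step)
#' @return numeric vector of delays (ms)
#' @export
draw_heterogeneous_delays <- function(base, cv, n, floor = 0.1) {
  stopifnot(base > 0, cv >= 0, n >= 0)
  if (cv == 0) return(rep(base, n))
  pmax(stats::rnorm(n, mean = base, sd = cv * base), floor)
}

# Bernoulli(eps) over the ordered (pre, post) grid; returns 0-based local
# index pairs. Used for every connection class (Erdos-Renyi reading of the
# uniform connection probability).
bernoulli_pairs <- function(n_pre, n_post, eps) {
  if (eps <= 0 || n_pre == 0 || n_post == 0)
    return(list(pre = integer(0), post = integer(0)))
  idx <- which(stats::runif(n_pre * n_post) < eps)
  list(pre = (idx - 1L) %% n_pre, post = (idx - 1L) %/% n_pre)
}

connection_block <- function(pre, post, g, class, base_delay, delay_cv, dt_floor = 0.1) {
  n <- length(pre)
  if (n == 0)
    return(data.frame(pre = integer(0), post = integer(0), g_peak = numeric(0),
                      reversal_class = character(0), delay = numeric(0),
                      stringsAsFactors = FALSE))
  data.frame(pre = pre, post = post, g_peak = rep(g, n),
             reversal_class = rep(class, n),
             delay = draw_heterogeneous_delays(base_delay, delay_cv, n, dt_floor),
             stringsAsFactors = FALSE)
}

#' Build a network instance from its specification
#'
#' Realizes the random connectivity of a [network_spec()]: within each layer
#' every ordered neuron pair is connected independently with probability
#' `eps_within` (no self-synapses), with strength and sign determined by the
#' pre/post populations; between consecutive layers each of the `N_proj`
#' randomly chosen projecting excitatory neurons connects to every next-layer
#' excitatory neuron with probability `eps_inter` at the forward strength. For
#' an RPN, `N_proj` layer-2 excitatory neurons -- disjoint from layer 2's
#' forward projectors -- feed back onto `N_proj` randomly chosen layer-1
#' excitatory neurons; any feedback synapse that would make a single neuron
#' pair bidirectional is re-targeted (rejection resampling), so no layer-1/2
#' neuron pair is connected in both directions.
#'
#' Construction is fully reproducible from `spec$seed`, and an FFN and an RPN
#' sharing a seed differ only by the feedback records.
#'
#' @param spec a [network_spec()]
#' @param neuron a [neuron_params()]
#' @param synapse a [synapse_params()]
#' @return an object of class `ctr_network`: list with the spec, parameter
#'   sets, per-neuron `membership` (id, layer, pop), per-layer
#'   `forward_projectors`, RPN `feedback_projectors`/`feedback_targets`, the
#'   flattened `connections` table (pre, post, g_peak, reversal_class, delay)
#'   and derived peak conductances `g`
#' @export
#' @examples
#' net <- build_network(network_spec(n_layers = 2, topology = "FFN", seed = 42))
#' nrow(net$connections)
build_network <- function(spec, neuron = neuron_params(),
                          synapse = synapse_params()) {
  stopifnot(inherits(spec, "network_spec"))
  ly <- spec$layer
  n_e <- ly$N_exc; n_i <- ly$N_inh; n_tot <- n_e + n_i
  n_layers <- spec$n_layers
  n_neurons <- n_layers * n_tot
  g <- class_conductances(neuron, synapse, spec$J_ff, spec$J_fb)
  eps_fb <- if (is.null(spec$eps_fb)) spec$eps_inter else spec$eps_fb

  offset <- function(l) (l - 1L) * n_tot          # global id of first neuron in layer l
  e_ids <- function(l) offset(l) + 0:(n_e - 1L)   # global excitatory ids

  membership <- data.frame(
    id = 0:(n_neurons - 1L),
    layer = rep(seq_len(n_layers), each = n_tot),
    pop = rep(rep(c("E", "I"), c(n_e, n_i)), n_layers),
    stringsAsFactors = FALSE)

  set.seed(spec$seed)
  blocks <- vector("list", 3L * n_layers + 2L)
  bi <- 0L
  forward_projectors <- vector("list", n_layers)

  for (l in seq_len(n_layers)) {
    pp <- bernoulli_pairs(n_tot, n_tot, ly$eps_within)
    keep <- pp$pre != pp$post            # no autapses
    pre_l <- pp$pre[keep]; post_l <- pp$post[keep]
    pre_is_e <- pre_l < n_e; post_is_e <- post_l < n_e
    gg <- ifelse(pre_is_e,
                 ifelse(post_is_e, g$g_ee, g$g_ei),
                 ifelse(post_is_e, g$g_ie, g$g_ii))
    cls <- ifelse(pre_is_e, "exc", "inh")
    n_rec <- length(pre_l)
    bi <- bi + 1L
    blocks[[bi]] <- data.frame(
      pre = offset(l) + pre_l, post = offset(l) + post_l, g_peak = gg,
      reversal_class = cls,
      delay = draw_heterogeneous_delays(synapse$d_within, spec$delay_cv, n_rec),
      stringsAsFactors = FALSE)
    forward_projectors[[l]] <- sort(offset(l) + (sample.int(n_e, ly$N_proj) - 1L))
  }

  for (l in seq_len(max(n_layers - 1L, 0L))) {
    if (l == n_layers) break
    proj <- forward_projectors[[l]]
    pp <- bernoulli_pairs(length(proj), n_e, spec$eps_inter)
    bi <- bi + 1L
    blocks[[bi]] <- connection_block(proj[pp$pre + 1L], offset(l + 1L) + pp$post,
                                     g$g_ff, "exc", spec$d_ff, spec$delay_cv)
  }

  feedback_projectors <- integer(0)
  feedback_targets <- integer(0)
  if (spec$topology == "RPN") {
    # layer-2 neurons that feed back must differ from layer 2's forward projectors
    pool <- setdiff(e_ids(2L), forward_projectors[[2L]])
    feedback_projectors <- sort(sample(pool, ly$N_proj))
    feedback_targets <- sort(sample(e_ids(1L), ly$N_proj))
    pp <- bernoulli_pairs(ly$N_proj, ly$N_proj, eps_fb)
    fb_pre <- feedback_projectors[pp$pre + 1L]
    fb_post <- feedback_targets[pp$post + 1L]
    # forbid neuron-level bidirectional layer-1 <-> layer-2 pairs: re-target
    # any feedback record whose reversed pair exists as a forward record
    ff12 <- blocks[[n_layers + 1L]]           # layer 1 -> layer 2 block
    ff_keys <- paste(ff12$pre, ff12$post)
    conflict <- which(paste(fb_post, fb_pre) %in% ff_keys)
    guard <- 0L
    while (length(conflict) > 0) {
      fb_post[conflict] <- sample(feedback_targets, length(conflict),
                                  replace = TRUE)
      conflict <- conflict[paste(fb_post[conflict], fb_pre[conflict]) %in% ff_keys]
      guard <- guard + 1L
      if (guard > 1000L)
        stop("could not resolve bidirectional feedback conflicts", call. = FALSE)
    }
    bi <- bi + 1L
    blocks[[bi]] <- connection_block(fb_pre, fb_post, g$g_fb, "exc",
                                     spec$d_fb, spec$delay_cv)
  }

  connections <- do.call(rbind, blocks[seq_len(bi)])
  rownames(connections) <- NULL

  structure(list(spec = spec, neuron = neuron, synapse = synapse,
                 n_neurons = n_neurons, membership = membership,
                 forward_projectors = forward_projectors,
                 feedback_projectors = feedback_projectors,
                 feedback_targets = feedback_targets,
                 connections = connections, g = g),
            class = "ctr_network")
}

#' Neuron ids of a layer population
#'
#' @param network a `ctr_network`
#' @param layer layer index (1-based)
#' @param pop `"E"`, `"I"`, or `"all"`
#' @return 0-based global neuron ids
#' @export
layer_members <- function(network, layer, pop = c("E", "I", "all")) {
  pop <- match.arg(pop)
  m <- network$membership
  sel <- m$layer == layer
  if (pop != "all") sel <- sel & m$pop == pop
  m$id[sel]
}

#' @export
print.ctr_network <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<ctr_network> %s: %d layers x (%dE + %dI), %d synapses\n",
              s$topology, s$n_layers, s$layer$N_exc, s$layer$N_inh,
              nrow(x$connections)))
  invisible(x)
}

#' Read and write network specifications and connection tables
#'
#' A `network_spec` round-trips through a flat `key = value` text file; a
#' connection table through a 5-column tab-separated file with columns
#' `pre`, `post`, `g_peak_nS`, `reversal_class`, `delay_ms`.
#'
#' @param spec a [network_spec()]
#' @param path file path
#' @return `read_network_spec()` returns a `network_spec`;
#'   `read_connections()` a connection data frame; the writers return their
#'   input invisibly
#' @export
write_network_spec <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  ly <- spec$layer
  kv <- c(n_layers = spec$n_layers, N_exc = ly$N_exc, N_inh = ly$N_inh,
          N_proj = ly$N_proj, eps_within = ly$eps_within,
          eps_inter = spec$eps_inter, topology = spec$topology,
          d_ff = spec$d_ff,
          d_fb = if (is.null(spec$d_fb)) "NA" else spec$d_fb,
          J_ff = if (is.null(spec$J_ff)) "NA" else spec$J_ff,
          eps_fb = if (is.null(spec$eps_fb)) "NA" else spec$eps_fb,
          J_fb = if (is.null(spec$J_fb)) "NA" else spec$J_fb,
          delay_cv = spec$delay_cv, seed = spec$seed)
  writeLines(paste(names(kv), kv, sep = " = "), path)
  invisible(spec)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[[1]]), "")
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = "=")), "")
  names(vals) <- keys
  num <- function(k) {
    v <- vals[[k]]
    if (identical(v, "NA")) NULL else as.numeric(v)
  }
  network_spec(
    n_layers = as.integer(vals[["n_layers"]]),
    layer = layer_spec(as.integer(vals[["N_exc"]]), as.integer(vals[["N_inh"]]),
                       as.integer(vals[["N_proj"]]), as.numeric(vals[["eps_within"]])),
    eps_inter = as.numeric(vals[["eps_inter"]]), topology = vals[["topology"]],
    d_ff = num("d_ff"), d_fb = num("d_fb"), J_ff = num("J_ff"),
    eps_fb = num("eps_fb"), J_fb = num("J_fb"),
    delay_cv = as.numeric(vals[["delay_cv"]]), seed = as.integer(vals[["seed"]]))
}

#' @rdname write_network_spec
#' @param network a `ctr_network` (or a bare connection data frame)
#' @export
write_connections <- function(network, path) {
  con <- if (inherits(network, "ctr_network")) network$connections else network
  out <- data.frame(pre = con$pre, post = con$post, g_peak_nS = con$g_peak,
                    reversal_class = con$reversal_class, delay_ms = con$delay)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(network)
}

#' @rdname write_network_spec
#' @export
read_connections <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  data.frame(pre = as.integer(d$pre), post = as.integer(d$post),
             g_peak = d$g_peak_nS, reversal_class = d$reversal_class,
             delay = d$delay_ms, stringsAsFactors = FALSE)
}
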