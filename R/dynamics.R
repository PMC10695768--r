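new_spike_trains <- function(tbl, n_neurons, duration, population = "CA3") {
  structure(tbl, n_neurons = as.integer(n_neurons),
            duration = as.numeric(duration), population = population,
            class = c("msb_spike_trains", class(tibble::tibble())))
}

#' @export
print.msb_spike_trains <- function(x, ...) {
  cat(sprintf("%s spike trains: %d neurons, %g s, %d spikes (%.2f Hz mean)\n",
              attr(x, "population"), attr(x, "n_neurons"),
              attr(x, "duration"), nrow(x),
              nrow(x) / (attr(x, "n_neurons") * max(attr(x, "duration"),
                                                    .Machine$double.eps))))
  NextMethod()
}

#' Generate independent Poisson spike trains
#'
#' Models the CA3/2 source population: each neuron fires as an independent
#' homogeneous Poisson process.
#'
#' @param n Number of neurons.
#' @param rate Firing rate, Hz (default 10).
#' @param duration Train length, seconds.
#' @return An `msb_spike_trains` tibble with columns `neuron_id` and `time`
#'   (seconds, strictly increasing within a neuron).
#' @examples
#' set.seed(1)
#' tr <- generate_poisson_trains(100, rate = 10, duration = 50)
#' nrow(tr) / (100 * 50)  # ~10 Hz
#' @export
generate_poisson_trains <- function(n, rate = 10, duration) {
  if (rate < 0 || duration < 0) {
    abort("`rate` and `duration` must be non-negative.",
          class = "msbnet_config_error")
  }
  counts <- stats::rpois(n, rate * duration)
  times <- runif(sum(counts), 0, duration)
  tbl <- tibble::tibble(neuron_id = rep(seq_len(n), counts), time = times)
  tbl <- dplyr::arrange(tbl, .data$neuron_id, .data$time)
  new_spike_trains(tbl, n, duration, "CA3")
}

#' Thin a spike train by Bernoulli sampling
#'
#' Each spike is kept independently with probability `p`, preserving order.
#' This is how stochastic vesicle release at an active zone samples its
#' bouton's presynaptic train: active zones of one bouton share `p` but each
#' draws its own realisation.
#'
#' @param train Numeric vector of spike times.
#' @param p Retention probability in \[0, 1\].
#' @return The retained spike times.
#' @export
thin_train <- function(train, p) {
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    abort("`p` must be a single probability in [0, 1].",
          class = "msbnet_config_error")
  }
  if (p == 1) return(train)
  if (p == 0) return(train[0])
  train[runif(length(train)) < p]
}

spike_list <- function(trains, n) {
  out <- vector("list", n)
  split_idx <- split(trains$time, factor(trains$neuron_id, levels = seq_len(n)))
  for (i in seq_len(n)) out[[i]] <- as.numeric(split_idx[[i]])
  out
}

#' Simulate the CA1 population
#'
#' Clock-driven leaky integrate-and-fire simulation of the CA1 neurons
#' driven by the connectivity graph and the CA3/2 spike trains. Every active
#' zone independently thins its bouton's train with the bouton's release
#' probability; transmitted spikes arrive after a fixed delay and inject
#' either a static exponential PSC (`stp_type == "static"`) or the
#' Tsodyks-Markram release current A u x of the facilitating/depressing
#' preset. Membrane and synaptic states advance with exact exponential
#' propagators at fixed step `dt`; background noise is redrawn per neuron
#' every `noise$update_interval` ms.
#'
#' @param graph An `msb_graph` (see [build_connectivity()]).
#' @param ca3_trains Source spike trains covering at least `duration`
#'   seconds for `spec$n_ca3` neurons.
#' @param neuron,noise Parameter sets ([neuron_params()], [noise_params()]).
#' @param facil,depress STP presets used for plastic boutons.
#' @param duration Simulated time, seconds (default: the graph spec's).
#' @param dt Step, ms (default: the graph spec's, 0.1).
#' @param delay Synaptic transmission delay, ms (default 1).
#' @param record Optional CA1 neuron id whose membrane potential and
#'   synaptic current are recorded each step.
#' @return An `msb_spike_trains` tibble of CA1 spikes; when `record` is set,
#'   attributes `v_trace` and `i_trace` hold the per-step traces (mV, pA) of
#'   that neuron.
#' @export
simulate_ca1 <- function(graph, ca3_trains, neuron = neuron_params(),
                         noise = noise_params(),
                         facil = stp_facilitating(), depress = stp_depressing(),
                         duration = NULL, dt = NULL, delay = 1,
                         record = NULL) {
  spec <- attr(graph, "spec")
  if (is.null(duration)) duration <- spec$sim_duration
  if (is.null(dt)) dt <- spec$dt
  if (max(graph$source_neuron) > spec$n_ca3 ||
      (nrow(ca3_trains) > 0 && max(ca3_trains$neuron_id) > spec$n_ca3)) {
    abort("Graph and source trains disagree on the number of CA3/2 neurons.",
          class = "msbnet_input_error")
  }
  if (facil$tau_syn != neuron$tau_syn || depress$tau_syn != neuron$tau_syn) {
    abort("All synapse types must share `tau_syn` (single aggregated PSC state per neuron).",
          class = "msbnet_config_error")
  }

  src <- spike_list(ca3_trains, spec$n_ca3)
  az <- tibble::as_tibble(graph)
  n_az <- nrow(az)

  # independent Bernoulli release realisation per active zone
  az_trains <- vector("list", n_az)
  for (k in seq_len(n_az)) {
    az_trains[[k]] <- thin_train(src[[az$source_neuron[k]]], az$p[k])
  }

  steps <- as.integer(round(duration * 1000 / dt))
  ev_step <- lapply(az_trains, function(tt) {
    s <- as.integer(round((tt * 1000 + delay) / dt))
    s[s < steps]
  })
  n_ev <- lengths(ev_step)
  event_az <- rep.int(seq_len(n_az) - 1L, n_ev)
  event_step <- unlist(ev_step, use.names = FALSE)
  if (is.null(event_step)) event_step <- integer(0)
  ord <- order(event_step)
  event_step <- event_step[ord]
  event_az <- event_az[ord]

  plastic <- as.integer(az$stp_type != "static")
  az_a <- ifelse(az$stp_type == "facilitating", facil$a,
                 ifelse(az$stp_type == "depressing", depress$a,
                        neuron$a_static))
  az_u <- ifelse(az$stp_type == "facilitating", facil$u_base,
                 ifelse(az$stp_type == "depressing", depress$u_base, 0))
  az_tr <- ifelse(az$stp_type == "facilitating", facil$tau_rec,
                  ifelse(az$stp_type == "depressing", depress$tau_rec, 1))
  az_tf <- ifelse(az$stp_type == "facilitating", facil$tau_fac,
                  ifelse(az$stp_type == "depressing", depress$tau_fac, 0))

  res <- lif_network_run(
    event_step, event_az,
    as.integer(az$target_neuron) - 1L, plastic,
    as.numeric(az_a), as.numeric(az_u), as.numeric(az_tr), as.numeric(az_tf),
    spec$n_ca1, steps, dt,
    neuron$tau_m, neuron$r_in, neuron$v_th, neuron$v_reset,
    as.integer(round(neuron$t_ref / dt)), neuron$tau_syn,
    noise$mu_b, noise$sigma_b,
    max(1L, as.integer(round(noise$update_interval / dt))),
    if (is.null(record)) -1L else as.integer(record) - 1L
  )

  counts <- lengths(res$spikes)
  out <- tibble::tibble(
    neuron_id = rep(seq_len(spec$n_ca1), counts),
    time = unlist(res$spikes, use.names = FALSE) %||% numeric(0)
  )
  out <- new_spike_trains(out, spec$n_ca1, duration, "CA1")
  if (!is.null(record)) {
    attr(out, "v_trace") <- res$v_trace
    attr(out, "i_trace") <- res$i_trace
    attr(out, "trace_dt") <- dt
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# read_tsv without the reader metadata (col spec / problems) attached, so
# round-tripped tables compare clean against their in-memory originals
read_tsv_plain <- function(path, col_types = NULL) {
  tbl <- readr::read_tsv(path, col_types = col_types, show_col_types = FALSE)
  attr(tbl, "spec") <- NULL
  attr(tbl, "problems") <- NULL
  tbl
}

#' Read and write spike trains as delimited text
#'
#' Two-column TSV (`neuron_id`, `time` in seconds).
#'
#' @param trains An `msb_spike_trains` (or any tibble with those columns).
#' @param path File path.
#' @param n_neurons,duration,population Metadata restored on read.
#' @return `write_spike_trains()` returns `path` invisibly;
#'   `read_spike_trains()` the `msb_spike_trains`.
#' @export
write_spike_trains <- function(trains, path) {
  readr::write_tsv(tibble::as_tibble(trains)[c("neuron_id", "time")], path)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path, n_neurons, duration, population = "CA3") {
  tbl <- read_tsv_plain(path, col_types = "id")
  new_spike_trains(tbl, n_neurons, duration, population)
}
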