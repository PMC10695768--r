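#' Network specification for the CA3/2 -> CA1 model
#'
#' Defines the architecture of the feed-forward hippocampal model: each of
#' `n_ca3` Poisson source neurons projects `boutons_per_neuron` boutons onto
#' the CA1 population, split between the stratum oriens (SO, basal dendrites)
#' and the stratum radiatum (SR, apical dendrites). Simulations run for
#' `sim_duration` seconds and correlations are computed over the trailing
#' `analysis_window` seconds, so the leading transient is discarded.
#'
#' @param n_ca1,n_ca3 Population sizes (default 100 each).
#' @param boutons_per_neuron Boutons per CA3/2 neuron (default 12).
#' @param boutons_so,boutons_sr How the boutons split between SO and SR
#'   (defaults 5 and 7; must sum to `boutons_per_neuron`).
#' @param sim_duration Simulated time, seconds (default 51).
#' @param analysis_window Trailing window used for analysis, seconds
#'   (default 50).
#' @param dt Integration step, milliseconds (default 0.1).
#' @param rate Source firing rate, Hz (default 10).
#' @return An object of class `msb_network_spec`.
#' @examples
#' network_spec()
#' network_spec(sim_duration = 11, analysis_window = 10)
#' @export
network_spec <- function(n_ca1 = 100, n_ca3 = 100, boutons_per_neuron = 12,
                         boutons_so = 5, boutons_sr = 7,
                         sim_duration = 51, analysis_window = 50,
                         dt = 0.1, rate = 10) {
  spec <- list(
    n_ca1 = as.integer(n_ca1), n_ca3 = as.integer(n_ca3),
    boutons_per_neuron = as.integer(boutons_per_neuron),
    boutons_so = as.integer(boutons_so), boutons_sr = as.integer(boutons_sr),
    sim_duration = as.numeric(sim_duration),
    analysis_window = as.numeric(analysis_window),
    dt = as.numeric(dt), rate = as.numeric(rate)
  )
  if (spec$boutons_so + spec$boutons_sr != spec$boutons_per_neuron) {
    abort("`boutons_so + boutons_sr` must equal `boutons_per_neuron`.",
          class = "msbnet_config_error")
  }
  if (spec$n_ca1 < 1 || spec$n_ca3 < 1 || spec$boutons_per_neuron < 1 ||
      spec$sim_duration <= 0 || spec$dt <= 0 || spec$rate < 0 ||
      spec$analysis_window <= 0 || spec$analysis_window > spec$sim_duration) {
    abort("Invalid network specification.", class = "msbnet_config_error")
  }
  structure(spec, class = "msb_network_spec")
}

#' @export
print.msb_network_spec <- function(x, ...) {
  cat(sprintf(
    "CA3/2 -> CA1 network spec: %d sources -> %d targets, %d boutons/source (%d SO + %d SR)\n",
    x$n_ca3, x$n_ca1, x$boutons_per_neuron, x$boutons_so, x$boutons_sr))
  cat(sprintf("  %g s simulated, last %g s analysed, dt = %g ms, rate = %g Hz\n",
              x$sim_duration, x$analysis_window, x$dt, x$rate))
  invisible(x)
}

new_msb_graph <- function(az, spec, condition) {
  structure(az, spec = spec, condition = condition,
            class = c("msb_graph", class(tibble::tibble())))
}

#' @export
print.msb_graph <- function(x, ...) {
  spec <- attr(x, "spec")
  nb <- dplyr::n_distinct(x$bouton_id)
  cat(sprintf("Connectivity graph [%s]: %d boutons, %d active zones\n",
              attr(x, "condition"), nb, nrow(x)))
  NextMethod()
}

# Draw a distinct CA1 target set for every bouton. alpha == 1 boutons are
# drawn in one vectorised call; multi-AZ boutons need per-bouton sampling
# without replacement.
draw_targets <- function(alpha, n_ca1) {
  if (any(alpha > n_ca1)) {
    abort(paste0("A bouton has more active zones (", max(alpha),
                 ") than there are CA1 neurons (", n_ca1,
                 "); distinct targets are impossible."),
          class = "msbnet_config_error")
  }
  targets <- vector("list", length(alpha))
  single <- alpha == 1L
  targets[single] <- as.list(sample.int(n_ca1, sum(single), replace = TRUE))
  for (i in which(!single)) {
    targets[[i]] <- sample.int(n_ca1, alpha[i])
  }
  targets
}

bouton_block <- function(spec, stratum, n_boutons, is_msb, dist) {
  n_total <- spec$n_ca3 * n_boutons
  alpha <- if (is_msb) sample_az_counts(n_total, dist) else rep(1L, n_total)
  tibble::tibble(
    source_neuron = rep(seq_len(spec$n_ca3), each = n_boutons),
    stratum = stratum,
    az_count = as.integer(alpha),
    target = draw_targets(alpha, spec$n_ca1)
  )
}

finish_graph <- function(boutons, spec, condition) {
  boutons$bouton_id <- seq_len(nrow(boutons))
  az <- tidyr::unnest(boutons, "target")
  az <- dplyr::mutate(
    dplyr::group_by(az, .data$bouton_id),
    az_index = dplyr::row_number(),
    .after = "az_count"
  )
  az <- dplyr::ungroup(az)
  az <- dplyr::rename(az, target_neuron = "target")
  az <- dplyr::relocate(az, "bouton_id")
  az$p <- 1
  az$stp_type <- "static"
  new_msb_graph(az, spec, condition)
}

#' Build the CA3/2 -> CA1 connectivity graph
#'
#' Constructs the bouton-centric wiring for one of the four connectivity
#' conditions: all inputs single-synaptic (`"ssb_all"`), MSBs only in the
#' stratum oriens (`"msb_so"`), only in the stratum radiatum (`"msb_sr"`), or
#' in both layers (`"msb_all"`). In an MSB-flagged layer every bouton draws
#' its active-zone count from that layer's distribution; in an SSB layer
#' every bouton has exactly one. Each active zone targets a uniformly random
#' CA1 neuron, distinct within a bouton, so one MSB contacts several
#' different cells.
#'
#' The returned graph has one row per active zone with columns `bouton_id`,
#' `source_neuron`, `stratum`, `az_count`, `az_index`, `target_neuron`, `p`
#' (release probability, initialised to 1) and `stp_type` (initialised to
#' `"static"`); see [sample_release_probabilities()] and [assign_stp_types()].
#'
#' @param spec A [network_spec()].
#' @param condition One of `"ssb_all"`, `"msb_so"`, `"msb_sr"`, `"msb_all"`.
#' @param so_dist,sr_dist Active-zone count distributions for the two layers.
#' @return An `msb_graph` tibble.
#' @examples
#' set.seed(7)
#' g <- build_connectivity(network_spec(), "msb_all")
#' dplyr::count(dplyr::distinct(g, bouton_id, stratum, az_count), stratum,
#'              msb = az_count >= 2)
#' @export
build_connectivity <- function(spec, condition = c("ssb_all", "msb_so",
                                                   "msb_sr", "msb_all"),
                               so_dist = az_dist_so(), sr_dist = az_dist_sr()) {
  condition <- match.arg(condition)
  so_msb <- condition %in% c("msb_so", "msb_all")
  sr_msb <- condition %in% c("msb_sr", "msb_all")
  per_neuron <- dplyr::bind_rows(
    bouton_block(spec, "so", spec$boutons_so, so_msb, so_dist),
    bouton_block(spec, "sr", spec$boutons_sr, sr_msb, sr_dist)
  )
  per_neuron <- dplyr::arrange(per_neuron, .data$source_neuron, .data$stratum)
  finish_graph(per_neuron, spec, condition)
}

bouton_table <- function(graph) {
  dplyr::distinct(tibble::as_tibble(graph), .data$bouton_id,
                  .data$source_neuron, .data$stratum, .data$az_count,
                  .data$p, .data$stp_type)
}

join_bouton_values <- function(graph, values) {
  az <- tibble::as_tibble(graph)
  for (col in setdiff(names(values), "bouton_id")) {
    az[[col]] <- values[[col]][match(az$bouton_id, values$bouton_id)]
  }
  new_msb_graph(az, attr(graph, "spec"), attr(graph, "condition"))
}

#' Assign per-bouton release probabilities
#'
#' Draws one release probability per bouton from a Gamma distribution
#' (default shape k = 2, scale 0.15) clipped at 1; every active zone of a
#' bouton inherits the bouton's value, but samples its own independent
#' realisation of vesicle release during simulation.
#'
#' @param graph An `msb_graph`.
#' @param shape,scale Gamma parameters (defaults 2 and 0.15).
#' @return The graph with column `p` replaced.
#' @examples
#' set.seed(1)
#' g <- sample_release_probabilities(build_connectivity(network_spec(), "ssb_all"))
#' range(g$p)
#' @export
sample_release_probabilities <- function(graph, shape = 2, scale = 0.15) {
  if (shape <= 0 || scale <= 0) {
    abort("Gamma `shape` and `scale` must be positive.",
          class = "msbnet_config_error")
  }
  b <- dplyr::distinct(tibble::as_tibble(graph), .data$bouton_id)
  b$p <- pmin(rgamma(nrow(b), shape = shape, scale = scale), 1)
  join_bouton_values(graph, b)
}

#' Assign short-term plasticity types to boutons
#'
#' Each bouton is facilitating, depressing, or static (no STP); the identity
#' is shared by all active zones of the bouton. Under `"independent"` each
#' bouton is facilitating with probability `facil_fraction` irrespective of
#' its release probability; under `"matched"` boutons with release
#' probability above `threshold` (default: the median of the assigned values)
#' are depressing and the rest facilitating, pairing high-Pr synapses with
#' depression and low-Pr synapses with facilitation; `"none"` makes every
#' bouton static.
#'
#' @param graph An `msb_graph`.
#' @param scheme `"independent"`, `"matched"` or `"none"`.
#' @param facil_fraction Probability a bouton facilitates under
#'   `"independent"` (default 0.5).
#' @param threshold Release-probability cut for `"matched"`; `NULL` uses the
#'   median of the graph's `p`.
#' @return The graph with column `stp_type` replaced.
#' @export
assign_stp_types <- function(graph, scheme = c("independent", "matched", "none"),
                             facil_fraction = 0.5, threshold = NULL) {
  scheme <- match.arg(scheme)
  b <- dplyr::distinct(tibble::as_tibble(graph), .data$bouton_id, .data$p)
  if (scheme == "none") {
    b$stp_type <- "static"
  } else if (scheme == "independent") {
    b$stp_type <- ifelse(runif(nrow(b)) < facil_fraction,
                         "facilitating", "depressing")
  } else {
    if (dplyr::n_distinct(b$p) == 1L && b$p[1] == 1) {
      abort("`matched` STP assignment needs release probabilities; call `sample_release_probabilities()` first.",
            class = "msbnet_order_error")
    }
    if (is.null(threshold)) threshold <- median(b$p)
    b$stp_type <- ifelse(b$p > threshold, "depressing", "facilitating")
  }
  join_bouton_values(graph, b[c("bouton_id", "stp_type")])
}

#' Build a single-mechanism connectivity variant
#'
#' Isolates one of the three candidate mechanisms by which MSBs could raise
#' CA1 correlations:
#' \describe{
#'   \item{`"multiplicative_only"`}{the stratified connectivity of
#'     [build_connectivity()] (condition `"msb_all"` when `msb = TRUE`, else
#'     `"ssb_all"`) with every release probability forced to 1 and no STP --
#'     only the one-spike-to-many-targets copying remains.}
#'   \item{`"release_only"`}{each source neuron has either 5 single-AZ
#'     boutons (`msb = FALSE`) or 1 bouton with 5 active zones (`msb = TRUE`),
#'     Gamma-distributed release probabilities and no STP -- active zones of
#'     one bouton share p, so only shared stochastic release differs.}
#'   \item{`"stp_only"`}{the same 5-vs-1 layout with p = 1 and STP types
#'     assigned -- only the shared facilitation/depression identity differs.}
#' }
#'
#' @param spec A [network_spec()]; `boutons_per_neuron` is ignored by the
#'   5-vs-1 layouts.
#' @param variant `"multiplicative_only"`, `"release_only"` or `"stp_only"`.
#' @param msb Logical; build the MSB (`TRUE`) or SSB (`FALSE`) scenario.
#' @param so_dist,sr_dist Layer distributions for `"multiplicative_only"`.
#' @param stp_scheme,facil_fraction Passed to [assign_stp_types()] for
#'   `"stp_only"`.
#' @return An `msb_graph`.
#' @export
build_mechanism_variant <- function(spec,
                                    variant = c("multiplicative_only",
                                                "release_only", "stp_only"),
                                    msb = TRUE,
                                    so_dist = az_dist_so(),
                                    sr_dist = az_dist_sr(),
                                    stp_scheme = "independent",
                                    facil_fraction = 0.5) {
  variant <- match.arg(variant)
  if (variant == "multiplicative_only") {
    g <- build_connectivity(spec, if (msb) "msb_all" else "ssb_all",
                            so_dist, sr_dist)
    attr(g, "condition") <- paste0("multiplicative_only_",
                                   if (msb) "msb" else "ssb")
    return(g)
  }
  alpha <- if (msb) rep(5L, spec$n_ca3) else rep(1L, spec$n_ca3 * 5L)
  per <- tibble::tibble(
    source_neuron = if (msb) seq_len(spec$n_ca3)
                    else rep(seq_len(spec$n_ca3), each = 5L),
    stratum = "none",
    az_count = alpha,
    target = draw_targets(alpha, spec$n_ca1)
  )
  g <- finish_graph(per, spec,
                    paste0(variant, "_", if (msb) "msb" else "ssb"))
  if (variant == "release_only") {
    g <- sample_release_probabilities(g)
  } else {
    g <- assign_stp_types(g, scheme = stp_scheme,
                          facil_fraction = facil_fraction)
  }
  attr(g, "condition") <- paste0(variant, "_", if (msb) "msb" else "ssb")
  g
}

#' Read and write connectivity graphs
#'
#' The on-disk form is a TSV with one active zone per row plus a JSON sidecar
#' (`<path>.json`) holding the network spec and condition label; the
#' round-trip is lossless.
#'
#' @param graph An `msb_graph`.
#' @param path TSV file path.
#' @return `write_connectivity()` returns `path` invisibly;
#'   `read_connectivity()` returns the `msb_graph`.
#' @export
write_connectivity <- function(graph, path) {
  readr::write_tsv(tibble::as_tibble(graph), path)
  sidecar <- list(spec = unclass(attr(graph, "spec")),
                  condition = attr(graph, "condition"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  az <- read_tsv_plain(path, col_types = readr::cols(
    stratum = readr::col_character(),
    stp_type = readr::col_character(),
    .default = readr::col_guess()))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- do.call(network_spec, side$spec[setdiff(names(side$spec), NULL)])
  new_msb_graph(az, spec, side$condition)
}
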