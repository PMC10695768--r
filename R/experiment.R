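condition_graph <- function(spec, model, condition, msb, stp_scheme,
                            so_dist, sr_dist, facil_fraction) {
  switch(model,
    full = {
      g <- build_connectivity(spec, condition, so_dist, sr_dist)
      g <- sample_release_probabilities(g)
      assign_stp_types(g, scheme = stp_scheme,
                       facil_fraction = facil_fraction)
    },
    multiplicative_only = build_mechanism_variant(
      spec, "multiplicative_only", msb = msb,
      so_dist = so_dist, sr_dist = sr_dist),
    release_only = build_mechanism_variant(spec, "release_only", msb = msb),
    stp_only = build_mechanism_variant(spec, "stp_only", msb = msb,
                                       stp_scheme = stp_scheme,
                                       facil_fraction = facil_fraction),
    abort(paste0("Unknown model '", model, "'."),
          class = "msbnet_config_error")
  )
}

#' Run repeated simulations of one experimental condition
#'
#' Executes `n_runs` independent end-to-end runs of a condition descriptor:
#' build the connectivity (afresh each run unless `fixed_graph`), draw fresh
#' CA3/2 Poisson trains and background noise, simulate CA1, bin the trailing
#' analysis window and compute the mean pairwise correlation mu_cc. Per-run
#' seeds are derived deterministically from `master_seed`, so the whole
#' experiment is reproducible.
#'
#' @param spec A [network_spec()].
#' @param model `"full"` (stratified connectivity, Gamma release
#'   probabilities, STP), `"multiplicative_only"`, `"release_only"` or
#'   `"stp_only"`.
#' @param condition Connectivity condition for stratified models
#'   (`"ssb_all"`, `"msb_so"`, `"msb_sr"`, `"msb_all"`).
#' @param msb Logical MSB/SSB flag for the 5-vs-1 mechanism variants.
#' @param stp_scheme STP assignment scheme where STP applies
#'   (`"independent"` or `"matched"`).
#' @param n_runs Number of independent runs (the reference analysis uses
#'   100).
#' @param master_seed Integer seed governing the whole set of runs.
#' @param fixed_graph If `TRUE`, the connectivity is built once and reused;
#'   only trains, release and noise are redrawn per run.
#' @param bin_ms Correlation bin width, ms (default 20).
#' @param so_dist,sr_dist Layer active-zone count distributions.
#' @param facil_fraction Facilitating fraction under `"independent"`.
#' @param label Condition label recorded in the output (default derived).
#' @return A tibble of class `msb_experiment` with columns `condition`,
#'   `run`, `seed`, `mu_cc`, `excluded_pairs`.
#' @examples
#' \donttest{
#' spec <- network_spec(sim_duration = 6, analysis_window = 5)
#' run_condition(spec, model = "full", condition = "msb_all",
#'               n_runs = 2, master_seed = 1)
#' }
#' @export
run_condition <- function(spec, model = "full", condition = "ssb_all",
                          msb = FALSE, stp_scheme = "independent",
                          n_runs = 100, master_seed = 1,
                          fixed_graph = FALSE, bin_ms = 20,
                          so_dist = az_dist_so(), sr_dist = az_dist_sr(),
                          facil_fraction = 0.5, label = NULL) {
  if (is.null(label)) {
    label <- if (model == "full") {
      if (stp_scheme == "matched") paste0("full_matched_", condition)
      else paste0("full_", condition)
    } else paste0(model, "_", if (msb) "msb" else "ssb")
  }
  set.seed(master_seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  window <- c(spec$sim_duration - spec$analysis_window, spec$sim_duration)
  graph <- NULL
  if (fixed_graph) {
    set.seed(run_seeds[1])
    graph <- condition_graph(spec, model, condition, msb, stp_scheme,
                             so_dist, sr_dist, facil_fraction)
  }
  res <- purrr::map(seq_len(n_runs), function(r) {
    set.seed(run_seeds[r])
    g <- if (fixed_graph) graph
         else condition_graph(spec, model, condition, msb, stp_scheme,
                              so_dist, sr_dist, facil_fraction)
    trains <- generate_poisson_trains(spec$n_ca3, spec$rate,
                                      spec$sim_duration)
    ca1 <- simulate_ca1(g, trains)
    cc <- mean_pairwise_correlation(bin_spike_trains(ca1, bin_ms, window))
    tibble::tibble(condition = label, run = r, seed = run_seeds[r],
                   mu_cc = cc$mu_cc, excluded_pairs = cc$excluded_pairs)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("msb_experiment", class(out))
  out
}

#' Condition grid of the correlation experiment
#'
#' Enumerates the 12 simulated conditions: the four full-model connectivity
#' conditions, SSB/MSB pairs for each of the three single-mechanism
#' variants, and the SSB/MSB pair of the full model with STP matched to
#' release probability.
#'
#' @return A tibble with columns `label`, `model`, `condition`, `msb`,
#'   `stp_scheme`.
#' @export
condition_grid <- function() {
  dplyr::bind_rows(
    tibble::tibble(model = "full",
                   condition = c("ssb_all", "msb_so", "msb_sr", "msb_all"),
                   msb = NA, stp_scheme = "independent"),
    tidyr::expand_grid(model = c("multiplicative_only", "release_only",
                                 "stp_only"),
                       msb = c(FALSE, TRUE)) %>%
      dplyr::mutate(condition = "ssb_all", stp_scheme = "independent"),
    tibble::tibble(model = "full", condition = c("ssb_all", "msb_all"),
                   msb = NA, stp_scheme = "matched")
  ) %>%
    dplyr::mutate(label = dplyr::if_else(
      .data$model == "full",
      paste0(dplyr::if_else(.data$stp_scheme == "matched", "full_matched_",
                            "full_"), .data$condition),
      paste0(.data$model, "_", dplyr::if_else(is.na(.data$msb) | !.data$msb,
                                              "ssb", "msb")))) %>%
    dplyr::relocate("label")
}

#' Run the full correlation experiment grid
#'
#' Runs [run_condition()] for every row of [condition_grid()], deriving one
#' sub-seed per condition from `master_seed`.
#'
#' @inheritParams run_condition
#' @return An `msb_experiment` tibble stacking all conditions.
#' @export
run_experiment_suite <- function(spec, n_runs = 100, master_seed = 1,
                             fixed_graph = FALSE) {
  grid <- condition_grid()
  set.seed(master_seed)
  cond_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  out <- purrr::pmap(
    list(grid$model, grid$condition, grid$msb, grid$stp_scheme, grid$label,
         cond_seeds),
    function(model, condition, msb, stp_scheme, label, seed) {
      run_condition(spec, model = model, condition = condition,
                    msb = isTRUE(msb), stp_scheme = stp_scheme,
                    n_runs = n_runs, master_seed = seed,
                    fixed_graph = fixed_graph, label = label)
    })
  out <- dplyr::bind_rows(out)
  class(out) <- c("msb_experiment", class(out))
  out
}

#' Summarise an experiment result
#'
#' @param x An `msb_experiment` tibble.
#' @param ... Unused.
#' @return One row per condition: mean, SD and quartiles of mu_cc.
#' @export
glance.msb_experiment <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$condition),
    n_runs = dplyr::n(),
    mean_mu_cc = mean(.data$mu_cc, na.rm = TRUE),
    sd_mu_cc = sd(.data$mu_cc, na.rm = TRUE),
    q25 = quantile(.data$mu_cc, 0.25, na.rm = TRUE, names = FALSE),
    median = median(.data$mu_cc, na.rm = TRUE),
    q75 = quantile(.data$mu_cc, 0.75, na.rm = TRUE, names = FALSE),
    .groups = "drop"
  )
}

#' Plot the distribution of mu_cc per condition
#'
#' @param object An `msb_experiment` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msb_experiment <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$condition, y = .data$mu_cc)) +
    ggplot2::geom_violin(fill = "grey85", colour = NA, scale = "width") +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA) +
    ggplot2::labs(x = NULL, y = expression(mu[cc]),
                  title = "Mean pairwise CA1 correlation by condition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}
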