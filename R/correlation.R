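#' Bin spike trains into a count matrix
#'
#' Counts spikes per neuron in consecutive half-open bins `[t, t + bin)`
#' covering the analysis window; spikes outside the window (including one
#' exactly at the window end) are dropped. The canonical analysis uses the
#' last 50 s of a 51 s run with 20 ms bins, i.e. 2500 bins per neuron.
#'
#' @param trains An `msb_spike_trains`.
#' @param bin_ms Bin width, ms (default 20).
#' @param window Length-2 numeric, window start/end in seconds. Default:
#'   the trailing `duration` of the trains starting at 0, i.e. `c(0, duration)`.
#' @return An `msb_binned` object: an integer matrix (neurons x bins) with
#'   attributes `bin_ms` and `window`.
#' @export
bin_spike_trains <- function(trains, bin_ms = 20, window = NULL) {
  duration <- attr(trains, "duration")
  n <- attr(trains, "n_neurons")
  if (is.null(window)) window <- c(0, duration)
  if (bin_ms <= 0) {
    abort("`bin_ms` must be positive.", class = "msbnet_input_error")
  }
  if (length(window) != 2L || window[2] <= window[1]) {
    abort("`window` must be a non-empty interval c(start, end).",
          class = "msbnet_input_error")
  }
  n_bins <- floor((window[2] - window[1]) / (bin_ms / 1000))
  keep <- trains$time >= window[1] &
    trains$time < window[1] + n_bins * bin_ms / 1000
  bin <- floor((trains$time[keep] - window[1]) / (bin_ms / 1000)) + 1L
  id <- trains$neuron_id[keep]
  counts <- matrix(0L, n, n_bins)
  tab <- table(factor(id, levels = seq_len(n)), factor(bin, levels = seq_len(n_bins)))
  counts[] <- as.integer(tab)
  structure(counts, bin_ms = bin_ms, window = window, class = "msb_binned")
}

#' Mean pairwise correlation of binned spike trains
#'
#' Pearson's correlation coefficient between the binned spike counts of
#' every distinct pair of neurons; the synchrony readout mu_cc is the mean
#' over all pairs. Pairs in which either train has zero variance over the
#' window (e.g. a silent neuron) have an undefined coefficient and are
#' excluded from the mean and counted; if every pair is excluded the result
#' is flagged degenerate and mu_cc is `NA`.
#'
#' @param binned An [bin_spike_trains()] result.
#' @return An `msb_correlation` list: `matrix` (neurons x neurons, unit
#'   diagonal), `mu_cc`, `n_pairs`, `excluded_pairs`, `degenerate`.
#' @export
mean_pairwise_correlation <- function(binned) {
  m <- unclass(binned)
  n <- nrow(m)
  if (n < 2) {
    abort("Need at least 2 neurons for pairwise correlation.",
          class = "msbnet_input_error")
  }
  sds <- apply(m, 1, sd)
  cm <- suppressWarnings(cor(t(m)))
  diag(cm) <- 1
  ok <- outer(sds > 0, sds > 0, `&`)
  up <- upper.tri(cm)
  vals <- cm[up & ok]
  excluded <- sum(up & !ok)
  structure(list(
    matrix = cm,
    mu_cc = if (length(vals)) mean(vals) else NA_real_,
    n_pairs = sum(up),
    excluded_pairs = excluded,
    degenerate = length(vals) == 0
  ), class = "msb_correlation")
}

#' @export
print.msb_correlation <- function(x, ...) {
  cat(sprintf("mu_cc = %s over %d pairs (%d excluded%s)\n",
              format(x$mu_cc, digits = 4), x$n_pairs - x$excluded_pairs,
              x$excluded_pairs, if (x$degenerate) "; DEGENERATE" else ""))
  invisible(x)
}
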