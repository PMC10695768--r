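#' Active-zone count distributions
#'
#' A bouton carries between 1 and 5 active zones (AZs); boutons with two or
#' more are multi-synaptic boutons (MSBs). The per-count probabilities differ
#' between the two CA1 input layers: in the stratum oriens roughly 45% of
#' boutons are MSBs and boutons with more than 3 contacts make up about 15%,
#' while in the stratum radiatum the MSB fraction is about 25% with the
#' multi-contact shape rescaled from the oriens distribution.
#'
#' `az_count_distribution()` validates an arbitrary probability vector over
#' counts 1..5; `az_dist_so()` and `az_dist_sr()` return the default layer
#' distributions.
#'
#' @param probs Numeric vector of length 5: probabilities of a bouton having
#'   1, 2, 3, 4 or 5 active zones. Must be non-negative and sum to 1.
#'
#' @return An `msb_az_dist` object (a named numeric vector of probabilities).
#' @examples
#' az_dist_so()
#' sum(az_dist_so()[2:5])   # MSB fraction in stratum oriens
#' az_count_distribution(c(1, 0, 0, 0, 0))  # pure-SSB distribution
#' @export
az_count_distribution <- function(probs) {
  if (!is.numeric(probs) || length(probs) != 5L || anyNA(probs)) {
    abort("`probs` must be a numeric vector of 5 probabilities (counts 1..5).",
          class = "msbnet_config_error")
  }
  if (any(probs < 0)) {
    abort("Active-zone count probabilities must be non-negative.",
          class = "msbnet_config_error")
  }
  if (abs(sum(probs) - 1) > 1e-12) {
    abort("Active-zone count probabilities must sum to 1 (within 1e-12).",
          class = "msbnet_config_error")
  }
  structure(stats::setNames(as.numeric(probs), as.character(1:5)),
            class = "msb_az_dist")
}

#' @rdname az_count_distribution
#' @export
az_dist_so <- function() {
  az_count_distribution(c(0.55, 0.18, 0.12, 0.10, 0.05))
}

#' @rdname az_count_distribution
#' @export
az_dist_sr <- function() {
  so <- c(0.55, 0.18, 0.12, 0.10, 0.05)
  msb <- so[2:5] * (0.25 / 0.45)
  az_count_distribution(c(1 - sum(msb), msb))
}

#' @export
print.msb_az_dist <- function(x, ...) {
  cat("Active-zone count distribution (P(alpha = 1..5)):\n")
  print(unclass(x))
  cat(sprintf("MSB fraction P(alpha >= 2): %.3f\n", sum(x[2:5])))
  invisible(x)
}

#' Sample active-zone counts
#'
#' Draw i.i.d. active-zone counts for `n` boutons from a count distribution.
#'
#' @param n Number of boutons.
#' @param dist An [az_count_distribution()] (defaults to the stratum-oriens
#'   distribution).
#' @return Integer vector of length `n` with values in 1..5.
#' @examples
#' set.seed(1)
#' mean(sample_az_counts(10000, az_dist_so()) >= 2)  # ~0.45
#' @export
sample_az_counts <- function(n, dist = az_dist_so()) {
  if (!inherits(dist, "msb_az_dist")) dist <- az_count_distribution(dist)
  if (length(n) != 1L || is.na(n) || n < 0) {
    abort("`n` must be a single non-negative count.",
          class = "msbnet_config_error")
  }
  if (n == 0) return(integer(0))
  sample.int(5L, size = n, replace = TRUE, prob = unclass(dist))
}
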