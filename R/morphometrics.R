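validate_synapse_table <- function(table) {
  need <- c("contact_id", "bouton_id", "dendrite_id", "position",
            "spine_volume", "psd_area", "az_area", "bouton_volume",
            "az_count")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    abort(paste0("Synapse table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "msbnet_input_error")
  }
  by_bouton <- dplyr::summarise(
    dplyr::group_by(table, .data$bouton_id),
    ok = dplyr::n_distinct(.data$az_count) == 1L &&
      dplyr::n_distinct(.data$bouton_volume) == 1L &&
      dplyr::n() == .data$az_count[1],
    .groups = "drop")
  if (!all(by_bouton$ok)) {
    abort("Each bouton's rows must share `az_count` and `bouton_volume`, with one row per contact.",
          class = "msbnet_input_error")
  }
  if (any(table$az_count < 1) ||
      any(table[c("spine_volume", "psd_area", "az_area",
                  "bouton_volume")] <= 0)) {
    abort("Measures must be positive and `az_count` >= 1.",
          class = "msbnet_input_error")
  }
  invisible(table)
}

#' Read and write synapse-morphology tables
#'
#' One row per synaptic contact: `contact_id`, `bouton_id`, `dendrite_id`,
#' `position` (um along the dendrite), `spine_volume` (um^3), `psd_area`
#' (um^2), `az_area` (um^2), `bouton_volume` (um^3) and `az_count` (the
#' bouton's number of contacts). The reader validates that all rows of a
#' bouton agree on `az_count` and `bouton_volume` and that measures are
#' positive.
#'
#' @param table A synapse table tibble.
#' @param path TSV path.
#' @return `read_synapse_table()` returns the validated tibble.
#' @export
read_synapse_table <- function(path) {
  tbl <- read_tsv_plain(path)
  validate_synapse_table(tbl)
  tbl
}

#' @rdname read_synapse_table
#' @export
write_synapse_table <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path)
  invisible(path)
}

#' Within-bouton variance of a synaptic measure
#'
#' For every multi-synaptic bouton whose contact count falls in
#' `alpha_range`, the unbiased sample variance of the chosen measure over
#' its contacts.
#'
#' @param table A synapse table (see [read_synapse_table()]).
#' @param measure Column name: `"spine_volume"`, `"psd_area"` or
#'   `"az_area"`.
#' @param alpha_range Contact counts to include (default 2:5).
#' @return A tibble with one row per qualifying bouton: `bouton_id`,
#'   `az_count`, `variance`.
#' @export
within_bouton_variances <- function(table, measure, alpha_range = 2:5) {
  if (!measure %in% names(table)) {
    abort(paste0("No column `", measure, "` in the synapse table."),
          class = "msbnet_input_error")
  }
  out <- dplyr::summarise(
    dplyr::group_by(
      dplyr::filter(tibble::as_tibble(table),
                    .data$az_count %in% alpha_range),
      .data$bouton_id),
    az_count = .data$az_count[1],
    variance = var(.data[[measure]]),
    .groups = "drop")
  if (nrow(out) == 0) {
    warn("No boutons with contact counts in `alpha_range`; empty result.")
  }
  out
}

#' Variances of neighboring single-synaptic boutons
#'
#' Groups single-AZ contacts (SSBs) into runs of consecutive neighbors along
#' each dendrite (ordered by position) and returns the unbiased variance of
#' the measure within each group. Group sizes are drawn to match the
#' multi-synaptic boutons' contact-count histogram in the same table
#' (`matching = "msb"`), so the SSB comparison groups mirror the MSB sizes;
#' alternatively all groups have a fixed `size`. Leftover contacts at the
#' end of a dendrite that cannot fill a group are unused; dendrites with a
#' single SSB contribute nothing.
#'
#' @param table A synapse table.
#' @param measure Measure column name.
#' @param matching `"msb"` (match the MSB contact-count histogram) or
#'   `"fixed"`.
#' @param size Group size when `matching = "fixed"` (default 2).
#' @param alpha_range MSB contact counts defining the matched histogram.
#' @return A tibble with one row per SSB group: `dendrite_id`, `group`,
#'   `n_contacts`, `variance`.
#' @export
ssb_neighbor_variances <- function(table, measure,
                                   matching = c("msb", "fixed"), size = 2,
                                   alpha_range = 2:5) {
  matching <- match.arg(matching)
  tbl <- tibble::as_tibble(table)
  if (!measure %in% names(tbl)) {
    abort(paste0("No column `", measure, "` in the synapse table."),
          class = "msbnet_input_error")
  }
  ssb <- dplyr::arrange(dplyr::filter(tbl, .data$az_count == 1L),
                        .data$dendrite_id, .data$position)
  if (matching == "msb") {
    msb_alpha <- dplyr::distinct(
      dplyr::filter(tbl, .data$az_count %in% alpha_range),
      .data$bouton_id, .data$az_count)$az_count
    if (length(msb_alpha) == 0) {
      abort("No MSBs available to match group sizes against; use `matching = \"fixed\"`.",
            class = "msbnet_input_error")
    }
  }
  draw_size <- function(remaining) {
    if (matching == "fixed") {
      if (remaining >= size) size else NA_integer_
    } else {
      pool <- msb_alpha[msb_alpha <= remaining]
      if (length(pool) == 0) NA_integer_
      else pool[sample.int(length(pool), 1L)]
    }
  }
  groups <- list()
  gid <- 0L
  for (d in split(ssb, ssb$dendrite_id)) {
    i <- 1L
    while (nrow(d) - i + 1L >= 2L) {
      s <- draw_size(nrow(d) - i + 1L)
      if (is.na(s) || s < 2L) break
      gid <- gid + 1L
      groups[[gid]] <- tibble::tibble(
        dendrite_id = d$dendrite_id[1], group = gid, n_contacts = s,
        variance = var(d[[measure]][i:(i + s - 1L)]))
      i <- i + s
    }
  }
  if (length(groups) == 0) {
    warn("No SSB neighbor groups could be formed; empty result.")
    return(tibble::tibble(dendrite_id = integer(0), group = integer(0),
                          n_contacts = integer(0), variance = numeric(0)))
  }
  dplyr::bind_rows(groups)
}

#' Cliff's delta effect size
#'
#' The dominance statistic
#' \eqn{\delta = (\#\{a_i > b_j\} - \#\{a_i < b_j\}) / (n_a n_b)}, computed
#' exactly via midranks, in \[-1, 1\]. Positive values mean `a` tends to
#' exceed `b`.
#'
#' @param a,b Numeric samples (non-empty).
#' @return A single number in \[-1, 1\].
#' @examples
#' cliffs_delta(c(1, 2), c(2, 3))  # -0.75
#' @export
cliffs_delta <- function(a, b) {
  if (length(a) == 0 || length(b) == 0 || anyNA(a) || anyNA(b)) {
    abort("`a` and `b` must be non-empty and free of NA.",
          class = "msbnet_input_error")
  }
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  # Mann-Whitney U counts #{a > b} + 0.5 #{ties}; delta = 2U/(n1 n2) - 1
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  2 * u / (n1 * n2) - 1
}

#' Two-sided permutation test for a group difference
#'
#' Reshuffles the group labels `n_perm` times (default 5000) and compares
#' the observed statistic with the permutation distribution. The default
#' statistic is the difference in means; a Welch t statistic is available.
#' The p value uses the add-one correction
#' \eqn{p = (1 + \#\{|s^*| \ge |s_{obs}|\}) / (n_{perm} + 1)} and therefore
#' never reaches exactly zero.
#'
#' @param a,b Numeric samples.
#' @param n_perm Number of reshuffles (default 5000).
#' @param statistic `"mean_difference"` or `"t"`.
#' @param two_sided Two-sided test (default `TRUE`).
#' @return A one-row tibble: `estimate` (observed statistic), `p.value`,
#'   `n_perm`, `method`.
#' @export
permutation_test <- function(a, b, n_perm = 5000,
                             statistic = c("mean_difference", "t"),
                             two_sided = TRUE) {
  statistic <- match.arg(statistic)
  if (length(a) == 0 || length(b) == 0 || n_perm < 1) {
    abort("Need two non-empty samples and `n_perm` >= 1.",
          class = "msbnet_input_error")
  }
  stat_fun <- if (statistic == "mean_difference") {
    function(x, y) mean(x) - mean(y)
  } else {
    function(x, y) {
      se <- sqrt(var(x) / length(x) + var(y) / length(y))
      if (se == 0) 0 else (mean(x) - mean(y)) / se
    }
  }
  obs <- stat_fun(a, b)
  pooled <- c(a, b)
  n1 <- length(a)
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pooled), n1)
    stat_fun(pooled[idx], pooled[-idx])
  }, numeric(1))
  hits <- if (two_sided) sum(abs(perm) >= abs(obs) - 1e-12)
          else sum(perm >= obs - 1e-12)
  tibble::tibble(estimate = obs, p.value = (1 + hits) / (n_perm + 1),
                 n_perm = as.integer(n_perm),
                 method = paste0(if (two_sided) "two-sided " else "one-sided ",
                                 "permutation (", statistic, ")"))
}

#' BCa bootstrap confidence interval for a two-sample difference
#'
#' Bias-corrected and accelerated bootstrap interval (default 5000
#' resamples, 95% level) for the difference in medians or means between two
#' independent samples, resampling each sample separately. The bias
#' correction z0 comes from the bootstrap distribution's position relative
#' to the observed statistic; the acceleration from the jackknife skewness
#' over both samples. Degenerate bootstrap distributions (zero spread or an
#' unusable z0) fall back to the percentile interval with a warning;
#' `method = "percentile"` requests the plain percentile interval.
#'
#' @param a,b Numeric samples.
#' @param stat `"median_difference"` or `"mean_difference"`.
#' @param n_boot Bootstrap resamples (default 5000).
#' @param level Confidence level (default 0.95).
#' @param method `"bca"` (default) or `"percentile"`.
#' @return One-row tibble: `estimate`, `conf.low`, `conf.high`, `level`,
#'   `n_boot`, `method`.
#' @export
bca_bootstrap_diff <- function(a, b, stat = c("median_difference",
                                              "mean_difference"),
                               n_boot = 5000, level = 0.95,
                               method = c("bca", "percentile")) {
  stat <- match.arg(stat)
  method <- match.arg(method)
  if (length(a) < 2 || length(b) < 2 || n_boot < 1) {
    abort("Need two samples of size >= 2 and `n_boot` >= 1.",
          class = "msbnet_input_error")
  }
  f <- if (stat == "median_difference") function(x, y) median(x) - median(y)
       else function(x, y) mean(x) - mean(y)
  obs <- f(a, b)
  n1 <- length(a); n2 <- length(b)
  boot_stats <- vapply(seq_len(n_boot), function(i) {
    f(a[sample.int(n1, n1, replace = TRUE)],
      b[sample.int(n2, n2, replace = TRUE)])
  }, numeric(1))
  alpha <- (1 - level) / 2
  used <- method
  lims <- NULL
  if (method == "bca") {
    p0 <- (sum(boot_stats < obs) + 0.5 * sum(boot_stats == obs)) / n_boot
    spread <- sd(boot_stats)
    if (spread == 0 || p0 <= 0 || p0 >= 1) {
      warn("Degenerate bootstrap distribution; falling back to the percentile interval.")
      used <- "percentile"
    } else {
      z0 <- qnorm(p0)
      # jackknife acceleration over the combined delete-one statistics
      jack <- c(
        vapply(seq_len(n1), function(i) f(a[-i], b), numeric(1)),
        vapply(seq_len(n2), function(j) f(a, b[-j]), numeric(1))
      )
      dev <- mean(jack) - jack
      denom <- sum(dev^2)^1.5
      acc <- if (denom == 0) 0 else sum(dev^3) / (6 * denom)
      adj <- function(z_alpha) {
        pnorm(z0 + (z0 + z_alpha) / (1 - acc * (z0 + z_alpha)))
      }
      probs <- c(adj(qnorm(alpha)), adj(qnorm(1 - alpha)))
      lims <- quantile(boot_stats, probs, names = FALSE, type = 6)
    }
  }
  if (is.null(lims)) {
    lims <- quantile(boot_stats, c(alpha, 1 - alpha), names = FALSE, type = 6)
  }
  tibble::tibble(estimate = obs, conf.low = lims[1], conf.high = lims[2],
                 level = level, n_boot = as.integer(n_boot),
                 method = paste0(used, " bootstrap (", stat, ")"))
}

#' Ryan-Holm step-down adjusted confidence levels
#'
#' When m confidence intervals are reported together, the step-down
#' Bonferroni extension assigns the rank-k comparison (k = 1 the most
#' extreme effect) the level \eqn{1 - \alpha / (m - k + 1)}: the most
#' extreme comparison gets the full Bonferroni correction and the least
#' extreme is unadjusted. The dual p-value adjustment is Holm's step-down
#' procedure, available via [ryan_holm_p()].
#'
#' @param n_comparisons Number m of simultaneous comparisons.
#' @param level Base confidence level (default 0.95).
#' @return A tibble with columns `rank` and `level` (adjusted, decreasing in
#'   stringency with rank).
#' @examples
#' ryan_holm_levels(4)   # rank 1: 1 - 0.05/4
#' ryan_holm_levels(12)  # rank 1: 1 - 0.05/12
#' @export
ryan_holm_levels <- function(n_comparisons, level = 0.95) {
  if (n_comparisons < 1) {
    abort("`n_comparisons` must be >= 1.", class = "msbnet_input_error")
  }
  alpha <- 1 - level
  k <- seq_len(n_comparisons)
  tibble::tibble(rank = k, level = 1 - alpha / (n_comparisons - k + 1))
}

#' @rdname ryan_holm_levels
#' @param p Vector of raw p values (ordered or not).
#' @return `ryan_holm_p()` returns Holm step-down adjusted p values
#'   (monotonicity enforced).
#' @export
ryan_holm_p <- function(p) {
  p.adjust(p, method = "holm")
}

#' Compare within-MSB and neighboring-SSB variance
#'
#' The bespoke homogeneity analysis: is a synaptic measure more similar
#' among the contacts of one multi-synaptic bouton than among equally many
#' neighboring single-synaptic boutons on a dendrite? Computes the per-MSB
#' variances ([within_bouton_variances()]) and the matched SSB group
#' variances ([ssb_neighbor_variances()]), then Cliff's delta (MSB vs SSB; a
#' negative delta means MSB contacts are more homogeneous), a two-sided
#' permutation test on the mean variance difference and a BCa bootstrap
#' confidence interval for it.
#'
#' @param table A synapse table.
#' @param measure Measure column.
#' @param alpha_range MSB contact counts included (default 2:5).
#' @param n_perm,n_boot Resampling sizes (defaults 5000 each).
#' @param level Confidence level (default 0.95).
#' @param matching SSB grouping strategy, see [ssb_neighbor_variances()].
#' @return An object of class `msb_variance_comparison`.
#' @export
compare_bouton_variance <- function(table, measure, alpha_range = 2:5,
                                    n_perm = 5000, n_boot = 5000,
                                    level = 0.95, matching = "msb") {
  msb <- within_bouton_variances(table, measure, alpha_range)
  ssb <- ssb_neighbor_variances(table, measure, matching = matching,
                                alpha_range = alpha_range)
  if (nrow(msb) == 0 || nrow(ssb) == 0) {
    abort("Not enough MSB or SSB variance groups to compare.",
          class = "msbnet_input_error")
  }
  perm <- permutation_test(msb$variance, ssb$variance, n_perm = n_perm)
  ci <- bca_bootstrap_diff(msb$variance, ssb$variance,
                           stat = "mean_difference", n_boot = n_boot,
                           level = level)
  structure(list(
    measure = measure,
    msb = msb, ssb = ssb,
    cliffs_delta = cliffs_delta(msb$variance, ssb$variance),
    mean_difference = perm$estimate,
    p_value = perm$p.value,
    conf_low = ci$conf.low, conf_high = ci$conf.high,
    level = level, n_perm = n_perm, n_boot = n_boot,
    ci_method = ci$method
  ), class = "msb_variance_comparison")
}

#' @export
print.msb_variance_comparison <- function(x, ...) {
  cat(sprintf("Within-MSB vs neighboring-SSB variance of %s\n", x$measure))
  cat(sprintf("  %d MSB groups, %d SSB groups\n", nrow(x$msb), nrow(x$ssb)))
  cat(sprintf("  mean difference (MSB - SSB): %.4g  [%.4g, %.4g] (%g%% BCa)\n",
              x$mean_difference, x$conf_low, x$conf_high, 100 * x$level))
  cat(sprintf("  Cliff's delta: %.3f   permutation p: %.4g\n",
              x$cliffs_delta, x$p_value))
  invisible(x)
}

#' @rdname compare_bouton_variance
#' @param x,object An `msb_variance_comparison`.
#' @param ... Unused.
#' @export
tidy.msb_variance_comparison <- function(x, ...) {
  tibble::tibble(
    measure = x$measure,
    estimate = x$mean_difference,
    conf.low = x$conf_low,
    conf.high = x$conf_high,
    cliffs_delta = x$cliffs_delta,
    p.value = x$p_value
  )
}

#' @rdname compare_bouton_variance
#' @export
glance.msb_variance_comparison <- function(x, ...) {
  tibble::tibble(
    measure = x$measure,
    n_msb = nrow(x$msb), n_ssb = nrow(x$ssb),
    mean_msb_variance = mean(x$msb$variance),
    mean_ssb_variance = mean(x$ssb$variance),
    n_perm = x$n_perm, n_boot = x$n_boot, level = x$level
  )
}

#' @rdname compare_bouton_variance
#' @export
autoplot.msb_variance_comparison <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(group = "SSB neighbors", variance = object$ssb$variance),
    tibble::tibble(group = "within MSB", variance = object$msb$variance)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$variance,
                                   colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.5, show.legend = FALSE) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          show.legend = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c("SSB neighbors" = "#4575b4",
                                            "within MSB" = "#f46d43")) +
    ggplot2::labs(
      x = NULL, y = paste("variance of", object$measure),
      title = sprintf("Cliff's delta = %.2f, permutation p = %.3g",
                      object$cliffs_delta, object$p_value)) +
    ggplot2::theme_minimal()
}
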