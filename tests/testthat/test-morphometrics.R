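make_table <- function(bouton_alpha, values, dendrite = NULL,
                       position = NULL) {
  # one measure copied into all three columns; bouton volume constant
  bouton_of <- rep(seq_along(bouton_alpha), bouton_alpha)
  n <- length(bouton_of)
  tibble::tibble(
    contact_id = seq_len(n),
    bouton_id = bouton_of,
    dendrite_id = dendrite %||% rep(1L, n),
    position = position %||% seq_len(n),
    spine_volume = values, psd_area = values, az_area = values,
    bouton_volume = rep(1, n),
    az_count = rep(bouton_alpha, bouton_alpha)
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("within-bouton variances are the unbiased per-MSB variances", {
  tab <- make_table(c(3, 2, 1), c(5, 5, 5, 2, 4, 9))
  v <- within_bouton_variances(tab, "psd_area")
  expect_equal(nrow(v), 2)                       # the SSB is excluded
  expect_equal(v$variance[v$bouton_id == 1], 0)  # identical contacts
  expect_equal(v$variance[v$bouton_id == 2], (2 - 4)^2 / 2)
  expect_warning(within_bouton_variances(tab, "psd_area", alpha_range = 5),
                 "No boutons")
  expect_error(within_bouton_variances(tab, "nope"),
               class = "msbnet_input_error")
})

test_that("SSB neighbor groups are consecutive along a dendrite", {
  # a dendrite with exactly 2 SSBs -> one group with the two-point variance
  tab <- make_table(c(2, 1, 1), c(1, 1, 3, 7),
                    dendrite = c(9L, 9L, 2L, 2L), position = c(1, 2, 5, 9))
  set.seed(1)
  v <- ssb_neighbor_variances(tab, "spine_volume")
  expect_equal(nrow(v), 1)
  expect_equal(v$variance, (3 - 7)^2 / 2)
  expect_equal(v$n_contacts, 2L)

  # all-equal SSB values give zero variances
  tab2 <- make_table(c(2, 1, 1, 1, 1), rep(4, 6),
                     dendrite = c(1L, 1L, 2L, 2L, 2L, 2L),
                     position = c(1, 2, 1, 2, 3, 4))
  set.seed(2)
  v2 <- ssb_neighbor_variances(tab2, "spine_volume")
  expect_true(all(v2$variance == 0))
})

test_that("SSB group sizes match the MSB contact-count histogram", {
  set.seed(33)
  tab <- generate_synapse_table(synapse_gen_params(
    n_boutons = 2000, n_dendrites = 40))
  v <- ssb_neighbor_variances(tab, "psd_area")
  msb_alpha <- dplyr::distinct(tab[tab$az_count >= 2, ],
                               bouton_id, az_count)$az_count
  h_groups <- prop.table(table(factor(v$n_contacts, levels = 2:5)))
  h_msb <- prop.table(table(factor(msb_alpha, levels = 2:5)))
  expect_equal(as.numeric(h_groups), as.numeric(h_msb), tolerance = 0.3)
})

test_that("Cliff's delta matches brute-force enumeration", {
  expect_equal(cliffs_delta(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cliffs_delta(10:12, 1:3), 1)
  expect_equal(cliffs_delta(c(1, 2), c(2, 3)), -0.75)
  expect_error(cliffs_delta(numeric(0), 1), class = "msbnet_input_error")

  set.seed(44)
  for (i in 1:10) {
    n1 <- sample(1:50, 1); n2 <- sample(1:50, 1)
    a <- sample(round(rnorm(n1, 0, 2), 1))   # rounding creates ties
    b <- sample(round(rnorm(n2, 0.5, 2), 1))
    expect_equal(cliffs_delta(a, b), brute_cliffs(a, b))
  }
})

test_that("Cliff's delta is antisymmetric and monotone-invariant", {
  set.seed(45)
  for (i in 1:5) {
    a <- rnorm(20); b <- rnorm(15, 0.3)
    d <- cliffs_delta(a, b)
    expect_equal(cliffs_delta(b, a), -d)
    expect_equal(cliffs_delta(exp(a), exp(b)), d)   # strictly monotone map
    expect_true(abs(d) <= 1)
  }
})

test_that("permutation p agrees with exhaustive enumeration for 3+3 groups", {
  a <- c(1.2, 3.4, 2.2)
  b <- c(4.1, 5.0, 3.9)
  p_ex <- exhaustive_perm_p(a, b)
  set.seed(46)
  p_mc <- permutation_test(a, b, n_perm = 5000)$p.value
  expect_equal(p_mc, p_ex, tolerance = 0.35)
  expect_lt(abs(p_mc - p_ex), 0.05)

  # identical groups -> p near 1; never exactly 0 by the add-one rule
  set.seed(47)
  same <- permutation_test(c(1, 2, 3), c(1, 2, 3), n_perm = 999)$p.value
  expect_gt(same, 0.9)
  sep <- permutation_test(1:20, 101:120, n_perm = 999)$p.value
  expect_equal(sep, 1 / 1000)
})

test_that("permutation test is invariant to a common shift", {
  set.seed(48)
  a <- rnorm(12); b <- rnorm(10, 0.8)
  set.seed(1); p1 <- permutation_test(a, b, n_perm = 2000)$p.value
  set.seed(1); p2 <- permutation_test(a + 100, b + 100, n_perm = 2000)$p.value
  expect_equal(p1, p2)
})

test_that("BCa interval reduces to percentile when bias and skew vanish", {
  set.seed(49)
  a <- rnorm(120); b <- rnorm(120, 0.5)
  set.seed(50)
  bca <- bca_bootstrap_diff(a, b, stat = "mean_difference", n_boot = 3000)
  set.seed(50)
  pct <- bca_bootstrap_diff(a, b, stat = "mean_difference", n_boot = 3000,
                            method = "percentile")
  width <- pct$conf.high - pct$conf.low
  expect_lt(abs(bca$conf.low - pct$conf.low), 0.1 * width)
  expect_lt(abs(bca$conf.high - pct$conf.high), 0.1 * width)
  expect_equal(bca$estimate, mean(a) - mean(b))

  # identical samples: the interval straddles zero
  set.seed(51)
  ident <- bca_bootstrap_diff(a, a, stat = "median_difference", n_boot = 500)
  expect_lte(ident$conf.low, 0)
  expect_gte(ident$conf.high, 0)
})

test_that("BCa interval agrees with an independent implementation", {
  skip_if_not_installed("boot")
  set.seed(52)
  a <- rlnorm(60, 0, 0.6); b <- rlnorm(50, 0.4, 0.6)
  ours <- bca_bootstrap_diff(a, b, stat = "mean_difference", n_boot = 4999)
  dat <- data.frame(v = c(a, b), g = rep(1:2, c(length(a), length(b))))
  bt <- boot::boot(dat, function(d, i) {
    x <- d$v[i]
    mean(x[d$g == 1]) - mean(x[d$g == 2])
  }, R = 4999, strata = dat$g)
  ci <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  width <- ci[2] - ci[1]
  expect_lt(abs(ours$conf.low - ci[1]), 0.15 * width)
  expect_lt(abs(ours$conf.high - ci[2]), 0.15 * width)
})

test_that("Ryan-Holm levels step down and p adjustment is monotone", {
  expect_equal(ryan_holm_levels(1)$level, 0.95)
  l4 <- ryan_holm_levels(4)
  expect_equal(l4$level, c(0.9875, 0.98 + 1 / 300, 0.975, 0.95),
               tolerance = 1e-10)
  expect_equal(ryan_holm_levels(12)$level[1], 1 - 0.05 / 12)
  expect_true(all(diff(l4$level) < 0))

  p <- c(0.04, 0.001, 0.3, 0.01)
  adj <- ryan_holm_p(p)
  expect_true(all(adj >= p))
  expect_equal(adj, p.adjust(p, "holm"))
})

test_that("the variance comparison pipeline recovers the planted effect", {
  set.seed(53)
  tab <- generate_synapse_table(synapse_gen_params(
    n_boutons = 200, sigma_within = 0.3, sigma_between = 0.6))
  cmp <- compare_bouton_variance(tab, "spine_volume", n_perm = 999,
                                 n_boot = 999)
  expect_lt(cmp$cliffs_delta, 0)     # MSB contacts more homogeneous
  expect_lt(cmp$p_value, 0.01)
  expect_lt(cmp$conf_high, 0)

  td <- tidy(cmp)
  expect_named(td, c("measure", "estimate", "conf.low", "conf.high",
                     "cliffs_delta", "p.value"))
  gl <- glance(cmp)
  expect_equal(gl$n_msb, nrow(cmp$msb))
  expect_s3_class(autoplot(cmp), "ggplot")
})
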