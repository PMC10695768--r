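test_that("active-zone count sampling follows the configured distribution", {
  expect_equal(sample_az_counts(100, az_count_distribution(c(1, 0, 0, 0, 0))),
               rep(1L, 100))
  expect_error(az_count_distribution(c(0.5, 0.5, 0.1, 0, 0)),
               class = "msbnet_config_error")
  expect_error(az_count_distribution(c(1.2, -0.2, 0, 0, 0)),
               class = "msbnet_config_error")

  set.seed(101)
  so <- sample_az_counts(10000, az_dist_so())
  sr <- sample_az_counts(10000, az_dist_sr())
  # binomial SE at n = 10,000 is ~0.5 pp; allow 4 SE
  expect_equal(mean(so >= 2), 0.45, tolerance = 0.045)
  expect_equal(mean(so > 3), 0.15, tolerance = 0.08)
  expect_equal(mean(sr >= 2), 0.25, tolerance = 0.06)
  expect_true(all(so %in% 1:5) && all(sr %in% 1:5))
})

test_that("connectivity honors the architecture in every condition", {
  spec <- network_spec()
  for (cond in c("ssb_all", "msb_so", "msb_sr", "msb_all")) {
    set.seed(7)
    g <- build_connectivity(spec, cond)
    boutons <- dplyr::distinct(tibble::as_tibble(g), bouton_id,
                               source_neuron, stratum, az_count)
    per_neuron <- dplyr::count(boutons, source_neuron, stratum)
    expect_true(all(per_neuron$n[per_neuron$stratum == "so"] == 5))
    expect_true(all(per_neuron$n[per_neuron$stratum == "sr"] == 7))
    expect_equal(nrow(boutons), spec$n_ca3 * 12)
    # AZ rows per bouton equal the bouton's count
    rows <- dplyr::count(tibble::as_tibble(g), bouton_id, az_count)
    expect_equal(rows$n, rows$az_count)
    # SSB-flagged strata are pure single-AZ
    if (cond %in% c("ssb_all", "msb_sr")) {
      expect_true(all(boutons$az_count[boutons$stratum == "so"] == 1))
    }
    if (cond %in% c("ssb_all", "msb_so")) {
      expect_true(all(boutons$az_count[boutons$stratum == "sr"] == 1))
    }
    expect_true(all(g$target_neuron >= 1 & g$target_neuron <= spec$n_ca1))
    dup <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(g), bouton_id),
                            distinct = dplyr::n_distinct(target_neuron) == dplyr::n())
    expect_true(all(dup$distinct))
  }
  # same seed, identical graph record-for-record
  set.seed(11); g1 <- build_connectivity(spec, "msb_all")
  set.seed(11); g2 <- build_connectivity(spec, "msb_all")
  expect_identical(tibble::as_tibble(g1), tibble::as_tibble(g2))
})

test_that("MSB fraction of a generated stratum converges to P(alpha >= 2)", {
  spec <- network_spec(n_ca3 = 850)  # 850 x 5 = 4250 SO boutons
  set.seed(3)
  g <- build_connectivity(spec, "msb_all")
  so <- dplyr::distinct(tibble::as_tibble(g)[g$stratum == "so", ],
                        bouton_id, az_count)
  expect_equal(mean(so$az_count >= 2), 0.45, tolerance = 0.06)
})

test_that("release probabilities are truncated-Gamma bouton-level draws", {
  spec <- network_spec(n_ca3 = 850)
  set.seed(5)
  g <- sample_release_probabilities(build_connectivity(spec, "msb_all"))
  expect_true(all(g$p > 0 & g$p <= 1))
  per_b <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(g), bouton_id),
                            one_p = dplyr::n_distinct(p) == 1L)
  expect_true(all(per_b$one_p))
  # Monte-Carlo oracle for the clipped-Gamma mean
  set.seed(999)
  oracle <- mean(pmin(rgamma(2e5, shape = 2, scale = 0.15), 1))
  b <- dplyr::distinct(tibble::as_tibble(g), bouton_id, p)
  expect_equal(mean(b$p), oracle, tolerance = 0.02)
  expect_error(sample_release_probabilities(g, shape = -1),
               class = "msbnet_config_error")
})

test_that("STP type assignment follows the requested scheme", {
  spec <- network_spec(n_ca3 = 850)
  set.seed(6)
  g <- sample_release_probabilities(build_connectivity(spec, "ssb_all"))
  g_none <- assign_stp_types(g, "none")
  expect_true(all(g_none$stp_type == "static"))

  g_ind <- assign_stp_types(g, "independent", facil_fraction = 0.5)
  b <- dplyr::distinct(tibble::as_tibble(g_ind), bouton_id, stp_type)
  expect_equal(mean(b$stp_type == "facilitating"), 0.5, tolerance = 0.02)

  g_m <- assign_stp_types(g, "matched")
  bm <- dplyr::distinct(tibble::as_tibble(g_m), bouton_id, p, stp_type)
  expect_true(max(bm$p[bm$stp_type == "facilitating"]) <=
              min(bm$p[bm$stp_type == "depressing"]))

  # matched before release probabilities exist is an ordering error
  fresh <- build_connectivity(spec, "ssb_all")
  expect_error(assign_stp_types(fresh, "matched"),
               class = "msbnet_order_error")
})

test_that("mechanism variants have the stated layouts", {
  spec <- network_spec()
  set.seed(8)
  ro_ssb <- build_mechanism_variant(spec, "release_only", msb = FALSE)
  b <- dplyr::distinct(tibble::as_tibble(ro_ssb), bouton_id, source_neuron,
                       az_count)
  expect_equal(nrow(b), spec$n_ca3 * 5)
  expect_true(all(b$az_count == 1))
  expect_true(all(table(b$source_neuron) == 5))
  expect_true(all(ro_ssb$stp_type == "static"))
  expect_true(all(ro_ssb$p > 0 & ro_ssb$p <= 1))

  ro_msb <- build_mechanism_variant(spec, "release_only", msb = TRUE)
  b2 <- dplyr::distinct(tibble::as_tibble(ro_msb), bouton_id, source_neuron,
                        az_count)
  expect_equal(nrow(b2), spec$n_ca3)
  expect_true(all(b2$az_count == 5))

  mult <- build_mechanism_variant(spec, "multiplicative_only", msb = TRUE)
  expect_true(all(mult$p == 1) && all(mult$stp_type == "static"))

  stp <- build_mechanism_variant(spec, "stp_only", msb = TRUE)
  expect_true(all(stp$p == 1))
  expect_true(all(stp$stp_type %in% c("facilitating", "depressing")))
})

test_that("a single-target network forces SSBs and rejects MSBs", {
  spec <- network_spec(n_ca1 = 1)
  set.seed(2)
  g <- build_connectivity(spec, "ssb_all")
  expect_true(all(g$target_neuron == 1))
  msb_forced <- az_count_distribution(c(0, 1, 0, 0, 0))
  expect_error(build_connectivity(spec, "msb_all", so_dist = msb_forced,
                                  sr_dist = msb_forced),
               class = "msbnet_config_error")
})

test_that("connectivity round-trips through TSV + JSON sidecar", {
  set.seed(4)
  g <- assign_stp_types(
    sample_release_probabilities(
      build_connectivity(network_spec(n_ca3 = 10), "msb_all")),
    "independent")
  path <- file.path(withr::local_tempdir(), "graph.tsv")
  write_connectivity(g, path)
  g2 <- read_connectivity(path)
  expect_equal(tibble::as_tibble(g2), tibble::as_tibble(g))
  expect_equal(unclass(attr(g2, "spec")), unclass(attr(g, "spec")))
  expect_equal(attr(g2, "condition"), attr(g, "condition"))
})
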