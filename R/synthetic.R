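#' Parameters of the synthetic synapse-table generator
#'
#' The generator emulates the statistical structure the morphometric
#' analyses assume: right-skewed (lognormal) synaptic size distributions, a
#' shared bouton-level factor that makes contacts of one bouton more alike
#' than contacts of different boutons (intraclass correlation
#' sigma_B^2 / (sigma_B^2 + sigma_W^2)), bouton volume growing as a power of
#' the contact count, and contacts scattered along dendrites.
#'
#' @param n_boutons Number of boutons (default 200).
#' @param az_dist Contact-count distribution (default: stratum oriens).
#' @param log_mean Named log-scale means for `spine_volume`, `psd_area`,
#'   `az_area` (um^3 / um^2).
#' @param sigma_within Within-bouton log SD sigma_W (default 0.3).
#' @param sigma_between Between-bouton log SD sigma_B (default 0.6).
#' @param rho_measures Latent correlation between the three measures of one
#'   contact (default 0.5).
#' @param volume_exponent Power gamma of bouton volume vs contact count
#'   (default 0.8).
#' @param volume_base Median bouton volume at one contact, um^3
#'   (default 0.1).
#' @param volume_sd Lognormal noise SD of bouton volume (default 0.25).
#' @param n_dendrites Number of dendrites contacts are scattered over
#'   (default 20).
#' @param dendrite_length Dendrite length, um (default 100).
#' @return A list of class `msb_synapse_gen_params`.
#' @export
synapse_gen_params <- function(n_boutons = 200, az_dist = az_dist_so(),
                               log_mean = c(spine_volume = log(0.05),
                                            psd_area = log(0.07),
                                            az_area = log(0.06)),
                               sigma_within = 0.3, sigma_between = 0.6,
                               rho_measures = 0.5,
                               volume_exponent = 0.8, volume_base = 0.1,
                               volume_sd = 0.25,
                               n_dendrites = 20, dendrite_length = 100) {
  if (sigma_within < 0 || sigma_between < 0 || volume_sd < 0 ||
      rho_measures < -1 || rho_measures > 1 || n_boutons < 1 ||
      n_dendrites < 1 || dendrite_length <= 0) {
    abort("Invalid synapse generator parameters.",
          class = "msbnet_config_error")
  }
  structure(list(n_boutons = as.integer(n_boutons), az_dist = az_dist,
                 log_mean = log_mean, sigma_within = sigma_within,
                 sigma_between = sigma_between, rho_measures = rho_measures,
                 volume_exponent = volume_exponent, volume_base = volume_base,
                 volume_sd = volume_sd, n_dendrites = as.integer(n_dendrites),
                 dendrite_length = dendrite_length),
            class = "msb_synapse_gen_params")
}

#' Generate a synthetic synapse-morphology table
#'
#' Bouton i draws a contact count from `az_dist` and a bouton-level latent
#' factor b_i ~ N(0, sigma_B); contact j of bouton i gets, for each measure
#' m, a log-value `log_mean[m] + b_i + e_ijm` where the contact noise `e`
#' has SD sigma_W and correlation `rho_measures` across measures (via a
#' shared per-contact latent). Measures are exponentiated, so they are
#' lognormal with within-bouton log SD sigma_W and between-bouton log SD
#' sigma_B. Bouton volume is `volume_base * alpha^volume_exponent` times
#' lognormal noise. Contacts land on uniformly chosen dendrites at uniform
#' positions.
#'
#' @param params A [synapse_gen_params()].
#' @return A validated synapse table tibble (see [read_synapse_table()]).
#' @examples
#' set.seed(1)
#' tab <- generate_synapse_table(synapse_gen_params(n_boutons = 50))
#' dplyr::count(dplyr::distinct(tab, bouton_id, az_count), az_count)
#' @export
generate_synapse_table <- function(params = synapse_gen_params()) {
  p <- params
  alpha <- sample_az_counts(p$n_boutons, p$az_dist)
  b_fac <- rnorm(p$n_boutons, 0, p$sigma_between)
  vol <- p$volume_base * alpha^p$volume_exponent *
    exp(rnorm(p$n_boutons, 0, p$volume_sd))
  n_contacts <- sum(alpha)
  bouton_of <- rep(seq_len(p$n_boutons), alpha)
  measures <- names(p$log_mean)
  shared <- rnorm(n_contacts)
  rho <- p$rho_measures
  logs <- sapply(measures, function(m) {
    eps <- sqrt(abs(rho)) * sign(rho) * shared +
      sqrt(1 - abs(rho)) * rnorm(n_contacts)
    p$log_mean[[m]] + b_fac[bouton_of] + p$sigma_within * eps
  })
  tbl <- tibble::tibble(
    contact_id = seq_len(n_contacts),
    bouton_id = bouton_of,
    dendrite_id = sample.int(p$n_dendrites, n_contacts, replace = TRUE),
    position = runif(n_contacts, 0, p$dendrite_length),
    spine_volume = exp(logs[, "spine_volume"]),
    psd_area = exp(logs[, "psd_area"]),
    az_area = exp(logs[, "az_area"]),
    bouton_volume = vol[bouton_of],
    az_count = alpha[bouton_of]
  )
  validate_synapse_table(tbl)
}

#' Parameters of the synthetic dendritic-tree generator
#'
#' Emulates basal dendrites fanning out from the soma: `n_primary` trunks
#' leave the soma with directions inside a cone of `fan_half_angle` degrees
#' about a common axis, grow in straight steps with small angular jitter,
#' and branch stochastically; branches diverge with distance, so separate
#' branches are close mainly near the soma.
#'
#' @param n_primary Primary branches from the soma (default 6).
#' @param branch_prob Branching probability per um of growth (default 0.01).
#' @param step_length Growth step, um (default 2).
#' @param fan_half_angle Cone half-angle about the fan axis, degrees
#'   (default 40).
#' @param extent Maximum path length from the soma, um (default 150).
#' @param jitter_sd Angular jitter per step, radians (default 0.08).
#' @param node_spacing Resampling spacing of the emitted tree, um
#'   (default 0.5).
#' @return A list of class `msb_tree_gen_params`.
#' @export
tree_gen_params <- function(n_primary = 6, branch_prob = 0.01,
                            step_length = 2, fan_half_angle = 40,
                            extent = 150, jitter_sd = 0.08,
                            node_spacing = 0.5) {
  if (n_primary < 1 || branch_prob < 0 || step_length <= 0 ||
      fan_half_angle <= 0 || fan_half_angle > 90 || extent <= 0 ||
      node_spacing <= 0) {
    abort("Invalid tree generator parameters.", class = "msbnet_config_error")
  }
  structure(list(n_primary = as.integer(n_primary),
                 branch_prob = branch_prob, step_length = step_length,
                 fan_half_angle = fan_half_angle, extent = extent,
                 jitter_sd = jitter_sd, node_spacing = node_spacing),
            class = "msb_tree_gen_params")
}

unit <- function(v) v / sqrt(sum(v^2))

# Constrain a direction to the cone of half-angle `ang` (radians) about +x.
clamp_cone <- function(dir, ang) {
  dir <- unit(dir)
  axis <- c(1, 0, 0)
  ct <- sum(dir * axis)
  if (ct >= cos(ang)) return(dir)
  perp <- dir - ct * axis
  if (sum(perp^2) < 1e-12) return(axis)
  unit(cos(ang) * axis + sin(ang) * unit(perp))
}

#' Generate a synthetic dendritic tree
#'
#' Grows a rooted tree from the soma per [tree_gen_params()] and resamples
#' it at constant node spacing. The result is a valid SWC table (see
#' [read_swc()]) with the soma as the single type-1 root.
#'
#' @param params A [tree_gen_params()].
#' @return An `msb_neurite` tibble.
#' @examples
#' set.seed(2)
#' tree <- generate_neurite_tree(tree_gen_params(n_primary = 3, extent = 60))
#' @export
generate_neurite_tree <- function(params = tree_gen_params()) {
  p <- params
  ang <- p$fan_half_angle * pi / 180
  rows <- list(tibble::tibble(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                              radius = 1, parent = -1L))
  nid <- 1L
  # initial fan: evenly spread azimuths at the cone half-angle
  tips <- lapply(seq_len(p$n_primary), function(k) {
    phi <- 2 * pi * (k - 1) / p$n_primary
    theta <- ang * sqrt(runif(1, 0.4, 1))
    list(pos = c(0, 0, 0),
         dir = unit(c(cos(theta), sin(theta) * cos(phi),
                      sin(theta) * sin(phi))),
         parent = 1L, grown = 0)
  })
  while (length(tips) > 0) {
    tip <- tips[[1]]
    tips <- tips[-1]
    while (tip$grown < p$extent) {
      d <- unit(tip$dir + rnorm(3, 0, p$jitter_sd))
      d <- clamp_cone(d, ang)
      new_pos <- tip$pos + d * p$step_length
      nid <- nid + 1L
      rows[[nid]] <- tibble::tibble(id = nid, type = 3L, x = new_pos[1],
                                    y = new_pos[2], z = new_pos[3],
                                    radius = 0.4, parent = tip$parent)
      tip$pos <- new_pos
      tip$dir <- d
      tip$parent <- nid
      tip$grown <- tip$grown + p$step_length
      if (tip$grown < p$extent &&
          runif(1) < p$branch_prob * p$step_length) {
        child_dir <- clamp_cone(unit(d + rnorm(3, 0, 0.35)), ang)
        tips[[length(tips) + 1]] <- list(pos = tip$pos, dir = child_dir,
                                         parent = tip$parent,
                                         grown = tip$grown)
      }
    }
  }
  tree <- as_neurite_tree(dplyr::bind_rows(rows))
  resample_neurite(tree, p$node_spacing)
}
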