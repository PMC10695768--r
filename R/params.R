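#' Leaky integrate-and-fire neuron parameters
#'
#' Membrane dynamics follow
#' \deqn{\tau_m \, dV/dt = -V + R (I_b + I_{syn}),}
#' with a spike whenever V crosses `v_th`, after which V is clamped at
#' `v_reset` for the refractory period. Without short-term plasticity each
#' transmitted presynaptic spike injects an exponential postsynaptic current
#' of peak `a_static` decaying with `tau_syn`.
#'
#' @param tau_m Membrane time constant, ms (default 60).
#' @param r_in Input resistance, GOhm (default 1; 1 GOhm x 1 pA = 1 mV).
#' @param v_th Spike threshold, mV (default 20).
#' @param v_reset Post-spike reset, mV (default 10).
#' @param t_ref Refractory period, ms (default 2).
#' @param a_static Static PSC peak amplitude, pA (default 200).
#' @param tau_syn PSC decay time constant, ms (default 1.5).
#' @return A list of class `msb_neuron_params`.
#' @export
neuron_params <- function(tau_m = 60, r_in = 1, v_th = 20, v_reset = 10,
                          t_ref = 2, a_static = 200, tau_syn = 1.5) {
  p <- list(tau_m = tau_m, r_in = r_in, v_th = v_th, v_reset = v_reset,
            t_ref = t_ref, a_static = a_static, tau_syn = tau_syn)
  if (p$v_reset >= p$v_th || p$tau_m <= 0 || p$tau_syn <= 0 || p$t_ref < 0) {
    abort("Invalid neuron parameters (need v_reset < v_th, positive time constants).",
          class = "msbnet_config_error")
  }
  structure(p, class = "msb_neuron_params")
}

#' Background-noise parameters
#'
#' The background input is a Gaussian current: a fresh value
#' N(`mu_b`, `sigma_b`) is drawn per neuron every `update_interval`
#' milliseconds and held constant in between.
#'
#' @param mu_b Mean background current, pA (default 12).
#' @param sigma_b Standard deviation, pA (default 20).
#' @param update_interval Hold interval, ms (default 1).
#' @return A list of class `msb_noise_params`.
#' @export
noise_params <- function(mu_b = 12, sigma_b = 20, update_interval = 1) {
  if (sigma_b < 0 || update_interval <= 0) {
    abort("Invalid noise parameters.", class = "msbnet_config_error")
  }
  structure(list(mu_b = mu_b, sigma_b = sigma_b,
                 update_interval = update_interval),
            class = "msb_noise_params")
}

#' Tsodyks-Markram short-term plasticity parameters
#'
#' Synaptic resources occupy recovered (x), active (y) and inactive (z)
#' states with x + y + z = 1; the utilisation variable u rises by U(1 - u) at
#' each spike and decays with `tau_fac`. A spike moves u x of resource from x
#' to y (the release), y decays to z with `tau_syn`, and z recovers to x with
#' `tau_rec`. The postsynaptic current contributed by a synapse is A y(t).
#'
#' The facilitating preset is A = 1540 pA, U = 0.03, tau_rec = 130 ms,
#' tau_fac = 530 ms; the depressing preset is A = 250 pA, U = 0.5,
#' tau_rec = 800 ms, tau_fac = 0 ms (tau_fac = 0 means u is simply U at
#' every spike).
#'
#' @param a Absolute synaptic weight, pA.
#' @param u_base Baseline utilisation U in (0, 1].
#' @param tau_rec Recovery time constant, ms.
#' @param tau_fac Facilitation time constant, ms (0 allowed).
#' @param tau_syn Active-state (PSC) decay, ms (default 1.5).
#' @return A list of class `msb_stp_params`.
#' @examples
#' stp_facilitating()
#' stp_depressing()
#' @export
stp_params <- function(a, u_base, tau_rec, tau_fac, tau_syn = 1.5) {
  if (u_base <= 0 || u_base > 1 || tau_rec <= 0 || tau_fac < 0 || tau_syn <= 0) {
    abort("Invalid STP parameters (need 0 < U <= 1, tau_rec > 0, tau_fac >= 0).",
          class = "msbnet_config_error")
  }
  structure(list(a = a, u_base = u_base, tau_rec = tau_rec,
                 tau_fac = tau_fac, tau_syn = tau_syn),
            class = "msb_stp_params")
}

#' @rdname stp_params
#' @export
stp_facilitating <- function() stp_params(1540, 0.03, 130, 530)

#' @rdname stp_params
#' @export
stp_depressing <- function() stp_params(250, 0.5, 800, 0)
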