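# Closed-form inter-event evolution of the Tsodyks-Markram state.
# Between spikes the system is linear:
#   y(t) = y0 exp(-t/ts)
#   z(t) = z0 exp(-t/tr) + (y0 / (ts c)) (exp(-t/tr) - exp(-t/ts)),
#          c = 1/ts - 1/tr
#   x(t) = x0 + (z0 + B)(1 - exp(-t/tr)) - (B ts/tr)(1 - exp(-t/ts)),
#          B = y0 / (ts c)
#   u(t) = u0 exp(-t/tf)           (u = 0 between spikes when tf = 0)
# x is propagated by its own integral rather than as 1 - y - z so that the
# conservation x + y + z = 1 is a genuine floating-point check, not an
# identity.
stp_decay <- function(state, dt, params) {
  if (dt <= 0) return(state)
  ts <- params$tau_syn; tr <- params$tau_rec; tf <- params$tau_fac
  es <- exp(-dt / ts); er <- exp(-dt / tr)
  cc <- 1 / ts - 1 / tr
  B <- if (abs(cc) < 1e-14) state$y * dt / ts else state$y / (ts * cc)
  z1 <- state$z * er + B * (er - es)
  x1 <- state$x + (state$z + B) * (1 - er) - (B * ts / tr) * (1 - es)
  y1 <- state$y * es
  u1 <- if (tf > 0) state$u * exp(-dt / tf) else 0
  list(x = x1, y = y1, z = z1, u = u1)
}

stp_spike_update <- function(state, params) {
  u_new <- state$u + params$u_base * (1 - state$u)
  rel <- u_new * state$x
  list(state = list(x = state$x - rel, y = state$y + rel, z = state$z,
                    u = u_new),
       release = rel)
}

#' Trace the Tsodyks-Markram state along a spike train
#'
#' Evolves the synaptic resource model deterministically through a sorted
#' train of (transmitted) presynaptic spike times, using the exact
#' closed-form solution of the linear inter-spike dynamics. At each spike the
#' utilisation is updated first (u <- u + U(1 - u)), then the release u x
#' moves from the recovered to the active state. The initial state is x = 1,
#' y = z = u = 0.
#'
#' @param times Sorted spike times, seconds.
#' @param params An [stp_params()] preset.
#' @param sample_times Optional times (seconds) at which to report the freely
#'   decaying state in addition to the spike events.
#' @return A list with `events`, a tibble of per-spike rows (`time`, `u`,
#'   `release`, `psc_peak` = A u x, and the post-release `x`, `y`, `z`), and
#'   `samples`, a tibble of the state at `sample_times` (empty if none
#'   requested).
#' @examples
#' tr <- stp_event_trace(c(0.1, 0.15, 0.2), stp_facilitating())
#' tr$events$release  # grows: facilitation
#' @export
stp_event_trace <- function(times, params, sample_times = NULL) {
  if (is.unsorted(times, strictly = FALSE)) {
    abort("`times` must be sorted non-decreasing.", class = "msbnet_input_error")
  }
  n <- length(times)
  state <- list(x = 1, y = 0, z = 0, u = 0)
  ev <- matrix(NA_real_, n, 6,
               dimnames = list(NULL, c("u", "release", "x", "y", "z",
                                       "psc_peak")))
  qs <- sort(sample_times)
  samp <- matrix(NA_real_, length(qs), 4,
                 dimnames = list(NULL, c("x", "y", "z", "u")))
  t_last <- 0
  qi <- 1L
  for (i in seq_len(n)) {
    # report any requested sample times that fall before this spike
    while (qi <= length(qs) && qs[qi] < times[i]) {
      s <- stp_decay(state, (qs[qi] - t_last) * 1000, params)
      samp[qi, ] <- c(s$x, s$y, s$z, s$u)
      qi <- qi + 1L
    }
    state <- stp_decay(state, (times[i] - t_last) * 1000, params)
    up <- stp_spike_update(state, params)
    state <- up$state
    ev[i, ] <- c(state$u, up$release, state$x, state$y, state$z,
                 params$a * up$release)
    t_last <- times[i]
  }
  while (qi <= length(qs)) {
    s <- stp_decay(state, (qs[qi] - t_last) * 1000, params)
    samp[qi, ] <- c(s$x, s$y, s$z, s$u)
    qi <- qi + 1L
  }
  list(
    events = tibble::tibble(time = as.numeric(times),
                            tibble::as_tibble(ev[, c("u", "release", "x",
                                                     "y", "z", "psc_peak"),
                                                 drop = FALSE])),
    samples = tibble::tibble(time = qs, tibble::as_tibble(samp))
  )
}

#' Analytic steady state of a periodically driven Tsodyks-Markram synapse
#'
#' For perfectly periodic transmitted spikes with period `period_ms` the
#' post-update utilisation and pre-release recovered fraction converge to the
#' classic fixed point
#' \deqn{u^* = U / (1 - (1-U) e^{-T/\tau_{fac}}),}
#' \deqn{x^* = (1 - e^{-T/\tau_{rec}}) / (1 - (1-u^*) e^{-T/\tau_{rec}}),}
#' exact in the limit where the active state empties between spikes
#' (tau_syn << T, tau_rec).
#'
#' @param params An [stp_params()].
#' @param period_ms Inter-spike interval, ms.
#' @return Named list with `u_star` (post-spike-update utilisation) and
#'   `x_star` (recovered fraction just before release).
#' @export
stp_fixed_point <- function(params, period_ms) {
  ef <- if (params$tau_fac > 0) exp(-period_ms / params$tau_fac) else 0
  u_star <- params$u_base / (1 - (1 - params$u_base) * ef)
  er <- exp(-period_ms / params$tau_rec)
  x_star <- (1 - er) / (1 - (1 - u_star) * er)
  list(u_star = u_star, x_star = x_star)
}
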