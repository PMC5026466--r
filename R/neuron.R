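#' Single-compartment neuron parameters
#'
#' Passive and spiking parameters of a leaky integrate-and-fire point
#' neuron. Units are fixed package-wide as mV, pA, nS, pF and ms, which
#' makes the membrane equation unit-consistent (nS * mV = pA).
#' Capacitance is derived as `membrane_time_constant / input_resistance`
#' (ms / GOhm = pF).
#'
#' @param resting_potential Resting membrane potential, mV.
#' @param membrane_time_constant Passive membrane time constant, ms.
#' @param input_resistance Input resistance, GOhm (> 0).
#' @param spike_threshold Action-potential threshold, mV. Must exceed
#'   `resting_potential` when spiking is enabled.
#' @param spike_reset Post-spike reset potential, mV.
#' @param refractory_period Absolute refractory period, ms (>= 0).
#' @param spiking_enabled Logical; `FALSE` emulates intracellular QX-314
#'   (fast sodium-channel blockade), leaving a purely passive membrane.
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(resting_potential = -68,
                          membrane_time_constant = 98.8,
                          input_resistance = 0.95,
                          spike_threshold = -43.7,
                          spike_reset = -54,
                          refractory_period = 2,
                          spiking_enabled = FALSE) {
  if (!(input_resistance > 0)) stop("`input_resistance` must be > 0")
  if (refractory_period < 0) stop("`refractory_period` must be >= 0")
  if (!(membrane_time_constant > 0))
    stop("`membrane_time_constant` must be > 0")
  if (isTRUE(spiking_enabled) && !(spike_threshold > resting_potential))
    stop("`spike_threshold` must exceed `resting_potential` when spiking")
  structure(
    list(resting_potential = resting_potential,
         membrane_time_constant = membrane_time_constant,
         input_resistance = input_resistance,
         capacitance = membrane_time_constant / input_resistance,
         spike_threshold = spike_threshold,
         spike_reset = spike_reset,
         refractory_period = refractory_period,
         spiking_enabled = isTRUE(spiking_enabled)),
    class = "neuron_params"
  )
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf(
    "<neuron_params> E_rest %.4g mV, tau_m %.4g ms, R_in %.3g GOhm (C %.4g pF)%s\n",
    x$resting_potential, x$membrane_time_constant, x$input_resistance,
    x$capacitance,
    if (x$spiking_enabled)
      sprintf(", spiking (theta %.4g mV, reset %.4g mV, refrac %.3g ms)",
              x$spike_threshold, x$spike_reset, x$refractory_period)
    else ", passive"))
  invisible(x)
}

# Internal membrane integrator: exponential Euler with conductances
# taken at the midpoint of each step. `conductances` is a list of
# list(g = <nS trace>, reversal = <mV>); `i_inj` is a scalar or a full
# pA trace. The scheme is exact for piecewise-constant inputs and
# second-order accurate for smooth conductance waveforms.
integrate_membrane <- function(neuron, time, conductances = list(),
                               i_inj = 0, spiking = neuron$spiking_enabled,
                               v_init = NULL) {
  dt <- check_uniform_grid(time)
  if (dt > neuron$membrane_time_constant / 50)
    stop("unstable integration step: dt must be <= tau_m / 50")
  n <- length(time)
  i_inj <- if (length(i_inj) == 1L) rep(i_inj, n) else i_inj
  stopifnot(length(i_inj) == n)

  g_leak <- 1 / neuron$input_resistance           # GOhm^-1 = nS
  cm <- neuron$capacitance
  g_tot <- rep(g_leak, n)
  gE_tot <- rep(g_leak * neuron$resting_potential, n)
  for (cond in conductances) {
    stopifnot(length(cond$g) == n)
    g_tot <- g_tot + cond$g
    gE_tot <- gE_tot + cond$g * cond$reversal
  }

  if (is.null(v_init)) {
    # start settled under the inputs present at t = 0
    v_init <- (gE_tot[1] + i_inj[1]) / g_tot[1]
  }

  v <- numeric(n)
  v[1] <- v_init
  spike_times <- numeric(0)
  spike_v <- numeric(0)
  refrac_until <- -Inf
  theta <- neuron$spike_threshold
  for (i in seq_len(n - 1L)) {
    g_mid <- (g_tot[i] + g_tot[i + 1L]) / 2
    b_mid <- (gE_tot[i] + gE_tot[i + 1L] + i_inj[i] + i_inj[i + 1L]) / 2
    v_inf <- b_mid / g_mid
    v_next <- v_inf + (v[i] - v_inf) * exp(-dt * g_mid / cm)
    if (spiking) {
      if (time[i + 1L] < refrac_until) {
        v_next <- neuron$spike_reset
      } else if (v_next >= theta) {
        spike_times <- c(spike_times, time[i + 1L])
        spike_v <- c(spike_v, v_next)
        v_next <- neuron$spike_reset
        refrac_until <- time[i + 1L] + neuron$refractory_period
      }
    }
    v[i + 1L] <- v_next
  }
  list(v = v, spike_times = spike_times, spike_crossings = spike_v)
}

#' Injected current needed to hold a passive neuron at a target potential
#'
#' Convenience for multi-holding current-clamp protocols: returns the
#' constant current (pA) that holds the passive membrane at `v_target`
#' at steady state.
#'
#' @param neuron A [neuron_params()].
#' @param v_target Target holding potential, mV.
#' @return Holding current in pA.
#' @export
holding_current <- function(neuron, v_target) {
  (v_target - neuron$resting_potential) / neuron$input_resistance
}
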