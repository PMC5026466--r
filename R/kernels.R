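#' Parametric bi-exponential synaptic conductance kernel
#'
#' Describes a single synapse type as a difference-of-exponentials
#' conductance waveform, amplitude-normalized so that the waveform peak
#' equals `amplitude`. This is the standard phenomenological shape for
#' AMPA- and GABA-A-mediated conductances and is the element from which
#' all simulated synaptic drive in this package is built.
#'
#' @param amplitude Peak conductance in nS (>= 0).
#' @param onset_latency Delay in ms between the presynaptic event and the
#'   foot of the conductance waveform (>= 0).
#' @param rise_tau Rise time constant in ms (> 0).
#' @param decay_tau Decay time constant in ms (> `rise_tau`).
#' @param reversal_potential Reversal potential of the synaptic current
#'   in mV (0 for glutamatergic excitation, -75 for chloride-mediated
#'   GABA-A inhibition in this preparation).
#' @return An object of class `synapse_kernel`.
#' @seealso [bi_exponential_waveform()]
#' @export
synapse_kernel <- function(amplitude, onset_latency = 0, rise_tau, decay_tau,
                           reversal_potential) {
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0)
    stop("`amplitude` must be a single non-negative number (nS)")
  if (onset_latency < 0) stop("`onset_latency` must be >= 0")
  if (!(rise_tau > 0)) stop("`rise_tau` must be > 0")
  if (!(decay_tau > rise_tau))
    stop("invalid kernel: `decay_tau` must exceed `rise_tau`")
  structure(
    list(amplitude = amplitude, onset_latency = onset_latency,
         rise_tau = rise_tau, decay_tau = decay_tau,
         reversal_potential = reversal_potential),
    class = "synapse_kernel"
  )
}

#' @export
print.synapse_kernel <- function(x, ...) {
  cat(sprintf(
    "<synapse_kernel> peak %.3g nS, onset %.3g ms, rise/decay %.3g/%.3g ms, E_rev %.4g mV\n",
    x$amplitude, x$onset_latency, x$rise_tau, x$decay_tau, x$reversal_potential))
  invisible(x)
}

# Time from waveform foot to peak (closed form for a difference of
# exponentials); used for amplitude normalization.
kernel_time_to_peak <- function(rise_tau, decay_tau) {
  decay_tau * rise_tau / (decay_tau - rise_tau) * log(decay_tau / rise_tau)
}

# Normalization constant so that the waveform maximum equals `amplitude`.
kernel_norm <- function(rise_tau, decay_tau) {
  tp <- kernel_time_to_peak(rise_tau, decay_tau)
  1 / (exp(-tp / decay_tau) - exp(-tp / rise_tau))
}

#' Evaluate a synaptic conductance waveform on a time grid
#'
#' Computes `g(t) = A * N * (exp(-(t - t0)/decay_tau) - exp(-(t - t0)/rise_tau))`
#' for `t >= t0 = event_time + onset_latency` and 0 before, with `N`
#' chosen so that the waveform peak equals the kernel amplitude.
#'
#' @param kernel A [synapse_kernel()].
#' @param time_grid Uniform time grid in ms.
#' @param event_time Presynaptic event time in ms.
#' @return Conductance trace in nS, same length as `time_grid`.
#' @examples
#' k <- synapse_kernel(1, onset_latency = 2, rise_tau = 2, decay_tau = 20,
#'                     reversal_potential = 0)
#' g <- bi_exponential_waveform(k, seq(0, 100, by = 0.05), event_time = 10)
#' max(g)  # 1 nS
#' @export
bi_exponential_waveform <- function(kernel, time_grid, event_time = 0) {
  stopifnot(inherits(kernel, "synapse_kernel"))
  check_uniform_grid(time_grid)
  s <- time_grid - (event_time + kernel$onset_latency)
  g <- numeric(length(time_grid))
  if (kernel$amplitude == 0) return(g)
  pos <- s > 0
  nrm <- kernel_norm(kernel$rise_tau, kernel$decay_tau)
  g[pos] <- kernel$amplitude * nrm *
    (exp(-s[pos] / kernel$decay_tau) - exp(-s[pos] / kernel$rise_tau))
  g
}

# Internal: validate a strictly increasing uniform grid.
check_uniform_grid <- function(time_grid) {
  if (length(time_grid) < 2L) stop("time grid must have at least 2 samples")
  d <- diff(time_grid)
  if (any(d <= 0)) stop("time grid must be strictly increasing")
  if (max(abs(d - d[1])) > 1e-9 * max(d[1], 1))
    stop("time grid must be uniform")
  invisible(d[1])
}

# Internal: scale a kernel's amplitude, returning a new kernel.
scale_kernel <- function(kernel, factor) {
  k <- kernel
  k$amplitude <- kernel$amplitude * factor
  k
}
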