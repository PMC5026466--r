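# Per-pulse postsynaptic-potential measurement with exponential decay
# subtraction, temporal-offset attenuation, cell-attached spike
# probability, and interneuron inhibition-pattern classification.

#' Measure per-pulse PSP amplitudes in a train with decay subtraction
#'
#' Later pulses in a 10 Hz train ride on the decay of earlier
#' responses. For each pulse after the first, a single exponential is
#' fitted to the `decay_window` ms of trace preceding the pulse,
#' extrapolated under the response and subtracted; the amplitude is the
#' baseline-to-peak of the residual within that pulse's window. The
#' first pulse's amplitude is raw peak minus the pre-stimulus baseline.
#'
#' @param sweep A current-clamp [recording_sweep()] with stimulus
#'   events.
#' @param polarity `"epsp"` (depolarizing) or `"ipsp"` (hyperpolarizing,
#'   amplitudes reported positive).
#' @param pulse_times Pulse times, ms; defaults to the sweep's visual
#'   (or only) stimulus train. For bimodal sweeps the visual train
#'   defines the per-pulse windows so the measured amplitude is that of
#'   the combined response.
#' @param decay_window Length, ms, of the pre-pulse segment used for
#'   the exponential decay fit.
#' @param baseline_window Length, ms, of the pre-stimulus baseline
#'   average.
#' @return An object of class `psp_train` with `pulse_times`,
#'   `amplitudes` (mV), `normalized` (amplitudes / first),
#'   `steady_state_ratio` (mean normalized amplitude after pulse 3),
#'   `polarity` and an `unreliable` flag per pulse (pulse falling within
#'   the rise time of its predecessor).
#' @export
measure_psp_train <- function(sweep, polarity = c("epsp", "ipsp"),
                              pulse_times = NULL, decay_window = 20,
                              baseline_window = 20) {
  polarity <- match.arg(polarity)
  sgn <- if (polarity == "epsp") 1 else -1
  if (is.null(pulse_times)) {
    ev <- sweep$stimulus_events
    mods <- unique(ev$modality)
    pulse_times <- if ("visual" %in% mods)
      sort(ev$time[ev$modality == "visual"]) else sort(unique(ev$time))
  }
  np <- length(pulse_times)
  stopifnot(np >= 1L)
  ipi <- if (np > 1) min(diff(pulse_times)) else
    max(sweep$time) - pulse_times[1]
  t <- sweep$time
  v <- sgn * sweep$primary_trace
  baseline <- mean(v[t >= pulse_times[1] - baseline_window &
                       t < pulse_times[1]])
  y <- v - baseline

  amps <- numeric(np)
  unreliable <- logical(np)
  for (k in seq_len(np)) {
    w_end <- if (k < np) pulse_times[k + 1] else
      min(pulse_times[k] + ipi, max(t))
    win <- t >= pulse_times[k] & t < w_end
    if (k == 1L) {
      amps[k] <- max(y[win])
      next
    }
    if (pulse_times[k] - pulse_times[k - 1] < 5) unreliable[k] <- TRUE
    fit_sel <- t >= pulse_times[k] - decay_window & t < pulse_times[k]
    dec <- fit_decay_exponential(t[fit_sel], y[fit_sel])
    resid <- y[win] - dec$predict(t[win])
    amps[k] <- max(resid) - resid[1]
  }
  structure(list(pulse_times = pulse_times, amplitudes = amps,
                 normalized = amps / amps[1],
                 steady_state_ratio = if (np > 3)
                   mean(amps[4:np] / amps[1]) else NA_real_,
                 polarity = toupper(polarity), unreliable = unreliable,
                 baseline = sgn * baseline),
            class = "psp_train")
}

# Log-linear single-exponential fit y ~ A exp(-t/tau); falls back to a
# straight-line extrapolation when the segment is not a clean decay
# (near-zero or sign-changing values).
fit_decay_exponential <- function(tt, yy) {
  usable <- yy > max(abs(yy)) * 1e-3
  if (sum(usable) >= 10 && all(diff(yy[usable]) <= max(abs(yy)) * 0.05)) {
    fit <- stats::lm(log(yy[usable]) ~ tt[usable])
    a <- unname(stats::coef(fit))
    if (is.finite(a[2]) && a[2] < 0)
      return(list(predict = function(x) exp(a[1] + a[2] * x)))
  }
  fit <- stats::lm(yy ~ tt)
  a <- unname(stats::coef(fit))
  list(predict = function(x) a[1] + a[2] * x)
}

#' @export
print.psp_train <- function(x, ...) {
  cat(sprintf("<psp_train> %s, %d pulses; first %.3g mV; steady-state ratio %.3g\n",
              x$polarity, length(x$amplitudes), x$amplitudes[1],
              x$steady_state_ratio))
  invisible(x)
}

#' Temporal-offset attenuation curve of the combined bimodal EPSP
#'
#' For a series of bimodal sweeps differing only in the temporal offset
#' between the two afferent trains, measures the combined first-EPSP
#' amplitude of each sweep (via [measure_psp_train()], pulse 1, window
#' anchored on the visual train) and normalizes to the temporally
#' aligned (offset 0) amplitude.
#'
#' @param sweeps List of bimodal current-clamp sweeps, one per offset;
#'   the offset-0 sweep must be present.
#' @return An object of class `offset_curve` with `offsets` (ms),
#'   `amplitude` (mV), `normalized_amplitude`,
#'   `max_attenuation_percent` (`100 (1 - min normalized)`) and
#'   `offset_at_max_attenuation` (ms).
#' @export
offset_attenuation_curve <- function(sweeps) {
  offs <- unname(vapply(sweeps, function(s) s$protocol$bimodal_offset,
                        numeric(1)))
  if (!any(offs == 0)) stop("offset-0 (aligned) sweep is required")
  ord <- order(offs)
  offs <- offs[ord]; sweeps <- sweeps[ord]
  amps <- unname(vapply(sweeps, function(s)
    measure_psp_train(s, "epsp")$amplitudes[1], numeric(1)))
  norm <- amps / amps[offs == 0][1]
  structure(list(offsets = offs, amplitude = amps,
                 normalized_amplitude = norm,
                 max_attenuation_percent = 100 * (1 - min(norm)),
                 offset_at_max_attenuation = offs[which.min(norm)]),
            class = "offset_curve")
}

#' @export
print.offset_curve <- function(x, ...) {
  cat(sprintf("<offset_curve> offsets %s ms; max attenuation %.3g%% at %g ms\n",
              paste(x$offsets, collapse = ","), x$max_attenuation_percent,
              x$offset_at_max_attenuation))
  invisible(x)
}

#' Stimulus-locked spike probability from cell-attached sweeps
#'
#' Fraction of (sweep, pulse) pairs containing at least one spike in
#' the response window after the pulse; at most one spike is counted
#' per pulse.
#'
#' @param sweeps List of cell-attached [recording_sweep()]s with spike
#'   times and stimulus events.
#' @param window Length-2 response window relative to each pulse, ms.
#' @return Probability in `[0, 1]`.
#' @export
spike_probability <- function(sweeps, window = c(0, 30)) {
  hits <- 0L; total <- 0L
  for (s in sweeps) {
    pulses <- sort(unique(s$stimulus_events$time))
    for (p in pulses) {
      total <- total + 1L
      if (any(s$spikes >= p + window[1] & s$spikes <= p + window[2]))
        hits <- hits + 1L
    }
  }
  if (total == 0L) return(0)
  hits / total
}

#' Threshold-crossing spike detector for voltage traces
#'
#' Event detector for trace-based inputs (the simulator's cell-attached
#' sweeps already carry event times): upward crossings of a voltage
#' threshold with a dead time.
#'
#' @param sweep A current-clamp [recording_sweep()].
#' @param threshold Detection threshold, mV.
#' @param dead_time Minimum separation between detected events, ms.
#' @return Spike times, ms.
#' @export
detect_spikes <- function(sweep, threshold = -20, dead_time = 2) {
  v <- sweep$primary_trace
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  times <- sweep$time[up]
  keep <- numeric(0)
  last <- -Inf
  for (tm in times) {
    if (tm - last >= dead_time) { keep <- c(keep, tm); last <- tm }
  }
  keep
}

#' Quadrant response of a tectal interneuron
#'
#' Maximal EPSP and IPSP amplitudes evoked from each of the four
#' retinal quadrants, sorted descending by EPSP (Q1 carries the largest
#' excitation).
#'
#' @param epsp,ipsp Numeric length-4 vectors of quadrant EPSP and IPSP
#'   amplitudes, mV (positive magnitudes).
#' @return An object of class `quadrant_response` (sorted).
#' @export
quadrant_response <- function(epsp, ipsp) {
  stopifnot(length(epsp) == 4L, length(ipsp) == 4L)
  ord <- order(epsp, decreasing = TRUE)
  structure(list(epsp = epsp[ord], ipsp = ipsp[ord],
                 quadrant = paste0("Q", 1:4)),
            class = "quadrant_response")
}

#' Classify an interneuron's inhibition pattern
#'
#' Three provisional classes by where inhibition appears relative to
#' excitation across the sorted quadrants: `no_inhibition` if every
#' quadrant's IPSP is below the floor; `global_inhibition` if any
#' quadrant without appreciable excitation still shows inhibition;
#' `local_inhibition` otherwise (inhibition only where excitation is
#' present).
#'
#' @param response A [quadrant_response()].
#' @param ipsp_floor Amplitude floor, mV, below which inhibition counts
#'   as absent (the boundary for "weak" inhibition).
#' @return One of `"local_inhibition"`, `"no_inhibition"`,
#'   `"global_inhibition"`.
#' @export
classify_interneuron <- function(response, ipsp_floor = 1.0) {
  stopifnot(inherits(response, "quadrant_response"))
  if (all(response$ipsp < ipsp_floor)) return("no_inhibition")
  if (any(response$epsp < ipsp_floor & response$ipsp >= ipsp_floor))
    return("global_inhibition")
  "local_inhibition"
}
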