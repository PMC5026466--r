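#' Afferent stimulation protocol
#'
#' Describes one stimulation protocol: which afferent pathway(s) are
#' driven, the pulse train, the stimulation strength, and (for bimodal
#' protocols) the temporal offset of the electrosensory train relative
#' to the visual one.
#'
#' @param modality One of `"visual"`, `"electrosensory"`, `"bimodal"`.
#' @param n_pulses Number of pulses in the train (>= 1).
#' @param frequency Train frequency, Hz (> 0).
#' @param intensity_scale Dimensionless stimulation strength scaling
#'   all afferent conductance amplitudes. With
#'   `intensity_unit = "threshold"` it is interpreted as a multiple of
#'   the profile's spike-threshold intensity T (e.g. 0.7 for the
#'   0.7 x T condition); with `"relative"` (default) it multiplies the
#'   kernel amplitudes directly.
#' @param intensity_unit `"relative"` or `"threshold"` (see
#'   `intensity_scale`).
#' @param bimodal_offset Delay in ms of the electrosensory train
#'   relative to the visual train in bimodal mode (>= 0).
#' @param stimulus_duration Extracellular stimulus duration in
#'   microseconds, or `NA` for intracellular protocols. When given, the
#'   afferent drive is additionally scaled by the profile's
#'   duration-recruitment curve.
#' @param n_sweeps Number of repeated sweeps.
#' @param seed Integer seed for any additive recording noise.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(modality = c("visual", "electrosensory", "bimodal"),
                              n_pulses = 1L, frequency = 10,
                              intensity_scale = 1,
                              intensity_unit = c("relative", "threshold"),
                              bimodal_offset = 0,
                              stimulus_duration = NA_real_,
                              n_sweeps = 1L, seed = 1L) {
  modality <- match.arg(modality)
  intensity_unit <- match.arg(intensity_unit)
  if (n_pulses < 1) stop("`n_pulses` must be >= 1")
  if (!(frequency > 0)) stop("`frequency` must be > 0")
  if (!(intensity_scale > 0)) stop("`intensity_scale` must be > 0")
  if (bimodal_offset < 0) stop("`bimodal_offset` must be >= 0")
  structure(
    list(modality = modality, n_pulses = as.integer(n_pulses),
         frequency = frequency, intensity_scale = intensity_scale,
         intensity_unit = intensity_unit,
         bimodal_offset = bimodal_offset,
         stimulus_duration = stimulus_duration,
         n_sweeps = as.integer(n_sweeps), seed = as.integer(seed)),
    class = "stimulus_protocol"
  )
}

# Pulse times (ms) for one modality of a protocol, relative to sweep
# time, with the train starting at `stim_onset`. The electrosensory
# train is the one delayed by `bimodal_offset` in bimodal mode.
protocol_pulse_times <- function(protocol, modality, stim_onset) {
  ipi <- 1000 / protocol$frequency
  base <- stim_onset + ipi * (seq_len(protocol$n_pulses) - 1L)
  if (protocol$modality == "bimodal" && modality == "electrosensory")
    base + protocol$bimodal_offset
  else
    base
}

# Modalities engaged by a protocol.
protocol_modalities <- function(protocol) {
  if (protocol$modality == "bimodal") c("visual", "electrosensory")
  else protocol$modality
}

#' A single recorded sweep
#'
#' The universal exchange record for one trial: a time series (membrane
#' potential, clamp current, LFP proxy, or spike raster) plus protocol
#' and provenance metadata. Constructed by the simulation functions and
#' by [read_bundle()]; all analysis functions consume it.
#'
#' @param kind One of `"current_clamp"`, `"voltage_clamp"`,
#'   `"cell_attached"`, `"lfp"`.
#' @param time Uniform, strictly increasing time grid, ms.
#' @param primary_trace Trace, same length as `time`: mV for
#'   current clamp, pA for voltage clamp, arbitrary units for LFP, a 0/1
#'   spike raster for cell-attached sweeps.
#' @param holding_level Command potential (mV, voltage clamp) or
#'   injected holding current (pA, current clamp); `NA` otherwise.
#' @param stimulus_events Data frame with columns `time` (ms) and
#'   `modality`.
#' @param protocol The [stimulus_protocol()] used.
#' @param spikes Numeric vector of spike times, ms (cell-attached and
#'   spiking current-clamp sweeps).
#' @param metadata Named list of provenance fields (profile, condition,
#'   step onset, units, ...).
#' @return An object of class `recording_sweep`.
#' @export
recording_sweep <- function(kind, time, primary_trace, holding_level = NA_real_,
                            stimulus_events = NULL, protocol = NULL,
                            spikes = numeric(0), metadata = list()) {
  kind <- match.arg(kind, c("current_clamp", "voltage_clamp",
                            "cell_attached", "lfp"))
  check_uniform_grid(time)
  if (length(primary_trace) != length(time))
    stop("`primary_trace` and `time` must have equal length")
  if (kind %in% c("current_clamp", "voltage_clamp") && is.na(holding_level))
    stop("`holding_level` is required for clamp sweeps")
  if (is.null(stimulus_events))
    stimulus_events <- data.frame(time = numeric(0), modality = character(0))
  structure(
    list(kind = kind, time = time, primary_trace = primary_trace,
         holding_level = holding_level, stimulus_events = stimulus_events,
         protocol = protocol, spikes = spikes, metadata = metadata),
    class = "recording_sweep"
  )
}

#' @export
print.recording_sweep <- function(x, ...) {
  cat(sprintf(
    "<recording_sweep> %s, %d samples (dt %.3g ms), %d stimulus events%s\n",
    x$kind, length(x$time), x$time[2] - x$time[1], nrow(x$stimulus_events),
    if (!is.na(x$holding_level))
      sprintf(", holding %.4g %s", x$holding_level,
              if (x$kind == "voltage_clamp") "mV" else "pA")
    else ""))
  invisible(x)
}

# Internal: sampling interval of a sweep.
sweep_dt <- function(sweep) sweep$time[2] - sweep$time[1]
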