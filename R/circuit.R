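#' Tectal microcircuit configuration
#'
#' Bundles the neuron models, synaptic kernels, connectivity and
#' condition flags of the simulated feedforward-inhibition microcircuit:
#' visual and electrosensory afferents excite both the deep-layer output
#' neuron and the superficial-layer GABAergic interneuron; the
#' interneuron in turn inhibits the output neuron with a disynaptic lag.
#' Off-field stimulation of a second column recruits lateral inhibition
#' only.
#'
#' @param output_neuron,interneuron [neuron_params()] for the two cell
#'   classes.
#' @param excitatory_kernels Nested list
#'   `list(visual = list(output =, interneuron =), electrosensory = ...)`
#'   of [synapse_kernel()]s for the monosynaptic afferent drive.
#' @param inhibitory_kernel [synapse_kernel()] for the
#'   interneuron-to-output feedforward inhibition. The interneuron to
#'   output coupling is a rate proxy: each afferent pulse contributes one
#'   inhibitory waveform whose amplitude scales with the afferent drive
#'   of that pulse (intensity and per-pulse depression included).
#' @param feedforward_lag Onset lag of feedforward (and lateral)
#'   inhibition relative to monosynaptic excitation, ms, in `[0, 50]`.
#' @param lateral_inhibition_weight Named numeric vector
#'   `c(visual =, electrosensory =)`: dimensionless scale of the lateral
#'   inhibition that an off-field stimulus of that modality recruits onto
#'   the on-field column.
#' @param depression_per_pulse Per-pulse amplitude scale factors in
#'   `(0, 1]` with first factor 1; pulses beyond the sequence reuse the
#'   last factor (steady state).
#' @param gabazine Logical; `TRUE` (GABA-A blockade) forces all
#'   inhibitory conductance amplitudes to zero.
#' @param noise_sd Standard deviation of additive Gaussian recording
#'   noise (mV, pA or a.u. according to sweep kind); 0 disables noise.
#' @param integration_step Integration step, ms (must be <= 0.1).
#' @param calibration_profile Name of the calibration profile this
#'   configuration derives from.
#' @param drive_duration_half,drive_duration_hill Parameters of the
#'   saturating stimulus-duration recruitment curve
#'   `s(d) = d^h / (d^h + d50^h)` (microseconds) applied when a protocol
#'   carries an extracellular `stimulus_duration`.
#' @param threshold_drive Dimensionless calibration factor mapping
#'   `intensity_scale = 1` to the spike-threshold stimulation intensity T
#'   of cell-attached protocols.
#' @param inhibitory_recruitment_power Exponent applied to the pooled
#'   afferent drive when scaling interneuron-mediated inhibition
#'   (> 1 makes combined-modality recruitment supralinear, reflecting
#'   interneurons sitting near spike threshold; 1 is linear).
#' @return An object of class `circuit_config`.
#' @export
circuit_config <- function(output_neuron, interneuron, excitatory_kernels,
                           inhibitory_kernel, feedforward_lag = 7.5,
                           lateral_inhibition_weight = c(visual = 0,
                                                         electrosensory = 0),
                           depression_per_pulse = c(1, 0.75, 0.62),
                           gabazine = FALSE, noise_sd = 0,
                           integration_step = 0.05,
                           calibration_profile = "custom",
                           drive_duration_half = 300,
                           drive_duration_hill = 1.3,
                           threshold_drive = 1,
                           inhibitory_recruitment_power = 1) {
  if (feedforward_lag < 0 || feedforward_lag > 50)
    stop("`feedforward_lag` must lie in [0, 50] ms")
  if (any(depression_per_pulse <= 0) || any(depression_per_pulse > 1))
    stop("depression scale factors must lie in (0, 1]")
  if (depression_per_pulse[1] != 1)
    stop("first depression factor must be 1")
  if (integration_step > 0.1)
    stop("configuration error: `integration_step` must be <= 0.1 ms")
  if (!(inhibitory_recruitment_power > 0))
    stop("`inhibitory_recruitment_power` must be > 0")
  for (m in c("visual", "electrosensory"))
    for (tg in c("output", "interneuron"))
      stopifnot(inherits(excitatory_kernels[[m]][[tg]], "synapse_kernel"))
  stopifnot(inherits(inhibitory_kernel, "synapse_kernel"))
  structure(
    list(output_neuron = output_neuron, interneuron = interneuron,
         excitatory_kernels = excitatory_kernels,
         inhibitory_kernel = inhibitory_kernel,
         feedforward_lag = feedforward_lag,
         lateral_inhibition_weight = lateral_inhibition_weight,
         depression_per_pulse = depression_per_pulse,
         gabazine = isTRUE(gabazine), noise_sd = noise_sd,
         integration_step = integration_step,
         calibration_profile = calibration_profile,
         drive_duration_half = drive_duration_half,
         drive_duration_hill = drive_duration_hill,
         threshold_drive = threshold_drive,
         inhibitory_recruitment_power = inhibitory_recruitment_power),
    class = "circuit_config"
  )
}

#' Condition modifiers: GABA-A and fast-sodium-channel blockade
#'
#' `apply_gabazine()` zeroes all inhibitory conductances (bath/local
#' GABA-A antagonist); `apply_qx314()` disables spiking in the recorded
#' output neuron (intracellular fast sodium-channel blocker), leaving
#' the membrane passive.
#'
#' @param config A [circuit_config()].
#' @return The modified configuration.
#' @export
apply_gabazine <- function(config) {
  config$gabazine <- TRUE
  config
}

#' @rdname apply_gabazine
#' @export
apply_qx314 <- function(config) {
  config$output_neuron$spiking_enabled <- FALSE
  config
}

# Per-pulse amplitude scale: intensity x short-term depression
# (sequence extended at its last value), x duration recruitment when an
# extracellular stimulus_duration is present, x the profile's
# threshold-intensity calibration.
pulse_scales <- function(protocol, config) {
  dep <- config$depression_per_pulse
  k <- pmin(seq_len(protocol$n_pulses), length(dep))
  unit <- protocol$intensity_unit %||% "relative"
  s <- protocol$intensity_scale * dep[k] *
    (if (identical(unit, "threshold")) config$threshold_drive else 1)
  if (!is.na(protocol$stimulus_duration)) {
    d <- protocol$stimulus_duration
    h <- config$drive_duration_hill
    s <- s * d^h / (d^h + config$drive_duration_half^h)
  }
  s
}

#' Monosynaptic afferent conductance drive
#'
#' Sums amplitude-scaled bi-exponential waveforms over the pulses of a
#' protocol, per engaged modality, onto the requested target cell.
#' Per-pulse amplitudes are scaled by the protocol intensity and the
#' configured short-term depression sequence; in bimodal mode the
#' electrosensory train is delayed by the protocol's `bimodal_offset`.
#'
#' @param protocol A [stimulus_protocol()].
#' @param config A [circuit_config()].
#' @param target `"output"` or `"interneuron"`.
#' @param time_grid Uniform time grid, ms.
#' @param stim_onset Time of the first visual-train pulse, ms.
#' @return List with `conductance` (named list of nS traces per
#'   modality) and `events` (data frame of pulse times and modalities).
#' @export
afferent_drive <- function(protocol, config, target = c("output", "interneuron"),
                           time_grid, stim_onset = 20) {
  target <- match.arg(target)
  mods <- protocol_modalities(protocol)
  if (!all(mods %in% names(config$excitatory_kernels)))
    stop("unknown modality: ", paste(setdiff(mods, names(config$excitatory_kernels)),
                                     collapse = ", "))
  scales <- pulse_scales(protocol, config)
  g <- list()
  ev_time <- numeric(0); ev_mod <- character(0)
  for (m in mods) {
    kern <- config$excitatory_kernels[[m]][[target]]
    pulses <- protocol_pulse_times(protocol, m, stim_onset)
    trace <- numeric(length(time_grid))
    for (k in seq_along(pulses))
      trace <- trace + bi_exponential_waveform(scale_kernel(kern, scales[k]),
                                               time_grid, pulses[k])
    g[[m]] <- trace
    ev_time <- c(ev_time, pulses); ev_mod <- c(ev_mod, rep(m, length(pulses)))
  }
  ord <- order(ev_time)
  list(conductance = g,
       events = data.frame(time = ev_time[ord], modality = ev_mod[ord]))
}

# Feedforward (or lateral) inhibitory conductance recruited by the
# afferent pulse trains: one inhibitory waveform per afferent event,
# delayed by the disynaptic lag, with amplitude following the same
# per-pulse drive scaling (rate-proxy coupling). Coincident events from
# different modalities pool their drive, and the pooled drive passes
# through the configured recruitment power (interneurons near
# threshold respond supralinearly, which makes combined-modality
# inhibition more than the sum of the unimodal recruitments). `weight`
# rescales for lateral inhibition. Returns a zero trace under gabazine.
inhibitory_drive <- function(protocol, config, time_grid, stim_onset = 20,
                             weight = 1) {
  trace <- numeric(length(time_grid))
  if (config$gabazine || weight == 0 ||
      config$inhibitory_kernel$amplitude == 0)
    return(trace)
  gamma <- config$inhibitory_recruitment_power %||% 1
  scales <- pulse_scales(protocol, config)
  ev_time <- numeric(0); ev_scale <- numeric(0)
  for (m in protocol_modalities(protocol)) {
    pulses <- protocol_pulse_times(protocol, m, stim_onset)
    ev_time <- c(ev_time, pulses)
    ev_scale <- c(ev_scale, scales)
  }
  pooled <- tapply(ev_scale, ev_time, sum)
  times <- as.numeric(names(pooled)) + config$feedforward_lag
  amps <- as.numeric(pooled)^gamma * weight
  for (k in seq_along(times))
    trace <- trace + bi_exponential_waveform(
      scale_kernel(config$inhibitory_kernel, amps[k]), time_grid, times[k])
  trace
}

# Internal: additive Gaussian recording noise, seeded from the protocol.
add_recording_noise <- function(trace, config, protocol, stream = 0L) {
  if (config$noise_sd <= 0) return(trace)
  seed <- (protocol$seed + 104729L * stream) %% .Machine$integer.max
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  trace + stats::rnorm(length(trace), 0, config$noise_sd)
}

#' Simulate one recorded cell
#'
#' Integrates the single-compartment membrane equation
#' `C dV/dt = -G_rest (V - E_rest) - sum_s g_s(t) (V - E_s) + I_inj`
#' (exponential-Euler scheme) for the requested recording kind. Only the
#' monosynaptic excitatory drive of the protocol is applied here;
#' [simulate_column()] adds the disynaptic feedforward inhibition.
#'
#' @param config A [circuit_config()].
#' @param protocol A [stimulus_protocol()], or `NULL` for stimulus-free
#'   (current-step) sweeps.
#' @param kind Recording kind: `"current_clamp"` (trace = mV; spiking if
#'   enabled), `"voltage_clamp"` (ideal clamp, no series resistance;
#'   trace = clamp current, pA) or `"cell_attached"` (spike raster).
#' @param holding_level Command potential (mV) for voltage clamp;
#'   injected holding current (pA) for current clamp, applied from
#'   `step_onset` onwards.
#' @param target `"output"` or `"interneuron"`.
#' @param extra_conductances Additional `list(g =, reversal =)` inputs
#'   (used internally for inhibition and in tests for known injected
#'   conductances).
#' @param i_inj Optional full injected-current trace (pA) overriding
#'   `holding_level`/`step_onset`.
#' @param t_end Sweep length, ms.
#' @param stim_onset First-pulse time, ms.
#' @param step_onset Onset of the holding-current step, ms (current
#'   clamp; before it the cell sits at rest, giving the charging phase
#'   used by the passive fits).
#' @return A [recording_sweep()].
#' @export
simulate_cell <- function(config, protocol = NULL,
                          kind = c("current_clamp", "voltage_clamp",
                                   "cell_attached"),
                          holding_level = 0, target = "output",
                          extra_conductances = list(), i_inj = NULL,
                          t_end = 400, stim_onset = 20, step_onset = 0) {
  kind <- match.arg(kind)
  neuron <- if (target == "output") config$output_neuron else config$interneuron
  dt <- config$integration_step
  time <- seq(0, t_end, by = dt)

  conds <- extra_conductances
  events <- NULL
  if (!is.null(protocol)) {
    drive <- afferent_drive(protocol, config, target, time, stim_onset)
    for (m in names(drive$conductance)) {
      kern <- config$excitatory_kernels[[m]][[target]]
      conds <- c(conds, list(list(g = drive$conductance[[m]],
                                  reversal = kern$reversal_potential)))
    }
    events <- drive$events
  }

  if (kind == "voltage_clamp") {
    vh <- holding_level
    i_clamp <- (vh - neuron$resting_potential) / neuron$input_resistance +
      Reduce(`+`, lapply(conds, function(cc) cc$g * (vh - cc$reversal)), 0)
    trace <- add_recording_noise(i_clamp, config, protocol %||% list(seed = 1L))
    return(recording_sweep("voltage_clamp", time, trace, holding_level = vh,
                           stimulus_events = events, protocol = protocol,
                           metadata = sweep_metadata(config, target, kind)))
  }

  if (is.null(i_inj)) {
    i_inj <- rep(0, length(time))
    i_inj[time >= step_onset] <- holding_level
  }
  spiking <- if (kind == "cell_attached") TRUE else neuron$spiking_enabled
  sim <- integrate_membrane(neuron, time, conds, i_inj, spiking = spiking)

  if (kind == "cell_attached") {
    raster <- numeric(length(time))
    raster[findInterval(sim$spike_times, time)] <- 1
    return(recording_sweep("cell_attached", time, raster,
                           stimulus_events = events, protocol = protocol,
                           spikes = sim$spike_times,
                           metadata = sweep_metadata(config, target, kind)))
  }

  trace <- add_recording_noise(sim$v, config, protocol %||% list(seed = 1L))
  recording_sweep("current_clamp", time, trace, holding_level = holding_level,
                  stimulus_events = events, protocol = protocol,
                  spikes = sim$spike_times,
                  metadata = c(sweep_metadata(config, target, kind),
                               list(step_onset = step_onset,
                                    spike_crossings = sim$spike_crossings)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sweep_metadata <- function(config, target, kind) {
  list(profile = config$calibration_profile,
       condition = if (config$gabazine) "gabazine" else "control",
       target = target,
       units = switch(kind, current_clamp = "mV", voltage_clamp = "pA",
                      cell_attached = "raster", lfp = "a.u."))
}

#' Simulate one tectal column (output neuron + interneuron)
#'
#' Drives both cell classes monosynaptically from the protocol's
#' afferents and adds the disynaptic feedforward inhibition onto the
#' output neuron: each afferent pulse contributes one inhibitory
#' conductance waveform delayed by `feedforward_lag`, with amplitude
#' scaled like the afferent drive of that pulse (rate-proxy
#' interneuron-to-output coupling). `gabazine = TRUE` in the
#' configuration zeroes all inhibition.
#'
#' @inheritParams simulate_cell
#' @param interneuron_sweep Logical; also simulate and return the
#'   interneuron's current-clamp sweep.
#' @return List with elements `output` and (optionally) `interneuron`,
#'   each a [recording_sweep()]. The injected ground-truth conductances
#'   are attached to `output$metadata$ground_truth` (nS traces `g_e`,
#'   `g_i`) for parameter-recovery validation.
#' @export
simulate_column <- function(config, protocol,
                            kind = c("current_clamp", "voltage_clamp",
                                     "cell_attached"),
                            holding_level = 0, t_end = 400, stim_onset = 20,
                            step_onset = 0, interneuron_sweep = FALSE) {
  kind <- match.arg(kind)
  dt <- config$integration_step
  time <- seq(0, t_end, by = dt)
  g_i <- inhibitory_drive(protocol, config, time, stim_onset)
  inh <- list(list(g = g_i,
                   reversal = config$inhibitory_kernel$reversal_potential))
  out <- simulate_cell(config, protocol, kind, holding_level,
                       target = "output", extra_conductances = inh,
                       t_end = t_end, stim_onset = stim_onset,
                       step_onset = step_onset)
  drive <- afferent_drive(protocol, config, "output", time, stim_onset)
  out$metadata$ground_truth <- list(
    g_e = Reduce(`+`, drive$conductance, numeric(length(time))),
    g_i = g_i)
  res <- list(output = out)
  if (interneuron_sweep)
    res$interneuron <- simulate_cell(config, protocol, kind, holding_level,
                                     target = "interneuron", t_end = t_end,
                                     stim_onset = stim_onset,
                                     step_onset = step_onset)
  res
}

#' Simulate the two-column extracellular (LFP proxy) experiment
#'
#' The recorded signal is modeled as the signed sum of synaptic
#' currents onto the on-field column's deep-layer population in the
#' current-source approximation (population driving forces evaluated at
#' rest, where the bulk of the contributing membrane sits):
#' `g_e (E_e - E_rest) + g_i (E_i - E_rest)`, inward (excitatory)
#' currents positive. The on-field column receives the on-field
#' excitation and its feedforward inhibition; an optional off-field
#' stimulus of a different modality recruits only lateral inhibition
#' (scaled by the configured modality-specific lateral weight) without
#' adding on-field excitation. The trace is deterministic unless
#' `noise_sd > 0`.
#'
#' @param config A [circuit_config()].
#' @param on_field_modality Modality driving the recorded (on-field)
#'   column: `"visual"`, `"electrosensory"` or `"bimodal"` (both
#'   afferents converging on the on-field column).
#' @param off_field_modality Optional distinct modality stimulating a
#'   spatially disparate column, or `NULL`.
#' @param protocol A [stimulus_protocol()]; its `modality` field is
#'   ignored in favor of the explicit on/off-field arguments.
#' @param t_end,stim_onset Sweep length and stimulus onset, ms.
#' @return A [recording_sweep()] of kind `"lfp"`.
#' @export
simulate_two_column_lfp <- function(config, on_field_modality,
                                    off_field_modality = NULL, protocol,
                                    t_end = 400, stim_onset = 50) {
  on_field_modality <- match.arg(on_field_modality,
                                 c("visual", "electrosensory", "bimodal"))
  if (!is.null(off_field_modality)) {
    off_field_modality <- match.arg(off_field_modality,
                                    c("visual", "electrosensory"))
    if (identical(off_field_modality, on_field_modality))
      stop("on- and off-field modalities must be distinct")
  }
  dt <- config$integration_step
  time <- seq(0, t_end, by = dt)
  on_proto <- protocol; on_proto$modality <- on_field_modality

  drive <- afferent_drive(on_proto, config, "output", time, stim_onset)
  g_e <- Reduce(`+`, drive$conductance, numeric(length(time)))
  g_i <- inhibitory_drive(on_proto, config, time, stim_onset)
  events <- drive$events
  if (!is.null(off_field_modality)) {
    off_proto <- protocol; off_proto$modality <- off_field_modality
    w <- config$lateral_inhibition_weight[[off_field_modality]]
    g_i <- g_i + inhibitory_drive(off_proto, config, time, stim_onset,
                                  weight = w)
    events <- rbind(events,
                    data.frame(time = protocol_pulse_times(off_proto,
                                                           off_field_modality,
                                                           stim_onset),
                               modality = paste0("off_", off_field_modality)))
    events <- events[order(events$time), , drop = FALSE]
  }

  e_e <- config$excitatory_kernels$visual$output$reversal_potential
  e_i <- config$inhibitory_kernel$reversal_potential
  e_rest <- config$output_neuron$resting_potential
  lfp <- g_e * (e_e - e_rest) + g_i * (e_i - e_rest)
  lfp <- add_recording_noise(lfp, config, protocol)
  recording_sweep("lfp", time, lfp, stimulus_events = events,
                  protocol = protocol,
                  metadata = c(sweep_metadata(config, "population", "lfp"),
                               list(on_field = on_field_modality,
                                    off_field = off_field_modality %||% "none")))
}
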