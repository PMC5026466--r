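# Deterministic fixture suite: every sweep collection the analysis
# chain is validated against, written as plain-text bundles.

#' Generate the standard fixture suite
#'
#' Writes, per profile, the sweep bundles used by the validation and
#' reproduction machinery:
#'
#' * `cellular_default`: passive current steps (-2/-4/-6 pA, 500 ms),
#'   f-I steps (2-60 pA), QX-314 V-I steps spanning -120 to -20 mV,
#'   multi-holding current-clamp triplets at -65/-45/-20 mV (visual and
#'   bimodal), a 10-pulse 10 Hz visual PSP train held at -65 mV, a
#'   control/gabazine whole-cell pair, and cell-attached trains at T
#'   and 0.7 T (unimodal and bimodal, 10 sweeps each).
#' * `offset_default`: the bimodal temporal-offset series
#'   (0, 5, 10, 20, 30, 40, 50 ms).
#' * `lfp_default`: the stimulus-duration series (50-1000 us, three
#'   modalities, control and gabazine) and the two-column on/off-field
#'   pairs.
#'
#' All sweeps are noiseless, so the suite is deterministic given the
#' seed (repeated calls produce byte-identical bundles).
#'
#' @param profile_name One profile name or `"all"`.
#' @param dir Output directory; one subdirectory per experiment.
#' @param seed Integer seed recorded in protocols and manifests.
#' @return Named character vector of manifest paths, invisibly.
#' @export
generate_fixture_suite <- function(profile_name = "all", dir, seed = 1L) {
  profiles <- if (profile_name == "all")
    c("cellular_default", "lfp_default", "offset_default")
  else match.arg(profile_name,
                 c("cellular_default", "lfp_default", "offset_default"))
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create fixture directory: ", dir)
  manifests <- character(0)
  put <- function(name, sweeps) {
    path <- write_bundle(sweeps, file.path(dir, name),
                         experiment_name = name, seed = seed,
                         overwrite = TRUE)
    manifests[[name]] <<- path
  }

  if ("cellular_default" %in% profiles) {
    cfg <- calibration_profile("cellular_default")
    passive <- apply_qx314(cfg)

    put("passive_steps", fixture_current_steps(passive, c(-2, -4, -6), seed))
    put("fi_steps", fixture_current_steps(cfg, seq(2, 60, by = 2), seed))
    put("vi_steps", fixture_current_steps(passive, seq(-56, 52, by = 12),
                                          seed))
    put("multiholding_visual",
        fixture_multiholding(passive, "visual", seed))
    put("multiholding_bimodal",
        fixture_multiholding(passive, "bimodal", seed))
    put("psp_train_visual", fixture_psp_train(passive, "visual", seed))
    put("gabazine_pair", fixture_gabazine_pair(cfg, seed))
    put("cell_attached", fixture_cell_attached(cfg, seed))
  }
  if ("offset_default" %in% profiles) {
    cfg <- apply_qx314(calibration_profile("offset_default"))
    put("offset_series", fixture_offset_series(cfg, seed))
  }
  if ("lfp_default" %in% profiles) {
    cfg <- calibration_profile("lfp_default")
    put("duration_series", fixture_duration_series(cfg, seed))
    put("two_column", fixture_two_column(cfg, seed))
  }
  invisible(manifests)
}

# 500 ms current steps from rest (step on at 20 ms).
fixture_current_steps <- function(config, currents, seed) {
  sweeps <- lapply(currents, function(i)
    simulate_cell(config, NULL, "current_clamp", holding_level = i,
                  t_end = 520, step_onset = 20))
  names(sweeps) <- sprintf("step_%+04.0fpA", currents)
  sweeps
}

# Multi-holding triplet at -65/-45/-20 mV: holding step at 20 ms,
# settle for 5 tau, single afferent impulse at 520 ms.
fixture_multiholding <- function(config, modality, seed,
                                 holdings = c(-65, -45, -20)) {
  proto <- stimulus_protocol(modality, n_pulses = 1L, seed = seed)
  sweeps <- lapply(holdings, function(vh)
    simulate_column(config, proto, "current_clamp",
                    holding_level = holding_current(config$output_neuron, vh),
                    t_end = 680, stim_onset = 520,
                    step_onset = 20)$output)
  names(sweeps) <- sprintf("hold_%+03.0fmV", holdings)
  sweeps
}

# 10-pulse 10 Hz train, output neuron held at the inhibitory reversal
# (settled from sweep start) so the measured EPSPs are uncontaminated
# by the feedforward IPSP; QX-314 passive.
fixture_psp_train <- function(config, modality, seed) {
  proto <- stimulus_protocol(modality, n_pulses = 10L, frequency = 10,
                             seed = seed)
  e_inh <- config$inhibitory_kernel$reversal_potential
  sw <- simulate_column(config, proto, "current_clamp",
                        holding_level = holding_current(config$output_neuron,
                                                        e_inh),
                        t_end = 1150, stim_onset = 100,
                        step_onset = 0)$output
  list(train = sw)
}

# Whole-cell control/gabazine pair: 10-pulse visual train at 0.7 T from
# rest, spiking enabled.
fixture_gabazine_pair <- function(config, seed) {
  proto <- stimulus_protocol("visual", n_pulses = 10L, frequency = 10,
                             intensity_scale = 0.7,
                             intensity_unit = "threshold", seed = seed)
  list(control = simulate_column(config, proto, "current_clamp",
                                 holding_level = 0, t_end = 1100,
                                 stim_onset = 50)$output,
       gabazine = simulate_column(apply_gabazine(config), proto,
                                  "current_clamp", holding_level = 0,
                                  t_end = 1100, stim_onset = 50)$output)
}

# Cell-attached trains at T and 0.7 T; deterministic noiseless sweeps
# are replicated to the protocol's sweep count.
fixture_cell_attached <- function(config, seed, n_sweeps = 10L) {
  out <- list()
  for (mod in c("visual", "bimodal")) {
    for (int in c(1, 0.7)) {
      proto <- stimulus_protocol(mod, n_pulses = 10L, frequency = 10,
                                 intensity_scale = int,
                                 intensity_unit = "threshold",
                                 n_sweeps = n_sweeps, seed = seed)
      sw <- simulate_column(config, proto, "cell_attached",
                            t_end = 1100, stim_onset = 50)$output
      for (r in seq_len(n_sweeps))
        out[[sprintf("%s_%03.0fT_sweep%02d", mod, 100 * int, r)]] <- sw
    }
  }
  out
}

# Bimodal temporal-offset series from rest, QX-314 passive.
fixture_offset_series <- function(config, seed,
                                  offsets = c(0, 5, 10, 20, 30, 40, 50)) {
  sweeps <- lapply(offsets, function(off) {
    proto <- stimulus_protocol("bimodal", n_pulses = 4L, frequency = 10,
                               bimodal_offset = off, seed = seed)
    simulate_column(config, proto, "current_clamp", holding_level = 0,
                    t_end = 600, stim_onset = 100)$output
  })
  names(sweeps) <- sprintf("offset_%02.0fms", offsets)
  sweeps
}

# Stimulus-duration series: 8 durations x 3 modalities x 2 conditions.
fixture_duration_series <- function(config, seed,
                                    durations = c(50, 100, 200, 300, 400,
                                                  500, 700, 1000)) {
  sweeps <- list()
  for (cond in c("control", "gabazine")) {
    cc <- if (cond == "gabazine") apply_gabazine(config) else config
    for (mod in c("visual", "electrosensory", "bimodal")) {
      for (d in durations) {
        proto <- stimulus_protocol(mod, n_pulses = 1L,
                                   stimulus_duration = d, seed = seed)
        sweeps[[sprintf("%s_%s_%04.0fus", cond, mod, d)]] <-
          simulate_two_column_lfp(cc, mod, NULL, proto,
                                  t_end = 400, stim_onset = 50)
      }
    }
  }
  sweeps
}

# Two-column on/off-field pairs at the standard 500 us duration.
fixture_two_column <- function(config, seed, duration = 500) {
  proto <- function(mod) stimulus_protocol(mod, n_pulses = 1L,
                                           stimulus_duration = duration,
                                           seed = seed)
  list(
    electro_alone = simulate_two_column_lfp(config, "electrosensory", NULL,
                                            proto("electrosensory"),
                                            t_end = 400, stim_onset = 50),
    electro_with_visual_off = simulate_two_column_lfp(
      config, "electrosensory", "visual", proto("electrosensory"),
      t_end = 400, stim_onset = 50),
    visual_alone = simulate_two_column_lfp(config, "visual", NULL,
                                           proto("visual"),
                                           t_end = 400, stim_onset = 50),
    visual_with_electro_off = simulate_two_column_lfp(
      config, "visual", "electrosensory", proto("visual"),
      t_end = 400, stim_onset = 50))
}
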