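test_that("an isolated PSP is measured baseline-to-peak", {
  tt <- seq(0, 300, by = 0.05)
  v <- -65 + 7.3 * psp_template(tt, onset = 100, rise = 4, decay = 40)
  sw <- as_cc_sweep(tt, v, events = data.frame(time = 100,
                                               modality = "visual"))
  m <- measure_psp_train(sw, "epsp")
  expect_equal(m$amplitudes[1], 7.3, tolerance = 1e-3)
  expect_equal(m$normalized[1], 1)
})

test_that("decay subtraction recovers an amplitude riding on an exponential tail", {
  # 5 mV PSP on the 10 mV, tau = 50 ms tail of a previous response
  tt <- seq(0, 400, by = 0.05)
  tail_v <- ifelse(tt >= 50, 10 * exp(-(tt - 50) / 50), 0)
  psp2 <- 5 * psp_template(tt, onset = 150, rise = 4, decay = 40)
  sw <- as_cc_sweep(tt, -65 + tail_v + psp2,
                    events = data.frame(time = c(50, 150),
                                        modality = "visual"))
  m <- measure_psp_train(sw, "epsp", pulse_times = c(50, 150))
  expect_equal(m$amplitudes[2], 5.00, tolerance = 0.01)
})

test_that("superposed template trains are fully recovered when pulses are well separated", {
  tt <- seq(0, 1200, by = 0.05)
  amps <- c(6, 4.5, 3.7, 3.7, 3.7)
  pulses <- 100 + 100 * (seq_along(amps) - 1)
  v <- -65
  for (k in seq_along(amps))
    v <- v + amps[k] * psp_template(tt, onset = pulses[k], rise = 4,
                                    decay = 30)
  sw <- as_cc_sweep(tt, v, events = data.frame(time = pulses,
                                               modality = "visual"))
  m <- measure_psp_train(sw, "epsp")
  expect_equal(m$amplitudes, amps, tolerance = 0.01)
  expect_equal(m$normalized, amps / amps[1], tolerance = 0.01)
  expect_equal(m$steady_state_ratio, mean(amps[4:5]) / amps[1],
               tolerance = 0.01)
  # IPSP polarity mirrors the same measurement
  swi <- as_cc_sweep(tt, -130 - v,
                     events = data.frame(time = pulses,
                                         modality = "visual"))
  mi <- measure_psp_train(swi, "ipsp")
  expect_equal(mi$amplitudes, amps, tolerance = 0.01)
})

test_that("simulated 10 Hz trains depress over the first pulses then plateau", {
  train <- fx_bundle("psp_train_visual")$train
  m <- measure_psp_train(train, "epsp")
  expect_equal(m$normalized[1], 1)
  expect_true(all(diff(m$normalized[1:3]) < 0))
  expect_lt(max(abs(diff(m$normalized[4:10]))), 0.05)
})

test_that("offset attenuation curve normalizes to temporal alignment and dips at the disynaptic lag", {
  sweeps <- fx_bundle("offset_series")
  curve <- offset_attenuation_curve(sweeps)
  expect_equal(curve$offsets, c(0, 5, 10, 20, 30, 40, 50))
  expect_equal(curve$normalized_amplitude[1], 1)
  expect_true(curve$offset_at_max_attenuation %in% c(5, 10))
  # recovery beyond the lag: 50 ms beats the maximally attenuated offset
  n50 <- curve$normalized_amplitude[curve$offsets == 50]
  expect_gt(n50, min(curve$normalized_amplitude))
  expect_error(offset_attenuation_curve(sweeps[-1]), "offset-0")
})

test_that("spike probability counts stimulus-locked spikes, bounded and order-invariant", {
  tt <- seq(0, 500, by = 0.05)
  mk <- function(spikes) recording_sweep(
    "cell_attached", tt, numeric(length(tt)),
    stimulus_events = data.frame(time = c(100, 200, 300),
                                 modality = "visual"),
    spikes = spikes)
  all_hit <- mk(c(105, 210, 308))
  none <- mk(numeric(0))
  late <- mk(c(140, 250, 370))     # outside the 0-30 ms windows
  expect_equal(spike_probability(list(all_hit)), 1)
  expect_equal(spike_probability(list(none)), 0)
  expect_equal(spike_probability(list(late)), 0)
  mixed <- list(all_hit, none, mk(c(106, 106.5)))  # burst counts once
  p <- spike_probability(mixed)
  expect_equal(p, 4 / 9)
  expect_equal(spike_probability(rev(mixed)), p)
  expect_gte(p, 0); expect_lte(p, 1)
})

test_that("near-threshold stimulation spikes only when both modalities combine", {
  ca <- fx_bundle("cell_attached")
  pick <- function(pattern) ca[grepl(pattern, names(ca))]
  expect_equal(spike_probability(pick("^visual_070T")), 0)
  expect_gt(spike_probability(pick("^bimodal_070T")), 0)
  expect_gt(spike_probability(pick("^visual_100T")), 0.5)
})

test_that("threshold-crossing detector honors its dead time", {
  tt <- seq(0, 100, by = 0.05)
  v <- rep(-65, length(tt))
  v[tt > 20 & tt < 21] <- 10
  v[tt > 21.5 & tt < 22] <- 10   # within dead time of the first event
  v[tt > 60 & tt < 61] <- 10
  sw <- as_cc_sweep(tt, v)
  expect_length(detect_spikes(sw, threshold = -20, dead_time = 2), 2)
})

test_that("interneurons are classified by where inhibition sits relative to excitation", {
  local <- quadrant_response(epsp = c(8, 5, 0.3, 0.2),
                             ipsp = c(6, 4, 0.2, 0.1))
  none <- quadrant_response(epsp = c(7, 6, 1.5, 0.4),
                            ipsp = c(0.6, 0.4, 0.2, 0.1))
  global <- quadrant_response(epsp = c(9, 2, 0.3, 0.1),
                              ipsp = c(5, 4, 6, 7))
  expect_equal(classify_interneuron(local), "local_inhibition")
  expect_equal(classify_interneuron(none), "no_inhibition")
  expect_equal(classify_interneuron(global), "global_inhibition")
  # quadrants arrive sorted by descending EPSP
  expect_true(all(diff(global$epsp) <= 0))
  # floor boundary: inhibition exactly at the floor counts as present
  edge <- quadrant_response(epsp = c(9, 8, 7, 6), ipsp = c(1, 0, 0, 0))
  expect_equal(classify_interneuron(edge, ipsp_floor = 1),
               "local_inhibition")
})
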