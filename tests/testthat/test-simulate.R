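cfg <- quick_passive_config()

test_that("membrane sits at rest indefinitely with no input", {
  sw <- simulate_cell(cfg, NULL, "current_clamp", holding_level = 0,
                      t_end = 1000)
  expect_lt(max(abs(sw$primary_trace - cfg$output_neuron$resting_potential)),
            1e-9)
})

test_that("passive step responses match the closed-form charging curve", {
  for (i_step in c(-2, -4, 10)) {
    sw <- simulate_cell(cfg, NULL, "current_clamp", holding_level = i_step,
                        t_end = 520, step_onset = 20)
    nn <- cfg$output_neuron
    t_rel <- pmax(sw$time - 20, 0)
    v_theory <- nn$resting_potential +
      i_step * nn$input_resistance * (1 - exp(-t_rel / nn$membrane_time_constant))
    deflect <- abs(i_step) * nn$input_resistance
    expect_lt(max(abs(sw$primary_trace - v_theory)), 0.005 * deflect)
  }
  # steady-state deflection of a -2 pA step is -I R = -1.9 mV
  sw <- simulate_cell(cfg, NULL, "current_clamp", holding_level = -2,
                      t_end = 1020, step_onset = 20)
  expect_equal(sw$primary_trace[length(sw$time)] -
                 cfg$output_neuron$resting_potential,
               -2 * 0.95, tolerance = 1e-3)
})

test_that("constant conductance input settles at the two-conductance fixed point", {
  nn <- cfg$output_neuron
  g_const <- 2  # nS, excitatory
  time <- seq(0, 1000, by = 0.05)
  extra <- list(list(g = rep(g_const, length(time)), reversal = 0))
  sw <- simulate_cell(cfg, NULL, "current_clamp", holding_level = 0,
                      extra_conductances = extra, t_end = 1000)
  g_rest <- 1 / nn$input_resistance
  v_fix <- (g_rest * nn$resting_potential + g_const * 0) / (g_rest + g_const)
  expect_equal(sw$primary_trace[length(time)], v_fix, tolerance = 1e-6)
})

test_that("ideal voltage clamp reports the analytic clamp current", {
  proto <- stimulus_protocol("visual", n_pulses = 1L)
  vh <- -65
  sw <- simulate_cell(cfg, proto, "voltage_clamp", holding_level = vh,
                      t_end = 200, stim_onset = 50)
  time <- sw$time
  drv <- afferent_drive(proto, cfg, "output", time, stim_onset = 50)
  nn <- cfg$output_neuron
  expected <- (vh - nn$resting_potential) / nn$input_resistance +
    drv$conductance$visual * (vh - 0)
  expect_equal(sw$primary_trace, expected, tolerance = 1e-12)
})

test_that("unstable integration steps and bad configs are rejected", {
  bad <- cfg
  bad$integration_step <- 0.1  # valid in general ...
  fast <- bad
  fast$output_neuron$membrane_time_constant <- 2  # ... but not for tau = 2 ms
  fast$output_neuron$capacitance <- 2 / fast$output_neuron$input_resistance
  expect_error(simulate_cell(fast, NULL, "current_clamp", holding_level = 0,
                             t_end = 10), "unstable")
  expect_error(circuit_config(cfg$output_neuron, cfg$interneuron,
                              cfg$excitatory_kernels, cfg$inhibitory_kernel,
                              integration_step = 0.2), "integration_step")
  expect_error(stimulus_protocol("visual", n_pulses = 0), "n_pulses")
  expect_error(neuron_params(input_resistance = 0), "input_resistance")
})

test_that("peak depolarization grows monotonically with excitatory amplitude", {
  peaks <- vapply(c(0.25, 0.5, 1, 2, 4), function(amp) {
    cc <- cfg
    cc$excitatory_kernels$visual$output$amplitude <- amp
    sw <- simulate_column(cc, stimulus_protocol("visual"), "current_clamp",
                          holding_level = 0, t_end = 300,
                          stim_onset = 50)$output
    max(sw$primary_trace)
  }, numeric(1))
  expect_true(all(diff(peaks) >= 0))
})

test_that("additive recording noise is reproducible from the protocol seed", {
  cc <- cfg
  cc$noise_sd <- 0.2
  p1 <- stimulus_protocol("visual", seed = 7L)
  p2 <- stimulus_protocol("visual", seed = 8L)
  a <- simulate_cell(cc, p1, "current_clamp", holding_level = 0, t_end = 100)
  b <- simulate_cell(cc, p1, "current_clamp", holding_level = 0, t_end = 100)
  c <- simulate_cell(cc, p2, "current_clamp", holding_level = 0, t_end = 100)
  expect_identical(a$primary_trace, b$primary_trace)
  expect_false(identical(a$primary_trace, c$primary_trace))
})

test_that("column simulation: gabazine zeroes inhibition, which otherwise lags excitation", {
  proto <- stimulus_protocol("visual", n_pulses = 1L)
  ctl <- simulate_column(cfg, proto, "current_clamp", holding_level = 0,
                         t_end = 300, stim_onset = 50)$output
  gbz <- simulate_column(apply_gabazine(cfg), proto, "current_clamp",
                         holding_level = 0, t_end = 300,
                         stim_onset = 50)$output
  expect_true(all(gbz$metadata$ground_truth$g_i == 0))
  g_e <- ctl$metadata$ground_truth$g_e
  g_i <- ctl$metadata$ground_truth$g_i
  t_on_e <- ctl$time[which(g_e > 0)[1]]
  t_on_i <- ctl$time[which(g_i > 0)[1]]
  expect_equal(t_on_i - t_on_e, cfg$feedforward_lag, tolerance = 0.05)
})

test_that("blocking inhibition converts a subthreshold train into repetitive firing", {
  spiking <- calibration_profile("cellular_default")
  pair <- tectosim:::fixture_gabazine_pair(spiking, 1L)
  expect_length(pair$control$spikes, 0)
  expect_gte(length(pair$gabazine$spikes), 2)
})

test_that("two-column LFP: zero lateral coupling is inert, off-field input is inhibitory-only", {
  proto <- stimulus_protocol("electrosensory", n_pulses = 1L,
                             stimulus_duration = 500)
  lfp <- calibration_profile("lfp_default")
  uncoupled <- lfp
  uncoupled$lateral_inhibition_weight[] <- 0
  alone <- simulate_two_column_lfp(uncoupled, "electrosensory", NULL, proto,
                                   stim_onset = 50)
  both <- simulate_two_column_lfp(uncoupled, "electrosensory", "visual",
                                  proto, stim_onset = 50)
  expect_equal(alone$primary_trace, both$primary_trace, tolerance = 1e-12)

  # off-field stimulus alone: no excitatory (positive) deflection
  off_proto <- proto; off_proto$modality <- "visual"
  quiet <- lfp
  quiet$excitatory_kernels$electrosensory$output$amplitude <- 0
  off_only <- simulate_two_column_lfp(quiet, "electrosensory", "visual",
                                      off_proto, stim_onset = 50)
  expect_lte(max(off_only$primary_trace), 1e-9)

  # with coupling, the off-field stimulus reduces the on-field response
  with_off <- simulate_two_column_lfp(lfp, "electrosensory", "visual", proto,
                                      stim_onset = 50)
  alone2 <- simulate_two_column_lfp(lfp, "electrosensory", NULL, proto,
                                    stim_onset = 50)
  expect_lt(rectified_integral(with_off), rectified_integral(alone2))
  expect_error(simulate_two_column_lfp(lfp, "visual", "visual", proto),
               "distinct")
})

test_that("per-pulse depression scales successive afferent volleys as configured", {
  time <- seq(0, 400, by = 0.05)
  proto2 <- stimulus_protocol("visual", n_pulses = 2L, frequency = 10)
  cc <- cfg
  cc$depression_per_pulse <- c(1, 0.7)
  two <- afferent_drive(proto2, cc, "output", time, stim_onset = 20)
  one <- afferent_drive(stimulus_protocol("visual"), cc, "output", time,
                        stim_onset = 20)
  second <- two$conductance$visual - one$conductance$visual
  expect_equal(max(second), 0.7 * max(one$conductance$visual),
               tolerance = 1e-6)
  expect_error(afferent_drive(proto2, cc, "nowhere", time), "arg")
})
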