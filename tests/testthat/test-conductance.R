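cfg <- quick_passive_config()

test_that("rest fit recovers leak conductance, rest potential and capacitance", {
  mh <- fx_multiholding()
  rest <- fit_rest(mh, baseline_window = c(460, 519))
  expect_equal(rest$rest_conductance, 1 / 0.95, tolerance = 1e-3)
  expect_lt(abs(rest$rest_potential - (-68)), 0.05)
  expect_equal(rest$capacitance, 98.8 / 0.95, tolerance = 0.01)
  # degenerate design: identical holding currents
  expect_error(fit_rest(list(mh[[1]], mh[[1]]), c(460, 519)),
               "rank deficiency")
  # baseline window must not run into the stimulus
  expect_error(fit_rest(mh, baseline_window = c(500, 560)), "baseline")
})

test_that("synaptic current vanishes on leak-only sweeps and matches injected conductances", {
  mh <- fx_multiholding()
  rest <- fit_rest(mh, baseline_window = c(460, 519))
  passive <- simulate_cell(cfg, NULL, "current_clamp", holding_level = 24,
                           t_end = 680, step_onset = 20)
  # away from the step discontinuity (where the central difference
  # spans the kink) the leak-only synaptic current is null
  smooth <- passive$time < 19.9 | passive$time > 20.2
  expect_lt(max(abs(synaptic_current(passive, rest)[smooth])), 0.5)

  # a known injected conductance is recovered as g (V - E_syn)
  time <- seq(0, 680, by = 0.05)
  kern <- synapse_kernel(1.5, onset_latency = 2, rise_tau = 3,
                         decay_tau = 25, reversal_potential = -20)
  g_true <- bi_exponential_waveform(kern, time, event_time = 520)
  sw <- simulate_cell(cfg, NULL, "current_clamp", holding_level = 24,
                      extra_conductances = list(list(g = g_true,
                                                     reversal = -20)),
                      t_end = 680, step_onset = 20)
  i_syn <- synaptic_current(sw, rest)
  expected <- g_true * (sw$primary_trace - (-20))
  late <- sw$time > 25  # past the holding-step kink
  expect_lt(max(abs(i_syn - expected)[late]), 0.02 * max(abs(expected)))
  no_cap <- rest; no_cap$capacitance <- NA_real_
  expect_error(synaptic_current(sw, no_cap), "capacitance")
})

test_that("per-sample I-V regression is exact for a constant injected conductance", {
  time <- seq(0, 680, by = 0.05)
  g_const <- ifelse(time >= 520, 1, 0)  # 1 nS step, reversal -50 mV
  sweeps <- lapply(c(-65, -45, -20), function(vh) {
    simulate_cell(cfg, NULL, "current_clamp",
                  holding_level = holding_current(cfg$output_neuron, vh),
                  extra_conductances = list(list(g = g_const,
                                                 reversal = -50)),
                  t_end = 680, step_onset = 20)
  })
  # stamp a nominal stimulus time so the default analysis window applies
  for (i in seq_along(sweeps))
    sweeps[[i]]$stimulus_events <- data.frame(time = 520,
                                              modality = "visual")
  rest <- fit_rest(sweeps, baseline_window = c(460, 519))
  est <- fit_gsyn_vrev(sweeps, rest)
  late <- est$time > 540  # past the step transient
  expect_lt(max(abs(est$g_syn[late] - 1)), 0.01)
  expect_lt(max(abs(est$v_rev[late] - (-50))), 0.5)
  expect_error(fit_gsyn_vrev(sweeps[1], rest), "design error")
})

test_that("no synaptic input gives a null estimate with undefined reversal", {
  sweeps <- lapply(c(3, 24, 50), function(ih)
    simulate_cell(cfg, NULL, "current_clamp", holding_level = ih,
                  t_end = 680, step_onset = 20))
  rest <- fit_rest(sweeps, baseline_window = c(460, 519))
  est <- fit_gsyn_vrev(sweeps, rest, window = c(510, 620))
  expect_lt(max(abs(est$g_syn)), 0.02)
  expect_true(all(is.na(est$v_rev)))
  expect_equal(nrow(phase_trajectory(est)), 0)
})

test_that("extraction recovers the injected kernel waveforms (oracle equivalence)", {
  mh <- fx_multiholding()
  est <- extract_conductances(mh, baseline_window = c(460, 519))
  gt <- mh[[1]]$metadata$ground_truth
  sel <- mh[[1]]$time >= est$time[1] & mh[[1]]$time <= est$time[length(est$time)]
  g_e_true <- gt$g_e[sel]; g_i_true <- gt$g_i[sel]
  expect_lt(max(abs(est$g_e - g_e_true)), 0.02 * max(g_e_true))
  expect_lt(max(abs(est$g_i - g_i_true)), 0.02 * max(g_i_true))

  # conservation holds sample-wise before clipping
  expect_lt(max(abs(est$g_e_raw + est$g_i_raw - est$g_syn)), 1e-9)

  # holding-set independence: two holdings agree with three within 1%
  rest <- fit_rest(mh, baseline_window = c(460, 519))
  est2 <- detect_onsets_and_peaks(decompose_ei(
    fit_gsyn_vrev(mh[c(1, 3)], rest)))
  expect_equal(est2$peaks[["g_syn"]], est$peaks[["g_syn"]],
               tolerance = 0.01)
  expect_equal(est2$peaks[["g_e"]], est$peaks[["g_e"]], tolerance = 0.01)
})

test_that("recovered conductance scales linearly with the injected amplitudes", {
  doubled <- cfg
  for (m in c("visual", "electrosensory"))
    doubled$excitatory_kernels[[m]]$output$amplitude <-
      2 * doubled$excitatory_kernels[[m]]$output$amplitude
  doubled$inhibitory_kernel$amplitude <- 2 * doubled$inhibitory_kernel$amplitude
  mh2 <- tectosim:::fixture_multiholding(doubled, "visual", 1L)
  est2 <- extract_conductances(mh2, baseline_window = c(460, 519))
  est1 <- extract_conductances(fx_multiholding(),
                               baseline_window = c(460, 519))
  expect_equal(est2$peaks[["g_syn"]] / est1$peaks[["g_syn"]], 2,
               tolerance = 0.01)
})

test_that("E/I decomposition inverts the algebraic forward composition", {
  # symmetric midpoint of the 0 / -75 mV reversals
  est <- list(g_syn = 2, intercept = -2 * (-37.5), time = 0, v_rev = -37.5)
  class(est) <- "conductance_estimate"
  est <- decompose_ei(est)
  expect_equal(est$g_e, 1, tolerance = 1e-12)
  expect_equal(est$g_i, 1, tolerance = 1e-12)

  # reversal at E_exc means pure excitation
  est <- list(g_syn = 1.5, intercept = -1.5 * 0, time = 0, v_rev = 0)
  class(est) <- "conductance_estimate"
  est <- decompose_ei(est)
  expect_equal(est$g_i, 0, tolerance = 1e-12)

  # forward-compose the reported bimodal component peaks, then invert
  g_e <- 1.96; g_i <- 1.81
  g_syn <- g_e + g_i
  v_rev <- (g_e * 0 + g_i * -75) / g_syn
  expect_equal(g_syn, 3.77, tolerance = 1e-12)
  expect_equal(v_rev, -36.0, tolerance = 0.02)
  est <- list(g_syn = g_syn, intercept = -g_syn * v_rev, time = 0,
              v_rev = v_rev)
  class(est) <- "conductance_estimate"
  est <- decompose_ei(est)
  expect_equal(est$g_e, 1.96, tolerance = 1e-12)
  expect_equal(est$g_i, 1.81, tolerance = 1e-12)
  expect_error(decompose_ei(est, e_exc = -75, e_inh = -75), "differ")
})

test_that("onset detection: matched kernel shapes give the constructed lag exactly", {
  same_shape <- cfg
  same_shape$inhibitory_kernel <- synapse_kernel(
    1.2, onset_latency = 2,
    rise_tau = same_shape$excitatory_kernels$visual$output$rise_tau,
    decay_tau = same_shape$excitatory_kernels$visual$output$decay_tau,
    reversal_potential = -75)
  mh <- tectosim:::fixture_multiholding(same_shape, "visual", 1L)
  est <- extract_conductances(mh, baseline_window = c(460, 519))
  expect_equal(est$lag, 7.5, tolerance = 0.051)
  expect_equal(est$onsets[["i"]] - est$onsets[["e"]], est$lag)
})

test_that("gabazine fixtures yield an undefined inhibition onset and an excitation-dominated phase plot", {
  gbz <- apply_gabazine(cfg)
  mh <- tectosim:::fixture_multiholding(gbz, "visual", 1L)
  est <- extract_conductances(mh, baseline_window = c(460, 519))
  expect_true(is.na(est$lag))
  expect_true(is.na(est$onsets[["i"]]))
  traj <- phase_trajectory(est)
  expect_gt(nrow(traj), 0)
  # pure excitation: defined reversals cluster at E_exc = 0
  expect_lt(max(abs(traj$v_rev)), 3)
  # the point at peak conductance is part of the trajectory
  expect_true(any(abs(traj$g_syn - est$peaks[["g_syn"]]) < 1e-12))
})

test_that("cellular profile: phase trajectory runs from excitation toward the E/I composite", {
  est <- extract_conductances(fx_multiholding(),
                              baseline_window = c(460, 519))
  traj <- phase_trajectory(est)
  early <- traj$v_rev[traj$time <= min(traj$time) + 3]
  expect_gt(mean(early), -20)          # early points near 0 mV
  expect_lt(est$v_rev_at_peak, -40)    # peak point near the composite
  expect_true(est$lag >= 5 && est$lag <= 10)
})
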