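# End-to-end reproduction of the package's headline quantities:
# generate the fixture suite, read it back from disk, run the analysis
# chain, and compare against the calibrated reference values.

# Reference table: quantity name, the calibration/recovery reference
# value, units, tolerance class (recovery targets 2%, calibrated
# emergent targets 10% relative; the onset lag is an upper bound).
reproduction_references <- function() {
  data.frame(
    quantity = c("tau_m", "r_input", "fi_slope", "offset_attenuation",
                 "ei_onset_lag", "crossmodal_suppression",
                 "gabazine_enhancement", "unisensory_ceiling",
                 "vrev_at_peak", "ge_peak", "epsp1_amplitude"),
    reference = c(98.8, 0.95, 0.53, 15, 10, 75, 85.5, 55, -48.2, 1.11,
                  12.8),
    units = c("ms", "GOhm", "spikes/pA", "%", "ms", "%", "%", "%", "mV",
              "nS", "mV"),
    comparison = c("relative", "relative", "relative", "relative",
                   "upper_bound", "relative", "relative", "relative",
                   "relative", "relative", "relative"),
    tolerance = c(0.02, 0.02, 0.02, 0.10, NA, 0.10, 0.10, 0.10, 0.02,
                  0.02, 0.10),
    stringsAsFactors = FALSE)
}

#' Recompute the package's headline quantities from scratch
#'
#' Generates the full fixture suite with [generate_fixture_suite()],
#' reads every bundle back from disk, runs the corresponding analysis
#' chain, and reports each quantity against its reference value:
#' membrane time constant and input resistance from passive steps, f-I
#' slope from spiking steps, conductance-extraction outputs (excitatory
#' peak, reversal at peak total conductance, inhibition onset lag) from
#' the multi-holding visual triplet, the first-EPSP amplitude from the
#' PSP train, the temporal-offset attenuation maximum, and the LFP
#' indices (cross-modal suppression, gabazine enhancement, unisensory
#' ceiling).
#'
#' @param dir Working directory for the fixture bundles (default: a
#'   temporary directory).
#' @param seed Integer seed passed to the fixture generator.
#' @param quantities Subset of quantity names to compute (default all;
#'   unknown names are an error).
#' @return Data frame with columns `quantity`, `value`, `reference`,
#'   `units`, `n` (problem size entering the computation),
#'   `comparison`, `tolerance` and `pass`.
#' @export
reproduce <- function(dir = file.path(tempdir(), "tectosim-fixtures"),
                      seed = 1L, quantities = NULL) {
  refs <- reproduction_references()
  if (is.null(quantities)) quantities <- refs$quantity
  unknown <- setdiff(quantities, refs$quantity)
  if (length(unknown)) stop("unknown quantities: ",
                            paste(unknown, collapse = ", "))
  manifests <- generate_fixture_suite("all", dir, seed)
  bundle <- function(name) read_bundle(manifests[[name]])

  values <- list(); sizes <- list()
  note <- function(q, v, n) { values[[q]] <<- v; sizes[[q]] <<- n }

  if (any(c("tau_m", "r_input") %in% quantities)) {
    steps <- bundle("passive_steps")
    small <- steps[[which(vapply(steps, `[[`, numeric(1),
                                 "holding_level") == -2)]]
    note("tau_m", fit_time_constant(small), length(small$time))
    note("r_input", fit_input_resistance(steps), length(steps))
  }
  if ("fi_slope" %in% quantities) {
    fi <- fi_curve(bundle("fi_steps"))
    note("fi_slope", fi$slope, length(fi$currents))
  }
  if ("offset_attenuation" %in% quantities) {
    curve <- offset_attenuation_curve(bundle("offset_series"))
    note("offset_attenuation", curve$max_attenuation_percent,
         length(curve$offsets))
  }
  if (any(c("ei_onset_lag", "vrev_at_peak", "ge_peak") %in% quantities)) {
    sweeps <- bundle("multiholding_visual")
    stim <- min(sweeps[[1]]$stimulus_events$time)
    est <- extract_conductances(sweeps, baseline_window = c(stim - 60,
                                                            stim - 1))
    note("ei_onset_lag", unname(est$lag), length(sweeps))
    note("vrev_at_peak", unname(est$v_rev_at_peak), length(est$time))
    note("ge_peak", unname(est$peaks["g_e"]), length(est$time))
  }
  if ("epsp1_amplitude" %in% quantities) {
    train <- measure_psp_train(bundle("psp_train_visual")$train, "epsp")
    note("epsp1_amplitude", train$amplitudes[1], length(train$amplitudes))
  }
  if ("crossmodal_suppression" %in% quantities) {
    tc <- bundle("two_column")
    note("crossmodal_suppression",
         suppression_index(tc$electro_alone, tc$electro_with_visual_off),
         length(tc$electro_alone$time))
  }
  if (any(c("gabazine_enhancement", "unisensory_ceiling") %in% quantities)) {
    tab <- duration_response_curve(bundle("duration_series"))
    vis <- tab[tab$modality == "visual", ]
    ctrl <- vis$rectified_integral[vis$condition == "control"]
    gbz <- vis$rectified_integral[vis$condition == "gabazine"]
    ord_c <- order(vis$stimulus_duration[vis$condition == "control"])
    ord_g <- order(vis$stimulus_duration[vis$condition == "gabazine"])
    note("gabazine_enhancement",
         mean(100 * (gbz[ord_g] / ctrl[ord_c] - 1)), length(ctrl))
    uni <- tab$normalized_value[tab$condition == "control" &
                                  tab$modality != "bimodal"]
    note("unisensory_ceiling", 100 * max(uni), length(uni))
  }

  refs <- refs[refs$quantity %in% quantities, , drop = FALSE]
  out <- data.frame(
    quantity = refs$quantity,
    value = vapply(refs$quantity, function(q) values[[q]], numeric(1)),
    reference = refs$reference, units = refs$units,
    n = vapply(refs$quantity, function(q) sizes[[q]], numeric(1)),
    comparison = refs$comparison, tolerance = refs$tolerance,
    stringsAsFactors = FALSE, row.names = NULL)
  out$pass <- ifelse(
    out$comparison == "upper_bound", out$value <= out$reference,
    abs(out$value - out$reference) <= out$tolerance * abs(out$reference))
  out
}
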