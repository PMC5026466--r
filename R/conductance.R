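# Synaptic conductance extraction from multi-holding current-clamp
# sweeps: per-sample I-V regression gives the total synaptic
# conductance and its apparent reversal; fixed excitatory/inhibitory
# reversals then split the total into G_e and G_i.

#' Fit resting membrane properties from multi-holding sweeps
#'
#' Linear fit of baseline steady-state injected current against
#' baseline membrane potential across sweeps at distinct holding
#' currents gives the rest conductance and rest potential; a
#' single-exponential fit to the holding-step charging phase gives the
#' membrane time constant and hence the capacitance (C = tau * G_rest).
#'
#' @param sweeps List of >= 2 current-clamp [recording_sweep()]s sharing
#'   a time grid, at distinct holding currents, each with a
#'   `step_onset` metadata field.
#' @param baseline_window Length-2 interval, ms: pre-stimulus window
#'   over which the baseline is averaged. Must end at or before the
#'   first stimulus event.
#' @return An object of class `rest_fit` with fields `rest_conductance`
#'   (nS), `rest_potential` (mV), `capacitance` (pF), `tau` (ms) and
#'   `baseline_window`.
#' @export
fit_rest <- function(sweeps, baseline_window) {
  stopifnot(length(sweeps) >= 2L)
  holds <- vapply(sweeps, function(s) s$holding_level, numeric(1))
  if (anyDuplicated(signif(holds, 12)))
    stop("rank deficiency: holding currents must be distinct")
  for (s in sweeps) {
    if (s$kind != "current_clamp") stop("sweeps must be current clamp")
    if (nrow(s$stimulus_events) &&
        baseline_window[2] > min(s$stimulus_events$time))
      stop("`baseline_window` must end at or before the first stimulus")
  }
  # Steady baseline per sweep: asymptote of the charging-phase
  # exponential (exact even when the settle time is only ~5 tau),
  # falling back to the window mean.
  vb <- vapply(sweeps, function(s) {
    onset <- s$metadata$step_onset %||% 0
    sel <- s$time > onset & s$time <= baseline_window[2]
    v_inf <- try(fit_single_exponential(s$time[sel] - onset,
                                        s$primary_trace[sel])$v_inf,
                 silent = TRUE)
    if (!inherits(v_inf, "try-error") && is.finite(v_inf)) v_inf
    else mean(s$primary_trace[s$time >= baseline_window[1] &
                                s$time <= baseline_window[2]])
  }, numeric(1))
  fit <- stats::lm(holds ~ vb)
  g_rest <- unname(stats::coef(fit)[2])
  e_rest <- -unname(stats::coef(fit)[1]) / g_rest

  # time constant from the charging phase of the largest step
  i_big <- which.max(abs(holds))
  tau <- charging_tau(sweeps[[i_big]], e_rest, baseline_window)
  structure(list(rest_conductance = g_rest, rest_potential = e_rest,
                 capacitance = tau * g_rest, tau = tau,
                 baseline_window = baseline_window),
            class = "rest_fit")
}

# Single-exponential fit of the charging phase between the
# holding-step onset and the baseline window.
charging_tau <- function(sweep, e_rest, baseline_window) {
  onset <- sweep$metadata$step_onset %||% 0
  sel <- sweep$time > onset & sweep$time < baseline_window[1]
  if (sum(sel) < 10) stop("charging phase too short for a tau fit")
  fit_single_exponential(sweep$time[sel] - onset,
                         sweep$primary_trace[sel])$tau
}

# Three-parameter single-exponential fit v(t) = v_inf + a exp(-t/tau),
# initialized from a log-linear fit and refined by nonlinear least
# squares.
fit_single_exponential <- function(tt, vv) {
  v_inf0 <- mean(vv[tt >= max(tt) * 0.8])
  y <- v_inf0 - vv
  scale <- max(abs(y))
  keep <- abs(y) > 1e-2 * scale & sign(y) == sign(y[1])
  fit0 <- stats::lm(log(abs(y[keep])) ~ tt[keep])
  tau0 <- -1 / unname(stats::coef(fit0)[2])
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(tt) / 3
  df <- data.frame(tt = tt, vv = vv)
  fit <- try(suppressWarnings(
    stats::nls(vv ~ v_inf + a * exp(-tt / tau), data = df,
               start = list(v_inf = v_inf0, a = -sign(y[1]) * scale,
                            tau = tau0),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE,
                                            scaleOffset = 1))),
    silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(tau = tau0, v_inf = v_inf0))
  cf <- stats::coef(fit)
  list(tau = unname(cf["tau"]), v_inf = unname(cf["v_inf"]))
}

#' @export
print.rest_fit <- function(x, ...) {
  cat(sprintf(
    "<rest_fit> G_rest %.4g nS (R_in %.3g GOhm), E_rest %.4g mV, C %.4g pF (tau %.4g ms)\n",
    x$rest_conductance, 1 / x$rest_conductance, x$rest_potential,
    x$capacitance, x$tau))
  invisible(x)
}

#' Synaptic current from a current-clamp sweep
#'
#' Solves the membrane equation for the synaptic current:
#' `I_syn(t) = I_inj(t) - C dV/dt - G_rest (V - E_rest)`, with `dV/dt`
#' by central differences on the recording grid.
#'
#' @param sweep A current-clamp [recording_sweep()].
#' @param rest A [fit_rest()] result (capacitance required).
#' @return Synaptic current trace, pA (endpoints set to the adjacent
#'   interior values).
#' @export
synaptic_current <- function(sweep, rest) {
  if (is.null(rest$capacitance) || !is.finite(rest$capacitance))
    stop("capacitance missing from rest fit")
  v <- sweep$primary_trace
  n <- length(v)
  dt <- sweep_dt(sweep)
  dvdt <- numeric(n)
  dvdt[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  dvdt[1] <- dvdt[2]; dvdt[n] <- dvdt[n - 1]
  onset <- sweep$metadata$step_onset %||% 0
  i_inj <- ifelse(sweep$time >= onset, sweep$holding_level, 0)
  i_inj - rest$capacitance * dvdt -
    rest$rest_conductance * (v - rest$rest_potential)
}

#' Total synaptic conductance and reversal by per-sample I-V regression
#'
#' At each sample inside the analysis window, ordinary least squares of
#' the leak-subtracted synaptic current against membrane potential
#' across the sweeps gives the total synaptic conductance (slope) and
#' the composite reversal (`v_rev = -intercept / slope`, since
#' `I_syn = g_syn (V - v_rev)` under this package's sign convention).
#' The reversal is reported `NA` where `g_syn` falls below `gsyn_floor`
#' (intercept/slope is ill-conditioned near zero slope) or where the
#' sweep voltages are collinear.
#'
#' @param sweeps List of >= 2 current-clamp [recording_sweep()]s at
#'   distinct holding levels sharing a time grid.
#' @param rest A [fit_rest()] result.
#' @param window Length-2 analysis interval, ms; default 10 ms before
#'   the first stimulus to 100 ms after it.
#' @param gsyn_floor Conductance floor (nS) below which `v_rev` is
#'   undefined.
#' @return An object of class `conductance_estimate` with `time`,
#'   `g_syn` (nS), `v_rev` (mV, `NA` below floor) filled.
#' @export
fit_gsyn_vrev <- function(sweeps, rest, window = NULL, gsyn_floor = 0.05) {
  if (length(sweeps) < 2L)
    stop("design error: >= 2 distinct holding levels required")
  t0 <- sweeps[[1]]$time
  for (s in sweeps[-1])
    if (length(s$time) != length(t0) || max(abs(s$time - t0)) > 1e-9)
      stop("sweeps must share the time grid")
  if (is.null(window)) {
    stim <- min(sweeps[[1]]$stimulus_events$time)
    window <- c(stim - 10, stim + 100)
  }
  sel <- which(t0 >= window[1] & t0 <= window[2])
  V <- vapply(sweeps, function(s) s$primary_trace[sel],
              numeric(length(sel)))
  I <- vapply(sweeps, function(s) synaptic_current(s, rest)[sel],
              numeric(length(sel)))
  vbar <- rowMeans(V); ibar <- rowMeans(I)
  sxx <- rowSums((V - vbar)^2)
  sxy <- rowSums((V - vbar) * (I - ibar))
  ok <- sxx > 1e-12
  slope <- ifelse(ok, sxy / sxx, NA_real_)
  g_syn <- slope
  intercept <- ibar - slope * vbar
  v_rev <- ifelse(!is.na(g_syn) & g_syn >= gsyn_floor,
                  -intercept / g_syn, NA_real_)
  structure(list(time = t0[sel], g_syn = g_syn, v_rev = v_rev,
                 intercept = intercept, gsyn_floor = gsyn_floor,
                 window = window, holdings = vapply(sweeps, `[[`,
                                                    numeric(1),
                                                    "holding_level"),
                 collinear = !ok),
            class = "conductance_estimate")
}

#' Decompose total synaptic conductance into excitation and inhibition
#'
#' With fixed reversal potentials `e_exc` and `e_inh`, the per-sample
#' split is `g_e = g_syn (v_rev - e_inh) / (e_exc - e_inh)` and
#' `g_i = g_syn - g_e`. The split is computed directly from the
#' regression intercept and slope (numerically stable where `g_syn` is
#' near zero); small negative excursions are clipped to zero with the
#' raw values retained for quality control.
#'
#' @param estimate A [fit_gsyn_vrev()] result.
#' @param e_exc,e_inh Excitatory and inhibitory reversal potentials, mV
#'   (glutamatergic 0 and chloride-mediated GABA-A -75 in this
#'   preparation).
#' @return The estimate with `g_e`, `g_i` (clipped, nS), `g_e_raw`,
#'   `g_i_raw` and the reversals filled.
#' @export
decompose_ei <- function(estimate, e_exc = 0, e_inh = -75) {
  if (e_exc == e_inh) stop("`e_exc` and `e_inh` must differ")
  g <- estimate$g_syn
  # g_e = (g*v_rev - g*e_inh) / (e_exc - e_inh); g*v_rev equals minus
  # the regression intercept, defined even where v_rev itself is not.
  g_e_raw <- (-estimate$intercept - g * e_inh) / (e_exc - e_inh)
  g_i_raw <- g - g_e_raw
  estimate$e_exc <- e_exc; estimate$e_inh <- e_inh
  estimate$g_e_raw <- g_e_raw; estimate$g_i_raw <- g_i_raw
  estimate$g_e <- pmax(g_e_raw, 0)
  estimate$g_i <- pmax(g_i_raw, 0)
  estimate
}

#' Onsets, peaks and excitation-inhibition lag of an estimate
#'
#' Onset of each component is the first sample where the trace exceeds
#' `threshold_fraction` of its own peak; the lag is
#' `onset(g_i) - onset(g_e)`; `v_rev_at_peak` is the fitted reversal at
#' the sample of maximal total synaptic conductance.
#'
#' @param estimate A decomposed [conductance_estimate][decompose_ei()].
#' @param threshold_fraction Own-peak fraction defining the onset.
#' @param zero_floor Peak amplitude (nS) below which a component counts
#'   as absent (its onset is undefined); keeps sub-floor regression
#'   noise from producing a spurious onset, e.g. for the inhibitory
#'   trace of a gabazine recording.
#' @return The estimate with `onsets` (ms, named `e`/`i`), `peaks`
#'   (nS, named `g_e`/`g_i`/`g_syn`), `lag` (ms) and `v_rev_at_peak`
#'   (mV) filled; onset and lag are `NA` for absent traces.
#' @export
detect_onsets_and_peaks <- function(estimate, threshold_fraction = 0.10,
                                    zero_floor = 0.01) {
  stopifnot(!is.null(estimate$g_e))
  onset_of <- function(g) {
    pk <- max(g, na.rm = TRUE)
    if (!is.finite(pk) || pk <= zero_floor) return(NA_real_)
    estimate$time[which(g > threshold_fraction * pk)[1]]
  }
  t_e <- onset_of(estimate$g_e)
  t_i <- onset_of(estimate$g_i)
  i_pk <- which.max(estimate$g_syn)
  estimate$onsets <- c(e = t_e, i = t_i)
  estimate$peaks <- c(g_e = max(estimate$g_e, na.rm = TRUE),
                      g_i = max(estimate$g_i, na.rm = TRUE),
                      g_syn = max(estimate$g_syn, na.rm = TRUE))
  estimate$lag <- t_i - t_e
  estimate$v_rev_at_peak <- estimate$v_rev[i_pk]
  estimate
}

#' Conductance-reversal phase trajectory
#'
#' Ordered `(v_rev, g_syn)` pairs over the analysis window, restricted
#' to samples with a defined reversal; includes the point at peak total
#' conductance.
#'
#' @param estimate A [conductance_estimate][fit_gsyn_vrev()].
#' @return Data frame with columns `time`, `v_rev`, `g_syn`.
#' @export
phase_trajectory <- function(estimate) {
  keep <- !is.na(estimate$v_rev)
  data.frame(time = estimate$time[keep], v_rev = estimate$v_rev[keep],
             g_syn = estimate$g_syn[keep])
}

#' @export
print.conductance_estimate <- function(x, ...) {
  cat(sprintf("<conductance_estimate> %d samples over [%.4g, %.4g] ms, %d holdings\n",
              length(x$time), x$window[1], x$window[2], length(x$holdings)))
  if (!is.null(x$peaks))
    cat(sprintf("  peaks: g_e %.3g, g_i %.3g, g_syn %.3g nS; v_rev at peak %.4g mV; lag %.3g ms\n",
                x$peaks["g_e"], x$peaks["g_i"], x$peaks["g_syn"],
                x$v_rev_at_peak, x$lag))
  invisible(x)
}

#' Run the full extraction chain on a multi-holding sweep set
#'
#' Convenience wrapper: [fit_rest()], [fit_gsyn_vrev()],
#' [decompose_ei()] and [detect_onsets_and_peaks()] in sequence.
#'
#' @inheritParams fit_rest
#' @inheritParams fit_gsyn_vrev
#' @inheritParams decompose_ei
#' @inheritParams detect_onsets_and_peaks
#' @return A completed `conductance_estimate`.
#' @export
extract_conductances <- function(sweeps, baseline_window, window = NULL,
                                 gsyn_floor = 0.05, e_exc = 0, e_inh = -75,
                                 threshold_fraction = 0.10) {
  rest <- fit_rest(sweeps, baseline_window)
  est <- fit_gsyn_vrev(sweeps, rest, window, gsyn_floor)
  est <- decompose_ei(est, e_exc, e_inh)
  est <- detect_onsets_and_peaks(est, threshold_fraction)
  est$rest <- rest
  est
}
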