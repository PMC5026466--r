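# Passive and firing characterization of model (or recorded) neurons:
# membrane time constant, input resistance, V-I linearity, f-I curve.

#' Membrane time constant from a current-step response
#'
#' Single-exponential fit to the charging phase of a passive step
#' response. An initial fit over the whole post-step segment estimates
#' tau; the fit is then repeated once restricted to the first 5 tau
#' after step onset.
#'
#' @param sweep A passive current-clamp [recording_sweep()] with a
#'   `step_onset` metadata field.
#' @return Fitted time constant, ms.
#' @export
fit_time_constant <- function(sweep) {
  if (length(sweep$spikes)) stop("spikes present: charging phase not passive")
  onset <- sweep$metadata$step_onset %||% 0
  t <- sweep$time; v <- sweep$primary_trace
  post <- t > onset
  tau0 <- fit_single_exponential(t[post] - onset, v[post])$tau
  sel <- post & t <= onset + 5 * tau0
  fit_single_exponential(t[sel] - onset, v[sel])$tau
}

#' Input resistance from steady-state deflections
#'
#' Least-squares slope of the steady-state voltage deflection against
#' injected current over current steps at three or more levels.
#'
#' @param sweeps List of current-clamp [recording_sweep()]s at distinct
#'   step currents (step length >= 5 tau so steady state is reached).
#' @param steady_window Length, ms, of the end-of-step window averaged
#'   as the steady-state level.
#' @return Input resistance, GOhm.
#' @export
fit_input_resistance <- function(sweeps, steady_window = 50) {
  if (length(sweeps) < 2L) stop("at least two current levels required")
  ii <- vapply(sweeps, function(s) s$holding_level, numeric(1))
  if (all(ii == 0)) stop("all-zero currents: no deflection to fit")
  if (length(unique(ii)) < 2L) stop("at least two distinct currents required")
  vv <- vapply(sweeps, steady_state_voltage, numeric(1),
               steady_window = steady_window)
  unname(stats::coef(stats::lm(vv ~ ii))[2])
}

# Steady-state level of a step response: asymptote of a
# single-exponential fit to the charging phase (exact even when the
# step ends near 5 tau), falling back to the end-of-step mean.
steady_state_voltage <- function(sweep, steady_window = 50) {
  t <- sweep$time
  onset <- sweep$metadata$step_onset %||% 0
  post <- t > onset
  v_inf <- try(fit_single_exponential(t[post] - onset,
                                      sweep$primary_trace[post])$v_inf,
               silent = TRUE)
  if (!inherits(v_inf, "try-error") && is.finite(v_inf)) return(v_inf)
  mean(sweep$primary_trace[t >= max(t) - steady_window])
}

#' Frequency-current curve and lower-range slope
#'
#' Counts spikes per 500 ms current step, locates the rheobase (first
#' current with at least one spike) and fits the least-squares slope
#' over the lower linear range (first `n_lower` supra-rheobase points).
#' The threshold voltage is the mean recorded threshold-crossing
#' potential across supra-rheobase sweeps.
#'
#' @param sweeps List of spiking current-clamp [recording_sweep()]s to
#'   increasing step currents.
#' @param n_lower Number of supra-rheobase points in the slope fit.
#' @return An object of class `fi_curve`: `currents` (pA),
#'   `spike_counts`, `slope` (spikes/pA; `NA` with no supra-rheobase
#'   step), `rheobase` (pA), `threshold_voltage` (mV).
#' @export
fi_curve <- function(sweeps, n_lower = 10) {
  ii <- vapply(sweeps, function(s) s$holding_level, numeric(1))
  ord <- order(ii)
  ii <- ii[ord]; sweeps <- sweeps[ord]
  counts <- vapply(sweeps, function(s) length(s$spikes), numeric(1))
  supra <- which(counts >= 1)
  if (!length(supra)) {
    return(structure(list(currents = ii, spike_counts = counts,
                          slope = NA_real_, rheobase = NA_real_,
                          threshold_voltage = NA_real_),
                     class = "fi_curve"))
  }
  rheo <- ii[supra[1]]
  fit_pts <- supra[seq_len(min(n_lower, length(supra)))]
  slope <- if (length(fit_pts) >= 2)
    unname(stats::coef(stats::lm(counts[fit_pts] ~ ii[fit_pts]))[2])
  else NA_real_
  crossings <- unlist(lapply(sweeps[supra], function(s)
    s$metadata$spike_crossings))
  structure(list(currents = ii, spike_counts = counts, slope = slope,
                 rheobase = rheo,
                 threshold_voltage = if (length(crossings))
                   mean(crossings) else NA_real_),
            class = "fi_curve")
}

#' @export
print.fi_curve <- function(x, ...) {
  cat(sprintf("<fi_curve> %d steps; rheobase %.4g pA; slope %.3g spikes/pA; threshold %.4g mV\n",
              length(x$currents), x$rheobase, x$slope, x$threshold_voltage))
  invisible(x)
}

#' Voltage-current linearity over a wide potential range
#'
#' With spiking blocked (QX-314 mode), fits steady-state membrane
#' potential against injected current and reports the linear fit and
#' its r-squared over the covered range. A `range_covered` flag marks
#' whether the requested voltage range was spanned.
#'
#' @param sweeps List of passive current-clamp step sweeps.
#' @param voltage_range Length-2 target range, mV.
#' @param steady_window Steady-state averaging window, ms.
#' @return List with `r_squared`, `slope` (GOhm), `intercept` (mV),
#'   `table` (I, V) and `range_covered`.
#' @export
vi_linearity <- function(sweeps, voltage_range = c(-120, -20),
                         steady_window = 50) {
  if (!length(sweeps)) stop("empty sweep set")
  if (any(vapply(sweeps, function(s) length(s$spikes) > 0, logical(1))))
    stop("spikes present: V-I linearity requires spiking blocked")
  ii <- vapply(sweeps, function(s) s$holding_level, numeric(1))
  vv <- vapply(sweeps, steady_state_voltage, numeric(1),
               steady_window = steady_window)
  fit <- stats::lm(vv ~ ii)
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       table = data.frame(current = ii, voltage = vv),
       range_covered = min(vv) <= voltage_range[1] &&
         max(vv) >= voltage_range[2])
}
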