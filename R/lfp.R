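# Rectified-integral quantification of extracellular (LFP proxy)
# responses: duration-response curves, additivity comparison, and
# enhancement/suppression indices.

#' Rectified integral of an LFP sweep
#'
#' Trapezoidal integral of the absolute baseline-subtracted signal over
#' a window. The baseline is the mean of the `baseline_length` ms
#' preceding the first stimulus event (or of the window start when the
#' sweep has no events).
#'
#' @param sweep An [recording_sweep()] (any kind; conventionally LFP).
#' @param window Length-2 integration interval, ms; default stimulus
#'   onset to 300 ms after it.
#' @param baseline_length Pre-stimulus baseline length, ms.
#' @return Rectified integral, a.u. * ms (non-negative).
#' @export
rectified_integral <- function(sweep, window = NULL, baseline_length = 50) {
  t <- sweep$time
  if (is.null(window)) {
    stim <- min(sweep$stimulus_events$time)
    window <- c(stim, stim + 300)
  }
  if (window[1] < t[1] || window[2] > t[length(t)])
    stop("integration window outside the trace")
  ref <- if (nrow(sweep$stimulus_events))
    min(sweep$stimulus_events$time) else window[1]
  base_sel <- t >= ref - baseline_length & t < ref
  baseline <- if (any(base_sel)) mean(sweep$primary_trace[base_sel]) else 0
  sel <- t >= window[1] & t <= window[2]
  pracma::trapz(t[sel], abs(sweep$primary_trace[sel] - baseline))
}

#' Stimulus-duration response table
#'
#' Rectified integrals of a duration x modality x condition sweep
#' collection, normalized to the maximal control bimodal response (no
#' monotone smoothing is applied).
#'
#' @param sweeps List of LFP [recording_sweep()]s whose protocols carry
#'   `stimulus_duration` and `modality` and whose metadata carry
#'   `condition` (`"control"`/`"gabazine"`).
#' @param window,baseline_length Passed to [rectified_integral()].
#' @return Data frame (class `lfp_response_table`) with columns
#'   `stimulus_duration` (us), `modality`, `condition`,
#'   `rectified_integral` and `normalized_value`.
#' @export
duration_response_curve <- function(sweeps, window = NULL,
                                    baseline_length = 50) {
  tab <- do.call(rbind, lapply(sweeps, function(s) {
    data.frame(stimulus_duration = s$protocol$stimulus_duration,
               modality = s$protocol$modality,
               condition = s$metadata$condition %||% "control",
               rectified_integral = rectified_integral(s, window,
                                                       baseline_length))
  }))
  anchor <- tab$rectified_integral[tab$modality == "bimodal" &
                                     tab$condition == "control"]
  if (!length(anchor))
    stop("normalization reference (control bimodal series) missing")
  tab$normalized_value <- tab$rectified_integral / max(anchor)
  class(tab) <- c("lfp_response_table", class(tab))
  tab
}

#' Bimodal additivity comparison
#'
#' Per duration and condition, compares the actual bimodal response
#' with the predicted arithmetic sum of the two unisensory responses.
#'
#' @param table A [duration_response_curve()] result.
#' @return Data frame with `stimulus_duration`, `condition`, `actual`,
#'   `predicted_sum` and `ratio` (actual / predicted; `NA` when the
#'   predicted sum is zero).
#' @export
additivity_comparison <- function(table) {
  keys <- unique(table[, c("stimulus_duration", "condition")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    d <- keys$stimulus_duration[i]; cond <- keys$condition[i]
    pick <- function(m) {
      v <- table$rectified_integral[table$stimulus_duration == d &
                                      table$condition == cond &
                                      table$modality == m]
      if (length(v)) v[1] else NA_real_
    }
    actual <- pick("bimodal")
    pred <- pick("visual") + pick("electrosensory")
    data.frame(stimulus_duration = d, condition = cond, actual = actual,
               predicted_sum = pred,
               ratio = if (is.na(pred) || pred == 0) NA_real_
                       else actual / pred)
  })
  do.call(rbind, out)
}

#' Cross-modal suppression index
#'
#' Percent reduction of an on-field response when a spatially disparate
#' off-field stimulus co-activates lateral inhibition:
#' `100 (1 - with_off_field / on_alone)`.
#'
#' @param on_alone,with_off_field Rectified integrals (numeric) or LFP
#'   [recording_sweep()]s of the on-field response without and with the
#'   off-field stimulus.
#' @param ... Passed to [rectified_integral()] when sweeps are given.
#' @return Percent reduction (`NA` when the reference response is 0).
#' @export
suppression_index <- function(on_alone, with_off_field, ...) {
  val <- function(x) if (inherits(x, "recording_sweep"))
    rectified_integral(x, ...) else x
  a <- val(on_alone); b <- val(with_off_field)
  if (a == 0) return(NA_real_)
  100 * (1 - b / a)
}
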