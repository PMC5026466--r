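# Shared, lazily-built fixtures. Everything is generated in code at
# test time; the standard suite is built once per session and cached.

.fx <- new.env(parent = emptyenv())

fx_manifests <- function() {
  if (is.null(.fx$manifests)) {
    dir <- file.path(tempdir(), "tectosim-test-fixtures")
    .fx$manifests <- generate_fixture_suite("all", dir, seed = 1L)
  }
  .fx$manifests
}

fx_bundle <- function(name) {
  key <- paste0("bundle_", name)
  if (is.null(.fx[[key]])) .fx[[key]] <- read_bundle(fx_manifests()[[name]])
  .fx[[key]]
}

# In-memory multi-holding triplet (keeps the ground-truth conductance
# traces that bundle serialization drops).
fx_multiholding <- function() {
  if (is.null(.fx$multiholding)) {
    cfg <- apply_qx314(calibration_profile("cellular_default"))
    .fx$multiholding <- tectosim:::fixture_multiholding(cfg, "visual", 1L)
  }
  .fx$multiholding
}

fx_report <- function() {
  if (is.null(.fx$report)) {
    dir <- file.path(tempdir(), "tectosim-test-reproduce")
    .fx$report <- reproduce(dir = dir, seed = 1L)
  }
  .fx$report
}

report_value <- function(quantity) {
  rep <- fx_report()
  rep$value[rep$quantity == quantity]
}

# A small passive configuration for quick simulations.
quick_passive_config <- function(...) {
  apply_qx314(calibration_profile("cellular_default"))
}

# Bi-exponential voltage template with unit peak (for constructing
# synthetic PSP traces with known amplitudes).
psp_template <- function(tt, onset, rise, decay) {
  s <- tt - onset
  y <- numeric(length(tt))
  tp <- decay * rise / (decay - rise) * log(decay / rise)
  nrm <- 1 / (exp(-tp / decay) - exp(-tp / rise))
  y[s > 0] <- nrm * (exp(-s[s > 0] / decay) - exp(-s[s > 0] / rise))
  y
}

# Wrap a bare voltage trace as a current-clamp sweep.
as_cc_sweep <- function(time, v, events = NULL, holding = 0, metadata = list()) {
  recording_sweep("current_clamp", time, v, holding_level = holding,
                  stimulus_events = events, metadata = metadata)
}
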