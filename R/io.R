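# Plain-text sweep bundles: one delimited trace file per sweep plus a
# JSON sidecar, listed by a manifest JSON with checksums. Traces are
# small, and text files keep bundles diff-able.

BUNDLE_FORMAT_VERSION <- "1.0"

#' Write a sweep bundle to disk
#'
#' Each sweep becomes `<id>.tsv` (column 1 time in ms, column 2 primary
#' trace; 9 significant digits) plus `<id>.json` (kind, holding level,
#' protocol, units, spikes, metadata). `manifest.json` lists the sweeps
#' with MD5 checksums; writes are deterministic so identical inputs
#' produce byte-identical bundles.
#'
#' @param sweeps Named or unnamed list of [recording_sweep()]s (names
#'   become sweep ids; unnamed sweeps get `sweep_001`, ...).
#' @param dir Bundle directory (created if missing).
#' @param experiment_name Label stored in the manifest.
#' @param seed Integer recorded in the manifest.
#' @param overwrite Logical; error on an existing manifest unless TRUE.
#' @return Path of the written manifest, invisibly.
#' @export
write_bundle <- function(sweeps, dir, experiment_name = "experiment",
                         seed = NA_integer_, overwrite = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest_path <- file.path(dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite)
    stop("manifest exists; use overwrite = TRUE")
  ids <- names(sweeps)
  if (is.null(ids) || any(ids == ""))
    ids <- sprintf("sweep_%03d", seq_along(sweeps))
  if (anyDuplicated(ids)) stop("duplicate sweep ids")

  entries <- vector("list", length(sweeps))
  for (i in seq_along(sweeps)) {
    s <- sweeps[[i]]
    stopifnot(inherits(s, "recording_sweep"))
    trace_file <- paste0(ids[i], ".tsv")
    side_file <- paste0(ids[i], ".json")
    con <- file(file.path(dir, trace_file), "wb")
    writeLines(sprintf("%.9g\t%.9g", s$time, s$primary_trace), con)
    close(con)
    meta <- s$metadata
    meta$ground_truth <- NULL  # in-memory validation aid, not serialized
    sidecar <- list(format_version = BUNDLE_FORMAT_VERSION,
                    kind = s$kind, holding_level = s$holding_level,
                    stimulus_events = s$stimulus_events,
                    protocol = unclass(s$protocol),
                    spikes = s$spikes, metadata = meta)
    jsonlite::write_json(sidecar, file.path(dir, side_file),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    entries[[i]] <- list(
      id = ids[i], path = trace_file, sidecar = side_file,
      kind = s$kind,
      checksum = unname(tools::md5sum(file.path(dir, trace_file))),
      sidecar_checksum = unname(tools::md5sum(file.path(dir, side_file))))
  }
  manifest <- list(format_version = BUNDLE_FORMAT_VERSION,
                   experiment_name = experiment_name,
                   seed = seed, sweeps = entries)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}

#' Read a sweep bundle
#'
#' Reconstructs the [recording_sweep()]s listed by a bundle manifest,
#' validating the format version, that every path is bundle-relative
#' and present, and that checksums match.
#'
#' @param manifest_path Path to a bundle `manifest.json`.
#' @return Named list of sweeps, with the manifest attached as
#'   attribute `manifest`.
#' @export
read_bundle <- function(manifest_path) {
  manifest <- jsonlite::read_json(manifest_path)
  if (!identical(manifest$format_version, BUNDLE_FORMAT_VERSION))
    stop("unknown bundle format_version: ", manifest$format_version)
  root <- dirname(manifest_path)
  ids <- vapply(manifest$sweeps, function(e) e$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sweep ids in manifest")
  sweeps <- vector("list", length(manifest$sweeps))
  for (i in seq_along(manifest$sweeps)) {
    e <- manifest$sweeps[[i]]
    for (p in c(e$path, e$sidecar)) {
      if (grepl("^([/\\\\]|[A-Za-z]:)", p) || grepl("\\.\\.", p))
        stop("manifest paths must be bundle-relative: ", p)
      if (!file.exists(file.path(root, p))) stop("missing bundle file: ", p)
    }
    if (!identical(unname(tools::md5sum(file.path(root, e$path))),
                   e$checksum))
      stop("checksum mismatch for ", e$path)
    if (!identical(unname(tools::md5sum(file.path(root, e$sidecar))),
                   e$sidecar_checksum))
      stop("checksum mismatch for ", e$sidecar)
    side <- jsonlite::read_json(file.path(root, e$sidecar),
                                simplifyVector = TRUE)
    if (!side$kind %in% c("current_clamp", "voltage_clamp",
                          "cell_attached", "lfp"))
      stop("unknown sweep kind: ", side$kind)
    mat <- utils::read.table(file.path(root, e$path), sep = "\t",
                             colClasses = "numeric")
    ev <- side$stimulus_events
    if (is.null(ev) || !length(ev))
      ev <- data.frame(time = numeric(0), modality = character(0))
    proto <- side$protocol
    if (!is.null(proto) && length(proto)) {
      proto$stimulus_duration <- proto$stimulus_duration %||% NA_real_
      class(proto) <- "stimulus_protocol"
    } else proto <- NULL
    sweeps[[i]] <- recording_sweep(
      kind = side$kind, time = mat[[1]], primary_trace = mat[[2]],
      holding_level = side$holding_level %||% NA_real_,
      stimulus_events = as.data.frame(ev), protocol = proto,
      spikes = as.numeric(side$spikes %||% numeric(0)),
      metadata = side$metadata %||% list())
  }
  names(sweeps) <- ids
  attr(sweeps, "manifest") <- manifest
  sweeps
}
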