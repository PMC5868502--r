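#' Write a radiometric frame to the open frame format
#'
#' Frames are stored as a 16-bit single-channel PNG of raw counts plus a JSON
#' sidecar `<stem>.json` carrying the Planck calibration constants and the
#' timestamp (keys `R1, R2, B, F, O, emissivity, reflected_temp_k,
#' timestamp_s, frame_id`). The representation is bit-exact: reading back
#' reproduces the counts and metadata identically.
#'
#' @param frame A [radiometric_frame()].
#' @param path Path of the PNG to write; the sidecar is written next to it.
#'
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "radiometric_frame"))
  write_png_gray16(frame$counts, path)
  sidecar <- sub("\\.png$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  meta <- c(unclass(frame$calibration),
            list(timestamp_s = frame$timestamp_s, frame_id = frame$frame_id))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a radiometric frame from the open frame format
#'
#' @param path Path to a 16-bit grayscale PNG with a `<stem>.json` sidecar.
#'
#' @return A [radiometric_frame()].
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) stop("frame file not found: ", path)
  sidecar <- sub("\\.png$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing JSON calibration sidecar: ", sidecar)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  cal_keys <- c("R1", "R2", "B", "F", "O", "emissivity", "reflected_temp_k")
  missing <- setdiff(cal_keys, names(meta))
  if (length(missing) > 0L) {
    stop("sidecar ", sidecar, " is missing key(s): ",
         paste(missing, collapse = ", "))
  }
  cal <- do.call(calibration_constants, meta[cal_keys])
  counts <- read_png_gray16(path)
  radiometric_frame(counts, timestamp_s = meta$timestamp_s %||% 0,
                    calibration = cal,
                    frame_id = meta$frame_id %||%
                      sub("\\.png$", "", basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a frame sequence with its manifest
#'
#' Writes every frame of a sequence with [write_frame()] and a manifest CSV
#' (`frame_id, path, timestamp_s, period`) naming the acquisition period of
#' each frame (`acclimatization`, `initial` or `final`).
#'
#' @param frames List of [radiometric_frame()] objects.
#' @param periods Character vector of period labels, one per frame.
#' @param dir Output directory (created if needed).
#'
#' @return Path of the manifest CSV, invisibly.
#' @export
write_sequence <- function(frames, periods, dir) {
  stopifnot(length(frames) == length(periods))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(frames, function(f) f$frame_id, character(1))
  ts <- vapply(frames, function(f) f$timestamp_s, numeric(1))
  if (is.unsorted(ts)) stop("frame timestamps must be non-decreasing")
  paths <- file.path(dir, paste0(ids, ".png"))
  for (i in seq_along(frames)) write_frame(frames[[i]], paths[i])
  manifest <- data.frame(frame_id = ids, path = paste0(ids, ".png"),
                         timestamp_s = ts, period = periods,
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}

#' Read a frame sequence from a manifest
#'
#' @param manifest_path Path to a manifest CSV written by [write_sequence()].
#' @param convert Convert frames to temperature on read (default `TRUE`).
#'
#' @return A list with elements `frames` (list of [temperature_frame()] or
#'   [radiometric_frame()]), `manifest` (the manifest data frame).
#' @export
read_sequence <- function(manifest_path, convert = TRUE) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  needed <- c("frame_id", "path", "timestamp_s", "period")
  if (!all(needed %in% names(manifest))) {
    stop("manifest must have columns: ", paste(needed, collapse = ", "))
  }
  if (is.unsorted(manifest$timestamp_s)) {
    stop("manifest timestamps must be non-decreasing")
  }
  dir <- dirname(manifest_path)
  frames <- lapply(file.path(dir, manifest$path), read_frame)
  dims <- vapply(frames, function(f) dim(f$counts), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("frames in one sequence must share dimensions")
  }
  if (convert) frames <- lapply(frames, counts_to_temperature)
  list(frames = frames, manifest = manifest)
}
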