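#' Radiometric calibration constants
#'
#' Planck-law calibration constants used to convert raw thermal-camera counts
#' (16-bit "radiometric" sensor values) into temperature. The model is the
#' standard single-band radiometric inversion used by research thermal
#' cameras: the object signal \eqn{S_{obj}} relates to temperature through
#' \deqn{T(K) = B / \ln(R_1 / (R_2 (S_{obj} + O)) + F)}
#' with an emissivity correction
#' \eqn{S_{obj} = (S_{raw} - (1-\epsilon) S_{refl}) / \epsilon}, where
#' \eqn{S_{refl}} is the signal a blackbody at the reflected apparent
#' temperature would produce. Atmospheric transmission is not modelled
#' (short indoor path); see the methods vignette.
#'
#' @param R1 Planck gain (counts). Must be positive.
#' @param R2 Planck scale (unitless). Must be positive.
#' @param B Planck spectral constant (K). Must be positive.
#' @param F Planck shape constant (unitless).
#' @param O Count offset (counts).
#' @param emissivity Surface emissivity in (0, 1]. Human skin is close to
#'   0.98 in the long-wave infrared band.
#' @param reflected_temp_k Reflected apparent temperature (K). Must be
#'   positive.
#'
#' @return An object of class `calibration_constants`.
#' @examples
#' cal <- calibration_constants()
#' cal$B
#' @export
calibration_constants <- function(R1 = 17000, R2 = 0.045, B = 1430, F = 1,
                                  O = -300, emissivity = 0.98,
                                  reflected_temp_k = 295.15) {
  cal <- list(R1 = R1, R2 = R2, B = B, F = F, O = O,
              emissivity = emissivity, reflected_temp_k = reflected_temp_k)
  validate_calibration(cal)
  structure(cal, class = "calibration_constants")
}

validate_calibration <- function(cal) {
  required <- c("R1", "R2", "B", "F", "O", "emissivity", "reflected_temp_k")
  missing <- setdiff(required, names(cal))
  if (length(missing) > 0L) {
    stop("calibration is missing key(s): ", paste(missing, collapse = ", "))
  }
  for (k in required) {
    if (!is.numeric(cal[[k]]) || length(cal[[k]]) != 1L || !is.finite(cal[[k]])) {
      stop("calibration constant '", k, "' must be a finite scalar")
    }
  }
  if (cal$B <= 0) stop("calibration constant 'B' must be > 0")
  if (cal$R1 <= 0) stop("calibration constant 'R1' must be > 0")
  if (cal$R2 <= 0) stop("calibration constant 'R2' must be > 0")
  if (cal$emissivity <= 0 || cal$emissivity > 1) {
    stop("'emissivity' must be in (0, 1]")
  }
  if (cal$reflected_temp_k <= 0) stop("'reflected_temp_k' must be > 0")
  invisible(cal)
}

#' Construct a raw radiometric frame
#'
#' A radiometric frame holds the unconverted 16-bit sensor counts together
#' with its acquisition timestamp and the calibration needed to convert the
#' counts to temperature.
#'
#' @param counts Integer-valued matrix of raw counts in \[0, 65535\].
#' @param timestamp_s Acquisition time in seconds since sequence start.
#' @param calibration A [calibration_constants()] object.
#' @param frame_id Character identifier for the frame.
#'
#' @return An object of class `radiometric_frame`.
#' @export
radiometric_frame <- function(counts, timestamp_s, calibration,
                              frame_id = "frame") {
  if (!is.matrix(counts) || length(counts) == 0L) {
    stop("'counts' must be a non-empty matrix")
  }
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts > 65535) ||
      any(counts != round(counts))) {
    stop("'counts' must be integers in [0, 65535]")
  }
  validate_calibration(calibration)
  structure(list(counts = counts, timestamp_s = as.numeric(timestamp_s),
                 calibration = calibration, frame_id = as.character(frame_id)),
            class = "radiometric_frame")
}

#' Construct a temperature frame
#'
#' The per-pixel temperature grid (degrees Celsius) all downstream analysis
#' operates on. Values outside the plausibility bounds indicate a conversion
#' or calibration fault and raise an error.
#'
#' @param temp_c Numeric matrix of temperatures in degrees Celsius.
#' @param timestamp_s Acquisition time in seconds since sequence start.
#' @param frame_id Character identifier.
#' @param bounds_c Length-2 plausibility bounds in degrees Celsius.
#'
#' @return An object of class `temperature_frame`.
#' @export
temperature_frame <- function(temp_c, timestamp_s, frame_id = "frame",
                              bounds_c = c(-40, 150)) {
  if (!is.matrix(temp_c) || length(temp_c) == 0L) {
    stop("'temp_c' must be a non-empty matrix")
  }
  if (any(!is.finite(temp_c))) stop("temperature values must all be finite")
  if (any(temp_c < bounds_c[1]) || any(temp_c > bounds_c[2])) {
    stop(sprintf("temperature outside plausibility bounds [%g, %g] degC",
                 bounds_c[1], bounds_c[2]))
  }
  structure(list(temp_c = temp_c, timestamp_s = as.numeric(timestamp_s),
                 frame_id = as.character(frame_id)),
            class = "temperature_frame")
}

# Blackbody signal (counts) at absolute temperature temp_k for a calibration.
planck_signal <- function(cal, temp_k) {
  cal$R1 / (cal$R2 * (exp(cal$B / temp_k) - cal$F)) - cal$O
}

#' Convert raw counts to temperature
#'
#' Applies the Planck radiometric inversion (see [calibration_constants()])
#' to every pixel. The conversion is strictly increasing in the raw count for
#' any valid calibration, so ordering of pixels by count and by temperature
#' is identical.
#'
#' @param frame A [radiometric_frame()].
#' @param bounds_c Plausibility bounds passed to [temperature_frame()].
#'
#' @return A [temperature_frame()] of identical dimensions.
#' @examples
#' cal <- calibration_constants()
#' rf <- radiometric_frame(matrix(4000, 2, 2), 0, cal)
#' counts_to_temperature(rf)$temp_c[1, 1]
#' @export
counts_to_temperature <- function(frame, bounds_c = c(-40, 150)) {
  stopifnot(inherits(frame, "radiometric_frame"))
  cal <- frame$calibration
  s_refl <- planck_signal(cal, cal$reflected_temp_k)
  s_obj <- (frame$counts - (1 - cal$emissivity) * s_refl) / cal$emissivity
  denom <- s_obj + cal$O
  arg <- cal$R1 / (cal$R2 * denom) + cal$F
  bad <- which(!is.finite(arg) | denom <= 0 | arg <= 1)
  if (length(bad) > 0L) {
    stop(sprintf(
      "count %d (pixel %d) is outside the invertible range of the calibration",
      as.integer(frame$counts[bad[1]]), bad[1]))
  }
  temp_c <- cal$B / log(arg) - 273.15
  temperature_frame(temp_c, frame$timestamp_s, frame$frame_id,
                    bounds_c = bounds_c)
}

#' Convert temperature to raw counts
#'
#' Exact algebraic inverse of [counts_to_temperature()] followed by
#' quantization to the nearest integer count. The quantization error,
#' propagated back through the conversion, is bounded by the local derivative
#' dT/dS times half a count.
#'
#' @param temp A [temperature_frame()] (or a bare numeric matrix of degrees
#'   Celsius).
#' @param calibration A [calibration_constants()] object.
#' @param quantize Round to integer counts (default `TRUE`). With
#'   `FALSE` the continuous signal is returned, useful for round-trip
#'   analysis.
#'
#' @return A [radiometric_frame()] when `quantize = TRUE`, otherwise a
#'   numeric matrix of continuous counts.
#' @export
temperature_to_counts <- function(temp, calibration, quantize = TRUE) {
  validate_calibration(calibration)
  if (inherits(temp, "temperature_frame")) {
    temp_c <- temp$temp_c
    timestamp_s <- temp$timestamp_s
    frame_id <- temp$frame_id
  } else {
    temp_c <- as.matrix(temp)
    timestamp_s <- 0
    frame_id <- "frame"
  }
  temp_k <- temp_c + 273.15
  if (any(temp_k <= 0)) stop("temperature outside invertible range (<= 0 K)")
  ex <- exp(calibration$B / temp_k)
  if (any(!is.finite(ex)) || any(ex <= calibration$F)) {
    stop("temperature outside invertible range of the calibration")
  }
  s_obj <- calibration$R1 / (calibration$R2 * (ex - calibration$F)) -
    calibration$O
  s_refl <- planck_signal(calibration, calibration$reflected_temp_k)
  s_raw <- calibration$emissivity * s_obj +
    (1 - calibration$emissivity) * s_refl
  if (!quantize) return(s_raw)
  counts <- round(s_raw)
  if (any(counts < 0) || any(counts > 65535)) {
    stop("temperature maps outside the 16-bit count range for this calibration")
  }
  radiometric_frame(counts, timestamp_s, calibration, frame_id)
}
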