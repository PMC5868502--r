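#' Construct a temperature time series
#'
#' @param timestamp_s Strictly increasing numeric timestamps (seconds).
#' @param value_c Temperatures (degrees Celsius), one per timestamp.
#' @param side `"left"`, `"right"` or `NA`.
#' @param kind `"absolute"` (hotspot statistic), `"reference"` or
#'   `"relative"` (hotspot minus reference).
#'
#' @return A data frame of class `temperature_series` with columns
#'   `timestamp_s`, `value_c` and attributes `side` and `kind`.
#' @export
temperature_series <- function(timestamp_s, value_c, side = NA_character_,
                               kind = c("absolute", "reference", "relative")) {
  kind <- match.arg(kind)
  if (length(timestamp_s) != length(value_c)) {
    stop("timestamps and values must have equal length")
  }
  if (any(diff(timestamp_s) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  structure(data.frame(timestamp_s = timestamp_s, value_c = value_c),
            side = side, kind = kind,
            class = c("temperature_series", "data.frame"))
}

# Select the k = ceil(frac * N) largest values; ties at the cutoff are
# broken by raster-scan order (stable). Returns indices into the scan-order
# vector and the values.
select_hottest <- function(values_scan, frac = 0.1) {
  n <- length(values_scan)
  if (n == 0L) stop("empty ROI")
  k <- ceiling(frac * n)
  ord <- order(-values_scan, seq_len(n)) # stable: scan order breaks ties
  ord[seq_len(k)]
}

roi_scan_order <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  o <- order(pts[, 1], pts[, 2])
  pts[o, , drop = FALSE]
}

#' Hotspot statistic: median of the hottest 10% of ROI pixels
#'
#' Identifies the hottest `frac` (default 10%) of pixels within the ROI —
#' `k = ceiling(frac * N)` pixels, ties at the cutoff broken by raster-scan
#' order — and returns their median (for even `k`, the mean of the two
#' middle values). With 10% this is equivalent to the 95th percentile of the
#' ROI.
#'
#' @param frame A [temperature_frame()] (or bare numeric matrix).
#' @param roi A `roi_mask`, `reference_region`, or logical matrix.
#' @param frac Fraction of ROI pixels in the hotspot.
#'
#' @return The hotspot temperature (scalar, degrees Celsius).
#' @examples
#' m <- matrix(1:100, 10, 10)
#' hotspot_statistic(m, matrix(TRUE, 10, 10)) # 95.5
#' @export
hotspot_statistic <- function(frame, roi, frac = 0.1) {
  img <- if (inherits(frame, "temperature_frame")) frame$temp_c else frame
  mask <- roi_mask_matrix(roi)
  if (!any(mask)) stop("empty ROI")
  pts <- roi_scan_order(mask)
  vals <- img[pts]
  stats::median(vals[select_hottest(vals, frac)])
}

#' Hotspot mask: the selected hottest-10% pixels as a binary image
#'
#' Same selection rule as [hotspot_statistic()]; returns the mask of
#' selected pixels, used for the spatial-overlap comparison against the
#' projection hotspot.
#'
#' @inheritParams hotspot_statistic
#' @return A logical matrix with `ceiling(frac * N)` `TRUE` pixels.
#' @export
hotspot_mask <- function(frame, roi, frac = 0.1) {
  img <- if (inherits(frame, "temperature_frame")) frame$temp_c else frame
  mask <- roi_mask_matrix(roi)
  if (!any(mask)) stop("empty ROI")
  pts <- roi_scan_order(mask)
  vals <- img[pts]
  sel <- pts[select_hottest(vals, frac), , drop = FALSE]
  out <- matrix(FALSE, nrow(img), ncol(img))
  out[sel] <- TRUE
  out
}

roi_mask_matrix <- function(roi) {
  if (inherits(roi, "roi_mask") || inherits(roi, "reference_region")) {
    roi$mask
  } else if (is.logical(roi) && is.matrix(roi)) {
    roi
  } else {
    stop("'roi' must be an roi_mask, reference_region or logical matrix")
  }
}

#' Reference-region statistic
#'
#' Summary temperature of the sternal reference circle; the arithmetic mean
#' by default, with the median available as an option.
#'
#' @inheritParams hotspot_statistic
#' @param ref A `reference_region` (or logical matrix).
#' @param stat `"mean"` (default) or `"median"`.
#' @return Scalar temperature (degrees Celsius).
#' @export
reference_statistic <- function(frame, ref, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  img <- if (inherits(frame, "temperature_frame")) frame$temp_c else frame
  mask <- roi_mask_matrix(ref)
  if (!any(mask)) stop("empty reference mask")
  vals <- img[mask]
  if (stat == "mean") mean(vals) else stats::median(vals)
}

#' Extract a per-frame statistic as a time series
#'
#' @param frames List of [temperature_frame()] objects with non-decreasing
#'   timestamps.
#' @param roi Region passed to `statistic`.
#' @param statistic Function `(frame, roi) -> scalar`;
#'   [hotspot_statistic()] or [reference_statistic()].
#' @param side,kind Labels stored on the resulting series.
#' @return A [temperature_series()].
#' @export
extract_series <- function(frames, roi, statistic = hotspot_statistic,
                           side = NA_character_, kind = "absolute") {
  ts <- vapply(frames, function(f) f$timestamp_s, numeric(1))
  vals <- vapply(frames, function(f) statistic(f, roi), numeric(1))
  temperature_series(ts, vals, side = side, kind = kind)
}

#' Pointwise difference of two series (hotspot minus reference)
#'
#' Computed per frame, before any smoothing. The two series must share
#' identical timestamps.
#'
#' @param hotspot,reference [temperature_series()] objects.
#' @return A [temperature_series()] of kind `"relative"`.
#' @export
relative_series <- function(hotspot, reference) {
  if (nrow(hotspot) != nrow(reference) ||
      any(hotspot$timestamp_s != reference$timestamp_s)) {
    stop("series timestamps must match exactly")
  }
  temperature_series(hotspot$timestamp_s,
                     hotspot$value_c - reference$value_c,
                     side = attr(hotspot, "side"), kind = "relative")
}

#' Moving-average smoothing
#'
#' Centered moving average in "valid" mode: the output has
#' `n - period + 1` samples, each the mean of `period` consecutive input
#' values, timestamped at the window's center sample.
#'
#' @param series A [temperature_series()].
#' @param period Window length in samples (default 5).
#' @return A smoothed [temperature_series()].
#' @examples
#' s <- temperature_series(1:6, c(1, 2, 3, 4, 5, 6))
#' smooth_series(s)$value_c # 3 4
#' @export
smooth_series <- function(series, period = 5L) {
  n <- nrow(series)
  if (n < period) stop("series shorter than the smoothing period")
  v <- series$value_c
  cs <- c(0, cumsum(v))
  out <- (cs[(period + 1L):(n + 1L)] - cs[1L:(n - period + 1L)]) / period
  center <- seq_len(n - period + 1L) + (period - 1L) %/% 2L
  temperature_series(series$timestamp_s[center], out,
                     side = attr(series, "side"), kind = attr(series, "kind"))
}

#' Base/peak/delta outcomes from a smoothed series
#'
#' Base is the mean of the smoothed series over the first
#' `base_window_s` seconds of stimulation (half-open window
#' `[onset, onset + base_window_s)`); peak is the maximum of the smoothed
#' series within the requested window (half-open `[onset, onset +
#' peak_window_s)`, with `peak_window_s = Inf` covering everything from
#' onset to the end — the "initial and final periods combined" outcome);
#' delta is exactly peak minus base.
#'
#' @param series A smoothed [temperature_series()].
#' @param onset_s Stimulation onset (seconds, series time base).
#' @param base_window_s Length of the base window (default 60 s).
#' @param peak_window_s Length of the peak window from onset (default 600 s,
#'   the first 10 min of cooling; use `Inf` for initial+final combined).
#' @param window_label Label stored on the result (e.g. `"initial"`,
#'   `"initial+final"`).
#'
#' @return An object of class `outcome_set`: list with `base`, `peak`,
#'   `delta` (degrees Celsius), `side`, `kind`, `window`.
#' @export
compute_outcomes <- function(series, onset_s, base_window_s = 60,
                             peak_window_s = 600,
                             window_label = if (is.finite(peak_window_s))
                               "initial" else "initial+final") {
  t <- series$timestamp_s
  if (onset_s < t[1] || onset_s > t[length(t)]) {
    stop("onset lies outside the series span")
  }
  in_base <- t >= onset_s & t < onset_s + base_window_s
  in_peak <- t >= onset_s & t < onset_s + peak_window_s
  if (!any(in_base)) stop("empty base window")
  if (!any(in_peak)) stop("empty peak window")
  base <- mean(series$value_c[in_base])
  peak <- max(series$value_c[in_peak])
  structure(list(base = base, peak = peak, delta = peak - base,
                 side = attr(series, "side"), kind = attr(series, "kind"),
                 window = window_label),
            class = "outcome_set")
}

#' Mean of a series over a half-open time window
#'
#' Supports the "at 10 min of cooling" and "in final minute" outcome rows.
#'
#' @param series A [temperature_series()].
#' @param start_s,end_s Window bounds; samples with
#'   `start_s <= t < end_s` contribute.
#' @return Scalar mean (degrees Celsius).
#' @export
window_mean <- function(series, start_s, end_s) {
  sel <- series$timestamp_s >= start_s & series$timestamp_s < end_s
  if (!any(sel)) stop("empty window")
  mean(series$value_c[sel])
}
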