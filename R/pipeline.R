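#' Analyze one thermal imaging session
#'
#' Runs the full thermal pipeline on a frame sequence: neck-contour and ROI
#' construction from the apices, per-frame hotspot and reference
#' extraction, relative series (hotspot minus reference, per frame, before
#' smoothing), moving-average smoothing, and the base/peak/delta outcomes
#' for both sides and both kinds, plus the end-of-initial-period composite
#' and its hotspot masks used for the projection comparison.
#'
#' @param frames List of [temperature_frame()]s (time-ordered).
#' @param apices An [apex_set()].
#' @param periods Character vector of period labels per frame
#'   (`acclimatization`/`initial`/`final`).
#' @param onset_s Cooling onset (s); defaults to the first `initial` frame.
#' @param smoothing_period Moving-average window (samples, default 5).
#' @param frac Hotspot fraction (default 0.1).
#' @param reference_offset_px Reference-circle offset below the sternal
#'   apex.
#' @param min_contrast,band_halfwidth Contour-detection parameters.
#'
#' @return An object of class `thermal_session`: list with `rois`,
#'   `reference`, `series` (raw and smoothed, per side/kind), `outcomes`
#'   (data frame), `composite`, `hotspot_masks` and geometry.
#' @export
analyze_thermal_session <- function(frames, apices, periods,
                                    onset_s = NULL,
                                    smoothing_period = 5L, frac = 0.1,
                                    reference_offset_px = 10,
                                    min_contrast = 3, band_halfwidth = 30) {
  stopifnot(length(frames) >= 1L, length(periods) == length(frames))
  dims <- dim(frames[[1]]$temp_c)
  if (is.null(onset_s)) {
    first_initial <- which(periods == "initial")[1]
    if (is.na(first_initial)) stop("no 'initial' period frames")
    onset_s <- frames[[first_initial]]$timestamp_s
  }
  ref <- build_reference_region(apices, dims,
                                offset_px = reference_offset_px)
  ref_series <- extract_series(frames, ref, reference_statistic,
                               kind = "reference")
  initial_frames <- frames[periods == "initial"]
  if (length(initial_frames) == 0L) stop("no 'initial' period frames")
  final_times <- vapply(frames[periods == "final"],
                        function(f) f$timestamp_s, numeric(1))
  interval <- if (length(frames) > 1L)
    frames[[2]]$timestamp_s - frames[[1]]$timestamp_s else 0
  initial_end <- max(vapply(initial_frames, function(f) f$timestamp_s,
                            numeric(1))) + interval
  composite <- mean_composite(initial_frames)

  rois <- list()
  hot_masks <- list()
  series <- list()
  outcomes <- list()
  for (side in c("left", "right")) {
    contour <- detect_neck_contour(frames[[1]], apices, side,
                                   min_contrast = min_contrast,
                                   band_halfwidth = band_halfwidth)
    roi <- build_roi_mask(apices, contour, dims)
    rois[[side]] <- roi
    hot_masks[[side]] <- hotspot_mask(composite, roi, frac = frac)
    abs_series <- extract_series(frames, roi,
                                 function(f, r) hotspot_statistic(f, r,
                                                                  frac = frac),
                                 side = side, kind = "absolute")
    rel_raw <- relative_series(abs_series, ref_series)
    for (kind in c("absolute", "relative")) {
      raw <- if (kind == "absolute") abs_series else rel_raw
      sm <- smooth_series(raw, period = smoothing_period)
      initial <- compute_outcomes(sm, onset_s, peak_window_s = 600)
      combined <- compute_outcomes(sm, onset_s, peak_window_s = Inf)
      at10 <- window_mean(sm, initial_end - 60, initial_end)
      finalmin <- if (length(final_times) > 0) {
        end <- max(final_times) + interval
        window_mean(sm, end - 60, end)
      } else NA_real_
      series[[paste(kind, side, sep = "_")]] <-
        list(raw = raw, smoothed = sm)
      outcomes[[paste(kind, side, sep = "_")]] <- data.frame(
        side = side, kind = kind,
        base = initial$base, peak_initial = initial$peak,
        delta10 = initial$delta, peak_combined = combined$peak,
        mean_last_minute_initial = at10,
        mean_last_minute_final = finalmin,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(rois = rois, reference = ref,
                 reference_series = ref_series,
                 series = series,
                 outcomes = do.call(rbind, unname(outcomes)),
                 composite = composite, hotspot_masks = hot_masks,
                 apices = apices, onset_s = onset_s, frac = frac),
            class = "thermal_session")
}

#' Compare the thermal hotspot with the projection hotspot
#'
#' Fits the locally weighted mean transformation in both directions from
#' the control-point pairs, maps the thermal ROI polygon onto the
#' projection to define the projection ROI, extracts the projection
#' hotspot (greatest 10% within that ROI), warps the thermal hotspot mask
#' into the projection frame, and computes the spatial overlap.
#'
#' @param session A `thermal_session` from [analyze_thermal_session()].
#' @param mip_img A `mip_image` of the glucose-uptake volume.
#' @param pairs [control_point_pairs()] (thermal = moving, projection =
#'   fixed).
#' @param side ROI side to compare (default `"right"`, the primary
#'   outcome side).
#' @param frac Hotspot fraction.
#' @param n_neighbors LWM neighborhood size.
#'
#' @return List with `overlap_pct`, `mip_hotspot_median`,
#'   `mip_hotspot_mask`, `warped_ti_mask`, `warped_roi_polygon`,
#'   `mip_roi_mask`, and the fitted `forward`/`inverse` transforms.
#' @export
compare_modalities <- function(session, mip_img, pairs, side = "right",
                               frac = 0.1, n_neighbors = 16L) {
  forward <- fit_lwm(pairs, n_neighbors = n_neighbors,
                     direction = "moving_to_fixed")
  inverse <- fit_lwm(pairs, n_neighbors = n_neighbors,
                     direction = "fixed_to_moving")
  mip_dims <- dim(if (inherits(mip_img, "mip_image")) mip_img$data else
    mip_img)
  poly <- warp_polygon(forward, session$rois[[side]]$polygon)
  roi_mip <- rasterize_polygon(poly$x, poly$y, mip_dims)
  if (!any(roi_mip)) stop("warped ROI falls outside the projection frame")
  hot <- mip_hotspot(mip_img, roi_mip, frac = frac)
  warped_ti <- warp_image(session$hotspot_masks[[side]], inverse,
                          out_dims = mip_dims)
  list(overlap_pct = spatial_overlap(warped_ti, hot$mask),
       mip_hotspot_median = hot$median,
       mip_hotspot_mask = hot$mask,
       warped_ti_mask = warped_ti,
       warped_roi_polygon = poly,
       mip_roi_mask = roi_mip,
       forward = forward, inverse = inverse)
}

#' Run the full analysis over a synthetic cohort
#'
#' For every subject and session: generates the thermal sequence and PET
#' volume, runs [analyze_thermal_session()], projects the uptake volume,
#' runs [compare_modalities()], and assembles one record per
#' subject-session with the overlap, the projection hotspot median, the
#' external regional uptake scalar and all IRT outcomes — the rows behind
#' the cohort report tables.
#'
#' @param cohort A `phantom_cohort` from [generate_cohort()].
#' @param sessions Sessions to run (default both).
#' @param side Primary comparison side.
#'
#' @return List with `records` (data frame), `truth` (per subject-session
#'   analytic outcome truth), and `tables` from [build_results_tables()].
#' @export
run_cohort <- function(cohort, sessions = c("cold", "vehicle"),
                       side = "right") {
  records <- list()
  truths <- list()
  for (subject in cohort$subjects) {
    for (session in sessions) {
      thermal <- generate_thermal_sequence(subject$spec, session)
      irt <- analyze_thermal_session(thermal$frames, thermal$apices,
                                     thermal$periods,
                                     onset_s = subject$spec$onset_s)
      amp <- if (session == "cold") subject$pet_amplitude else
        subject$pet_amplitude_vehicle
      pet <- generate_pet_volume(subject$spec, session, amplitude = amp)
      pairs <- generate_control_points(subject$spec)
      cmp <- compare_modalities(irt, mip(pet$mrgluc), pairs, side = side)
      out <- irt$outcomes
      row <- data.frame(subject = subject$id, session = session,
                        overlap_pct = cmp$overlap_pct,
                        mrgluc_mip = cmp$mip_hotspot_median,
                        mrgluc_bat = if (session == "cold")
                          subject$mrgluc_bat else
                            subject$mrgluc_bat * 0.1,
                        stringsAsFactors = FALSE)
      for (i in seq_len(nrow(out))) {
        pre <- paste0("_", out$kind[i], "_", out$side[i])
        row[[paste0("base", pre)]] <- out$base[i]
        row[[paste0("peak_initial", pre)]] <- out$peak_initial[i]
        row[[paste0("delta10", pre)]] <- out$delta10[i]
        row[[paste0("peak_combined", pre)]] <- out$peak_combined[i]
      }
      records[[paste(subject$id, session)]] <- row
      tr <- analytic_outcomes(subject$spec, session)
      truths[[paste(subject$id, session)]] <- data.frame(
        subject = subject$id, session = session,
        delta10_true = tr$delta10, base_true = tr$base,
        peak_initial_true = tr$peak_initial, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, unname(records))
  truth <- do.call(rbind, unname(truths))
  list(records = records, truth = truth,
       tables = build_results_tables(records))
}

#' Write cohort results to CSV and a JSON run summary
#'
#' Writes `records.csv`, `outcomes.csv`, `overlap.csv`, `r2_grid.csv` and
#' `run_summary.json` (per-subject overlaps, correlation grid, p-values,
#' package version).
#'
#' @param results Output of [run_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(results$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(results$tables$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  ov <- results$tables$overlap
  utils::write.csv(ov$per_subject, file.path(dir, "overlap.csv"),
                   row.names = FALSE)
  utils::write.csv(results$tables$r2_grid, file.path(dir, "r2_grid.csv"),
                   row.names = FALSE)
  summary <- list(
    overlap = ov[setdiff(names(ov), "per_subject")],
    per_subject_overlap = ov$per_subject,
    r2_grid = results$tables$r2_grid,
    package_version = as.character(utils::packageVersion("thermobat")))
  jsonlite::write_json(summary, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Write a complete synthetic study directory
#'
#' Materializes one subject's synthetic study on disk in the open formats
#' the pipeline reads: `frames/` (16-bit PNG + JSON sidecars with a
#' manifest), `volumes/` (NIfTI), `apices.csv`, `control_points.csv`,
#' `ground_truth.json` and `spec.yaml`.
#'
#' @param spec A [phantom_spec()].
#' @param dir Output directory.
#' @param session `"cold"` or `"vehicle"`.
#' @return `dir`, invisibly.
#' @export
write_study <- function(spec, dir, session = "cold") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  thermal <- generate_thermal_sequence(spec, session, return_counts = TRUE)
  write_sequence(thermal$raw_frames, thermal$periods,
                 file.path(dir, "frames"))
  pet <- generate_pet_volume(spec, session)
  dir.create(file.path(dir, "volumes"), showWarnings = FALSE)
  write_volume(pet$mrgluc, file.path(dir, "volumes", "mrgluc.nii.gz"))
  write_volume(pet$ct, file.path(dir, "volumes", "ct.nii.gz"))
  write_apices(thermal$apices, file.path(dir, "apices.csv"),
               frame_id = thermal$frames[[1]]$frame_id)
  write_control_points(generate_control_points(spec),
                       file.path(dir, "control_points.csv"))
  truth <- thermal$truth
  jsonlite::write_json(
    list(blob_centers_ti = truth$blob_centers_ti,
         blob_centers_mip = truth$blob_centers_mip,
         warp_coef = truth$warp_coef,
         outcomes_true = truth$outcomes_true,
         seed = spec$seed, session = session),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  writeable <- spec[!vapply(spec, is.function, logical(1))]
  writeable$calibration <- unclass(writeable$calibration)
  yaml::write_yaml(writeable, file.path(dir, "spec.yaml"))
  invisible(dir)
}
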