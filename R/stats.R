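#' Percentage spatial overlap of two hotspot masks
#'
#' The overlap between the warped thermal hotspot and the projection
#' hotspot is the number of pixels the hotspots share, divided by the size
#' of either hotspot (both are defined as the same fraction of the same
#' ROI, so they are nominally the same size). Because nearest-neighbor
#' warping can change a mask's pixel count slightly, the default
#' denominator is the projection-hotspot count (measured in the fixed
#' frame); `denominator = "mean"` uses the mean of the two counts instead.
#'
#' @param ti_mask Warped thermal-image hotspot (logical matrix, projection
#'   frame).
#' @param mip_mask Projection hotspot (logical matrix, same dimensions).
#' @param denominator `"mip"` (default) or `"mean"`.
#'
#' @return Overlap percentage in \[0, 100\].
#' @examples
#' a <- matrix(FALSE, 4, 4); a[1, 1:2] <- TRUE
#' spatial_overlap(a, a)
#' @export
spatial_overlap <- function(ti_mask, mip_mask,
                            denominator = c("mip", "mean")) {
  denominator <- match.arg(denominator)
  if (!all(dim(ti_mask) == dim(mip_mask))) {
    stop("masks must share dimensions")
  }
  na <- sum(ti_mask); nb <- sum(mip_mask)
  if (na == 0L || nb == 0L) stop("empty hotspot mask")
  common <- sum(ti_mask & mip_mask)
  denom <- if (denominator == "mip") nb else (na + nb) / 2
  100 * common / denom
}

#' Mean and standard error of the mean
#'
#' SEM is the sample standard deviation (`n - 1` denominator) divided by
#' the square root of `n`.
#'
#' @param values Numeric vector.
#' @return List with `mean`, `sem` and `n`.
#' @export
mean_sem <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1L) stop("no values")
  list(mean = mean(values),
       sem = if (n >= 2L) stats::sd(values) / sqrt(n) else NA_real_,
       n = n)
}

#' Squared Pearson correlation with a two-sided p-value
#'
#' The square of the Pearson coefficient; the p-value comes from the
#' t-distribution with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, both with nonzero
#'   variance.
#' @return List with `r2`, `r` and `p`.
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in 'x' or 'y'")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r2 = r^2, r = r, p = p)
}

#' Paired two-sided comparison
#'
#' Paired two-sided t-test by default, with the Wilcoxon signed-rank test
#' as an option. Degenerate input (all differences equal) is an error.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @param method `"t"` (default) or `"wilcoxon"`.
#' @return Two-sided p-value.
#' @export
paired_comparison <- function(a, b, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L) stop("need at least 2 complete pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    stop("degenerate paired comparison: all differences are equal")
  }
  if (method == "t") {
    stats::t.test(a, b, paired = TRUE)$p.value
  } else {
    stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
  }
}

#' Published per-participant hotspot overlap percentages
#'
#' The per-participant percentage spatial overlap between the
#' glucose-uptake projection hotspot and the thermal hotspot reported for
#' the eight-man validation cohort, under cold stimulation and (for the
#' four participants who also underwent a control scan) under vehicle.
#' Useful as a reference input for the summary statistics this package
#' computes.
#'
#' @return Data frame with columns `participant`, `session`
#'   (`cold`/`vehicle`), `overlap_pct` and `paired` (`TRUE` for the four
#'   participants with both sessions).
#' @export
published_overlaps <- function() {
  data.frame(
    participant = c("A", "B", "C", "D", "E", "F", "G", "H",
                    "B", "C", "F", "G"),
    session = c(rep("cold", 8L), rep("vehicle", 4L)),
    overlap_pct = c(31.6, 11.6, 36.6, 55.5, 14.3, 38.5, 24.9, 22.9,
                    0.1, 8.4, 14.1, 2.6),
    paired = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE,
               TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

# round half up at `digits` decimal places (report convention)
round_half_up <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Assemble cohort results tables
#'
#' Builds the report tables from per-subject records: (1) outcome summary —
#' mean, SEM and paired cold-vs-vehicle p-value per IRT outcome and kind;
#' (2) per-subject overlap with cold/vehicle group statistics; (3) a grid
#' of squared Pearson correlations between the relative IRT outcomes
#' (left/right) and the PET measures, computed on cold sessions.
#' Statistics requiring more observations than available are `NA`.
#'
#' @param records Data frame with one row per subject-session; columns
#'   `subject`, `session` (`"cold"`/`"vehicle"`), `overlap_pct`,
#'   `mrgluc_mip`, `mrgluc_bat`, and outcome columns named
#'   `<outcome>_<kind>_<side>` for outcome in `base`, `peak_initial`,
#'   `delta10`; kind in `absolute`, `relative`; side in `left`, `right`.
#'
#' @return List of data frames: `outcomes`, `overlap`, `r2_grid`.
#' @export
build_results_tables <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("'records' must be a non-empty data frame")
  }
  cold <- records[records$session == "cold", , drop = FALSE]
  veh <- records[records$session == "vehicle", , drop = FALSE]

  outcome_cols <- intersect(
    as.vector(outer(as.vector(outer(c("base", "peak_initial", "delta10"),
                                    c("absolute", "relative"), paste,
                                    sep = "_")),
                    c("left", "right"), paste, sep = "_")),
    names(records))
  paired_p <- function(col) {
    common <- intersect(cold$subject, veh$subject)
    if (length(common) < 2L) return(NA_real_)
    a <- cold[[col]][match(common, cold$subject)]
    b <- veh[[col]][match(common, veh$subject)]
    if (stats::sd(a - b, na.rm = TRUE) == 0) return(NA_real_)
    paired_comparison(a, b)
  }
  outcomes <- do.call(rbind, lapply(outcome_cols, function(col) {
    mc <- mean_sem(cold[[col]])
    mv <- if (nrow(veh) > 0L) mean_sem(veh[[col]]) else
      list(mean = NA_real_, sem = NA_real_)
    data.frame(outcome = col,
               cold_mean = mc$mean, cold_sem = mc$sem,
               vehicle_mean = mv$mean, vehicle_sem = mv$sem,
               p = paired_p(col), stringsAsFactors = FALSE)
  }))

  ov_cold <- mean_sem(cold$overlap_pct)
  paired_subjects <- intersect(cold$subject, veh$subject)
  ov_cold_paired <- if (length(paired_subjects) > 0L) {
    mean_sem(cold$overlap_pct[cold$subject %in% paired_subjects])
  } else list(mean = NA_real_, sem = NA_real_)
  ov_veh <- if (nrow(veh) > 0L) mean_sem(veh$overlap_pct) else
    list(mean = NA_real_, sem = NA_real_)
  overlap <- list(
    per_subject = records[, c("subject", "session", "overlap_pct")],
    cold_mean = ov_cold$mean, cold_sem = ov_cold$sem,
    cold_paired_mean = ov_cold_paired$mean,
    cold_paired_sem = ov_cold_paired$sem,
    vehicle_mean = ov_veh$mean, vehicle_sem = ov_veh$sem,
    p = paired_p("overlap_pct"))

  rel_outcomes <- intersect(
    as.vector(outer(paste0(c("base", "peak_initial", "delta10"),
                           "_relative"),
                    c("left", "right"), paste, sep = "_")),
    names(records))
  r2_grid <- do.call(rbind, lapply(rel_outcomes, function(col) {
    do.call(rbind, lapply(c("mrgluc_mip", "mrgluc_bat"), function(m) {
      res <- if (nrow(cold) >= 3L && m %in% names(cold) &&
                 !all(is.na(cold[[m]]))) {
        tryCatch(pearson_r2(cold[[col]], cold[[m]]),
                 error = function(e) list(r2 = NA_real_, p = NA_real_))
      } else list(r2 = NA_real_, p = NA_real_)
      data.frame(irt_outcome = col, pet_measure = m,
                 r2 = res$r2, p = res$p, stringsAsFactors = FALSE)
    }))
  }))

  list(outcomes = outcomes, overlap = overlap, r2_grid = r2_grid)
}
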