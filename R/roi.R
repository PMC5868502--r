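#' Labelled ROI apices
#'
#' The five anatomical key points from which the left and right
#' supraclavicular regions of interest are constructed: the superolateral
#' apex of each side (on the neck), the acromioclavicular apex of each side
#' (lateral end of the clavicle) and the single sternal apex shared by both
#' sides. Coordinates are 1-based pixel indices, `x` = column, `y` = row,
#' origin at the top-left of the image.
#'
#' @param superolateral_left,superolateral_right,acromioclavicular_left,acromioclavicular_right,sternal
#'   Length-2 numeric vectors `c(x, y)`.
#' @param dims Image dimensions `c(nrow, ncol)` used for bounds checking.
#'
#' @return An object of class `apex_set`.
#' @export
apex_set <- function(superolateral_left, superolateral_right,
                     acromioclavicular_left, acromioclavicular_right,
                     sternal, dims) {
  pts <- list(superolateral_left = superolateral_left,
              superolateral_right = superolateral_right,
              acromioclavicular_left = acromioclavicular_left,
              acromioclavicular_right = acromioclavicular_right,
              sternal = sternal)
  for (nm in names(pts)) {
    p <- pts[[nm]]
    if (!is.numeric(p) || length(p) != 2L || any(!is.finite(p))) {
      stop("apex '", nm, "' must be a finite c(x, y) pair")
    }
    if (p[1] < 1 || p[1] > dims[2] || p[2] < 1 || p[2] > dims[1]) {
      stop("apex '", nm, "' lies outside the frame bounds")
    }
  }
  if (!(pts$sternal[1] > max(pts$superolateral_left[1],
                             pts$acromioclavicular_left[1]) &&
        pts$sternal[1] < min(pts$superolateral_right[1],
                             pts$acromioclavicular_right[1]))) {
    stop("sternal apex must lie between the left and right apex pairs in x")
  }
  if (pts$superolateral_left[2] >= pts$acromioclavicular_left[2] ||
      pts$superolateral_right[2] >= pts$acromioclavicular_right[2]) {
    stop("superolateral apices must lie above the acromioclavicular apices")
  }
  structure(c(pts, list(dims = as.integer(dims))), class = "apex_set")
}

#' Read/write apex annotations
#'
#' Apices are exchanged as CSV with columns `frame_id, label, x, y`
#' (1-based pixel coordinates).
#'
#' @param path CSV path.
#' @param frame_id Frame whose apices to extract.
#' @param dims Image dimensions `c(nrow, ncol)`.
#' @return [read_apices()]: an [apex_set()]; [write_apices()]: `path`,
#'   invisibly.
#' @export
read_apices <- function(path, frame_id, dims) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$frame_id == frame_id, , drop = FALSE]
  get <- function(lbl) {
    row <- df[df$label == lbl, , drop = FALSE]
    if (nrow(row) != 1L) stop("expected exactly one '", lbl, "' apex")
    c(row$x, row$y)
  }
  apex_set(get("superolateral_left"), get("superolateral_right"),
           get("acromioclavicular_left"), get("acromioclavicular_right"),
           get("sternal"), dims = dims)
}

#' @rdname read_apices
#' @param apices An [apex_set()].
#' @export
write_apices <- function(apices, path, frame_id = "frame") {
  labels <- c("superolateral_left", "superolateral_right",
              "acromioclavicular_left", "acromioclavicular_right", "sternal")
  df <- data.frame(frame_id = frame_id, label = labels,
                   x = vapply(labels, function(l) apices[[l]][1], numeric(1)),
                   y = vapply(labels, function(l) apices[[l]][2], numeric(1)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Detect the neck contour from the skin/background temperature gradient
#'
#' For every image row between a side's superolateral and acromioclavicular
#' apices, the lateral ROI border is placed at the column of maximum
#' horizontal temperature gradient within a search band around the straight
#' line joining the two apices. The gradient is signed toward the body: at
#' the left border the background (cooler) lies at smaller x so the
#' transition gradient is positive, at the right border negative — which
#' disambiguates the two sides of a narrow neck when both fall inside the
#' band. The skin must be warmer than the background by at least
#' `min_contrast` within the band of every row.
#'
#' @param frame A [temperature_frame()].
#' @param apices An [apex_set()].
#' @param side `"left"` or `"right"`.
#' @param min_contrast Minimum skin/background contrast in degrees Celsius.
#' @param band_halfwidth Half-width (px) of the lateral search band around
#'   the straight-line prior.
#'
#' @return An object of class `neck_contour`: a data frame with one `x` per
#'   `y` row, ordered superolateral to acromioclavicular, plus a `side`
#'   attribute. Endpoints coincide with the two lateral apices.
#' @export
detect_neck_contour <- function(frame, apices, side = c("left", "right"),
                                min_contrast = 3, band_halfwidth = 30) {
  side <- match.arg(side)
  stopifnot(inherits(frame, "temperature_frame"))
  tm <- frame$temp_c
  sl <- apices[[paste0("superolateral_", side)]]
  ac <- apices[[paste0("acromioclavicular_", side)]]
  y0 <- sl[2]; y1 <- ac[2]
  if (y1 <= y0) stop("apices on wrong side: contour rows are empty")
  rows <- seq(ceiling(y0), floor(y1))
  if (length(rows) < 3L) stop("apices too close: no interior contour rows")
  prior_x <- sl[1] + (ac[1] - sl[1]) * (rows - y0) / (y1 - y0)
  nc <- ncol(tm)
  xs <- numeric(length(rows))
  # endpoints are the apices by definition; the gradient is traced on the
  # interior rows only
  for (i in seq(2L, length(rows) - 1L)) {
    lo <- max(2L, floor(prior_x[i] - band_halfwidth))
    hi <- min(nc - 1L, ceiling(prior_x[i] + band_halfwidth))
    if (hi <= lo) stop("search band empty in row ", rows[i])
    band <- tm[rows[i], (lo - 1L):(hi + 1L)]
    if (diff(range(band)) < min_contrast) {
      stop("insufficient contrast between skin and background in row ",
           rows[i])
    }
    # signed central-difference horizontal gradient over the band
    grad <- (band[-(1:2)] - band[seq_len(length(band) - 2L)]) / 2
    if (side == "right") grad <- -grad
    # gradient ties (a discrete step straddles two columns) resolve to the
    # candidate nearest the straight-line prior, keeping detection
    # mirror-symmetric
    cand <- which(grad >= max(grad) - 1e-12)
    xs[i] <- lo + cand[which.min(abs(lo + cand - 1L - prior_x[i]))] - 1L
  }
  xs[1] <- sl[1]
  xs[length(xs)] <- ac[1]
  structure(data.frame(x = xs, y = rows), side = side,
            class = c("neck_contour", "data.frame"))
}

# Segment-crossing test for polygon self-intersection (adjacent edges skip).
polygon_self_intersects <- function(px, py) {
  n <- length(px)
  seg <- cbind(px, py, c(px[-1], px[1]), c(py[-1], py[1]))
  ccw <- function(ax, ay, bx, by, cx, cy) {
    (cy - ay) * (bx - ax) - (by - ay) * (cx - ax)
  }
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)] # edges sharing a vertex are fine
    for (j in js) {
      d1 <- ccw(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d2 <- ccw(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      d3 <- ccw(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d4 <- ccw(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      if (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
          ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Rasterize a polygon: pixels whose centers lie inside (even-odd rule),
# boundary pixels included.
rasterize_polygon <- function(px, py, dims) {
  x0 <- max(1L, floor(min(px)))
  x1 <- min(dims[2], ceiling(max(px)))
  y0 <- max(1L, floor(min(py)))
  y1 <- min(dims[1], ceiling(max(py)))
  mask <- matrix(FALSE, dims[1], dims[2])
  if (x1 < x0 || y1 < y0) return(mask)
  gx <- rep(x0:x1, times = y1 - y0 + 1L)
  gy <- rep(y0:y1, each = x1 - x0 + 1L)
  inside <- pracma::inpolygon(gx, gy, px, py, boundary = TRUE)
  mask[cbind(gy[inside], gx[inside])] <- TRUE
  mask
}

#' Build a supraclavicular ROI mask
#'
#' Closes the polygon superolateral apex -> neck contour ->
#' acromioclavicular apex -> straight line -> sternal apex -> straight line
#' -> superolateral apex, and rasterizes it: a pixel belongs to the mask when
#' its center lies inside the polygon (even-odd rule), boundary pixels
#' included.
#'
#' @param apices An [apex_set()].
#' @param contour A `neck_contour` from [detect_neck_contour()].
#' @param dims Image dimensions `c(nrow, ncol)`.
#'
#' @return An object of class `roi_mask`: list with `mask` (logical matrix),
#'   `polygon` (data frame of vertices) and `side`.
#' @export
build_roi_mask <- function(apices, contour, dims) {
  side <- attr(contour, "side")
  sl <- apices[[paste0("superolateral_", side)]]
  ac <- apices[[paste0("acromioclavicular_", side)]]
  if (abs(contour$x[1] - sl[1]) > 1e-6 || abs(contour$y[1] - sl[2]) > 0.5 ||
      abs(contour$x[nrow(contour)] - ac[1]) > 1e-6 ||
      abs(contour$y[nrow(contour)] - ac[2]) > 0.5) {
    stop("contour endpoints must coincide with the lateral apices")
  }
  px <- c(contour$x, apices$sternal[1])
  py <- c(contour$y, apices$sternal[2])
  if (polygon_self_intersects(px, py)) {
    stop("ROI polygon is self-intersecting")
  }
  mask <- rasterize_polygon(px, py, dims)
  if (abs(pracma::polyarea(px, py)) < 0.5 || !any(mask)) {
    stop("degenerate (empty) ROI mask: apices are collinear")
  }
  structure(list(mask = mask, polygon = data.frame(x = px, y = py),
                 side = side),
            class = "roi_mask")
}

#' Build the sternal reference region
#'
#' A circle of the given diameter centred `offset_px` pixels below the
#' sternal apex. A pixel belongs to the region when its center lies within
#' `diameter/2` of the circle center (ties included).
#'
#' @param apices An [apex_set()].
#' @param dims Image dimensions `c(nrow, ncol)`.
#' @param offset_px Downward offset of the circle center from the sternal
#'   apex (default one diameter).
#' @param diameter_px Circle diameter in pixels (default 10).
#'
#' @return An object of class `reference_region`: list with `mask`,
#'   `center` and `diameter_px`.
#' @examples
#' ap <- apex_set(c(20, 10), c(80, 10), c(15, 40), c(85, 40), c(50, 50),
#'                dims = c(100, 100))
#' sum(build_reference_region(ap, c(100, 100))$mask) # 81 pixels
#' @export
build_reference_region <- function(apices, dims, offset_px = 10,
                                   diameter_px = 10) {
  center <- c(apices$sternal[1], apices$sternal[2] + offset_px)
  r <- diameter_px / 2
  if (center[1] - r < 1 || center[1] + r > dims[2] ||
      center[2] - r < 1 || center[2] + r > dims[1]) {
    stop("reference circle does not fit inside the frame")
  }
  x0 <- floor(center[1] - r); x1 <- ceiling(center[1] + r)
  y0 <- floor(center[2] - r); y1 <- ceiling(center[2] + r)
  gx <- rep(x0:x1, times = y1 - y0 + 1L)
  gy <- rep(y0:y1, each = x1 - x0 + 1L)
  keep <- (gx - center[1])^2 + (gy - center[2])^2 <= r^2
  mask <- matrix(FALSE, dims[1], dims[2])
  mask[cbind(gy[keep], gx[keep])] <- TRUE
  structure(list(mask = mask, center = center, diameter_px = diameter_px),
            class = "reference_region")
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}
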