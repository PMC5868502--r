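#' Control-point pairs between thermal and projection coordinates
#'
#' Corresponding anatomic points identified in a thermal image ("moving")
#' and a maximum intensity projection ("fixed"). At least 6 pairs are
#' required (a bivariate degree-2 polynomial has 6 coefficients).
#'
#' @param moving,fixed n-by-2 matrices (or data frames) of `c(x, y)` pixel
#'   coordinates.
#'
#' @return An object of class `control_point_pairs`.
#' @export
control_point_pairs <- function(moving, fixed) {
  moving <- as.matrix(moving)
  fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed) || ncol(moving) != 2L ||
      ncol(fixed) != 2L) {
    stop("'moving' and 'fixed' must be n-by-2 with matching n")
  }
  if (nrow(moving) < 6L) {
    stop("at least 6 control-point pairs are required (degree-2 polynomial)")
  }
  if (anyDuplicated(fixed[, 1] + 1i * fixed[, 2]) ||
      anyDuplicated(moving[, 1] + 1i * moving[, 2])) {
    stop("duplicated control points")
  }
  structure(list(moving = unname(moving), fixed = unname(fixed),
                 n = nrow(moving)),
            class = "control_point_pairs")
}

#' Read / write control-point pairs as CSV
#'
#' Columns: `pair_id, x_ti, y_ti, x_mip, y_mip` (1-based pixel
#' coordinates; thermal image = moving, projection = fixed).
#'
#' @param path CSV path.
#' @return [read_control_points()]: a [control_point_pairs()].
#' @export
read_control_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  control_point_pairs(cbind(df$x_ti, df$y_ti), cbind(df$x_mip, df$y_mip))
}

#' @rdname read_control_points
#' @param pairs A [control_point_pairs()].
#' @export
write_control_points <- function(pairs, path) {
  df <- data.frame(pair_id = seq_len(pairs$n),
                   x_ti = pairs$moving[, 1], y_ti = pairs$moving[, 2],
                   x_mip = pairs$fixed[, 1], y_mip = pairs$fixed[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

quad_design <- function(x, y) {
  cbind(1, x, y, x^2, x * y, y^2)
}

#' Locally weighted mean (LWM) weight function
#'
#' The smooth taper `W(t) = 1 - 3 t^2 + 2 t^3` on `[0, 1]`, zero beyond:
#' `W(0) = 1`, `W(1) = 0`, continuously differentiable and monotone
#' decreasing on the unit interval.
#'
#' @param t Non-negative normalized distances.
#' @return Weights in \[0, 1\].
#' @export
lwm_weight <- function(t) {
  ifelse(t >= 0 & t <= 1, 1 - 3 * t^2 + 2 * t^3, 0)
}

#' Fit a locally weighted mean transformation
#'
#' For each control point, a full bivariate second-degree polynomial (terms
#' `1, x, y, x^2, xy, y^2`) is least-squares fitted per output coordinate to
#' its `n_neighbors` nearest control points (Euclidean distance in source
#' coordinates, the point itself included). Each local polynomial's
#' influence radius `R_i` is the distance to the most distant neighbor
#' used. Applying the transform blends the local polynomials with the
#' smooth distance taper [lwm_weight()].
#'
#' The mapping is not analytically invertible; fit the two directions
#' separately (`"moving_to_fixed"` for mapping points/polygons onto the
#' projection, `"fixed_to_moving"` for resampling images).
#'
#' @param pairs A [control_point_pairs()].
#' @param n_neighbors Neighborhood size (default 16).
#' @param direction `"moving_to_fixed"` (default) or `"fixed_to_moving"`.
#'
#' @return An object of class `lwm_transform`.
#' @export
fit_lwm <- function(pairs, n_neighbors = 16L,
                    direction = c("moving_to_fixed", "fixed_to_moving")) {
  direction <- match.arg(direction)
  stopifnot(inherits(pairs, "control_point_pairs"))
  src <- if (direction == "moving_to_fixed") pairs$moving else pairs$fixed
  dst <- if (direction == "moving_to_fixed") pairs$fixed else pairs$moving
  n <- nrow(src)
  if (n_neighbors < 6L) stop("'n_neighbors' must be at least 6")
  if (n_neighbors > n) stop("'n_neighbors' exceeds the number of pairs")
  coefs <- array(NA_real_, c(6L, 2L, n))
  radii <- numeric(n)
  d2 <- as.matrix(stats::dist(src))
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[seq_len(n_neighbors)] # self included (distance 0)
    X <- quad_design(src[nb, 1], src[nb, 2])
    qr_x <- qr(X)
    if (qr_x$rank < 6L) {
      stop("rank-deficient neighborhood at control point ", i,
           " (collinear points)")
    }
    coefs[, , i] <- qr.coef(qr_x, dst[nb, , drop = FALSE])
    radii[i] <- max(d2[i, nb])
  }
  if (any(radii <= 0)) stop("zero neighborhood radius (duplicate points)")
  structure(list(centers = src, coefs = coefs, radii = radii,
                 n_neighbors = as.integer(n_neighbors),
                 direction = direction),
            class = "lwm_transform")
}

#' Apply a locally weighted mean transformation to points
#'
#' The mapped position of `p` is the weighted average of all local
#' polynomials whose influence disk covers `p`:
#' `sum_i W(d_i / R_i) P_i(p) / sum_i W(d_i / R_i)`, with `d_i` the distance
#' from `p` to control point `i`. Points covered by no influence disk fall
#' back to the nearest control point's polynomial (or raise an error when
#' `fallback = "error"`); the number of fallback points is recorded in the
#' `n_fallback` attribute of the result.
#'
#' @param transform An `lwm_transform` from [fit_lwm()].
#' @param points n-by-2 matrix of `c(x, y)` points in source coordinates.
#' @param fallback `"nearest"` (default) or `"error"`.
#'
#' @return n-by-2 matrix of mapped points, with attribute `n_fallback`.
#' @export
apply_lwm <- function(transform, points, fallback = c("nearest", "error")) {
  fallback <- match.arg(fallback)
  points <- matrix(as.numeric(as.matrix(points)), ncol = 2L)
  np <- nrow(points)
  ctr <- transform$centers
  ncp <- nrow(ctr)
  # distances points x centers
  d <- sqrt(outer(points[, 1], ctr[, 1], `-`)^2 +
              outer(points[, 2], ctr[, 2], `-`)^2)
  w <- lwm_weight(sweep(d, 2, transform$radii, `/`))
  X <- quad_design(points[, 1], points[, 2]) # np x 6
  px <- X %*% matrix(transform$coefs[, 1L, ], nrow = 6L) # np x ncp
  py <- X %*% matrix(transform$coefs[, 2L, ], nrow = 6L)
  wsum <- rowSums(w)
  out <- cbind(rowSums(w * px), rowSums(w * py)) / wsum
  uncovered <- which(wsum == 0)
  if (length(uncovered) > 0L) {
    if (fallback == "error") {
      stop(length(uncovered), " point(s) outside all influence disks")
    }
    nearest <- apply(d[uncovered, , drop = FALSE], 1L, which.min)
    out[uncovered, 1] <- rowSums(X[uncovered, , drop = FALSE] *
                                   t(transform$coefs[, 1L, nearest]))
    out[uncovered, 2] <- rowSums(X[uncovered, , drop = FALSE] *
                                   t(transform$coefs[, 2L, nearest]))
  }
  attr(out, "n_fallback") <- length(uncovered)
  out
}

#' Warp an image through an inverse-direction LWM transformation
#'
#' Inverse mapping: each output pixel `p` (fixed/projection coordinates) is
#' sampled from the input image at `t_inverse(p)` with bilinear
#' interpolation (nearest neighbor for binary masks, which therefore stay
#' binary). Samples falling outside the input are invalid: `NA` for numeric
#' images, `FALSE` for masks.
#'
#' @param image Numeric or logical matrix (thermal frame or mask).
#' @param t_inverse An `lwm_transform` fitted with
#'   `direction = "fixed_to_moving"` — it must map output coordinates to
#'   input coordinates.
#' @param out_dims Output dimensions `c(nrow, ncol)` (default: input dims).
#' @param interpolation `"bilinear"` (default for numeric) or `"nearest"`
#'   (forced for logical input).
#'
#' @return Matrix of dimension `out_dims`.
#' @export
warp_image <- function(image, t_inverse, out_dims = dim(image),
                       interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  is_mask <- is.logical(image)
  if (is_mask) interpolation <- "nearest"
  img <- if (is_mask) (image * 1) else image
  nr <- out_dims[1]; nc <- out_dims[2]
  gx <- rep(seq_len(nc), each = nr)
  gy <- rep(seq_len(nr), times = nc)
  src <- apply_lwm(t_inverse, cbind(gx, gy))
  if (interpolation == "nearest") {
    sx <- round(src[, 1]); sy <- round(src[, 2])
    ok <- sx >= 1 & sx <= ncol(img) & sy >= 1 & sy <= nrow(img)
    vals <- rep(NA_real_, length(sx))
    vals[ok] <- img[cbind(sy[ok], sx[ok])]
  } else {
    vals <- bilinear_sample(img, src[, 1], src[, 2])
  }
  out <- matrix(vals, nr, nc)
  if (is_mask) {
    out[is.na(out)] <- 0
    out <- out > 0.5
  }
  out
}

#' Warp a polygon through a forward LWM transformation
#'
#' Vertices are mapped pointwise after edge densification: extra vertices
#' are inserted (by linear interpolation in source space) until no mapped
#' segment is longer than `max_seg_px`, so the mapped outline follows the
#' curved transformation closely enough for rasterization.
#'
#' @param t_forward An `lwm_transform` fitted `moving_to_fixed`.
#' @param polygon Data frame or matrix with columns `x`, `y` (closed
#'   implicitly).
#' @param max_seg_px Maximum mapped segment length (default 1 px).
#'
#' @return Data frame with columns `x`, `y` of the mapped, densified
#'   polygon.
#' @export
warp_polygon <- function(t_forward, polygon, max_seg_px = 1) {
  poly <- as.matrix(as.data.frame(polygon)[, c("x", "y")])
  for (pass in 1:6) {
    mapped <- apply_lwm(t_forward, poly)
    nxt <- rbind(mapped[-1, , drop = FALSE], mapped[1, , drop = FALSE])
    seg_len <- sqrt(rowSums((nxt - mapped)^2))
    if (all(seg_len <= max_seg_px)) break
    pieces <- pmax(1L, ceiling(seg_len / max_seg_px))
    src_nxt <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
    new_poly <- vector("list", nrow(poly))
    for (i in seq_len(nrow(poly))) {
      f <- seq(0, 1, length.out = pieces[i] + 1L)[-(pieces[i] + 1L)]
      new_poly[[i]] <- cbind(poly[i, 1] + f * (src_nxt[i, 1] - poly[i, 1]),
                             poly[i, 2] + f * (src_nxt[i, 2] - poly[i, 2]))
    }
    poly <- do.call(rbind, new_poly)
  }
  mapped <- apply_lwm(t_forward, poly)
  data.frame(x = mapped[, 1], y = mapped[, 2])
}

#' Serialize / restore an LWM transformation as JSON
#'
#' @param transform An `lwm_transform`.
#' @param path JSON path.
#' @return [read_lwm()]: an `lwm_transform`.
#' @export
write_lwm <- function(transform, path) {
  jsonlite::write_json(
    list(centers = transform$centers,
         coefs = transform$coefs,
         radii = transform$radii,
         n_neighbors = transform$n_neighbors,
         direction = transform$direction),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lwm
#' @export
read_lwm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(centers = matrix(unlist(obj$centers), ncol = 2L),
                 coefs = array(unlist(obj$coefs),
                               c(6L, 2L, length(obj$radii))),
                 radii = as.numeric(obj$radii),
                 n_neighbors = as.integer(obj$n_neighbors),
                 direction = obj$direction),
            class = "lwm_transform")
}
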