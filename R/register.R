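#' Similarity transform (translation, rotation, scale)
#'
#' The geometric transform family used to register sequential thermal frames
#' to the baseline frame. A point `p` (in `c(x, y)` pixel coordinates) maps
#' to `s * R(theta) * (p - c) + c + t`, where `c` is the rotation center
#' (by default the image center).
#'
#' @param tx,ty Translation in pixels.
#' @param rotation_deg Rotation in degrees (counter-clockwise in x/y
#'   coordinates).
#' @param scale Isotropic scale factor; must be positive.
#'
#' @return An object of class `similarity_transform`.
#' @export
similarity_transform <- function(tx = 0, ty = 0, rotation_deg = 0,
                                 scale = 1) {
  if (scale <= 0) stop("'scale' must be positive")
  structure(list(tx = tx, ty = ty, rotation_deg = rotation_deg,
                 scale = scale),
            class = "similarity_transform")
}

#' Apply / invert similarity transforms
#'
#' @param tf A [similarity_transform()].
#' @param points n-by-2 matrix of `c(x, y)` points.
#' @param center Rotation center `c(x, y)`.
#' @return Transformed points (n-by-2), or the inverse transform.
#' @export
apply_similarity <- function(tf, points, center = c(0, 0)) {
  th <- tf$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  p <- sweep(as.matrix(points), 2, center)
  out <- tf$scale * (p %*% t(R))
  sweep(out, 2, center + c(tf$tx, tf$ty), `+`)
}

#' @rdname apply_similarity
#' @export
invert_similarity <- function(tf) {
  th <- -tf$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t_inv <- -(R %*% c(tf$tx, tf$ty)) / tf$scale
  similarity_transform(t_inv[1], t_inv[2], -tf$rotation_deg, 1 / tf$scale)
}

# Bilinear sampling of matrix img at fractional (x = col, y = row)
# coordinates; NA outside the image.
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  eps <- 1e-6 # snap coordinates a rounding error outside the frame
  ok <- x >= 1 - eps & x <= nc + eps & y >= 1 - eps & y <= nr + eps &
    is.finite(x) & is.finite(y)
  x <- pmin(pmax(x, 1), nc)
  y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1) # clamp so the exact boundary samples cleanly
  y0 <- pmin(floor(y), nr - 1)
  fx <- x - x0; fy <- y - y0
  out <- rep(NA_real_, length(x))
  if (any(ok)) {
    xo <- x0[ok]; yo <- y0[ok]; fxo <- fx[ok]; fyo <- fy[ok]
    i00 <- (xo - 1) * nr + yo
    v00 <- img[i00]; v10 <- img[i00 + nr]
    v01 <- img[i00 + 1]; v11 <- img[i00 + nr + 1]
    out[ok] <- v00 * (1 - fxo) * (1 - fyo) + v10 * fxo * (1 - fyo) +
      v01 * (1 - fxo) * fyo + v11 * fxo * fyo
  }
  out
}

#' Warp a temperature frame with a similarity transform
#'
#' Inverse-mapping bilinear resampling: output pixel `p` is sampled at
#' `M^{-1}(p)` where `M` is the transform about the image center. Pixels
#' whose source falls outside the input are `NA` and are excluded from
#' registration metrics.
#'
#' @param frame A [temperature_frame()] or numeric matrix.
#' @param tf A [similarity_transform()].
#' @return A numeric matrix with `NA` for invalid pixels.
#' @export
warp_frame <- function(frame, tf) {
  img <- if (inherits(frame, "temperature_frame")) frame$temp_c else frame
  center <- (dim(img)[2:1] + 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  gx <- rep(seq_len(nc), each = nr)
  gy <- rep(seq_len(nr), times = nc)
  # source position: p_src solves M(p_src) = p_out, with M about `center`
  th <- tf$rotation_deg * pi / 180
  Rinv <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  p <- cbind(gx, gy)
  q <- sweep(p, 2, center + c(tf$tx, tf$ty))
  src <- sweep((q %*% t(Rinv)) / tf$scale, 2, center, `+`)
  matrix(bilinear_sample(img, src[, 1], src[, 2]), nr, nc)
}

# Block-mean downsampling by integer factor (trailing partial blocks
# dropped).
downsample_mean <- function(img, f) {
  if (f == 1L) return(img)
  nr <- (nrow(img) %/% f) * f
  nc <- (ncol(img) %/% f) * f
  img <- img[seq_len(nr), seq_len(nc)]
  a <- array(img, c(f, nr %/% f, f, nc %/% f))
  apply(a, c(2, 4), mean)
}

#' Register a frame to the baseline frame
#'
#' Estimates the similarity transform (translation, rotation, scale)
#' minimizing the mean-squared temperature difference between the warped
#' frame and the baseline, by multi-resolution Nelder-Mead optimization over
#' `(tx, ty, rotation, log scale)`.
#'
#' @param frame,baseline [temperature_frame()] objects or matrices of equal
#'   dimensions.
#' @param levels Integer downsampling factors, coarse to fine.
#' @param maxit Nelder-Mead iteration cap per level.
#'
#' @return A [similarity_transform()] with attribute `residual` (final MSE).
#' @export
register_to_baseline <- function(frame, baseline, levels = c(4L, 2L, 1L),
                                 maxit = 400L) {
  a <- if (inherits(frame, "temperature_frame")) frame$temp_c else frame
  b <- if (inherits(baseline, "temperature_frame")) baseline$temp_c else
    baseline
  if (!all(dim(a) == dim(b))) stop("frames must share dimensions")
  par <- c(0, 0, 0, 0) # tx, ty, theta_deg, log(scale) in full-res units
  level_cost <- function(af, bf, f) {
    force(af); force(bf); force(f)
    function(p) {
      tf <- similarity_transform(p[1] / f, p[2] / f, p[3], exp(p[4]))
      w <- warp_frame(af, tf)
      ok <- !is.na(w) & !is.na(bf)
      if (sum(ok) < 0.25 * length(w)) return(1e6)
      mean((w[ok] - bf[ok])^2)
    }
  }
  first <- TRUE
  for (f in levels) {
    af <- downsample_mean(a, f)
    bf <- downsample_mean(b, f)
    cost <- level_cost(af, bf, f)
    if (first) {
      # coarse translation sweep to escape the wrong basin
      grid <- expand.grid(tx = seq(-12, 12, by = 3),
                          ty = seq(-12, 12, by = 3))
      vals <- apply(grid, 1L, function(g) cost(c(g[1], g[2], 0, 0)))
      best <- which.min(vals)
      par[1:2] <- as.numeric(grid[best, ])
      first <- FALSE
    }
    opt <- stats::optim(par, cost, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10,
                                       parscale = c(2, 2, 1, 0.02)))
    # one perturbed restart guards against premature simplex collapse
    opt2 <- stats::optim(opt$par + c(1, -1, 0.5, 0.005), cost,
                         method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = 1e-10,
                                        parscale = c(2, 2, 1, 0.02)))
    opt <- if (opt2$value < opt$value) opt2 else opt
    par <- opt$par
  }
  if (!is.finite(opt$value) || opt$value >= 1e6) {
    stop("registration failed to converge; residual = ", opt$value)
  }
  tf <- similarity_transform(par[1], par[2], par[3], exp(par[4]))
  attr(tf, "residual") <- opt$value
  tf
}

#' Pixelwise temporal averaging
#'
#' Sliding mean of `window` consecutive frames; each output frame carries
#' the center frame's timestamp. Supports the 3-frame averaging used for
#' the difference video and for the end-of-period composite.
#'
#' @param frames List of [temperature_frame()] objects of equal dimensions.
#' @param window Number of consecutive frames per average (default 3).
#' @return List of `length(frames) - window + 1` [temperature_frame()]s.
#' @export
temporal_average <- function(frames, window = 3L) {
  n <- length(frames)
  if (n < window) stop("need at least ", window, " frames")
  dims <- dim(frames[[1]]$temp_c)
  out <- vector("list", n - window + 1L)
  for (i in seq_along(out)) {
    acc <- matrix(0, dims[1], dims[2])
    for (j in seq_len(window)) {
      fj <- frames[[i + j - 1L]]
      if (!all(dim(fj$temp_c) == dims)) stop("frames must share dimensions")
      acc <- acc + fj$temp_c
    }
    center <- frames[[i + (window - 1L) %/% 2L]]
    out[[i]] <- temperature_frame(acc / window, center$timestamp_s,
                                  paste0(center$frame_id, "_avg"))
  }
  out
}

#' Mean composite of the last frames of a period
#'
#' Pixelwise mean of the last `n` frames (default 3) — the thermal image
#' used for comparison against the PET-derived projection.
#'
#' @param frames List of [temperature_frame()] objects (one period,
#'   time-ordered).
#' @param n Number of trailing frames to average.
#' @return A single [temperature_frame()].
#' @export
mean_composite <- function(frames, n = 3L) {
  if (length(frames) < n) stop("need at least ", n, " frames")
  temporal_average(frames[(length(frames) - n + 1L):length(frames)],
                   window = n)[[1L]]
}

#' Render a relative-change (difference) frame
#'
#' Maps the temperature change relative to baseline through a fixed
#' piecewise-linear colormap: unchanged pixels are white; warming runs
#' white -> red (at `+range_c/2`) -> yellow (at `+range_c`); cooling runs
#' white -> blue (at `-range_c/2`) -> black (at `-range_c`). Changes beyond
#' the range clamp to the end colors.
#'
#' @param frame,baseline [temperature_frame()] objects or matrices
#'   (registered, equal dimensions).
#' @param range_c Full-scale temperature change (default 2 degrees Celsius).
#' @return An `nrow x ncol x 3` array of RGB values in \[0, 1\].
#' @export
render_difference_frame <- function(frame, baseline, range_c = 2) {
  a <- if (inherits(frame, "temperature_frame")) frame$temp_c else frame
  b <- if (inherits(baseline, "temperature_frame")) baseline$temp_c else
    baseline
  if (!all(dim(a) == dim(b))) stop("frames must share dimensions")
  d <- pmin(pmax(a - b, -range_c), range_c)
  bp <- c(-range_c, -range_c / 2, 0, range_c / 2, range_c)
  cols <- rbind(c(0, 0, 0),   # black
                c(0, 0, 1),   # blue
                c(1, 1, 1),   # white
                c(1, 0, 0),   # red
                c(1, 1, 0))   # yellow
  out <- array(0, c(nrow(a), ncol(a), 3))
  for (ch in 1:3) {
    out[, , ch] <- matrix(stats::approx(bp, cols[, ch], xout = as.vector(d),
                                        rule = 2)$y, nrow(a), ncol(a))
  }
  out
}

#' Write an RGB array as an 8-bit PNG
#'
#' @param rgb `h x w x 3` array in \[0, 1\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rgb <- function(rgb, path) {
  png::writePNG(rgb, path)
  invisible(path)
}
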