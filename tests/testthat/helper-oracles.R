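# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized implementations.

# Ray-casting point-in-polygon (even-odd rule, boundary not handled -- use
# off-lattice vertices when comparing masks).
pip_oracle <- function(x, y, px, py) {
  n <- length(px)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if (((py[i] > y) != (py[j] > y)) &&
        (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

rasterize_oracle <- function(px, py, dims) {
  mask <- matrix(FALSE, dims[1], dims[2])
  for (r in seq_len(dims[1])) {
    for (c in seq_len(dims[2])) {
      mask[r, c] <- pip_oracle(c, r, px, py)
    }
  }
  mask
}

# Triple-loop maximum intensity projection.
mip_oracle <- function(vol) {
  d <- dim(vol)
  out <- matrix(-Inf, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      for (k in seq_len(d[3])) {
        if (vol[i, j, k] > out[i, j]) out[i, j] <- vol[i, j, k]
      }
    }
  }
  out
}

# Sort-and-index hotspot oracle: median of the k = ceiling(frac * n)
# largest values (tie composition does not change the median).
hotspot_oracle <- function(values, frac = 0.1) {
  k <- ceiling(frac * length(values))
  stats::median(sort(values, decreasing = TRUE)[seq_len(k)])
}

quad_design_oracle <- function(p) {
  cbind(1, p[, 1], p[, 2], p[, 1]^2, p[, 1] * p[, 2], p[, 2]^2)
}

# A tiny fast phantom spec for pipeline-level unit tests.
small_spec <- function(seed = 1L, ...) {
  phantom_spec(acclim_s = 30, initial_s = 180, final_s = 30, seed = seed,
               ...)
}
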