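make_poly_pairs <- function(coef, n = 70, seed = 1,
                            xr = c(10, 110), yr = c(10, 90)) {
  set.seed(seed)
  mov <- cbind(runif(n, xr[1], xr[2]), runif(n, yr[1], yr[2]))
  control_point_pairs(mov, quad_design_oracle(mov) %*% coef)
}

identity_coef <- rbind(c(0, 0), c(1, 0), c(0, 1),
                       c(0, 0), c(0, 0), c(0, 0))

test_that("the weight taper is a smooth monotone bump on [0, 1]", {
  expect_equal(lwm_weight(0), 1)
  expect_equal(lwm_weight(1), 0)
  expect_equal(lwm_weight(c(-0.5, 1.5)), c(0, 0))
  t <- seq(0, 1, by = 0.01)
  w <- lwm_weight(t)
  expect_true(all(diff(w) <= 0))
  # C1 at both ends: derivative -6t + 6t^2 vanishes at 0 and 1
  h <- 1e-6
  expect_lt(abs((lwm_weight(h) - lwm_weight(0)) / h), 1e-4)
  expect_lt(abs((lwm_weight(1) - lwm_weight(1 - h)) / h), 1e-4)
})

test_that("identity and affine control points reproduce their map exactly", {
  pairs <- make_poly_pairs(identity_coef)
  tfm <- fit_lwm(pairs)
  pts <- cbind(runif(200, 15, 105), runif(200, 15, 85))
  expect_equal(apply_lwm(tfm, pts), pts, tolerance = 1e-9,
               ignore_attr = TRUE)

  affine <- rbind(c(5, -3), c(1.02, 0.05), c(-0.04, 0.97),
                  c(0, 0), c(0, 0), c(0, 0))
  pairs2 <- make_poly_pairs(affine, seed = 2)
  tfm2 <- fit_lwm(pairs2)
  expect_equal(apply_lwm(tfm2, pts), quad_design_oracle(pts) %*% affine,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("global degree-2 warps are reproduced everywhere covered", {
  set.seed(30)
  for (i in 1:3) {
    coef <- identity_coef + matrix(rnorm(12, 0, 2e-3), 6, 2)
    coef[1, ] <- coef[1, ] + rnorm(2, 0, 3)
    pairs <- make_poly_pairs(coef, seed = 30 + i)
    tfm <- fit_lwm(pairs)
    pts <- cbind(runif(500, 15, 105), runif(500, 15, 85))
    expect_equal(apply_lwm(tfm, pts), quad_design_oracle(pts) %*% coef,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("each control point maps to its paired location", {
  coef <- identity_coef + rbind(c(1, -2), c(0.02, -0.01), c(0.03, -0.02),
                                c(1e-4, 1e-4), c(1e-4, 1e-4),
                                c(1e-4, 1e-4))
  pairs <- make_poly_pairs(coef, seed = 7)
  tfm <- fit_lwm(pairs)
  mapped <- apply_lwm(tfm, pairs$moving)
  expect_equal(mapped, pairs$fixed, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("underdetermined or degenerate fits are rejected", {
  mov5 <- cbind(runif(5, 0, 10), runif(5, 0, 10))
  expect_error(control_point_pairs(mov5, mov5), "at least 6")
  pairs <- make_poly_pairs(identity_coef, n = 10)
  expect_error(fit_lwm(pairs, n_neighbors = 12), "exceeds")
  expect_error(fit_lwm(pairs, n_neighbors = 5), "at least 6")
  # all points on one line: quadratic design is rank deficient
  x <- seq(1, 20, length.out = 10)
  line <- cbind(x, 2 * x + 1)
  expect_error(fit_lwm(control_point_pairs(line, line), n_neighbors = 10),
               "rank-deficient")
  expect_error(control_point_pairs(cbind(c(1, 1, 2, 3, 4, 5), 1:6),
                                   cbind(rep(1, 6), rep(2, 6))),
               "duplicated")
})

test_that("held-out error under jitter stays below the jitter scale", {
  set.seed(44)
  coef <- identity_coef + matrix(rnorm(12, 0, 1e-3), 6, 2)
  mov <- cbind(runif(90, 10, 110), runif(90, 10, 90))
  fixed <- quad_design_oracle(mov) %*% coef +
    matrix(rnorm(180, 0, 0.5), 90, 2)
  tfm <- fit_lwm(control_point_pairs(mov[1:70, ], fixed[1:70, ]))
  held <- mov[71:90, ]
  pred <- apply_lwm(tfm, held)
  truth <- quad_design_oracle(held) %*% coef
  rms <- sqrt(mean(rowSums((pred - truth)^2)))
  expect_lt(rms, 1)
})

test_that("forward and inverse fits compose to near-identity", {
  # smooth warp: few-px translation, mild shear, gentle quadratic terms
  coef <- identity_coef + rbind(c(2, -1),       # constant
                                c(0.01, 0.005), # x
                                c(-0.008, 0.02), # y
                                c(8e-5, -5e-5), # x^2
                                c(-6e-5, 7e-5), # xy
                                c(5e-5, 9e-5))  # y^2
  pairs <- make_poly_pairs(coef, seed = 12)
  fwd <- fit_lwm(pairs, direction = "moving_to_fixed")
  inv <- fit_lwm(pairs, direction = "fixed_to_moving")
  grid <- as.matrix(expand.grid(x = seq(25, 95, by = 5),
                                y = seq(25, 75, by = 5)))
  round_trip <- apply_lwm(inv, apply_lwm(fwd, grid))
  rms <- sqrt(mean(rowSums((round_trip - grid)^2)))
  expect_lt(rms, 0.5)
})

test_that("image warping honours interpolation and validity rules", {
  set.seed(6)
  img <- matrix(rnorm(30 * 40), 30, 40)
  idp <- make_poly_pairs(identity_coef, xr = c(2, 39), yr = c(2, 29))
  tid <- fit_lwm(idp, direction = "fixed_to_moving")
  wid <- warp_image(img, tid)
  expect_equal(wid, img, tolerance = 1e-6)

  # pure translation: output shifted, border invalid
  shift_coef <- identity_coef; shift_coef[1, ] <- c(5, 0)
  sp <- make_poly_pairs(shift_coef, xr = c(2, 39), yr = c(2, 29), seed = 3)
  # to sample output p from input p - (5, 0), fit the fixed -> moving map
  tinv <- fit_lwm(sp, direction = "fixed_to_moving")
  ws <- warp_image(img, tinv)
  expect_equal(ws[, 6:40], img[, 1:35], tolerance = 1e-6)
  expect_true(all(is.na(ws[, 1:5])))

  # binary masks stay binary under nearest-neighbour warping
  mask <- matrix(FALSE, 30, 40); mask[10:15, 18:25] <- TRUE
  wm <- warp_image(mask, tid)
  expect_type(wm, "logical")
  expect_gt(sum(wm & mask) / sum(mask), 0.95)
})

test_that("polygon warping densifies edges to follow the curved map", {
  sq <- data.frame(x = c(20, 90, 90, 20), y = c(20, 20, 80, 80))
  idp <- make_poly_pairs(identity_coef)
  tid <- fit_lwm(idp)
  wsq <- warp_polygon(tid, sq)
  expect_true(all(c(20, 90) %in% round(wsq$x)))

  affine <- rbind(c(3, 1), c(1.1, 0.02), c(-0.03, 0.95),
                  c(0, 0), c(0, 0), c(0, 0))
  ap <- make_poly_pairs(affine, seed = 5)
  ta <- fit_lwm(ap)
  wa <- warp_polygon(ta, sq)
  want <- quad_design_oracle(as.matrix(sq)) %*% affine
  # original vertices must appear among the densified mapped vertices
  for (k in 1:4) {
    d <- sqrt((wa$x - want[k, 1])^2 + (wa$y - want[k, 2])^2)
    expect_lt(min(d), 1e-6)
  }

  # curved map: densified rasterization close to a high-density truth
  coef <- identity_coef
  coef[4:6, 1] <- c(2e-3, -1e-3, 1e-3)
  coef[4:6, 2] <- c(-1e-3, 1e-3, 2e-3)
  cp <- make_poly_pairs(coef, seed = 8)
  tc <- fit_lwm(cp)
  wc <- warp_polygon(tc, sq, max_seg_px = 1)
  dense_src <- do.call(rbind, lapply(1:4, function(i) {
    j <- if (i == 4) 1 else i + 1
    f <- seq(0, 1, length.out = 400)[-400]
    cbind(sq$x[i] + f * (sq$x[j] - sq$x[i]),
          sq$y[i] + f * (sq$y[j] - sq$y[i]))
  }))
  dense_mapped <- quad_design_oracle(dense_src) %*% coef
  dims <- c(120L, 140L)
  area_got <- sum(thermobat:::rasterize_polygon(wc$x, wc$y, dims))
  area_true <- sum(thermobat:::rasterize_polygon(dense_mapped[, 1],
                                                 dense_mapped[, 2], dims))
  expect_lt(abs(area_got - area_true) / area_true, 0.02)
})

test_that("transforms serialize to JSON and back without changing output", {
  coef <- identity_coef + matrix(rnorm(12, 0, 1e-3), 6, 2)
  pairs <- make_poly_pairs(coef, seed = 9)
  tfm <- fit_lwm(pairs)
  path <- withr::local_tempfile(fileext = ".json")
  write_lwm(tfm, path)
  back <- read_lwm(path)
  pts <- cbind(runif(50, 20, 100), runif(50, 20, 80))
  expect_equal(apply_lwm(back, pts), apply_lwm(tfm, pts),
               tolerance = 1e-12)
  # CSV round trip
  csv <- withr::local_tempfile(fileext = ".csv")
  write_control_points(pairs, csv)
  pairs2 <- read_control_points(csv)
  expect_equal(pairs2$moving, pairs$moving)
  expect_equal(pairs2$fixed, pairs$fixed)
})
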