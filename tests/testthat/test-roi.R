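test_that("a vertical step edge is traced exactly at the step column", {
  # skin 34 degC at x <= 40, background 22 degC beyond: right-side border
  ph <- generate_edge_phantom(edge_x = 40, slope = 0, y0 = 10, y1 = 40,
                              side = "right")
  ct <- detect_neck_contour(ph$frame, ph$apices, "right")
  expect_equal(ct$y, 10:40)
  expect_true(all(ct$x == 40))
})

test_that("a blurred noisy slanted edge is recovered within 1 px RMS", {
  for (seed in 1:3) {
    ph <- generate_edge_phantom(seed = seed, edge_x = 38, slope = 0.3,
                                blur_sigma_px = 1, noise_sd_c = 0.1,
                                side = "left")
    ct <- detect_neck_contour(ph$frame, ph$apices, "left")
    rms <- sqrt(mean((ct$x - ph$true_edge$x)^2))
    expect_lt(rms, 1)
  }
})

test_that("a uniform frame raises an insufficient-contrast error", {
  ph <- generate_edge_phantom(edge_x = 40, side = "left")
  flat <- temperature_frame(matrix(30, 60, 80), 0)
  expect_error(detect_neck_contour(flat, ph$apices, "left"),
               "insufficient contrast")
})

test_that("contour detection is invariant to adding a constant", {
  ph <- generate_edge_phantom(seed = 4, edge_x = 38, slope = 0.3,
                              blur_sigma_px = 1, noise_sd_c = 0.1)
  ct1 <- detect_neck_contour(ph$frame, ph$apices, "left")
  shifted <- temperature_frame(ph$frame$temp_c + 7, 0)
  ct2 <- detect_neck_contour(shifted, ph$apices, "left")
  expect_identical(ct1$x, ct2$x)
})

test_that("ROI rasterization matches a brute-force point-in-polygon oracle", {
  dims <- c(70L, 70L)
  # right-triangle ROI with legs 30 and 40 px, off-lattice vertices so the
  # oracle and the implementation agree on boundary handling
  apices <- apex_set(superolateral_left = c(20.5, 10.5),
                     superolateral_right = c(60.25, 10.5),
                     acromioclavicular_left = c(18.5, 40.2),
                     acromioclavicular_right = c(60.25, 50.5),
                     sternal = c(30.5, 50.5), dims = dims)
  contour <- structure(
    data.frame(x = c(60.25, 60.25), y = c(10.5, 50.5)),
    side = "right", class = c("neck_contour", "data.frame"))
  roi <- build_roi_mask(apices, contour, dims)
  oracle <- rasterize_oracle(roi$polygon$x, roi$polygon$y, dims)
  expect_identical(roi$mask, oracle)
  # triangle area: legs 40 (vertical) and 29.75 (horizontal)
  true_area <- 0.5 * 40 * 29.75
  expect_lt(abs(sum(roi$mask) - true_area) / true_area, 0.05)
})

test_that("collinear apices give an empty-mask error", {
  dims <- c(60L, 60L)
  # contour and both closing lines collapse onto (essentially) x = 30
  apices <- apex_set(superolateral_left = c(10, 10),
                     superolateral_right = c(30, 10),
                     acromioclavicular_left = c(10, 40),
                     acromioclavicular_right = c(30, 40),
                     sternal = c(29.99, 55), dims = dims)
  contour <- structure(data.frame(x = c(30, 30), y = c(10, 40)),
                       side = "left",
                       class = c("neck_contour", "data.frame"))
  apices$superolateral_left <- c(30, 10)
  apices$acromioclavicular_left <- c(30, 40)
  expect_error(build_roi_mask(apices, contour, dims), "degenerate|collinear")
})

test_that("left and right masks mirror for a mirror-symmetric apex set", {
  # odd frame width with the body midline on the central column makes the
  # phantom exactly mirror-symmetric
  spec <- phantom_spec(dims = c(96L, 129L), cx = 65, noise_sd_c = 0)
  th <- generate_thermal_sequence(spec, "vehicle")
  frame <- th$frames[[1]]
  dims <- dim(frame$temp_c)
  masks <- lapply(c("left", "right"), function(side) {
    ct <- detect_neck_contour(frame, th$apices, side, band_halfwidth = 8)
    build_roi_mask(th$apices, ct, dims)$mask
  })
  mirrored <- masks[[2]][, rev(seq_len(dims[2]))]
  jaccard <- sum(masks[[1]] & mirrored) / sum(masks[[1]] | mirrored)
  expect_gt(jaccard, 0.98)
})

test_that("reference circle follows the 81-pixel inclusive-disk rule", {
  dims <- c(100L, 100L)
  apices <- apex_set(c(20, 10), c(80, 10), c(15, 40), c(85, 40),
                     sternal = c(50, 50), dims = dims)
  ref <- build_reference_region(apices, dims, offset_px = 10)
  expect_equal(sum(ref$mask), 81L) # integer offsets with dx^2+dy^2 <= 25
  expect_equal(ref$center, c(50, 60))
  ref0 <- build_reference_region(apices, dims, offset_px = 0)
  expect_equal(ref0$center, c(50, 50))
  tall <- apex_set(c(20, 10), c(80, 10), c(15, 40), c(85, 40),
                   sternal = c(50, 97), dims = dims)
  expect_error(build_reference_region(tall, dims), "fit")
})

test_that("ROI and reference region are disjoint on the default phantom", {
  spec <- phantom_spec(noise_sd_c = 0)
  th <- generate_thermal_sequence(spec, "vehicle")
  dims <- dim(th$frames[[1]]$temp_c)
  ref <- build_reference_region(th$apices, dims)
  for (side in c("left", "right")) {
    ct <- detect_neck_contour(th$frames[[1]], th$apices, side,
                              band_halfwidth = 8)
    roi <- build_roi_mask(th$apices, ct, dims)
    expect_false(any(roi$mask & ref$mask))
  }
})

test_that("apex annotations round-trip through CSV", {
  dims <- c(100L, 120L)
  apices <- apex_set(c(20, 10), c(80, 10), c(15, 40), c(85, 40),
                     c(50, 50), dims = dims)
  path <- withr::local_tempfile(fileext = ".csv")
  write_apices(apices, path, frame_id = "f1")
  back <- read_apices(path, "f1", dims)
  expect_equal(back$sternal, apices$sternal)
  expect_equal(back$acromioclavicular_right, apices$acromioclavicular_right)
})

test_that("apex sets violating anatomical ordering are rejected", {
  dims <- c(100L, 100L)
  expect_error(apex_set(c(20, 10), c(80, 10), c(15, 40), c(85, 40),
                        sternal = c(5, 50), dims = dims), "between")
  expect_error(apex_set(c(20, 45), c(80, 10), c(15, 40), c(85, 40),
                        sternal = c(50, 50), dims = dims), "above")
  expect_error(apex_set(c(20, 10), c(80, 10), c(15, 40), c(85, 400),
                        sternal = c(50, 50), dims = dims), "outside")
})
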