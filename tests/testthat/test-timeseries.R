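test_that("hotspot statistic matches the sort-and-index oracle", {
  m <- matrix(1:100, 10, 10)
  all_roi <- matrix(TRUE, 10, 10)
  expect_equal(hotspot_statistic(m, all_roi), 95.5)

  # constant field
  expect_equal(hotspot_statistic(matrix(35, 7, 7), matrix(TRUE, 7, 7)), 35)

  # N = 95: k = ceiling(9.5) = 10
  set.seed(3)
  m2 <- matrix(rnorm(100), 10, 10)
  roi95 <- matrix(c(rep(TRUE, 95), rep(FALSE, 5)), 10, 10)
  expect_equal(hotspot_statistic(m2, roi95), hotspot_oracle(m2[roi95]))

  # random ROIs including heavy ties
  for (i in 1:25) {
    set.seed(i)
    n <- sample(5:200, 1)
    vals <- if (i %% 3 == 0) {
      sample(round(rnorm(4), 1), n, replace = TRUE) # tie-heavy
    } else {
      rnorm(n)
    }
    mask <- matrix(FALSE, 20, 20)
    mask[sample(400, n)] <- TRUE
    img <- matrix(0, 20, 20)
    img[mask] <- vals
    expect_equal(hotspot_statistic(img, mask), hotspot_oracle(img[mask]))
  }
  expect_error(hotspot_statistic(m, matrix(FALSE, 10, 10)), "empty")
})

test_that("hotspot is at least the ROI median and equals the max for k = 1", {
  set.seed(8)
  for (i in 1:10) {
    img <- matrix(rnorm(144), 12, 12)
    mask <- matrix(FALSE, 12, 12)
    mask[sample(144, sample(3:60, 1))] <- TRUE
    expect_gte(hotspot_statistic(img, mask), stats::median(img[mask]))
  }
  small <- matrix(FALSE, 12, 12); small[1:7] <- TRUE # k = 1
  img <- matrix(rnorm(144), 12, 12)
  expect_equal(hotspot_statistic(img, small), max(img[small]))
})

test_that("hotspot mask selects exactly k pixels, ties in scan order", {
  img <- matrix(5, 6, 6)
  mask <- matrix(TRUE, 6, 6)
  hm <- hotspot_mask(img, mask) # k = 4, all tied
  expect_equal(sum(hm), 4L)
  # raster-scan order: first 4 pixels of row 1
  expect_true(all(hm[1, 1:4]))
})

test_that("reference statistic is the mean, with a median option", {
  img <- matrix(c(rep(32, 8), rep(34, 8)), 4, 4)
  mask <- matrix(TRUE, 4, 4)
  expect_equal(reference_statistic(img, mask), 33)
  expect_equal(reference_statistic(matrix(33, 3, 3), matrix(TRUE, 3, 3)), 33)
  set.seed(2)
  img2 <- matrix(rnorm(64, 33), 8, 8)
  mask2 <- matrix(FALSE, 8, 8); mask2[sample(64, 20)] <- TRUE
  expect_equal(reference_statistic(img2, mask2),
               sum(img2[mask2]) / 20, tolerance = 1e-12)
  expect_equal(reference_statistic(img2, mask2, stat = "median"),
               stats::median(img2[mask2]))
  expect_error(reference_statistic(img2, matrix(FALSE, 8, 8)), "empty")
})

test_that("moving average uses valid mode with centered timestamps", {
  s <- temperature_series(seq(0, 25, by = 5), c(1, 2, 3, 4, 5, 6))
  sm <- smooth_series(s, 5)
  expect_equal(sm$value_c, c(3, 4))
  expect_equal(sm$timestamp_s, c(10, 15))

  const <- temperature_series(1:10, rep(7, 10))
  smc <- smooth_series(const, 5)
  expect_equal(smc$value_c, rep(7, 6))

  ramp <- temperature_series(1:20, 2 * (1:20) + 1)
  smr <- smooth_series(ramp, 5)
  expect_equal(smr$value_c, 2 * (3:18) + 1) # linear input is preserved

  expect_error(smooth_series(temperature_series(1:3, 1:3), 5), "shorter")
})

test_that("moving average stays within the window range", {
  set.seed(5)
  s <- temperature_series(1:50, rnorm(50))
  sm <- smooth_series(s, 5)
  for (i in seq_len(nrow(sm))) {
    win <- s$value_c[i:(i + 4)]
    expect_lte(sm$value_c[i], max(win) + 1e-12)
    expect_gte(sm$value_c[i], min(win) - 1e-12)
  }
})

test_that("relative series subtracts per frame and checks timestamps", {
  a <- temperature_series(1:10, rnorm(10, 35))
  b <- temperature_series(1:10, a$value_c - 1.9)
  rel <- relative_series(a, b)
  expect_equal(rel$value_c, rep(1.9, 10))
  expect_equal(attr(rel, "kind"), "relative")
  mismatched <- temperature_series(2:11, rnorm(10))
  expect_error(relative_series(a, mismatched), "timestamps")
})

test_that("outcomes use half-open windows anchored at onset", {
  s <- temperature_series(seq(0, 600, by = 5), rep(1.5, 121))
  out <- compute_outcomes(s, onset_s = 0)
  expect_equal(out$delta, 0)
  expect_equal(out$base, 1.5)

  # a lone maximum exactly at onset + 600 s must be excluded
  vals <- rep(0, 121); vals[121] <- 9 # t = 600
  s2 <- temperature_series(seq(0, 600, by = 5), vals)
  out2 <- compute_outcomes(s2, onset_s = 0, peak_window_s = 600)
  expect_equal(out2$peak, 0)
  out_all <- compute_outcomes(s2, onset_s = 0, peak_window_s = Inf)
  expect_equal(out_all$peak, 9)

  expect_error(compute_outcomes(s, onset_s = 1e5), "span")
  expect_identical(out$delta, out$peak - out$base)
})

test_that("constant shifts move absolute outcomes and not relative ones", {
  spec <- small_spec(seed = 2)
  th <- generate_thermal_sequence(spec, "cold")
  irt1 <- analyze_thermal_session(th$frames, th$apices, th$periods,
                                  onset_s = spec$onset_s,
                                  band_halfwidth = 8)
  shifted_frames <- lapply(th$frames, function(f) {
    temperature_frame(f$temp_c + 0.7, f$timestamp_s, f$frame_id)
  })
  irt2 <- analyze_thermal_session(shifted_frames, th$apices, th$periods,
                                  onset_s = spec$onset_s,
                                  band_halfwidth = 8)
  o1 <- irt1$outcomes; o2 <- irt2$outcomes
  abs1 <- o1[o1$kind == "absolute", ]; abs2 <- o2[o2$kind == "absolute", ]
  rel1 <- o1[o1$kind == "relative", ]; rel2 <- o2[o2$kind == "relative", ]
  expect_equal(abs2$base, abs1$base + 0.7, tolerance = 1e-10)
  expect_equal(abs2$peak_initial, abs1$peak_initial + 0.7, tolerance = 1e-10)
  expect_equal(rel2$base, rel1$base, tolerance = 1e-10)
  expect_equal(rel2$delta10, rel1$delta10, tolerance = 1e-10)
})

test_that("saturating-rise phantoms recover the analytic delta", {
  for (seed in 1:3) {
    spec <- phantom_spec(seed = seed, delta_t_max_c = 0.3, tau_s = 120)
    th <- generate_thermal_sequence(spec, "cold")
    irt <- analyze_thermal_session(th$frames, th$apices, th$periods,
                                   onset_s = spec$onset_s,
                                   band_halfwidth = 8)
    o <- irt$outcomes
    got <- o$delta10[o$kind == "relative" & o$side == "right"]
    expect_lt(abs(got - th$truth$outcomes_true$delta10), 0.05)
  }
})
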