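# Depth profiling: interface detection, centre-band extraction, depth
# normalization, and zone statistics.

test_that("interfaces are the first/last foreground pixel, thin columns excluded", {
  mask <- matrix(FALSE, 20, 6)
  mask[3:12, 2] <- TRUE          # 10-pixel column starting at row 3
  mask[5:7, 4] <- TRUE           # 3-pixel column: excluded
  iface <- detect_interfaces(mask)
  expect_equal(iface$surface[2], 3)
  expect_equal(iface$bone[2], 12)
  expect_true(is.na(iface$surface[4]))
  expect_error(detect_interfaces(matrix(FALSE, 4, 4)), "non-empty")
})

test_that("detected surface matches the phantom geometry", {
  spec <- phantom_spec()
  s <- generate_series(spec, sample_orientation_deg = 0, kind = "T2")
  iface <- detect_interfaces(s$mask)
  expect_true(all(iface$surface == spec$surface_row))
  expect_true(all(iface$bone == spec$surface_row + spec$cartilage_depth_px - 1))
})

test_that("the centre band has round(width/pixel) columns and averages converged pixels", {
  cfg <- profile_config()      # 1.75 mm at 62.5 um -> 28 columns
  expect_equal(round(cfg$column_width_mm / cfg$pixel_size_mm), 28)
  mask <- matrix(TRUE, 30, 40)
  map <- matrix(50, 30, 40)
  v <- extract_profile(map, mask, cfg)
  expect_equal(length(v), 30)
  expect_true(all(v == 50))
  # one non-converged pixel per row: mean over the remaining 27
  conv <- matrix(TRUE, 30, 40)
  band_mid <- 20
  map2 <- matrix(50, 30, 40); map2[, band_mid] <- 1e6
  conv[, band_mid] <- FALSE
  v2 <- extract_profile(map2, mask, cfg, converged = conv)
  expect_true(all(v2 == 50))
  # band wider than the image is rejected
  expect_error(extract_profile(map[, 1:10], mask[, 1:10], cfg), "width")
})

test_that("depth normalization preserves linearity, constants, and is idempotent", {
  ramp <- seq(0, 100, length.out = 48)
  p <- normalize_depth(ramp, 100)
  expect_equal(p$value, 100 * p$depth_fraction, tolerance = 1e-9)
  expect_equal(range(p$depth_fraction), c(0, 1))
  const <- normalize_depth(rep(26, 30), 100)
  expect_true(all(const$value == 26))
  twice <- normalize_depth(p$value, 100)
  expect_equal(twice$value, p$value, tolerance = 1e-12)
  expect_error(normalize_depth(5, 100), "at least 2")
})

test_that("depth normalization preserves monotonicity and extremum location", {
  x <- seq(0, 1, length.out = 64)
  mono <- normalize_depth(cumsum(runif(64)), 100)
  expect_true(all(diff(mono$value) >= -1e-12))
  bump <- sin(pi * pmin(x / 0.3, 1))^2 + 0.1 * x   # interior max near 0.15
  pb <- normalize_depth(bump, 100)
  true_pos <- x[which.max(bump)]
  est_pos <- pb$depth_fraction[which.max(pb$value)]
  expect_lt(abs(est_pos - true_pos), 1 / 100 + 1e-9)
})

test_that("zone statistics aggregate profile means with min/max over profiles", {
  zb <- c(sz = 0.08, tz = 0.20)
  const <- normalize_depth(rep(26, 40), 100)
  zs <- zone_stats(const, zb)
  expect_equal(zs$mean, rep(26, 3))
  expect_equal(zs$min, rep(26, 3))
  expect_equal(zs$max, rep(26, 3))
  two <- zone_stats(list(normalize_depth(rep(20, 40), 100),
                         normalize_depth(rep(40, 40), 100)), zb)
  expect_equal(two$mean, rep(30, 3))
  expect_equal(two$min, rep(20, 3))
  expect_equal(two$max, rep(40, 3))
  # phantom T2 at 0 deg: deep zone relaxes faster than the TZ
  spec <- phantom_spec(snr = Inf)
  d <- seq(0, 1, length.out = 100)
  prof <- depth_profile(d, true_time_ms(d, 0, "T2", spec))
  zsp <- zone_stats(prof, zb)
  expect_lt(zsp$mean[zsp$zone == "RZ"], zsp$mean[zsp$zone == "TZ"])
})

test_that("zone statistics are stable under profile refinement", {
  x <- seq(0, 1, length.out = 49)
  vals <- 30 + 50 * x + 20 * pmax(0, x - 0.3)      # piecewise linear
  coarse <- zone_stats(normalize_depth(vals, 60))
  fine <- zone_stats(normalize_depth(vals, 400))
  expect_equal(coarse$mean, fine$mean, tolerance = 0.005)
})
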