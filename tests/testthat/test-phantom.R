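# Synthetic phantom: fibre geometry, dipolar forward model, series and
# PLM map generation.

test_that("fibre angle profile spans 90 deg at the surface to 0 deg deep", {
  spec <- phantom_spec()
  expect_equal(fibre_angle_profile(0, spec), 90)
  expect_equal(fibre_angle_profile(1, spec), 0)
  expect_equal(fibre_angle_profile(0.5, spec), 0)       # inside RZ
  expect_equal(fibre_angle_profile(0.05, spec), 90)     # inside SZ
  d <- seq(0, 1, by = 0.01)
  expect_true(all(diff(fibre_angle_profile(d, spec)) <= 1e-12))  # monotone
  expect_error(fibre_angle_profile(-0.1, spec), "depth")
  expect_error(fibre_angle_profile(1.1, spec), "depth")
})

test_that("surface fibre angle is configurable below 90 degrees", {
  spec <- phantom_spec(surface_angle_deg = 75)
  expect_equal(fibre_angle_profile(0, spec), 75)
  expect_equal(fibre_angle_profile(1, spec), 0)
})

test_that("dipolar factor has the magic-angle null and known endpoints", {
  expect_equal(dipolar_factor(0), 2)
  expect_equal(dipolar_factor(90), -1)
  expect_lt(abs(dipolar_factor(54.74)), 1e-3)
  expect_equal(dipolar_factor(30), dipolar_factor(-30))      # symmetry
  expect_equal(dipolar_factor(10), dipolar_factor(190))      # period 180
})

test_that("dispersion-averaged squared dipolar factor matches Monte Carlo", {
  expect_equal(mean_sq_dipolar_factor(0, 0), 4)
  expect_equal(mean_sq_dipolar_factor(90, 0), 1)
  expect_lt(abs(mean_sq_dipolar_factor(54.7356, 0)), 1e-8)
  set.seed(42)
  for (mu in c(0, 30, 70)) {
    th <- rnorm(2e5, mu, 20)
    mc <- mean((3 * cos(th * pi / 180)^2 - 1)^2)
    expect_equal(mean_sq_dipolar_factor(mu, 20), mc, tolerance = 0.01)
  }
})

test_that("true rates follow the angular law and T1 is orientation-free", {
  spec <- spec_with_params("T2", R_iso = 10, c_dip = 40)
  # theta_eff = 0 deep at orientation 0: R = 10 + 40 * 4/4 = 50
  expect_equal(true_rate(1, 0, "T2", spec, dispersion = FALSE), 50)
  # magic-angle orientation nulls the dipolar term
  expect_equal(true_rate(1, 54.7356, "T2", spec, dispersion = FALSE), 10,
               tolerance = 1e-8)
  expect_equal(true_rate(c(0, 0.5, 1), 0, "T1", spec),
               true_rate(c(0, 0.5, 1), 90, "T1", spec))
  expect_error(true_rate(0.5, 0, "bogus", spec), "unknown")
})

test_that("deep-zone anisotropy calibration is exact on the forward model", {
  spec <- phantom_spec()
  rp <- spec$relax_params
  for (kind in c("T2", "CWT1rho500", "AdT1rhoHS1")) {
    rates <- vapply(seq(0, 90, 15), function(o)
      true_rate(0.999, o, kind, spec), numeric(1))
    expect_equal(michelson(rates),
                 rp$deep_anisotropy_target[rp$kind == kind],
                 tolerance = 1e-3)
  }
})

test_that("orientation sweep of the deep-zone time peaks nearest the magic angle", {
  spec <- phantom_spec(snr = Inf)
  grid <- seq(0, 90, 15)
  tt <- vapply(grid, function(o) true_time_ms(0.9, o, "T2", spec), numeric(1))
  expect_equal(grid[which.max(tt)], 60)   # grid point closest to 54.74
})

test_that("series generation is seed-deterministic and models are exact without noise", {
  spec <- phantom_spec(image_shape = c(32, 32), surface_row = 5,
                       cartilage_depth_px = 24, snr = 50, seed = 7)
  s1 <- generate_series(spec, sample_orientation_deg = 30, kind = "T2")
  s2 <- generate_series(spec, sample_orientation_deg = 30, kind = "T2")
  expect_identical(s1$data, s2$data)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))

  spec0 <- phantom_spec(image_shape = c(32, 32), surface_row = 5,
                        cartilage_depth_px = 24, snr = Inf)
  s0 <- generate_series(spec0, sample_orientation_deg = 30, kind = "T2")
  depth <- seq(0, 1, length.out = 24)
  R <- true_rate(depth, 30, "T2", spec0)
  t <- s0$schedule$prep_times_ms
  for (i in c(1, 12, 24))
    expect_equal(s0$data[, 4 + i, 16], spec0$s0 * exp(-t * R[i] / 1000),
                 tolerance = 1e-12)
  expect_true(all(s0$data[1, , ][s0$background_roi] == 0))
  expect_false(any(s0$mask & s0$background_roi))
})

test_that("measured SNR is within 20 percent of the nominal SNR", {
  spec <- phantom_spec(snr = 50, seed = 11)
  s <- generate_series(spec, sample_orientation_deg = 0, kind = "T2")
  expect_gt(sum(s$mask), 1000)
  expect_equal(measure_snr(s), 50, tolerance = 0.2)
})

test_that("T1 series at different orientations differ only by noise", {
  spec <- phantom_spec(snr = 40, seed = 3)
  s0 <- generate_series(spec, sample_orientation_deg = 0, kind = "T1")
  s90 <- generate_series(spec, sample_orientation_deg = 90, kind = "T1")
  set.seed(1)
  idx <- sample(which(s0$mask), 500)
  ks <- suppressWarnings(ks.test(s0$data[1, , ][idx], s90$data[1, , ][idx]))
  expect_gt(ks$p.value, 0.01)
})

test_that("RAFF series carries an exact inversion pair", {
  spec <- phantom_spec(image_shape = c(32, 32), surface_row = 5,
                       cartilage_depth_px = 24, snr = Inf)
  s <- generate_series(spec, sample_orientation_deg = 0, kind = "RAFF2")
  expect_false(is.null(s$data_inverted))
  t <- s$schedule$prep_times_ms
  R <- true_rate(1, 0, "RAFF2", spec)
  ss <- spec$raff_ss_frac * spec$s0
  E <- exp(-t * R / 1000)
  expect_equal(s$data[, 28, 16], ss + (spec$s0 - ss) * E, tolerance = 1e-12)
  expect_equal(s$data_inverted[, 28, 16],
               abs(ss + (-spec$raff_inv_eff * spec$s0 - ss) * E),
               tolerance = 1e-12)
})

test_that("PLM maps reproduce the fibre profile and its dispersion structure", {
  # zero dispersion: the map is exactly the depth profile in every column
  spec0 <- phantom_spec(dispersion_deg = c(sz = 0, tz = 0, rz = 0), snr = Inf)
  maps0 <- generate_plm_maps(spec0, scale = 1)
  rows <- 9:56
  depth <- seq(0, 1, length.out = 48)
  prof <- fibre_angle_profile(depth, spec0) %% 180
  for (j in c(1, 32, 64))
    expect_equal(maps0$orientation[rows, j], prof, tolerance = 1e-12)

  spec <- phantom_spec(seed = 2)
  maps <- generate_plm_maps(spec)
  expect_true(all(maps$orientation >= 0 & maps$orientation < 180))
  scale <- 4
  rz_rows <- ((9 - 1) * scale + 1) + round(0.5 * 48 * scale):round(0.9 * 48 * scale)
  tz_rows <- ((9 - 1) * scale + 1) + round(0.13 * 48 * scale):round(0.16 * 48 * scale)
  sd_rz <- circular_sd_180(maps$orientation[rz_rows, ])
  sd_tz <- circular_sd_180(maps$orientation[tz_rows, ])
  expect_lte(sd_rz, spec$dispersion_deg[["rz"]] + 1)
  expect_gt(sd_tz, sd_rz)   # dispersion maximal in the transitional zone
  # SZ vs RZ mean orientation difference ~ 90 degrees by construction
  sz_rows <- ((9 - 1) * scale + 1):((9 - 1) * scale + round(0.06 * 48 * scale))
  msz <- circular_mean_180(maps$orientation[sz_rows, ])
  mrz <- circular_mean_180(maps$orientation[rz_rows, ])
  d <- abs(msz - mrz); d <- min(d, 180 - d)
  expect_equal(d, 90, tolerance = 0.05)
})

test_that("phantom spec validates its geometry and noise level", {
  expect_error(phantom_spec(snr = 0), "snr")
  expect_error(phantom_spec(surface_row = 40), "fit inside")
  expect_error(phantom_spec(dispersion_deg = c(sz = 5, tz = 2, rz = 10)),
               "maximal in the transitional")
})
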