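# Michelson-contrast anisotropy across orientations.

test_that("Michelson contrast matches hand values and rejects bad input", {
  expect_equal(michelson(c(1, 2)), 1 / 3)
  expect_equal(michelson(c(5, 5, 5)), 0)
  v <- c(2, 7, 3)
  expect_equal(michelson(10 * v), michelson(v))      # scale invariance
  expect_equal(michelson(rev(v)), michelson(v))      # order invariance
  expect_error(michelson(c(1, -2)), "positive")
  expect_error(michelson(3), "at least 2")
})

test_that("anisotropy profiles combine orientations depth point by depth point", {
  d <- seq(0, 1, length.out = 5)
  p1 <- depth_profile(d, rep(100, 5))    # times: rate 10/s
  p2 <- depth_profile(d, rep(100 / 3, 5))  # rate 30/s
  ap <- mr_anisotropy_profile(list(p1, p2))
  expect_equal(ap$value, rep(0.5, 5))    # (30-10)/40
  # identical profiles (orientation-independent kind): A == 0
  ap0 <- mr_anisotropy_profile(list(p1, p1, p1))
  expect_equal(ap0$value, rep(0, 5))
  # missing depth points propagate
  p3 <- depth_profile(d, c(100, NA, 100, 100, 100))
  apm <- mr_anisotropy_profile(list(p2, p3))
  expect_equal(apm$value[2], NA_real_)
  expect_error(mr_anisotropy_profile(list(p1)), "at least 2")
})

test_that("two-orientation anisotropy is identical from times or rates", {
  d <- seq(0, 1, length.out = 7)
  ta <- 30 + 20 * d; tb <- 80 - 10 * d
  from_times <- mr_anisotropy_profile(
    list(depth_profile(d, ta), depth_profile(d, tb)), values_are = "time_ms")
  from_rates <- mr_anisotropy_profile(
    list(depth_profile(d, 1000 / ta), depth_profile(d, 1000 / tb)),
    values_are = "rate_per_s")
  expect_equal(from_times$value, from_rates$value, tolerance = 1e-12)
})

test_that("an orientation strictly inside the range leaves A unchanged", {
  d <- seq(0, 1, length.out = 4)
  lo <- depth_profile(d, rep(100, 4))      # 10/s
  hi <- depth_profile(d, rep(25, 4))       # 40/s
  mid <- depth_profile(d, rep(50, 4))      # 20/s, interior
  expect_equal(mr_anisotropy_profile(list(lo, hi))$value,
               mr_anisotropy_profile(list(lo, mid, hi))$value)
})

test_that("deep-zone anisotropy averages the 40-80 percent ROI on the x100 scale", {
  d <- seq(0, 1, length.out = 101)
  expect_equal(deep_zone_anisotropy(depth_profile(d, rep(0.8, 101))), 80)
  ramp <- depth_profile(d, d)              # A rises linearly 0 -> 1
  expect_equal(deep_zone_anisotropy(ramp), 60)   # midpoint of [0.4, 0.8]
  expect_error(deep_zone_anisotropy(ramp, c(0.8, 0.4)), "ordered")
})

test_that("deep-zone anisotropy ranking follows the configured dipolar strengths", {
  spec <- phantom_spec(snr = Inf)
  rp <- spec$relax_params
  kinds <- c("T2", "RAFF2", "CWT1rho500", "CWT1rho2000", "AdT1rhoHS1")
  d <- seq(0, 1, length.out = 100)
  deep <- vapply(kinds, function(kind) {
    profs <- lapply(seq(0, 90, 15), function(o)
      depth_profile(d, true_time_ms(d, o, kind, spec)))
    deep_zone_anisotropy(mr_anisotropy_profile(profs))
  }, numeric(1))
  ratio <- vapply(kinds, function(k)
    rp$c_dip_s[rp$kind == k] / rp$R_iso_s[rp$kind == k], numeric(1))
  expect_equal(order(-deep), order(-ratio))
})
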