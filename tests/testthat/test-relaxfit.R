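# Relaxation-model fitting: noise sigma estimation, the four signal
# models, and pixel-wise map fitting.

t_te <- c(10, 20, 40, 80, 100, 128)
t_sl <- c(0, 24, 48, 96, 192)
t_ti <- c(200, 500, 800, 1100, 1400, 3000)

test_that("background sigma estimator inverts the Rayleigh mean", {
  mk_series <- function(bg_values) {
    nr <- 20; nc <- 20
    bg <- matrix(FALSE, nr, nc); bg[1:10, ] <- TRUE
    data <- array(0, dim = c(1, nr, nc))
    data[1, , ][bg] <- bg_values
    structure(list(data = data, background_roi = bg,
                   mask = matrix(FALSE, nr, nc)),
              class = "image_series")
  }
  expect_equal(estimate_noise_sigma(mk_series(rep(0, 200))), 0)
  set.seed(8)
  draws <- 10 * sqrt(rnorm(200)^2 + rnorm(200)^2)   # Rayleigh, sigma = 10
  est <- estimate_noise_sigma(mk_series(draws))
  expect_equal(est, 10, tolerance = 0.05)
  small <- mk_series(rep(1, 200))
  small$background_roi[] <- FALSE
  expect_error(estimate_noise_sigma(small), "50 pixels")
})

test_that("noise-floor subtraction is exact and idempotent on clean data", {
  s <- 1000 * exp(-t_te / 50)
  expect_identical(noise_floor_subtract(s, 0), s)
  lifted <- sqrt(s^2 + 30^2)
  expect_equal(noise_floor_subtract(lifted, 30), s, tolerance = 1e-12)
})

test_that("monoexponential fit recovers exact and floor-lifted curves", {
  f <- fit_monoexp_noisefloor(t_te, 1000 * exp(-t_te / 50))
  expect_equal(f$T_ms, 50, tolerance = 1e-6)
  expect_equal(f$S0, 1000, tolerance = 1e-6)
  expect_true(f$converged)

  lifted <- sqrt((1000 * exp(-t_te / 50))^2 + 30^2)
  f2 <- fit_monoexp_noisefloor(t_te, lifted, sigma = 30)
  expect_equal(f2$T_ms, 50, tolerance = 1e-6)

  f3 <- fit_monoexp_noisefloor(t_te, rep(400, 6))
  expect_false(f3$converged)
  expect_error(fit_monoexp_noisefloor(c(-5, t_te[-1]), 1000 * exp(-t_te / 50)),
               "negative")
})

test_that("exponential-with-baseline fit recovers its parameters and nests the monoexp", {
  f <- fit_exp_baseline(t_sl, 800 * exp(-t_sl / 60) + 50)
  expect_equal(f$A, 800, tolerance = 1e-6)
  expect_equal(f$C, 50, tolerance = 1e-4)
  expect_equal(f$T_ms, 60, tolerance = 1e-6)

  s <- 900 * exp(-t_sl / 45)
  fb <- fit_exp_baseline(t_sl, s)
  fm <- fit_monoexp_noisefloor(t_sl, s, sigma = 0)
  expect_equal(fb$T_ms, fm$T_ms, tolerance = 1e-6)

  expect_false(fit_exp_baseline(t_sl, rep(100, 5))$converged)
})

test_that("magnitude inversion recovery is exact and scale invariant", {
  s <- 1000 * abs(1 - 2 * exp(-t_ti / 1400))
  f <- fit_inversion_recovery(t_ti, s)
  expect_equal(f$T1_ms, 1400, tolerance = 1e-6)
  expect_equal(f$S0, 1000, tolerance = 1e-6)
  expect_true(f$converged)
  for (k in c(0.01, 3.7)) {
    fk <- fit_inversion_recovery(t_ti, k * s)
    expect_equal(fk$T1_ms, f$T1_ms, tolerance = 1e-8)
  }
  # reduced inversion efficiency is recovered too
  s2 <- 500 * abs(1 - 2 * 0.85 * exp(-t_ti / 900))
  f2 <- fit_inversion_recovery(t_ti, s2)
  expect_equal(f2$T1_ms, 900, tolerance = 1e-5)
  expect_equal(f2$f, 0.85, tolerance = 1e-5)
  expect_false(fit_inversion_recovery(t_ti, rep(7, 6))$converged)
})

test_that("joint RAFF steady-state fit recovers shared SS and T", {
  np <- c(0, 2, 4, 6, 8); tt <- np * 9
  E <- exp(-tt / 70)
  sp <- 200 + (1000 - 200) * E
  si <- abs(200 + (-600 - 200) * E)
  f <- fit_raff_steadystate(np, sp, si)
  expect_equal(f$T_ms, 70, tolerance = 1e-6)
  expect_equal(f$SS, 200, tolerance = 1e-5)
  expect_equal(f$S0_plain, 1000, tolerance = 1e-5)
  expect_equal(f$S0_inv, -600, tolerance = 1e-4)
  expect_true(f$converged)
  expect_false(fit_raff_steadystate(np, rep(300, 5), rep(300, 5))$converged)
  expect_error(fit_raff_steadystate(np, sp, si[-1]), "share")
})

test_that("median fit bias is small at moderate SNR", {
  # 1000 Monte-Carlo Rician curves, T = 50 ms at SNR 30
  set.seed(21)
  n <- 1000
  sigma <- 1000 / 30
  Ts <- vapply(seq_len(n), function(i) {
    clean <- 1000 * exp(-t_te / 50)
    noisy <- sqrt((clean + rnorm(6, 0, sigma))^2 + rnorm(6, 0, sigma)^2)
    fit_monoexp_noisefloor(t_te, noisy, sigma = sigma)$T_ms
  }, numeric(1))
  expect_lt(abs(median(Ts - 50) / 50), 0.02)
})

test_that("map fitting honours masks, flags failures, and matches ground truth", {
  spec <- phantom_spec(image_shape = c(32, 32), surface_row = 5,
                       cartilage_depth_px = 24, snr = Inf)
  s <- generate_series(spec, sample_orientation_deg = 0, kind = "T2")
  sub <- matrix(FALSE, 32, 32); sub[, 10:20] <- TRUE
  m <- fit_map(s, mask = sub)
  expect_true(all(is.na(m$times[, 1])))            # outside mask: missing
  expect_true(all(is.na(m$converged[, 1])))
  depth <- seq(0, 1, length.out = 24)
  truth <- true_time_ms(depth, 0, "T2", spec)
  expect_equal(m$times[5:28, 15], truth, tolerance = 1e-4)
  expect_equal(m$rates[5:28, 15] * m$times[5:28, 15], rep(1000, 24),
               tolerance = 1e-9)                   # rate-time reciprocity
  expect_error(fit_map(s, fit_model_spec("raff_steadystate")), "inversion")
})
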