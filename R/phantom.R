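# Synthetic magic-angle cartilage phantom: multi-orientation relaxometry
# series and matched polarized-light-microscopy (PLM) maps with known
# ground truth.

.KINDS <- c("T1", "T2", "T2star",
            "CWT1rho250", "CWT1rho500", "CWT1rho1000", "CWT1rho2000",
            "AdT1rhoHS1", "AdT1rhoHS4", "AdT1rhoHS8",
            "AdT2rho", "RAFF2")

#' Dipolar angular factor
#'
#' The residual dipolar interaction between two nuclei scales with
#' `3*cos(theta)^2 - 1`, where `theta` is the angle between the internuclear
#' vector (here, the collagen fibre axis) and the main magnetic field B0.
#' The factor vanishes at the magic angle (54.7356 degrees), has period
#' 180 degrees and is symmetric about 0.
#'
#' @param theta_deg angle in degrees (any real value).
#' @return dimensionless factor in `[-1, 2]`.
#' @export
#' @examples
#' dipolar_factor(0)      # 2
#' dipolar_factor(90)     # -1
#' dipolar_factor(54.7356)  # ~0
dipolar_factor <- function(theta_deg) {
  3 * cos(theta_deg * pi / 180)^2 - 1
}

#' Magic angle of the dipolar factor
#'
#' Numerically locates the root of [dipolar_factor()] on `[0, 90]` degrees.
#'
#' @param tol convergence tolerance passed to [stats::uniroot()].
#' @return angle in degrees (54.7356...).
#' @export
magic_angle <- function(tol = 1e-12) {
  stats::uniroot(dipolar_factor, c(0, 90), tol = tol)$root
}

#' Dispersion-averaged squared dipolar factor
#'
#' Expectation of `(3*cos(theta)^2 - 1)^2` for `theta ~ N(mu, sd^2)`,
#' modelling sub-voxel spread of fibre orientations.  Closed form via
#' `E[cos(k theta)] = exp(-k^2 sd^2 / 2) * cos(k mu)`:
#' `11/8 + 3/2 e^{-2 s^2} cos(2 mu) + 9/8 e^{-8 s^2} cos(4 mu)`.
#' With `sd = 0` this reduces to `dipolar_factor(mu)^2`.
#'
#' @param mu_deg mean angle, degrees.
#' @param sd_deg angular spread (standard deviation), degrees.
#' @return expectation, in `[0, 4]`.
#' @export
mean_sq_dipolar_factor <- function(mu_deg, sd_deg = 0) {
  mu <- mu_deg * pi / 180
  s2 <- (sd_deg * pi / 180)^2
  11 / 8 + 1.5 * exp(-2 * s2) * cos(2 * mu) + 1.125 * exp(-8 * s2) * cos(4 * mu)
}

#' Default per-kind relaxation parameters
#'
#' Ground-truth parameters of the phantom's forward model, one row per
#' relaxation parameter kind.  Transverse-like kinds relax with
#' `R(depth, orientation) = R_iso + c_dip * E[(3 cos^2 theta_eff - 1)^2] / 4`
#' so that `c_dip` is the full excess rate at `theta_eff = 0`;
#' longitudinal-like kinds (T1) are orientation-independent with time
#' constant `T1_true`.  `R_iso` is set from the deep-zone maximum
#' (magic-angle) relaxation time of each kind, and `c_dip` is calibrated
#' with [calibrate_c_dip()] so that the noiseless deep-zone Michelson
#' anisotropy over the default 7-orientation grid equals
#' `deep_anisotropy_target` (values typical of bovine patellar cartilage
#' at 9.4 T).
#'
#' @param orientations_deg orientation grid used for the calibration.
#' @param dispersion_rz_deg fibre-angle spread in the radial zone, degrees.
#' @return data.frame with columns `kind`, `family`, `model`, `R_iso_s`,
#'   `c_dip_s`, `T1_true_ms`, `deep_anisotropy_target`.
#' @export
default_relax_params <- function(orientations_deg = seq(0, 90, by = 15),
                                 dispersion_rz_deg = 4) {
  tbl <- data.frame(
    kind   = .KINDS,
    family = c("longitudinal", rep("transverse", 11)),
    model  = c("inversion_recovery", "monoexp_noisefloor", "monoexp_noisefloor",
               "exp_baseline", "exp_baseline", "exp_baseline", "exp_baseline",
               "monoexp_noisefloor", "monoexp_noisefloor", "monoexp_noisefloor",
               "monoexp_noisefloor", "raff_steadystate"),
    # deep-zone magic-angle relaxation time, ms
    T_max_ms = c(NA, 68, 55, 85, 90, 97, 108, 224, 145, 151, 80, 96),
    # deep-zone Michelson anisotropy (fraction) the phantom reproduces
    deep_anisotropy_target =
      c(NA, 0.800, 0.794, 0.646, 0.436, 0.226, 0.120,
        0.068, 0.176, 0.173, 0.713, 0.696),
    stringsAsFactors = FALSE
  )
  tbl$R_iso_s    <- ifelse(is.na(tbl$T_max_ms), NA, 1000 / tbl$T_max_ms)
  tbl$T1_true_ms <- ifelse(tbl$family == "longitudinal", 1400, NA)
  tbl$c_dip_s <- vapply(seq_len(nrow(tbl)), function(i) {
    if (tbl$family[i] == "longitudinal") return(0)
    calibrate_c_dip(tbl$R_iso_s[i], tbl$deep_anisotropy_target[i],
                    orientations_deg, dispersion_rz_deg)
  }, numeric(1))
  tbl[, c("kind", "family", "model", "R_iso_s", "c_dip_s",
          "T1_true_ms", "deep_anisotropy_target")]
}

#' Calibrate the dipolar amplitude for a target deep-zone anisotropy
#'
#' Solves for `c_dip` such that the Michelson contrast of the noiseless
#' deep-zone rate over the orientation grid equals `target_A`.  In the
#' deep (radial) zone the fibre angle is 0, so the effective angle equals
#' minus the sample orientation.
#'
#' @param R_iso_s isotropic rate, 1/s.
#' @param target_A target Michelson anisotropy, fraction in (0, 1).
#' @param orientations_deg orientation grid, degrees.
#' @param dispersion_rz_deg deep-zone fibre-angle spread, degrees.
#' @return `c_dip` in 1/s.
#' @export
calibrate_c_dip <- function(R_iso_s, target_A,
                            orientations_deg = seq(0, 90, by = 15),
                            dispersion_rz_deg = 4) {
  f <- mean_sq_dipolar_factor(-orientations_deg, dispersion_rz_deg) / 4
  fmax <- max(f); fmin <- min(f)
  amax <- (fmax - fmin) / (fmax + fmin)
  .check(target_A > 0 && target_A < amax,
         sprintf("target anisotropy must be in (0, %.3f) for this grid", amax))
  2 * target_A * R_iso_s / ((fmax - fmin) - target_A * (fmax + fmin))
}

#' Phantom specification
#'
#' Ground-truth description of the synthetic layered specimen: geometry,
#' depth-wise collagen fibre-angle profile (superficial / transitional /
#' radial zones), per-kind relaxation parameters, fibre-angle dispersion
#' and noise level.
#'
#' @param image_shape `c(rows, cols)` in pixels.
#' @param pixel_size_mm pixel size along depth, mm.
#' @param surface_row first cartilage row (articular surface).
#' @param cartilage_depth_px cartilage thickness, pixels.
#' @param sz_span,tz_span,rz_span depth-fraction spans of the superficial,
#'   transitional and radial zones; must tile `[0, 1]`.
#' @param surface_angle_deg fibre angle vs. surface normal at the surface
#'   (90 is fully tangential; ~75 mimics real sections).
#' @param deep_angle_deg fibre angle in the radial zone (0 = radial).
#' @param dispersion_deg named vector `c(sz=, tz=, rz=)` of fibre-angle
#'   spread (degrees); must be maximal in the transitional zone.
#' @param relax_params per-kind parameter table, see [default_relax_params()].
#' @param raff_ss_frac RAFF steady-state fraction of S0.
#' @param raff_inv_eff RAFF inversion efficiency (S0_inv = -eff * S0).
#' @param s0 noiseless signal amplitude, arbitrary units.
#' @param snr signal-to-noise ratio (noiseless mean foreground signal at the
#'   first preparation time over the Gaussian channel sigma); `Inf` disables
#'   noise.
#' @param seed integer seed; the same spec and seed give bit-identical output.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(64, 64),
                         pixel_size_mm = 0.0625,
                         surface_row = 9,
                         cartilage_depth_px = 48,
                         sz_span = c(0, 0.08),
                         tz_span = c(0.08, 0.20),
                         rz_span = c(0.20, 1),
                         surface_angle_deg = 90,
                         deep_angle_deg = 0,
                         dispersion_deg = c(sz = 12, tz = 28, rz = 4),
                         relax_params = NULL,
                         raff_ss_frac = 0.30,
                         raff_inv_eff = 0.95,
                         s0 = 1000,
                         snr = 40,
                         seed = 1L) {
  .check(length(image_shape) == 2 && all(image_shape >= 8), "image_shape must be rows x cols >= 8")
  .check(surface_row >= 1 && surface_row + cartilage_depth_px - 1 <= image_shape[1],
         "cartilage must fit inside the image")
  .check(isTRUE(all.equal(sz_span[2], tz_span[1])) &&
         isTRUE(all.equal(tz_span[2], rz_span[1])) &&
         sz_span[1] == 0 && rz_span[2] == 1,
         "zone spans must tile [0, 1]")
  .check(all(c("sz", "tz", "rz") %in% names(dispersion_deg)),
         "dispersion_deg needs named entries sz, tz, rz")
  .check(dispersion_deg[["tz"]] >= dispersion_deg[["rz"]] &&
         dispersion_deg[["tz"]] >= dispersion_deg[["sz"]],
         "dispersion must be maximal in the transitional zone")
  .check(snr > 0, "snr must be positive")
  if (is.null(relax_params)) relax_params <- default_relax_params()
  .check(all(relax_params$c_dip_s >= 0, na.rm = TRUE) &&
         all(relax_params$R_iso_s > 0, na.rm = TRUE),
         "c_dip >= 0 and R_iso > 0 required")
  structure(list(
    image_shape = as.integer(image_shape), pixel_size_mm = pixel_size_mm,
    surface_row = as.integer(surface_row),
    cartilage_depth_px = as.integer(cartilage_depth_px),
    sz_span = sz_span, tz_span = tz_span, rz_span = rz_span,
    surface_angle_deg = surface_angle_deg, deep_angle_deg = deep_angle_deg,
    dispersion_deg = dispersion_deg, relax_params = relax_params,
    raff_ss_frac = raff_ss_frac, raff_inv_eff = raff_inv_eff,
    s0 = s0, snr = snr, seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d x %d px, cartilage rows %d-%d, SNR %s, seed %d\n",
              x$image_shape[1], x$image_shape[2], x$surface_row,
              x$surface_row + x$cartilage_depth_px - 1,
              format(x$snr), x$seed))
  cat(sprintf("  zones SZ [%.2f,%.2f) TZ [%.2f,%.2f) RZ [%.2f,%.2f]; %d kinds\n",
              x$sz_span[1], x$sz_span[2], x$tz_span[1], x$tz_span[2],
              x$rz_span[1], x$rz_span[2], nrow(x$relax_params)))
  invisible(x)
}

#' Depth-wise collagen fibre-angle profile
#'
#' Fibre angle relative to the surface normal as a function of normalized
#' depth: constant `surface_angle_deg` within the superficial zone,
#' constant `deep_angle_deg` within the radial zone, and a smooth
#' (raised-cosine) monotone transition across the transitional zone.
#'
#' @param depth_fraction depth in `[0, 1]` (0 = articular surface,
#'   1 = cartilage-bone interface); vectorized.
#' @param spec a [phantom_spec()].
#' @return fibre angle(s), degrees.
#' @export
fibre_angle_profile <- function(depth_fraction, spec) {
  .check(all(depth_fraction >= 0 & depth_fraction <= 1),
         "depth_fraction must lie in [0, 1]")
  a0 <- spec$surface_angle_deg; a1 <- spec$deep_angle_deg
  lo <- spec$tz_span[1]; hi <- spec$tz_span[2]
  u <- pmin(pmax((depth_fraction - lo) / (hi - lo), 0), 1)
  w <- (1 - cos(pi * u)) / 2   # smoothstep: 0 at TZ start, 1 at TZ end
  a0 + (a1 - a0) * w
}

#' Depth-wise fibre-angle dispersion profile
#'
#' Piecewise-linear interpolation of the per-zone dispersion values,
#' peaking at the middle of the transitional zone.
#'
#' @inheritParams fibre_angle_profile
#' @return dispersion (standard deviation of local fibre angle), degrees.
#' @export
dispersion_profile <- function(depth_fraction, spec) {
  .check(all(depth_fraction >= 0 & depth_fraction <= 1),
         "depth_fraction must lie in [0, 1]")
  d <- spec$dispersion_deg
  tz_mid <- mean(spec$tz_span)
  xs <- c(0, spec$sz_span[2], tz_mid, min(spec$rz_span[1] + 0.05, 1), 1)
  ys <- c(d[["sz"]], d[["sz"]], d[["tz"]], d[["rz"]], d[["rz"]])
  stats::approx(xs, ys, xout = depth_fraction, rule = 2)$y
}

#' Ground-truth relaxation rate of the phantom
#'
#' Forward model: transverse-like kinds relax at
#' `R_iso + c_dip * E[(3 cos^2 theta_eff - 1)^2] / 4`, where
#' `theta_eff = fibre_angle(depth) - sample_orientation` and the
#' expectation averages the sub-voxel fibre-angle dispersion at that depth
#' (see [mean_sq_dipolar_factor()]).  Longitudinal-like kinds return
#' `1000 / T1_true`, independent of orientation.
#'
#' @param depth_fraction depth in `[0, 1]`; vectorized.
#' @param sample_orientation_deg angle of the cartilage surface normal
#'   vs. B0, degrees.
#' @param kind parameter kind, one of the rows of `spec$relax_params`.
#' @param spec a [phantom_spec()].
#' @param dispersion if `FALSE`, ignore sub-voxel dispersion (point-fibre
#'   model).
#' @return relaxation rate(s), 1/s.
#' @export
true_rate <- function(depth_fraction, sample_orientation_deg, kind, spec,
                      dispersion = TRUE) {
  p <- spec$relax_params[spec$relax_params$kind == kind, ]
  .check(nrow(p) == 1, sprintf("unknown parameter kind '%s'", kind))
  if (p$family == "longitudinal")
    return(rep(1000 / p$T1_true_ms, length(depth_fraction)))
  mu <- fibre_angle_profile(depth_fraction, spec) - sample_orientation_deg
  sd <- if (dispersion) dispersion_profile(depth_fraction, spec) else 0
  p$R_iso_s + p$c_dip_s * mean_sq_dipolar_factor(mu, sd) / 4
}

#' Ground-truth relaxation time of the phantom
#'
#' @inheritParams true_rate
#' @return relaxation time(s), ms.
#' @export
true_time_ms <- function(depth_fraction, sample_orientation_deg, kind, spec,
                         dispersion = TRUE) {
  1000 / true_rate(depth_fraction, sample_orientation_deg, kind, spec,
                   dispersion = dispersion)
}

#' Acquisition schedule for a parameter kind
#'
#' Preparation-time lists mirroring a 9.4 T ex-vivo protocol: inversion
#' recovery TIs for T1, spin-echo TEs for T2, multi-echo GRE TEs for T2*,
#' spin-lock durations for CW-T1rho, and pulse-train counts times pulse
#' duration for the adiabatic and RAFF kinds.
#'
#' @param kind parameter kind.
#' @return list of class `acquisition_schedule` with fields
#'   `parameter_kind`, `prep_times_ms`, `spinlock_amplitude_hz`,
#'   `n_pulses`, `pulse_duration_ms`, `has_inversion_pair`.
#' @export
acquisition_schedule <- function(kind) {
  kind <- match.arg(kind, .KINDS)
  sl <- list(
    T1     = list(prep = c(200, 500, 800, 1100, 1400, 3000)),
    T2     = list(prep = c(10, 20, 40, 80, 100, 128)),
    T2star = list(prep = c(2.5, 7.5, 12.5, 17.5, 22.5, 27.5, 32.5, 37.5)),
    CWT1rho250  = list(prep = c(0, 24, 48, 96, 192), hz = 250),
    CWT1rho500  = list(prep = c(0, 24, 48, 96, 192), hz = 500),
    CWT1rho1000 = list(prep = c(0, 24, 48, 96, 192), hz = 1000),
    CWT1rho2000 = list(prep = c(0, 24, 48, 96, 192), hz = 2000),
    AdT1rhoHS1 = list(np = c(0, 4, 8, 12, 24), tau = 4.5),
    AdT1rhoHS4 = list(np = c(0, 4, 8, 12, 24), tau = 4.5),
    AdT1rhoHS8 = list(np = c(0, 4, 8, 12, 24), tau = 4.5),
    AdT2rho    = list(np = c(0, 4, 8, 12, 24), tau = 4.5),
    RAFF2      = list(np = c(0, 2, 4, 6, 8), tau = 9, inv = TRUE)
  )[[kind]]
  prep <- if (!is.null(sl$np)) sl$np * sl$tau else sl$prep
  .check(all(diff(prep) > 0) && length(prep) >= 4,
         "prep times must be strictly increasing with >= 4 entries")
  structure(list(
    parameter_kind = kind,
    prep_times_ms = prep,
    spinlock_amplitude_hz = if (!is.null(sl$hz)) sl$hz else NA_real_,
    n_pulses = if (!is.null(sl$np)) sl$np else NULL,
    pulse_duration_ms = if (!is.null(sl$tau)) sl$tau else NA_real_,
    has_inversion_pair = isTRUE(sl$inv)
  ), class = "acquisition_schedule")
}

# Noiseless signal stack for one orientation: list(plain=, inverted=NULL|)
# Each element: matrix ntimes x nrow (per-row signal; columns identical).
.noiseless_signals <- function(spec, schedule, orientation_deg) {
  kind <- schedule$parameter_kind
  p <- spec$relax_params[spec$relax_params$kind == kind, ]
  .check(nrow(p) == 1, sprintf("unknown parameter kind '%s'", kind))
  t <- schedule$prep_times_ms
  depth <- seq(0, 1, length.out = spec$cartilage_depth_px)
  if (p$family == "longitudinal") {
    T1 <- p$T1_true_ms
    sig <- spec$s0 * abs(1 - 2 * exp(-t / T1))
    return(list(plain = matrix(sig, length(t), length(depth)), inverted = NULL))
  }
  R <- true_rate(depth, orientation_deg, kind, spec)          # 1/s
  E <- exp(-outer(t, R) / 1000)                               # ntimes x ndepth
  if (kind == "RAFF2") {
    ss <- spec$raff_ss_frac * spec$s0
    s0p <- spec$s0
    s0i <- -spec$raff_inv_eff * spec$s0
    list(plain    = ss + (s0p - ss) * E,
         inverted = abs(ss + (s0i - ss) * E))
  } else {
    list(plain = spec$s0 * E, inverted = NULL)
  }
}

#' Generate a multi-orientation relaxometry image series
#'
#' Builds the magnitude image stack (preparation time x rows x cols) for
#' one parameter kind at one sample orientation.  The noiseless signal
#' follows a monoexponential decay for transverse-like kinds, a magnitude
#' inversion-recovery curve for T1, and an exponential approach to steady
#' state (with and without inversion preparation) for RAFF2.  Rician
#' magnitude noise is applied at `spec$snr` (Gaussian noise of equal sigma
#' on two quadrature channels); the sigma is defined as the mean noiseless
#' foreground signal at the first preparation time divided by `spec$snr`.
#'
#' @param spec a [phantom_spec()].
#' @param schedule an [acquisition_schedule()]; defaults to the kind's
#'   standard schedule.
#' @param sample_orientation_deg surface-normal angle vs. B0, degrees.
#' @param kind parameter kind (used when `schedule` is `NULL`).
#' @return object of class `image_series`: fields `data` (and
#'   `data_inverted` for RAFF2), `schedule`, `sample_orientation_deg`,
#'   `mask`, `background_roi`, `pixel_size_mm`; ground-truth sigma kept in
#'   attribute `sigma_true`.
#' @export
generate_series <- function(spec, schedule = NULL, sample_orientation_deg = 0,
                            kind = NULL) {
  if (is.null(schedule)) {
    .check(!is.null(kind), "either a schedule or a kind is required")
    schedule <- acquisition_schedule(kind)
  }
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  rows <- spec$surface_row:(spec$surface_row + spec$cartilage_depth_px - 1)
  nt <- length(schedule$prep_times_ms)
  sig <- .noiseless_signals(spec, schedule, sample_orientation_deg)

  build <- function(per_row) {                 # ntimes x ndepth -> stack
    stack <- array(0, dim = c(nt, nr, nc))
    for (i in seq_len(nt))
      stack[i, rows, ] <- matrix(per_row[i, ], length(rows), nc)
    stack
  }
  data <- build(sig$plain)
  data_inv <- if (!is.null(sig$inverted)) build(sig$inverted) else NULL

  mask <- matrix(FALSE, nr, nc); mask[rows, ] <- TRUE
  bg_rows <- seq_len(max(1, spec$surface_row - 3))
  background_roi <- matrix(FALSE, nr, nc); background_roi[bg_rows, ] <- TRUE

  sigma <- if (is.finite(spec$snr)) {
    mean(data[1, rows, ]) / spec$snr
  } else 0
  if (sigma > 0) {
    ki <- match(schedule$parameter_kind, .KINDS)
    seed <- (spec$seed + 1009L * ki +
             97L * round(sample_orientation_deg)) %% .Machine$integer.max
    local_seed(seed, {
      rician <- function(x) {
        n <- length(x)
        sqrt((x + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
      }
      data <- array(rician(data), dim = dim(data))
      if (!is.null(data_inv))
        data_inv <- array(rician(data_inv), dim = dim(data_inv))
    })
  }
  structure(list(
    data = data, data_inverted = data_inv, schedule = schedule,
    sample_orientation_deg = sample_orientation_deg,
    mask = mask, background_roi = background_roi,
    pixel_size_mm = spec$pixel_size_mm
  ), class = "image_series", sigma_true = sigma)
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_series> %s at %g deg: %d prep times, %d x %d px%s\n",
              x$schedule$parameter_kind, x$sample_orientation_deg,
              d[1], d[2], d[3],
              if (!is.null(x$data_inverted)) " (+ inversion pair)" else ""))
  invisible(x)
}

#' Measure the foreground signal-to-noise ratio of a series
#'
#' Mean foreground signal at the first preparation time divided by the
#' Rayleigh-corrected background sigma (`mean(background) / sqrt(pi/2)`).
#'
#' @param series an `image_series`.
#' @return SNR estimate (Inf for a noiseless series).
#' @export
measure_snr <- function(series) {
  sigma <- estimate_noise_sigma(series)
  fg <- mean(series$data[1, , ][series$mask])
  if (sigma == 0) Inf else fg / sigma
}

# Smooth 2-D Gaussian random field with unit marginal variance: iid noise
# convolved separably with a Gaussian kernel (reflected edges), then
# rescaled.  corr_px = 0 returns the iid field.
.smooth_field <- function(nr, nc, corr_px) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corr_px <= 0) return(z)
  r <- ceiling(3 * corr_px)
  k <- stats::dnorm(-r:r, 0, corr_px); k <- k / sum(k)
  conv1 <- function(m) {
    n <- nrow(m)
    mp <- m[c(r:1, seq_len(n), n:(n - r + 1)), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k))
      out <- out + k[i] * mp[seq_len(n) + i - 1L, , drop = FALSE]
    out
  }
  z <- conv1(z); z <- t(conv1(t(z)))
  z / stats::sd(as.vector(z))
}

#' Generate matched polarized-light-microscopy maps
#'
#' Emulates qPLM measurements of a specimen section: an orientation-angle
#' map (degrees, wrapped to `[0, 180)`) that follows the phantom's fibre
#' profile with Gaussian dispersion (maximal in the transitional zone), and
#' a retardation map that is lowest in the transitional zone and increases
#' toward the deep tissue.  The maps are generated on a grid `scale` times
#' finer than the MRI grid, reflecting the much higher resolution of
#' optical sections, and the orientation noise is a spatially correlated
#' field (correlation length `orientation_corr_px`), since real collagen
#' orientation varies smoothly at the scale of the entropy-filter window.
#' Pixels outside the tissue mask are 0.
#'
#' @param spec a [phantom_spec()].
#' @param scale PLM grid refinement relative to the MRI grid.
#' @param orientation_corr_px correlation length of the orientation noise,
#'   PLM pixels (0 for independent pixels).
#' @param retardation_noise relative noise of the retardation map.
#' @return object of class `plm_maps`: fields `orientation`, `retardation`,
#'   `mask`, `pixel_size_um`.
#' @export
generate_plm_maps <- function(spec, scale = 4L, orientation_corr_px = 2,
                              retardation_noise = 0.02) {
  nr <- spec$image_shape[1] * scale; nc <- spec$image_shape[2] * scale
  rows <- ((spec$surface_row - 1L) * scale + 1L):
          ((spec$surface_row + spec$cartilage_depth_px - 1L) * scale)
  depth <- seq(0, 1, length.out = length(rows))
  ang <- fibre_angle_profile(depth, spec)
  dsp <- dispersion_profile(depth, spec)
  tz_mid <- mean(spec$tz_span)
  ret <- stats::approx(
    x = c(0, spec$sz_span[2], tz_mid, min(spec$rz_span[1] + 0.1, 1), 1),
    y = c(0.45, 0.40, 0.18, 0.60, 0.90),
    xout = depth, rule = 2)$y

  orientation <- matrix(0, nr, nc)
  retardation <- matrix(0, nr, nc)
  local_seed(spec$seed + 777L, {
    field <- .smooth_field(length(rows), nc, orientation_corr_px)
    orientation[rows, ] <- (ang + dsp * field) %% 180
    retardation[rows, ] <- pmax(
      ret * (1 + matrix(stats::rnorm(length(rows) * nc, 0, retardation_noise),
                        length(rows), nc)), 0)
  })
  mask <- matrix(FALSE, nr, nc); mask[rows, ] <- TRUE
  structure(list(orientation = orientation, retardation = retardation,
                 mask = mask,
                 pixel_size_um = spec$pixel_size_mm * 1000 / scale),
            class = "plm_maps")
}
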