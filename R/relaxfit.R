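# Pixel-wise relaxation-model fitting with Rician noise-floor handling.
#
# Models: 2-parameter monoexponential after quadrature noise-floor
# subtraction; 3-parameter exponential with baseline (CW spin-lock);
# 3-parameter magnitude inversion recovery; joint steady-state fit of the
# inverted/non-inverted RAFF pulse-train pair.

.MODELS <- c("monoexp_noisefloor", "exp_baseline",
             "inversion_recovery", "raff_steadystate")

#' Fit-model specification
#'
#' @param model one of `monoexp_noisefloor`, `exp_baseline`,
#'   `inversion_recovery`, `raff_steadystate`.
#' @param t_bounds_ms lower/upper bounds on the fitted time constant, ms.
#' @param max_iter maximum optimizer iterations.
#' @param tol relative convergence tolerance on parameters and objective.
#' @param noise_sigma Rician channel sigma in signal units
#'   (`monoexp_noisefloor` only); `NA` means estimate from the series
#'   background.
#' @return list of class `fit_model_spec`.
#' @export
fit_model_spec <- function(model = .MODELS, t_bounds_ms = c(1, 10000),
                           max_iter = 100L, tol = 1e-8, noise_sigma = NA_real_) {
  model <- match.arg(model)
  .check(t_bounds_ms[1] > 0 && t_bounds_ms[2] > t_bounds_ms[1],
         "time-constant bounds must satisfy 0 < lower < upper")
  .check(tol > 0, "tolerance must be positive")
  structure(list(model = model, t_bounds_ms = t_bounds_ms,
                 max_iter = as.integer(max_iter), tol = tol,
                 noise_sigma = noise_sigma),
            class = "fit_model_spec")
}

# Bounded Levenberg-Marquardt wrapper around minpack.lm::nls.lm.
.lm_solve <- function(par, resid_fn, lower, upper, max_iter = 100L, tol = 1e-8) {
  fit <- try(minpack.lm::nls.lm(
    par = par, fn = resid_fn, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                         ftol = tol, ptol = tol)),
    silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(par = par, rss = NA_real_, converged = FALSE))
  list(par = fit$par, rss = fit$deviance,
       converged = fit$info %in% 1:3)
}

# Interior check: a time constant pinned at its bounds is not trusted.
.t_interior <- function(T, bounds) {
  is.finite(T) && T > bounds[1] * (1 + 1e-6) && T < bounds[2] * (1 - 1e-6)
}

#' Estimate the Rician channel sigma from a background region
#'
#' Pure-noise magnitude pixels follow a Rayleigh distribution with mean
#' `sigma * sqrt(pi/2)`; the estimator inverts this:
#' `sigma = mean(background) / sqrt(pi/2)`.  All preparation times of the
#' stack contribute.
#'
#' @param series an `image_series` with a non-empty `background_roi`
#'   (at least 50 pixels).
#' @return sigma in signal units.
#' @export
estimate_noise_sigma <- function(series) {
  roi <- series$background_roi
  .check(!is.null(roi) && sum(roi) >= 50,
         "background ROI must contain at least 50 pixels")
  nt <- dim(series$data)[1]
  vals <- as.vector(apply(series$data, 1, function(im) im[roi]))
  mean(vals) / sqrt(pi / 2)
}

#' Quadrature noise-floor subtraction
#'
#' `s' = sqrt(max(s^2 - sigma^2, 0))`: removes the Rician noise floor from
#' magnitude data before monoexponential fitting.  Idempotent on noiseless
#' data (`sigma = 0` leaves the signal unchanged).
#'
#' @param signals magnitude signals (non-negative).
#' @param sigma Rician channel sigma.
#' @return corrected signals.
#' @export
noise_floor_subtract <- function(signals, sigma) {
  .check(sigma >= 0, "sigma must be non-negative")
  sqrt(pmax(signals^2 - sigma^2, 0))
}

# Log-linear initial guess for S0 * exp(-t/T) on points with usable signal.
.loglin_init <- function(t, s, floor_level) {
  ok <- s > floor_level & s > 0
  if (sum(ok) < 2) return(NULL)
  cf <- stats::lm.fit(cbind(1, -t[ok]), log(s[ok]))$coefficients
  if (!all(is.finite(cf)) || cf[2] <= 0) return(NULL)
  c(S0 = unname(exp(cf[1])), T = unname(1 / cf[2]))
}

#' Fit a 2-parameter monoexponential with noise-floor subtraction
#'
#' Subtracts the Rician noise floor in quadrature, then fits
#' `S0 * exp(-t/T)` by bounded nonlinear least squares, initialized from a
#' log-linear fit on points above the noise floor.
#'
#' @param prep_times preparation times (TE, spin-lock duration, ...), ms,
#'   non-negative.
#' @param signals magnitude signals, same length.
#' @param sigma Rician channel sigma (0 for noiseless data).
#' @param spec a [fit_model_spec()] (bounds/tolerances).
#' @return list with `S0`, `T_ms`, `rss`, `converged`.
#' @export
fit_monoexp_noisefloor <- function(prep_times, signals, sigma = 0,
                                   spec = fit_model_spec("monoexp_noisefloor")) {
  .check(length(prep_times) >= 3 && length(signals) == length(prep_times),
         "need >= 3 matched points")
  .check(all(prep_times >= 0), "negative preparation times are not allowed")
  .check(all(signals >= 0), "magnitude signals must be non-negative")
  bounds <- spec$t_bounds_ms
  s <- noise_floor_subtract(signals, sigma)
  if (all(s <= max(sigma, 0) * 1e-6) || stats::sd(s) == 0)
    return(list(S0 = NA_real_, T_ms = NA_real_, rss = NA_real_,
                converged = FALSE))
  init <- .loglin_init(prep_times, s, max(sigma, max(s) * 1e-3))
  if (is.null(init)) init <- c(S0 = max(s), T = diff(range(prep_times)) / 2)
  init["T"] <- min(max(init["T"], bounds[1]), bounds[2])
  fit <- .lm_solve(c(S0 = max(init["S0"], 1e-12), T = unname(init["T"])),
                   function(p) s - p[1] * exp(-prep_times / p[2]),
                   lower = c(0, bounds[1]), upper = c(Inf, bounds[2]),
                   spec$max_iter, spec$tol)
  T_ms <- unname(fit$par[2])
  list(S0 = unname(fit$par[1]), T_ms = T_ms, rss = fit$rss,
       converged = fit$converged && .t_interior(T_ms, bounds))
}

#' Fit an exponential decay with baseline
#'
#' Fits `S(t) = A * exp(-t/T) + C` (baseline `C` unconstrained in sign),
#' the model used for continuous-wave spin-lock relaxometry.
#'
#' @param prep_times spin-lock durations, ms (>= 4 points).
#' @param signals magnitude signals.
#' @param spec a [fit_model_spec()].
#' @return list with `A`, `C`, `T_ms`, `rss`, `converged`.
#' @export
fit_exp_baseline <- function(prep_times, signals,
                             spec = fit_model_spec("exp_baseline")) {
  .check(length(prep_times) >= 4 && length(signals) == length(prep_times),
         "need >= 4 matched points")
  .check(all(prep_times >= 0), "negative preparation times are not allowed")
  bounds <- spec$t_bounds_ms
  if (stats::sd(signals) == 0)
    return(list(A = NA_real_, C = signals[1], T_ms = NA_real_,
                rss = NA_real_, converged = FALSE))
  ord <- order(prep_times)
  C0 <- signals[ord[length(ord)]]
  y <- signals - C0
  init <- .loglin_init(prep_times, pmax(y, 0), max(y, 0) * 1e-3)
  T0 <- if (is.null(init)) diff(range(prep_times)) / 3 else init["T"]
  T0 <- min(max(T0, bounds[1]), bounds[2])
  A0 <- signals[ord[1]] - C0
  if (!is.finite(A0) || A0 == 0) A0 <- max(signals) - min(signals)
  fit <- .lm_solve(c(A = A0, C = C0, T = unname(T0)),
                   function(p) signals - (p[1] * exp(-prep_times / p[3]) + p[2]),
                   lower = c(-Inf, -Inf, bounds[1]),
                   upper = c(Inf, Inf, bounds[2]),
                   spec$max_iter, spec$tol)
  T_ms <- unname(fit$par[3])
  list(A = unname(fit$par[1]), C = unname(fit$par[2]), T_ms = T_ms,
       rss = fit$rss,
       converged = fit$converged && .t_interior(T_ms, bounds))
}

#' Fit a magnitude inversion-recovery curve
#'
#' Fits `S(t) = S0 * |1 - 2 f exp(-t/T1)|` with inversion efficiency
#' `f` in `[0.5, 1]` (3-parameter magnitude model).  Initialization uses
#' the signal-null TI (`T1 ~ TI_null / ln 2`); if no null is bracketed by
#' the sampled TIs, a coarse log-grid initialization is used instead and
#' the result is flagged in `init_fallback`.
#'
#' @param TIs inversion times, ms (>= 4 points).
#' @param signals magnitude signals.
#' @param spec a [fit_model_spec()].
#' @return list with `S0`, `T1_ms`, `f`, `rss`, `converged`,
#'   `init_fallback`.
#' @export
fit_inversion_recovery <- function(TIs, signals,
                                   spec = fit_model_spec("inversion_recovery")) {
  .check(length(TIs) >= 4 && length(signals) == length(TIs),
         "need >= 4 matched points")
  .check(all(TIs > 0), "inversion times must be positive")
  .check(all(signals >= 0), "magnitude signals required")
  bounds <- spec$t_bounds_ms
  if (stats::sd(signals) == 0)
    return(list(S0 = NA_real_, T1_ms = NA_real_, f = NA_real_,
                rss = NA_real_, converged = FALSE, init_fallback = FALSE))
  i0 <- which.min(signals)
  fallback <- i0 == 1L || i0 == length(signals)
  if (!fallback) {
    T1_0 <- TIs[i0] / log(2)
  } else {
    grid <- exp(seq(log(max(min(TIs) / 2, bounds[1])),
                    log(min(max(TIs) * 5, bounds[2])), length.out = 40))
    rss_g <- vapply(grid, function(T1) {
      g <- abs(1 - 2 * 0.95 * exp(-TIs / T1))
      S0 <- sum(signals * g) / sum(g^2)
      sum((signals - S0 * g)^2)
    }, numeric(1))
    T1_0 <- grid[which.min(rss_g)]
  }
  T1_0 <- min(max(T1_0, bounds[1]), bounds[2])
  # fit in the unconstrained parametrization |S0 - b exp(-t/T1)| with
  # b = 2 f S0: the f/T1 ridge of the magnitude model otherwise pins f
  # at its bound; f is recovered afterwards and re-fitted constrained
  # only if it falls outside [0.5, 1]
  S0_0 <- max(signals)
  fit <- .lm_solve(c(S0 = S0_0, b = 1.9 * S0_0, T1 = unname(T1_0)),
                   function(p)
                     signals - abs(p[1] - p[2] * exp(-TIs / p[3])),
                   lower = c(0, 0, bounds[1]),
                   upper = c(Inf, Inf, bounds[2]),
                   spec$max_iter, spec$tol)
  S0 <- unname(fit$par[1]); f <- unname(fit$par[2] / (2 * fit$par[1]))
  T1 <- unname(fit$par[3]); rss <- fit$rss; conv <- fit$converged
  if (!is.finite(f) || f < 0.5 || f > 1) {
    f0 <- min(max(f, 0.5, na.rm = TRUE), 1)
    con <- .lm_solve(c(S0 = S0_0, T1 = unname(T1_0), f = f0),
                     function(p)
                       signals - p[1] * abs(1 - 2 * p[3] * exp(-TIs / p[2])),
                     lower = c(0, bounds[1], 0.5),
                     upper = c(Inf, bounds[2], 1),
                     spec$max_iter, spec$tol)
    S0 <- unname(con$par[1]); T1 <- unname(con$par[2])
    f <- unname(con$par[3]); rss <- con$rss; conv <- con$converged
  }
  list(S0 = S0, T1_ms = T1, f = f, rss = rss,
       converged = conv && .t_interior(T1, bounds),
       init_fallback = fallback)
}

#' Joint steady-state fit of a RAFF pulse-train pair
#'
#' Fits the inverted and non-inverted pulse-train decays jointly:
#' `S_plain(t) = SS + (S0_plain - SS) exp(-t/T)` and
#' `S_inv(t)   = SS + (S0_inv   - SS) exp(-t/T)` with shared steady state
#' `SS` and time constant `T`, where `t = n_pulses * pulse_duration`.
#' With `magnitude = TRUE` (the default for magnitude MRI data) the
#' inverted-curve prediction is folded through `abs()`.
#'
#' @param n_pulses pulse counts shared by both curves.
#' @param signals_plain signals without inversion preparation.
#' @param signals_inverted signals with inversion preparation.
#' @param pulse_duration_ms duration of one pulse, ms (default 9).
#' @param magnitude fold the inverted prediction to magnitude.
#' @param spec a [fit_model_spec()].
#' @return list with `T_ms`, `SS`, `S0_plain`, `S0_inv`, `rss`,
#'   `converged`.
#' @export
fit_raff_steadystate <- function(n_pulses, signals_plain, signals_inverted,
                                 pulse_duration_ms = 9, magnitude = TRUE,
                                 spec = fit_model_spec("raff_steadystate")) {
  .check(length(signals_plain) == length(n_pulses) &&
         length(signals_inverted) == length(n_pulses),
         "both curves must share the pulse-count axis")
  .check(pulse_duration_ms > 0, "pulse duration must be positive")
  .check(length(n_pulses) >= 3, "need >= 3 pulse counts")
  bounds <- spec$t_bounds_ms
  t <- n_pulses * pulse_duration_ms
  if (stats::sd(c(signals_plain, signals_inverted)) == 0)
    return(list(T_ms = NA_real_, SS = NA_real_, S0_plain = NA_real_,
                S0_inv = NA_real_, rss = NA_real_, converged = FALSE))
  resid <- function(p) {
    E <- exp(-t / p[2])
    pred_p <- p[1] + (p[3] - p[1]) * E
    pred_i <- p[1] + (p[4] - p[1]) * E
    if (magnitude) pred_i <- abs(pred_i)
    c(signals_plain - pred_p, signals_inverted - pred_i)
  }
  # Initialization by fold-sign enumeration: with the signed inverted
  # curve recovered (it crosses zero at most once, so the magnitude fold
  # flips a prefix of the time axis), plain - signed_inverted is a pure
  # exponential giving T by log-linear regression, and (SS, S0p, S0i) are
  # linear given T.  The two best candidate starts are polished by LM.
  ord <- order(t)
  m <- length(t)
  cands <- list()
  for (k in 0:(if (magnitude) m else 0)) {
    sgn <- rep(1, m); if (k > 0) sgn[ord[seq_len(k)]] <- -1
    dif <- signals_plain - sgn * signals_inverted
    init <- .loglin_init(t, pmax(dif, 0), max(dif, 0) * 1e-3)
    if (is.null(init)) next
    T0 <- min(max(init["T"], bounds[1]), bounds[2])
    E <- exp(-t / T0)
    X <- rbind(cbind(1 - E, E, 0 * E), cbind(sgn * (1 - E), 0 * E, sgn * E))
    y <- c(signals_plain, signals_inverted)
    cf <- tryCatch(qr.solve(X, y), error = function(e) NULL)
    if (is.null(cf)) next
    cands[[length(cands) + 1]] <-
      list(par = c(SS = unname(cf[1]), T = unname(T0),
                   S0p = unname(cf[2]), S0i = unname(cf[3])),
           rss = sum((y - X %*% cf)^2))
  }
  if (!length(cands)) {
    first <- which.min(t); last <- which.max(t)
    cands <- list(list(par = c(
      SS = mean(c(signals_plain[last], signals_inverted[last])),
      T = diff(range(t)) / 3,
      S0p = signals_plain[first], S0i = -signals_inverted[first]), rss = Inf))
  }
  cands <- cands[order(vapply(cands, `[[`, numeric(1), "rss"))]
  fit <- NULL
  for (cand in cands[seq_len(min(2, length(cands)))]) {
    cur <- .lm_solve(cand$par, resid,
                     lower = c(-Inf, bounds[1], -Inf, -Inf),
                     upper = c(Inf, bounds[2], Inf, Inf),
                     spec$max_iter, spec$tol)
    if (is.null(fit) || !is.finite(fit$rss) ||
        (is.finite(cur$rss) && cur$rss < fit$rss))
      fit <- cur
  }
  T_ms <- unname(fit$par[2])
  list(T_ms = T_ms, SS = unname(fit$par[1]),
       S0_plain = unname(fit$par[3]), S0_inv = unname(fit$par[4]),
       rss = fit$rss,
       converged = fit$converged && .t_interior(T_ms, bounds))
}

# Default model for each parameter kind.
.model_for_kind <- function(kind) {
  if (kind == "T1") "inversion_recovery"
  else if (grepl("^CWT1rho", kind)) "exp_baseline"
  else if (kind == "RAFF2") "raff_steadystate"
  else "monoexp_noisefloor"
}

#' Fit a relaxation map pixel-wise
#'
#' Applies the appropriate relaxation model to every masked pixel of an
#' image series and assembles per-pixel time, rate and diagnostic maps.
#' Non-converged pixels are flagged, never silently zeroed; pixels outside
#' the mask are left missing.
#'
#' @param series an `image_series`.
#' @param model_spec a [fit_model_spec()]; by default chosen from the
#'   series' parameter kind (`T1` -> inversion recovery, `CWT1rho*` ->
#'   exponential with baseline, `RAFF2` -> joint steady state, others ->
#'   monoexponential with noise-floor subtraction).
#' @param mask optional logical matrix restricting which pixels to fit
#'   (intersected with the series mask).
#' @return object of class `relax_map`: matrices `times` (ms), `rates`
#'   (1/s), `amplitude`, `baseline`, `rss`, logical `converged` and
#'   `fitted`, plus `kind`, `orientation_deg`, `model`, `sigma`.
#' @export
fit_map <- function(series, model_spec = NULL, mask = NULL) {
  kind <- series$schedule$parameter_kind
  if (is.null(model_spec)) model_spec <- fit_model_spec(.model_for_kind(kind))
  model <- model_spec$model
  .check(!(model == "raff_steadystate") || !is.null(series$data_inverted),
         "raff_steadystate requires an inversion pair in the series")
  .check(!(model != "raff_steadystate") || is.null(series$data_inverted),
         sprintf("series with an inversion pair cannot be fitted with '%s'",
                 model))
  m <- series$mask
  if (!is.null(mask)) m <- m & mask
  nr <- dim(series$data)[2]; nc <- dim(series$data)[3]
  t <- series$schedule$prep_times_ms
  sigma <- model_spec$noise_sigma
  if (model == "monoexp_noisefloor" && is.na(sigma))
    sigma <- estimate_noise_sigma(series)
  if (is.na(sigma)) sigma <- 0

  times <- rates <- amplitude <- baseline <- rss <- matrix(NA_real_, nr, nc)
  converged <- matrix(NA, nr, nc)
  idx <- which(m)
  for (k in idx) {
    s <- series$data[, ((k - 1) %% nr) + 1, ((k - 1) %/% nr) + 1]
    f <- switch(model,
      monoexp_noisefloor = fit_monoexp_noisefloor(t, s, sigma, model_spec),
      exp_baseline       = fit_exp_baseline(t, s, model_spec),
      inversion_recovery = {
        r <- fit_inversion_recovery(t, s, model_spec)
        list(S0 = r$S0, T_ms = r$T1_ms, rss = r$rss, converged = r$converged)
      },
      raff_steadystate   = {
        si <- series$data_inverted[, ((k - 1) %% nr) + 1, ((k - 1) %/% nr) + 1]
        r <- fit_raff_steadystate(series$schedule$n_pulses, s, si,
                                  series$schedule$pulse_duration_ms,
                                  spec = model_spec)
        list(S0 = r$S0_plain, T_ms = r$T_ms, rss = r$rss,
             converged = r$converged, C = r$SS)
      })
    times[k] <- f$T_ms
    rates[k] <- 1000 / f$T_ms
    amplitude[k] <- if (!is.null(f$S0)) f$S0 else f$A
    if (!is.null(f$C)) baseline[k] <- f$C
    rss[k] <- f$rss
    converged[k] <- isTRUE(f$converged)
  }
  structure(list(times = times, rates = rates, amplitude = amplitude,
                 baseline = baseline, rss = rss, converged = converged,
                 fitted = m, kind = kind,
                 orientation_deg = series$sample_orientation_deg,
                 model = model, sigma = sigma),
            class = "relax_map")
}

#' @export
print.relax_map <- function(x, ...) {
  n <- sum(x$fitted)
  nc <- sum(x$converged[x$fitted])
  cat(sprintf("<relax_map> %s at %g deg (%s): %d pixels fitted, %d converged, median T = %.3g ms\n",
              x$kind, x$orientation_deg, x$model, n, nc,
              stats::median(x$times[x$fitted & x$converged], na.rm = TRUE)))
  invisible(x)
}
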