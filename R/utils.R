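# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the caller's
#' RNG state afterwards so that generator calls do not perturb user code.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# stopifnot() with a readable message
.check <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Circular mean of orientation angles with 180-degree period
#'
#' Orientations of axial data (e.g. collagen fibres) are only defined modulo
#' 180 degrees; the mean is computed on doubled angles so that, e.g.,
#' \{179, 1\} averages to 0, not 90.
#'
#' @param theta_deg angles in degrees.
#' @param na.rm drop missing values.
#' @return mean angle in `[0, 180)`.
#' @export
circular_mean_180 <- function(theta_deg, na.rm = TRUE) {
  if (na.rm) theta_deg <- theta_deg[!is.na(theta_deg)]
  if (!length(theta_deg)) return(NA_real_)
  a <- theta_deg * pi / 90          # doubled angle in radians
  m <- atan2(mean(sin(a)), mean(cos(a))) * 90 / pi
  m %% 180
}

#' Circular standard deviation for 180-degree periodic angles
#'
#' @param theta_deg angles in degrees.
#' @param na.rm drop missing values.
#' @return circular standard deviation in degrees.
#' @export
circular_sd_180 <- function(theta_deg, na.rm = TRUE) {
  if (na.rm) theta_deg <- theta_deg[!is.na(theta_deg)]
  if (length(theta_deg) < 2) return(NA_real_)
  a <- theta_deg * pi / 90
  R <- sqrt(mean(sin(a))^2 + mean(cos(a))^2)
  R <- min(max(R, 1e-12), 1)
  sqrt(-2 * log(R)) * 90 / pi
}
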