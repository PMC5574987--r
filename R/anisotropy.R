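# Michelson-contrast orientation anisotropy of relaxation rates across
# sample orientations.

#' Michelson contrast
#'
#' `(max - min) / (max + min)` of a set of positive values; here applied to
#' relaxation rates measured at different sample orientations.  Invariant
#' to ordering and to positive scaling; bounded by `[0, 1)` for positive
#' inputs.
#'
#' @param values at least 2 finite positive values.
#' @return dimensionless contrast in `[0, 1)`.
#' @export
#' @examples
#' michelson(c(1, 2))   # 1/3
michelson <- function(values) {
  values <- values[is.finite(values)]
  .check(length(values) >= 2, "need at least 2 finite values")
  .check(all(values > 0), "all values must be positive (rates)")
  (max(values) - min(values)) / (max(values) + min(values))
}

#' Depth-wise MR anisotropy profile
#'
#' Given one depth profile of a relaxation parameter per sample
#' orientation (common normalized depth axis), converts times to rates
#' (`rate = 1000 / T_ms`) and applies the Michelson contrast across
#' orientations at each depth point.  A depth point contributes only when
#' at least two orientations are non-missing; otherwise it propagates as
#' missing.
#'
#' @param profiles list of [depth_profile()]s, one per orientation.
#' @param values_are `"time_ms"` (converted to rates) or `"rate_per_s"`.
#' @param trim_mad if non-`NULL`, per-depth values farther than
#'   `trim_mad` MADs from the median are excluded before the contrast
#'   (an optional guard against noise-driven extremes; off by default).
#' @return data.frame of class `anisotropy_profile` (also a
#'   `depth_profile` with the anisotropy as `value`), with attribute
#'   `n_orientations`.
#' @export
mr_anisotropy_profile <- function(profiles,
                                  values_are = c("time_ms", "rate_per_s"),
                                  trim_mad = NULL) {
  values_are <- match.arg(values_are)
  .check(is.list(profiles) && length(profiles) >= 2,
         "need profiles for at least 2 orientations")
  axis <- profiles[[1]]$depth_fraction
  for (p in profiles)
    .check(isTRUE(all.equal(p$depth_fraction, axis)),
           "profiles must share a common depth axis")
  V <- vapply(profiles, function(p) p$value, numeric(length(axis)))
  V <- matrix(V, nrow = length(axis))
  if (values_are == "time_ms") V <- 1000 / V
  A <- apply(V, 1, function(r) {
    r <- r[is.finite(r) & r > 0]
    if (!is.null(trim_mad) && length(r) > 2) {
      md <- stats::median(r); s <- stats::mad(r)
      if (s > 0) r <- r[abs(r - md) <= trim_mad * s]
    }
    if (length(r) < 2) NA_real_ else michelson(r)
  })
  structure(data.frame(depth_fraction = axis, value = A),
            class = c("anisotropy_profile", "depth_profile", "data.frame"),
            kind = attr(profiles[[1]], "kind"),
            sample_id = attr(profiles[[1]], "sample_id"),
            n_orientations = length(profiles))
}

#' Deep-zone bulk anisotropy
#'
#' Mean of the anisotropy profile over the deep-zone ROI (default depth
#' 40--80%), reported on a 0--100 scale.
#'
#' @param aniso_profile an [mr_anisotropy_profile()] result (or any
#'   `depth_profile` of values in `[0, 1]`).
#' @param deep_roi depth-fraction interval.
#' @return scalar anisotropy on the 0--100 reporting scale.
#' @export
deep_zone_anisotropy <- function(aniso_profile, deep_roi = c(0.40, 0.80)) {
  .check(length(deep_roi) == 2 && deep_roi[1] < deep_roi[2],
         "deep ROI must be an ordered interval")
  sel <- aniso_profile$depth_fraction >= deep_roi[1] &
         aniso_profile$depth_fraction <= deep_roi[2]
  .check(any(sel), "deep ROI contains no depth points")
  v <- aniso_profile$value[sel]
  .check(mean(!is.na(v)) >= 0.5, "deep ROI is mostly missing")
  mean(v, na.rm = TRUE) * 100
}
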