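# Correlation of depth-wise MR anisotropy with PLM anisotropy and
# retardation, averaged across samples via Fisher's z transform.

#' Pearson correlation of two depth profiles
#'
#' Product-moment correlation over paired non-missing depth points;
#' missing depths are dropped pairwise.
#'
#' @param x,y [depth_profile()]s on a common depth axis, or plain numeric
#'   vectors of equal length.
#' @param depth_window optional `c(lo, hi)` depth-fraction window to
#'   restrict the correlation (default: full axis).
#' @return Pearson r.
#' @export
profile_correlation <- function(x, y, depth_window = NULL) {
  if (inherits(x, "depth_profile") && inherits(y, "depth_profile")) {
    .check(isTRUE(all.equal(x$depth_fraction, y$depth_fraction)),
           "profiles must share a common depth axis")
    if (!is.null(depth_window)) {
      sel <- x$depth_fraction >= depth_window[1] &
             x$depth_fraction <= depth_window[2]
      x <- x[sel, ]; y <- y[sel, ]
    }
    xv <- x$value; yv <- y$value
  } else {
    .check(length(x) == length(y), "x and y must have equal length")
    xv <- as.numeric(x); yv <- as.numeric(y)
  }
  ok <- is.finite(xv) & is.finite(yv)
  .check(sum(ok) >= 3, "need at least 3 paired non-missing points")
  .check(stats::sd(xv[ok]) > 0 && stats::sd(yv[ok]) > 0,
         "zero variance in a profile")
  stats::cor(xv[ok], yv[ok])
}

#' Fisher-z average of correlation coefficients
#'
#' `tanh(mean(atanh(r)))`: correlations are averaged on the
#' variance-stabilized z scale.  Coefficients with `|r| = 1` (infinite z)
#' are clipped to `|r| = 1 - 1e-12` and flagged via the `clipped`
#' attribute.
#'
#' @param r correlation coefficients, each in `[-1, 1]`.
#' @return averaged correlation in `(-1, 1)`; attribute `clipped` is set
#'   when clipping occurred.
#' @export
fisher_mean <- function(r) {
  r <- r[!is.na(r)]
  .check(length(r) >= 1, "need at least one coefficient")
  .check(all(abs(r) <= 1), "correlations must lie in [-1, 1]")
  clipped <- any(abs(r) >= 1)
  if (clipped) {
    warning("|r| = 1 clipped before Fisher averaging")
    r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  }
  out <- tanh(mean(atanh(r)))
  if (clipped) attr(out, "clipped") <- TRUE
  out
}

#' Summary table of deep-zone anisotropy and PLM correlations
#'
#' One row per parameter kind: mean (min/max over samples) deep-zone
#' anisotropy on the 0--100 scale, and Fisher-z-averaged correlation
#' (min/max) of the depth-wise MR anisotropy with the PLM anisotropy and
#' retardation profiles.  Rows are ordered by descending anisotropy, ties
#' broken by kind name.
#'
#' @param deep_a matrix of deep-zone anisotropies (kinds x samples,
#'   0--100 scale) with kind rownames.
#' @param r_aniso,r_ret matrices of per-sample correlations (kinds x
#'   samples) vs. PLM anisotropy and retardation.
#' @return data.frame of class `anisotropy_summary`.
#' @export
summarize_anisotropy <- function(deep_a, r_aniso, r_ret) {
  .check(is.matrix(deep_a) && !is.null(rownames(deep_a)),
         "deep_a must be a kinds x samples matrix with rownames")
  .check(all(dim(r_aniso) == dim(deep_a)) && all(dim(r_ret) == dim(deep_a)),
         "matrices must share dimensions")
  kinds <- rownames(deep_a)
  df <- data.frame(
    kind = kinds,
    anisotropy      = rowMeans(deep_a, na.rm = TRUE),
    anisotropy_min  = apply(deep_a, 1, min, na.rm = TRUE),
    anisotropy_max  = apply(deep_a, 1, max, na.rm = TRUE),
    r_plm_anisotropy     = apply(r_aniso, 1, function(r) as.numeric(fisher_mean(r))),
    r_plm_anisotropy_min = apply(r_aniso, 1, min, na.rm = TRUE),
    r_plm_anisotropy_max = apply(r_aniso, 1, max, na.rm = TRUE),
    r_plm_retardation     = apply(r_ret, 1, function(r) as.numeric(fisher_mean(r))),
    r_plm_retardation_min = apply(r_ret, 1, min, na.rm = TRUE),
    r_plm_retardation_max = apply(r_ret, 1, max, na.rm = TRUE),
    n_samples = ncol(deep_a),
    row.names = NULL
  )
  df <- df[order(-df$anisotropy, df$kind), ]
  rownames(df) <- NULL
  class(df) <- c("anisotropy_summary", "data.frame")
  df
}
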