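# Quantitative polarized light microscopy (qPLM): entropy-filter collagen
# anisotropy from orientation-angle maps and depth profiles of
# orientation, retardation and anisotropy.

#' Local entropy filter of an orientation map
#'
#' Per pixel, the Shannon entropy (base 2) of the histogram of quantized
#' orientation values inside an odd-sized square window.  Values are
#' quantized to `n_bins` uniform bins over `[0, max_angle)`; borders are
#' handled by symmetric padding.  With `circular = TRUE` the angles are
#' doubled before binning so the 0/180-degree seam does not inflate the
#' entropy (off by default, matching the conventional rectilinear
#' behaviour of texture entropy filters).
#'
#' @param x orientation map, degrees in `[0, max_angle)`.
#' @param window odd window size (default 5).
#' @param n_bins histogram bins (default 256).
#' @param max_angle angular period (default 180).
#' @param circular seam-aware binning via angle doubling.
#' @param mask optional logical matrix; output is `NA` outside it.
#' @return entropy map in bits, same dimensions as `x`.
#' @export
entropy_filter <- function(x, window = 5L, n_bins = 256L, max_angle = 180,
                           circular = FALSE, mask = NULL) {
  .check(is.matrix(x), "x must be a matrix")
  .check(window %% 2 == 1 && window >= 1, "window must be odd")
  .check(window <= min(dim(x)), "window larger than image")
  ang <- if (circular) (2 * x) %% (2 * max_angle) else x %% max_angle
  q <- pmin(floor(ang / (if (circular) 2 * max_angle else max_angle) * n_bins),
            n_bins - 1L)
  h <- (window - 1L) %/% 2L
  reflect <- function(n) {           # symmetric padding indices
    if (h == 0) return(seq_len(n))
    c(h:1, seq_len(n), n:(n - h + 1))
  }
  qp <- q[reflect(nrow(x)), reflect(ncol(x)), drop = FALSE]
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(NA_real_, nr, nc)
  w <- window
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!is.null(mask) && !mask[i, j]) next
      win <- qp[i:(i + w - 1L), j:(j + w - 1L)]
      p <- tabulate(win + 1L, n_bins)
      p <- p[p > 0] / (w * w)
      out[i, j] <- -sum(p * log2(p))
    }
  }
  out
}

#' Anisotropy from a local entropy map
#'
#' `a = 1 / (entropy + 1)`: a strictly decreasing map of the entropy onto
#' `(0, 1]`, so that perfectly uniform local orientation (entropy 0) gives
#' anisotropy 1.
#'
#' @param entropy entropy values (bits), non-negative.
#' @return anisotropy values in `(0, 1]`.
#' @export
plm_anisotropy <- function(entropy) {
  .check(all(entropy >= 0, na.rm = TRUE), "entropy must be non-negative")
  1 / (entropy + 1)
}

#' Depth profiles of PLM orientation, retardation and anisotropy
#'
#' Computes, per depth row between the detected articular surface and bone
#' interface: the circular mean (180-degree period) of the orientation
#' map, the arithmetic mean of the retardation map, and the arithmetic
#' mean of the entropy-filter anisotropy; each is then depth-normalized.
#' All tissue-mask columns contribute (PLM sections span the whole
#' specimen).
#'
#' @param maps a `plm_maps` object (see [generate_plm_maps()]).
#' @param config a [profile_config()] (supplies `n_depth_points` and the
#'   thin-column rule).
#' @param window,n_bins,circular passed to [entropy_filter()].
#' @param sample_id metadata for the resulting profiles.
#' @return list of three [depth_profile()]s: `orientation`, `retardation`,
#'   `anisotropy`.
#' @export
plm_profiles <- function(maps, config = profile_config(), window = 5L,
                         n_bins = 256L, circular = FALSE,
                         sample_id = NA_character_) {
  .check(!is.null(maps$mask) && any(maps$mask), "empty tissue mask")
  ent <- entropy_filter(maps$orientation, window = window, n_bins = n_bins,
                        circular = circular, mask = maps$mask)
  an <- plm_anisotropy(ent)
  iface <- detect_interfaces(maps$mask, config$min_column_px)
  valid <- !is.na(iface$surface)
  .check(any(valid), "no usable columns in mask")
  surface <- round(stats::median(iface$surface[valid]))
  bone <- round(stats::median(iface$bone[valid]))
  rows <- surface:bone
  ori_raw <- vapply(rows, function(r) {
    circular_mean_180(maps$orientation[r, ][maps$mask[r, ]])
  }, numeric(1))
  ret_raw <- vapply(rows, function(r) {
    mean(maps$retardation[r, ][maps$mask[r, ]], na.rm = TRUE)
  }, numeric(1))
  ani_raw <- vapply(rows, function(r) {
    mean(an[r, ][maps$mask[r, ]], na.rm = TRUE)
  }, numeric(1))
  n <- config$n_depth_points
  list(
    orientation = normalize_depth(ori_raw, n, kind = "plm_orientation",
                                  sample_id = sample_id),
    retardation = normalize_depth(ret_raw, n, kind = "plm_retardation",
                                  sample_id = sample_id),
    anisotropy  = normalize_depth(ani_raw, n, kind = "plm_anisotropy",
                                  sample_id = sample_id)
  )
}
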