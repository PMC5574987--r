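# Depth-wise profiling: interface detection, centre-band extraction,
# depth normalization between articular surface (0) and bone interface (1),
# and zone statistics.

#' Profile-extraction configuration
#'
#' @param column_width_mm width of the centre column band, mm.
#' @param pixel_size_mm pixel size along depth, mm.
#' @param n_depth_points number of points of the normalized profile.
#' @param zone_bounds depth fractions ending the superficial and
#'   transitional zones, `c(sz = , tz = )`; zones are half-open
#'   `[0, sz)`, `[sz, tz)` and closed `[tz, 1]`.
#' @param deep_roi depth-fraction interval of the deep-zone bulk ROI.
#' @param min_column_px columns with fewer foreground pixels are excluded
#'   from interface detection.
#' @param min_converged_frac depth points with a smaller converged fraction
#'   in the band are marked missing and linearly bridged.
#' @return list of class `profile_config`.
#' @export
profile_config <- function(column_width_mm = 1.75, pixel_size_mm = 0.0625,
                           n_depth_points = 100L,
                           zone_bounds = c(sz = 0.08, tz = 0.20),
                           deep_roi = c(0.40, 0.80),
                           min_column_px = 5L,
                           min_converged_frac = 0.5) {
  .check(column_width_mm > 0 && pixel_size_mm > 0, "widths must be positive")
  .check(all(c("sz", "tz") %in% names(zone_bounds)) &&
         zone_bounds[["sz"]] > 0 && zone_bounds[["tz"]] > zone_bounds[["sz"]] &&
         zone_bounds[["tz"]] < 1,
         "zone bounds must satisfy 0 < sz < tz < 1")
  .check(length(deep_roi) == 2 && deep_roi[1] < deep_roi[2] &&
         deep_roi[1] >= 0 && deep_roi[2] <= 1,
         "deep ROI must be an ordered interval within [0, 1]")
  structure(list(column_width_mm = column_width_mm,
                 pixel_size_mm = pixel_size_mm,
                 n_depth_points = as.integer(n_depth_points),
                 zone_bounds = zone_bounds, deep_roi = deep_roi,
                 min_column_px = as.integer(min_column_px),
                 min_converged_frac = min_converged_frac),
            class = "profile_config")
}

#' Detect the articular surface and bone interface per column
#'
#' Along the depth axis (rows), the surface is the first foreground pixel
#' and the bone interface the last.  Columns with fewer than
#' `min_column_px` foreground pixels are excluded (`NA`).
#'
#' @param mask logical matrix, depth along rows.
#' @param min_column_px minimum foreground pixels per column.
#' @return data.frame with columns `col`, `surface`, `bone`.
#' @export
detect_interfaces <- function(mask, min_column_px = 5L) {
  .check(is.matrix(mask) && any(mask), "mask must be a non-empty logical matrix")
  res <- t(vapply(seq_len(ncol(mask)), function(j) {
    idx <- which(mask[, j])
    if (length(idx) < min_column_px) c(NA_real_, NA_real_)
    else c(idx[1], idx[length(idx)])
  }, numeric(2)))
  data.frame(col = seq_len(ncol(mask)), surface = res[, 1], bone = res[, 2])
}

# Columns of the centre band: n = round(width/pixel) columns centred on the
# midline of the columns with valid interfaces.
.band_columns <- function(mask, config) {
  iface <- detect_interfaces(mask, config$min_column_px)
  valid <- iface$col[!is.na(iface$surface)]
  .check(length(valid) > 0, "no usable columns in mask")
  nb <- round(config$column_width_mm / config$pixel_size_mm)
  .check(nb <= ncol(mask), "column band exceeds image width")
  mid <- round(mean(valid))
  cols <- (mid - floor((nb - 1) / 2)):(mid + ceiling((nb - 1) / 2))
  .check(all(cols >= 1 & cols <= ncol(mask)),
         "column band exceeds image width")
  list(cols = cols, interfaces = iface)
}

#' Extract a raw depth profile over the centre column band
#'
#' Mean per depth row over a band of `round(column_width / pixel_size)`
#' columns centred on the specimen midline, from the articular surface to
#' the bone interface.  Only converged pixels contribute; depth rows where
#' fewer than `min_converged_frac` of the band converged are marked missing
#' and linearly bridged.
#'
#' @param map numeric matrix (e.g. `relax_map$times`) or a `relax_map`.
#' @param mask logical foreground matrix (taken from the `relax_map` if
#'   omitted).
#' @param config a [profile_config()].
#' @param converged optional logical matrix of trustworthy pixels.
#' @return numeric vector of per-row values with attribute `rows`
#'   (image rows spanned).
#' @export
extract_profile <- function(map, mask = NULL, config = profile_config(),
                            converged = NULL) {
  if (inherits(map, "relax_map")) {
    if (is.null(mask)) mask <- map$fitted
    if (is.null(converged)) converged <- map$converged
    map <- map$times
  }
  .check(is.matrix(map) && !is.null(mask), "map matrix and mask required")
  if (is.null(converged)) converged <- !is.na(map)
  band <- .band_columns(mask, config)
  iface <- band$interfaces[band$cols, ]
  surface <- round(stats::median(iface$surface, na.rm = TRUE))
  bone <- round(stats::median(iface$bone, na.rm = TRUE))
  rows <- surface:bone
  ok <- mask[rows, band$cols, drop = FALSE] &
        converged[rows, band$cols, drop = FALSE] &
        !is.na(map[rows, band$cols, drop = FALSE])
  vals <- map[rows, band$cols, drop = FALSE]
  vals[!ok] <- NA
  frac <- rowMeans(ok)
  v <- rowMeans(vals, na.rm = TRUE)
  v[frac < config$min_converged_frac | !is.finite(v)] <- NA
  if (anyNA(v)) {
    .check(sum(!is.na(v)) >= 2, "too few usable depth rows")
    v <- stats::approx(seq_along(v)[!is.na(v)], v[!is.na(v)],
                       xout = seq_along(v), rule = 2)$y
  }
  attr(v, "rows") <- rows
  v
}

#' Construct a depth profile
#'
#' @param depth_fraction strictly increasing axis spanning `[0, 1]`.
#' @param value profile values.
#' @param kind,orientation_deg,sample_id metadata carried as attributes.
#' @return data.frame of class `depth_profile`.
#' @export
depth_profile <- function(depth_fraction, value, kind = NA_character_,
                          orientation_deg = NA_real_, sample_id = NA_character_) {
  .check(length(depth_fraction) == length(value) &&
         all(diff(depth_fraction) > 0) &&
         isTRUE(all.equal(range(depth_fraction), c(0, 1))),
         "depth axis must strictly increase from 0 to 1")
  structure(data.frame(depth_fraction = depth_fraction, value = value),
            class = c("depth_profile", "data.frame"),
            kind = kind, orientation_deg = orientation_deg,
            sample_id = sample_id)
}

#' Depth-normalize a raw profile
#'
#' Linear interpolation of a raw per-row profile onto a uniform `[0, 1]`
#' axis with `n_depth_points` points; the endpoints map exactly to the
#' surface and bone values.
#'
#' @param values raw per-row values (surface first), at least 2.
#' @param n_depth_points number of output points.
#' @param kind,orientation_deg,sample_id metadata for the profile.
#' @return a [depth_profile()].
#' @export
normalize_depth <- function(values, n_depth_points = 100L,
                            kind = NA_character_, orientation_deg = NA_real_,
                            sample_id = NA_character_) {
  .check(length(values) >= 2, "need at least 2 raw points")
  x <- seq(0, 1, length.out = length(values))
  xout <- seq(0, 1, length.out = n_depth_points)
  depth_profile(xout, stats::approx(x, values, xout = xout)$y,
                kind = kind, orientation_deg = orientation_deg,
                sample_id = sample_id)
}

# Half-open zone membership: SZ [0, sz), TZ [sz, tz), RZ [tz, 1].
.zone_of <- function(depth, zone_bounds) {
  ifelse(depth < zone_bounds[["sz"]], "SZ",
         ifelse(depth < zone_bounds[["tz"]], "TZ", "RZ"))
}

#' Zone statistics over one or more depth profiles
#'
#' Per-zone mean of each profile, aggregated as mean/min/max over all
#' contributing profiles (samples and orientations).
#'
#' @param profiles a [depth_profile()] or list of them.
#' @param zone_bounds see [profile_config()].
#' @return data.frame with one row per zone: `zone`, `mean`, `min`, `max`,
#'   `n_profiles`.
#' @export
zone_stats <- function(profiles, zone_bounds = c(sz = 0.08, tz = 0.20)) {
  if (inherits(profiles, "depth_profile")) profiles <- list(profiles)
  .check(length(profiles) >= 1, "at least one profile required")
  zones <- c("SZ", "TZ", "RZ")
  per <- vapply(profiles, function(p) {
    z <- .zone_of(p$depth_fraction, zone_bounds)
    vapply(zones, function(zz) {
      v <- p$value[z == zz]
      .check(length(v) > 0, sprintf("zone %s holds no depth points", zz))
      mean(v, na.rm = TRUE)
    }, numeric(1))
  }, numeric(3))
  per <- matrix(per, nrow = 3)
  data.frame(zone = zones,
             mean = rowMeans(per),
             min = apply(per, 1, min),
             max = apply(per, 1, max),
             n_profiles = length(profiles))
}
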