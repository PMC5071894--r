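# Radar-facing transforms and analytics: dB conversions, differential
# RCS (plain and simultaneous-transmit), dynamic-range clipping, circular
# median filtering, sector statistics, pattern comparison metrics and the
# wavelength-to-body-length (size-ratio) analysis.

#' Linear RCS to dBsm
#'
#' @param sigma RCS in m^2 (> 0 unless a `floor` is supplied).
#' @param floor Optional floor in m^2 applied before conversion (deep
#'   pattern nulls otherwise have no dB representation).
#' @return `10 * log10(sigma / 1 m^2)`.
#' @examples
#' to_dbsm(2.21e-4) # 2.21 cm^2 -> -36.56 dBsm
#' @export
to_dbsm <- function(sigma, floor = NULL) {
  if (!is.null(floor)) sigma <- pmax(sigma, floor)
  if (any(sigma <= 0 | !is.finite(sigma))) {
    stop("domain error: sigma must be > 0 (supply `floor` to clamp nulls)")
  }
  10 * log10(sigma)
}

#' dBsm to linear RCS (m^2)
#' @param db Value in dBsm.
#' @export
from_dbsm <- function(db) 10^(db / 10)

#' Differential polarimetric RCS (dB)
#'
#' `10 log10(sigma_hh / sigma_vv)`: the single-scatterer analogue of
#' differential reflectivity Z_DR.
#'
#' @param sigma_hh,sigma_vv Linear RCS (m^2, > 0).
#' @export
differential_rcs <- function(sigma_hh, sigma_vv) {
  if (any(sigma_hh <= 0) || any(sigma_vv <= 0)) {
    stop("domain error: sigma values must be > 0")
  }
  10 * log10(sigma_hh / sigma_vv)
}

#' Differential RCS under simultaneous H+V transmission (SHV mode)
#'
#' Weather radars that transmit and receive both polarizations
#' simultaneously receive co-polar signals contaminated coherently by the
#' cross-polar field; the emulation adds the complex co- and cross-polar
#' scattering amplitudes before forming powers:
#' `10 log10(|S_HH + S_HV|^2 / |S_VV + S_VH|^2)`.
#' Reduces to [differential_rcs()] when the cross-polar terms vanish.
#'
#' @param s A `scattering_matrix`, or a complex length-4 named vector /
#'   list with elements `hh`, `hv`, `vh`, `vv`.
#' @export
shv_differential_rcs <- function(s) {
  if (inherits(s, "scattering_matrix")) {
    s <- c(hh = s$S["h", "h"], hv = s$S["h", "v"],
           vh = s$S["v", "h"], vv = s$S["v", "v"])
  }
  num <- Mod(s[["hh"]] + s[["hv"]])^2
  den <- Mod(s[["vv"]] + s[["vh"]])^2
  if (den == 0) stop("domain error: zero vertical-channel power")
  if (num == 0) stop("domain error: zero horizontal-channel power")
  10 * log10(num / den)
}

#' SHV differential RCS series from a pattern's scattering amplitudes
#'
#' @param pattern A `polar_pattern` carrying its `smatrix` attribute.
#' @return Numeric vector of SHV differential RCS (dB) per azimuth.
#' @export
shv_differential_series <- function(pattern) {
  sm <- attr(pattern, "smatrix")
  if (is.null(sm)) stop("pattern has no stored scattering amplitudes")
  vapply(seq_len(nrow(sm)), function(i) {
    shv_differential_rcs(sm[i, c("hh", "hv", "vh", "vv")])
  }, numeric(1))
}

#' Radar emulation configuration
#'
#' @param dynamic_range_limit Clipping limit in dB (default 8, a mobile
#'   X-band system's differential-channel dynamic range).
#' @param median_halfwidth Circular median filter half-width in degrees
#'   (default 15, emulating heading spread in an ensemble of animals).
#' @param mode `"shv"` (simultaneous transmit) or `"plain"`.
#' @export
radar_emulation_config <- function(dynamic_range_limit = 8,
                                   median_halfwidth = 15,
                                   mode = c("shv", "plain")) {
  mode <- match.arg(mode)
  if (!is.numeric(dynamic_range_limit) || dynamic_range_limit <= 0) {
    stop("dynamic_range_limit must be > 0")
  }
  if (!is.numeric(median_halfwidth) || median_halfwidth < 0) {
    stop("median_halfwidth must be >= 0")
  }
  structure(list(dynamic_range_limit = dynamic_range_limit,
                 median_halfwidth = median_halfwidth, mode = mode),
            class = "radar_emulation_config")
}

#' Clip a dB series to a symmetric dynamic range
#'
#' @param values dB series.
#' @param config A `radar_emulation_config` (or a numeric limit).
#' @export
clip_dynamic_range <- function(values, config = radar_emulation_config()) {
  lim <- if (is.numeric(config)) config else config$dynamic_range_limit
  if (lim <= 0) stop("dynamic range limit must be > 0")
  pmin(pmax(values, -lim), lim)
}

#' Circular median filter on a closed angular grid
#'
#' Each output sample is the median of all input samples whose azimuth
#' lies within +-`halfwidth` degrees (endpoints included), indices
#' wrapping modulo 360.
#'
#' @param values Values on a regular azimuth grid covering [0, 360).
#' @param halfwidth Half-width in degrees.
#' @param step Grid step (default inferred from `length(values)`).
#' @export
circular_median_filter <- function(values, halfwidth = 15,
                                   step = 360 / length(values)) {
  n <- length(values)
  if (halfwidth < step) {
    if (halfwidth > 0) {
      warning("median half-width ", halfwidth,
              " deg is below the grid step; returning input unchanged")
    }
    return(values)
  }
  w <- floor(halfwidth / step + 1e-9)
  offs <- -w:w
  vapply(seq_len(n), function(i) {
    stats::median(values[((i - 1 + offs) %% n) + 1])
  }, numeric(1))
}

sector_windows <- function() {
  list(head_on = c(-45, 45), side_on = c(45, 135), tail_on = c(135, 225))
}

#' Sector statistics of a polar pattern
#'
#' Mean and median of the linear RCS over the canonical 90-degree view
#' sectors: head-on (-45 to +45 deg), side-on (+45 to +135) and tail-on
#' (+135 to +225, centered on the rear aspect), plus the full circle.
#' Sector windows are half-open `[lo, hi)`; dB values are computed from
#' the unrounded linear aggregates.
#'
#' @param pattern A `polar_pattern` covering the full circle.
#' @param channels Channels to summarize.
#' @return Data frame with sector, channel, mean/median in cm^2 and dBsm.
#' @export
sector_stats <- function(pattern, channels = c("vv", "hh")) {
  stopifnot(inherits(pattern, "polar_pattern"))
  az <- pattern$azimuth_deg
  if (length(az) < 4L || (360 - max(az)) > 2 * stats::median(diff(az))) {
    stop("validation error: pattern does not cover the full circle")
  }
  win <- c(sector_windows(), list(full_circle = c(0, 360)))
  rows <- list()
  for (sec in names(win)) {
    lo <- win[[sec]][1]; hi <- win[[sec]][2]
    in_sec <- ((az - lo) %% 360) < (hi - lo)
    for (ch in channels) {
      sig <- pattern[[paste0("sigma_", ch, "_m2")]][in_sec]
      rows[[length(rows) + 1L]] <- data.frame(
        sector = sec, channel = ch, n = length(sig),
        mean_cm2 = mean(sig) * 1e4,
        median_cm2 = stats::median(sig) * 1e4,
        mean_dbsm = to_dbsm(mean(sig), floor = 1e-30),
        median_dbsm = to_dbsm(stats::median(sig), floor = 1e-30)
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sector_stats", "data.frame")
  out
}

#' @export
print.sector_stats <- function(x, digits = 3, ...) {
  cat("Sector statistics (linear means; dBsm from unrounded aggregates)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Pearson correlation of two patterns on the linear RCS scale
#'
#' @param a,b Numeric series, or `polar_pattern`s (matched azimuth grids).
#' @param channel Channel used when patterns are supplied.
#' @return Pearson r.
#' @export
pearson_linear <- function(a, b, channel = "hh") {
  ab <- comparison_series(a, b, channel)
  if (length(ab$a) < 3L) stop("need at least 3 matched samples")
  if (stats::sd(ab$a) == 0 || stats::sd(ab$b) == 0) {
    stop("undefined correlation: zero variance in a series")
  }
  stats::cor(ab$a, ab$b)
}

#' Root-mean-square error between two patterns
#'
#' @param a,b Series or `polar_pattern`s on matched grids.
#' @param scale `"db"` (default; differences of dBsm values) or
#'   `"linear"` (differences in m^2).
#' @param channel Channel used when patterns are supplied.
#' @param floor Linear floor applied before dB conversion.
#' @export
rmse_pattern <- function(a, b, scale = c("db", "linear"), channel = "hh",
                         floor = 1e-10) {
  scale <- match.arg(scale)
  ab <- comparison_series(a, b, channel)
  if (scale == "db") {
    da <- to_dbsm(ab$a, floor = floor)
    db <- to_dbsm(ab$b, floor = floor)
  } else {
    da <- ab$a; db <- ab$b
  }
  sqrt(mean((da - db)^2))
}

comparison_series <- function(a, b, channel) {
  col <- paste0("sigma_", channel, "_m2")
  if (inherits(a, "polar_pattern")) {
    if (!inherits(b, "polar_pattern")) stop("both or neither must be patterns")
    if (nrow(a) != nrow(b) ||
        max(abs(a$azimuth_deg - b$azimuth_deg)) > 1e-9) {
      stop("validation error: azimuth grids do not match")
    }
    list(a = a[[col]], b = b[[col]])
  } else {
    a <- as.numeric(a); b <- as.numeric(b)
    if (length(a) != length(b)) stop("validation error: series lengths differ")
    list(a = a, b = b)
  }
}

#' Wavelength-to-body-length (size ratio) analysis
#'
#' For two per-frequency pattern lists (e.g. a detailed body model and
#' its equivalent ellipsoid), computes at each frequency the size ratio
#' `lambda / body_length`, the Pearson correlation (on linear RCS) and
#' the RMSE between the horizontally polarized patterns.
#'
#' @param patterns_a,patterns_b Lists of `polar_pattern`s from
#'   [frequency_sweep()] (matched frequency lists).
#' @param body_length Body length in meters (e.g. 0.05 for a small bat).
#' @param channel Compared channel (default `"hh"`).
#' @param rmse_scale Passed to [rmse_pattern()].
#' @return Data frame (class `size_ratio_curve`) with frequency,
#'   wavelength, ratio, pearson_r, rmse; ascending in ratio.
#' @export
size_ratio_analysis <- function(patterns_a, patterns_b, body_length,
                                channel = "hh", rmse_scale = "db") {
  fa <- attr(patterns_a, "frequencies")
  fb <- attr(patterns_b, "frequencies")
  if (is.null(fa) || is.null(fb)) {
    fa <- vapply(patterns_a, function(p) .c_mps / attr(p, "wavelength"),
                 numeric(1))
    fb <- vapply(patterns_b, function(p) .c_mps / attr(p, "wavelength"),
                 numeric(1))
  }
  if (length(fa) != length(fb) || max(abs(fa - fb) / fa) > 1e-9) {
    stop("validation error: frequency lists do not match")
  }
  if (!is.numeric(body_length) || body_length <= 0) {
    stop("body_length must be > 0")
  }
  lam <- .c_mps / fa
  out <- data.frame(
    frequency_hz = fa,
    wavelength_m = lam,
    ratio = lam / body_length,
    pearson_r = vapply(seq_along(fa), function(i) {
      pearson_linear(patterns_a[[i]], patterns_b[[i]], channel)
    }, numeric(1)),
    rmse = vapply(seq_along(fa), function(i) {
      rmse_pattern(patterns_a[[i]], patterns_b[[i]], scale = rmse_scale,
                   channel = channel)
    }, numeric(1))
  )
  out <- out[order(out$ratio), ]
  rownames(out) <- NULL
  class(out) <- c("size_ratio_curve", "data.frame")
  out
}

#' Equivalence threshold of a size-ratio curve
#'
#' The smallest size ratio at which the correlation reaches `r_min` and
#' stays at or above it for all larger ratios; `NA` if never sustained.
#'
#' @param curve A `size_ratio_curve`.
#' @param r_min Correlation threshold (default 0.9).
#' @export
equivalence_threshold <- function(curve, r_min = 0.9) {
  ok <- rev(cumprod(rev(curve$pearson_r >= r_min))) > 0
  if (!any(ok)) return(NA_real_)
  curve$ratio[which(ok)[1]]
}
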