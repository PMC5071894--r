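# Azimuth-indexed polarimetric RCS patterns: construction, CSV round
# trip, printing, sector summary and a base-graphics polar diagram.

#' Construct a polar RCS pattern
#'
#' @param azimuth Azimuths in degrees, ascending in [0, 360), no
#'   duplicates, 0 = head-on.
#' @param sigma_hh,sigma_vv,sigma_hv,sigma_vh Linear RCS per azimuth (m^2).
#' @param wavelength Wavelength in meters (metadata).
#' @param tilt Scan-plane tilt in degrees (metadata).
#' @param spacing Lattice spacing used (metadata).
#' @param residual Solver residual (metadata).
#' @param smatrix Optional complex n x 4 matrix (columns hh, hv, vh, vv)
#'   of scattering amplitudes.
#' @return Object of class `polar_pattern` (a data frame).
#' @export
polar_pattern <- function(azimuth, sigma_hh, sigma_vv,
                          sigma_hv = 0, sigma_vh = 0,
                          wavelength = NA_real_, tilt = 0,
                          spacing = NA_real_, residual = NA_real_,
                          smatrix = NULL) {
  azimuth <- as.numeric(azimuth)
  n <- length(azimuth)
  if (is.unsorted(azimuth, strictly = TRUE) || any(azimuth < 0) ||
      any(azimuth >= 360)) {
    stop("azimuths must be strictly ascending within [0, 360)")
  }
  df <- data.frame(
    azimuth_deg = azimuth,
    sigma_hh_m2 = rep_len(as.numeric(sigma_hh), n),
    sigma_vv_m2 = rep_len(as.numeric(sigma_vv), n),
    sigma_hv_m2 = rep_len(as.numeric(sigma_hv), n),
    sigma_vh_m2 = rep_len(as.numeric(sigma_vh), n)
  )
  if (any(vapply(df[-1], function(x) any(x < 0 | !is.finite(x)), logical(1)))) {
    stop("all sigma values must be finite and >= 0")
  }
  structure(df, wavelength = wavelength, tilt = tilt, spacing = spacing,
            residual = residual, smatrix = smatrix,
            class = c("polar_pattern", "data.frame"))
}

#' @export
print.polar_pattern <- function(x, ...) {
  cat(sprintf(
    "<polar_pattern> %d azimuths (step %g deg), lambda = %g m, tilt = %g deg\n",
    nrow(x), if (nrow(x) > 1) x$azimuth_deg[2] - x$azimuth_deg[1] else NA,
    attr(x, "wavelength"), attr(x, "tilt")))
  mean_db <- vapply(
    c("sigma_hh_m2", "sigma_vv_m2", "sigma_hv_m2", "sigma_vh_m2"),
    function(cn) to_dbsm(mean(x[[cn]]), floor = 1e-30), numeric(1))
  cat(sprintf("  full-circle mean [dBsm]: HH %.2f | VV %.2f | HV %.2f | VH %.2f\n",
              mean_db[1], mean_db[2], mean_db[3], mean_db[4]))
  invisible(x)
}

#' @export
summary.polar_pattern <- function(object, ...) {
  sector_stats(object)
}

#' Polar diagram of a pattern in dBsm
#'
#' @param x A `polar_pattern`.
#' @param channels Channels to draw.
#' @param floor_db Radial axis floor in dBsm.
#' @param ... Unused.
#' @export
plot.polar_pattern <- function(x, channels = c("vv", "hh"), floor_db = -70,
                               ...) {
  cols <- c(hh = "firebrick", vv = "navy", hv = "darkgreen", vh = "orange")
  az <- x$azimuth_deg * pi / 180
  vals <- lapply(channels, function(ch) {
    db <- to_dbsm(x[[paste0("sigma_", ch, "_m2")]], floor = 1e-30)
    pmax(db, floor_db) - floor_db
  })
  rmax <- max(unlist(vals))
  op <- graphics::par(mar = c(1, 1, 2, 1), pty = "s")
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(-rmax, rmax), ylim = c(-rmax, rmax),
                 axes = FALSE, xlab = "", ylab = "", asp = 1,
                 main = sprintf("RCS polar diagram (floor %g dBsm)", floor_db))
  for (ring in pretty(c(0, rmax))) {
    graphics::lines(ring * cos(seq(0, 2 * pi, length.out = 181)),
                    ring * sin(seq(0, 2 * pi, length.out = 181)),
                    col = "grey85")
  }
  # azimuth 0 (head-on) up, clockwise positive
  for (i in seq_along(channels)) {
    r <- c(vals[[i]], vals[[i]][1])
    a <- c(az, az[1])
    graphics::lines(r * sin(a), r * cos(a), col = cols[channels[i]], lwd = 2)
  }
  graphics::legend("topright", legend = toupper(channels), bty = "n",
                   col = cols[channels], lwd = 2)
  invisible(x)
}

#' Write a pattern to CSV (with metadata header)
#'
#' @param pattern A `polar_pattern`.
#' @param path Output path.
#' @export
write_pattern_csv <- function(pattern, path) {
  stopifnot(inherits(pattern, "polar_pattern"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# wavelength_m=%.12g", attr(pattern, "wavelength")), con)
  writeLines(sprintf("# tilt_deg=%.12g", attr(pattern, "tilt")), con)
  writeLines(sprintf("# spacing_m=%.12g", attr(pattern, "spacing")), con)
  writeLines(sprintf("# residual=%.6g", attr(pattern, "residual")), con)
  utils::write.table(as.data.frame(pattern), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pattern written by [write_pattern_csv()]
#'
#' @param path CSV path.
#' @return A `polar_pattern`.
#' @export
read_pattern_csv <- function(path) {
  if (!file.exists(path)) stop("io error: no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- function(keypat, default = NA_real_) {
    ln <- grep(keypat, hdr, value = TRUE)
    if (length(ln) == 0L) return(default)
    as.numeric(sub(".*=", "", ln[1]))
  }
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  need <- c("azimuth_deg", "sigma_hh_m2", "sigma_vv_m2", "sigma_hv_m2",
            "sigma_vh_m2")
  if (!all(need %in% names(df))) {
    stop("validation error: pattern CSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  polar_pattern(df$azimuth_deg, df$sigma_hh_m2, df$sigma_vv_m2,
                df$sigma_hv_m2, df$sigma_vh_m2,
                wavelength = meta("wavelength_m"), tilt = meta("tilt_deg", 0),
                spacing = meta("spacing_m"), residual = meta("residual"))
}
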