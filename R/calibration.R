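# Emulation and processing of controlled RCS measurements: synthetic
# vector-network-analyzer frequency sweeps, temporal averaging, noise
# floor estimation, range (time) gating, substitution calibration against
# the Mie sphere, and the cross-polar isolation check.
#
# Power bookkeeping: complex transmission amplitudes are in arbitrary
# linear units anchored so that |amplitude|^2 = power in milliwatts;
# dBm = 10 log10(P / 1 mW). Absolute levels only matter relatively in
# substitution calibration.

sweep_channels <- c("hh", "hv", "vh", "vv")

#' Construct a frequency-sweep record
#'
#' @param frequencies Uniform frequency grid in Hz (>= 2 points).
#' @param s Named list of complex matrices (n_freq x n_repeats), one per
#'   polarization channel `hh`, `hv`, `vh`, `vv`.
#' @return Object of class `sweep_record`.
#' @export
sweep_record <- function(frequencies, s) {
  frequencies <- as.numeric(frequencies)
  if (length(frequencies) < 2L) stop("need at least 2 frequency points")
  df <- diff(frequencies)
  if (max(abs(df - df[1])) > 1e-6 * df[1]) {
    stop("frequency grid must be uniform")
  }
  if (!all(sweep_channels %in% names(s))) {
    stop("`s` must have channels ", paste(sweep_channels, collapse = ", "))
  }
  s <- lapply(s[sweep_channels], function(m) {
    m <- as.matrix(m)
    if (nrow(m) != length(frequencies)) {
      stop("channel matrices must have one row per frequency")
    }
    m
  })
  structure(list(frequencies = frequencies, s = s),
            class = "sweep_record")
}

#' @export
print.sweep_record <- function(x, ...) {
  cat(sprintf(
    "<sweep_record> %d frequencies %.4g-%.4g GHz (step %.4g MHz), %d repeat(s)\n",
    length(x$frequencies), min(x$frequencies) / 1e9, max(x$frequencies) / 1e9,
    diff(x$frequencies[1:2]) / 1e6, ncol(x$s$hh)))
  cat(sprintf("  unambiguous range %.1f m\n",
              unambiguous_range(diff(x$frequencies[1:2]))))
  invisible(x)
}

#' Alias-free (unambiguous) range of a stepped-frequency sweep
#'
#' `c / (2 * frequency_step)`: echoes beyond this range wrap around in
#' the inverse transform.
#'
#' @param frequency_step Frequency step in Hz.
#' @export
unambiguous_range <- function(frequency_step) {
  if (frequency_step <= 0) stop("frequency step must be > 0")
  .c_mps / (2 * frequency_step)
}

#' Synthesize a vector-network-analyzer sweep of a measurement scene
#'
#' Each target contributes, per channel, an amplitude proportional to
#' sqrt(sigma) with the two-way phase `exp(-j 2 k R)`; complex white
#' Gaussian noise is added at the requested floor. The record emulates
#' what a dual-polarization VNA stores while a suspended target (plus
#' multipath clutter at other ranges) sits above the antennas.
#'
#' @param frequencies Frequency grid in Hz.
#' @param targets Data frame with columns `range_m` and per-channel RCS
#'   `sigma_hh_m2`, `sigma_hv_m2`, `sigma_vh_m2`, `sigma_vv_m2` (missing
#'   channel columns default to 0).
#' @param noise_floor_dbm Per-bin noise power (dBm); `-Inf` for no noise.
#' @param n_repeats Number of consecutive records (for temporal averaging).
#' @param seed Optional integer seed (reproducible records).
#' @return A `sweep_record`.
#' @export
synth_sweep <- function(frequencies, targets, noise_floor_dbm = -103,
                        n_repeats = 10L, seed = NULL) {
  frequencies <- as.numeric(frequencies)
  if (length(frequencies) < 2L) stop("need at least 2 frequency points")
  r_max <- unambiguous_range(diff(frequencies[1:2]))
  targets <- as.data.frame(targets)
  if (is.null(targets$range_m)) stop("targets need a range_m column")
  if (any(targets$range_m <= 0 | targets$range_m >= r_max)) {
    stop("validation error: target range beyond the unambiguous range (",
         signif(r_max, 4), " m)")
  }
  for (ch in sweep_channels) {
    cn <- paste0("sigma_", ch, "_m2")
    if (is.null(targets[[cn]])) targets[[cn]] <- 0
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  nf <- length(frequencies)
  npow <- if (is.finite(noise_floor_dbm)) 10^(noise_floor_dbm / 10) else 0
  k <- 2 * pi * frequencies / .c_mps
  s <- lapply(sweep_channels, function(ch) {
    sig <- targets[[paste0("sigma_", ch, "_m2")]]
    clean <- rep(0 + 0i, nf)
    for (t in seq_len(nrow(targets))) {
      if (sig[t] <= 0) next
      clean <- clean + sqrt(sig[t]) * exp(-2i * k * targets$range_m[t])
    }
    noise <- matrix(complex(
      real = stats::rnorm(nf * n_repeats, sd = sqrt(npow / 2)),
      imaginary = stats::rnorm(nf * n_repeats, sd = sqrt(npow / 2))
    ), nf, n_repeats)
    matrix(clean, nf, n_repeats) + noise
  })
  names(s) <- sweep_channels
  sweep_record(frequencies, s)
}

#' Average consecutive sweep repeats in time
#'
#' Coherent (complex) mean across repeats; incoherent noise power drops
#' by about the repeat count. Set `coherent = FALSE` for power averaging.
#'
#' @param record A `sweep_record` (or list of single-repeat records on a
#'   common grid).
#' @param coherent Complex mean (default) or power mean.
#' @return A `sweep_record` with one repeat.
#' @export
temporal_average <- function(record, coherent = TRUE) {
  if (!inherits(record, "sweep_record") && is.list(record)) {
    freqs <- record[[1]]$frequencies
    for (r in record) {
      if (!inherits(r, "sweep_record") ||
          length(r$frequencies) != length(freqs) ||
          max(abs(r$frequencies - freqs)) > 1e-3) {
        stop("validation error: records are not on a common frequency grid")
      }
    }
    s <- lapply(sweep_channels, function(ch) {
      do.call(cbind, lapply(record, function(r) r$s[[ch]]))
    })
    names(s) <- sweep_channels
    record <- sweep_record(freqs, s)
  }
  stopifnot(inherits(record, "sweep_record"))
  s <- lapply(record$s, function(m) {
    if (coherent) {
      matrix(rowMeans(m), ncol = 1L)
    } else {
      matrix(complex(real = sqrt(rowMeans(Mod(m)^2))), ncol = 1L)
    }
  })
  sweep_record(record$frequencies, s)
}

#' Estimate the noise floor from background records
#'
#' Mean per-bin power of target-free background records, in dBm.
#'
#' @param background A `sweep_record` (all repeats used).
#' @export
estimate_noise_floor <- function(background) {
  stopifnot(inherits(background, "sweep_record"))
  p <- unlist(lapply(background$s, function(m) Mod(m)^2))
  if (length(p) == 0L) stop("validation error: empty background set")
  10 * log10(mean(p))
}

#' Range profile of a sweep record (inverse transform)
#'
#' Inverse DFT of the frequency response onto a range axis with bin
#' `c / (2 B)` (B = total swept bandwidth) and unambiguous span
#' `c / (2 delta_f)`.
#'
#' @param record A `sweep_record` (averaged to one repeat, or the first
#'   repeat is used).
#' @param window `"rectangular"` (default) or `"hann"`.
#' @return Object of class `range_profile`: list with `ranges` (m) and
#'   complex `amplitude` per channel.
#' @export
range_profile <- function(record, window = c("rectangular", "hann")) {
  stopifnot(inherits(record, "sweep_record"))
  window <- match.arg(window)
  nf <- length(record$frequencies)
  df <- diff(record$frequencies[1:2])
  w <- switch(window,
              rectangular = rep(1, nf),
              hann = 0.5 - 0.5 * cos(2 * pi * seq_len(nf) / (nf + 1)))
  w <- w / mean(w)
  amp <- lapply(record$s, function(m) {
    stats::fft(m[, 1L] * w, inverse = TRUE) / nf
  })
  structure(
    list(ranges = (seq_len(nf) - 1L) * .c_mps / (2 * nf * df),
         amplitude = amp,
         unambiguous_range = unambiguous_range(df)),
    class = "range_profile"
  )
}

#' @export
print.range_profile <- function(x, ...) {
  pk <- x$ranges[which.max(Mod(x$amplitude$hh)^2 + Mod(x$amplitude$vv)^2)]
  cat(sprintf(
    "<range_profile> %d bins, resolution %.4g m, unambiguous %.4g m; strongest co-pol return near %.3g m\n",
    length(x$ranges), diff(x$ranges[1:2]), x$unambiguous_range, pk))
  invisible(x)
}

#' Time (range) gate a profile
#'
#' Zeroes the profile outside `[center - width/2, center + width/2]`,
#' suppressing multipath and clutter away from the target.
#'
#' @param profile A `range_profile`.
#' @param center Gate center in meters.
#' @param width Gate width in meters (default 0.15).
#' @return Gated `range_profile`.
#' @export
time_gate <- function(profile, center, width = 0.15) {
  stopifnot(inherits(profile, "range_profile"))
  if (center - width / 2 > max(profile$ranges) ||
      center + width / 2 < min(profile$ranges)) {
    stop("validation error: gate lies outside the profile span")
  }
  keep <- profile$ranges >= center - width / 2 &
    profile$ranges <= center + width / 2
  profile$amplitude <- lapply(profile$amplitude, function(a) a * keep)
  profile$gate <- c(center = center, width = width)
  profile
}

#' Peak power of a (gated) range profile
#'
#' @param profile A `range_profile`.
#' @param channel Polarization channel.
#' @return Peak linear power (mW units).
#' @export
peak_power <- function(profile, channel = "hh") {
  max(Mod(profile$amplitude[[channel]])^2)
}

#' Calibration reference from the conducting sphere
#'
#' @param diameter Sphere diameter in meters (default 15.82 mm).
#' @param frequency Radar frequency in Hz.
#' @param measured_peak_power Peak gated power of the sphere measurement
#'   (linear units).
#' @return Object of class `calibration_reference`.
#' @export
calibration_reference <- function(diameter = 0.01582, frequency,
                                  measured_peak_power) {
  if (measured_peak_power <= 0) stop("validation error: non-positive power")
  structure(
    list(diameter = diameter, frequency = frequency,
         sigma_true = calibration_sphere_rcs(diameter, frequency),
         power = measured_peak_power),
    class = "calibration_reference"
  )
}

#' Substitution calibration
#'
#' Converts a measured target power to absolute RCS by ratio against the
#' sphere reference measured in the same configuration:
#' `sigma_target = sigma_sphere * P_target / P_sphere`.
#'
#' @param target_power Gated peak power of the target (linear units).
#' @param reference A `calibration_reference`.
#' @return Calibrated RCS in m^2.
#' @export
substitution_calibrate <- function(target_power, reference) {
  stopifnot(inherits(reference, "calibration_reference"))
  if (any(target_power <= 0)) stop("validation error: non-positive power")
  reference$sigma_true * target_power / reference$power
}

#' Cross-polar isolation of a gated sphere measurement
#'
#' A sphere has no cross-polar backscatter, so any cross-polar return
#' measures the instrument's polarization isolation:
#' `10 log10(P_co / P_cross)`. Returns `Inf` for a perfectly clean
#' record.
#'
#' @param profile Gated `range_profile` of the sphere.
#' @param co,cross Channel names (defaults `"hh"`, `"hv"`).
#' @export
cross_pol_isolation <- function(profile, co = "hh", cross = "hv") {
  stopifnot(inherits(profile, "range_profile"))
  pco <- peak_power(profile, co)
  px <- peak_power(profile, cross)
  if (pco <= 0) stop("validation error: zero co-polar power")
  if (px == 0) return(Inf)
  10 * log10(pco / px)
}
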