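test_that("dBsm conversion matches the printed table convention", {
  expect_equal(to_dbsm(1), 0)
  expect_equal(to_dbsm(1e-4), -40)              # 1 cm^2
  expect_lt(abs(to_dbsm(2.21e-4) - (-36.55)), 0.05)
  expect_error(to_dbsm(0), "domain error")
  expect_equal(to_dbsm(0, floor = 1e-10), -100)
  expect_equal(from_dbsm(to_dbsm(3.7e-3)), 3.7e-3)
})

test_that("differential RCS arithmetic", {
  expect_equal(differential_rcs(2, 2), 0)
  expect_equal(differential_rcs(2, 1), 10 * log10(2), tolerance = 1e-12)
  # side-on ellipsoid entries: 4.04 cm^2 over 3.48 cm^2
  expect_equal(differential_rcs(4.04e-4, 3.48e-4), 0.65, tolerance = 0.01)
  expect_error(differential_rcs(0, 1), "domain error")
})

test_that("SHV emulation adds complex fields before forming powers", {
  # zero cross-pol: reduces exactly to the plain differential RCS
  s <- c(hh = 1.3 + 0.2i, hv = 0 + 0i, vh = 0 + 0i, vv = 0.9 - 0.1i)
  expect_equal(shv_differential_rcs(s),
               differential_rcs(4 * pi * Mod(s[["hh"]])^2,
                                4 * pi * Mod(s[["vv"]])^2))
  # sphere: equal co-pol, no cross-pol -> 0 dB
  expect_equal(shv_differential_rcs(c(hh = 1 + 0i, hv = 0i, vh = 0i,
                                      vv = 1 + 0i)), 0)
  # symmetric real cross-pol cancels; antisymmetric biases the ratio
  expect_equal(shv_differential_rcs(c(hh = 1 + 0i, hv = 0.1 + 0i,
                                      vh = 0.1 + 0i, vv = 1 + 0i)), 0)
  expect_equal(shv_differential_rcs(c(hh = 1 + 0i, hv = 0.1 + 0i,
                                      vh = -0.1 + 0i, vv = 1 + 0i)),
               10 * log10(1.21 / 0.81), tolerance = 1e-12)
})

test_that("dynamic-range clipping is an idempotent clamp", {
  cfg <- radar_emulation_config()
  expect_equal(clip_dynamic_range(c(10, -12, 3), cfg), c(8, -8, 3))
  x <- rnorm(100, sd = 10)
  once <- clip_dynamic_range(x, cfg)
  expect_equal(clip_dynamic_range(once, cfg), once)
  expect_true(all(abs(once) <= 8))
  # commutes with adding a constant for interior points
  expect_equal(clip_dynamic_range(c(-3, 2) + 1, cfg),
               c(-3, 2) + 1)
})

test_that("circular median filter wraps and kills single-sample spikes", {
  expect_equal(circular_median_filter(rep(2.5, 360), 15), rep(2.5, 360))
  spike <- rep(0, 360)
  spike[90] <- 20
  expect_equal(circular_median_filter(spike, 15), rep(0, 360))
  # brute-force wrapped-window oracle on an asymmetric series
  set.seed(42)
  vals <- rnorm(72)  # 5 degree grid
  hw <- 15
  filt <- circular_median_filter(vals, hw, step = 5)
  oracle <- vapply(seq_len(72), function(i) {
    angles <- (seq_len(72) - 1) * 5
    delta <- abs(((angles - angles[i] + 180) %% 360) - 180)
    median(vals[delta <= hw + 1e-9])
  }, numeric(1))
  expect_equal(filt, oracle)
  expect_warning(out <- circular_median_filter(vals, 2, step = 5),
                 "grid step")
  expect_equal(out, vals)
})

test_that("sector statistics integrate the linear pattern correctly", {
  az <- 0:359
  uni <- polar_pattern(az, sigma_hh = 1e-4, sigma_vv = 1e-4)
  ss <- sector_stats(uni)
  expect_equal(ss$mean_cm2, rep(1, nrow(ss)))
  expect_equal(ss$median_cm2, rep(1, nrow(ss)))
  expect_equal(ss$mean_dbsm, rep(-40, nrow(ss)))
  # cos^2 + 0.5 profile against a brute-force sum
  f <- cos(az * pi / 180)^2 + 0.5
  pat <- polar_pattern(az, sigma_hh = f * 1e-4, sigma_vv = f * 1e-4)
  ss2 <- sector_stats(pat, "vv")
  head_idx <- az < 45 | az >= 315
  side_idx <- az >= 45 & az < 135
  tail_idx <- az >= 135 & az < 225
  expect_equal(ss2$mean_cm2[ss2$sector == "head_on"], mean(f[head_idx]),
               tolerance = 1e-10)
  expect_equal(ss2$mean_cm2[ss2$sector == "side_on"], mean(f[side_idx]),
               tolerance = 1e-10)
  expect_equal(ss2$mean_cm2[ss2$sector == "tail_on"], mean(f[tail_idx]),
               tolerance = 1e-10)
  # half-open edges: each sector holds exactly 90 of the 360 samples
  expect_equal(ss2$n[ss2$sector != "full_circle"], rep(90L, 3))
  # the three named sectors plus the implied fourth average to the
  # full-circle mean
  other_idx <- az >= 225 & az < 315
  quarters <- c(mean(f[head_idx]), mean(f[side_idx]), mean(f[tail_idx]),
                mean(f[other_idx]))
  expect_equal(mean(quarters),
               ss2$mean_cm2[ss2$sector == "full_circle"], tolerance = 1e-10)
  expect_error(sector_stats(polar_pattern(c(0, 10, 20), 1e-4, 1e-4)),
               "full circle")
})

test_that("pattern comparison metrics match brute-force formulas", {
  a <- c(1, 2, 3, 4)
  b <- c(1.1, 1.9, 3.2, 3.8)
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_linear(a, b), r_oracle)
  expect_equal(pearson_linear(a, b), 0.99085, tolerance = 1e-4)
  expect_equal(pearson_linear(a, a), 1)
  expect_equal(pearson_linear(a, 2 * mean(a) - a), -1)
  expect_error(pearson_linear(a, rep(1, 4)), "zero variance")
  # RMSE: identical -> 0; constant dB offset -> that offset
  az <- seq(0, 350, 10)
  p1 <- polar_pattern(az, sigma_hh = 1e-4 * (1 + 0.5 * sin(az * pi / 180)),
                      sigma_vv = 1e-4)
  expect_equal(rmse_pattern(p1, p1), 0)
  p2 <- polar_pattern(az, sigma_hh = p1$sigma_hh_m2 * 10^(2 / 10),
                      sigma_vv = p1$sigma_vv_m2)
  expect_equal(rmse_pattern(p1, p2, scale = "db"), 2, tolerance = 1e-9)
  d1 <- c(0.8, 1.1, 0.9, 1.4)
  d2 <- c(1.0, 1.0, 1.0, 1.0)
  expect_equal(rmse_pattern(d1, d2, scale = "linear"),
               sqrt(mean((d1 - d2)^2)))
})

test_that("size-ratio analysis recovers a known equivalence threshold", {
  az <- seq(0, 350, 10)
  base <- 1e-4 * (1.5 + cos(2 * az * pi / 180))
  freqs <- c_mps / (0.05 * c(1, 2, 4, 8, 16))  # ratios 1..16
  rs <- c(0.3, 0.7, 0.95, 0.97, 0.999)
  mk <- function(r) {
    # construct b with exact correlation r to `base`
    resid <- sin(7 * az * pi / 180)
    resid <- resid - mean(resid)
    bb <- base - mean(base)
    resid <- resid - sum(resid * bb) / sum(bb^2) * bb
    b <- r * bb / sd(bb) + sqrt(1 - r^2) * resid / sd(resid)
    polar_pattern(az, sigma_hh = 1e-4 * (3 + b), sigma_vv = 1e-4)
  }
  pa <- lapply(rs, function(r) mk(1))
  pb <- lapply(rs, mk)
  attr(pa, "frequencies") <- freqs
  attr(pb, "frequencies") <- freqs
  curve <- size_ratio_analysis(pa, pb, 0.05)
  expect_equal(curve$ratio, c(1, 2, 4, 8, 16))
  expect_equal(curve$pearson_r, rs, tolerance = 1e-6)
  expect_true(all(diff(curve$pearson_r) > 0))
  expect_equal(equivalence_threshold(curve), 4)
  # identical sets: r = 1, rmse = 0 everywhere; ratio sanity 20 cm / 5 cm = 4
  curve_id <- size_ratio_analysis(pa, pa, 0.05)
  expect_equal(curve_id$pearson_r, rep(1, 5))
  expect_equal(curve_id$rmse, rep(0, 5))
  expect_equal(curve$ratio[curve$wavelength_m == 0.2], 4)
})
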