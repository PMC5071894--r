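# A compact VNA-like scene shared by several tests: 2 GHz of bandwidth
# around X band (7.5 cm range bins), target at 3 m, clutter at 5 m.
scene_freqs <- function() seq(9e9, 11e9, length.out = 401)

test_that("the alias-free range relation is c / (2 df)", {
  # 0.5614 MHz steps put the alias-free limit at 267 m
  expect_equal(unambiguous_range(0.5614e6), 267, tolerance = 1e-3)
  # brute-force aliasing: a target beyond the limit wraps onto a shorter
  # apparent range in the profile
  f <- seq(10e9, 10.1e9, length.out = 101)  # df = 1 MHz -> 149.9 m limit
  r_ua <- unambiguous_range(1e6)
  expect_error(
    synth_sweep(f, data.frame(range_m = r_ua + 5, sigma_hh_m2 = 1e-4),
                noise_floor_dbm = -Inf, n_repeats = 1),
    "unambiguous")
  ghost <- synth_sweep(f, data.frame(range_m = r_ua - 5, sigma_hh_m2 = 1e-4),
                       noise_floor_dbm = -Inf, n_repeats = 1)
  prof <- range_profile(ghost)
  expect_equal(prof$ranges[which.max(Mod(prof$amplitude$hh))], r_ua - 5,
               tolerance = diff(prof$ranges[1:2]) / (r_ua - 5))
})

test_that("synthetic sweeps place echoes at their ranges, reproducibly", {
  tg <- data.frame(range_m = 3, sigma_hh_m2 = 2e-4, sigma_vv_m2 = 1e-4)
  rec <- synth_sweep(scene_freqs(), tg, noise_floor_dbm = -Inf, n_repeats = 1)
  prof <- range_profile(rec)
  bin <- diff(prof$ranges[1:2])
  expect_equal(bin, c_mps / (2 * 2e9 * 401 / 400), tolerance = 1e-6)
  expect_lt(abs(prof$ranges[which.max(Mod(prof$amplitude$hh))] - 3), bin)
  # two targets 1 m apart resolve at 7.5 cm resolution
  tg2 <- data.frame(range_m = c(3, 4), sigma_hh_m2 = c(2e-4, 2e-4))
  p2 <- range_profile(synth_sweep(scene_freqs(), tg2,
                                  noise_floor_dbm = -Inf, n_repeats = 1))
  pk <- Mod(p2$amplitude$hh)
  near <- function(r) which(abs(p2$ranges - r) < 0.2)
  # both peaks stand well above the inter-target valley (rectangular
  # window sidelobes limit the notch depth)
  expect_gt(max(pk[near(3)]), 4 * max(pk[abs(p2$ranges - 3.5) < 0.2]))
  expect_gt(max(pk[near(4)]), 4 * max(pk[abs(p2$ranges - 3.5) < 0.2]))
  # fixed seed -> bitwise identical records
  r1 <- synth_sweep(scene_freqs(), tg, -103, n_repeats = 3, seed = 11)
  r2 <- synth_sweep(scene_freqs(), tg, -103, n_repeats = 3, seed = 11)
  expect_identical(r1, r2)
})

test_that("temporal averaging reduces incoherent noise about n-fold", {
  tg <- data.frame(range_m = 3, sigma_hh_m2 = 2e-4)
  rec <- synth_sweep(scene_freqs(), tg, -103, n_repeats = 10, seed = 5)
  expect_equal(temporal_average(rec)$s$hh[, 1],
               rowMeans(rec$s$hh))
  # identical (noise-free) repeats: unchanged
  clean <- synth_sweep(scene_freqs(), tg, -Inf, n_repeats = 10)
  expect_equal(temporal_average(clean)$s$hh[, 1], clean$s$hh[, 1])
  # pure noise: Monte Carlo power ratio ~ 1/10
  ratios <- vapply(1:8, function(s) {
    bg <- synth_sweep(scene_freqs(), data.frame(range_m = 3,
                                                sigma_hh_m2 = 0),
                      -103, n_repeats = 10, seed = s)
    mean(Mod(temporal_average(bg)$s$hh)^2) / mean(Mod(bg$s$hh)^2)
  }, numeric(1))
  expect_equal(mean(ratios), 0.1, tolerance = 0.3)
})

test_that("noise floor estimates recover the generation level", {
  bg <- synth_sweep(scene_freqs(), data.frame(range_m = 1, sigma_hh_m2 = 0),
                    noise_floor_dbm = -103, n_repeats = 10, seed = 2)
  expect_equal(estimate_noise_floor(bg), -103, tolerance = 0.5)
  # constant-amplitude record: exact closed form
  s <- lapply(c(hh = 1, hv = 2, vh = 3, vv = 4), function(a) {
    matrix(complex(modulus = a, argument = 0.3), 11, 1)
  })
  names(s) <- c("hh", "hv", "vh", "vv")
  rec <- sweep_record(seq(1e9, 2e9, length.out = 11), s)
  expect_equal(estimate_noise_floor(rec), 10 * log10(mean(c(1, 4, 9, 16))))
  expect_error(estimate_noise_floor(list()), "inherits")
})

test_that("time gating isolates the target and preserves its peak", {
  tg <- data.frame(range_m = c(3, 5), sigma_hh_m2 = c(2e-4, 8e-4))
  prof <- range_profile(synth_sweep(scene_freqs(), tg,
                                    noise_floor_dbm = -Inf, n_repeats = 1))
  gated <- time_gate(prof, center = 3, width = 0.15)
  # clutter energy at 5 m removed
  expect_equal(max(Mod(gated$amplitude$hh[abs(gated$ranges - 5) < 0.5])), 0)
  # target peak barely affected (well-resolved)
  p0 <- max(Mod(prof$amplitude$hh[abs(prof$ranges - 3) < 0.1]))
  p1 <- peak_power(gated, "hh")
  expect_equal(sqrt(p1), p0, tolerance = 0.01)
  # 15 cm gate at 7.5 cm bins keeps 2-3 bins (brute-force count)
  bin <- diff(prof$ranges[1:2])
  kept <- sum(prof$ranges >= 3 - 0.075 & prof$ranges <= 3 + 0.075)
  expect_true(kept %in% 2:3)
  expect_equal(sum(Mod(gated$amplitude$hh) > 0) <= kept, TRUE)
  # gate over an empty region: only window-sidelobe residue survives
  empty <- time_gate(prof, center = 10, width = 0.15)
  expect_lt(peak_power(empty, "hh"), 1e-4 * peak_power(prof, "hh"))
  expect_error(time_gate(prof, center = 1e4), "validation error")
})

test_that("substitution calibration is exact on clean scenes and linear", {
  ref <- calibration_reference(0.01582, 10e9, measured_peak_power = 4e-6)
  expect_equal(substitution_calibrate(4e-6, ref), ref$sigma_true)
  expect_equal(substitution_calibrate(8e-6, ref), 2 * ref$sigma_true)
  expect_error(substitution_calibrate(-1, ref), "validation error")
})

test_that("full pipeline recovers an injected RCS within 5% at 30 dB SNR", {
  freqs <- scene_freqs()
  sigma_true <- 2e-4  # 2 cm^2
  sigma_sphere <- calibration_sphere_rcs(0.01582, 10e9)
  # noise floor 30 dB below the sphere echo power
  floor_dbm <- 10 * log10(sigma_sphere) - 30
  run <- function(sig, seed) {
    rec <- synth_sweep(freqs,
                       data.frame(range_m = c(3, 5.2),
                                  sigma_hh_m2 = c(sig, 5 * sig)),
                       noise_floor_dbm = floor_dbm, n_repeats = 10,
                       seed = seed)
    peak_power(time_gate(range_profile(temporal_average(rec)), 3, 0.15), "hh")
  }
  recovered <- vapply(1:6, function(s) {
    ref <- calibration_reference(0.01582, 10e9, run(sigma_sphere, 100 + s))
    substitution_calibrate(run(sigma_true, 200 + s), ref)
  }, numeric(1))
  expect_lt(max(abs(recovered / sigma_true - 1)), 0.05)
  # calibration is invariant under a common complex gain
  gain <- 3.7 * exp(1i * 1.2)
  rec_t <- synth_sweep(freqs, data.frame(range_m = 3, sigma_hh_m2 = sigma_true),
                       -Inf, n_repeats = 1)
  rec_s <- synth_sweep(freqs, data.frame(range_m = 3,
                                         sigma_hh_m2 = sigma_sphere),
                       -Inf, n_repeats = 1)
  scale_rec <- function(r) { r$s <- lapply(r$s, function(m) m * gain); r }
  p_t <- peak_power(range_profile(scale_rec(rec_t)), "hh")
  p_s <- peak_power(range_profile(scale_rec(rec_s)), "hh")
  ref <- calibration_reference(0.01582, 10e9, p_s)
  expect_equal(substitution_calibrate(p_t, ref), sigma_true,
               tolerance = 1e-10)
})

test_that("cross-polar isolation flags instrument leakage on the sphere", {
  freqs <- scene_freqs()
  sig <- calibration_sphere_rcs(0.01582, 10e9)
  clean <- range_profile(synth_sweep(
    freqs, data.frame(range_m = 3, sigma_hh_m2 = sig), -Inf, n_repeats = 1))
  expect_equal(cross_pol_isolation(time_gate(clean, 3, 0.15)), Inf)
  leaky <- range_profile(synth_sweep(
    freqs, data.frame(range_m = 3, sigma_hh_m2 = sig,
                      sigma_hv_m2 = sig / 251), -Inf, n_repeats = 1))
  expect_equal(cross_pol_isolation(time_gate(leaky, 3, 0.15)),
               10 * log10(251), tolerance = 0.01)
  none <- range_profile(synth_sweep(
    freqs, data.frame(range_m = 3, sigma_vv_m2 = sig), -Inf, n_repeats = 1))
  expect_error(cross_pol_isolation(time_gate(none, 3, 0.15), co = "hh"),
               "validation error")
})

test_that("gating a clutter-free scene does not change calibration", {
  freqs <- scene_freqs()
  rec <- synth_sweep(freqs, data.frame(range_m = 3, sigma_hh_m2 = 3e-4),
                     -Inf, n_repeats = 1)
  prof <- range_profile(rec)
  expect_equal(peak_power(time_gate(prof, 3, 0.15), "hh"),
               peak_power(prof, "hh"), tolerance = 1e-9)
})
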