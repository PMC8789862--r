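test_that("stage I finds exactly one EoI for a single injected burst", {
  fs <- 1024
  x0 <- test_noise(3, seconds = 20)
  env_bg <- envelope(bandpass_filter(x0, fs, c(80, 250)))
  loc <- median(env_bg[(9 * fs):(11 * fs)])
  x <- x0 + test_burst(length(x0), fs, 10, 100, 0.08, 20 * loc)  # SNR 20
  s1 <- stage1_detect(x, fs)
  expect_equal(nrow(s1$eoi), 1L)
  expect_lt(abs(mean(c(s1$eoi$onset_s, s1$eoi$offset_s)) - 10), 0.05)
  expect_gt(sum(s1$baseline_windows$baseline), 0)
})

test_that("stage I false positives on pure 1/f noise stay within budget", {
  # regression fixture: <= 1 EoI per minute at default thresholds,
  # measured over 50 seeded one-minute noise draws
  counts <- vapply(1:50, function(s)
    nrow(stage1_detect(test_noise(s, seconds = 60), 1024)$eoi), 0L)
  expect_lte(mean(counts), 1)
})

test_that("stage I handles degenerate signals", {
  expect_equal(nrow(stage1_detect(rep(0, 4096), 1024)$eoi), 0L)
  expect_error(stage1_detect(rnorm(100), 1024), "shorter")
})

test_that("stage II accepts isolated ripple peaks and rejects monotone spectra", {
  fs <- 1024
  x0 <- test_noise(5, seconds = 10)
  env_bg <- envelope(bandpass_filter(x0, fs, c(80, 250)))
  x <- x0 + test_burst(length(x0), fs, 5, 120, 0.08, 15 * median(env_bg))
  p <- detector_params()
  freqs <- seq(p$stage2_low_freq_hz, p$ripple_band[2], by = p$freq_step_hz)
  S <- stockwell_transform(x, fs, freqs)
  span <- (5 * fs - 41):(5 * fs + 41)
  v <- stage2_validate(rowMeans(Mod(S[, span])^2), attr(S, "freqs"), p)
  expect_true(v$accepted)
  expect_lt(abs(v$peak_freq_hz - 120), 10)
  # slow square wave: filter ringing leaks into band but the time-averaged
  # spectrum decreases monotonically, no isolated ripple peak
  sq <- 30 * sign(sin(2 * pi * 3 * (seq_along(x0) - 1) / fs))
  S2 <- stockwell_transform(x0 / 10 + sq, fs, freqs)
  v2 <- stage2_validate(rowMeans(Mod(S2[, span])^2), attr(S2, "freqs"), p)
  expect_false(v2$accepted)
})

test_that("stage II trough boundary at 50% of peak power is inclusive", {
  p <- detector_params()
  freqs <- c(40, 60, 80, 100, 120, 140)
  # the sub-peak minimum is the low-frequency trough value itself
  spec_at <- function(trough) c(trough, trough, 8, 10, 4, 2)
  # trough exactly at 50% -> accepted; just above -> rejected
  expect_true(stage2_validate(spec_at(5.0), freqs, p)$accepted)
  expect_equal(stage2_validate(spec_at(5.0), freqs, p)$peak_freq_hz, 100)
  expect_false(stage2_validate(spec_at(5.0 + 1e-9), freqs, p)$accepted)
})

test_that("stage III boundaries sit exactly at the printed thresholds", {
  m <- default_montage()
  base <- data.frame(channel = "F3-C3", onset_s = 1, offset_s = 1.05,
                     pp_uV = 20, snr = 100, zmax_excess = -1,
                     stringsAsFactors = FALSE)
  flags <- function(ev) stage3_reject(ev, m)
  # peak-to-peak: >= 40 rejected, 39.9 kept
  ev <- base; ev$pp_uV <- 39.9
  expect_equal(flags(ev)$status, "accepted")
  ev$pp_uV <- 40.0
  expect_equal(flags(ev)$status, "rejected")
  expect_equal(flags(ev)$reject_reason, "amplitude")
  # SNR: < 9 rejected, exactly 9 kept
  ev <- base; ev$snr <- 9.0
  expect_equal(flags(ev)$status, "accepted")
  ev$snr <- 8.999
  expect_equal(flags(ev)$reject_reason, "snr")
  # z-score: above the median + 1.5 iqr cutoff rejected, at it kept
  ev <- base; ev$zmax_excess <- 0
  expect_equal(flags(ev)$status, "accepted")
  ev$zmax_excess <- 1e-9
  expect_equal(flags(ev)$reject_reason, "zscore")
})

test_that("fast-ripple z-score cutoff is median plus 1.5 iqr", {
  set.seed(9)
  x <- test_noise(9, seconds = 10)
  zr <- scalphfo:::fr_zscore(x, 1024, detector_params())
  expect_equal(zr$cutoff, median(zr$z) + 1.5 * IQR(zr$z))
  # factor is configurable
  zr2 <- scalphfo:::fr_zscore(x, 1024,
                              detector_params(zscore_iqr_factor = 3))
  expect_equal(zr2$cutoff, median(zr2$z) + 3 * IQR(zr2$z))
})

test_that("simultaneous homologous events are both rejected as bilateral", {
  m <- default_montage()
  ev <- data.frame(channel = c("F3-C3", "F4-C4"),
                   onset_s = c(1, 1.01), offset_s = c(1.06, 1.07),
                   pp_uV = 20, snr = 100, zmax_excess = -1,
                   stringsAsFactors = FALSE)
  out <- stage3_reject(ev, m)
  expect_equal(out$status, c("rejected", "rejected"))
  expect_equal(out$reject_reason, c("bilateral", "bilateral"))
  # non-overlapping events on homologous channels survive
  ev2 <- ev; ev2$onset_s[2] <- 2; ev2$offset_s[2] <- 2.06
  expect_equal(stage3_reject(ev2, m)$status, c("accepted", "accepted"))
  # midline channels have no mirror partner to co-occur with
  ev3 <- data.frame(channel = c("Fz-Cz", "Cz-Pz"),
                    onset_s = 1, offset_s = 1.06, pp_uV = 20, snr = 100,
                    zmax_excess = -1, stringsAsFactors = FALSE)
  expect_equal(stage3_reject(ev3, m)$status, c("accepted", "accepted"))
})

test_that("full detector reaches recall and precision 0.8 on injected events", {
  m <- default_montage()
  chs <- hot_neighborhood(m)
  stats <- vapply(1:20, function(s) {
    cfg <- detection_config(s)
    ses <- generate_recording(cfg, 1, "pre")
    ev <- detect_hfo(ses$recording, m, synthetic_intervals(ses),
                     channels = chs)
    mt <- match_events(ev, ses$ground_truth, m)
    c(sum(mt$truth_hit), mt$n_truth, sum(mt$det_hit), mt$n_detected)
  }, numeric(4))
  expect_gte(sum(stats[1, ]) / sum(stats[2, ]), 0.8)   # pooled recall
  expect_gte(sum(stats[3, ]) / sum(stats[4, ]), 0.8)   # pooled precision
})

test_that("a recording with only bilateral artifact pairs yields no events", {
  cfg <- detection_config(21, hfo_rate_area_pre = 0,
                          artifact_rates = c(amplitude = 0, fastripple = 0,
                                             bilateral = 4))
  ses <- generate_recording(cfg, 1, "pre")
  expect_true(all(ses$ground_truth$class == "artifact_bilateral"))
  ev <- detect_hfo(ses$recording, intervals = synthetic_intervals(ses))
  expect_equal(sum(ev$status == "accepted"), 0L)
})

test_that("amplitude scaling leaves stage-I EoI invariant, flips the 40 uV rule", {
  fs <- 1024
  x0 <- test_noise(13, seconds = 20, rms = 1.5)
  env_bg <- envelope(bandpass_filter(x0, fs, c(80, 250)))
  x <- x0 + test_burst(length(x0), fs, 10, 130, 0.08, 15 * median(env_bg))
  s1 <- stage1_detect(x, fs)
  s1c <- stage1_detect(3 * x, fs)
  expect_equal(s1c$threshold, 3 * s1$threshold, tolerance = 1e-9)
  expect_equal(s1c$eoi, s1$eoi)
  # in the full pipeline, doubling amplitudes pushes pp past 40 uV
  cfg <- detection_config(14, hfo_rate_area_pre = 3)
  ses <- generate_recording(cfg, 1, "pre")
  iv <- synthetic_intervals(ses)
  ev1 <- detect_hfo(ses$recording, intervals = iv, channels = "F3-C3")
  rec2 <- ses$recording
  rec2$samples <- rec2$samples * 2
  ev2 <- detect_hfo(rec2, intervals = iv, channels = "F3-C3")
  expect_equal(ev2$pp_uV, 2 * ev1$pp_uV, tolerance = 1e-9)
  was_ok <- ev1$status == "accepted"
  expect_true(all(ev2$status[was_ok & ev2$pp_uV >= 40] == "rejected"))
})

test_that("detection is deterministic and stage flags are consistent", {
  cfg <- detection_config(15, artifact_rates = c(amplitude = 1,
                                                 fastripple = 1,
                                                 bilateral = 1))
  ses <- generate_recording(cfg, 1, "pre")
  iv <- synthetic_intervals(ses)
  chs <- hot_neighborhood()
  ev1 <- detect_hfo(ses$recording, intervals = iv, channels = chs)
  ev2 <- detect_hfo(ses$recording, intervals = iv, channels = chs)
  expect_identical(as.data.frame(ev1), as.data.frame(ev2))
  # stage ordering: accepted events passed stage 2; stage-2 rejects carry
  # no stage-3 flags
  expect_true(all(ev1$passed_stage2[ev1$status == "accepted"]))
  s2rej <- ev1[ev1$status == "rejected_stage2", ]
  expect_false(any(s2rej$rejected_amplitude | s2rej$rejected_snr |
                     s2rej$rejected_bilateral | s2rej$rejected_zscore))
})

test_that("a ripple burst riding on a broadband spike is z-score rejected", {
  # construct the composite directly: ripple burst (passes stage II)
  # coinciding with a fast-ripple transient (high 250-500 Hz envelope)
  fs <- 1024
  m <- default_montage()
  x0 <- test_noise(17, seconds = 30, rms = 1.5)
  env_bg <- envelope(bandpass_filter(x0, fs, c(80, 250)))
  loc <- median(env_bg)
  n <- length(x0)
  x <- x0 + test_burst(n, fs, 10, 130, 0.08, 15 * loc) +
    test_burst(n, fs, 20, 130, 0.08, 15 * loc) +
    test_burst(n, fs, 20, 350, 0.05, 40 * loc)   # fr content under burst 2
  X <- matrix(0, n, 21, dimnames = list(NULL, electrode_labels()))
  X[, "F3"] <- x
  for (el in setdiff(electrode_labels(), "F3"))
    X[, el] <- test_noise(17 + match(el, electrode_labels()),
                          seconds = 30, rms = 1.5)
  rec <- eeg_recording(X, fs)
  iv <- data.frame(interval_id = "iv01", start_s = 0, end_s = 30,
                   stage = "N3", minutes = 0.5, partial = FALSE)
  ev <- detect_hfo(rec, m, iv, channels = "F3-C3")
  at20 <- ev[ev$onset_s > 19.5 & ev$offset_s < 20.5, ]
  at10 <- ev[ev$onset_s > 9.5 & ev$offset_s < 10.5, ]
  expect_equal(at20$reject_reason, "zscore")
  expect_equal(at10$status, "accepted")
})
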