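test_that("identical seed and config reproduce signals and event tables", {
  cfg <- detection_config(31, hfo_rate_area_pre = 2,
                          artifact_rates = c(amplitude = 0.5,
                                             fastripple = 0.5,
                                             bilateral = 0.5))
  a <- generate_recording(cfg, 1, "pre")
  b <- generate_recording(cfg, 1, "pre")
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$ground_truth, b$ground_truth)
  # different session draws a different stream
  c_ <- generate_recording(cfg, 1, "post")
  expect_false(identical(a$ground_truth, c_$ground_truth))
})

test_that("zero rates give an empty ground truth and pure background", {
  cfg <- detection_config(32, hfo_rate_area_pre = 0,
                          hfo_rate_background = 0)
  ses <- generate_recording(cfg, 1, "pre")
  expect_equal(nrow(ses$ground_truth), 0L)
  # pure 1/f background at the configured RMS
  expect_equal(sd(ses$recording$samples[, "Cz"]), 1.5, tolerance = 0.05)
})

test_that("per-channel event counts are Poisson with the configured rate", {
  # hot channel at 2/min over one 5-min interval: mean count 10;
  # empirical mean over 200 seeded draws within 3 standard errors
  counts <- vapply(1:200, function(s) {
    cfg <- sim_config(seed = s, n_intervals_per_session = 1L,
                      interval_s = 300, hfo_rate_area_pre = 2,
                      hfo_rate_background = 0,
                      artifact_rates = c(amplitude = 0, fastripple = 0,
                                         bilateral = 0))
    gt <- generate_recording(cfg, 1, "pre", signals = FALSE)$ground_truth
    sum(gt$class == "true_hfo" & gt$channel == "F3-C3")
  }, 0L)
  se <- sqrt(10 / 200)
  expect_lt(abs(mean(counts) - 10), 3 * se)
  expect_equal(var(counts), 10, tolerance = 0.35)   # Poisson dispersion
})

test_that("invalid configurations are refused", {
  expect_error(sim_config(event_freq_range = c(70, 220)), "ripple band")
  expect_error(sim_config(event_freq_range = c(90, 260)), "ripple band")
  expect_error(sim_config(post_rate_multiplier_engel1 = -0.1))
  expect_error(sim_config(n_patients = 1))
  expect_error(sim_config(event_duration_range = c(0, 0.1)))
  cfg <- sim_config()
  expect_error(generate_recording(cfg, 1, "pre", hot_rate = -1))
  bad <- sim_config(hot_channels = "C3-O2")
  expect_error(generate_recording(bad, 1, "pre"), "not in montage")
})

test_that("true events lie inside intervals; bilateral artifacts pair up", {
  cfg <- detection_config(33, n_intervals_per_session = 2L,
                          hfo_rate_area_pre = 3,
                          artifact_rates = c(amplitude = 0, fastripple = 0,
                                             bilateral = 2))
  ses <- generate_recording(cfg, 1, "pre", signals = FALSE)
  gt <- ses$ground_truth
  expect_true(all(gt$onset_s >= 0 & gt$offset_s <= 120))
  expect_true(all(gt$offset_s > gt$onset_s))
  bil <- gt[gt$class == "artifact_bilateral", ]
  expect_equal(nrow(bil) %% 2, 0)
  m <- default_montage()
  for (i in which(duplicated(bil$onset_s) == FALSE)) {
    twin <- bil[bil$onset_s == bil$onset_s[i], ]
    expect_equal(nrow(twin), 2L)
    expect_equal(homologous_channel(m, twin$channel[1]), twin$channel[2])
    expect_true(twin$onset_s[1] < twin$offset_s[2] &&
                  twin$onset_s[2] < twin$offset_s[1])
  }
})

test_that("realized bipolar envelope SNR is within 20% of the drawn target", {
  cfg <- detection_config(34, hfo_rate_area_pre = 2)
  ses <- generate_recording(cfg, 1, "pre")
  gt <- ses$ground_truth
  # keep events that do not overlap any other event
  keep <- vapply(seq_len(nrow(gt)), function(i)
    !any(gt$onset_s[-i] < gt$offset_s[i] + 0.3 &
           gt$offset_s[-i] > gt$onset_s[i] - 0.3), TRUE)
  gt <- gt[keep & gt$class == "true_hfo", ]
  expect_gt(nrow(gt), 0)
  m <- default_montage()
  fs <- cfg$sampling_rate
  bip <- rereference(ses$recording, m)
  for (i in seq_len(nrow(gt))) {
    x <- bip$samples[, gt$channel[i]]
    env <- envelope(bandpass_filter(x, fs, c(80, 250)))
    span <- (floor(gt$onset_s[i] * fs) + 1L):ceiling(gt$offset_s[i] * fs)
    around <- max(1, span[1] - fs):min(length(x), span[length(span)] + fs)
    baseline <- median(env[setdiff(around, span)])
    realized <- max(env[span]) / baseline
    expect_lt(abs(realized - gt$snr[i]) / gt$snr[i], 0.2)
  }
})

test_that("cohort composition, outcome link and post rates follow the config", {
  cfg <- sim_config(seed = 35)
  coh <- generate_cohort(cfg, signals = FALSE)
  tab <- coh$cohort_table
  expect_equal(nrow(tab), 14L)
  expect_equal(sum(tab$engel == "Ia"), 10L)
  expect_equal(sum(tab$engel %in% c("II", "III", "IV")), 4L)
  # post seizure frequency is zero exactly for Engel I
  expect_true(all(tab$seizure_freq_post[tab$engel == "Ia"] == 0))
  expect_true(all(tab$seizure_freq_post[tab$engel != "Ia"] > 0))
  # post hot rates scaled by the outcome multiplier
  expect_equal(tab$hot_rate_post[tab$engel == "Ia"],
               0.05 * tab$hot_rate_pre[tab$engel == "Ia"])
  expect_equal(tab$hot_rate_post[tab$engel != "Ia"],
               tab$hot_rate_pre[tab$engel != "Ia"])
  # monotone link: noise-free config gives rank correlation exactly 1
  cfg0 <- sim_config(seed = 36, seizure_freq_noise_sd = 0)
  tab0 <- generate_cohort(cfg0, signals = FALSE)$cohort_table
  expect_equal(cor(tab0$hot_rate_pre, tab0$seizure_freq_pre,
                   method = "spearman"), 1)
  expect_error(generate_cohort(sim_config(n_patients = 3, n_engel1 = 3)))
})

test_that("configs load from YAML with validation", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 5", "n_patients: 6", "n_engel1: 4",
               "hfo_rate_area_pre: 1.5",
               "artifact_rates: {amplitude: 0, fastripple: 0, bilateral: 0}"),
             f)
  cfg <- sim_config_from_yaml(f)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_patients, 6)
  expect_equal(cfg$hfo_rate_area_pre, 1.5)
  expect_equal(cfg$sampling_rate, 1024)          # default retained
  writeLines("not_a_field: 3", f)
  expect_error(sim_config_from_yaml(f), "unknown config field")
})

test_that("cohort generation is deterministic given the seed", {
  cfg <- sim_config(seed = 37)
  t1 <- generate_cohort(cfg, signals = FALSE)
  t2 <- generate_cohort(cfg, signals = FALSE)
  expect_identical(t1$cohort_table, t2$cohort_table)
  expect_identical(t1$sessions$p03$post$ground_truth,
                   t2$sessions$p03$post$ground_truth)
})

test_that("head geometry honors the 10-20 placement constraints", {
  cfg <- sim_config(defect_center_electrode = "C3", defect_radius = 2)
  h <- generate_head_geometry(cfg)
  el <- h$electrodes
  # all electrodes on the sphere
  expect_equal(unname(sqrt(rowSums(el^2))), rep(9, 21), tolerance = 1e-9)
  # mirror symmetry through the midsagittal plane to 1e-9 cm
  for (lab in c("F3", "F7", "Fp1", "T3", "C3", "T5", "P3", "O1", "A1")) {
    mir <- el[lab, ] * c(-1, 1, 1)
    expect_equal(unname(mir), unname(el[mirror_electrode(lab), ]),
                 tolerance = 1e-9)
  }
  # midline electrodes on the sagittal plane
  expect_equal(unname(el[c("Fz", "Cz", "Pz"), "x"]), rep(0, 3),
               tolerance = 1e-9)
  # defect boundary: >= 64 points, all on the sphere, centered at C3
  expect_gte(nrow(h$defect_boundary), 64L)
  expect_equal(unname(sqrt(rowSums(h$defect_boundary^2))),
               rep(9, nrow(h$defect_boundary)), tolerance = 1e-9)
  d <- electrode_defect_distances(h)
  expect_equal(d[["C3"]], 2, tolerance = 0.01)   # chord vs geodesic radius
  expect_true("C3" %in% classify_defect_electrodes(h))
  expect_error(head_model("Oz", 2), "unknown")
  expect_error(head_model("C3", -1), "defect_radius")
  # degenerate fiducials are refused
  fid <- rbind(nasion = c(0, 9, 0), inion = c(0, -9, 0),
               tragus_left = c(0, 4, 0), tragus_right = c(0, -4, 0))
  expect_error(place_electrodes_1020(9, fid), "degenerate")
})
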