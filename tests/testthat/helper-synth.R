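# Shared fixtures for the detector tests.
#
# Detection studies use a quiet background (1.5 uV RMS) with target SNR
# 12-20 so that injected events satisfy both sides of the stage-III rules:
# ripple-band peak-to-peak stays below 40 uV while power SNR stays far
# above 9. Intervals are 60 s to keep signal synthesis and the S-transform
# affordable at full channel count.

detection_config <- function(seed, ...) {
  defaults <- list(seed = seed, n_intervals_per_session = 1L,
                   interval_s = 30, background_amplitude = 1.5,
                   event_snr_range = c(12, 20), hfo_rate_area_pre = 4,
                   hfo_rate_background = 0,
                   artifact_rates = c(amplitude = 0, fastripple = 0,
                                      bilateral = 0))
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# channels neighboring the default hot channel F3-C3 plus their mirrors:
# the set an injected F3/C3 burst can physically reach, and the homologous
# channels the bilateral rule needs
hot_neighborhood <- function(montage = default_montage()) {
  chs <- montage$channel[montage$e1 %in% c("F3", "C3") |
                         montage$e2 %in% c("F3", "C3")]
  unique(c(chs, homologous_channel(montage, chs)))
}

# deterministic pink-noise channel for detector unit tests
test_noise <- function(seed, seconds = 20, fs = 1024, rms = 15,
                       exponent = 1) {
  set.seed(seed)
  scalphfo:::pink_noise(seconds * fs, fs, exponent, rms)
}

# Gaussian-windowed sinusoid burst, amplitude in uV
test_burst <- function(n, fs, t0, freq, dur, amp) {
  scalphfo:::gauss_burst(n, fs, t0, freq, dur, amp)
}

# exhaustive sign-flip oracle for the signed-rank test: two-sided p-value
# of W+ over all 2^n equally likely sign assignments (zero differences
# removed beforehand)
exact_signedrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}
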