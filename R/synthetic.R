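#' Configuration of the synthetic cohort generator
#'
#' Defines a seeded synthetic study: per-patient pre/post-surgical scalp
#' EEG sessions with 1/f background, ripple-band HFO bursts injected on the
#' designated hot channels, three artifact classes, a spherical head with a
#' craniotomy defect patch, and an outcome table in which seizure frequency
#' increases monotonically with the patient's hot-channel HFO rate.
#'
#' @param seed master integer seed; identical seed + config give
#'   bit-identical signals, event lists and tables.
#' @param n_patients number of patients (>= 2).
#' @param n_engel1 how many patients are seizure-free (Engel Ia) after
#'   surgery; the rest draw Engel II-IV.
#' @param sampling_rate Hz (> 1000 per the inclusion criterion).
#' @param n_intervals_per_session number of analysis intervals per session.
#' @param interval_s interval length in seconds (default 300).
#' @param background_amplitude background RMS in uV.
#' @param background_exponent spectral slope of the 1/f^a background.
#' @param hfo_rate_area_pre presurgical true-HFO rate on hot channels,
#'   events/min.
#' @param hfo_rate_background true-HFO rate elsewhere, events/min.
#' @param post_rate_multiplier_engel1 post/pre hot-channel rate ratio for
#'   seizure-free patients (default 0.05).
#' @param post_rate_multiplier_engel24 same for Engel II-IV (default 1).
#' @param event_freq_range true-event frequency range, Hz; must lie inside
#'   the ripple band (80, 250).
#' @param event_duration_range true-event duration range, s.
#' @param event_snr_range target envelope SNR range (ripple-band envelope
#'   peak over local baseline envelope).
#' @param artifact_rates named events/min: \code{amplitude} (high-amplitude
#'   bursts), \code{fastripple} (broadband spikes with strong 250-500 Hz
#'   content), \code{bilateral} (simultaneous homologous-pair bursts).
#' @param hot_channels bipolar channel names designated as the HFO area.
#' @param defect_center_electrode,defect_radius craniotomy patch, cm.
#' @param seizure_freq_coef,seizure_freq_noise_sd log-linear link from the
#'   hot-channel rate to presurgical seizure frequency:
#'   \code{freq = exp(a + b log(rate) + N(0, sd))}.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_patients = 14L, n_engel1 = 10L,
                       sampling_rate = 1024, n_intervals_per_session = 2L,
                       interval_s = 300, background_amplitude = 15,
                       background_exponent = 1.0, hfo_rate_area_pre = 2,
                       hfo_rate_background = 0.05,
                       post_rate_multiplier_engel1 = 0.05,
                       post_rate_multiplier_engel24 = 1.0,
                       event_freq_range = c(90, 220),
                       event_duration_range = c(0.04, 0.1),
                       event_snr_range = c(10, 25),
                       artifact_rates = c(amplitude = 0.1, fastripple = 0.1,
                                          bilateral = 0.1),
                       hot_channels = "F3-C3",
                       defect_center_electrode = "C3", defect_radius = 2,
                       seizure_freq_coef = c(a = log(10), b = 1),
                       seizure_freq_noise_sd = 0.3) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_patients >= 2, cfg$n_engel1 >= 1,
            cfg$n_engel1 < cfg$n_patients,
            cfg$hfo_rate_area_pre >= 0, cfg$hfo_rate_background >= 0,
            all(cfg$artifact_rates >= 0),
            cfg$post_rate_multiplier_engel1 >= 0,
            cfg$post_rate_multiplier_engel24 >= 0,
            cfg$event_duration_range[1] > 0)
  if (cfg$event_freq_range[1] <= 80 || cfg$event_freq_range[2] >= 250)
    stop("event_freq_range must lie strictly inside the ripple band (80, 250) Hz")
  if (!all(c("amplitude", "fastripple", "bilateral") %in%
           names(cfg$artifact_rates)))
    stop("artifact_rates needs named entries amplitude, fastripple, bilateral")
  class(cfg) <- "sim_config"
  cfg
}

# deterministic per-(patient, session) RNG seed below 2^31
session_seed <- function(config, patient_index, session) {
  (config$seed * 10007L + patient_index * 131L +
     as.integer(session == "post")) %% 2000000000L
}

# 1/f^a Gaussian noise scaled to a target RMS
pink_noise <- function(n, fs, exponent, rms) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- seq(0, n - 1) / n * fs
  f[f > fs / 2] <- fs - f[f > fs / 2]
  g <- c(0, 1 / f[-1]^(exponent / 2))    # zero out DC
  x <- Re(stats::fft(X * g, inverse = TRUE) / n)
  x / stats::sd(x) * rms
}

gauss_burst <- function(n, fs, t0, freq, dur, amp) {
  t <- (seq_len(n) - 1) / fs
  sigma <- dur / 6
  amp * exp(-(t - t0)^2 / (2 * sigma^2)) * sin(2 * pi * freq * (t - t0))
}

# broadband biphasic spike (derivative of a Gaussian), width w seconds
spike_transient <- function(n, fs, t0, w, amp) {
  t <- (seq_len(n) - 1) / fs
  u <- (t - t0) / w
  amp * (-u) * exp(-u^2 / 2) * exp(0.5)   # peak amplitude = amp
}

draw_events_one_class <- function(rate, minutes, iv_start, iv_len, channel,
                                  class, config) {
  n <- stats::rpois(1, rate * minutes)
  if (n == 0L) return(NULL)
  dur <- stats::runif(n, config$event_duration_range[1],
                      config$event_duration_range[2])
  onset <- stats::runif(n, 0.5, iv_len - 0.5 - max(dur))
  data.frame(channel = channel,
             onset_s = iv_start + onset, offset_s = iv_start + onset + dur,
             class = class,
             freq_hz = stats::runif(n, config$event_freq_range[1],
                                    config$event_freq_range[2]),
             snr = stats::runif(n, config$event_snr_range[1],
                                config$event_snr_range[2]),
             amplitude_uV = NA_real_, stringsAsFactors = FALSE)
}

#' Generate one synthetic session
#'
#' Draws the ground-truth event list first (true HFO on hot channels and,
#' at the background rate, elsewhere; the three artifact classes), then
#' synthesizes the referential signals: independent 1/f background per
#' electrode plus Gaussian-windowed sinusoid bursts added to exactly one
#' electrode of each target bipolar pair, so the bipolar derivation carries
#' the event unambiguously. Each true event's amplitude is calibrated so
#' that the bipolar ripple-band envelope peak divided by the local baseline
#' envelope equals the drawn SNR.
#'
#' @param config a \code{sim_config}.
#' @param patient_index 1-based patient number (drives the derived seed).
#' @param session "pre" or "post".
#' @param hot_rate true-HFO rate on hot channels for this session
#'   (default: the config's presurgical rate).
#' @param signals if FALSE, skip signal synthesis and return only the
#'   ground truth (fast path for statistics-level simulations).
#' @param montage bipolar montage (default the shipped 52-channel one).
#' @return list of class \code{synthetic_session}: \code{recording} (an
#'   \code{eeg_recording} with a single all-covering N3 annotation, or NULL
#'   when \code{signals = FALSE}), \code{ground_truth} (event data.frame
#'   with class labels), \code{hot_channels}.
#' @export
generate_recording <- function(config, patient_index = 1L,
                               session = c("pre", "post"),
                               hot_rate = config$hfo_rate_area_pre,
                               signals = TRUE,
                               montage = default_montage()) {
  session <- match.arg(session)
  stopifnot(inherits(config, "sim_config"), hot_rate >= 0)
  unknown <- setdiff(config$hot_channels, montage$channel)
  if (length(unknown))
    stop("hot channel(s) not in montage: ", paste(unknown, collapse = ", "))
  set.seed(session_seed(config, patient_index, session))
  fs <- config$sampling_rate
  iv_len <- config$interval_s
  n_iv <- config$n_intervals_per_session
  total_s <- iv_len * n_iv
  minutes <- iv_len / 60

  ev <- list(); k <- 0L
  lateral <- montage$channel[montage$homologous != montage$channel]
  for (i in seq_len(n_iv)) {
    iv0 <- (i - 1) * iv_len
    for (ch in montage$channel) {
      rate <- if (ch %in% config$hot_channels) hot_rate
              else config$hfo_rate_background
      if (rate > 0) {
        e <- draw_events_one_class(rate, minutes, iv0, iv_len, ch,
                                   "true_hfo", config)
        if (!is.null(e)) { k <- k + 1L; ev[[k]] <- e }
      }
    }
    # artifact classes on uniformly drawn channels
    for (cls in c("amplitude", "fastripple", "bilateral")) {
      pool <- if (cls == "bilateral") lateral else montage$channel
      rate <- config$artifact_rates[[cls]]
      n_art <- stats::rpois(1, rate * minutes)
      for (j in seq_len(n_art)) {
        ch <- sample(pool, 1)
        dur <- stats::runif(1, 0.05, 0.1)
        onset <- iv0 + stats::runif(1, 0.5, iv_len - 1)
        base <- data.frame(channel = ch, onset_s = onset,
                           offset_s = onset + dur,
                           class = paste0("artifact_", cls),
                           freq_hz = stats::runif(1, 100, 200),
                           snr = NA_real_, amplitude_uV = NA_real_,
                           stringsAsFactors = FALSE)
        k <- k + 1L; ev[[k]] <- base
        if (cls == "bilateral") {
          twin <- base
          twin$channel <- homologous_channel(montage, ch)
          k <- k + 1L; ev[[k]] <- twin
        }
      }
    }
  }
  gt <- if (k) do.call(rbind, ev) else
    data.frame(channel = character(0), onset_s = numeric(0),
               offset_s = numeric(0), class = character(0),
               freq_hz = numeric(0), snr = numeric(0),
               amplitude_uV = numeric(0), stringsAsFactors = FALSE)
  if (nrow(gt)) {
    gt <- cbind(patient = sprintf("p%02d", patient_index),
                session = session, gt, stringsAsFactors = FALSE)
  } else {
    gt$patient <- character(0); gt$session <- character(0)
  }

  recording <- NULL
  if (signals) {
    n <- total_s * fs
    labs <- electrode_labels()
    X <- matrix(0, n, length(labs), dimnames = list(NULL, labs))
    for (el in labs)
      X[, el] <- pink_noise(n, fs, config$background_exponent,
                            config$background_amplitude)
    # event amplitude calibration needs the bipolar ripple envelope of the
    # background; compute it once per channel that carries events
    carriers <- unique(gt$channel)
    for (ch in carriers) {
      m <- montage[montage$channel == ch, ]
      bg_bip <- X[, m$e1] - X[, m$e2]
      env_bg <- envelope(bandpass_filter(bg_bip, fs, c(80, 250)))
      rows_ch <- which(gt$channel == ch)
      for (r in rows_ch) {
        t0 <- (gt$onset_s[r] + gt$offset_s[r]) / 2
        i0 <- max(1, floor((t0 - 1) * fs)); i1 <- min(n, ceiling((t0 + 1) * fs))
        local_env <- stats::median(env_bg[i0:i1])
        dur <- gt$offset_s[r] - gt$onset_s[r]
        cls <- gt$class[r]
        if (cls == "true_hfo") {
          amp <- gt$snr[r] * local_env
          burst <- gauss_burst(n, fs, t0, gt$freq_hz[r], dur, amp)
        } else if (cls == "artifact_amplitude") {
          amp <- 80                     # well above the 40 uV rule
          burst <- gauss_burst(n, fs, t0, gt$freq_hz[r], dur, amp)
        } else if (cls == "artifact_fastripple") {
          amp <- 60 * local_env         # sharp broadband transient
          burst <- spike_transient(n, fs, t0, 0.003, amp)
        } else {                        # bilateral: ordinary strong burst
          amp <- 15 * local_env
          burst <- gauss_burst(n, fs, t0, gt$freq_hz[r], dur, amp)
        }
        gt$amplitude_uV[r] <- amp
        X[, m$e1] <- X[, m$e1] + burst
      }
    }
    ann <- data.frame(start_s = 0, end_s = total_s, stage = "N3")
    recording <- eeg_recording(X, fs,
                               patient_id = sprintf("p%02d", patient_index),
                               session = session, annotations = ann)
  }
  structure(list(recording = recording, ground_truth = gt,
                 hot_channels = config$hot_channels, config = config,
                 patient_index = patient_index, session = session),
            class = "synthetic_session")
}

#' Generate a full synthetic cohort
#'
#' Draws per-patient outcome structure (Engel class, hot-channel rate,
#' seizure frequencies, follow-up) and the pre and post sessions of every
#' patient. Presurgical seizure frequency is log-linear in the patient's
#' hot-channel rate (monotone before noise), postsurgical frequency is 0
#' for Engel I and remains positive for Engel II-IV; postsurgical
#' hot-channel rates are scaled by the outcome's multiplier.
#'
#' @param config a \code{sim_config}.
#' @param signals synthesize signals (TRUE) or ground truth only (FALSE).
#' @return list of class \code{synthetic_cohort}: \code{sessions} (list of
#'   per-patient lists with \code{pre} and \code{post}
#'   \code{synthetic_session}s), \code{cohort_table} (one row per patient:
#'   patient, engel, hot_rate_pre, hot_rate_post, seizure_freq_pre,
#'   seizure_freq_post, followup_years, defect_center_electrode),
#'   \code{head} (the shared \code{head_model}), \code{config}.
#' @export
generate_cohort <- function(config = sim_config(), signals = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  np <- config$n_patients
  engel <- c(rep("Ia", config$n_engel1),
             sample(c("II", "III", "IV"), np - config$n_engel1,
                    replace = TRUE))
  rate_noise <- stats::rlnorm(np, 0, 0.4)
  hot_pre <- config$hfo_rate_area_pre * rate_noise
  a <- config$seizure_freq_coef[["a"]]; b <- config$seizure_freq_coef[["b"]]
  sf_noise <- stats::rnorm(np, 0, config$seizure_freq_noise_sd)
  sf_pre <- exp(a + b * log(hot_pre) + sf_noise)
  mult <- ifelse(engel == "Ia", config$post_rate_multiplier_engel1,
                 config$post_rate_multiplier_engel24)
  hot_post <- hot_pre * mult
  sf_post <- ifelse(engel == "Ia", 0, sf_pre * stats::runif(np, 0.5, 1.5))
  followup <- round(stats::runif(np, 1.0, 4.8), 1)
  tab <- data.frame(patient = sprintf("p%02d", seq_len(np)), engel = engel,
                    hot_rate_pre = hot_pre, hot_rate_post = hot_post,
                    seizure_freq_pre = sf_pre, seizure_freq_post = sf_post,
                    followup_years = followup,
                    defect_center_electrode = config$defect_center_electrode,
                    stringsAsFactors = FALSE)
  sessions <- lapply(seq_len(np), function(i) {
    list(pre = generate_recording(config, i, "pre", hot_rate = hot_pre[i],
                                  signals = signals),
         post = generate_recording(config, i, "post", hot_rate = hot_post[i],
                                   signals = signals))
  })
  names(sessions) <- tab$patient
  structure(list(sessions = sessions, cohort_table = tab,
                 head = generate_head_geometry(config), config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tb <- table(x$cohort_table$engel)
  cat(sprintf("Synthetic cohort: %d patients (%s), hot channels {%s}\n",
              nrow(x$cohort_table),
              paste(sprintf("%s:%d", names(tb), tb), collapse = ", "),
              paste(x$config$hot_channels, collapse = ", ")))
  invisible(x)
}

#' Load a simulation configuration from a YAML file
#'
#' Reads a flat YAML mapping of \code{\link{sim_config}} argument names to
#' values and builds the config; unnamed fields keep their defaults.
#' Requires the \code{yaml} package.
#'
#' @param path YAML file path.
#' @return A \code{sim_config}.
#' @export
sim_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configs")
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(vals$artifact_rates))
    vals$artifact_rates <- unlist(vals$artifact_rates)
  if (!is.null(vals$seizure_freq_coef))
    vals$seizure_freq_coef <- unlist(vals$seizure_freq_coef)
  do.call(sim_config, vals)
}

#' Spherical head geometry for a simulation config
#'
#' @param config a \code{sim_config}.
#' @param radius sphere radius in cm.
#' @param n_boundary defect boundary discretization (>= 64).
#' @return a \code{head_model} (see \code{\link{head_model}}).
#' @export
generate_head_geometry <- function(config, radius = 9, n_boundary = 64L) {
  head_model(config$defect_center_electrode, config$defect_radius,
             radius = radius, n_boundary = n_boundary)
}

#' Interval table of a synthetic session
#'
#' Convenience wrapper: the analysis intervals a synthetic session was
#' built around (its generation grid), without needing the signals.
#'
#' @param session a \code{synthetic_session} (or a \code{sim_config}).
#' @return data.frame as from \code{\link{select_intervals}}.
#' @export
synthetic_intervals <- function(session) {
  config <- if (inherits(session, "sim_config")) session else session$config
  n_iv <- config$n_intervals_per_session
  data.frame(interval_id = sprintf("iv%02d", seq_len(n_iv)),
             start_s = (seq_len(n_iv) - 1) * config$interval_s,
             end_s = seq_len(n_iv) * config$interval_s,
             stage = "N3", minutes = config$interval_s / 60,
             partial = FALSE, stringsAsFactors = FALSE)
}

#' Rate table from ground-truth events
#'
#' Builds the per-channel rate table directly from a session's true-HFO
#' ground-truth events (detector bypass, used for statistics-level
#' simulations).
#'
#' @param session a \code{synthetic_session}.
#' @param montage bipolar montage.
#' @return an \code{hfo_rate_table}.
#' @export
ground_truth_rates <- function(session, montage = default_montage()) {
  gt <- session$ground_truth
  gt <- gt[gt$class == "true_hfo", , drop = FALSE]
  iv <- synthetic_intervals(session)
  gt$interval_id <- iv$interval_id[findInterval(gt$onset_s, iv$start_s)]
  compute_rates(gt, iv, channels = montage$channel)
}
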