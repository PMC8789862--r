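#' Detector parameters
#'
#' All tunable constants of the three-stage HFO detector. The printed study
#' thresholds are the defaults of \code{amplitude_reject_uV} (40 uV
#' peak-to-peak on the ripple-band trace), \code{snr_reject} (9, linear
#' power ratio) and \code{zscore_iqr_factor} (1.5 x iqr above the median
#' z-score of the 250-500 Hz envelope). The remaining constants (entropy
#' quantile, baseline envelope quantile, minimum duration, merge gap,
#' stage-2 trough fraction) parameterize detector internals and are
#' deliberately exposed here.
#'
#' @param ripple_band HFO passband in Hz (default 80-250).
#' @param fr_band fast-ripple band used only by the artifact z-score rule
#'   (default 250-500 Hz).
#' @param entropy_window_s window length for the Stockwell-entropy baseline
#'   search (s).
#' @param entropy_quantile fraction of the theoretical maximum entropy
#'   log(n_freqs) above which a window counts as baseline.
#' @param baseline_envelope_quantile quantile of the ripple envelope over
#'   baseline windows that sets the event threshold.
#' @param min_event_duration_s minimum accepted event duration (s).
#' @param merge_gap_s threshold crossings closer than this are merged (s).
#' @param amplitude_reject_uV reject events with ripple-band peak-to-peak
#'   amplitude greater than or equal to this (uV).
#' @param snr_reject reject events whose ripple power SNR is below this.
#' @param zscore_iqr_factor multiple of the iqr above the median z-score of
#'   the fast-ripple envelope beyond which event samples mark an artifact.
#' @param freq_step_hz frequency grid step for the S-transform (Hz).
#' @param stage2_low_freq_hz lower edge of the stage-2 validation spectrum;
#'   the spectrum must dip below \code{stage2_trough_fraction} of the peak
#'   somewhere below the peak frequency for the event to count as isolated.
#' @param stage2_trough_fraction trough acceptance fraction (inclusive).
#' @param n_baseline_ref number of nearest baseline windows used as the SNR
#'   noise reference.
#' @param fir_order order of the zero-phase FIR band-pass filters.
#' @return A list of class \code{detector_params}.
#' @export
detector_params <- function(ripple_band = c(80, 250), fr_band = c(250, 500),
                            entropy_window_s = 1.0, entropy_quantile = 0.90,
                            baseline_envelope_quantile = 0.995,
                            min_event_duration_s = 0.02, merge_gap_s = 0.01,
                            amplitude_reject_uV = 40, snr_reject = 9,
                            zscore_iqr_factor = 1.5, freq_step_hz = 5,
                            stage2_low_freq_hz = 40,
                            stage2_trough_fraction = 0.5,
                            n_baseline_ref = 5, fir_order = 256L) {
  p <- list(ripple_band = ripple_band, fr_band = fr_band,
            entropy_window_s = entropy_window_s,
            entropy_quantile = entropy_quantile,
            baseline_envelope_quantile = baseline_envelope_quantile,
            min_event_duration_s = min_event_duration_s,
            merge_gap_s = merge_gap_s,
            amplitude_reject_uV = amplitude_reject_uV,
            snr_reject = snr_reject,
            zscore_iqr_factor = zscore_iqr_factor,
            freq_step_hz = freq_step_hz,
            stage2_low_freq_hz = stage2_low_freq_hz,
            stage2_trough_fraction = stage2_trough_fraction,
            n_baseline_ref = n_baseline_ref, fir_order = fir_order)
  stopifnot(p$ripple_band[1] > 0, p$ripple_band[2] > p$ripple_band[1],
            p$amplitude_reject_uV > 0, p$snr_reject > 0,
            p$zscore_iqr_factor > 0, p$min_event_duration_s > 0)
  class(p) <- "detector_params"
  p
}

# runs of TRUE in a logical vector -> matrix of (start, end) indices
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# merge runs separated by gaps shorter than gap_n samples
merge_runs <- function(runs, gap_n) {
  if (nrow(runs) <= 1L) return(runs)
  out <- runs[1, , drop = FALSE]
  for (i in 2:nrow(runs)) {
    if (runs[i, "start"] - out[nrow(out), "end"] - 1L < gap_n) {
      out[nrow(out), "end"] <- runs[i, "end"]
    } else {
      out <- rbind(out, runs[i, , drop = FALSE])
    }
  }
  out
}

#' Stage I: baseline detection and events of interest
#'
#' Splits the signal into windows, computes the spectral entropy of the
#' normalized ripple-band Stockwell power in each, and takes
#' high-entropy (oscillation-free) windows as baseline. The event threshold
#' is a high quantile of the ripple-band analytic envelope over baseline
#' samples; events of interest (EoI) are the threshold crossings of minimum
#' duration, after merging across short gaps.
#'
#' @param x one channel's signal for one analysis interval (uV).
#' @param fs sampling rate (Hz).
#' @param params a \code{detector_params}.
#' @param S optional precomputed Stockwell power for this signal (voices x
#'   time, attribute \code{freqs}); computed if missing.
#' @return list with \code{eoi} (data.frame onset_s / offset_s),
#'   \code{threshold}, \code{envelope}, \code{baseline_windows}
#'   (data.frame of window start/end sample indices and entropy flags).
#' @export
stage1_detect <- function(x, fs, params = detector_params(), S = NULL) {
  n <- length(x)
  win_n <- round(params$entropy_window_s * fs)
  if (n < win_n) stop("interval shorter than the entropy window")
  filtered <- bandpass_filter(x, fs, params$ripple_band, params$fir_order)
  env <- envelope(filtered)
  if (is.null(S)) {
    freqs <- seq(params$ripple_band[1], params$ripple_band[2],
                 by = params$freq_step_hz)
    S <- stockwell_transform(x, fs, freqs)
  }
  fhz <- attr(S, "freqs")
  in_band <- fhz >= params$ripple_band[1] & fhz <= params$ripple_band[2]
  P <- Mod(S[in_band, , drop = FALSE])^2
  nf <- sum(in_band)
  n_win <- floor(n / win_n)
  ent <- numeric(n_win)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1L) * win_n + 1L):(w * win_n)
    pw <- rowSums(P[, idx, drop = FALSE])
    tot <- sum(pw)
    if (tot <= 0) { ent[w] <- log(nf); next }   # silent window: flat spectrum
    p <- pw / tot
    p <- p[p > 0]
    ent[w] <- -sum(p * log(p))
  }
  is_base <- ent >= params$entropy_quantile * log(nf)
  if (!any(is_base))
    stop("no baseline window found: signal is oscillatory or artifactual throughout")
  base_idx <- unlist(lapply(which(is_base), function(w)
    ((w - 1L) * win_n + 1L):(w * win_n)))
  threshold <- as.numeric(stats::quantile(env[base_idx],
                                          params$baseline_envelope_quantile,
                                          type = 7))
  above <- env > threshold
  runs <- logical_runs(above)
  eoi <- data.frame(onset_s = numeric(0), offset_s = numeric(0))
  if (nrow(runs)) {
    runs <- merge_runs(runs, max(1L, round(params$merge_gap_s * fs)))
    dur <- (runs[, "end"] - runs[, "start"] + 1L) / fs
    runs <- runs[dur >= params$min_event_duration_s, , drop = FALSE]
    if (nrow(runs))
      eoi <- data.frame(onset_s = (runs[, "start"] - 1L) / fs,
                        offset_s = runs[, "end"] / fs)
  }
  list(eoi = eoi, threshold = threshold, envelope = env,
       filtered = filtered,
       baseline_windows = data.frame(
         window = seq_len(n_win),
         start_s = (seq_len(n_win) - 1L) * win_n / fs,
         end_s = seq_len(n_win) * win_n / fs,
         entropy = ent, baseline = is_base))
}

#' Stage II: time-frequency validation of an event of interest
#'
#' An EoI is validated as an HFO when its time-averaged Stockwell power
#' spectrum has a local maximum at a ripple-band frequency that is isolated
#' from low-frequency activity: some frequency below the peak must carry no
#' more than \code{stage2_trough_fraction} (inclusive) of the peak power.
#'
#' @param P time-averaged power spectrum over the event span (numeric).
#' @param freqs frequencies (Hz) of \code{P}, spanning from below the
#'   ripple band up to its upper edge.
#' @param params a \code{detector_params}.
#' @return list \code{accepted} (logical) and \code{peak_freq_hz} (NA when
#'   rejected).
#' @export
stage2_validate <- function(P, freqs, params = detector_params()) {
  in_band <- freqs >= params$ripple_band[1] & freqs <= params$ripple_band[2]
  nfr <- length(freqs)
  # local maxima on the full grid (ends count with one-sided comparison)
  left <- c(-Inf, P[-nfr]); right <- c(P[-1], -Inf)
  is_max <- P >= left & P >= right & (P > left | P > right)
  cand <- which(is_max & in_band)
  if (!length(cand)) return(list(accepted = FALSE, peak_freq_hz = NA_real_))
  cand <- cand[order(P[cand], decreasing = TRUE)]
  for (i in cand) {
    if (i == 1L) next                       # nothing below the peak to dip
    if (min(P[1:(i - 1L)]) <= params$stage2_trough_fraction * P[i])
      return(list(accepted = TRUE, peak_freq_hz = freqs[i]))
  }
  list(accepted = FALSE, peak_freq_hz = NA_real_)
}

# per-channel z-score rejection threshold on the fast-ripple envelope
fr_zscore <- function(x, fs, params) {
  band <- c(params$fr_band[1], min(params$fr_band[2], 0.97 * fs / 2))
  env_fr <- envelope(bandpass_filter(x, fs, band, params$fir_order))
  z <- as.numeric(scale(env_fr))
  if (all(!is.finite(z))) z <- rep(0, length(env_fr))   # constant signal
  list(z = z, cutoff = stats::median(z) + params$zscore_iqr_factor * stats::IQR(z))
}

#' Stage III: artifact rejection
#'
#' Applies the four rejection rules to stage-II-validated events:
#' bilateral co-occurrence on homologous channels (any temporal overlap),
#' ripple-band peak-to-peak amplitude >= 40 uV, SNR < 9 (event peak ripple
#' power over the mean ripple power of the nearest baseline windows), and
#' the fast-ripple envelope z-score rule: an event occurring at a
#' high-z-score timepoint -- its ripple-envelope peak sample's 250-500 Hz
#' envelope z-score exceeding the channel's median + 1.5 iqr over the
#' analyzed data -- is rejected as a broadband artifact.
#'
#' Operates on the annotated event table produced inside
#' \code{\link{detect_hfo}}; exported for direct use on pre-computed event
#' metrics.
#'
#' @param events data.frame with columns channel, onset_s, offset_s,
#'   pp_uV, snr, zmax_excess (max event z minus the channel cutoff).
#' @param montage a \code{bipolar_montage} (for the homologous mapping).
#' @param params a \code{detector_params}.
#' @return the event table with logical columns \code{rejected_bilateral},
#'   \code{rejected_amplitude}, \code{rejected_snr},
#'   \code{rejected_zscore} and a \code{status} column.
#' @export
stage3_reject <- function(events, montage, params = detector_params()) {
  n <- nrow(events)
  events$rejected_amplitude <- events$pp_uV >= params$amplitude_reject_uV
  events$rejected_snr <- events$snr < params$snr_reject
  events$rejected_zscore <- events$zmax_excess > 0
  events$rejected_bilateral <- rep(FALSE, n)
  if (n) {
    hom <- homologous_channel(montage, events$channel)
    for (i in seq_len(n)) {
      if (hom[i] == events$channel[i]) next    # midline channels have no mirror
      j <- which(events$channel == hom[i] &
                 events$onset_s < events$offset_s[i] &
                 events$offset_s > events$onset_s[i])
      if (length(j)) events$rejected_bilateral[i] <- TRUE
    }
  }
  rej <- events$rejected_bilateral | events$rejected_amplitude |
         events$rejected_snr | events$rejected_zscore
  reason <- character(n)
  if (n) {
    reason[events$rejected_zscore] <- "zscore"
    reason[events$rejected_snr] <- "snr"
    reason[events$rejected_amplitude] <- "amplitude"
    reason[events$rejected_bilateral] <- "bilateral"
  }
  events$status <- ifelse(rej, "rejected", "accepted")
  events$reject_reason <- reason
  events
}

#' Run the full three-stage HFO detector
#'
#' Re-references the recording to the bipolar montage and runs, for every
#' bipolar channel and every analysis interval, stage I (entropy baseline +
#' envelope threshold), stage II (time-frequency peak isolation) and stage
#' III (artifact rejection). Fully deterministic.
#'
#' @param recording a referential \code{eeg_recording} (or an already
#'   bipolar one, in which case it is used as-is).
#' @param montage a \code{bipolar_montage}.
#' @param intervals data.frame from \code{\link{select_intervals}}.
#' @param params a \code{detector_params}.
#' @param channels optional subset of bipolar channel names to analyze.
#' @return data.frame of class \code{hfo_events} with one row per stage-I
#'   EoI and columns patient, session, channel, interval_id, onset_s,
#'   offset_s (absolute, seconds), peak_freq_hz, pp_uV, snr, the stage
#'   flags, status ("accepted" / "rejected" / "rejected_stage2") and
#'   reject_reason.
#' @export
detect_hfo <- function(recording, montage = default_montage(), intervals,
                       params = detector_params(), channels = NULL) {
  bip <- if (identical(recording$reference, "bipolar")) recording
         else rereference(recording, montage)
  fs <- bip$sampling_rate
  if (is.null(channels)) channels <- montage$channel
  freqs_rip <- seq(params$ripple_band[1], params$ripple_band[2],
                   by = params$freq_step_hz)
  freqs_low <- seq(params$stage2_low_freq_hz,
                   params$ripple_band[1] - params$freq_step_hz,
                   by = params$freq_step_hz)
  rows <- list(); k <- 0L
  for (ch in channels) {
    # fast-ripple z-score statistic over the channel's analyzed data
    xs <- lapply(seq_len(nrow(intervals)), function(i)
      interval_samples(bip, intervals[i, ])[, ch])
    zr <- fr_zscore(unlist(xs), fs, params)
    offset0 <- 0L
    for (i in seq_len(nrow(intervals))) {
      x <- xs[[i]]
      S <- stockwell_transform(x, fs, freqs_rip)
      s1 <- stage1_detect(x, fs, params, S = S)
      zslice <- zr$z[offset0 + seq_along(x)]
      offset0 <- offset0 + length(x)
      if (!nrow(s1$eoi)) next
      # below-band voices are only needed to judge peak isolation, so they
      # are computed lazily for intervals that produced EoIs
      S_low <- stockwell_transform(x, fs, freqs_low)
      S_all <- rbind(S_low, S)
      attr(S_all, "freqs") <- c(attr(S_low, "freqs"), attr(S, "freqs"))
      S <- S_all
      xr <- s1$filtered
      base <- s1$baseline_windows[s1$baseline_windows$baseline, ]
      P2 <- Mod(S)^2
      for (e in seq_len(nrow(s1$eoi))) {
        i0 <- floor(s1$eoi$onset_s[e] * fs) + 1L
        i1 <- min(ceiling(s1$eoi$offset_s[e] * fs), length(x))
        span <- i0:i1
        v2 <- stage2_validate(rowMeans(P2[, span, drop = FALSE]),
                              attr(S, "freqs"), params)
        mid <- mean(c(s1$eoi$onset_s[e], s1$eoi$offset_s[e]))
        near <- base[order(abs((base$start_s + base$end_s) / 2 - mid)), ]
        near <- near[seq_len(min(params$n_baseline_ref, nrow(near))), ]
        ref_idx <- unlist(lapply(seq_len(nrow(near)), function(b)
          (floor(near$start_s[b] * fs) + 1L):min(ceiling(near$end_s[b] * fs),
                                                 length(x))))
        noise <- mean(s1$envelope[ref_idx]^2)
        snr <- if (noise > 0) max(s1$envelope[span]^2) / noise else Inf
        peak_at <- span[which.max(s1$envelope[span])]
        k <- k + 1L
        rows[[k]] <- data.frame(
          patient = bip$patient_id, session = bip$session, channel = ch,
          interval_id = intervals$interval_id[i],
          onset_s = intervals$start_s[i] + s1$eoi$onset_s[e],
          offset_s = intervals$start_s[i] + s1$eoi$offset_s[e],
          peak_freq_hz = v2$peak_freq_hz,
          pp_uV = max(xr[span]) - min(xr[span]),
          snr = snr,
          zmax_excess = zslice[peak_at] - zr$cutoff,
          passed_stage2 = v2$accepted,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!k) {
    ev <- data.frame(patient = character(0), session = character(0),
                     channel = character(0), interval_id = character(0),
                     onset_s = numeric(0), offset_s = numeric(0),
                     peak_freq_hz = numeric(0), pp_uV = numeric(0),
                     snr = numeric(0), zmax_excess = numeric(0),
                     passed_stage2 = logical(0),
                     rejected_bilateral = logical(0),
                     rejected_amplitude = logical(0),
                     rejected_snr = logical(0), rejected_zscore = logical(0),
                     status = character(0), reject_reason = character(0))
    class(ev) <- c("hfo_events", "data.frame")
    return(ev)
  }
  ev <- do.call(rbind, rows)
  # stage 3 runs on stage-2-validated events only
  s2 <- ev[ev$passed_stage2, , drop = FALSE]
  s2 <- stage3_reject(s2, montage, params)
  rest <- ev[!ev$passed_stage2, , drop = FALSE]
  if (nrow(rest)) {
    rest$rejected_bilateral <- rest$rejected_amplitude <-
      rest$rejected_snr <- rest$rejected_zscore <- FALSE
    rest$status <- "rejected_stage2"
    rest$reject_reason <- "no_isolated_peak"
  }
  ev <- rbind(s2, rest)
  ev <- ev[order(ev$channel, ev$onset_s), ]
  rownames(ev) <- NULL
  class(ev) <- c("hfo_events", "data.frame")
  ev
}

#' @export
print.hfo_events <- function(x, ...) {
  cat("HFO event table:", nrow(x), "events of interest,",
      sum(x$status == "accepted"), "accepted\n")
  if (nrow(x)) {
    tb <- table(x$status)
    cat(paste(sprintf("  %s: %d", names(tb), tb), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Accepted events only
#' @param events an \code{hfo_events} table.
#' @return the accepted subset.
#' @export
accepted_events <- function(events) {
  events[events$status == "accepted", , drop = FALSE]
}

#' Match detected events against ground truth
#'
#' Overlap-based matching of accepted detections to ground-truth events.
#' Because an injected burst lives on one referential electrode, it
#' physically appears on every bipolar channel containing that electrode;
#' by default a detection therefore matches a ground-truth event when
#' their time spans overlap and their channels share an electrode. Set
#' \code{same_channel = TRUE} for strict channel-identity matching.
#'
#' @param events an \code{hfo_events} table (accepted rows are used).
#' @param truth ground-truth data.frame with channel, onset_s, offset_s;
#'   if it has a \code{class} column, only rows in \code{truth_classes}
#'   are treated as events the detector should find.
#' @param montage a \code{bipolar_montage}.
#' @param same_channel require identical channel names (default FALSE).
#' @param truth_classes ground-truth classes that count as targets
#'   (default \code{"true_hfo"}; artifacts are meant to be rejected).
#' @return list \code{recall}, \code{precision}, \code{n_truth},
#'   \code{n_detected}, \code{truth_hit} (logical per truth row),
#'   \code{det_hit} (logical per accepted detection).
#' @export
match_events <- function(events, truth, montage = default_montage(),
                         same_channel = FALSE, truth_classes = "true_hfo") {
  if (!is.null(truth$class))
    truth <- truth[truth$class %in% truth_classes, , drop = FALSE]
  det <- accepted_events(events)
  electrodes_of <- function(chs) {
    i <- match(chs, montage$channel)
    cbind(montage$e1[i], montage$e2[i])
  }
  de <- electrodes_of(det$channel)
  te <- electrodes_of(truth$channel)
  compatible <- function(i, j) {
    if (same_channel) det$channel[i] == truth$channel[j]
    else any(de[i, ] %in% te[j, ])
  }
  truth_hit <- logical(nrow(truth))
  det_hit <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    for (j in seq_len(nrow(truth))) {
      if (det$onset_s[i] < truth$offset_s[j] &&
          det$offset_s[i] > truth$onset_s[j] && compatible(i, j)) {
        truth_hit[j] <- TRUE
        det_hit[i] <- TRUE
      }
    }
  }
  list(recall = if (nrow(truth)) mean(truth_hit) else NA_real_,
       precision = if (nrow(det)) mean(det_hit) else NA_real_,
       n_truth = nrow(truth), n_detected = nrow(det),
       truth_hit = truth_hit, det_hit = det_hit)
}
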