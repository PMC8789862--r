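#' Construct an EEG recording object
#'
#' Container for one session's multichannel scalp EEG in microvolts, plus
#' sleep-stage annotations and session metadata.
#'
#' @param samples numeric matrix, time points x channels, in uV; column
#'   names are channel labels.
#' @param sampling_rate sampling rate in Hz.
#' @param patient_id patient identifier.
#' @param session session label, \code{"pre"} or \code{"post"} surgery.
#' @param annotations data.frame with columns \code{start_s}, \code{end_s},
#'   \code{stage} (one of W, N1, N2, N3, REM), or NULL.
#' @param reference \code{"referential"} or \code{"bipolar"}.
#' @param enforce_min_fs if non-NULL, error unless
#'   \code{sampling_rate > enforce_min_fs} (the study inclusion criterion
#'   uses 1000 Hz).
#' @return An object of class \code{eeg_recording}.
#' @export
eeg_recording <- function(samples, sampling_rate, patient_id = "p1",
                          session = c("pre", "post"),
                          annotations = NULL, reference = "referential",
                          enforce_min_fs = NULL) {
  session <- match.arg(session)
  samples <- as.matrix(samples)
  if (is.null(colnames(samples)))
    stop("samples must have channel labels as column names")
  if (!is.null(enforce_min_fs) && sampling_rate <= enforce_min_fs)
    stop("sampling rate ", sampling_rate,
         " Hz fails the inclusion criterion (> ", enforce_min_fs, " Hz)")
  if (!is.null(annotations)) {
    stopifnot(all(c("start_s", "end_s", "stage") %in% names(annotations)))
    stopifnot(all(annotations$end_s > annotations$start_s))
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 channel_labels = colnames(samples),
                 patient_id = patient_id, session = session,
                 annotations = annotations, reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: patient %s, %s-surgical, %d channels (%s), %.1f s @ %g Hz\n",
              x$patient_id, x$session, ncol(x$samples), x$reference,
              nrow(x$samples) / x$sampling_rate, x$sampling_rate))
  if (!is.null(x$annotations))
    cat("  annotations:", nrow(x$annotations), "stage bouts (",
        paste(unique(x$annotations$stage), collapse = ", "), ")\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording an \code{eeg_recording}.
#' @return numeric seconds.
#' @export
recording_duration <- function(recording) {
  nrow(recording$samples) / recording$sampling_rate
}

#' Select 5-minute analysis intervals from sleep-stage annotations
#'
#' Carves consecutive fixed-length intervals (default 300 s) out of each
#' annotated bout of the requested sleep stages; the interval grid restarts
#' at each bout so intervals never cross stage boundaries. Trailing partial
#' intervals are dropped by default. Intervals named in the exclusion list
#' are removed (mirroring visual screening of artifact-laden intervals).
#'
#' @param recording an \code{eeg_recording} with annotations.
#' @param stages sleep stages to analyze (default \code{"N3"}).
#' @param min_total_minutes inclusion criterion: error if the selected
#'   intervals total fewer minutes than this (default 10).
#' @param exclusions character vector of interval ids to drop, or a
#'   data.frame with a column \code{interval_id}.
#' @param interval_s interval length in seconds (default 300).
#' @param drop_partial drop trailing sub-length intervals (default TRUE);
#'   if FALSE they are kept and flagged \code{partial = TRUE}.
#' @return data.frame with columns \code{interval_id}, \code{start_s},
#'   \code{end_s}, \code{stage}, \code{minutes}, \code{partial}.
#' @export
select_intervals <- function(recording, stages = "N3",
                             min_total_minutes = 10,
                             exclusions = NULL, interval_s = 300,
                             drop_partial = TRUE) {
  ann <- recording$annotations
  if (is.null(ann)) stop("recording has no stage annotations")
  ann <- ann[ann$stage %in% stages, , drop = FALSE]
  dur <- recording_duration(recording)
  out <- list()
  k <- 0L
  for (i in seq_len(nrow(ann))) {
    b0 <- ann$start_s[i]; b1 <- min(ann$end_s[i], dur)
    t <- b0
    while (t < b1) {
      e <- min(t + interval_s, b1)
      partial <- (e - t) < interval_s
      if (!partial || !drop_partial) {
        k <- k + 1L
        out[[k]] <- data.frame(interval_id = NA_character_, start_s = t,
                               end_s = e, stage = ann$stage[i],
                               minutes = (e - t) / 60, partial = partial,
                               stringsAsFactors = FALSE)
      }
      t <- t + interval_s
    }
  }
  if (length(out) == 0L)
    stop("inclusion failure: no ", paste(stages, collapse = "/"),
         " intervals available")
  iv <- do.call(rbind, out)
  iv$interval_id <- sprintf("iv%02d", seq_len(nrow(iv)))
  if (!is.null(exclusions)) {
    excl <- if (is.data.frame(exclusions)) exclusions$interval_id else exclusions
    iv <- iv[!(iv$interval_id %in% excl), , drop = FALSE]
  }
  if (sum(iv$minutes) < min_total_minutes)
    stop("inclusion failure: only ", round(sum(iv$minutes), 2),
         " min of ", paste(stages, collapse = "/"), " sleep selected (need >= ",
         min_total_minutes, " min)")
  rownames(iv) <- NULL
  iv
}

#' Extract the sample matrix of one analysis interval
#' @param recording an \code{eeg_recording}.
#' @param interval one row of the data.frame from
#'   \code{\link{select_intervals}} (or any list with start_s/end_s).
#' @return numeric matrix, time x channels.
#' @export
interval_samples <- function(recording, interval) {
  fs <- recording$sampling_rate
  i0 <- floor(interval$start_s * fs) + 1L
  i1 <- min(floor(interval$end_s * fs), nrow(recording$samples))
  recording$samples[i0:i1, , drop = FALSE]
}
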