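# Minimal European Data Format (EDF) I/O: fixed-layout ASCII header plus
# little-endian int16 data records. Supports the subset this package needs:
# identical sampling rate across channels, physical dimension uV,
# 1-second data records.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to a European Data Format file
#'
#' Signals are quantized to 16 bits over each channel's physical range
#' (physical dimension uV). The recording is padded with zeros to a whole
#' number of 1-second data records.
#'
#' @param recording an \code{eeg_recording}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$sampling_rate
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate")
  x <- recording$samples
  ns <- ncol(x)
  n_rec <- ceiling(nrow(x) / fs)
  if (nrow(x) < n_rec * fs)
    x <- rbind(x, matrix(0, n_rec * fs - nrow(x), ns,
                         dimnames = list(NULL, colnames(x))))
  pmin_ <- apply(x, 2, min); pmax_ <- apply(x, 2, max)
  flat <- pmax_ - pmin_ <= 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(
    edf_pad("0", 8), edf_pad(recording$patient_id, 80),
    edf_pad(paste0("session ", recording$session), 80),
    edf_pad("01.01.20", 8), edf_pad("00.00.00", 8),
    edf_pad(hdr_bytes, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4)),
    con, eos = NULL)
  fields <- list(
    list(colnames(x), 16), list(rep("", ns), 80), list(rep("uV", ns), 8),
    list(format(pmin_, trim = TRUE, digits = 7), 8),
    list(format(pmax_, trim = TRUE, digits = 7), 8),
    list(rep(dmin, ns), 8), list(rep(dmax, ns), 8),
    list(rep("", ns), 80), list(rep(fs, ns), 8), list(rep("", ns), 32))
  for (f in fields)
    writeChar(paste(vapply(f[[1]], edf_pad, "", width = f[[2]]),
                    collapse = ""), con, eos = NULL)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  dig <- round(sweep(sweep(x, 2, pmin_), 2, scale, "/")) + dmin
  dig <- pmin(pmax(dig, dmin), dmax)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(dig[idx, ]), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a European Data Format file
#'
#' @param path EDF file path.
#' @param annotations optional annotations data.frame to attach (EDF proper
#'   carries no stage annotations; this package stores them in a sidecar
#'   CSV, see \code{\link{read_annotations}}).
#' @param session session label for the returned recording.
#' @param enforce_min_fs if non-NULL, reject files whose sampling rate is
#'   not strictly greater (inclusion criterion; the study required
#'   > 1000 Hz).
#' @return An \code{eeg_recording} in uV.
#' @export
read_edf <- function(path, annotations = NULL, session = "pre",
                     enforce_min_fs = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)
  patient_id <- rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  if (!all(units %in% c("uV", "µV")))
    stop("unsupported physical dimension(s): ",
         paste(unique(setdiff(units, c("uV"))), collapse = ", "))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("read_edf supports a single sampling rate across channels")
  fs <- spr[1] / rec_dur
  out <- matrix(0, n_rec * spr[1], ns, dimnames = list(NULL, labels))
  for (r in seq_len(n_rec)) {
    d <- readBin(con, "integer", n = spr[1] * ns, size = 2,
                 signed = TRUE, endian = "little")
    out[((r - 1L) * spr[1] + 1L):(r * spr[1]), ] <- matrix(d, spr[1], ns)
  }
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  phys <- sweep(sweep(out, 2, dmin), 2, scale, "*")
  phys <- sweep(phys, 2, pmin_, "+")
  eeg_recording(phys, fs, patient_id = patient_id, session = session,
                annotations = annotations, enforce_min_fs = enforce_min_fs)
}

#' Read / write sleep-stage annotations
#'
#' Annotations live in a plain CSV with columns \code{start_s},
#' \code{end_s}, \code{stage}.
#' @param path CSV path.
#' @return data.frame (for \code{read_annotations}).
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("start_s", "end_s", "stage") %in% names(ann)))
  ann
}

#' @rdname read_annotations
#' @param annotations data.frame to write.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}
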