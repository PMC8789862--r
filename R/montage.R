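#' The 21 scalp electrodes of the international 10-20 system
#'
#' Ordered labels of the 21-electrode montage used throughout the package,
#' including the ear electrodes A1/A2.
#'
#' @return Character vector of length 21.
#' @export
electrode_labels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "A1", "T3", "C3", "Cz",
    "C4", "T4", "A2", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Left-right mirror map of the 10-20 electrode set
#'
#' Maps each electrode to its homologue across the midsagittal plane;
#' midline electrodes (Fz, Cz, Pz) map to themselves. The map is an
#' involution: \code{mirror_electrode(mirror_electrode(x)) == x}.
#'
#' @param labels electrode labels to mirror (default: all 21).
#' @return Character vector of mirrored labels.
#' @export
mirror_electrode <- function(labels = electrode_labels()) {
  pairs <- c(Fp1 = "Fp2", Fp2 = "Fp1", F7 = "F8", F8 = "F7", F3 = "F4",
             F4 = "F3", A1 = "A2", A2 = "A1", T3 = "T4", T4 = "T3",
             C3 = "C4", C4 = "C3", T5 = "T6", T6 = "T5", P3 = "P4",
             P4 = "P3", O1 = "O2", O2 = "O1", Fz = "Fz", Cz = "Cz",
             Pz = "Pz")
  unknown <- setdiff(labels, names(pairs))
  if (length(unknown))
    stop("unknown electrode label(s): ", paste(unknown, collapse = ", "))
  unname(pairs[labels])
}

# order-free key for an electrode pair (channels are unordered pairs)
pair_key <- function(e1, e2) {
  ord <- match(e1, electrode_labels()) <= match(e2, electrode_labels())
  ifelse(ord, paste0(e1, "|", e2), paste0(e2, "|", e1))
}

#' Construct a bipolar montage
#'
#' @param pairs two-column character matrix or data.frame of electrode pairs.
#' @param enforce_52 if TRUE, require exactly 52 unique channels (the shipped
#'   default adjacency); user-supplied montages may disable this.
#' @return Object of class \code{bipolar_montage}: a data.frame with columns
#'   \code{e1}, \code{e2}, \code{channel}, \code{homologous}.
#' @export
bipolar_montage <- function(pairs, enforce_52 = FALSE) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stopifnot(ncol(pairs) >= 2)
  e1 <- as.character(pairs[[1]]); e2 <- as.character(pairs[[2]])
  unknown <- setdiff(c(e1, e2), electrode_labels())
  if (length(unknown))
    stop("unknown electrode label(s): ", paste(unknown, collapse = ", "))
  key <- pair_key(e1, e2)
  if (anyDuplicated(key)) {
    dup <- paste0(e1, "-", e2)[duplicated(key)]
    stop("duplicate bipolar pair(s): ", paste(dup, collapse = ", "))
  }
  if (enforce_52 && length(key) != 52L)
    stop("expected 52 bipolar channels, got ", length(key))
  # channel names keep the pair orientation as given (the field's naming,
  # e.g. "T5-C3"); homologues are resolved through the order-free key
  ch <- paste0(e1, "-", e2)
  hom_key <- pair_key(mirror_electrode(e1), mirror_electrode(e2))
  hom <- ch[match(hom_key, key)]
  m <- data.frame(e1 = e1, e2 = e2, channel = ch, homologous = hom,
                  stringsAsFactors = FALSE)
  class(m) <- c("bipolar_montage", "data.frame")
  m
}

#' The shipped default 52-channel bipolar montage
#'
#' All pairs of neighboring electrodes of the 21-electrode 10-20 set,
#' yielding 52 bipolar channels. The adjacency is mirror-symmetric (the
#' left-right reflection of the edge set maps the montage onto itself) and
#' C3 participates in exactly the five channels F3-C3, C3-P3, T5-C3, C3-Pz,
#' C3-Fz.
#'
#' @return A \code{bipolar_montage} with 52 channels.
#' @export
default_montage <- function() {
  path <- system.file("extdata", "montage_bipolar_default.tsv",
                      package = "scalphfo", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  bipolar_montage(tab, enforce_52 = TRUE)
}

#' @export
print.bipolar_montage <- function(x, ...) {
  cat("Bipolar montage:", nrow(x), "channels over",
      length(unique(c(x$e1, x$e2))), "electrodes\n")
  cat(strwrap(paste(x$channel, collapse = ", "), width = 76), sep = "\n")
  invisible(x)
}

#' Homologous (contralateral) channel of a bipolar channel
#'
#' The channel obtained by mirroring both electrodes through the midsagittal
#' plane; channels made of midline electrodes only map to themselves.
#'
#' @param montage a \code{bipolar_montage}.
#' @param channels channel names (default: all).
#' @return Character vector of homologous channel names.
#' @export
homologous_channel <- function(montage, channels = montage$channel) {
  idx <- match(channels, montage$channel)
  if (anyNA(idx))
    stop("channel(s) not in montage: ",
         paste(channels[is.na(idx)], collapse = ", "))
  hom <- montage$homologous[idx]
  if (anyNA(hom))
    stop("montage is missing the homologous mapping for: ",
         paste(channels[is.na(hom)], collapse = ", "))
  hom
}

#' Re-reference a referential recording to a bipolar montage
#'
#' Each bipolar channel is the first electrode's signal minus the second
#' electrode's, sample-aligned.
#'
#' @param recording an \code{eeg_recording} (see \code{\link{eeg_recording}})
#'   with referential channels.
#' @param montage a \code{bipolar_montage}.
#' @return An \code{eeg_recording} whose channels are the montage's bipolar
#'   channels, in montage order.
#' @export
rereference <- function(recording, montage = default_montage()) {
  stopifnot(inherits(recording, "eeg_recording"))
  missing <- setdiff(unique(c(montage$e1, montage$e2)),
                     colnames(recording$samples))
  if (length(missing))
    stop("recording is missing electrode(s): ", paste(missing, collapse = ", "))
  out <- recording$samples[, montage$e1, drop = FALSE] -
         recording$samples[, montage$e2, drop = FALSE]
  colnames(out) <- montage$channel
  rec <- recording
  rec$samples <- out
  rec$channel_labels <- montage$channel
  rec$reference <- "bipolar"
  rec
}

#' Channels touching skull-defect electrodes
#'
#' A bipolar channel is a skull-defect channel if it contains at least one
#' electrode classified as lying within the distance cutoff of the
#' craniotomy defect border.
#'
#' @param montage a \code{bipolar_montage}.
#' @param defect_electrodes character vector of electrode labels.
#' @return Character vector of channel names (montage order).
#' @export
skull_defect_channels <- function(montage, defect_electrodes) {
  if (length(defect_electrodes) == 0L) return(character(0))
  unknown <- setdiff(defect_electrodes, electrode_labels())
  if (length(unknown))
    stop("unknown electrode label(s): ", paste(unknown, collapse = ", "))
  montage$channel[montage$e1 %in% defect_electrodes |
                  montage$e2 %in% defect_electrodes]
}
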