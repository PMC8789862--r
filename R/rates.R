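#' Per-channel, per-interval HFO rates
#'
#' Counts accepted events per (channel, interval) and divides by the
#' interval duration, giving HFO/min. Channels without events appear with
#' rate 0 so the rate matrix is complete.
#'
#' @param events an \code{hfo_events} table (only rows with
#'   \code{status == "accepted"} are counted) or any data.frame with
#'   \code{channel} and \code{interval_id} columns (all rows counted).
#' @param intervals data.frame from \code{\link{select_intervals}}.
#' @param channels character vector of all channels the table should cover
#'   (default: the 52 channels of \code{\link{default_montage}}).
#' @return Object of class \code{hfo_rate_table}: a data.frame (channel,
#'   interval_id, n_events, minutes, rate) with attribute
#'   \code{channel_means} (named per-channel mean rate over intervals).
#' @export
compute_rates <- function(events, intervals,
                          channels = default_montage()$channel) {
  if (nrow(intervals) == 0L) stop("empty interval list")
  if (!is.null(events$status))
    events <- events[events$status == "accepted", , drop = FALSE]
  grid <- expand.grid(channel = channels,
                      interval_id = intervals$interval_id,
                      stringsAsFactors = FALSE)
  grid$minutes <- intervals$minutes[match(grid$interval_id,
                                          intervals$interval_id)]
  key <- paste(grid$channel, grid$interval_id)
  cnt <- table(paste(events$channel, events$interval_id))
  grid$n_events <- as.integer(cnt[key])
  grid$n_events[is.na(grid$n_events)] <- 0L
  grid$rate <- grid$n_events / grid$minutes
  cm <- tapply(grid$rate, grid$channel, mean)[channels]
  structure(grid, channel_means = cm,
            class = c("hfo_rate_table", "data.frame"))
}

#' Per-channel mean rates of a rate table
#' @param rate_table an \code{hfo_rate_table}.
#' @return named numeric vector, HFO/min.
#' @export
channel_mean_rates <- function(rate_table) attr(rate_table, "channel_means")

#' @export
print.hfo_rate_table <- function(x, ...) {
  cm <- channel_mean_rates(x)
  cat(sprintf("HFO rate table: %d channels x %d intervals, %d events, mean rate %.3f HFO/min\n",
              length(cm), length(unique(x$interval_id)), sum(x$n_events),
              mean(cm)))
  top <- sort(cm, decreasing = TRUE)[seq_len(min(5, length(cm)))]
  cat("  highest channels:",
      paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' The HFO area: channels with consistently high presurgical rates
#'
#' Double 97.5th-percentile procedure on the presurgical rate table:
#' (1) the rate threshold is the 97.5th percentile of the pooled
#' channel-by-interval rate distribution; (2) each channel's occurrence is
#' the number of intervals in which its rate strictly exceeds that
#' threshold; (3) the occurrence threshold is the 97.5th percentile of the
#' occurrence values, and channels strictly above it form the HFO area.
#' Percentiles use linear interpolation between order statistics
#' (\code{stats::quantile} type 7). With an all-constant rate matrix (e.g.
#' no events) the area is empty, since no channel strictly exceeds.
#'
#' @param pre_rate_table the presurgical \code{hfo_rate_table}.
#' @param percentile percentile used in both steps (default 0.975).
#' @param strict use strict inequalities as printed (default TRUE).
#' @return list of class \code{hfo_area}: \code{channels},
#'   \code{rate_threshold}, \code{occurrence_threshold},
#'   \code{occurrence} (named vector), \code{source_session = "pre"}.
#' @export
compute_hfo_area <- function(pre_rate_table, percentile = 0.975,
                             strict = TRUE) {
  if (nrow(pre_rate_table) == 0L) stop("empty rate table")
  cmp <- if (strict) `>` else `>=`
  rate_threshold <- as.numeric(stats::quantile(pre_rate_table$rate,
                                               percentile, type = 7))
  above <- cmp(pre_rate_table$rate, rate_threshold)
  occurrence <- tapply(above, pre_rate_table$channel, sum)
  occurrence <- occurrence[unique(pre_rate_table$channel)]
  occurrence_threshold <- as.numeric(stats::quantile(occurrence,
                                                     percentile, type = 7))
  area <- names(occurrence)[cmp(occurrence, occurrence_threshold)]
  structure(list(channels = area, rate_threshold = rate_threshold,
                 occurrence_threshold = occurrence_threshold,
                 occurrence = occurrence, source_session = "pre"),
            class = "hfo_area")
}

#' @export
print.hfo_area <- function(x, ...) {
  cat(sprintf("HFO area: {%s} (rate threshold %.3f HFO/min, occurrence threshold %.2f)\n",
              paste(x$channels, collapse = ", "), x$rate_threshold,
              x$occurrence_threshold))
  invisible(x)
}

#' Channel-of-interest groups
#'
#' Partitions the channels of interest into the four groups compared in the
#' skull-defect analysis: skull-defect channels inside the HFO area,
#' skull-defect channels outside it, area channels away from the defect,
#' and the contralateral homologues of the defect-outside-area group.
#'
#' @param area an \code{hfo_area}.
#' @param defect_channels character vector from
#'   \code{\link{skull_defect_channels}}.
#' @param montage a \code{bipolar_montage}.
#' @return list with character vectors \code{area_defect},
#'   \code{defect_outside_area}, \code{area_outside_defect},
#'   \code{contralateral}.
#' @export
channel_groups <- function(area, defect_channels, montage = default_montage()) {
  a <- area$channels
  d <- defect_channels
  defect_outside <- setdiff(d, a)
  list(area_defect = intersect(a, d),
       defect_outside_area = defect_outside,
       area_outside_defect = setdiff(a, d),
       contralateral = homologous_channel(montage, defect_outside))
}

#' Mean HFO rate over a set of channels
#'
#' The per-recording summary statistic: the mean of the per-channel mean
#' rates over the named channels (HFO/min).
#'
#' @param rate_table an \code{hfo_rate_table}.
#' @param channels non-empty character vector of channel names.
#' @return numeric scalar, HFO/min.
#' @export
recording_summary <- function(rate_table, channels) {
  if (length(channels) == 0L) stop("empty channel set")
  cm <- channel_mean_rates(rate_table)
  missing <- setdiff(channels, names(cm))
  if (length(missing))
    stop("channel(s) not in rate table: ", paste(missing, collapse = ", "))
  mean(cm[channels])
}

#' Mean event amplitude over a set of channels
#'
#' Companion to \code{\link{recording_summary}} for peak-to-peak amplitudes:
#' mean over the named channels of each channel's mean accepted-event
#' ripple-band peak-to-peak amplitude (uV). Channels without accepted
#' events contribute 0.
#'
#' @param events an \code{hfo_events} table.
#' @param channels non-empty character vector.
#' @return numeric scalar, uV.
#' @export
amplitude_summary <- function(events, channels) {
  if (length(channels) == 0L) stop("empty channel set")
  acc <- accepted_events(events)
  per <- vapply(channels, function(ch) {
    a <- acc$pp_uV[acc$channel == ch]
    if (length(a)) mean(a) else 0
  }, 0)
  mean(per)
}
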