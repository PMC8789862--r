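#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' t-approximation t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees
#' of freedom, two-sided.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list \code{rho}, \code{p}, \code{n}. Constant input yields
#'   \code{rho = NA} with \code{degenerate = TRUE}.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, p = NA_real_, n = length(x),
                degenerate = TRUE))
  rx <- rank(x); ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n, degenerate = FALSE)
}

#' Wilcoxon signed-rank test with zero-difference discarding
#'
#' Paired test of pre versus post values. Zero differences are discarded
#' first (the zero-inflation convention of the original analysis), then
#' absolute differences are ranked with average ranks. For small samples
#' (\code{n_effective <= 15}, the convention of common statistical
#' packages) the two-sided p-value comes from the exact sign-flip
#' distribution of the rank sum; beyond that, from the normal
#' approximation with tie-corrected variance and 0.5 continuity
#' correction. The z statistic is always reported from the approximation;
#' its sign is that of the pre-minus-post rank sum (positive z means pre
#' exceeds post).
#'
#' @param pre,post paired numeric vectors.
#' @param method \code{"auto"} (exact up to n = 15), \code{"exact"}, or
#'   \code{"approximate"}.
#' @return list \code{p}, \code{z}, \code{n_effective}, \code{w_plus},
#'   \code{method} (the method that produced \code{p}).
#' @export
signed_rank <- function(pre, post,
                        method = c("auto", "exact", "approximate")) {
  method <- match.arg(method)
  stopifnot(length(pre) == length(post))
  d <- pre - post
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero: signed-rank test undefined")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  sigma <- sqrt(sigma2)
  delta <- w_plus - mu
  z <- if (delta == 0) 0 else (delta - sign(delta) * 0.5) / sigma
  if (method == "auto") method <- if (n <= 15L) "exact" else "approximate"
  p <- if (method == "exact") signed_rank_exact_p(r, w_plus)
       else 2 * stats::pnorm(-abs(z))
  list(p = min(p, 1), z = z, n_effective = n, w_plus = w_plus,
       method = method)
}

# exact two-sided p of the signed-rank sum by generating-function counting
# over all 2^n sign assignments: P(|W - mu| >= |w_obs - mu|). Average
# ranks are half-integers, so everything is doubled to stay integral.
signed_rank_exact_p <- function(r, w_obs) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  counts <- c(1, numeric(total))        # counts[w + 1] over doubled sums
  for (ri in r2) {
    shifted <- c(numeric(ri), counts[seq_len(total + 1 - ri)])
    counts <- counts + shifted
  }
  w2 <- round(2 * w_obs)
  dev <- abs(w2 - total / 2)
  sums <- seq(0, total)
  sum(counts[abs(sums - total / 2) >= dev - 1e-9]) / 2^length(r2)
}

#' ROC optimal operating-point threshold
#'
#' Scans candidate thresholds (midpoints between consecutive sorted unique
#' rates, plus one below the minimum and one above the maximum) with the
#' positive rule "rate >= threshold", and returns the candidate maximizing
#' Youden's J = sensitivity + specificity - 1. Ties are broken toward
#' higher specificity, then toward the higher threshold.
#'
#' @param rates per-recording values (e.g. mean HFO-area rate, HFO/min).
#' @param labels logical (or 0/1): TRUE for the positive class (active
#'   epilepsy).
#' @return list \code{threshold}, \code{J}, \code{sensitivity},
#'   \code{specificity}, \code{degenerate} (TRUE when J = 0 everywhere).
#' @export
roc_threshold <- function(rates, labels) {
  labels <- as.logical(labels)
  stopifnot(length(rates) == length(labels))
  if (!any(labels) || all(labels))
    stop("roc_threshold requires both classes")
  u <- sort(unique(rates))
  cand <- if (length(u) == 1L) u else
    c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  best <- NULL
  for (th in cand) {
    pos <- rates >= th
    sens <- sum(pos & labels) / sum(labels)
    spec <- sum(!pos & !labels) / sum(!labels)
    J <- sens + spec - 1
    if (is.null(best) || J > best$J + 1e-12 ||
        (abs(J - best$J) <= 1e-12 &&
         (spec > best$specificity + 1e-12 ||
          (abs(spec - best$specificity) <= 1e-12 && th > best$threshold)))) {
      best <- list(threshold = th, J = J, sensitivity = sens,
                   specificity = spec)
    }
  }
  best$degenerate <- best$J <= 1e-12
  best
}

#' Confusion counts and predictive values of the rate threshold
#'
#' Classifies each recording as positive when its rate is greater than or
#' equal to the threshold, and scores against the active-epilepsy labels:
#' TP = active and positive, FP = seizure-free and positive, FN = active
#' and negative, TN = seizure-free and negative. PPV, NPV and accuracy are
#' returned both raw and rounded to whole percent (the reporting
#' convention); undefined ratios (zero denominator) are NA.
#'
#' @param rates per-recording values.
#' @param labels logical active-epilepsy flags.
#' @param threshold classification threshold (HFO/min).
#' @return list of class \code{confusion_counts}: TP, FP, FN, TN, ppv,
#'   npv, accuracy (percent, rounded), and \code{raw} with unrounded
#'   values.
#' @export
classify_and_score <- function(rates, labels, threshold) {
  labels <- as.logical(labels)
  pos <- rates >= threshold
  TP <- sum(pos & labels); FP <- sum(pos & !labels)
  FN <- sum(!pos & labels); TN <- sum(!pos & !labels)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  raw <- list(ppv = pct(TP, TP + FP), npv = pct(TN, TN + FN),
              accuracy = pct(TP + TN, TP + FP + FN + TN))
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN,
                 ppv = round(raw$ppv), npv = round(raw$npv),
                 accuracy = round(raw$accuracy), raw = raw,
                 threshold = threshold),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  TN %d | PPV %s%%  NPV %s%%  accuracy %s%%\n",
              x$TP, x$FP, x$FN, x$TN, x$ppv, x$npv, x$accuracy))
  invisible(x)
}

#' Two-fold cross-validation of the rate-threshold classifier
#'
#' Repeats, 2 x n times by default: shuffle the recordings, split them into
#' two equal halves d0 and d1, fit the ROC threshold on d0 and score d1,
#' then fit on d1 and score d0. Splits leaving a training half with only
#' one class are redrawn (up to \code{max_resample} attempts per
#' repetition). Returns the per-fold metrics and their median/iqr.
#'
#' @param rates per-recording values.
#' @param labels logical active-epilepsy flags.
#' @param seed integer seed for the shuffles.
#' @param n_reps number of shuffle repetitions (default 2 x the number of
#'   recordings).
#' @param max_resample resample attempts for class-degenerate splits.
#' @return list \code{folds} (data.frame threshold/ppv/npv/accuracy, two
#'   rows per repetition) and \code{summary} (median and iqr per metric,
#'   NA-dropping).
#' @export
twofold_cv <- function(rates, labels, seed = 1L,
                       n_reps = 2L * length(rates), max_resample = 100L) {
  labels <- as.logical(labels)
  n <- length(rates)
  stopifnot(n >= 4)
  set.seed(seed)
  rows <- list(); k <- 0L
  for (rep_i in seq_len(n_reps)) {
    for (attempt in seq_len(max_resample)) {
      idx <- sample.int(n)
      h0 <- idx[seq_len(floor(n / 2))]
      h1 <- idx[(floor(n / 2) + 1L):n]
      ok <- function(h) any(labels[h]) && !all(labels[h])
      if (ok(h0) && ok(h1)) break
      if (attempt == max_resample)
        stop("could not draw class-balanced folds after ", max_resample,
             " attempts")
    }
    for (fold in list(list(train = h0, test = h1),
                      list(train = h1, test = h0))) {
      th <- roc_threshold(rates[fold$train], labels[fold$train])$threshold
      sc <- classify_and_score(rates[fold$test], labels[fold$test], th)
      k <- k + 1L
      rows[[k]] <- data.frame(threshold = th, ppv = sc$raw$ppv,
                              npv = sc$raw$npv, accuracy = sc$raw$accuracy)
    }
  }
  folds <- do.call(rbind, rows)
  summ <- lapply(folds, function(v)
    c(median = stats::median(v, na.rm = TRUE),
      iqr = stats::IQR(v, na.rm = TRUE)))
  list(folds = folds, summary = summ)
}

#' Build per-recording labels for the threshold analysis
#'
#' Active epilepsy is TRUE for every presurgical recording and for
#' postsurgical recordings of patients with seizure recurrence
#' (Engel II-IV); postsurgical recordings of Engel I patients are the
#' negative class.
#'
#' @param session character vector, "pre"/"post" per recording.
#' @param engel character vector of Engel classes per recording
#'   ("Ia", "I", "II", "III", "IV", ...).
#' @return logical vector.
#' @export
epilepsy_active <- function(session, engel) {
  seizure_free <- grepl("^I[a-d]?$", engel)
  session == "pre" | !seizure_free
}
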