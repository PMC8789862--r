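#' Discrete Stockwell (S-) transform
#'
#' Time-frequency transform with a frequency-dependent Gaussian window of
#' standard deviation 1/f in time: low frequencies get long windows, high
#' frequencies short ones. Computed in the frequency domain: for the voice
#' at DFT bin k, the shifted spectrum X(k + m) is multiplied by the Gaussian
#' exp(-2 pi^2 m^2 / k^2) and inverse-transformed. The zero-frequency voice
#' equals the signal mean, and the transform satisfies the exact marginal
#' identity sum_t S(t, f_k) = X(f_k), the DFT coefficient.
#'
#' @param x numeric signal (finite values).
#' @param fs sampling rate in Hz.
#' @param freqs frequencies (Hz) at which to compute voices; rounded to the
#'   nearest DFT bin of the signal length. All must lie below Nyquist.
#' @return Complex matrix, \code{length(freqs)} x \code{length(x)}, with
#'   attributes \code{freqs} (the bin-snapped frequencies in Hz) and
#'   \code{times} (seconds).
#' @export
stockwell_transform <- function(x, fs, freqs) {
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  n <- length(x)
  if (any(freqs >= fs / 2)) stop("frequencies must lie below Nyquist (fs/2)")
  if (any(freqs < 0)) stop("frequencies must be non-negative")
  k <- as.integer(round(freqs * n / fs))   # DFT bin per requested frequency
  X <- stats::fft(x) / n
  m <- 0:(n - 1)
  m_sym <- ifelse(m > n / 2, m - n, m)     # wrapped frequency offsets
  S <- matrix(0+0i, length(k), n)
  S[k == 0L, ] <- mean(x)
  nz <- which(k > 0L)
  if (length(nz)) {
    # all voices at once: columns are shifted spectra times the Gaussian,
    # inverse-transformed together
    G <- exp(outer(m_sym^2, -2 * pi^2 / k[nz]^2))
    XS <- vapply(k[nz], function(kj) X[((kj + m) %% n) + 1L],
                 complex(n))
    S[nz, ] <- t(stats::mvfft(XS * G, inverse = TRUE))
  }
  attr(S, "freqs") <- k * fs / n
  attr(S, "times") <- (m) / fs
  S
}

#' Zero-phase FIR band-pass filter
#'
#' Blackman-window FIR designed with \code{signal::fir1} (> 60 dB stopband,
#' doubled by the two passes), applied forward and backward so event timing
#' is preserved. The two-pass filter is applied in the frequency domain --
#' multiplying by the squared magnitude response \code{|B(f)|^2}, which is
#' exactly the zero-phase forward-backward response -- with zero padding
#' beyond twice the filter length to keep circular wrap-around out of the
#' signal span.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param band length-2 numeric, passband edges in Hz. The upper edge is
#'   capped at 0.97 * Nyquist.
#' @param order FIR order (default 256; even).
#' @return Filtered signal, same length as \code{x}.
#' @export
bandpass_filter <- function(x, fs, band, order = 256L) {
  nyq <- fs / 2
  w <- c(band[1], min(band[2], 0.97 * nyq)) / nyq
  if (w[1] <= 0 || w[1] >= w[2]) stop("invalid passband ", band[1], "-", band[2])
  b <- signal::fir1(order, w, type = "pass",
                    window = signal::blackman(order + 1))
  n <- length(x)
  N <- stats::nextn(n + 2L * (order + 1L), c(2, 3, 5))
  H <- Mod(stats::fft(c(as.numeric(b), numeric(N - order - 1L))))^2
  y <- Re(stats::fft(stats::fft(c(x, numeric(N - n))) * H,
                     inverse = TRUE)) / N
  y[seq_len(n)]
}

#' Analytic-signal envelope
#'
#' Magnitude of the analytic signal computed by the FFT method (positive
#' frequencies doubled, negative zeroed).
#'
#' @param x numeric signal (typically band-pass filtered).
#' @return Non-negative envelope, same length as \code{x}.
#' @export
envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}
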