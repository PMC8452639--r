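#' Uniformly sampled recording
#'
#' Light container for a single-channel electrophysiology trace: a numeric
#' sample vector, its sampling rate and a unit label (pA for patch-clamp
#' currents, uV for field potentials, mV for simulated membrane mixtures).
#'
#' @param samples numeric vector of finite samples.
#' @param sampling_rate Hz, positive.
#' @param units unit label.
#' @return object of class `trace_recording`.
#' @export
trace_recording <- function(samples, sampling_rate, units = "uV") {
  samples <- as.numeric(samples)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive", call. = FALSE)
  if (any(!is.finite(samples)))
    stop("samples must be finite", call. = FALSE)
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 units = units),
            class = "trace_recording")
}

#' @export
print.trace_recording <- function(x, ...) {
  cat(sprintf("trace_recording: %d samples @ %g Hz (%.3g s), units %s\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, x$units))
  invisible(x)
}

#' Trace time axis in seconds
#' @param trace a `trace_recording`.
#' @export
trace_times <- function(trace) {
  (seq_along(trace$samples) - 1) / trace$sampling_rate
}

#' Welch power spectral density estimate
#'
#' Hann-windowed averaged periodogram with 50% segment overlap, one-sided
#' normalization so that `sum(power) * df` approximates the signal variance.
#' The global mean is removed before segmentation (no per-segment
#' detrending, preserving the Parseval identity for band-limited signals).
#'
#' @param x numeric samples or a `trace_recording`.
#' @param fs sampling rate in Hz (ignored when `x` is a trace).
#' @param nperseg segment length in samples; default gives 0.5 Hz
#'   resolution (2 s segments), capped at the signal length.
#' @return data.frame with columns `freq` (Hz) and `power` (units^2/Hz).
#' @export
welch_psd <- function(x, fs = NULL, nperseg = NULL) {
  if (inherits(x, "trace_recording")) {
    fs <- x$sampling_rate
    x <- x$samples
  }
  stopifnot(!is.null(fs), length(x) >= 8)
  if (is.null(nperseg)) nperseg <- round(2 * fs)
  nperseg <- min(as.integer(nperseg), length(x))
  x <- x - mean(x)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, length(x) - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))  # Hann
  scale <- fs * sum(w^2)
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * w
    p <- Mod(stats::fft(seg))^2 / scale
    acc <- acc + p[seq_len(nf)]
  }
  p <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nperseg even)
  if (nperseg %% 2L == 0L) {
    p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
  } else {
    p[2:nf] <- 2 * p[2:nf]
  }
  data.frame(freq = (seq_len(nf) - 1L) * fs / nperseg, power = p)
}

#' Gaussian noise with a prescribed one-sided power spectrum
#'
#' Frequency-domain shaping: white Gaussian noise is transformed, its
#' Fourier coefficients scaled to the square root of the target spectrum,
#' and transformed back. The DC component is zeroed. Uses the current RNG
#' state (callers seed it).
#'
#' @param n number of samples.
#' @param fs sampling rate in Hz.
#' @param shape_fn function of frequency (Hz) returning the target one-sided
#'   PSD (units^2/Hz); evaluated on (0, fs/2].
#' @return numeric vector of length `n`.
#' @keywords internal
shaped_noise <- function(n, fs, shape_fn) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- seq(0, n - 1) * fs / n
  f_fold <- pmin(f, fs - f)           # magnitude frequency per FFT bin
  g <- numeric(n)
  pos <- f_fold > 0
  g[pos] <- sqrt(shape_fn(f_fold[pos]) / 2)  # two-sided = one-sided / 2
  shaped <- Re(stats::fft(spec * g, inverse = TRUE)) / n * sqrt(fs)
  shaped
}

#' Integrate a PSD over a frequency band
#' @param psd data.frame (freq, power).
#' @param lo,hi band edges in Hz; bins with lo < f <= hi are summed.
#' @keywords internal
integrate_band <- function(psd, lo, hi) {
  df <- if (nrow(psd) > 1) psd$freq[2] - psd$freq[1] else 0
  sel <- psd$freq > lo & psd$freq <= hi
  sum(psd$power[sel]) * df
}
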