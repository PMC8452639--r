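#' Electrophysiology signal metrics
#'
#' Operational metrics used on field and patch-clamp recordings: RMS
#' amplitude, threshold event detection with an interevent-interval filter,
#' coastline, band power over the standard eight EEG bands, six per-second
#' segment metrics with a nearest-neighbour library classifier, and
#' synaptic feature extraction (amplitude, decay, half-life, cumulative
#' amplitude sigmoid slope).
#'
#' @name ephys_metrics
NULL

#' Default EEG analysis bands (Hz)
#' @export
EEG_BANDS <- data.frame(
  low = c(1, 4, 8, 12, 30, 50, 70, 120),
  high = c(4, 8, 12, 30, 50, 70, 120, 180))

#' Root-mean-square amplitude
#'
#' RMS of the mean-subtracted samples over the whole recording.
#'
#' @param trace a `trace_recording` (non-empty).
#' @return scalar in trace units.
#' @export
rms <- function(trace) {
  x <- trace$samples
  if (!length(x)) stop("empty trace", call. = FALSE)
  sqrt(mean((x - mean(x))^2))
}

#' Threshold-based event detection
#'
#' Samples whose absolute deviation from the trace mean exceeds
#' `threshold_factor` times the RMS amplitude are grouped into contiguous
#' suprathreshold runs; each run contributes one event at its
#' absolute-peak sample. Events are then scanned in time order and any
#' event closer than `min_iei` to the previously kept event is removed
#' (the earlier event of a violating pair is kept).
#'
#' @param trace a `trace_recording`.
#' @param threshold_factor multiple of the RMS amplitude (default 4).
#' @param min_iei minimum interevent interval in ms (default 15).
#' @param polarity "both" (default, absolute deviation), "inward"
#'   (negative deflections only) or "outward".
#' @return list of class `detected_events`: `times` (s), `peak_amplitudes`
#'   (signed trace units), `threshold_used`, `rms`.
#' @export
detect_events <- function(trace, threshold_factor = 4, min_iei = 15,
                          polarity = c("both", "inward", "outward")) {
  polarity <- match.arg(polarity)
  x <- trace$samples
  if (!length(x)) stop("empty trace", call. = FALSE)
  dev <- x - mean(x)
  r <- sqrt(mean(dev^2))
  thr <- threshold_factor * r
  score <- switch(polarity, both = abs(dev), inward = -dev, outward = dev)
  above <- score > thr
  times <- numeric(0); peaks <- numeric(0)
  if (any(above)) {
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (j in which(runs$values)) {
      idx <- starts[j]:ends[j]
      pk <- idx[which.max(score[idx])]
      times <- c(times, (pk - 1) / trace$sampling_rate)
      peaks <- c(peaks, dev[pk])
    }
    keep <- logical(length(times))
    last <- -Inf
    for (k in seq_along(times)) {
      if ((times[k] - last) * 1000 >= min_iei) {
        keep[k] <- TRUE
        last <- times[k]
      }
    }
    times <- times[keep]; peaks <- peaks[keep]
  }
  structure(list(times = times, peak_amplitudes = peaks,
                 threshold_used = thr, rms = r),
            class = "detected_events")
}

#' Interevent intervals
#'
#' @param events a `detected_events` (or numeric vector of times in s).
#' @return numeric vector of successive differences in ms (empty when fewer
#'   than two events).
#' @export
interevent_intervals <- function(events) {
  t <- if (inherits(events, "detected_events")) events$times else events
  if (length(t) < 2) return(numeric(0))
  diff(t) * 1000
}

#' Per-window coastline length
#'
#' Sum of absolute successive sample differences within each
#' non-overlapping window — the total variation of the signal per window,
#' a standard summary of epileptiform EEG activity.
#'
#' @param trace a `trace_recording`.
#' @param window window length in seconds (default 1).
#' @return numeric vector, one value per complete window, trace units.
#' @export
coastline <- function(trace, window = 1) {
  nw <- round(window * trace$sampling_rate)
  if (nw < 2) stop("window must span at least 2 samples", call. = FALSE)
  x <- trace$samples
  nwin <- length(x) %/% nw
  if (nwin < 1) stop("trace shorter than one window", call. = FALSE)
  vapply(seq_len(nwin), function(k) {
    seg <- x[((k - 1) * nw + 1):(k * nw)]
    sum(abs(diff(seg)))
  }, numeric(1))
}

#' Band power table
#'
#' Welch PSD (2 s Hann segments, 50% overlap) integrated over each band.
#'
#' @param trace a `trace_recording`, at least 2 s long.
#' @param bands data.frame with columns `low`, `high` in Hz; defaults to
#'   the eight standard EEG bands in [EEG_BANDS].
#' @return data.frame with columns `low`, `high`, `power` (units^2).
#' @export
band_power <- function(trace, bands = EEG_BANDS) {
  dur <- length(trace$samples) / trace$sampling_rate
  if (dur < 2) stop("trace must be at least 2 s long", call. = FALSE)
  if (any(bands$high > trace$sampling_rate / 2))
    stop("band extends above the Nyquist frequency", call. = FALSE)
  psd <- welch_psd(trace)
  bands$power <- mapply(function(lo, hi) integrate_band(psd, lo, hi),
                        bands$low, bands$high)
  bands
}

#' Six metrics of a one-second EEG segment
#'
#' Reconstructed segment descriptors for library-based event
#' classification: `power` (mean squared mean-subtracted amplitude),
#' `coastline` (total variation), `intermittency` (fraction of 100 ms
#' sub-windows whose coastline exceeds twice the segment median),
#' `coherence` (maximum normalized autocorrelation at lags 10--500 ms),
#' `asymmetry` (sample skewness) and `spikiness` (peak absolute deviation
#' over RMS). These formulas are reconstructions of an external classifier's
#' metrics from their names; they are defined here operationally.
#'
#' @param segment a `trace_recording` of exactly 1 s.
#' @return named list of six scalars, class `segment_metrics`.
#' @export
segment_metrics <- function(segment) {
  fs <- segment$sampling_rate
  x <- segment$samples
  if (abs(length(x) / fs - 1) > 1e-9)
    stop("segment must be exactly 1 s long", call. = FALSE)
  xc <- x - mean(x)
  pw <- mean(xc^2)
  cl <- sum(abs(diff(x)))
  # intermittency: uneven distribution of activity across 100 ms sub-windows
  nsub <- max(1L, round(0.1 * fs))
  nw <- length(x) %/% nsub
  sub_cl <- vapply(seq_len(nw), function(k)
    sum(abs(diff(x[((k - 1) * nsub + 1):(k * nsub)]))), numeric(1))
  med <- stats::median(sub_cl)
  interm <- if (med > 0) mean(sub_cl > 2 * med) else 0
  # coherence: rhythmicity via the autocorrelation peak at 10-500 ms lags
  lags <- max(1L, round(0.01 * fs)):min(length(x) - 1L, round(0.5 * fs))
  coh <- if (pw > 0) {
    ac <- stats::acf(x, lag.max = max(lags), plot = FALSE,
                     demean = TRUE)$acf[-1]
    max(ac[lags])
  } else 0
  asym <- if (pw > 0) mean(xc^3) / pw^1.5 else 0
  spik <- if (pw > 0) max(abs(xc)) / sqrt(pw) else 0
  structure(list(power = pw, coastline = cl, intermittency = interm,
                 coherence = coh, asymmetry = asym, spikiness = spik),
            class = "segment_metrics")
}

#' Nearest-neighbour segment classification against a labelled library
#'
#' Metrics are z-scored with the library's mean and standard deviation;
#' the query takes the label of the closest library entry in Euclidean
#' distance over the six metrics. Metrics with zero variance in the library
#' are dropped from the distance (with a message). Ties go to the first
#' occurrence.
#'
#' @param metrics a `segment_metrics` for the query segment.
#' @param library data.frame with the six metric columns plus `label`.
#' @return character label.
#' @export
classify_segment <- function(metrics, library) {
  stopifnot(nrow(library) >= 1, "label" %in% names(library))
  cols <- c("power", "coastline", "intermittency", "coherence",
            "asymmetry", "spikiness")
  stopifnot(all(cols %in% names(library)))
  mu <- vapply(library[cols], mean, numeric(1))
  sd_ <- vapply(library[cols], stats::sd, numeric(1))
  sd_[is.na(sd_)] <- 0
  use <- sd_ > 0
  if (!any(use)) return(library$label[1])
  if (any(!use))
    message("dropping zero-variance metrics: ",
            paste(cols[!use], collapse = ", "))
  q <- unlist(metrics[cols])
  z_lib <- scale(as.matrix(library[cols[use]]), center = mu[use],
                 scale = sd_[use])
  z_q <- (q[use] - mu[use]) / sd_[use]
  d2 <- rowSums(sweep(z_lib, 2, z_q)^2)
  library$label[which.min(d2)]
}

#' Segment a recording and build a metric table
#'
#' Convenience wrapper: cuts the trace into non-overlapping 1 s segments
#' and computes [segment_metrics()] for each.
#'
#' @param trace a `trace_recording`.
#' @return data.frame with one row per segment (columns: the six metrics
#'   plus `start`, the segment onset in s).
#' @export
segment_metric_table <- function(trace) {
  fs <- trace$sampling_rate
  nseg <- length(trace$samples) %/% fs
  do.call(rbind, lapply(seq_len(nseg), function(k) {
    seg <- trace_recording(
      trace$samples[((k - 1) * fs + 1):(k * fs)], fs, trace$units)
    m <- segment_metrics(seg)
    data.frame(start = k - 1, as.data.frame(unclass(m)))
  }))
}

# mono-exponential decay fit of the averaged event from peak to 10% of peak;
# log-linear start values refined by nonlinear least squares
fit_decay_tau <- function(avg, fs) {
  pk <- which.max(avg)
  tail_ <- avg[pk:length(avg)]
  stop_at <- which(tail_ <= 0.1 * tail_[1])[1]
  if (is.na(stop_at) || stop_at < 4) stop_at <- length(tail_)
  y <- tail_[seq_len(stop_at)]
  t_ms <- (seq_along(y) - 1) * 1000 / fs
  pos <- y > 0
  if (sum(pos) < 3) stop("fit-failure: decay segment not positive",
                         call. = FALSE)
  lf <- stats::lm(log(y[pos]) ~ t_ms[pos])
  tau0 <- as.numeric(-1 / stats::coef(lf)[2])
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- t_ms[length(t_ms)] / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-t_ms / tau),
                      start = list(a = y[1], tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) as.numeric(tau0) else as.numeric(stats::coef(fit)["tau"])
}

# logistic fit of the empirical amplitude CDF; slope capped for step CDFs
fit_amplitude_sigmoid <- function(amps, slope_cap = 1e6) {
  if (stats::sd(amps) < 1e-12 * max(abs(amps), 1))
    return(list(slope = slope_cap, midpoint = amps[1], capped = TRUE))
  # evaluate the cumulative frequency on a uniform amplitude grid so the
  # fit weighs the full amplitude range, not the sample density
  a <- seq(0, max(amps) * 1.1, length.out = 120)
  cdf <- stats::ecdf(amps)(a)
  s0 <- 1.7 / max(stats::IQR(amps), 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(cdf ~ 1 / (1 + exp(-s * (a - a50))),
                      start = list(s = s0, a50 = stats::median(amps)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    list(slope = s0, midpoint = stats::median(amps), capped = FALSE)
  } else {
    cf <- stats::coef(fit)
    list(slope = min(as.numeric(cf["s"]), slope_cap),
         midpoint = as.numeric(cf["a50"]),
         capped = as.numeric(cf["s"]) > slope_cap)
  }
}

#' Synaptic feature extraction from a patch-clamp trace
#'
#' Detects events (threshold crossing with the polarity of the recorded
#' currents), then summarizes transmission with: mean absolute peak
#' amplitude, interevent intervals, the decay time constant of the
#' peak-aligned average event (mono-exponential least squares from the peak
#' to 10% of peak), the half-life tau * ln 2, and the midpoint slope of a
#' logistic fit to the cumulative amplitude distribution (larger slope =
#' more homogeneous amplitudes).
#'
#' @param trace a `trace_recording` of membrane currents (pA).
#' @param polarity "inward" or "outward" event polarity.
#' @param threshold_factor RMS multiple for detection (default 4).
#' @param min_iei minimum interevent interval, ms.
#' @return list of class `synaptic_features`: `mean_amplitude` (pA),
#'   `ieis` (ms), `decay_tau` (ms), `half_life` (ms),
#'   `sigmoid_midpoint_slope` (1/pA), `n_events`.
#' @export
extract_synaptic_features <- function(trace,
                                      polarity = c("inward", "outward"),
                                      threshold_factor = 4, min_iei = 15) {
  polarity <- match.arg(polarity)
  ev <- detect_events(trace, threshold_factor, min_iei, polarity = polarity)
  if (length(ev$times) < 5)
    stop("insufficient-events: need at least 5 detected events, got ",
         length(ev$times), call. = FALSE)
  amps <- abs(ev$peak_amplitudes)
  fs <- trace$sampling_rate
  # peak-aligned average over a window of [-5, +50] ms
  pre <- round(0.005 * fs); post <- round(0.05 * fs)
  dev <- trace$samples - mean(trace$samples)
  if (polarity == "inward") dev <- -dev
  idx <- round(ev$times * fs) + 1L
  ok <- idx - pre >= 1 & idx + post <= length(dev)
  sweeps <- vapply(idx[ok], function(i) dev[(i - pre):(i + post)],
                   numeric(pre + post + 1))
  avg <- rowMeans(sweeps)
  tau <- fit_decay_tau(avg, fs)
  sig <- fit_amplitude_sigmoid(amps)
  structure(list(mean_amplitude = mean(amps),
                 ieis = interevent_intervals(ev),
                 decay_tau = tau,
                 half_life = tau * log(2),
                 sigmoid_midpoint_slope = sig$slope,
                 slope_capped = isTRUE(sig$capped),
                 n_events = length(ev$times)),
            class = "synaptic_features")
}
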