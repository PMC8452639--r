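#' Synthetic electrophysiology generators
#'
#' Everything the analysis pipeline consumes can be generated here with
#' known ground truth: patch-clamp synaptic-event traces (Poisson event
#' timing, log-normal amplitudes, bi-exponential kernels, Gaussian baseline
#' noise), field recordings (1/f background, suprathreshold interictal
#' transients, ictal epochs with added beta-band oscillation), and
#' "observed" power spectra drawn around microcircuit model predictions.
#'
#' @name synthetic_data
NULL

#' Configuration for a synaptic-event trace
#'
#' @param duration seconds (> 0).
#' @param sampling_rate Hz (>= 1000).
#' @param event_rate mean event rate, events/s (>= 0).
#' @param amp_median median event amplitude, pA.
#' @param amp_log_sd log-normal spread of amplitudes (sd of log amplitude).
#' @param tau_rise,tau_decay bi-exponential kernel time constants in ms
#'   (tau_rise < tau_decay).
#' @param noise_sd Gaussian baseline noise sd, pA.
#' @param polarity "inward" (negative deflections, the voltage-clamp
#'   convention for PSCs at -70 mV) or "outward".
#' @param seed integer RNG seed.
#' @return list of class `synaptic_trace_config`.
#' @export
synaptic_trace_config <- function(duration = 60, sampling_rate = 10000,
                                  event_rate = 2, amp_median = 15,
                                  amp_log_sd = 0.4, tau_rise = 1,
                                  tau_decay = 8, noise_sd = 2,
                                  polarity = c("inward", "outward"),
                                  seed = 1) {
  polarity <- match.arg(polarity)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (sampling_rate < 1000)
    stop("sampling_rate must be at least 1000 Hz", call. = FALSE)
  if (event_rate < 0) stop("event_rate must be non-negative", call. = FALSE)
  if (tau_rise >= tau_decay)
    stop("tau_rise must be smaller than tau_decay", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(list(duration = duration, sampling_rate = sampling_rate,
                 event_rate = event_rate, amp_median = amp_median,
                 amp_log_sd = amp_log_sd, tau_rise = tau_rise,
                 tau_decay = tau_decay, noise_sd = noise_sd,
                 polarity = polarity, seed = as.integer(seed)),
            class = "synaptic_trace_config")
}

#' Condition effects on synaptic transmission
#'
#' Multiplicative effects of the experimental condition on event rate,
#' amplitude, decay time constant and amplitude spread. NMDAR-antibody
#' exposure reduces excitatory (EPSC) rate, amplitude and decay and makes
#' the amplitude distribution more homogeneous (smaller log-normal
#' spread), while leaving inhibitory (IPSC) transmission unchanged; the
#' 7-day condition depresses the EPSC rate further than 48 h.
#'
#' @param condition "control", "nmdar_48h" or "nmdar_7d".
#' @param applies_to "EPSC" or "IPSC".
#' @return list of class `condition_effects` with fields `rate_mult`,
#'   `amp_mult`, `decay_mult`, `spread_mult`.
#' @export
condition_effects <- function(condition = c("control", "nmdar_48h",
                                            "nmdar_7d"),
                              applies_to = c("EPSC", "IPSC")) {
  condition <- match.arg(condition)
  applies_to <- match.arg(applies_to)
  eff <- if (applies_to == "IPSC" || condition == "control") {
    c(rate_mult = 1, amp_mult = 1, decay_mult = 1, spread_mult = 1)
  } else if (condition == "nmdar_48h") {
    c(rate_mult = 0.6, amp_mult = 0.8, decay_mult = 0.7, spread_mult = 0.9)
  } else {
    c(rate_mult = 0.45, amp_mult = 0.7, decay_mult = 0.7, spread_mult = 0.85)
  }
  structure(c(as.list(eff),
              list(condition = condition, applies_to = applies_to)),
            class = "condition_effects")
}

#' Apply condition effects to a trace configuration
#'
#' Multiplies event rate, median amplitude, decay time constant and
#' log-normal amplitude spread by the condition's factors; everything else
#' (including the seed) is unchanged.
#'
#' @param base a `synaptic_trace_config`.
#' @param effects a `condition_effects`.
#' @return a new `synaptic_trace_config`.
#' @export
make_condition_config <- function(base, effects) {
  stopifnot(inherits(base, "synaptic_trace_config"),
            inherits(effects, "condition_effects"))
  synaptic_trace_config(
    duration = base$duration, sampling_rate = base$sampling_rate,
    event_rate = base$event_rate * effects$rate_mult,
    amp_median = base$amp_median * effects$amp_mult,
    amp_log_sd = base$amp_log_sd * effects$spread_mult,
    tau_rise = base$tau_rise,
    tau_decay = base$tau_decay * effects$decay_mult,
    noise_sd = base$noise_sd, polarity = base$polarity, seed = base$seed)
}

#' Homogeneous Poisson event train
#'
#' @param rate events per second (>= 0).
#' @param duration seconds (> 0).
#' @param seed integer RNG seed.
#' @return sorted numeric vector of event times in seconds.
#' @export
sample_event_train <- function(rate, duration, seed = 1) {
  if (rate < 0) stop("rate must be non-negative", call. = FALSE)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  set.seed(as.integer(seed))
  n <- stats::rpois(1, rate * duration)
  sort(stats::runif(n, 0, duration))
}

# bi-exponential synaptic kernel, normalized to unit peak
# w(t) = (exp(-t/tau_decay) - exp(-t/tau_rise)) / peak
psc_kernel <- function(tau_rise, tau_decay, fs, length_sd = 8) {
  t_ms <- seq(0, tau_decay * length_sd, by = 1000 / fs)
  w <- exp(-t_ms / tau_decay) - exp(-t_ms / tau_rise)
  t_peak <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  peak <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  w / peak
}

#' Render a synaptic-event trace with ground truth
#'
#' Sum of unit-peak bi-exponential kernels at Poisson event times, with
#' log-normal amplitudes (median `amp_median`, log-sd `amp_log_sd`) and
#' additive Gaussian baseline noise. Inward polarity renders events as
#' negative deflections.
#'
#' @param config a `synaptic_trace_config`.
#' @return list with `trace` (a `trace_recording`, units pA) and `truth`
#'   (list of `event_times` in s and `event_amps` in pA, both sorted by
#'   time).
#' @export
render_synaptic_trace <- function(config) {
  stopifnot(inherits(config, "synaptic_trace_config"))
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  kern <- psc_kernel(config$tau_rise, config$tau_decay, fs)
  if (length(kern) >= n)
    stop("synaptic kernel longer than the trace; increase duration",
         call. = FALSE)
  times <- sample_event_train(config$event_rate, config$duration,
                              config$seed)
  # drop events too close to the end for a full kernel footprint
  times <- times[round(times * fs) + length(kern) <= n]
  amps <- exp(log(config$amp_median) +
                config$amp_log_sd * stats::rnorm(length(times)))
  x <- numeric(n)
  for (k in seq_along(times)) {
    i0 <- round(times[k] * fs) + 1L
    idx <- i0:(i0 + length(kern) - 1L)
    x[idx] <- x[idx] + amps[k] * kern
  }
  if (config$polarity == "inward") x <- -x
  if (config$noise_sd > 0) x <- x + config$noise_sd * stats::rnorm(n)
  list(trace = trace_recording(x, fs, units = "pA"),
       truth = list(event_times = times, event_amps = amps))
}

#' Configuration for a synthetic field recording
#'
#' @param duration seconds.
#' @param sampling_rate Hz.
#' @param background_exponent beta of the 1/f^beta background.
#' @param background_scale background RMS amplitude, uV.
#' @param spike_rate interictal transient rate, events/s.
#' @param spike_amp_factor transient peak amplitude in multiples of the
#'   background RMS (> 4 for reliably detectable fixtures).
#' @param spike_tau_rise,spike_tau_decay transient kernel time constants, ms.
#' @param ictal_epochs data.frame with columns `start`, `end` (s),
#'   `beta_amp` (RMS amplitude in uV of an added 12--30 Hz oscillation) and
#'   `spike_rate_mult`; epochs must lie within the recording and must not
#'   overlap. NULL for none.
#' @param seed integer RNG seed.
#' @export
field_trace_config <- function(duration = 120, sampling_rate = 1000,
                               background_exponent = 1.5,
                               background_scale = 20,
                               spike_rate = 0.5, spike_amp_factor = 8,
                               spike_tau_rise = 3, spike_tau_decay = 25,
                               ictal_epochs = NULL, seed = 1) {
  if (duration <= 0 || sampling_rate <= 0)
    stop("duration and sampling_rate must be positive", call. = FALSE)
  if (!is.null(ictal_epochs)) {
    ictal_epochs <- as.data.frame(ictal_epochs)
    stopifnot(all(c("start", "end", "beta_amp", "spike_rate_mult") %in%
                    names(ictal_epochs)))
    if (any(ictal_epochs$start < 0) || any(ictal_epochs$end > duration) ||
        any(ictal_epochs$end <= ictal_epochs$start))
      stop("ictal epochs must lie within [0, duration]", call. = FALSE)
    o <- order(ictal_epochs$start)
    ictal_epochs <- ictal_epochs[o, ]
    if (nrow(ictal_epochs) > 1 &&
        any(ictal_epochs$start[-1] < ictal_epochs$end[-nrow(ictal_epochs)]))
      stop("ictal epochs must not overlap", call. = FALSE)
  }
  structure(list(duration = duration, sampling_rate = sampling_rate,
                 background_exponent = background_exponent,
                 background_scale = background_scale,
                 spike_rate = spike_rate,
                 spike_amp_factor = spike_amp_factor,
                 spike_tau_rise = spike_tau_rise,
                 spike_tau_decay = spike_tau_decay,
                 ictal_epochs = ictal_epochs, seed = as.integer(seed)),
            class = "field_trace_config")
}

#' Render a synthetic field recording with ground truth
#'
#' Background: white Gaussian noise spectrally shaped to 1/f^beta and scaled
#' to the requested RMS. Interictal transients: bi-exponential kernels with
#' peak amplitude `spike_amp_factor` times the background RMS, alternating
#' polarity. Within ictal epochs the spike rate is multiplied and a
#' band-limited 12--30 Hz oscillation of the requested RMS amplitude is
#' added.
#'
#' @param config a `field_trace_config`.
#' @return list with `trace` (units uV) and `truth` (`event_times`,
#'   `event_amps`, `epochs`).
#' @export
render_field_trace <- function(config) {
  stopifnot(inherits(config, "field_trace_config"))
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  set.seed(config$seed)
  beta <- config$background_exponent
  bg <- shaped_noise(n, fs, function(f) f^(-beta))
  bg <- bg / stats::sd(bg) * config$background_scale
  x <- bg

  in_epoch <- function(t) {
    ep <- config$ictal_epochs
    if (is.null(ep) || nrow(ep) == 0) return(rep(0L, length(t)))
    out <- integer(length(t))
    for (j in seq_len(nrow(ep)))
      out[t >= ep$start[j] & t < ep$end[j]] <- j
    out
  }

  # piecewise-constant-rate spike train via thinning of a dominating train
  mults <- if (is.null(config$ictal_epochs)) 1 else
    c(1, config$ictal_epochs$spike_rate_mult)
  rate_max <- config$spike_rate * max(mults)
  times <- amps <- numeric(0)
  if (rate_max > 0) {
    cand <- sample_event_train(rate_max, config$duration,
                               seed = config$seed + 1L)
    ep_id <- in_epoch(cand)
    local_rate <- config$spike_rate *
      ifelse(ep_id == 0, 1, config$ictal_epochs$spike_rate_mult[pmax(ep_id, 1)])
    keep <- stats::runif(length(cand)) < local_rate / rate_max
    times <- cand[keep]
  }
  if (length(times)) {
    kern <- psc_kernel(config$spike_tau_rise, config$spike_tau_decay, fs)
    amp0 <- config$spike_amp_factor * config$background_scale
    amps <- amp0 * (1 + 0.1 * stats::rnorm(length(times))) *
      rep_len(c(1, -1), length(times))  # alternating polarity transients
    keep <- round(times * fs) + length(kern) <= n
    times <- times[keep]; amps <- amps[keep]
    for (k in seq_along(times)) {
      i0 <- round(times[k] * fs) + 1L
      idx <- i0:(i0 + length(kern) - 1L)
      x[idx] <- x[idx] + amps[k] * kern
    }
  }

  ep <- config$ictal_epochs
  if (!is.null(ep) && nrow(ep)) {
    t <- trace_times(trace_recording(x, fs))
    for (j in seq_len(nrow(ep))) {
      sel <- t >= ep$start[j] & t < ep$end[j]
      m <- sum(sel)
      if (m < 8 || ep$beta_amp[j] <= 0) next
      osc <- shaped_noise(m, fs, function(f)
        ifelse(f >= 12 & f <= 30, 1, 0))
      osc <- osc / stats::sd(osc) * ep$beta_amp[j]
      x[sel] <- x[sel] + osc
    }
  }

  epochs <- if (is.null(ep)) NULL else
    data.frame(start = ep$start, end = ep$end, label = "ictal")
  list(trace = trace_recording(x, fs, units = "uV"),
       truth = list(event_times = times, event_amps = amps,
                    epochs = epochs))
}

#' Observed spectra for a triplet of circuit states
#'
#' Draws "empirical" power spectra around the model-predicted spectra of
#' three microcircuit parameterizations (control, interictal, ictal):
#' observed log-PSD = predicted log-PSD + independent Gaussian noise per
#' frequency.
#'
#' @param params_list list of three (or more) `cmc_params`, all stable.
#' @param log_noise_sd sd of the additive log-domain noise.
#' @param freqs frequency grid in Hz.
#' @param seed integer RNG seed.
#' @return list of data.frames (freq, power), one per state, named as
#'   `params_list`.
#' @export
generate_state_psd_data <- function(params_list, log_noise_sd, freqs,
                                    seed = 1) {
  set.seed(as.integer(seed))
  lapply(params_list, function(p) {
    psd <- predict_psd(p, freqs)  # errors if unstable
    psd$power <- exp(log(psd$power) +
                       log_noise_sd * stats::rnorm(nrow(psd)))
    psd
  })
}
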