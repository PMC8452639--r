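#' Canonical microcircuit neural mass model
#'
#' Four neural populations -- spiny stellate cells (ss), inhibitory
#' interneurons (ii), superficial pyramidal cells (sp) and deep pyramidal
#' cells (dp) -- arranged as two coupled excitatory--inhibitory oscillator
#' pairs: a fast superficial pair (ss, sp) and a slow deep pair (ii, dp).
#' Each population is a second-order ("alpha") synaptic kernel with time
#' constant tau; populations interact through ten signed effective couplings
#' gamma, with presynaptic firing passed through a zero-centred sigmoid of
#' slope sigma. The local field potential is read out as a weighted mix of
#' the two pyramidal membrane potentials.
#'
#' Time is handled internally in milliseconds (tau is specified in ms);
#' frequencies at the interface are in Hz.
#'
#' @name cmc_model
NULL

# population order used throughout: state vector is
# (v_ss, i_ss, v_ii, i_ii, v_sp, i_sp, v_dp, i_dp)
CMC_POPULATIONS <- c("ss", "ii", "sp", "dp")

# coupling table: gamma_k scales src -> tgt with the given sign
CMC_WIRING <- data.frame(
  gamma = paste0("gamma", 1:10),
  src  = c("ss", "dp", "ss", "sp", "ii", "ii", "sp", "ii", "ss", "dp"),
  tgt  = c("ii", "ii", "sp", "ss", "ss", "dp", "sp", "ii", "ss", "dp"),
  sign = c(1L, 1L, 1L, -1L, -1L, -1L, -1L, -1L, -1L, -1L),
  stringsAsFactors = FALSE
)

#' Construct a canonical microcircuit parameter set
#'
#' @param tau named numeric of length 4, postsynaptic time constants in ms
#'   for populations `ss`, `ii`, `sp`, `dp`.
#' @param gamma numeric of length 10, signed effective coupling strengths
#'   `gamma1`..`gamma10`. Excitatory couplings (gamma1--gamma3) must be
#'   non-negative, inhibitory ones (gamma4--gamma10) non-positive.
#' @param sigma named numeric of length 4 (or a single value, recycled),
#'   sigmoid slopes in 1/mV per population.
#' @param obs_gain scalar observation gain.
#' @param obs_mix length-2 weights (alpha_sp, alpha_dp) mixing the two
#'   pyramidal potentials into the observed signal.
#' @param innov input-noise spectrum parameters (a_u, b_u, c_u): the
#'   innovations driving the spiny stellate population have one-sided power
#'   spectral density a_u * f^(-b_u) + c_u.
#' @param chan_noise flat additive observation-noise spectral level a_n.
#' @return An object of class `cmc_params`.
#' @export
cmc_params <- function(tau = c(ss = 4, ii = 16, sp = 8, dp = 28),
                       gamma = c(0.5, 0.4, 1.5, -1.5, -0.5,
                                 -0.4, -0.5, -0.2, -0.5, -0.2),
                       sigma = c(ss = 1, ii = 1, sp = 1, dp = 1),
                       obs_gain = 1,
                       obs_mix = c(sp = 1, dp = 0.5),
                       innov = c(a_u = 1, b_u = 1, c_u = 0.05),
                       chan_noise = 1e-4) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 4L)
  tau <- stats::setNames(as.numeric(tau), CMC_POPULATIONS)
  sigma <- stats::setNames(as.numeric(sigma), CMC_POPULATIONS)
  gamma <- stats::setNames(as.numeric(gamma), paste0("gamma", 1:10))
  stopifnot(length(tau) == 4L, length(gamma) == 10L, length(sigma) == 4L)
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("tau must be positive and finite", call. = FALSE)
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  bad <- sign(gamma) * CMC_WIRING$sign < 0
  if (any(bad))
    stop("gamma sign violates wiring convention for: ",
         paste(names(gamma)[bad], collapse = ", "), call. = FALSE)
  innov <- stats::setNames(as.numeric(innov), c("a_u", "b_u", "c_u"))
  if (innov[["a_u"]] < 0 || innov[["c_u"]] < 0 || chan_noise < 0)
    stop("noise spectral levels must be non-negative", call. = FALSE)
  structure(list(tau = tau, gamma = gamma, sigma = sigma,
                 obs_gain = obs_gain,
                 obs_mix = stats::setNames(as.numeric(obs_mix), c("sp", "dp")),
                 innov = innov, chan_noise = as.numeric(chan_noise)),
            class = "cmc_params")
}

#' @export
print.cmc_params <- function(x, ...) {
  cat("Canonical microcircuit parameters\n")
  cat("  tau (ms):  ", paste(sprintf("%s=%.3g", names(x$tau), x$tau),
                             collapse = "  "), "\n")
  cat("  gamma:     ", paste(sprintf("%.3g", x$gamma), collapse = " "), "\n")
  cat("  sigma (1/mV):", paste(sprintf("%s=%.3g", names(x$sigma), x$sigma),
                               collapse = "  "), "\n")
  st <- stability(x)
  cat(sprintf("  stable: %s (max Re eig = %.3g /s)\n",
              st$is_stable, st$max_real_eig))
  invisible(x)
}

#' Zero-centred population firing sigmoid
#'
#' S(v) = 1 / (1 + exp(-sigma * v)) - 1/2, mapping membrane potential to a
#' normalized firing rate in (-1/2, 1/2) with S(0) = 0 and slope sigma/4 at
#' the origin, so the resting point of the circuit is exactly the origin.
#'
#' @param v membrane potential (mV).
#' @param sigma sigmoid slope (1/mV), positive.
#' @return Normalized rate, same shape as `v`.
#' @export
firing_sigmoid <- function(v, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  1 / (1 + exp(-sigma * v)) - 0.5
}

#' Time derivatives of the microcircuit state
#'
#' Each population obeys v' = i and
#' i' = m / tau - 2 i / tau - v / tau^2, with synaptic drive
#' m_p = sum over afferents of gamma * S(v_src) and the exogenous input `u`
#' added to the spiny stellate drive. Time unit: ms.
#'
#' @param states numeric length 8, ordered (v, i) per population ss, ii, sp, dp.
#' @param params a `cmc_params` object.
#' @param u exogenous input to the spiny stellate population (scalar).
#' @return numeric length 8 of derivatives (per ms).
#' @export
state_derivatives <- function(states, params, u = 0) {
  stopifnot(length(states) == 8L, all(is.finite(states)))
  v <- states[c(1, 3, 5, 7)]
  ii <- states[c(2, 4, 6, 8)]
  names(v) <- names(ii) <- CMC_POPULATIONS
  s <- firing_sigmoid(v, params$sigma)
  m <- c(ss = u, ii = 0, sp = 0, dp = 0)
  for (k in seq_len(10)) {
    src <- CMC_WIRING$src[k]; tgt <- CMC_WIRING$tgt[k]
    m[tgt] <- m[tgt] + params$gamma[k] * s[src]
  }
  tau <- params$tau
  di <- m / tau - 2 * ii / tau - v / tau^2
  out <- numeric(8)
  out[c(1, 3, 5, 7)] <- ii
  out[c(2, 4, 6, 8)] <- di
  out
}

#' Linearize the microcircuit at its resting point
#'
#' The origin is a fixed point by construction (S(0) = 0). The sigmoid is
#' replaced by its slope sigma/4, giving an 8x8 Jacobian A (units 1/ms),
#' an input map B routing innovations into the spiny stellate current
#' equation, and an output row C = obs_gain * (alpha_sp v_sp + alpha_dp v_dp).
#'
#' @param params a `cmc_params` object.
#' @return list with `A`, `B`, `C`, `stable` (logical) and `max_real_eig`
#'   (1/s), of class `cmc_linsys`.
#' @export
linearize <- function(params) {
  A <- matrix(0, 8, 8)
  iv <- function(p) 2L * match(p, CMC_POPULATIONS) - 1L
  ic <- function(p) 2L * match(p, CMC_POPULATIONS)
  tau <- params$tau
  for (p in CMC_POPULATIONS) {
    A[iv(p), ic(p)] <- 1
    A[ic(p), iv(p)] <- -1 / tau[p]^2
    A[ic(p), ic(p)] <- -2 / tau[p]
  }
  for (k in seq_len(10)) {
    src <- CMC_WIRING$src[k]; tgt <- CMC_WIRING$tgt[k]
    A[ic(tgt), iv(src)] <- A[ic(tgt), iv(src)] +
      params$gamma[k] * params$sigma[src] / 4 / tau[tgt]
  }
  B <- matrix(0, 8, 1)
  B[ic("ss"), 1] <- 1 / tau["ss"]
  C <- matrix(0, 1, 8)
  C[1, iv("sp")] <- params$obs_gain * params$obs_mix[["sp"]]
  C[1, iv("dp")] <- params$obs_gain * params$obs_mix[["dp"]]
  ev <- eigen(A, only.values = TRUE)$values
  mre <- max(Re(ev)) * 1000  # convert 1/ms -> 1/s
  structure(list(A = A, B = B, C = C,
                 stable = mre < 0, max_real_eig = mre),
            class = "cmc_linsys")
}

#' Stability of a parameterization
#'
#' @param params a `cmc_params` object.
#' @return list(is_stable, max_real_eig) with the eigenvalue in 1/s.
#' @export
stability <- function(params) {
  ls <- linearize(params)
  list(is_stable = ls$stable, max_real_eig = ls$max_real_eig)
}

#' Transfer function of the linearized circuit
#'
#' T(omega) = C (i omega I - A)^-1 B evaluated on a grid of frequencies.
#' Uses the eigendecomposition of A for speed, falling back to direct
#' per-frequency solves when A is defective (e.g. fully decoupled
#' populations give repeated eigenvalues).
#'
#' @param linsys a `cmc_linsys` from [linearize()].
#' @param freqs frequencies in Hz (positive).
#' @return complex vector of gains, one per frequency.
#' @export
transfer_function <- function(linsys, freqs) {
  stopifnot(all(freqs >= 0))
  w <- 2 * pi * freqs / 1000  # rad/ms
  A <- linsys$A
  eg <- eigen(A)
  rc <- tryCatch(rcond(eg$vectors), error = function(e) 0)
  if (is.finite(rc) && rc > 1e-10) {
    w1 <- as.vector(linsys$C %*% eg$vectors)
    w2 <- as.vector(solve(eg$vectors, linsys$B))
    r <- w1 * w2
    # T(w) = sum_k r_k / (i w - d_k), vectorized over frequencies
    denom <- outer(1i * w, eg$values, "-")
    as.vector(denom^(-1) %*% r)
  } else {
    vapply(w, function(wi) {
      (linsys$C %*% solve(diag(1i * wi, 8) - A, linsys$B))[1, 1]
    }, complex(1))
  }
}

#' Predicted steady-state power spectral density
#'
#' PSD(f) = |T(f)|^2 * (a_u f^-b_u + c_u) + a_n: the squared transfer gain
#' shaped by the innovation spectrum plus a flat observation-noise floor.
#'
#' @param params a `cmc_params` object (must be stable).
#' @param freqs frequencies in Hz, strictly increasing and positive.
#' @return data.frame with columns `freq` (Hz) and `power`.
#' @export
predict_psd <- function(params, freqs) {
  stopifnot(all(diff(freqs) > 0), all(freqs > 0))
  ls <- linearize(params)
  if (!ls$stable)
    stop(sprintf("unstable parameterization (max Re eig = %.3g /s)",
                 ls$max_real_eig), call. = FALSE)
  tf <- transfer_function(ls, freqs)
  gu <- params$innov[["a_u"]] * freqs^(-params$innov[["b_u"]]) +
    params$innov[["c_u"]]
  data.frame(freq = freqs, power = Mod(tf)^2 * gu + params$chan_noise)
}

#' Stochastic time-domain simulation of the full nonlinear circuit
#'
#' Euler--Maruyama integration driven by an input realization whose
#' one-sided spectrum equals the model innovation spectrum (generated by
#' frequency-domain shaping of white Gaussian noise), plus flat channel
#' noise on the output, so that in the small-noise (linear) regime the Welch
#' spectrum of the output matches [predict_psd()]. Used as the numerical
#' oracle for the analytic spectral prediction.
#'
#' @param params a `cmc_params` object.
#' @param duration seconds.
#' @param fs sampling rate in Hz (>= 1000).
#' @param noise_sd multiplier on the innovation amplitude (1 reproduces the
#'   parameterized innovation spectrum; 0 gives the silent equilibrium).
#' @param seed integer RNG seed.
#' @return a [trace_recording()] of the observed output.
#' @export
simulate_timeseries <- function(params, duration, fs = 1000, noise_sd = 1,
                                seed = 1) {
  stopifnot(fs >= 1000, duration > 0)
  n <- round(duration * fs)
  dt <- 1000 / fs  # ms per step
  set.seed(as.integer(seed))
  # innovation realization with one-sided PSD noise_sd^2 * (a_u f^-b_u + c_u)
  u <- shaped_noise(n, fs, function(f) {
    params$innov[["a_u"]] * f^(-params$innov[["b_u"]]) + params$innov[["c_u"]]
  }) * noise_sd
  # precomputed 4x4 rate->drive coupling matrix (rows = target population)
  G <- matrix(0, 4, 4, dimnames = list(CMC_POPULATIONS, CMC_POPULATIONS))
  for (k in seq_len(10))
    G[CMC_WIRING$tgt[k], CMC_WIRING$src[k]] <-
      G[CMC_WIRING$tgt[k], CMC_WIRING$src[k]] + params$gamma[k]
  tau <- params$tau; sig <- params$sigma
  e_ss <- c(1, 0, 0, 0)
  deriv <- function(v, i, uk) {
    s <- 1 / (1 + exp(-sig * v)) - 0.5
    m <- as.vector(G %*% s) + uk * e_ss
    list(dv = i, di = m / tau - 2 * i / tau - v / tau^2)
  }
  v <- i <- numeric(4)
  out <- numeric(n)
  Cw <- c(0, 0, params$obs_gain * params$obs_mix[["sp"]],
          params$obs_gain * params$obs_mix[["dp"]])
  # Heun (improved Euler) steps: preserves the damping of the fast
  # oscillatory modes at 1 ms steps where plain forward Euler does not
  for (k in seq_len(n)) {
    d1 <- deriv(v, i, u[k])
    vp <- v + dt * d1$dv; ip <- i + dt * d1$di
    d2 <- deriv(vp, ip, u[k])
    v <- v + dt * (d1$dv + d2$dv) / 2
    i <- i + dt * (d1$di + d2$di) / 2
    if (!all(is.finite(v)) || max(abs(v)) > 1e6)
      stop("unstable simulation: state overflow at t = ",
           signif(k / fs, 4), " s", call. = FALSE)
    out[k] <- sum(Cw * v)
  }
  if (params$chan_noise > 0) {
    # flat one-sided PSD a_n  ->  per-sample variance a_n * fs / 2
    out <- out + noise_sd * sqrt(params$chan_noise * fs / 2) *
      stats::rnorm(n)
  }
  trace_recording(out, fs, units = "mV")
}

#' Scale a parameter set by log-scaling factors
#'
#' Applies theta = theta_default * exp(lambda) to the 18 free neuronal
#' parameters (4 tau, 10 gamma, 4 sigma). `lambda` may be a full named
#' vector in [cmc_free_param_names()] order or any named subset.
#'
#' @param params baseline `cmc_params`.
#' @param lambda named numeric of log-scaling factors.
#' @return a new `cmc_params`.
#' @export
apply_log_scaling <- function(params, lambda) {
  nm <- names(lambda)
  if (is.null(nm)) {
    stopifnot(length(lambda) == 18L)
    nm <- cmc_free_param_names()
    names(lambda) <- nm
  }
  unknown <- setdiff(nm, cmc_free_param_names())
  if (length(unknown))
    stop("unknown parameter names: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p <- params
  for (f in nm) {
    v <- exp(lambda[[f]])
    if (startsWith(f, "tau_")) {
      p$tau[sub("tau_", "", f)] <- p$tau[sub("tau_", "", f)] * v
    } else if (startsWith(f, "gamma")) {
      p$gamma[f] <- p$gamma[f] * v
    } else {
      p$sigma[sub("sigma_", "", f)] <- p$sigma[sub("sigma_", "", f)] * v
    }
  }
  p
}

#' Names of the free neuronal parameters, in canonical order
#'
#' @return character vector: 4 time constants, 10 couplings, 4 sigmoid
#'   slopes.
#' @export
cmc_free_param_names <- function() {
  c(paste0("tau_", CMC_POPULATIONS), paste0("gamma", 1:10),
    paste0("sigma_", CMC_POPULATIONS))
}

#' Serialize / restore parameters as JSON
#'
#' @param params a `cmc_params` object.
#' @param path file path.
#' @export
write_cmc_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cmc_params
#' @export
read_cmc_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cmc_params(tau = x$tau, gamma = x$gamma, sigma = x$sigma,
             obs_gain = x$obs_gain, obs_mix = x$obs_mix,
             innov = x$innov, chan_noise = x$chan_noise)
}
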