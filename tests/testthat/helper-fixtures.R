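# shared fixtures: small, fast constructions used across test files

make_sine_trace <- function(amp = 1, freq = 10, fs = 5000, duration = 5) {
  t <- (0:(fs * duration - 1)) / fs
  trace_recording(amp * sin(2 * pi * freq * t), fs)
}

# trace with isolated injected unit-peak spikes on a flat baseline plus
# small noise; returns trace and true spike times
make_spike_fixture <- function(n_spikes = 20, spacing = 0.25, amp = 10,
                               noise_sd = 0.5, fs = 2000, seed = 1) {
  set.seed(seed)
  duration <- (n_spikes + 2) * spacing
  n <- round(duration * fs)
  x <- noise_sd * rnorm(n)
  times <- spacing * seq_len(n_spikes)
  kern <- epicmc:::psc_kernel(2, 12, fs)
  rms0 <- sd(x)
  for (tt in times) {
    i0 <- round(tt * fs) + 1L
    idx <- i0:(i0 + length(kern) - 1L)
    x[idx] <- x[idx] + amp * rms0 * kern
  }
  list(trace = trace_recording(x, fs), times = times)
}

# linear-Gaussian toy forward model and its exact log evidence
make_linear_toy <- function(np = 4, ny = 40, noise_var = 0.04, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(ny * np), ny, np)
  lam_true <- seq(-0.3, 0.3, length.out = np)
  y <- as.numeric(X %*% lam_true + sqrt(noise_var) * rnorm(ny))
  prior <- param_density(stats::setNames(rep(0, np), paste0("b", seq_len(np))),
                         0.25)
  S <- X %*% prior$cov %*% t(X) + diag(noise_var, ny)
  log_ev <- as.numeric(-0.5 * (t(y) %*% solve(S, y)) -
                         0.5 * determinant(S)$modulus -
                         ny / 2 * log(2 * pi))
  list(X = X, y = y, prior = prior, noise_var = noise_var,
       forward = function(l) as.numeric(X %*% l), log_evidence = log_ev)
}

# fast inversion settings used throughout the suite (coarser grid than the
# interface default, same structure)
test_settings <- function(max_iter = 48, ...) {
  fit_settings(freq_step = 1, max_iter = max_iter, ...)
}
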