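test_that("event trains are Poisson, sorted, seeded and validated", {
  expect_identical(sample_event_train(0, 100, seed = 1), numeric(0))
  a <- sample_event_train(3, 50, seed = 7)
  b <- sample_event_train(3, 50, seed = 7)
  expect_identical(a, b)
  expect_false(is.unsorted(a))
  expect_true(all(a >= 0 & a <= 50))
  expect_error(sample_event_train(-1, 10), "non-negative")
  expect_error(sample_event_train(1, -10), "positive")

  # mean count over seeds matches the Poisson expectation (rate*duration)
  counts <- vapply(1:200, function(s)
    length(sample_event_train(5, 100, seed = s)), numeric(1))
  expect_lt(abs(mean(counts) - 500), 3 * sqrt(500))
})

test_that("synaptic traces match their ground truth construction", {
  # no events, no noise -> all-zero trace
  cfg0 <- synaptic_trace_config(duration = 2, event_rate = 0, noise_sd = 0)
  r0 <- render_synaptic_trace(cfg0)
  expect_equal(max(abs(r0$trace$samples)), 0)
  expect_length(r0$truth$event_times, 0)

  # single isolated event, no noise: peak equals the drawn amplitude
  cfg1 <- synaptic_trace_config(duration = 5, event_rate = 0.2,
                                amp_log_sd = 0, noise_sd = 0, seed = 3)
  r1 <- render_synaptic_trace(cfg1)
  if (length(r1$truth$event_times) >= 1) {
    expect_equal(max(abs(r1$trace$samples)),
                 max(r1$truth$event_amps), tolerance = 1e-3)
  }
  # inward polarity renders negative deflections
  expect_lte(min(r1$trace$samples), 0)

  # reproducibility: pure function of config
  r1b <- render_synaptic_trace(cfg1)
  expect_identical(r1$trace$samples, r1b$trace$samples)
})

test_that("near-zero rise time gives a mono-exponential decay", {
  cfg <- synaptic_trace_config(duration = 30, sampling_rate = 10000,
                               event_rate = 0.3, amp_log_sd = 0,
                               tau_rise = 0.05, tau_decay = 10,
                               noise_sd = 0, seed = 8)
  feat <- extract_synaptic_features(render_synaptic_trace(cfg)$trace,
                                    "inward")
  expect_equal(feat$decay_tau, 10, tolerance = 0.02)
  expect_equal(feat$half_life, feat$decay_tau * log(2))
})

test_that("condition effects rescale configs as documented", {
  base <- synaptic_trace_config()
  ident <- make_condition_config(base, condition_effects("control", "EPSC"))
  expect_equal(unclass(ident), unclass(base))
  # IPSCs are untouched by the NMDAR condition
  ipsc <- make_condition_config(base, condition_effects("nmdar_48h", "IPSC"))
  expect_equal(unclass(ipsc), unclass(base))

  eff <- condition_effects("nmdar_48h", "EPSC")
  mod <- make_condition_config(base, eff)
  expect_equal(mod$event_rate, base$event_rate * eff$rate_mult)
  expect_equal(mod$amp_median, base$amp_median * eff$amp_mult)
  expect_equal(mod$tau_decay, base$tau_decay * eff$decay_mult)
  expect_equal(mod$sampling_rate, base$sampling_rate)

  # rate thinning: mean detected count scales with rate_mult across seeds
  n_ctrl <- vapply(1:12, function(s) {
    cfg <- synaptic_trace_config(duration = 40, seed = s)
    length(render_synaptic_trace(cfg)$truth$event_times)
  }, numeric(1))
  n_nmdar <- vapply(1:12, function(s) {
    cfg <- make_condition_config(synaptic_trace_config(duration = 40,
                                                       seed = s + 500), eff)
    length(render_synaptic_trace(cfg)$truth$event_times)
  }, numeric(1))
  expect_equal(mean(n_nmdar) / mean(n_ctrl), eff$rate_mult,
               tolerance = 0.15)

  # the 7-day condition depresses the rate further than 48 h
  expect_lt(condition_effects("nmdar_7d", "EPSC")$rate_mult,
            condition_effects("nmdar_48h", "EPSC")$rate_mult)
})

test_that("field traces have the requested spectral and event content", {
  # pure shaped background: log-log PSD slope near -beta, low FP rate
  cfg <- field_trace_config(duration = 60, spike_rate = 0, seed = 3)
  ft <- render_field_trace(cfg)
  w <- welch_psd(ft$trace)
  sel <- w$freq >= 2 & w$freq <= 80
  slope <- unname(coef(lm(log(w$power[sel]) ~ log(w$freq[sel])))[2])
  expect_equal(slope, -cfg$background_exponent, tolerance = 0.2)
  fp_rate <- length(detect_events(ft$trace)$times) / cfg$duration
  expect_lt(fp_rate, 0.5)

  # far-suprathreshold spikes are recovered exactly
  fx <- render_field_trace(field_trace_config(
    duration = 30, spike_rate = 0.5, spike_amp_factor = 10, seed = 4))
  ev <- detect_events(fx$trace)
  expect_equal(length(ev$times), length(fx$truth$event_times))

  # ictal epoch carries excess 12-30 Hz power
  ep <- data.frame(start = 20, end = 40, beta_amp = 30, spike_rate_mult = 3)
  fe <- render_field_trace(field_trace_config(
    duration = 60, spike_rate = 0, ictal_epochs = ep, seed = 5))
  fs <- fe$trace$sampling_rate
  seg_in <- trace_recording(fe$trace$samples[(20 * fs + 1):(40 * fs)], fs)
  seg_out <- trace_recording(fe$trace$samples[(40 * fs + 1):(60 * fs)], fs)
  bp_in <- band_power(seg_in)$power[4]    # 12-30 Hz band
  bp_out <- band_power(seg_out)$power[4]
  expect_gt(bp_in, bp_out)
  expect_equal(fe$truth$epochs$label, "ictal")

  expect_error(field_trace_config(
    duration = 60,
    ictal_epochs = data.frame(start = c(0, 5), end = c(10, 15),
                              beta_amp = 1, spike_rate_mult = 1)),
    "overlap")
})

test_that("state PSD data scatters around the model prediction", {
  trip <- default_state_triplet()
  fr <- seq(2, 80, 2)
  exact <- generate_state_psd_data(trip$params["control"], 0, fr, seed = 1)
  expect_equal(exact$control$power, predict_psd(trip$params0, fr)$power)

  d1 <- generate_state_psd_data(trip$params, 0.1, fr, seed = 1)
  d2 <- generate_state_psd_data(trip$params, 0.1, fr, seed = 2)
  expect_false(identical(d1$control$power, d2$control$power))

  # log-domain average over replicates approaches the noiseless spectrum
  reps <- vapply(1:50, function(s)
    log(generate_state_psd_data(trip$params["control"], 0.1, fr,
                                seed = s)$control$power),
    numeric(length(fr)))
  se <- 0.1 / sqrt(50)
  dev <- rowMeans(reps) - log(predict_psd(trip$params0, fr)$power)
  expect_lt(max(abs(dev)), 3 * se + 1e-12)

  # unstable parameterization is refused
  hot <- apply_log_scaling(trip$params0,
                           c(gamma2 = 1.5, gamma6 = 1.5))
  expect_error(generate_state_psd_data(list(hot), 0.1, fr), "unstable")
})

test_that("traces round-trip through the two-column text format", {
  tr <- make_sine_trace(duration = 1)
  path <- withr::local_tempfile(fileext = ".txt")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$sampling_rate, tr$sampling_rate)
  expect_equal(back$samples, tr$samples, tolerance = 1e-6)
  expect_equal(back$units, tr$units)
})
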