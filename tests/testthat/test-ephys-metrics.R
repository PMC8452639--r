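test_that("rms matches closed forms", {
  expect_equal(rms(trace_recording(rep(3.7, 100), 1000)), 0)
  tr <- make_sine_trace(amp = 2, freq = 20, fs = 5000, duration = 5)
  expect_equal(rms(tr), 2 / sqrt(2), tolerance = 1e-3)
  set.seed(1)
  wn <- trace_recording(rnorm(1e6), 1000)
  expect_equal(rms(wn), 1, tolerance = 0.01)
  expect_error(rms(trace_recording(numeric(0), 1000)), "empty")
})

test_that("event detection applies the threshold and the IEI rule", {
  flat <- trace_recording(rep(0.5, 2000), 1000)
  expect_length(detect_events(flat)$times, 0)

  # two suprathreshold spikes 10 ms apart collapse to one event
  fs <- 2000
  x <- rnorm(fs, sd = 0.1)
  x[c(1000, 1020)] <- 10   # 10 ms apart at 2 kHz
  ev <- detect_events(trace_recording(x, fs))
  near <- ev$times[ev$times > 0.45 & ev$times < 0.55]
  expect_length(near, 1)
  expect_equal(near, 999 / fs, tolerance = 1e-9)

  # fixture recovery: exact count, times within 2 ms
  fx <- make_spike_fixture(n_spikes = 20, amp = 10)
  ev2 <- detect_events(fx$trace)
  expect_length(ev2$times, 20)
  expect_lt(max(abs(ev2$times - (fx$times +
                                   which.max(epicmc:::psc_kernel(2, 12, 2000)) / 2000))),
            0.002 + 0.005)  # peak offset of the kernel plus slack
})

test_that("detection is invariant to DC offset and events carry the rms", {
  fx <- make_spike_fixture(n_spikes = 10, amp = 8, seed = 5)
  ev <- detect_events(fx$trace)
  shifted <- trace_recording(fx$trace$samples + 1000, fx$trace$sampling_rate)
  ev_s <- detect_events(shifted)
  expect_equal(ev$times, ev_s$times)
  expect_equal(ev$peak_amplitudes, ev_s$peak_amplitudes, tolerance = 1e-9)
  expect_equal(ev_s$rms, ev$rms, tolerance = 1e-9)
  expect_equal(ev$threshold_used, 4 * ev$rms)
})

test_that("interevent intervals are successive differences in ms", {
  expect_length(interevent_intervals(numeric(0)), 0)
  expect_length(interevent_intervals(1.5), 0)
  expect_equal(interevent_intervals(c(0, 0.1, 0.3)), c(100, 200))

  # Poisson fixture: mean IEI near 1/rate
  times <- sample_event_train(2, 500, seed = 9)
  iei <- interevent_intervals(times)
  se <- 500 / sqrt(length(iei))
  expect_lt(abs(mean(iei) - 500), 3 * se)
})

test_that("coastline matches the total variation of a sinusoid", {
  expect_equal(coastline(trace_recording(rep(1, 3000), 1000)),
               rep(0, 3))
  tr <- make_sine_trace(amp = 3, freq = 10, fs = 5000, duration = 5)
  cl <- coastline(tr)
  expect_equal(mean(cl), 4 * 3 * 10, tolerance = 0.01)
  # linearity under amplitude scaling
  tr2 <- trace_recording(2 * tr$samples, tr$sampling_rate)
  expect_equal(coastline(tr2), 2 * cl, tolerance = 1e-9)
})

test_that("band power integrates the Welch spectrum", {
  tr <- make_sine_trace(amp = 1, freq = 20, fs = 1000, duration = 20)
  bp <- band_power(tr)
  expect_gte(bp$power[4] / sum(bp$power), 0.9)  # 12-30 Hz band

  set.seed(2)
  wn <- trace_recording(rnorm(120000), 400)
  bpw <- band_power(wn, bands = data.frame(low = c(1, 41), high = c(41, 81)))
  expect_equal(bpw$power[1] / bpw$power[2], 1, tolerance = 0.1)

  z <- trace_recording(rep(0, 4000), 1000)
  expect_equal(band_power(z)$power, rep(0, 8))
  expect_error(band_power(tr, bands = data.frame(low = 100, high = 600)),
               "Nyquist")

  # Parseval: total band power across 0-Nyquist close to the variance
  set.seed(3)
  x <- trace_recording(rnorm(60000), 500)
  tot <- band_power(x, bands = data.frame(low = 0, high = 250))$power
  expect_equal(tot, var(x$samples), tolerance = 0.05)
})

test_that("segment metrics behave on canonical segments", {
  fs <- 512
  z <- segment_metrics(trace_recording(rep(0, fs), fs))
  expect_equal(z$power, 0)
  expect_equal(z$coastline, 0)
  expect_equal(z$spikiness, 0)

  # symmetric noise: near-zero skewness on average
  sk <- vapply(1:100, function(s) {
    set.seed(s)
    segment_metrics(trace_recording(rnorm(fs), fs))$asymmetry
  }, numeric(1))
  expect_lt(abs(mean(sk)), 0.1)

  # one large spike is spikier than a sine of equal RMS
  spike <- rep(0, fs); spike[200] <- 5
  spike <- spike + rnorm(fs, sd = 0.01)
  sine <- sin(2 * pi * 8 * (0:(fs - 1)) / fs)
  sine <- sine / sd(sine) * sd(spike)
  m_spike <- segment_metrics(trace_recording(spike, fs))
  m_sine <- segment_metrics(trace_recording(sine, fs))
  expect_gt(m_spike$spikiness, m_sine$spikiness)

  expect_error(segment_metrics(trace_recording(rep(0, fs * 2), fs)),
               "1 s")
})

test_that("library classification is nearest-neighbour in z-space", {
  set.seed(4)
  lib <- do.call(rbind, lapply(1:10, function(k) {
    m <- segment_metrics(trace_recording(rnorm(512, sd = k), 512))
    data.frame(as.data.frame(unclass(m)), label = ifelse(k > 5, "big", "small"))
  }))
  q <- lapply(lib[3, 1:6], identity)
  expect_equal(classify_segment(q, lib), lib$label[3])
  one <- lib[7, ]
  expect_equal(classify_segment(q, one), "big")
})

test_that("ictal and background segments separate by library matching", {
  fs <- 512
  gen_seg <- function(kind, seed) {
    set.seed(seed)
    x <- epicmc:::shaped_noise(fs, fs, function(f) f^-1.5)
    x <- x / sd(x) * 20
    if (kind == "ictal") {
      osc <- epicmc:::shaped_noise(fs, fs, function(f)
        ifelse(f >= 12 & f <= 30, 1, 0))
      x <- x + osc / sd(osc) * 60
      x[sample(fs, 3)] <- x[sample(fs, 3)] + 200
    }
    segment_metrics(trace_recording(x, fs))
  }
  lib <- do.call(rbind, lapply(1:40, function(k) {
    kind <- if (k <= 20) "background" else "ictal"
    data.frame(as.data.frame(unclass(gen_seg(kind, k))), label = kind)
  }))
  held <- vapply(1:40, function(k) {
    kind <- if (k %% 2 == 0) "background" else "ictal"
    classify_segment(gen_seg(kind, 1000 + k), lib) == kind
  }, logical(1))
  expect_gte(mean(held), 0.9)
})

test_that("synaptic features capture amplitude, decay and homogeneity", {
  cfg <- synaptic_trace_config(duration = 120, seed = 5)
  feat <- extract_synaptic_features(render_synaptic_trace(cfg)$trace,
                                    "inward")
  expect_gt(feat$n_events, 50)
  expect_equal(length(feat$ieis), feat$n_events - 1)
  expect_equal(feat$half_life, feat$decay_tau * log(2))
  expect_gt(feat$mean_amplitude, cfg$amp_median * 0.8)

  # degenerate amplitude distribution: capped slope
  sig <- epicmc:::fit_amplitude_sigmoid(rep(12, 30))
  expect_equal(sig$slope, 1e6)
  expect_true(sig$capped)

  # logistic-drawn amplitudes: fitted midpoint slope recovers 1/scale
  sl <- vapply(1:20, function(s) {
    set.seed(s)
    a <- stats::rlogis(400, location = 15, scale = 2)
    epicmc:::fit_amplitude_sigmoid(a[a > 0])$slope
  }, numeric(1))
  expect_equal(mean(sl), 1 / 2, tolerance = 0.1)

  expect_error(
    extract_synaptic_features(
      render_synaptic_trace(synaptic_trace_config(duration = 2,
                                                  event_rate = 0.5,
                                                  seed = 2))$trace,
      "inward"),
    "insufficient-events")
})

test_that("condition contrast reproduces the expected effect directions", {
  base <- synaptic_trace_config(duration = 60, seed = 11)
  cfgn <- make_condition_config(base, condition_effects("nmdar_48h", "EPSC"))
  fc <- extract_synaptic_features(render_synaptic_trace(base)$trace, "inward")
  fn <- extract_synaptic_features(render_synaptic_trace(cfgn)$trace, "inward")
  ct <- contrast_from_features(fc, fn)
  expect_lt(ct$amplitude_ratio, 1)
  expect_lt(ct$half_life_ratio, 1)
  # smaller and more homogeneous amplitudes steepen the cumulative curve
  expect_gt(ct$slope_ratio, 1)
  expect_gt(mean(fn$ieis), mean(fc$ieis))
})
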