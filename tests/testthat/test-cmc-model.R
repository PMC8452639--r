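test_that("the firing sigmoid is zero-centred with slope sigma/4", {
  expect_equal(firing_sigmoid(0, 2), 0)
  expect_equal(firing_sigmoid(1e3, 1), 0.5, tolerance = 1e-9)
  expect_equal(firing_sigmoid(-1e3, 1), -0.5, tolerance = 1e-9)
  h <- 1e-6
  for (sig in c(0.5, 1, 4)) {
    num <- (firing_sigmoid(h, sig) - firing_sigmoid(-h, sig)) / (2 * h)
    expect_equal(num, sig / 4, tolerance = 1e-6)
  }
  expect_error(firing_sigmoid(0, -1), "positive")
})

test_that("parameter validation enforces signs and positivity", {
  expect_error(cmc_params(tau = c(ss = -1, ii = 16, sp = 8, dp = 28)),
               "positive")
  g <- cmc_params()$gamma
  g["gamma1"] <- -1  # excitatory coupling must stay non-negative
  expect_error(cmc_params(gamma = g), "sign")
  expect_error(cmc_params(sigma = -1), "positive")
})

test_that("the origin is an equilibrium and derivatives follow the wiring", {
  p <- cmc_params()
  expect_equal(state_derivatives(rep(0, 8), p, u = 0), rep(0, 8))

  # decoupled population: damped second-order dynamics with poles -1/tau
  g0 <- rep(0, 10)
  pd <- cmc_params(gamma = g0)
  ls <- linearize(pd)
  ev <- eigen(ls$A, only.values = TRUE)$values
  expect_equal(sort(unique(round(Re(ev) * 1000, 6))),
               unname(sort(-1000 / pd$tau)), tolerance = 1e-6)
  expect_true(ls$stable)
  # block-diagonal in populations when uncoupled
  off <- ls$A
  for (k in 1:4) off[2 * k - 1:0, 2 * k - 1:0] <- 0
  expect_equal(max(abs(off)), 0)
})

test_that("the analytic Jacobian matches finite differences", {
  p <- cmc_params()
  A <- linearize(p)$A
  h <- 1e-6
  A_fd <- matrix(0, 8, 8)
  for (j in 1:8) {
    e <- rep(0, 8); e[j] <- h
    A_fd[, j] <- (state_derivatives(e, p) - state_derivatives(-e, p)) / (2 * h)
  }
  expect_equal(A, A_fd, tolerance = 1e-6)
})

test_that("sigma and gamma scalings are equivalent at the origin", {
  p <- cmc_params()
  p_sig <- p; p_sig$sigma <- p$sigma * 1.1
  p_gam <- p; p_gam$gamma <- p$gamma * 1.1
  expect_equal(linearize(p_sig)$A, linearize(p_gam)$A, tolerance = 1e-12)
  f <- seq(2, 80, 1)
  expect_equal(predict_psd(p_sig, f)$power, predict_psd(p_gam, f)$power,
               tolerance = 1e-9)
})

test_that("transfer function has the right asymptotics and DC gain", {
  p <- cmc_params()
  ls <- linearize(p)
  tf <- transfer_function(ls, c(0, 1, 500, 5000))
  expect_equal(tf[1], (-ls$C %*% solve(ls$A, ls$B))[1, 1] + 0i,
               tolerance = 1e-9)
  expect_lt(Mod(tf[4]), Mod(tf[2]) / 100)  # strictly proper decay

  # single underdamped pair: gain peaks near its resonance
  g <- rep(0, 10); g[3] <- 1.5; g[4] <- -1.5
  pp <- cmc_params(gamma = g)
  lsp <- linearize(pp)
  fgrid <- seq(1, 100, 0.5)
  gains <- Mod(transfer_function(lsp, fgrid))
  expect_gt(fgrid[which.max(gains)], 10)
  expect_lt(fgrid[which.max(gains)], 60)
})

test_that("the default spectrum has fast-superficial and slow-deep peaks", {
  p <- cmc_params()
  f <- seq(1, 100, 0.25)
  psd <- predict_psd(p, f)
  expect_true(all(psd$power > 0))
  lp <- log(psd$power)
  pk <- f[which(diff(sign(diff(lp))) == -2) + 1]
  expect_gte(length(pk), 2)
  expect_lt(pk[1], 15)   # deep (slow) oscillator peak
  expect_gt(pk[length(pk)], 20)  # superficial (fast) oscillator peak

  # noise floor only when the innovation spectrum is switched off
  p0 <- p; p0$innov[c("a_u", "c_u")] <- 0
  flat <- predict_psd(p0, f)
  expect_equal(flat$power, rep(p$chan_noise, length(f)))
})

test_that("deep-pair peak frequency decreases with its time constants", {
  p <- cmc_params()
  f <- seq(1, 100, 0.25)
  low_peak <- function(pp) {
    lp <- log(predict_psd(pp, f)$power)
    pk <- f[which(diff(sign(diff(lp))) == -2) + 1]
    pk <- pk[pk < 20]
    if (length(pk)) pk[1] else NA_real_
  }
  peaks <- vapply(c(0.75, 1, 1.25, 1.5), function(m) {
    pp <- p; pp$tau["dp"] <- p$tau["dp"] * m
    expect_true(stability(pp)$is_stable)
    low_peak(pp)
  }, numeric(1))
  expect_true(all(diff(peaks[!is.na(peaks)]) <= 0))
  # raising both deep time constants moves the slow peak lower still
  p2 <- p; p2$tau[c("ii", "dp")] <- p$tau[c("ii", "dp")] * 1.5
  expect_lt(low_peak(p2), low_peak(p))
})

test_that("stability flags extreme couplings without exceptions", {
  p <- cmc_params()
  expect_true(stability(p)$is_stable)
  hot <- p; hot$gamma <- p$gamma * 100
  st <- stability(hot)
  expect_false(st$is_stable)
  expect_true(is.finite(st$max_real_eig))
  # decoupled circuits stay stable under common tau rescaling
  pd <- cmc_params(gamma = rep(0, 10))
  for (c_ in c(0.5, 2, 5)) {
    ps <- pd; ps$tau <- pd$tau * c_
    expect_true(stability(ps)$is_stable)
    expect_equal(stability(ps)$max_real_eig,
                 stability(pd)$max_real_eig / c_, tolerance = 1e-6)
  }
})

test_that("simulation is seeded, silent at zero noise and scales linearly", {
  p <- cmc_params()
  z <- simulate_timeseries(p, duration = 2, fs = 1000, noise_sd = 0, seed = 1)
  expect_equal(max(abs(z$samples)), 0)

  a <- simulate_timeseries(p, duration = 5, fs = 1000, noise_sd = 0.01,
                           seed = 3)
  b <- simulate_timeseries(p, duration = 5, fs = 1000, noise_sd = 0.01,
                           seed = 3)
  expect_identical(a$samples, b$samples)

  # doubling the noise amplitude quadruples broadband power (linear regime)
  d <- simulate_timeseries(p, duration = 60, fs = 1000, noise_sd = 0.02,
                           seed = 4)
  expect_equal(var(d$samples) / var(
    simulate_timeseries(p, duration = 60, fs = 1000, noise_sd = 0.01,
                        seed = 4)$samples),
    4, tolerance = 0.05)
})

test_that("simulated spectra match the analytic prediction", {
  # the stochastic simulator is the numerical oracle for predict_psd:
  # at small noise the Welch log-PSD of a long simulation must match the
  # linearized transfer-function prediction
  p <- cmc_params()
  check_match <- function(params, seed, tol = 0.05) {
    tr <- simulate_timeseries(params, duration = 100, fs = 1000,
                              noise_sd = 0.02, seed = seed)
    w <- welch_psd(tr)
    sel <- w$freq >= 2 & w$freq <= 80
    pred <- predict_psd(params, w$freq[sel])
    lw <- log(w$power[sel] / 0.02^2)
    lp <- log(pred$power)
    mean((lw - lp)^2) / mean(lp^2)
  }
  expect_lt(check_match(p, 11), 0.05)
  bumped <- apply_log_scaling(p, c(gamma3 = 0.1, tau_dp = -0.1))
  expect_lt(check_match(bumped, 12), 0.05)
})

test_that("parameters round-trip through JSON and log-scaling", {
  p <- cmc_params()
  path <- withr::local_tempfile(fileext = ".json")
  write_cmc_params(p, path)
  q <- read_cmc_params(path)
  expect_equal(q$tau, p$tau)
  expect_equal(q$gamma, p$gamma)
  expect_equal(q$sigma, p$sigma)

  lam <- c(tau_ss = 0.2, gamma4 = -0.1, sigma_dp = 0.3)
  ps <- apply_log_scaling(p, lam)
  expect_equal(ps$tau[["ss"]], p$tau[["ss"]] * exp(0.2))
  expect_equal(ps$gamma[["gamma4"]], p$gamma[["gamma4"]] * exp(-0.1))
  expect_equal(ps$sigma[["dp"]], p$sigma[["dp"]] * exp(0.3))
  expect_equal(ps$gamma[["gamma1"]], p$gamma[["gamma1"]])
  expect_error(apply_log_scaling(p, c(nonsense = 1)), "unknown")
})
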