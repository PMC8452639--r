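#' Spectral model inversion by variational Laplace
#'
#' Fits the microcircuit's predicted log power spectrum to an observed
#' log-PSD under a Gaussian prior on log-scaling parameters, by
#' Levenberg--Marquardt damped Gauss--Newton ascent on the variational free
#' energy. The free energy approximates the log model evidence and is the
#' quantity compared across models; parameter posteriors are Gaussian.
#'
#' @name inversion
NULL

#' Gaussian density over log-scaling parameters
#'
#' @param mean named numeric vector of log-scaling factors (theta =
#'   theta_default * exp(lambda)).
#' @param cov covariance matrix (symmetric positive semi-definite) or a
#'   single scalar variance applied to all parameters.
#' @return object of class `param_density`.
#' @export
param_density <- function(mean, cov) {
  mean <- unlist(mean)
  k <- length(mean)
  if (is.null(dim(cov))) {
    stopifnot(length(cov) %in% c(1L, k))
    cov <- diag(rep(as.numeric(cov), length.out = k), k)
  }
  cov <- as.matrix(cov)
  stopifnot(nrow(cov) == k, ncol(cov) == k)
  if (max(abs(cov - t(cov))) > 1e-8 * max(abs(cov), 1))
    stop("covariance must be symmetric", call. = FALSE)
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("covariance must be positive semi-definite", call. = FALSE)
  structure(list(mean = mean, cov = cov), class = "param_density")
}

#' Default prior over the 18 free microcircuit parameters
#'
#' Zero-mean log-scaling (the default parameterization itself) with
#' independent variance 1/16 per parameter — a multiplicative 1 sd of
#' about 28%.
#'
#' @param var prior variance per parameter.
#' @return a `param_density`.
#' @export
default_cmc_prior <- function(var = 1 / 16) {
  nm <- cmc_free_param_names()
  param_density(stats::setNames(rep(0, length(nm)), nm), var)
}

#' Inversion settings
#'
#' @param freq_range fit range in Hz.
#' @param freq_step grid step in Hz.
#' @param max_iter maximum outer iterations.
#' @param f_tolerance convergence: |dF| below this for 4 consecutive
#'   accepted steps.
#' @param lm_damping_init initial Levenberg--Marquardt damping.
#' @param fixed_noise_var if non-NULL, the observation noise variance is
#'   fixed at this value instead of being estimated as a log-precision
#'   hyperparameter.
#' @param seed integer seed (recorded; the inversion itself is
#'   deterministic).
#' @return list of class `fit_settings`.
#' @export
fit_settings <- function(freq_range = c(1, 100), freq_step = 0.5,
                         max_iter = 128, f_tolerance = 0.01,
                         lm_damping_init = 1 / 32,
                         fixed_noise_var = NULL, seed = 1) {
  stopifnot(max_iter >= 1, f_tolerance > 0, freq_step > 0,
            length(freq_range) == 2L, freq_range[1] < freq_range[2])
  structure(list(freq_range = freq_range, freq_step = freq_step,
                 max_iter = as.integer(max_iter),
                 f_tolerance = f_tolerance,
                 lm_damping_init = lm_damping_init,
                 fixed_noise_var = fixed_noise_var,
                 seed = as.integer(seed)),
            class = "fit_settings")
}

#' Frequency grid of a settings object
#' @param settings a `fit_settings`.
#' @export
fit_freqs <- function(settings) {
  seq(settings$freq_range[1], settings$freq_range[2],
      by = settings$freq_step)
}

#' Log-PSD data features on the fit grid
#'
#' A precomputed PSD (data.frame freq/power) is log-transformed and
#' linearly interpolated onto the grid; a `trace_recording` is first
#' reduced by Welch's method at a resolution matching the grid step.
#'
#' @param x a PSD data.frame (freq, power) or a `trace_recording`.
#' @param settings a `fit_settings`.
#' @return numeric vector of log-power values on [fit_freqs()].
#' @export
data_features <- function(x, settings = fit_settings()) {
  grid <- fit_freqs(settings)
  if (inherits(x, "trace_recording")) {
    if (settings$freq_range[2] > x$sampling_rate / 2)
      stop("fit range extends above the Nyquist frequency", call. = FALSE)
    nper <- round(x$sampling_rate / settings$freq_step)
    x <- welch_psd(x, nperseg = min(nper, length(x$samples)))
  }
  stopifnot(is.data.frame(x), all(c("freq", "power") %in% names(x)))
  if (min(x$freq) > grid[1] || max(x$freq) < grid[length(grid)])
    stop("PSD does not cover the fit frequency range", call. = FALSE)
  lp <- stats::approx(x$freq, log(x$power), xout = grid)$y
  stats::setNames(lp, sprintf("f%g", grid))
}

#' Forward model: predicted log-PSD as a function of log-scalings
#'
#' @param params0 baseline `cmc_params`.
#' @param freqs frequency grid in Hz.
#' @return function(lambda) -> numeric log-power vector (errors when the
#'   scaled parameterization is unstable).
#' @export
cmc_forward <- function(params0, freqs) {
  force(params0); force(freqs)
  function(lambda) {
    log(predict_psd(apply_log_scaling(params0, lambda), freqs)$power)
  }
}

# central finite-difference Jacobian; one-sided fallback when a
# perturbation lands on an unstable parameterization
fd_jacobian <- function(forward, lambda, g0, step = 1e-3) {
  np <- length(lambda)
  J <- matrix(0, length(g0), np)
  for (j in seq_len(np)) {
    lp <- lambda; lp[j] <- lp[j] + step
    lm_ <- lambda; lm_[j] <- lm_[j] - step
    gp <- tryCatch(forward(lp), error = function(e) NULL)
    gm <- tryCatch(forward(lm_), error = function(e) NULL)
    J[, j] <- if (!is.null(gp) && !is.null(gm)) (gp - gm) / (2 * step)
    else if (!is.null(gp)) (gp - g0) / step
    else if (!is.null(gm)) (g0 - gm) / step
    else 0
  }
  J
}

gaussian_kl <- function(mu1, S1, mu0, S0) {
  k <- length(mu1)
  S0inv <- solve(S0)
  dm <- mu0 - mu1
  0.5 * (sum(diag(S0inv %*% S1)) + sum(dm * (S0inv %*% dm)) - k +
           determinant(S0)$modulus - determinant(S1)$modulus)[1]
}

# free energy and components at a candidate point
vl_objective <- function(r, J, Sl, lambda, prior, h, Vh, h0, vh0, fixed_h) {
  ny <- length(r)
  R <- sum(r^2) + sum(diag(J %*% Sl %*% t(J)))
  accuracy <- -0.5 * exp(h) * R + 0.5 * ny * h - 0.5 * ny * log(2 * pi)
  klh <- if (fixed_h) 0 else
    0.5 * (Vh / vh0 + (h - h0)^2 / vh0 - 1 + log(vh0) - log(Vh))
  kll <- gaussian_kl(lambda, Sl, prior$mean, prior$cov)
  list(F = accuracy - klh - kll, accuracy = accuracy,
       complexity = klh + kll, R = R)
}

#' Variational Laplace inversion
#'
#' Gauss--Newton ascent on the free energy of a Gaussian posterior over
#' log-scaling parameters, with Levenberg--Marquardt damping (doubled on
#' step rejection, relaxed by 0.7 on acceptance), an observation-noise
#' log-precision hyperparameter re-optimized at every candidate (Gaussian
#' hyperprior N(0, 1)), and acceptance only of steps that do not decrease
#' the free energy. Stops when |dF| stays below `f_tolerance` for 4
#' consecutive accepted iterations, or at `max_iter`.
#'
#' @param features observed feature vector (log-PSD on the fit grid).
#' @param priors a `param_density` over the model's free parameters.
#' @param settings a `fit_settings`.
#' @param forward function(lambda) -> predicted feature vector; defaults
#'   require `params0`.
#' @param params0 baseline `cmc_params` used to build the default forward
#'   model when `forward` is NULL.
#' @return list of class `inversion_result`: `posterior` (a
#'   `param_density`), `free_energy`, `accuracy`, `complexity`,
#'   `f_trajectory` (accepted values), `noise_logprec_posterior`
#'   (mean, variance), `converged`, `n_iter`.
#' @export
variational_laplace <- function(features, priors, settings = fit_settings(),
                                forward = NULL, params0 = NULL) {
  stopifnot(inherits(priors, "param_density"))
  if (is.null(forward)) {
    stopifnot(inherits(params0, "cmc_params"))
    forward <- cmc_forward(params0, fit_freqs(settings))
  }
  y <- as.numeric(features)
  stopifnot(all(is.finite(y)))
  np <- length(priors$mean)
  ny <- length(y)
  S0inv <- solve(priors$cov)

  fixed_h <- !is.null(settings$fixed_noise_var)
  h0 <- 0; vh0 <- 1
  opt_h <- function(R) {
    if (fixed_h) return(list(h = -log(settings$fixed_noise_var), Vh = 0))
    h <- h0
    for (it in 1:32) {
      g1 <- 0.5 * ny - 0.5 * exp(h) * R - (h - h0) / vh0
      g2 <- -0.5 * exp(h) * R - 1 / vh0
      step <- g1 / g2
      h <- h - step
      # clamp: keeps noiseless (infinite-precision) limits numerically sane
      h <- min(max(h, -16), 16)
      if (abs(step) < 1e-10) break
    }
    list(h = h, Vh = 1 / (0.5 * exp(h) * R + 1 / vh0))
  }

  eval_point <- function(lambda) {
    g <- forward(lambda)
    if (any(!is.finite(g))) stop("non-finite forward prediction")
    r <- y - g
    J <- fd_jacobian(forward, lambda, g)
    # hyperparameter and posterior covariance are mutually dependent;
    # a couple of fixed-point sweeps suffice
    h <- if (fixed_h) -log(settings$fixed_noise_var) else h0
    Vh <- if (fixed_h) 0 else vh0
    for (sweep in 1:3) {
      H <- exp(h) * crossprod(J) + S0inv
      Sl <- solve((H + t(H)) / 2)
      R <- sum(r^2) + sum(diag(J %*% Sl %*% t(J)))
      hh <- opt_h(R)
      if (abs(hh$h - h) < 1e-8) { h <- hh$h; Vh <- hh$Vh; break }
      h <- hh$h; Vh <- hh$Vh
    }
    ob <- vl_objective(r, J, Sl, lambda, priors, h, Vh, h0, vh0, fixed_h)
    list(lambda = lambda, g = g, r = r, J = J, Sl = Sl, h = h, Vh = Vh,
         F = ob$F, accuracy = ob$accuracy, complexity = ob$complexity)
  }

  # start at the prior mean; if that parameterization is unstable, shrink
  # the start toward the origin (the stable default) -- the prior itself is
  # untouched, only the optimizer's initial point moves
  cur <- NULL
  shrink <- 1
  for (try_ in 1:24) {
    cur <- tryCatch(eval_point(priors$mean * shrink),
                    error = function(e) NULL)
    if (!is.null(cur)) break
    shrink <- shrink * 0.7
  }
  if (is.null(cur))
    stop("no stable starting point found near the prior mean",
         call. = FALSE)
  delta <- settings$lm_damping_init
  f_traj <- cur$F
  slow <- 0L
  converged <- FALSE
  iter <- 0L
  while (iter < settings$max_iter) {
    iter <- iter + 1L
    Pi_ <- exp(cur$h)
    H <- Pi_ * crossprod(cur$J) + S0inv
    grad <- Pi_ * crossprod(cur$J, cur$r) -
      S0inv %*% (cur$lambda - priors$mean)
    accepted <- FALSE
    for (try_ in 1:12) {
      step <- tryCatch(
        solve(H + diag(delta * diag(H), np), grad),
        error = function(e) NULL)
      cand <- if (is.null(step)) NULL else tryCatch(
        eval_point(cur$lambda + as.numeric(step)),
        error = function(e) NULL)
      if (!is.null(cand) && is.finite(cand$F) && cand$F >= cur$F) {
        dF <- cand$F - cur$F
        cur <- cand
        f_traj <- c(f_traj, cur$F)
        delta <- max(delta * 0.7, 1e-8)
        slow <- if (dF < settings$f_tolerance) slow + 1L else 0L
        accepted <- TRUE
        break
      }
      delta <- delta * 2
    }
    if (!accepted) break  # damping exhausted: local optimum
    if (slow >= 4L) { converged <- TRUE; break }
  }
  post_mean <- stats::setNames(as.numeric(cur$lambda), names(priors$mean))
  structure(list(
    posterior = param_density(post_mean, (cur$Sl + t(cur$Sl)) / 2),
    free_energy = cur$F,
    accuracy = cur$accuracy,
    complexity = cur$complexity,
    f_trajectory = f_traj,
    noise_logprec_posterior = c(mean = cur$h, variance = cur$Vh),
    converged = converged,
    n_iter = iter,
    residuals = cur$r),
    class = "inversion_result")
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf(
    "inversion_result: F = %.3f (accuracy %.3f, complexity %.3f), %d iterations%s\n",
    x$free_energy, x$accuracy, x$complexity, x$n_iter,
    if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Accuracy / complexity decomposition of the free energy
#'
#' F = accuracy - complexity, where complexity is the KL divergence of the
#' posterior from the prior (plus the hyperparameter KL) and is always
#' non-negative.
#'
#' @param result an `inversion_result`.
#' @return list(accuracy, complexity).
#' @export
free_energy_components <- function(result) {
  list(accuracy = result$accuracy, complexity = result$complexity)
}

#' Bayesian model comparison from free energies
#'
#' @param f_values numeric vector of free energies (log evidences).
#' @param labels model labels.
#' @return data.frame with `label`, `free_energy`, `delta_f` (vs the best),
#'   `bayes_factor` (vs the best) and `posterior_prob` (softmax under
#'   uniform model priors).
#' @export
compare_models <- function(f_values, labels = NULL) {
  stopifnot(length(f_values) >= 2)
  if (is.null(labels)) labels <- paste0("model", seq_along(f_values))
  d <- f_values - max(f_values)
  p <- exp(d) / sum(exp(d))
  data.frame(label = labels, free_energy = f_values, delta_f = d,
             bayes_factor = exp(d), posterior_prob = p)
}

#' Empirical prior from a previous posterior
#'
#' Chains posterior expected values into the next fit's prior means while
#' resetting the prior covariance to the base prior's (only the means are
#' carried over between conditions).
#'
#' @param posterior,base_prior `param_density` objects of equal dimension.
#' @return a `param_density`.
#' @export
empirical_prior_from <- function(posterior, base_prior) {
  if (length(posterior$mean) != length(base_prior$mean))
    stop("dimension mismatch between posterior and base prior",
         call. = FALSE)
  param_density(stats::setNames(posterior$mean, names(base_prior$mean)),
                base_prior$cov)
}

#' Three-stage condition fitting with model comparison
#'
#' Stage 1 fits the control-state spectrum from the base prior. Stage 2
#' fits the interictal spectrum once per model specification: each model's
#' prior takes the stage-1 posterior means (empirical prior) plus the
#' microscale-informed shifts prescribed by that placement; the winner
#' maximizes free energy. Stage 3 fits the ictal spectrum using the winning
#' model's posterior means as empirical priors.
#'
#' @param features_control,features_interictal,features_ictal log-PSD
#'   feature vectors on the fit grid.
#' @param model_space a `model_space` from [build_model_space()].
#' @param settings a `fit_settings`.
#' @param params0 baseline `cmc_params` defining the forward model.
#' @param shifts named log shifts (`gamma`, `tau`, `sigma`) from
#'   [shifts_from_contrast()].
#' @param base_prior prior for stage 1 (default [default_cmc_prior()]).
#' @return list of class `condition_fit`: `control`, `interictal` (winning
#'   model's result), `ictal` (inversion results), `f_table` (one row per
#'   model), `winner` (label), `posteriors` (list of the three state
#'   posteriors).
#' @export
fit_condition_sequence <- function(features_control, features_interictal,
                                   features_ictal, model_space,
                                   settings = fit_settings(),
                                   params0 = cmc_params(),
                                   shifts = c(gamma = 0, tau = 0, sigma = 0),
                                   base_prior = default_cmc_prior()) {
  forward <- cmc_forward(params0, fit_freqs(settings))
  stage1 <- variational_laplace(features_control, base_prior, settings,
                                forward = forward)
  emp <- empirical_prior_from(stage1$posterior, base_prior)

  fits2 <- lapply(model_space$specs, function(spec) {
    pr <- informed_priors(emp, spec, shifts)
    variational_laplace(features_interictal, pr, settings, forward = forward)
  })
  f_vals <- vapply(fits2, function(f) f$free_energy, numeric(1))
  labels <- vapply(model_space$specs, function(s) s$label, character(1))
  f_table <- if (length(f_vals) >= 2) compare_models(f_vals, labels) else
    data.frame(label = labels, free_energy = f_vals, delta_f = 0,
               bayes_factor = 1, posterior_prob = 1)
  win <- which.max(f_vals)

  prior3 <- empirical_prior_from(fits2[[win]]$posterior, base_prior)
  stage3 <- variational_laplace(features_ictal, prior3, settings,
                                forward = forward)

  structure(list(control = stage1, interictal = fits2[[win]],
                 ictal = stage3, f_table = f_table,
                 winner = labels[win], all_interictal = fits2,
                 triplet = state_triplet(
                   stage1$posterior$mean,
                   fits2[[win]]$posterior$mean,
                   stage3$posterior$mean)),
            class = "condition_fit")
}
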