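#' Epileptogenicity x ictogenicity state-space analysis
#'
#' Post-fit analyses of the three fitted circuit states: effect vectors
#' (epileptogenesis = interictal - control, ictogenesis = ictal -
#' interictal in log-scaling space), a principal-component view of state
#' separability, a two-dimensional grid of simulated spectra along linear
#' combinations of the two effects, nearest-reference spectral
#' classification, a high/low frequency log-amplitude ratio map, and a
#' neighbour-MSE sensitivity map along the ictogenicity axis.
#'
#' @name state_space
NULL

#' Triplet of fitted state parameter vectors
#'
#' @param lambda_control,lambda_interictal,lambda_ictal log-scaling
#'   vectors (posterior means) of equal length.
#' @return object of class `state_triplet`.
#' @export
state_triplet <- function(lambda_control, lambda_interictal, lambda_ictal) {
  if (length(lambda_control) != length(lambda_interictal) ||
      length(lambda_control) != length(lambda_ictal))
    stop("state vectors must have equal dimension", call. = FALSE)
  structure(list(lambda_control = lambda_control,
                 lambda_interictal = lambda_interictal,
                 lambda_ictal = lambda_ictal),
            class = "state_triplet")
}

#' Epileptogenesis and ictogenesis effect vectors
#'
#' @param triplet a `state_triplet`.
#' @return list with `delta_epi` (interictal - control) and `delta_icto`
#'   (ictal - interictal).
#' @export
effect_vectors <- function(triplet) {
  stopifnot(inherits(triplet, "state_triplet"))
  list(delta_epi = triplet$lambda_interictal - triplet$lambda_control,
       delta_icto = triplet$lambda_ictal - triplet$lambda_interictal)
}

#' Principal-component projection of the three states
#'
#' Centres the three parameter vectors, decomposes them by singular values
#' and projects onto the first two components (three points span at most a
#' plane, so pairwise distances are preserved exactly). Also reports the
#' angle between the projected effect vectors.
#'
#' @param triplet a `state_triplet`.
#' @return list: `projections` (3 x 2 matrix, rows control / interictal /
#'   ictal), `singular_values`, `effect_angle_deg`.
#' @export
pca_states <- function(triplet) {
  X <- rbind(control = triplet$lambda_control,
             interictal = triplet$lambda_interictal,
             ictal = triplet$lambda_ictal)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (max(abs(Xc)) == 0)
    stop("degenerate decomposition: all states identical", call. = FALSE)
  sv <- svd(Xc)
  proj <- Xc %*% sv$v[, 1:2, drop = FALSE]
  ev <- effect_vectors(triplet)
  p_epi <- as.numeric(crossprod(sv$v[, 1:2, drop = FALSE], ev$delta_epi))
  p_icto <- as.numeric(crossprod(sv$v[, 1:2, drop = FALSE], ev$delta_icto))
  ang <- if (sum(p_epi^2) == 0 || sum(p_icto^2) == 0) NA_real_ else {
    cosang <- sum(p_epi * p_icto) /
      sqrt(sum(p_epi^2) * sum(p_icto^2))
    acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  }
  list(projections = proj, singular_values = sv$d,
       effect_angle_deg = ang)
}

#' Simulate spectra over the epileptogenicity x ictogenicity grid
#'
#' At grid point (e, i) the circuit parameters are
#' lambda = lambda_control + e * delta_epi + i * delta_icto; the predicted
#' spectrum is computed where the parameterization is stable, and the
#' point is flagged unstable otherwise.
#'
#' @param lambda_control control-state log-scaling vector.
#' @param effects effect vectors from [effect_vectors()].
#' @param params0 baseline `cmc_params`.
#' @param n_e,n_i grid sizes (>= 2).
#' @param range_e,range_i coordinate ranges (default the unit interval).
#' @param freqs frequency grid in Hz.
#' @return object of class `grid_result`: `e_values`, `i_values`,
#'   `log_spectra` (n_e x n_i x n_freq array, NA where unstable),
#'   `stable` (n_e x n_i logical), `freqs`, plus the inputs.
#' @export
simulate_grid <- function(lambda_control, effects, params0 = cmc_params(),
                          n_e = 21, n_i = 21,
                          range_e = c(0, 1), range_i = c(0, 1),
                          freqs = seq(1, 100, 0.5)) {
  stopifnot(n_e >= 2, n_i >= 2)
  e_values <- seq(range_e[1], range_e[2], length.out = n_e)
  i_values <- seq(range_i[1], range_i[2], length.out = n_i)
  logspec <- array(NA_real_, c(n_e, n_i, length(freqs)))
  stable <- matrix(FALSE, n_e, n_i)
  for (a in seq_len(n_e)) {
    for (b in seq_len(n_i)) {
      lam <- lambda_control + e_values[a] * effects$delta_epi +
        i_values[b] * effects$delta_icto
      p <- apply_log_scaling(params0, lam)
      if (stability(p)$is_stable) {
        logspec[a, b, ] <- log(predict_psd(p, freqs)$power)
        stable[a, b] <- TRUE
      }
    }
  }
  structure(list(e_values = e_values, i_values = i_values,
                 log_spectra = logspec, stable = stable, freqs = freqs,
                 lambda_control = lambda_control, effects = effects,
                 n_unstable = sum(!stable)),
            class = "grid_result")
}

#' Classify grid spectra against three reference spectra
#'
#' Each stable grid point takes the label of the reference spectrum with
#' the smallest mean squared difference in log amplitude; ties go to the
#' lower-index reference. Unstable points are labelled "unstable".
#'
#' @param grid a `grid_result`.
#' @param references list of three PSD data.frames (freq, power) on the
#'   grid's frequency grid, in the order control, interictal, seizure.
#' @param labels reference labels.
#' @return character matrix (n_e x n_i) of labels.
#' @export
classify_grid <- function(grid, references,
                          labels = c("control-like", "interictal-like",
                                     "seizure-like")) {
  stopifnot(length(references) == length(labels))
  ref_log <- lapply(references, function(r) {
    stopifnot(is.data.frame(r), nrow(r) == length(grid$freqs))
    if (max(abs(r$freq - grid$freqs)) > 1e-9)
      stop("reference spectra must be on the grid frequency axis",
           call. = FALSE)
    log(r$power)
  })
  out <- matrix("unstable", length(grid$e_values), length(grid$i_values))
  for (a in seq_along(grid$e_values)) {
    for (b in seq_along(grid$i_values)) {
      if (!grid$stable[a, b]) next
      ls <- grid$log_spectra[a, b, ]
      mse <- vapply(ref_log, function(rl) mean((ls - rl)^2), numeric(1))
      out[a, b] <- labels[which.min(mse)]
    }
  }
  out
}

#' High/low frequency log-amplitude ratio map
#'
#' Mean log amplitude above `split_high` divided by mean log amplitude
#' below `split_low`, per grid point.
#'
#' @param grid a `grid_result`.
#' @param split_high,split_low band edges in Hz (defaults 20 and 8).
#' @return numeric matrix (n_e x n_i), NA at unstable points.
#' @export
ratio_map <- function(grid, split_high = 20, split_low = 8) {
  hi <- grid$freqs > split_high
  lo <- grid$freqs < split_low
  stopifnot(any(hi), any(lo))
  apply(grid$log_spectra, c(1, 2), function(ls) {
    if (any(is.na(ls))) return(NA_real_)
    mean(ls[hi]) / mean(ls[lo])
  })
}

#' Sensitivity map along the ictogenicity axis
#'
#' For each epileptogenicity row, the mean squared difference between
#' log spectra at adjacent ictogenicity grid points, reported on a log10
#' scale (values floored at 1e-12 before the log so identical spectra map
#' to -12).
#'
#' @param grid a `grid_result` with at least 2 ictogenicity points.
#' @param floor lower bound applied to the MSE before the log10.
#' @return numeric matrix (n_e x (n_i - 1)), NA where either neighbour is
#'   unstable.
#' @export
sensitivity_map <- function(grid, floor = 1e-12) {
  n_i <- length(grid$i_values)
  stopifnot(n_i >= 2)
  out <- matrix(NA_real_, length(grid$e_values), n_i - 1L)
  for (a in seq_along(grid$e_values)) {
    for (b in seq_len(n_i - 1L)) {
      if (!grid$stable[a, b] || !grid$stable[a, b + 1L]) next
      d <- grid$log_spectra[a, b + 1L, ] - grid$log_spectra[a, b, ]
      out[a, b] <- log10(max(mean(d^2), floor))
    }
  }
  out
}

#' Distance to seizure-like territory along the ictogenicity axis
#'
#' Per epileptogenicity row, the smallest ictogenicity coordinate whose
#' point is labelled seizure-like (NA when the row has none).
#'
#' @param grid a `grid_result`.
#' @param labels label matrix from [classify_grid()].
#' @param seizure_label the label marking seizure-like territory.
#' @return numeric vector of length n_e.
#' @export
seizure_onset_distance <- function(grid, labels,
                                   seizure_label = "seizure-like") {
  vapply(seq_along(grid$e_values), function(a) {
    hit <- which(labels[a, ] == seizure_label)
    if (!length(hit)) NA_real_ else grid$i_values[min(hit)]
  }, numeric(1))
}

#' Documented default synthetic state triplet
#'
#' The reference parameterizations used throughout the worked examples and
#' end-to-end checks. The control state is the default microcircuit. The
#' interictal (NMDAR-antibody) state carries the microscale-predicted
#' shifts on the slow-oscillator (deep-pair) coupling and sigmoid
#' parameters: coupling reduced by the EPSC amplitude ratio 0.8 and sigmoid
#' slope increased by the amplitude-homogeneity ratio 1.39 (the generator's
#' default condition effects). The ictal state additionally increases
#' deep-pair coupling gain and sigmoid slope, moving the circuit toward
#' its oscillatory instability.
#'
#' @param params0 baseline `cmc_params`.
#' @return list: `params0`, `lambda` (list of three named vectors),
#'   `params` (list of three `cmc_params`), `shifts` (the microscale shift
#'   vector implied by the interictal state).
#' @export
default_state_triplet <- function(params0 = cmc_params()) {
  nm <- cmc_free_param_names()
  zero <- stats::setNames(rep(0, length(nm)), nm)
  deep_gamma <- gamma_names_for(c("ii", "dp"))
  interictal <- zero
  interictal[deep_gamma] <- log(0.8)
  interictal[c("sigma_ii", "sigma_dp")] <- log(1 / (0.8 * 0.9))
  ictal <- interictal
  ictal[c("gamma2", "gamma6")] <- ictal[c("gamma2", "gamma6")] + 0.2
  ictal[c("sigma_ii", "sigma_dp")] <- ictal[c("sigma_ii", "sigma_dp")] + 0.15
  ictal[c("gamma8", "gamma10")] <- ictal[c("gamma8", "gamma10")] + 0.3
  list(params0 = params0,
       lambda = list(control = zero, interictal = interictal, ictal = ictal),
       params = list(control = params0,
                     interictal = apply_log_scaling(params0, interictal),
                     ictal = apply_log_scaling(params0, ictal)),
       shifts = c(gamma = log(0.8), tau = log(0.7),
                  sigma = log(1 / (0.8 * 0.9))))
}
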