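#' Microscale-informed priors and the 22-model space
#'
#' Patch-clamp feature contrasts between conditions are turned into
#' quantitative prior shifts on microcircuit parameters: EPSC amplitude
#' informs population coupling (gamma), EPSC half-life informs the
#' postsynaptic time constant (tau), and the homogeneity of the amplitude
#' distribution (cumulative-amplitude sigmoid midpoint slope) informs the
#' population response sigmoid (sigma). Prior placements are enumerated as
#' a 22-model space: the null model plus every non-empty subset of
#' {gamma, tau, sigma} crossed with three population subsets (superficial
#' pair, deep pair, both).
#'
#' @name microscale_priors
NULL

#' Feature contrast between two conditions
#'
#' Element-wise ratios (NMDAR / control) of mean amplitude, half-life and
#' sigmoid midpoint slope.
#'
#' @param control,nmdar `synaptic_features` objects.
#' @return list of class `microscale_contrast` with `amplitude_ratio`,
#'   `half_life_ratio`, `slope_ratio`.
#' @export
contrast_from_features <- function(control, nmdar) {
  vals <- c(control$mean_amplitude, control$half_life,
            control$sigmoid_midpoint_slope)
  if (any(vals == 0))
    stop("control features must be non-zero", call. = FALSE)
  structure(list(
    amplitude_ratio = nmdar$mean_amplitude / control$mean_amplitude,
    half_life_ratio = nmdar$half_life / control$half_life,
    slope_ratio = nmdar$sigmoid_midpoint_slope /
      control$sigmoid_midpoint_slope),
    class = "microscale_contrast")
}

#' Log prior shifts from a feature contrast
#'
#' Population parameters are assumed to scale proportionally with the
#' single-cell features they reflect, so the log-scaling shift for each
#' parameter group is the natural log of the corresponding feature ratio.
#'
#' @param contrast a `microscale_contrast`.
#' @return named numeric: `gamma` = ln(amplitude ratio), `tau` =
#'   ln(half-life ratio), `sigma` = ln(slope ratio).
#' @export
shifts_from_contrast <- function(contrast) {
  stopifnot(inherits(contrast, "microscale_contrast"))
  c(gamma = log(contrast$amplitude_ratio),
    tau = log(contrast$half_life_ratio),
    sigma = log(contrast$slope_ratio))
}

# population subsets used for prior placement
POPULATION_SETS <- list(
  superficial = c("ss", "sp"),
  deep = c("ii", "dp"),
  both = c("ss", "sp", "ii", "dp"))

# a coupling belongs to the population whose synaptic response it scales,
# i.e. its target
gamma_names_for <- function(pops) {
  paste0("gamma", which(CMC_WIRING$tgt %in% pops))
}

model_spec <- function(groups, populations, label) {
  structure(list(informed_groups = groups,
                 informed_populations = populations,
                 is_null = length(groups) == 0L,
                 label = label),
            class = "model_spec")
}

#' Enumerate the 22-model space of prior placements
#'
#' One null model (no microscale-informed priors) plus the 7 non-empty
#' subsets of {gamma, tau, sigma} crossed with 3 population subsets
#' (superficial pair ss+sp, deep pair ii+dp, both), in deterministic
#' order: null first, then group subsets in the order gamma, tau, sigma,
#' gamma+tau, gamma+sigma, tau+sigma, gamma+tau+sigma, each over
#' (superficial, deep, both).
#'
#' @return object of class `model_space` with `specs`, a list of 22
#'   `model_spec`s.
#' @export
build_model_space <- function() {
  group_subsets <- list("gamma", "tau", "sigma",
                        c("gamma", "tau"), c("gamma", "sigma"),
                        c("tau", "sigma"), c("gamma", "tau", "sigma"))
  specs <- list(model_spec(character(0), character(0), "null"))
  for (g in group_subsets) {
    for (p in names(POPULATION_SETS)) {
      specs <- c(specs, list(model_spec(
        g, p, paste0(paste(g, collapse = "+"), ".", p))))
    }
  }
  structure(list(specs = specs), class = "model_space")
}

#' @export
print.model_space <- function(x, ...) {
  cat(sprintf("model_space: %d prior-placement specifications\n",
              length(x$specs)))
  cat(" ", paste(vapply(x$specs, function(s) s$label, character(1)),
                 collapse = ", "), "\n")
  invisible(x)
}

#' Apply microscale-informed shifts to a prior
#'
#' Shifts the prior means of every parameter selected by the model
#' specification (groups crossed with populations): tau shifts apply to the
#' populations' time constants, gamma shifts to couplings targeting the
#' populations, sigma shifts to the populations' sigmoid slopes. Prior
#' covariance is never altered. The null specification returns the base
#' prior unchanged.
#'
#' @param base a `param_density` over the 18 free parameters.
#' @param spec a `model_spec`.
#' @param shifts named shifts from [shifts_from_contrast()].
#' @return a `param_density`.
#' @export
informed_priors <- function(base, spec, shifts) {
  stopifnot(inherits(base, "param_density"), inherits(spec, "model_spec"))
  if (spec$is_null) return(base)
  pops <- POPULATION_SETS[[spec$informed_populations]]
  mean <- base$mean
  for (g in spec$informed_groups) {
    nm <- switch(g,
                 tau = paste0("tau_", pops),
                 gamma = gamma_names_for(pops),
                 sigma = paste0("sigma_", pops))
    stopifnot(all(nm %in% names(mean)))
    mean[nm] <- mean[nm] + shifts[[g]]
  }
  param_density(mean, base$cov)
}
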