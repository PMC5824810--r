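#' Simulation configuration
#'
#' Ground-truth parameters for the synthetic-data generators. Defaults mirror
#' the experimental conditions of the moderately curved scaffold (Q3):
#' Kd = 0.68 nM, titrations over 0.01-50 nM, ~15 GUVs per concentration,
#' 20% multiplicative intensity noise; FCS curves with N = 12, tauD = 20 ms
#' and small additive noise on G; a logistic density-to-tubulation link with
#' half-point 62 um^-2 and Hill slope 4 (which puts the >80% point near
#' 90 um^-2); tube cross-sections drawn as Normal(220, 70) nm.
#'
#' @param seed Integer seed; fixed seed gives identical tables.
#' @param n_guvs GUVs per concentration in binding titrations.
#' @param concentrations_nM Titration concentrations.
#' @param true_kd_nM,true_imax Langmuir ground truth.
#' @param intensity_cv Multiplicative lognormal noise CV on intensities.
#' @param fcs List: true_n, true_tau_d_s, n_lags, lag_decades, lag_min_s,
#'   noise_sd.
#' @param morphology List: sigma50_per_um2, hill_slope, baseline (named
#'   probabilities over the non-tubulated categories).
#' @param tube List: mean_diameter_nm, sd_nm, n_sections.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_guvs = 15L,
    concentrations_nM = c(0.01, 0.05, 0.2, 0.5, 2, 5, 20, 50),
    true_kd_nM = 0.68,
    true_imax = 1000,
    intensity_cv = 0.2,
    fcs = list(true_n = 12, true_tau_d_s = 0.02, n_lags = 80,
               lag_decades = 5, lag_min_s = 1e-5, noise_sd = 0.002),
    morphology = list(sigma50_per_um2 = 62, hill_slope = 4,
                      baseline = c(spherical = 0.6, flaccid = 0.15,
                                   evagination_invagination = 0.1,
                                   inward_tubules = 0.05, burst = 0.1)),
    tube = list(mean_diameter_nm = 220, sd_nm = 70, n_sections = 35)) {
  stopifnot(true_kd_nM > 0, true_imax > 0, intensity_cv >= 0,
            all(concentrations_nM > 0), n_guvs >= 1,
            fcs$true_n > 0, fcs$true_tau_d_s > 0, fcs$noise_sd >= 0,
            morphology$sigma50_per_um2 > 0, morphology$hill_slope > 0,
            abs(sum(morphology$baseline) - 1) < 1e-9,
            tube$sd_nm >= 0, tube$n_sections >= 2)
  structure(list(seed = as.integer(seed), n_guvs = as.integer(n_guvs),
                 concentrations_nM = concentrations_nM,
                 true_kd_nM = true_kd_nM, true_imax = true_imax,
                 intensity_cv = intensity_cv, fcs = fcs,
                 morphology = morphology, tube = tube),
            class = "simulation_config")
}

#' Generate a synthetic binding titration
#'
#' Per-GUV intensities on the Langmuir curve I = Imax/(1 + Kd/C) with
#' multiplicative lognormal noise of coefficient of variation
#' `intensity_cv` (the lognormal is parameterized to have mean 1). With
#' `intensity_cv = 0` the points lie exactly on the curve.
#'
#' @param config A [simulation_config()].
#' @param condition Label attached to all rows.
#' @return Data frame: guv_id, condition, bulk_conc_nM, intensity_au.
#' @export
gen_binding_dataset <- function(config = simulation_config(), condition = "Q3") {
  set.seed(config$seed)
  conc <- rep(config$concentrations_nM, each = config$n_guvs)
  mu <- langmuir_model(conc, config$true_kd_nM, config$true_imax)
  noise <- if (config$intensity_cv > 0) {
    sdlog <- sqrt(log(1 + config$intensity_cv^2))
    stats::rlnorm(length(conc), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else rep(1, length(conc))
  data.frame(
    guv_id = sprintf("guv%03d", seq_along(conc)),
    condition = condition,
    bulk_conc_nM = conc,
    intensity_au = mu * noise)
}

#' Generate a synthetic FCS autocorrelation curve
#'
#' Evaluates G(tau) = (1/N)/(1 + tau/tauD) on a log-spaced lag grid and adds
#' i.i.d. Gaussian noise of standard deviation `noise_sd` to G. With zero
#' noise the curve is exact.
#'
#' @param config A [simulation_config()] (fields under `fcs`).
#' @param curve_id Label.
#' @return Data frame: curve_id, lag_s, g.
#' @export
gen_fcs_curve <- function(config = simulation_config(), curve_id = "curve1") {
  set.seed(config$seed)
  f <- config$fcs
  lags <- 10^seq(log10(f$lag_min_s),
                 log10(f$lag_min_s) + f$lag_decades,
                 length.out = f$n_lags)
  g <- fcs_model_2d(lags, f$true_n, f$true_tau_d_s)
  if (f$noise_sd > 0) g <- g + stats::rnorm(length(g), 0, f$noise_sd)
  data.frame(curve_id = curve_id, lag_s = lags, g = g)
}

#' Tubulation probability at a given surface density
#'
#' Logistic (Hill-type) link: P(tubules | sigma) = 1 / (1 + (sigma50/sigma)^h),
#' which is exactly 0.5 at sigma = sigma50 and 0 at sigma = 0.
#'
#' @param sigma_per_um2 Surface density.
#' @param sigma50_per_um2 Half-point density.
#' @param hill_slope Hill coefficient h.
#' @return Probability in [0, 1).
#' @export
tubulation_probability <- function(sigma_per_um2, sigma50_per_um2 = 62,
                                   hill_slope = 4) {
  stopifnot(all(sigma_per_um2 >= 0), sigma50_per_um2 > 0, hill_slope > 0)
  ifelse(sigma_per_um2 == 0, 0,
         1 / (1 + (sigma50_per_um2 / sigma_per_um2)^hill_slope))
}

#' Generate synthetic per-GUV morphology calls
#'
#' Each GUV at density sigma tubulates with probability
#' [tubulation_probability()]; otherwise its morphology is drawn from the
#' configured baseline distribution over the remaining categories.
#'
#' @param config A [simulation_config()].
#' @param densities_per_um2 One surface density per GUV.
#' @param condition Label attached to all rows.
#' @return Data frame: guv_id, condition, density_per_um2, morphology.
#' @export
gen_morphology_dataset <- function(config = simulation_config(),
                                   densities_per_um2, condition = "Q3") {
  stopifnot(all(densities_per_um2 >= 0))
  set.seed(config$seed)
  m <- config$morphology
  p_tub <- tubulation_probability(densities_per_um2, m$sigma50_per_um2,
                                  m$hill_slope)
  tubulated <- stats::runif(length(p_tub)) < p_tub
  other <- sample(names(m$baseline), length(p_tub), replace = TRUE,
                  prob = m$baseline)
  data.frame(
    guv_id = sprintf("guv%03d", seq_along(p_tub)),
    condition = condition,
    density_per_um2 = densities_per_um2,
    morphology = ifelse(tubulated, "outward_tubules", other))
}

#' Generate synthetic tube cross-section diameters
#'
#' Normal draws emulating repeated cross-section measurements along
#' scaffold-decorated membrane tubes.
#'
#' @param config A [simulation_config()] (fields under `tube`).
#' @return Numeric vector of diameters in nm (negative draws are rejected
#'   and redrawn; at the default mean/sd this is astronomically rare).
#' @export
gen_tube_sections <- function(config = simulation_config()) {
  set.seed(config$seed)
  t <- config$tube
  d <- stats::rnorm(t$n_sections, t$mean_diameter_nm, t$sd_nm)
  while (any(d <= 0)) {
    d[d <= 0] <- stats::rnorm(sum(d <= 0), t$mean_diameter_nm, t$sd_nm)
  }
  d
}
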