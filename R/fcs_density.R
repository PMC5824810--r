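#' One-component 2D FCS autocorrelation model
#'
#' Autocorrelation of fluorescence fluctuations for N particles diffusing in
#' a membrane plane through a Gaussian detection spot:
#' G(tau) = (1/N) * 1 / (1 + tau/tauD). The amplitude G(0) = 1/N and the
#' half-decay lag equals the diffusion time tauD.
#'
#' @param lag_s Lag time(s) in seconds, >= 0.
#' @param n Mean particle number in the detection area (> 0).
#' @param tau_d_s Diffusion time in seconds (> 0).
#' @return G(tau), dimensionless.
#' @export
fcs_model_2d <- function(lag_s, n, tau_d_s) {
  stopifnot(n > 0, tau_d_s > 0, all(lag_s >= 0))
  (1 / n) / (1 + lag_s / tau_d_s)
}

#' Fit the 2D diffusion model to an autocorrelation curve
#'
#' Unweighted least squares of G(tau) = (1/N)/(1 + tau/tauD) on a curve
#' sampled over (typically log-spaced) lags. Fitting is done in
#' log-parameter space to keep N and tauD positive; standard errors are
#' delta-method back-transforms. Initialization is deterministic: N from
#' the amplitude at the smallest lag, tauD from the lag nearest half
#' amplitude.
#'
#' @param curve Data frame (or list) with elements `lag_s` (strictly
#'   increasing, > 0) and `g`.
#' @param min_points Minimum number of lag points (default 10).
#' @return An object of class `fcs_fit`: `n_particles`, `tau_d_s`, their
#'   SDs, `residual_norm`, `residuals`.
#' @export
fit_fcs <- function(curve, min_points = 10L) {
  lag <- curve$lag_s; g <- curve$g
  stopifnot(length(lag) == length(g))
  if (length(lag) < min_points) stop("need at least ", min_points, " lag points")
  if (any(diff(lag) <= 0) || any(lag <= 0)) {
    stop("lags must be strictly increasing and positive")
  }
  g0 <- g[1]
  if (g0 <= 0) stop("non-positive amplitude: curve is not a decaying correlation")
  if (stats::sd(g) < 1e-12 * abs(g0)) {
    stop("flat curve: no decay within the lag range (tauD >> max lag?)")
  }
  n0 <- 1 / g0
  tau0 <- lag[which.min(abs(g - g0 / 2))]
  df <- data.frame(lag = lag, g = g)
  fit <- minpack.lm::nlsLM(
    g ~ exp(-ln_n) / (1 + lag / exp(ltau)),
    data = df,
    start = list(ln_n = log(n0), ltau = log(tau0)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA_real_, NA_real_))
  n_hat <- exp(est[["ln_n"]]); tau_hat <- exp(est[["ltau"]])
  res <- stats::residuals(fit)
  structure(
    list(n_particles = n_hat, tau_d_s = tau_hat,
         n_sd = n_hat * se[["ln_n"]], tau_d_sd = tau_hat * se[["ltau"]],
         residual_norm = sqrt(sum(res^2)), residuals = as.numeric(res)),
    class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("<fcs_fit> N = %.3g +/- %.2g, tauD = %.3g +/- %.2g s\n",
              x$n_particles, x$n_sd, x$tau_d_s, x$tau_d_sd))
  invisible(x)
}

#' Detection-volume waist from a reference dye
#'
#' The diffusion time through a Gaussian spot of waist r0 is
#' tauD = r0^2 / (4 D), so a calibration measurement of tauD for a dye with
#' known diffusion coefficient D yields r0 = sqrt(4 D tauD).
#'
#' @param tau_d_s Measured diffusion time of the reference dye, in s.
#' @param d_um2_s Reference diffusion coefficient in um^2/s.
#' @return Waist radius r0 in nm.
#' @export
waist_from_reference <- function(tau_d_s, d_um2_s) {
  stopifnot(tau_d_s > 0, d_um2_s > 0)
  sqrt(4 * d_um2_s * tau_d_s) * 1000   # um -> nm
}

#' Dynamic viscosity of water
#'
#' Vogel-type correlation for liquid water between 15 and 40 degC
#' (coefficients from the standard correlation anchored at
#' 1.002 mPa s at 20 degC); agreement with tabulated values is within
#' ~0.1% over this range.
#'
#' @param temperature_K Temperature(s) in K, within [288.15, 313.15].
#' @return Viscosity in mPa s.
#' @export
water_viscosity <- function(temperature_K) {
  t_c <- temperature_K - 273.15
  if (any(t_c < 15 | t_c > 40)) {
    stop("temperature outside the supported 15-40 degC range")
  }
  dt <- 20 - t_c
  1.002 * 10^(dt * (1.2378 - 1.303e-3 * dt + 3.06e-6 * dt^2 + 2.55e-8 * dt^3) /
                (t_c + 96))
}

#' Temperature-correct a diffusion coefficient
#'
#' Stokes-Einstein scaling between a reference temperature and the working
#' temperature: D2 = D1 * (T2/T1) * (eta(T1)/eta(T2)), with water viscosity
#' from [water_viscosity()].
#'
#' @param d_um2_s Diffusion coefficient at `t_ref_K`, in um^2/s.
#' @param t_ref_K Reference temperature in K.
#' @param t_work_K Working temperature in K.
#' @return Diffusion coefficient at `t_work_K`, in um^2/s.
#' @examples
#' temperature_correct_d(414, 298.15, 300.65)  # ~441 um^2/s
#' @export
temperature_correct_d <- function(d_um2_s, t_ref_K, t_work_K) {
  stopifnot(d_um2_s > 0)
  d_um2_s * (t_work_K / t_ref_K) *
    (water_viscosity(t_ref_K) / water_viscosity(t_work_K))
}

#' Absolute and reduced surface density from an FCS fit
#'
#' sigma = N / (pi r0^2) in particles per um^2; the reduced (dimensionless)
#' density is rho = sigma L^2 with L the scaffold length. FCS-derived
#' densities are trusted only below the crowding regime: the estimate is
#' flagged invalid when rho > 0.2 (rho = 0.2 exactly is still valid).
#'
#' @param fit An `fcs_fit` object, or a particle number N.
#' @param r0_nm Detection-volume waist radius in nm.
#' @param scaffold_length_nm Scaffold length L in nm (default 110).
#' @return An object of class `density_estimate`: `sigma_per_um2`, `rho`,
#'   `valid`, `source`.
#' @export
surface_density <- function(fit, r0_nm, scaffold_length_nm = 110) {
  n <- if (inherits(fit, "fcs_fit")) fit$n_particles else fit
  stopifnot(n >= 0, r0_nm > 0, scaffold_length_nm > 0)
  sigma <- n / (pi * (r0_nm / 1000)^2)
  density_estimate(sigma, scaffold_length_nm, source = "fcs")
}

#' Construct a density estimate with crowding-validity flag
#'
#' @param sigma_per_um2 Surface density in particles per um^2 (>= 0).
#' @param scaffold_length_nm Scaffold length L in nm.
#' @param source "fcs" or "intensity_calibration".
#' @param rho_max Crowding threshold on rho (default 0.2).
#' @return `density_estimate` object.
#' @export
density_estimate <- function(sigma_per_um2, scaffold_length_nm = 110,
                             source = c("fcs", "intensity_calibration"),
                             rho_max = 0.2) {
  source <- match.arg(source)
  stopifnot(sigma_per_um2 >= 0)
  rho <- sigma_per_um2 * (scaffold_length_nm / 1000)^2
  structure(
    list(sigma_per_um2 = sigma_per_um2, rho = rho,
         valid = rho <= rho_max, source = source,
         scaffold_length_nm = scaffold_length_nm),
    class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("<density_estimate> sigma = %.3g um^-2, rho = %.3g (%s, %s)\n",
              x$sigma_per_um2, x$rho, if (x$valid) "valid" else "crowded",
              x$source))
  invisible(x)
}

#' Build the intensity-to-density calibration line
#'
#' Ordinary least-squares line sigma = slope * I + intercept through pairs of
#' confocal intensity and FCS-derived surface density, using only pairs in
#' the valid (uncrowded, rho <= 0.2) regime. Crowded pairs are dropped and
#' counted. This line lets densities be read off intensity alone in the
#' high-density regime where FCS itself fails.
#'
#' @param intensity_au Per-GUV confocal intensities.
#' @param densities List of `density_estimate` objects (or a numeric vector
#'   of sigma values paired with `valid`).
#' @param valid Logical vector; defaults to the estimates' own flags.
#' @return An object of class `density_calibration`: `slope`, `intercept`,
#'   `n_guvs`, `n_excluded`, `r_squared`.
#' @export
build_intensity_calibration <- function(intensity_au, densities, valid = NULL) {
  if (is.list(densities) && inherits(densities[[1]], "density_estimate")) {
    sigma <- vapply(densities, `[[`, numeric(1), "sigma_per_um2")
    if (is.null(valid)) valid <- vapply(densities, `[[`, logical(1), "valid")
  } else {
    sigma <- as.numeric(densities)
    if (is.null(valid)) valid <- rep(TRUE, length(sigma))
  }
  stopifnot(length(intensity_au) == length(sigma))
  keep <- which(valid)
  n_excluded <- length(sigma) - length(keep)
  if (n_excluded > 0) {
    message(n_excluded, " pair(s) in the crowded regime (rho > 0.2) excluded from calibration")
  }
  if (length(keep) < 3L) stop("need >= 3 valid (rho <= 0.2) pairs to calibrate")
  fit <- stats::lm(sigma ~ intensity, data = data.frame(
    intensity = intensity_au[keep], sigma = sigma[keep]))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((sigma[keep] - mean(sigma[keep]))^2)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         n_guvs = length(keep), n_excluded = n_excluded,
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1),
    class = "density_calibration")
}

#' @export
print.density_calibration <- function(x, ...) {
  cat(sprintf("<density_calibration> sigma = %.4g * I + %.4g (n = %d, R^2 = %.3f)\n",
              x$slope, x$intercept, x$n_guvs, x$r_squared))
  invisible(x)
}

#' Surface density from intensity via the calibration line
#'
#' sigma = slope * I + intercept, clipped at zero (with a warning) if the
#' line predicts a negative density. The crowding flag is recomputed from
#' the predicted density, so estimates in the crowded regime are marked as
#' coming from the calibration rather than from a (there unreliable) FCS fit.
#'
#' @param intensity_au Confocal intensity.
#' @param calibration A `density_calibration` object.
#' @param scaffold_length_nm Scaffold length L in nm.
#' @return `density_estimate` with `source = "intensity_calibration"`.
#' @export
density_from_intensity <- function(intensity_au, calibration,
                                   scaffold_length_nm = 110) {
  stopifnot(inherits(calibration, "density_calibration"))
  sigma <- calibration$slope * intensity_au + calibration$intercept
  if (sigma < 0) {
    warning("calibration predicts negative density; clipping to 0")
    sigma <- 0
  }
  density_estimate(sigma, scaffold_length_nm, source = "intensity_calibration")
}
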