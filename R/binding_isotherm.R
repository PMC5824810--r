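#' Langmuir binding isotherm
#'
#' Equilibrium membrane-bound fluorescence intensity as a function of bulk
#' scaffold concentration: I = Imax / (1 + Kd / Cbulk). Strictly increasing
#' in Cbulk, half-saturated at Cbulk = Kd, saturating at Imax. The limit at
#' Cbulk = 0 is 0.
#'
#' @param bulk_conc_nM Bulk concentration(s) in nM.
#' @param kd_nM Dissociation constant in nM.
#' @param imax Saturation intensity (arbitrary units).
#' @return Predicted intensity, same length as `bulk_conc_nM`.
#' @export
langmuir_model <- function(bulk_conc_nM, kd_nM, imax) {
  stopifnot(kd_nM > 0, imax > 0, all(bulk_conc_nM >= 0))
  ifelse(bulk_conc_nM == 0, 0, imax / (1 + kd_nM / bulk_conc_nM))
}

#' Fit a Langmuir isotherm to a binding titration
#'
#' Least-squares fit of per-GUV intensities versus bulk concentration to
#' I = Imax / (1 + Kd / Cbulk). The fit is performed in log-parameter space
#' (log Kd, log Imax) so both parameters stay positive; reported standard
#' errors are delta-method back-transforms of the log-scale errors from the
#' Jacobian. By default all GUVs are pooled into one fit; `mode =
#' "per_concentration"` first averages intensities per concentration.
#' Independent titration repeats (a `repeat` column) can be fit separately
#' with [fit_langmuir_repeats()].
#'
#' @param data Data frame with columns `bulk_conc_nM` and `intensity_au`
#'   (extra columns such as `guv_id`, `condition` are ignored).
#' @param mode "pooled" (default) or "per_concentration".
#' @param weights Optional per-point weights (e.g. inverse variances).
#' @return An object of class `langmuir_fit`: `kd_nM`, `imax`, `kd_sd_nM`,
#'   `imax_sd`, `n_guvs`, `residual_norm`, `residuals`, `mode`.
#' @export
fit_langmuir <- function(data, mode = c("pooled", "per_concentration"),
                         weights = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(c("bulk_conc_nM", "intensity_au") %in% names(data)))
  df <- data.frame(conc = data$bulk_conc_nM, y = data$intensity_au)
  if (any(df$conc <= 0)) stop("bulk concentrations must be positive")
  if (any(df$y < 0)) stop("intensities must be non-negative")
  if (length(unique(df$conc)) < 2L) {
    stop("degenerate titration: need >= 2 distinct concentrations")
  }
  if (all(df$y == 0)) stop("degenerate titration: all intensities zero")
  span <- max(df$conc) / min(df$conc)
  if (span < 4) {
    warning(sprintf("concentration range spans only %.1f-fold; Kd poorly constrained", span))
  }
  if (mode == "per_concentration") {
    agg <- stats::aggregate(y ~ conc, df, mean)
    df <- data.frame(conc = agg$conc, y = agg$y)
    weights <- NULL
  }
  n_guvs <- nrow(df)

  # deterministic initialization: Imax from the upper tail, Kd at half-Imax
  imax0 <- max(stats::quantile(df$y, 0.95, names = FALSE), max(df$y) * 0.5,
               .Machine$double.eps)
  kd0 <- df$conc[which.min(abs(df$y - imax0 / 2))]
  if (kd0 <= 0) kd0 <- stats::median(df$conc)

  fit <- minpack.lm::nlsLM(
    y ~ exp(limax) / (1 + exp(lkd) / conc),
    data = df,
    start = list(lkd = log(kd0), limax = log(imax0)),
    weights = if (is.null(weights)) rep(1, nrow(df)) else weights,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA_real_, NA_real_))
  kd <- exp(est[["lkd"]]); imax <- exp(est[["limax"]])
  res <- stats::residuals(fit)
  structure(
    list(kd_nM = kd, imax = imax,
         kd_sd_nM = kd * se[["lkd"]],      # delta method on exp()
         imax_sd = imax * se[["limax"]],
         n_guvs = n_guvs,
         residual_norm = sqrt(sum(res^2)),
         residuals = as.numeric(res),
         mode = mode),
    class = "langmuir_fit")
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat(sprintf("<langmuir_fit> Kd = %.3g +/- %.2g nM, Imax = %.4g +/- %.2g (n = %d, %s)\n",
              x$kd_nM, x$kd_sd_nM, x$imax, x$imax_sd, x$n_guvs, x$mode))
  invisible(x)
}

#' Fit independent titration repeats separately
#'
#' Mirrors the reporting convention "Kd +/- s.d., k repeats": each repeat is
#' fit on its own and the per-repeat Kd values are summarised as mean and
#' sample standard deviation.
#'
#' @param data Data frame with columns `bulk_conc_nM`, `intensity_au` and
#'   `repeat` (or `rep`).
#' @param ... Passed to [fit_langmuir()].
#' @return List with `kd_mean_nM`, `kd_sd_nM`, `n_repeats`, `fits`.
#' @export
fit_langmuir_repeats <- function(data, ...) {
  repcol <- intersect(c("repeat.", "repeat", "rep"), names(data))[1]
  if (is.na(repcol)) stop("no repeat column found ('repeat' or 'rep')")
  groups <- split(data, data[[repcol]])
  fits <- lapply(groups, fit_langmuir, ...)
  kds <- vapply(fits, `[[`, numeric(1), "kd_nM")
  list(kd_mean_nM = mean(kds),
       kd_sd_nM = if (length(kds) > 1L) stats::sd(kds) else NA_real_,
       n_repeats = length(fits),
       fits = fits)
}
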