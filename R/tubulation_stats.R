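#' Closed morphology vocabulary
#'
#' The deformation categories scored per GUV after scaffold binding.
#' @export
morphology_levels <- function() {
  c("spherical", "outward_tubules", "inward_tubules",
    "evagination_invagination", "flaccid", "burst")
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k Successes.
#' @param n Trials.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector c(lower, upper).
#' @export
wilson_interval <- function(k, n, level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Per-condition morphology fractions with confidence intervals
#'
#' Tallies per-GUV morphology calls into counts and fractions per condition,
#' with Wilson score intervals. Burst GUVs count towards the denominator.
#' Morphology labels are case-normalized and must come from
#' [morphology_levels()].
#'
#' @param observations Data frame with columns `condition` and `morphology`
#'   (and optionally `guv_id`, `density_per_um2`).
#' @param ci_level Confidence level for the Wilson intervals.
#' @return Data frame of class `morphology_table`: condition, morphology,
#'   count, n, fraction, ci_lower, ci_upper. Every (condition, level) pair
#'   appears, including zero counts.
#' @export
morphology_fractions <- function(observations, ci_level = 0.95) {
  stopifnot(all(c("condition", "morphology") %in% names(observations)))
  morph <- tolower(trimws(observations$morphology))
  bad <- setdiff(unique(morph), morphology_levels())
  if (length(bad) > 0) {
    stop("unknown morphology label(s): ", paste(bad, collapse = ", "))
  }
  conds <- unique(observations$condition)
  rows <- lapply(conds, function(cond) {
    m <- morph[observations$condition == cond]
    n <- length(m)
    do.call(rbind, lapply(morphology_levels(), function(lev) {
      k <- sum(m == lev)
      ci <- wilson_interval(k, n, ci_level)
      data.frame(condition = cond, morphology = lev, count = k, n = n,
                 fraction = k / n, ci_lower = ci[["lower"]],
                 ci_upper = ci[["upper"]])
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("morphology_table", "data.frame")
  out
}

#' Smallest density reaching a target tubulation fraction
#'
#' Given per-condition (surface density, tubulated fraction) points, returns
#' the smallest density at which the (monotone) interpolated fraction reaches
#' `target_fraction`. Non-monotone inputs are first smoothed by isotonic
#' regression (tubulation probability is assumed non-decreasing in density);
#' interpolation between the smoothed points is linear.
#'
#' @param density_per_um2 Surface densities in particles per um^2.
#' @param fraction Tubulated fraction at each density, in [0, 1].
#' @param target_fraction Target fraction in [0, 1].
#' @return List with `reached` (logical), `density_per_um2` (the threshold,
#'   or NA) and `max_fraction`.
#' @export
threshold_density <- function(density_per_um2, fraction, target_fraction) {
  stopifnot(length(density_per_um2) == length(fraction),
            length(density_per_um2) >= 2,
            all(fraction >= 0 & fraction <= 1),
            target_fraction >= 0, target_fraction <= 1)
  ord <- order(density_per_um2)
  x <- density_per_um2[ord]; y <- fraction[ord]
  if (any(diff(y) < 0)) y <- stats::isoreg(x, y)$yf
  if (max(y) < target_fraction) {
    return(list(reached = FALSE, density_per_um2 = NA_real_,
                max_fraction = max(y)))
  }
  i <- which(y >= target_fraction)[1]
  dens <- if (i == 1L) x[1] else {
    # linear interpolation between the last point below and the first at/above
    x[i - 1] + (target_fraction - y[i - 1]) * (x[i] - x[i - 1]) / (y[i] - y[i - 1])
  }
  list(reached = TRUE, density_per_um2 = dens, max_fraction = max(y))
}

#' Summarize measured tube diameters against a geometric prediction
#'
#' Sample mean and standard deviation (n - 1 denominator) of cross-section
#' diameters, plus the ratio of the measured mean to the scaffold-curvature
#' prediction.
#'
#' @param diameters_nm Measured cross-section diameters in nm (n >= 2).
#' @param predicted_nm Predicted diameter (2R) in nm.
#' @return List: `mean_nm`, `sd_nm`, `n`, `predicted_nm`, `ratio`.
#' @export
summarize_tube_diameters <- function(diameters_nm, predicted_nm) {
  stopifnot(length(diameters_nm) >= 2, predicted_nm > 0)
  m <- mean(diameters_nm)
  list(mean_nm = m, sd_nm = stats::sd(diameters_nm),
       n = length(diameters_nm), predicted_nm = predicted_nm,
       ratio = m / predicted_nm)
}
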