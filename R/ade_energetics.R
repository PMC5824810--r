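#' Membrane mechanical parameters
#'
#' Elastic constants of the bilayer used by the Area-Difference-Elasticity
#' (ADE) bending model. Defaults describe a DOPC bilayer: bending modulus
#' kappa = 23.1 kBT, non-local-to-local rigidity ratio alpha = 3/pi,
#' spontaneous curvature C0 = 0 (symmetric bilayer), thickness D = 4 nm,
#' equilibrium leaflet area difference 0.
#'
#' @param kappa_kBT Bending modulus in kBT.
#' @param alpha Ratio of non-local to local bending rigidity (dimensionless).
#' @param c0_per_nm Spontaneous curvature in nm^-1.
#' @param thickness_nm Bilayer thickness in nm.
#' @param delta_a0_nm2 Equilibrium leaflet area difference in nm^2.
#' @param temperature_K Temperature used for conversions to Joules.
#' @return An object of class `membrane_mechanics`.
#' @export
membrane_mechanics <- function(kappa_kBT = 23.1, alpha = 3 / pi,
                               c0_per_nm = 0, thickness_nm = 4,
                               delta_a0_nm2 = 0, temperature_K = 298.15) {
  stopifnot(kappa_kBT > 0, alpha > 0, thickness_nm > 0, temperature_K > 0)
  structure(
    list(kappa_kBT = kappa_kBT, alpha = alpha, c0_per_nm = c0_per_nm,
         thickness_nm = thickness_nm, delta_a0_nm2 = delta_a0_nm2,
         temperature_K = temperature_K),
    class = "membrane_mechanics")
}

#' @export
print.membrane_mechanics <- function(x, ...) {
  cat(sprintf("<membrane_mechanics> kappa = %g kBT, alpha = %.4f, C0 = %g nm^-1, D = %g nm\n",
              x$kappa_kBT, x$alpha, x$c0_per_nm, x$thickness_nm))
  invisible(x)
}

#' ADE bending energy of a uniformly curved membrane patch
#'
#' Evaluates the Area-Difference-Elasticity energy
#' \deqn{\epsilon = \kappa\left[\frac{A}{2}(C_1 + C_2 - C_0)^2 +
#'   \frac{\alpha}{2}\frac{\pi}{A D^2}(\Delta A - \Delta A_0)^2\right]}
#' for a patch of area A with uniform principal curvatures C1, C2 (so the
#' surface integral reduces to multiplication by A). The first term is the
#' local Helfrich bending energy; the second penalises the difference in
#' area between the two leaflets, which a finite-thickness bilayer must
#' accommodate when it bends.
#'
#' @param area_nm2 Patch area A in nm^2.
#' @param c1_per_nm,c2_per_nm Principal curvatures in nm^-1.
#' @param delta_a_nm2 Leaflet area difference Delta A in nm^2. For a
#'   cylindrical tube use [tube_area_difference()] or [tube_bending_energy()].
#' @param mech A [membrane_mechanics()] object.
#' @return Bending energy in kBT.
#' @export
ade_bending_energy <- function(area_nm2, c1_per_nm, c2_per_nm,
                               delta_a_nm2, mech = membrane_mechanics()) {
  stopifnot(inherits(mech, "membrane_mechanics"), area_nm2 > 0)
  if (missing(delta_a_nm2) || is.null(delta_a_nm2) || anyNA(delta_a_nm2)) {
    stop("delta_a_nm2 is required; supply it or use tube_bending_energy() ",
         "which derives Delta A = D*A/R for a cylinder")
  }
  local <- (area_nm2 / 2) * (c1_per_nm + c2_per_nm - mech$c0_per_nm)^2
  nonlocal <- (mech$alpha / 2) * pi / (area_nm2 * mech$thickness_nm^2) *
    (delta_a_nm2 - mech$delta_a0_nm2)^2
  mech$kappa_kBT * (local + nonlocal)
}

#' Leaflet area difference of a cylindrical tube patch
#'
#' Two leaflets separated by the membrane thickness D and bent to cylinder
#' radius R differ in area by Delta A = D * A / R for a mid-surface patch of
#' area A. A flat patch (infinite R) has Delta A = 0.
#'
#' @param area_nm2 Patch area in nm^2.
#' @param radius_nm Cylinder radius in nm (`Inf` for flat).
#' @param thickness_nm Bilayer thickness in nm.
#' @return Delta A in nm^2.
#' @export
tube_area_difference <- function(area_nm2, radius_nm, thickness_nm = 4) {
  stopifnot(area_nm2 > 0, thickness_nm > 0)
  if (is.infinite(radius_nm)) return(0)
  stopifnot(radius_nm > 0)
  thickness_nm * area_nm2 / radius_nm
}

#' Bending energy of wrapping a flat patch into a tube
#'
#' Convenience form of [ade_bending_energy()] for a cylinder: C1 = 1/R,
#' C2 = 0, C0 = 0, Delta A = D*A/R, Delta A0 = 0. With alpha = 3/pi the
#' expression collapses analytically to
#' \deqn{\epsilon = 2 \kappa A / R^2,}
#' independent of the membrane thickness (D cancels between the curvatures
#' and the leaflet area difference).
#'
#' @param area_nm2 Patch area in nm^2.
#' @param radius_nm Target tube radius in nm.
#' @param mech A [membrane_mechanics()] object.
#' @return Bending energy in kBT.
#' @examples
#' tube_bending_energy(1800, 84)  # ~11.8 kBT
#' tube_bending_energy(1800, 46)  # ~39.3 kBT
#' @export
tube_bending_energy <- function(area_nm2, radius_nm, mech = membrane_mechanics()) {
  stopifnot(area_nm2 > 0, radius_nm > 0)
  da <- tube_area_difference(area_nm2, radius_nm, mech$thickness_nm)
  ade_bending_energy(area_nm2, 1 / radius_nm, 0, da, mech)
}

#' Adhesion free energy from a dissociation constant
#'
#' Delta G = ln(Kd / c0) in kBT, with standard state c0 = 1 M. A
#' sub-micromolar Kd therefore gives a strongly negative adhesion energy.
#' Temperature only matters for conversion to J/mol and is carried along.
#'
#' @param kd_M Dissociation constant in molar.
#' @param temperature_K Temperature in K.
#' @return An object of class `adhesion_energy` with fields `delta_g_kBT`,
#'   `kd_M`, `temperature_K`.
#' @examples
#' adhesion_free_energy(0.68e-9)$delta_g_kBT  # -21.1
#' @export
adhesion_free_energy <- function(kd_M, temperature_K = 298.15) {
  if (any(kd_M <= 0)) stop("kd must be positive")
  structure(
    list(delta_g_kBT = log(kd_M / 1), kd_M = kd_M,
         temperature_K = temperature_K),
    class = "adhesion_energy")
}

#' @export
print.adhesion_energy <- function(x, ...) {
  cat(sprintf("<adhesion_energy> Kd = %.3g M -> dG = %.1f kBT\n",
              x$kd_M, x$delta_g_kBT))
  invisible(x)
}

#' Adhesion-versus-bending cost-benefit rule
#'
#' A bound scaffold can deform the membrane when the magnitude of its
#' adhesion free energy is at least the bending cost of the deformation it
#' templates. Equality counts as permitted (fixed tie-break).
#'
#' @param adhesion An `adhesion_energy` object or a Delta G in kBT
#'   (negative for favourable binding).
#' @param bending_kBT Bending energy cost in kBT (non-negative).
#' @return List with `permitted` (logical) and `margin_kBT`
#'   (= |Delta G| - bending cost; positive means energy to spare).
#' @export
cost_benefit <- function(adhesion, bending_kBT) {
  stopifnot(bending_kBT >= 0)
  dg <- if (inherits(adhesion, "adhesion_energy")) adhesion$delta_g_kBT else adhesion
  margin <- abs(dg) - bending_kBT
  list(permitted = margin >= 0, margin_kBT = margin)
}

#' Convert an energy in kBT to Joules
#'
#' @param energy_kBT Energy in units of kBT.
#' @param temperature_K Temperature in K (default 298.15).
#' @return Energy in Joules.
#' @export
kBT_to_joule <- function(energy_kBT, temperature_K = 298.15) {
  kB <- 1.380649e-23
  energy_kBT * kB * temperature_K
}
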