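#' Scaffold design
#'
#' Describes one curved (or flat) membrane-binding nanoscaffold: an arc of
#' fixed contour length that imprints its curvature on the bilayer it binds.
#' Lengths are stored in nm; curvature is exposed in inverse micrometres,
#' the unit conventional for membrane curvature.
#'
#' Two radii can coexist for one design: the radius measured from micrographs
#' (`radius_nm`) and the radius implied by the arc length and curvature angle
#' (`arc_radius_nm = L / theta_rad`). They typically disagree by a few
#' percent; reported curvature and predicted tube diameter key off the
#' measured radius when it is present.
#'
#' @param name Short label, e.g. "H", "Q", "L".
#' @param arc_length_nm Contour length of the scaffold in nm (110 for the
#'   designs studied here).
#' @param angle_deg Curvature angle in degrees, or `NA` for a flat design.
#' @param radius_nm Measured radius of curvature in nm, or `NA` for flat.
#' @param footprint_nm2 Membrane footprint area of one scaffold in nm^2.
#' @param n_anchors Number of membrane anchors.
#' @param anchor_face One of "concave", "convex", "lateral", "none".
#' @return An object of class `scaffold_design`.
#' @export
scaffold_design <- function(name, arc_length_nm = 110, angle_deg = NA_real_,
                            radius_nm = NA_real_, footprint_nm2 = 1800,
                            n_anchors = 3L,
                            anchor_face = c("concave", "convex", "lateral", "none")) {
  anchor_face <- match.arg(anchor_face)
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(arc_length_nm), arc_length_nm > 0,
            is.numeric(footprint_nm2), footprint_nm2 > 0,
            n_anchors >= 0)
  flat <- is.na(radius_nm)
  if (!flat && radius_nm <= 0) stop("radius_nm must be positive or NA (flat)")
  if (!is.na(angle_deg) && (angle_deg <= 0 || angle_deg > 360)) {
    stop("angle_deg must lie in (0, 360]")
  }
  arc_radius_nm <- if (is.na(angle_deg)) NA_real_ else
    radius_from_arc(arc_length_nm, angle_deg)
  structure(
    list(name = name,
         arc_length_nm = arc_length_nm,
         angle_deg = angle_deg,
         radius_nm = if (flat) NA_real_ else radius_nm,
         arc_radius_nm = arc_radius_nm,
         curvature_per_um = curvature_from_radius(if (flat) Inf else radius_nm),
         footprint_nm2 = footprint_nm2,
         n_anchors = as.integer(n_anchors),
         anchor_face = anchor_face,
         flat = flat),
    class = "scaffold_design")
}

#' @export
print.scaffold_design <- function(x, ...) {
  cat(sprintf("<scaffold_design> %s: L = %g nm", x$name, x$arc_length_nm))
  if (x$flat) {
    cat(", flat (C = 0)\n")
  } else {
    cat(sprintf(", theta = %g deg, R = %g nm, C = %.1f um^-1\n",
                x$angle_deg, x$radius_nm, x$curvature_per_um))
  }
  cat(sprintf("  footprint %g nm^2, %d anchors (%s face)\n",
              x$footprint_nm2, x$n_anchors, x$anchor_face))
  invisible(x)
}

#' Curvature from radius
#'
#' Converts a radius of curvature in nm to curvature in inverse micrometres.
#' A flat scaffold is represented by `Inf` (or `NA`) and maps to zero
#' curvature.
#'
#' @param radius_nm Radius in nm; `Inf`/`NA` means flat.
#' @return Curvature C = 1/R in um^-1 (0 for flat).
#' @examples
#' curvature_from_radius(46)  # 21.7 um^-1
#' @export
curvature_from_radius <- function(radius_nm) {
  out <- vapply(radius_nm, function(r) {
    if (is.na(r) || is.infinite(r)) return(0)
    if (r <= 0) stop("radius must be positive, Inf or NA")
    1000 / r            # 1/nm -> 1/um
  }, numeric(1))
  out
}

#' Radius from arc length and curvature angle
#'
#' For a circular arc of contour length L subtending angle theta,
#' R = L / theta (theta in radians).
#'
#' @param arc_length_nm Arc length in nm.
#' @param angle_deg Subtended angle in degrees, in (0, 360].
#' @return Radius in nm.
#' @examples
#' radius_from_arc(110, 131)  # ~48 nm; measured value on micrographs is 46 nm
#' @export
radius_from_arc <- function(arc_length_nm, angle_deg) {
  stopifnot(all(arc_length_nm > 0))
  if (any(angle_deg <= 0 | angle_deg > 360)) {
    stop("angle_deg must lie in (0, 360]; flat designs have no arc radius")
  }
  arc_length_nm / (angle_deg * pi / 180)
}

#' Predicted membrane tube diameter
#'
#' A scaffold of radius R wrapped around a membrane tube sets the tube
#' diameter at 2R. Reporting rounds to the nearest 10 nm, matching how such
#' predictions are usually quoted.
#'
#' @param design A `scaffold_design` (or a radius in nm).
#' @param rounded Round to nearest 10 nm for reporting? Default FALSE.
#' @return Diameter in nm; error for a flat design (no finite tube).
#' @export
predicted_tube_diameter <- function(design, rounded = FALSE) {
  r <- if (inherits(design, "scaffold_design")) design$radius_nm else design
  if (any(is.na(r) | is.infinite(r))) {
    stop("flat scaffold: no finite tube diameter predicted")
  }
  d <- 2 * r
  if (rounded) round(d / 10) * 10 else d
}

#' Membrane coverage fraction
#'
#' Fraction of the membrane surface covered by bound scaffolds at surface
#' density sigma (particles per um^2) with per-particle footprint A (nm^2):
#' coverage = sigma * A, with the unit conversion 1 um^2 = 1e6 nm^2 applied
#' internally.
#'
#' @param sigma_per_um2 Surface density in particles per um^2.
#' @param footprint_nm2 Footprint area per particle in nm^2.
#' @param percent Return integer-rounded percent instead of a fraction?
#' @return Dimensionless fraction (or percent if `percent = TRUE`).
#' @examples
#' coverage_fraction(50, 1800)               # 0.09
#' coverage_fraction(90, 1800, percent = TRUE)  # 16
#' @export
coverage_fraction <- function(sigma_per_um2, footprint_nm2, percent = FALSE) {
  if (any(sigma_per_um2 < 0) || any(footprint_nm2 < 0)) {
    stop("density and footprint must be non-negative")
  }
  frac <- sigma_per_um2 * footprint_nm2 / 1e6
  if (percent) round(100 * frac) else frac
}

#' Built-in scaffold designs
#'
#' The three arc variants studied: H (semi-circle, highly curved), Q
#' (quarter-circle, moderately curved) and L (straight). Radii are the
#' micrograph-measured values; arc-derived radii are carried alongside.
#'
#' @return Named list of `scaffold_design` objects.
#' @export
default_scaffolds <- function() {
  list(
    H = scaffold_design("H", 110, angle_deg = 131, radius_nm = 46,
                        anchor_face = "concave"),
    Q = scaffold_design("Q", 110, angle_deg = 73, radius_nm = 84,
                        anchor_face = "concave"),
    L = scaffold_design("L", 110, anchor_face = "concave")
  )
}

#' Read scaffold designs from CSV
#'
#' Expected columns: name, arc_length_nm, angle_deg, radius_nm,
#' curvature_per_um, footprint_nm2, n_anchors, anchor_face. Blank angle and
#' radius mean a flat design. A stored curvature, when present, is checked
#' against 1/radius.
#'
#' @param path Path to CSV file.
#' @return Named list of `scaffold_design` objects.
#' @export
read_scaffolds <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "arc_length_nm", "footprint_nm2", "n_anchors", "anchor_face")
  if (!all(need %in% names(df))) {
    stop("scaffolds.csv missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    d <- scaffold_design(row$name, row$arc_length_nm,
                         angle_deg = if ("angle_deg" %in% names(df)) row$angle_deg else NA_real_,
                         radius_nm = if ("radius_nm" %in% names(df)) row$radius_nm else NA_real_,
                         footprint_nm2 = row$footprint_nm2,
                         n_anchors = row$n_anchors,
                         anchor_face = row$anchor_face)
    if ("curvature_per_um" %in% names(df) && !is.na(row$curvature_per_um) &&
        row$curvature_per_um > 0) {
      rel <- abs(row$curvature_per_um - d$curvature_per_um) /
        max(d$curvature_per_um, .Machine$double.eps)
      if (rel > 0.05) {
        warning(sprintf("stored curvature %.3g disagrees with 1/radius %.3g for %s",
                        row$curvature_per_um, d$curvature_per_um, d$name))
      }
    }
    d
  })
  names(out) <- df$name
  out
}
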