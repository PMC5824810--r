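#' Run the full analysis chain on synthetic or supplied tables
#'
#' Composes the stages end to end for one scaffold condition: binding
#' titration -> Langmuir Kd -> adhesion free energy; scaffold geometry ->
#' tube bending energy; the two combine into the cost-benefit tubulation
#' decision; FCS curve -> particle number -> surface density and coverage;
#' per-GUV morphology calls -> fractions with confidence intervals. When
#' `inputs` is NULL the tables are simulated from `sim_config` (all
#' randomness flows from its single seed).
#'
#' @param design A [scaffold_design()] (flat designs get no bending energy
#'   or decision).
#' @param mech A [membrane_mechanics()].
#' @param sim_config A [simulation_config()]; used when `inputs` is NULL.
#' @param inputs Optional list with elements `binding` (data frame for
#'   [fit_langmuir()]), `fcs` (curve for [fit_fcs()]), `morphology` (data
#'   frame for [morphology_fractions()]), `tube_sections` (numeric, nm).
#'   Missing elements are simulated.
#' @param r0_nm Detection-volume waist in nm.
#' @return List of class `run_report` with per-stage results and provenance.
#' @export
run_pipeline <- function(design = default_scaffolds()$Q,
                         mech = membrane_mechanics(),
                         sim_config = simulation_config(),
                         inputs = NULL,
                         r0_nm = 207) {
  get_input <- function(name, gen) {
    if (!is.null(inputs) && !is.null(inputs[[name]])) inputs[[name]] else gen()
  }
  binding <- get_input("binding", function()
    gen_binding_dataset(sim_config, condition = design$name))
  fcs_curve <- get_input("fcs", function() gen_fcs_curve(sim_config))
  tube_sections <- get_input("tube_sections", function() gen_tube_sections(sim_config))

  lf <- fit_langmuir(binding)
  adhesion <- adhesion_free_energy(lf$kd_nM * 1e-9, mech$temperature_K)

  ff <- fit_fcs(fcs_curve)
  dens <- surface_density(ff, r0_nm, design$arc_length_nm)
  coverage <- coverage_fraction(dens$sigma_per_um2, design$footprint_nm2)

  bending <- NULL; decision <- NULL; tube_summary <- NULL
  if (!design$flat) {
    bending <- tube_bending_energy(design$footprint_nm2, design$radius_nm, mech)
    decision <- cost_benefit(adhesion, bending)
    tube_summary <- summarize_tube_diameters(
      tube_sections, predicted_tube_diameter(design, rounded = TRUE))
  }

  morphology <- get_input("morphology", function() {
    dens_draw <- pmax(0, dens$sigma_per_um2 *
                        stats::runif(100, 0.2, 1.6))
    gen_morphology_dataset(sim_config, dens_draw, condition = design$name)
  })
  morph_tab <- morphology_fractions(morphology)

  structure(
    list(condition = design$name,
         langmuir = lf,
         adhesion = adhesion,
         fcs = ff,
         density = dens,
         coverage = coverage,
         bending_kBT = bending,
         decision = decision,
         tube_summary = tube_summary,
         morphology = morph_tab,
         provenance = list(seed = sim_config$seed,
                           r0_nm = r0_nm,
                           mechanics = unclass(mech),
                           package_version = as.character(utils::packageVersion("memsculpt")))),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> condition %s\n", x$condition))
  cat(sprintf("  Kd = %.3g nM -> dG = %.1f kBT\n",
              x$langmuir$kd_nM, x$adhesion$delta_g_kBT))
  cat(sprintf("  sigma = %.3g um^-2 (rho = %.3g), coverage = %.1f%%\n",
              x$density$sigma_per_um2, x$density$rho, 100 * x$coverage))
  if (!is.null(x$bending_kBT)) {
    cat(sprintf("  bending cost = %.1f kBT -> tubulation %s (margin %.1f kBT)\n",
                x$bending_kBT,
                if (x$decision$permitted) "permitted" else "not permitted",
                x$decision$margin_kBT))
  } else {
    cat("  flat scaffold: no tube energy / decision\n")
  }
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' Writes the report (fits, energies, decision, morphology table,
#' provenance) as pretty-printed JSON that round-trips to identical values.
#'
#' @param report A `run_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  out <- list(
    condition = report$condition,
    langmuir = report$langmuir[c("kd_nM", "imax", "kd_sd_nM", "imax_sd",
                                 "n_guvs", "residual_norm", "mode")],
    adhesion_dG_kBT = report$adhesion$delta_g_kBT,
    fcs = report$fcs[c("n_particles", "tau_d_s", "n_sd", "tau_d_sd")],
    density = unclass(report$density),
    coverage_fraction = report$coverage,
    bending_kBT = report$bending_kBT,
    decision = report$decision,
    tube_summary = report$tube_summary,
    morphology = as.data.frame(report$morphology),
    provenance = report$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read an analysis configuration file
#'
#' YAML with flat sections `mechanics` (kappa_kBT, alpha, c0_per_nm,
#' thickness_nm, delta_a0_nm2, temperature_K), `fcs` (r0_nm), `simulation`
#' (seed, true_kd_nM, ...) and `scaffolds` (path to scaffolds.csv or an
#' inline list). Missing fields fall back to package defaults.
#'
#' @param path Path to a YAML config.
#' @return List with `mechanics` ([membrane_mechanics()]), `sim_config`
#'   ([simulation_config()]), `r0_nm`, `scaffolds`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  mech_args <- cfg$mechanics %||% list()
  mech <- do.call(membrane_mechanics, mech_args)
  sim_args <- cfg$simulation %||% list()
  sim <- do.call(simulation_config, sim_args)
  scaffolds <- if (!is.null(cfg$scaffolds) && is.character(cfg$scaffolds)) {
    read_scaffolds(cfg$scaffolds)
  } else {
    default_scaffolds()
  }
  list(mechanics = mech, sim_config = sim,
       r0_nm = cfg$fcs$r0_nm %||% 207, scaffolds = scaffolds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
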