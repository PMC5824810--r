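#!/usr/bin/env Rscript
# Fit the one-component 2D diffusion model to the simulated autocorrelation
# curve and convert the particle number to an absolute surface density with
# the crowding-validity flag; also illustrate the waist calibration chain
# (reference dye -> temperature-corrected D -> r0).
# Output: results/fcs_density.json

library(memsculpt)

curve <- read.csv("results/tables/fcs.csv")
fit <- fit_fcs(curve)
print(fit)

# detection-volume calibration: reference dye D = 414 um^2/s at 25 degC,
# corrected to the 27.5 degC working temperature
d_work <- temperature_correct_d(414, 298.15, 300.65)
tau_ref <- (0.207^2) / (4 * d_work)    # what a 207-nm waist implies
r0 <- waist_from_reference(tau_ref, d_work)
cat(sprintf("working-T diffusion %.1f um^2/s; waist round-trip %.1f nm\n",
            d_work, r0))

dens <- surface_density(fit, r0_nm = 207, scaffold_length_nm = 110)
print(dens)
cov <- coverage_fraction(dens$sigma_per_um2, 1800)
cat(sprintf("coverage at this density: %.1f%%\n", 100 * cov))

jsonlite::write_json(
  list(n_particles = fit$n_particles, tau_d_s = fit$tau_d_s,
       sigma_per_um2 = dens$sigma_per_um2, rho = dens$rho,
       valid = dens$valid, coverage_fraction = cov,
       d_work_um2_s = d_work),
  "results/fcs_density.json", auto_unbox = TRUE, digits = NA)
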