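#!/usr/bin/env Rscript
# Fit the Langmuir isotherm to the simulated titration and convert the
# fitted Kd to an adhesion free energy. Run analysis/01_simulate.R first.
# Output: results/binding_fit.json

library(memsculpt)

binding <- read.csv("results/tables/binding.csv")
truth <- jsonlite::read_json("results/tables/ground_truth.json")

fit <- fit_langmuir(binding)
print(fit)
dg <- adhesion_free_energy(fit$kd_nM * 1e-9)
cat(sprintf("true Kd %.3g nM -> fitted %.3g +/- %.2g nM; dG = %.1f kBT\n",
            truth$true_kd_nM, fit$kd_nM, fit$kd_sd_nM, dg$delta_g_kBT))

jsonlite::write_json(
  list(kd_nM = fit$kd_nM, kd_sd_nM = fit$kd_sd_nM, imax = fit$imax,
       imax_sd = fit$imax_sd, n_guvs = fit$n_guvs,
       residual_norm = fit$residual_norm,
       adhesion_dG_kBT = dg$delta_g_kBT,
       true_kd_nM = truth$true_kd_nM),
  "results/binding_fit.json", auto_unbox = TRUE, digits = NA)
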