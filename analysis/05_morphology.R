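#!/usr/bin/env Rscript
# Aggregate the simulated per-GUV morphology calls into per-density
# tubulated fractions, extract the densities for tubulation onset (50%)
# and near-complete tubulation (80%), and compare synthetic tube
# cross-sections with the geometric prediction.
# Output: results/morphology_summary.json

library(memsculpt)

morph <- read.csv("results/tables/morphology.csv")
sections <- read.csv("results/tables/tube_sections.csv")$diameter_nm

frac <- tapply(morph$morphology == "outward_tubules",
               morph$density_per_um2, mean)
dens <- as.numeric(names(frac))

th50 <- threshold_density(dens, as.numeric(frac), 0.5)
th80 <- threshold_density(dens, as.numeric(frac), 0.8)
cat(sprintf("tubulation onset (50%%) at %.0f um^-2; near-complete (80%%) at %.0f um^-2\n",
            th50$density_per_um2, th80$density_per_um2))
cat(sprintf("coverage at those densities: %d%% and %d%%\n",
            coverage_fraction(th50$density_per_um2, 1800, percent = TRUE),
            coverage_fraction(th80$density_per_um2, 1800, percent = TRUE)))

pred <- predicted_tube_diameter(default_scaffolds()$Q, rounded = TRUE)
ts <- summarize_tube_diameters(sections, pred)
cat(sprintf("tube diameters %.0f +/- %.0f nm (n = %d) vs predicted %d nm (ratio %.2f)\n",
            ts$mean_nm, ts$sd_nm, ts$n, pred, ts$ratio))

jsonlite::write_json(
  list(per_density_fraction = data.frame(density_per_um2 = dens,
                                         tubulated_fraction = as.numeric(frac)),
       threshold_50pct_per_um2 = th50$density_per_um2,
       threshold_80pct_per_um2 = th80$density_per_um2,
       tube_diameter = ts),
  "results/morphology_summary.json", auto_unbox = TRUE, digits = NA)
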