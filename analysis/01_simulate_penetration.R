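#!/usr/bin/env Rscript
# Antibody penetration under temperature-dependent binding kinetics.
#
# Solves the radial reaction-diffusion system for the four canonical
# scenarios (room-temperature kinetics vs heated-first-phase kinetics,
# baseline vs Stokes-Einstein-elevated diffusivity) on the production
# grid, and summarizes depth and homogeneity of the final bound-complex
# profile. The headline comparison: weakening the association
# equilibrium during the long hot phase (k_on 1 -> 2, k_off 1 -> 60.75)
# deepens and homogenizes staining far more than the ~11% diffusivity
# gain from heating ever could.

library(deepstain)

dir.create("results", showWarnings = FALSE)

cat("Stokes-Einstein diffusivity ratio 22 -> 55 C:",
    round(stokes_einstein_ratio(22, 55), 2), "\n")

cfg <- sim_config()          # r in [0, 2], 1000 x 500 grid
metrics <- rd_scenarios(cfg)
print(metrics, digits = 3)
write.csv(metrics, "results/penetration_metrics.csv", row.names = FALSE)

# final bound-complex profiles of the two headline scenarios
sol_conv <- solve_rd(cfg, rd_schedule(list(list(
  start = 0, params = kinetic_params_22c()))))
sol_hot <- solve_rd(cfg, two_phase_schedule(kinetic_params_55c(),
                                            kinetic_params_22c()))
p_conv <- profile_at(sol_conv, 1, "ab_ag")
p_hot <- profile_at(sol_hot, 1, "ab_ag")
write.csv(data.frame(r = p_conv$r, inside = p_conv$inside,
                     ab_ag_conventional = p_conv$value,
                     ab_ag_heated = p_hot$value),
          "results/final_profiles.csv", row.names = FALSE)

imp <- function(a, b) sprintf("%.3f -> %.3f", a, b)
cat("\nInside-cylinder CV of [Ab-Ag]:",
    imp(metrics$cv_in[metrics$scenario == "conventional"],
        metrics$cv_in[metrics$scenario == "heated"]),
    "\nCenter/edge ratio:",
    imp(metrics$center_edge_ratio[metrics$scenario == "conventional"],
        metrics$center_edge_ratio[metrics$scenario == "heated"]), "\n")
cat("Wrote results/penetration_metrics.csv and results/final_profiles.csv\n")
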