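#!/usr/bin/env Rscript
# Simulate the study's raw inputs: a 230-line single-agent screen with a
# planted KRAS resistance multiplier, and write the plate, ground truth and
# mutation tables that the downstream drivers consume.

library(panelscreen)

outdir <- "results/simulated"
seed <- 20240901

cfg <- panel_config(seed = seed)  # defaults: 230 lines, KRAS x3, cv 5%
panel <- synth_single_agent_panel(cfg)

write_table_csv(panel$plate, file.path(outdir, "plate_single_agent.csv"))
write_table_csv(panel$truth, file.path(outdir, "truth_single_agent.csv"))
write_table_csv(panel$mutations, file.path(outdir, "mutations.csv"))
write_config_yaml(cfg, file.path(outdir, "panel_config.yaml"))
write_manifest(file.path(outdir, "manifest.yaml"), config = cfg, seed = seed,
               inputs = file.path(outdir, c("plate_single_agent.csv",
                                            "truth_single_agent.csv",
                                            "mutations.csv")))

n_mut <- colSums(panel$mutation_calls)
message(sprintf("Simulated %d lines x %d doses x %d replicates (%d wells).",
                cfg$n_lines, cfg$dose_grid$n_points, cfg$n_replicates,
                nrow(panel$plate)))
message(sprintf("Mutant line counts: %s.",
                paste(sprintf("%s=%d", names(n_mut), n_mut), collapse = ", ")))
message(sprintf("True median inflection, KRAS mutant vs WT: %.0f vs %.0f nM.",
                median(panel$truth$inflection_nM[panel$mutation_calls[, "KRAS"] == 1]),
                median(panel$truth$inflection_nM[panel$mutation_calls[, "KRAS"] == 0])))
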