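#!/usr/bin/env Rscript
# Single-agent screen analysis: T0-normalize and fit every line, extract
# growth metrics with censoring, then run the genome-wide mutation-vs-potency
# association screen (rank-sum on log10 gIC50) and the net-death depletion
# test for KRAS.

library(panelscreen)

indir <- "results/simulated"
outdir <- "results/screen"
if (!file.exists(file.path(indir, "plate_single_agent.csv")))
  stop("run analysis/01_simulate_screen.R first")

plate <- read_plate_csv(file.path(indir, "plate_single_agent.csv"))
maf <- read_maf_csv(file.path(indir, "mutations.csv"))

scr <- run_single_agent_screen(plate, maf)
write_table_csv(scr$metrics, file.path(outdir, "growth_metrics.csv"))
write_table_csv(scr$associations, file.path(outdir, "associations.csv"))

n_cens <- sum(scr$metrics$gic50_censor != "none")
message(sprintf("Fitted %d lines; %d gIC50 values censored (> max tested or degenerate).",
                nrow(scr$metrics), n_cens))
message(sprintf("%d markers tested; %d significant at unadjusted p < 0.05.",
                nrow(scr$associations), sum(scr$associations$significant)))
message("Top associations:")
print(head(scr$associations[, c("marker", "marker_type", "n_mut", "median_nM_mut",
                                "median_nM_wt", "direction", "p_value", "q_value")], 5),
      row.names = FALSE)

# KRAS depletion among net-death lines (Fisher exact on the 2x2)
ph <- build_binary_phenotypes(scr$metrics, mm = scr$mutation_matrix)
enr <- enrichment_2x2(ph$ras_pathway_mut, ph$net_death)
message(sprintf("RAS-pathway mutation vs net cell death: OR %.2f, Fisher p = %.4g.",
                enr$odds_ratio, enr$p_value))
write_table_csv(ph, file.path(outdir, "phenotypes.csv"))
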