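#!/usr/bin/env Rscript
# Batch workflow over a 34-member synthetic fentanyl-analog panel sharing
# fentanyl's human clearance, with brain/plasma exposure ranking against
# fentanyl as reference. Writes the ranked batch report.
library(opbpk)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)
seed <- 7L

phys <- get_physiology("human", 70)
panel <- gen_compound_panel(34, seed = seed, clsys = 62.66)
panel$fentanyl <- load_compound_table()[["fentanyl_human"]]

batch <- run_batch(panel, phys, dose_regimen(amount = 100),
                   kp = list(fentanyl = load_kp_table("fentanyl_human_qsar")),
                   reference = "fentanyl", t_end = 504)
rep <- batch$report
write.csv(rep, file.path(out_dir, "analog_batch_report.csv"), row.names = FALSE)

cat(sprintf("%d/%d analogs simulated; %d flagged with brain/plasma Cmax ratio above fentanyl\n",
            nrow(rep) - 1, length(panel) - 1,
            sum(rep$vs_reference == "higher")))
cat(sprintf("Shared clearance makes exposures near-identical: AUC0-inf CV %.2f%% (Dose/CL = %.1f pg.h/mL)\n",
            100 * sd(rep$auc_0_inf) / mean(rep$auc_0_inf),
            auc_inf_iv(100, 62.66)))
print(utils::head(rep[, c("name", "brain_plasma_cmax", "brain_plasma_auc",
                          "vs_reference")], 10))
write_run_manifest(file.path(out_dir, "analog_batch_manifest.json"),
                   inputs = list(n_analogs = 34, clsys_L_h = 62.66,
                                 dose_ug = 100, species = "human",
                                 t_end_h = 504),
                   seed = seed)
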