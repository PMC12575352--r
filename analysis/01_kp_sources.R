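#!/usr/bin/env Rscript
# Tissue/blood partition coefficient (Kp) sources for fentanyl-class opioids:
# packaged published tables, the tissue-composition predictor, and the
# interspecies extrapolation formula. Writes tidy Kp tables and the fitted
# rat-to-human scale factor to results/.
library(opbpk)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

fixtures <- c("bht_rat_qsar", "fentanyl_rat_report", "fentanyl_rat_qsar",
              "fentanyl_human_extrapolated", "fentanyl_human_qsar")
sets <- lapply(fixtures, load_kp_table)
names(sets) <- fixtures

compounds <- load_compound_table()
sets$fentanyl_rat_composition <-
  predict_kp_composition(compounds[["fentanyl_rat"]])
sets$fentanyl_human_composition <-
  predict_kp_composition(compounds[["fentanyl_human"]])

kp_long <- do.call(rbind, lapply(names(sets), function(id) {
  s <- sets[[id]]
  data.frame(set = id, compound = s$compound, species = s$species,
             source = s$source, tissue = names(s$kp), kp = unname(s$kp))
}))
write.csv(kp_long, file.path(out_dir, "kp_sources.csv"), row.names = FALSE)

# the published extrapolated-human row is a single multiple of the rat row
ratio <- sets$fentanyl_human_extrapolated$kp / sets$fentanyl_rat_report$kp
s_hat <- median(ratio)
cv <- sd(ratio) / mean(ratio)
cat(sprintf("Published human-extrapolated / rat-report Kp ratio: %.4f (CV %.2f%%)\n",
            s_hat, 100 * cv))
cat(sprintf("Printed unbound-fraction pair implies %.3f instead (documented discrepancy)\n",
            0.255 / 0.083 * (1.01 / 1.01)))

write.csv(data.frame(statistic = c("scale_factor_median", "scale_factor_cv",
                                   "printed_fup_implied_factor"),
                     value = c(s_hat, cv, 0.255 / 0.083)),
          file.path(out_dir, "kp_extrapolation_summary.csv"),
          row.names = FALSE)

cat(sprintf("Composition predictor (fentanyl, human): brain Kp %.2f vs published QSAR row %.2f\n",
            sets$fentanyl_human_composition$kp[["brain"]],
            sets$fentanyl_human_qsar$kp[["brain"]]))
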