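#!/usr/bin/env Rscript
# Fold-error scoring of the model-predicted PK parameters against published
# clinical observations for sufentanil, alfentanil and remifentanil, using
# the exact unit conversions of the source studies.
library(opbpk)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

# observed-study conversions: 164 min half-life; 1.7 L/kg Vss at 70 kg
cat(sprintf("sufentanil observed: T1/2 %.2f h, Vss %.0f L\n",
            convert_units(164, "min", "h"),
            convert_units(1.7, "L/kg", "L", body_weight = 70)))

pairs <- read.csv(system.file("extdata", "observed_pk.csv", package = "opbpk"),
                  comment.char = "#")
report <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
  fe <- fold_error(pairs$predicted[i], pairs$observed[i],
                   parameter = paste(pairs$analog[i], pairs$parameter[i]))
  data.frame(analog = pairs$analog[i], parameter = pairs$parameter[i],
             predicted = fe$predicted, observed = fe$observed,
             ratio = round(fe$ratio_as_printed, 2),
             fold_error = round(fe$fold_error, 2),
             within_2fold = fe$within_2fold, within_1.3_1.7 = fe$within_range)
}))
print(report)
write.csv(report, file.path(out_dir, "clinical_fold_errors.csv"),
          row.names = FALSE)
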