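#!/usr/bin/env Rscript
# Summarise the stress tests into basal / ATP-linked / maximal / spare /
# non-mitochondrial respiration per condition and evaluate the three
# directional predictions: lactic acid lowers basal OCR, intracellular
# protons alone lower basal OCR, sodium lactate leaves it unchanged.
#
# Run from the repository root:  Rscript analysis/03_compare_conditions.R

suppressPackageStartupMessages(library(qnflux))

dir.create("results", showWarnings = FALSE)

model <- frc_reference_model()
cmp <- compare_conditions(model)
verdicts <- attr(cmp, "verdicts")

write.table(cmp, "results/stress_metrics.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(
  data.frame(prediction = names(verdicts), holds = unname(verdicts)),
  "results/predictions.tsv", sep = "\t", quote = FALSE, row.names = FALSE
)

cat("Stress-test metrics by condition (model OCR levels, 0-10):\n")
print(cmp, row.names = FALSE)
cat("\nDirectional predictions:\n")
for (nm in names(verdicts)) {
  cat(sprintf("  %-24s %s\n", nm, if (verdicts[[nm]]) "holds" else "FAILS"))
}
stopifnot(all(verdicts))
cat("\nWrote results/stress_metrics.tsv and results/predictions.tsv\n")
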