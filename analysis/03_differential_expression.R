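#!/usr/bin/env Rscript
# Stage 3: time-paired differential expression. For every gene, two-sided
# paired t-tests across the 12 matched time points for RF vs CF, SF vs CF
# and SF vs RF, followed by one Benjamini-Hochberg correction over the
# pooled p-values of all genes and all three comparisons.

library(dietswitch)
expr <- read_expression("results/data/expression.tsv", "results/data/samples.tsv")

comp <- run_comparisons(expr)
write_comparisons(comp, "results/comparisons.tsv")

for (cm in unique(comp$comparison)) {
  sub <- comp[comp$comparison == cm, ]
  sig <- sub$q < 0.05
  message(sprintf("%s: %d of %d genes significant (q < 0.05); %.1f%% down",
                  cm, sum(sig), nrow(sub),
                  100 * mean(sub$mean_diff_log2[sig] < 0)))
}
dd <- comp[comp$comparison == "RF_vs_CF" & comp$q < 0.05, ]
message(sprintf("diet-dependent fold-change range: %.2f to %.2f",
                min(dd$fold_change), max(dd$fold_change)))
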