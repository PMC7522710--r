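#!/usr/bin/env Rscript
# Prevalence of the EVE in the isofemale line from the genotyping counts:
# 28 of 31 individual mosquitoes positive. Wilson score interval.

suppressPackageStartupMessages(library(evepirna))
dir.create("results", showWarnings = FALSE)

p <- prevalence(28, 31)
out <- data.frame(positive = 28L, tested = 31L, percent = p$percent,
                  ci_low = p$ci_low, ci_high = p$ci_high)
write.table(out, "results/prevalence.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("EVE prevalence: %.0f%% (%d/%d), 95%% Wilson CI %.1f%%-%.1f%%\n",
            p$percent, 28L, 31L, p$ci_low, p$ci_high))
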