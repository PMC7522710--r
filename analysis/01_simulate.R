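#!/usr/bin/env Rscript
# Build the synthetic study system: a ~10.7 kb virus, a host contig carrying
# a four-fragment EVE (two fragments flipped, 4% diverged), and three
# truth-labelled small-RNA populations (21-nt siRNAs, 1U-biased 26-30 nt
# primary piRNAs from the EVE transcript, secondary piRNAs cut from the
# virus with an exact 10-nt 5' overlap). Writes references, reads and truth
# tables under results/data/.

suppressPackageStartupMessages(library(evepirna))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(seed = 20260920L)
sim <- simulate_dataset(cfg)

write_fasta(c(sim$virus, sim$host_contig), file.path(out, "references.fasta"))
write_fastq(sim$reads, file.path(out, "reads.fastq"))
write.table(sim$fragments, file.path(out, "truth_fragments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$labels, file.path(out, "truth_read_labels.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Simulated dataset (seed ", cfg$seed, "):\n", sep = "")
cat("  virus: ", nchar(sim$virus[[1]]), " nt; host contig: ",
    nchar(sim$host_contig[[1]]), " nt\n", sep = "")
cat("  EVE: ", nrow(sim$fragments), " fragments, ",
    sum(sim$fragments$orientation == "-"), " flipped, planted identity ",
    sprintf("%.1f", sum(sim$fragments$percent_identity * sim$fragments$length) /
              sum(sim$fragments$length)), "%\n", sep = "")
cat("  reads: ", nrow(sim$reads), " emitted (",
    sim$n_rejected, " rejected by 19-33 nt size selection)\n", sep = "")
print(table(sim$labels$class))
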