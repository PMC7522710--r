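#!/usr/bin/env Rscript
# Scan the host contig for virus-derived segments by seed-and-extend local
# alignment, chain the HSPs into EVE fragments, and compare the recovered
# structure (count, orientation, boundaries, percent identity) against the
# planted truth. Requires analysis/01_simulate.R to have run.

suppressPackageStartupMessages(library(evepirna))

refs <- read_fasta("results/data/references.fasta")
virus <- refs["virus"]
contig <- refs["host"]
truth <- read.table("results/data/truth_fragments.tsv", sep = "\t",
                    header = TRUE)

fragments <- discover_eve(contig, virus)
rep <- fragment_identity_report(fragments, contig, virus,
                                tsv = "results/eve_fragments.tsv",
                                bed = "results/eve_fragments.bed")

cat("Recovered", nrow(fragments), "EVE fragments (planted:",
    nrow(truth), "):\n")
print(rep$fragments[, c("contig_start", "contig_end", "virus_start",
                        "virus_end", "orientation", "percent_identity")])
cat(sprintf("Length-weighted overall identity: %.2f%%\n",
            rep$overall_identity))

fr <- rep$fragments[order(rep$fragments$contig_start), ]
tr <- truth[order(truth$contig_start), ]
cat("Orientations match truth:",
    all(fr$orientation == tr$orientation), "\n")
cat("Max boundary error:",
    max(abs(fr$contig_start - tr$contig_start),
        abs(fr$contig_end - tr$contig_end)), "nt\n")
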