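#!/usr/bin/env Rscript
# Align the small-RNA library to the virus with the 0/1-mismatch stratum
# aligner and derive the strand-resolved size spectrum and per-nucleotide
# coverage of the piRNA-sized (26-30 nt) reads. Writes the tabulated tracks
# (and, when ggplot2 is present, the standard profile figures) under
# results/.

suppressPackageStartupMessages(library(evepirna))

refs <- read_fasta("results/data/references.fasta")
virus <- refs["virus"]
reads <- read_fastq("results/data/reads.fastq")

aln <- align_reads(reads, virus, max_mismatch = 1)
cat("Mapped", length(unique(aln$read_id)), "of", nrow(reads),
    "reads to the virus (<=1 mismatch)\n")

spec <- size_spectrum(aln)
write.table(spec, "results/size_spectrum.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
by_len <- tapply(spec$count, spec$length, sum)
cat("Size spectrum mode:", names(which.max(by_len)), "nt;",
    sprintf("strand balance (+): %.2f\n",
            sum(spec$count[spec$strand == "+"]) / sum(spec$count)))

cov <- coverage_track(aln, nchar(virus[[1]]), size_class = c(26L, 30L))
write.table(cov, "results/coverage_26_30.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Uncovered positions (26-30 nt class):",
    length(attr(cov, "uncovered")), "of", nchar(virus[[1]]), "\n")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  ggplot2::ggsave("results/size_spectrum.png", plot_size_spectrum(spec),
                  width = 6, height = 4, dpi = 150)
  cat("Wrote results/size_spectrum.png\n")
}
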