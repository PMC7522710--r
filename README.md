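# evepirna

Strand-resolved small-RNA analysis of endogenous viral elements (EVEs) and
their cognate viruses in insect genomes.

EVEs are fragments of viral genomes integrated into a host chromosome.
When an EVE sits in a piRNA cluster, its transcript is processed into
26–30 nt PIWI-interacting RNAs; fragments inserted antisense to a
circulating cognate virus yield piRNAs complementary to the viral RNA,
which can prime ping-pong amplification: a primary piRNA (uridine at
position 1, the "1U bias") guides slicing of viral RNA ten bases from its
5' end, producing secondary piRNAs with an exact 10-nt 5' overlap and an
adenine at position 10 (the "10A bias"). This package implements the full
analysis chain used to demonstrate that mechanism from sequencing data,
for researchers studying antiviral RNAi/piRNA immunity in insects:

* **EVE discovery** — seed-and-extend ungapped local alignment (X-drop
  extension, diagonal chaining) reporting fragment structure, orientation
  and percent identity;
* **small-read alignment** — an exact 0/1-mismatch stratum aligner for
  small references (all best-stratum hits, multi-mappers down-weighted
  1/n), validated against an exhaustive-scan oracle;
* **profiles** — strand-resolved size spectra and per-nucleotide 5'-end /
  depth coverage;
* **piRNA signatures** — positional nucleotide bias matrices (1U/10A,
  sequence-logo input) and the 5'-overlap spectrum
  `c(d) = Σ_i S(i)·A(i+d−1)` with z-scores over the d = 1..30 background;
  the ping-pong statistic is z(10);
* **disambiguation** — EVE-derived vs virus-derived read classification by
  zero-mismatch mapping to both references, with diagnostic-site density;
* **simulation** — a ground-truthed generator of siRNA / primary /
  secondary piRNA populations emulating the study system (a ~10.7 kb
  flavivirus, a four-fragment EVE with two fragments flipped and 4%
  divergence), used for parameter-recovery validation of everything above.

## Worked example

The `analysis/` directory holds the numbered workflow drivers
(`01_simulate.R` … `06_prevalence.R`), which write their tables under
`results/`. Running them in order prints, among other things:

```
== analysis/02_eve_discovery.R
Recovered 4 EVE fragments (planted: 4):
  contig_start contig_end virus_start virus_end orientation percent_identity
1         5001       5706        2687      3392           +         96.17564
2         5704       6060         452       808           -         95.79832
3         6062       6925        4622      5485           -         96.75926
4         6926       8438        6761      8273           +         95.96827
Length-weighted overall identity: 96.19%
Orientations match truth: TRUE
Max boundary error: 2 nt

== analysis/04_pirna_signatures.R
Primary piRNA 1U fraction:   0.901 (simulated enforcement 0.9)
Secondary piRNA 10A fraction: 0.966 (expected ~0.96 at 4% divergence)
Overlap spectrum: argmax at d = 10, z(10) = 5.28

== analysis/05_knockout_contrast.R
Control: median z(10) = 5.31; peak at d = 10 in 20/20 runs
Knockout: median z(10) = 0.00; all below 2: TRUE
Median contrast: 5.31

== analysis/06_prevalence.R
EVE prevalence: 90% (28/31), 95% Wilson CI 75.1%-96.7%
```

Reading the output: the discovery module recovers the planted EVE
structure (four fragments, two antisense, ≈96% identity to the virus)
from sequence alone; the 1U and 10A fractions recover the simulation's
generative parameters; the overlap spectrum peaks at exactly 10 nt — the
ping-pong signature — and ablating the EVE (no primary piRNAs) collapses
it; and the prevalence helper reproduces the genotyping summary with a
Wilson interval.

The same steps are available programmatically (see the methods vignette,
`vignettes/eve-pirna-signatures.Rmd`) and as a one-call orchestrated run
over a YAML config:

```r
library(evepirna)
run_pipeline(list(seed = 1L, out_dir = "run1",
                  simulate = list(n_sirna = 5000L, n_primary = 5000L,
                                  n_secondary = 5000L)))
```

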