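---
title: "EVE-derived piRNAs and the ping-pong signature: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EVE-derived piRNAs and the ping-pong signature: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological model

Endogenous viral elements (EVEs) are fragments of viral genomes integrated
into a host chromosome and inherited like any host allele. In *Aedes*
mosquitoes, EVE loci sit inside piRNA clusters: the locus is transcribed as
a single-stranded precursor and diced into 26–30 nt PIWI-interacting RNAs
(piRNAs). When an EVE fragment is inserted in reverse orientation relative
to a circulating cognate virus, its piRNAs are *antisense* to the viral
genome and can prime the ping-pong amplification cycle on viral RNA:

* **primary piRNAs** are cut directly from the precursor and carry a
  uridine at position 1 (the 1U bias);
* a PIWI protein loaded with a primary piRNA slices complementary viral
  RNA ten bases from the piRNA's 5' end, producing **secondary piRNAs**
  whose 5' ends overlap the primary's 5' end by exactly 10 nt and which
  inherit an adenine at position 10 (the 10A bias, the base-pairing partner
  of the 1U);
* 21-nt siRNAs, cut from double-stranded replication intermediates on both
  strands, are an independent marker of active infection.

This package implements the complete small-RNA analysis used to establish
that chain of evidence: EVE discovery in a host contig, strand-resolved
size and coverage profiles, the positional nucleotide biases, the 5'
overlap spectrum with its z-score, EVE-versus-virus read disambiguation,
and a generative simulator that produces all read populations with ground
truth, so that every statistic can be validated by parameter recovery.

## Statistics

**Overlap spectrum.** Let \(S(i)\) be the weighted count of + strand 5'
ends at reference position \(i\) and \(A(j)\) the weighted count of −
strand 5' ends (a − read's 5' base is the *rightmost* base of its
footprint in + coordinates; this convention is load-bearing and asserted
in the tests). The pair count at overlap distance \(d\) is

\[ c(d) = \sum_i S(i)\,A(i + d - 1), \qquad d = 1,\dots,D_{max} . \]

Probabilities are \(p(d) = c(d)/\sum_{d'} c(d')\) and z-scores are
computed against the mean and *population* SD of \(c(\cdot)\) over the
full background window \(d = 1..D_{max}\); the 10-nt bin belongs to its
own background, matching the convention of the standard small-RNA
signature tools. The ping-pong statistic is \(z(10)\). Because z-scores
are affine-invariant it is immaterial whether they are computed on counts
or probabilities (asserted by test). When the spectrum is constant — in
particular all-zero, i.e. no opposite-strand pairs at all — z is
undefined and reported as `NA`; in knockout *contrasts* an undefined z is
scored as 0 ("no signature"), since a library without a single
opposite-strand piRNA pair cannot display one. A useful closed form: a
spectrum with exactly one nonzero bin has \(z = \sqrt{D_{max}-1}\) at
that bin (5.385 for \(D_{max} = 30\)), which the tests check to machine
precision against an independent brute-force pair loop.

**Nucleotide profiles.** Logo matrices use the read sequences as
sequenced (5'→3', T reported as U), truncated at the 3' end to 20 nt, so
sequencing errors and EVE/virus divergence show through rather than being
flattened onto the reference. Information content is
\(I(p) = 2 + \sum_b f_b \log_2 f_b\) with \(0\log 0 = 0\) and no
small-sample correction. The 1U and 10A biases are read off positions 1
and 10 of this matrix.

**Percent identity.** Fragment identity is matches divided by aligned
columns over the reported intervals, with inter-HSP chaining gaps counted
as mismatch columns. After chaining, identity is *recomputed directly
from the two sequences* over the merged intervals, so the reported value
is exactly reproducible from the coordinates — an invariant the tests
enforce. The length-weighted mean over fragments gives the overall
EVE–virus identity.

**Prevalence.** The point estimate is \(100\,k/n\); the confidence
interval is the Wilson score interval (`prop.test` without continuity
correction). For 28 positives out of 31 this gives 90.3%
(75.1%–96.7%). Wilson was chosen for its behaviour at boundary counts
(0/n and n/n); Clopper–Pearson would be slightly wider.

## The aligner

Small references (≤ ~1 Mb) and short reads permit an exact contract
instead of a heuristic one. Reads are seeded with their first and last
k-mer (both orientations) against a hash index of the reference and every
candidate is verified by full-length comparison. By the pigeonhole
principle a single mismatch cannot corrupt both seeds when
\(k \le \lfloor \mathrm{readlen}/2 \rfloor\), so with the default
pipeline seed of **k = 9** every placement with at most one mismatch is
found for every read of ≥ 18 nt — the entire 19–33 nt library window.
(`build_index()` itself defaults to k = 12 for generic use; the pipeline
drivers pass k = 9.) The aligner returns only the best stratum: all
0-mismatch placements if any exist, otherwise all 1-mismatch placements.
Multi-mappers are reported in full and down-weighted by \(1/n_{best}\);
this is deterministic and seed-free, unlike single-random-hit reporting,
and every profile statistic uses these weights by default (a raw-count
mode exists for parity experiments). Ungapped alignment mirrors the
standard small-RNA mapping model; there is no indel handling. Tests prove
exhaustive-scan equivalence against an independent Biostrings
`matchPattern` oracle at both mismatch strata.

## EVE discovery

Exact 11-mer seeds between contig and both virus strands are extended
ungapped under an X-drop rule (match +1, mismatch −2, abandon when the
running score falls more than 20 below its maximum; the reported end is
the maximum-scoring column). Seeds inside an already-extended HSP on the
same diagonal are skipped; HSPs scoring below 30 are dropped — on a
~10.7 kb virus versus a ~20 kb contig the expected number of random
seed hits surviving that threshold is far below one. HSPs are chained
greedily in contig order when they share an orientation and diagonal and
both coordinate gaps are ≤ 50 nt. Extension may absorb a few
chance-matching flank columns beyond a planted boundary (the score stays
net positive for short matched runs); recovered boundaries are accurate
to a few nucleotides, and the acceptance suite requires ±11 nt (the seed
length). Ungapped extension is a deliberate choice: the integration
process modelled here produces substitution divergence, not indels, and
it keeps the identity definition exact and testable.

## The simulator

The generator's defaults are the study conditions the analysis is meant
to emulate, and they are not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `virus_length` | 10,700 nt | positive-strand RNA virus genome |
| `n_fragments` | 4 | EVE fragments copied from the virus |
| `flipped_fragments` | 2 of 4 (indices 2, 3) | fragments inserted antisense |
| `divergence` | 0.04 | per-site EVE–virus substitutions |
| `host_flank_length` | 5,000 nt | host sequence on each side |
| `n_sirna`, `n_primary`, `n_secondary` | 20,000 each | library sizes |
| `sirna_length` | 21 nt | siRNA length |
| `pirna_length_range` | 26–30 nt | piRNA lengths (uniform) |
| `u1_enforcement` | 0.9 | expected 1U fraction of primaries |
| `size_selection` | 19–33 nt | gel size window |
| `error_rate` | 0.001 | per-base sequencing substitutions |

Design decisions that matter:

* **U1 enforcement by start-position sampling.** With probability
  `u1_enforcement` a primary start is drawn uniformly among template
  positions whose first transcribed base is U, otherwise uniformly among
  non-U starts. The read is never mutated, so sequence–template
  consistency is never violated, and the parameter *is* the expected 1U
  fraction exactly.
* **Secondary piRNAs are sliced from the virus, primaries from the EVE.**
  This asymmetry is the biological model and is fixed, not configurable.
  A secondary's 5' end sits at \(i = j - 9\) where \(j\) is the virus
  coordinate of its partner primary's 5' end on the − strand: an exact
  10-nt 5' overlap by construction.
* **Secondary partners are U-initiated primaries.** PIWI loading strongly
  prefers 1U piRNAs, so ping-pong partners are drawn from the U-initiated
  subset of virus-antisense primaries. A consequence worth knowing: the
  secondary 10A fraction is then ≈ \(1 -\) divergence (≈ 0.96) regardless
  of `u1_enforcement`, because position 10 of the secondary is the virus
  base that paired with a U on the EVE template. Had partners been drawn
  from *all* primaries, the 10A fraction would be diluted by the non-U
  fraction (≈ 0.87 at the defaults).
* **Fragments are concatenated adjacently** (no host spacers), mirroring
  the adjacency of natural multi-fragment EVEs.
* **Qualities** are constant Phred 40; `degrade_quality` writes Phred-2
  3' tails for exercising the quality filter.

Reads spanning a fragment–fragment junction (a few percent) have no
single virus placement; their truth labels carry `NA` virus coordinates
and they never spawn secondaries. At one allowed mismatch such a read can
still align overhanging a planted boundary by a base or two — visible as
a sliver of coverage just outside a fragment.

What the simulator deliberately does **not** model: PCR/ligation bias,
indel sequencing errors, quality-dependent error rates, piRNA production
from the EVE's host flanks (reported for natural EVE loci, but its
magnitude is not quantified well enough to simulate honestly), and
transposon-rich genomic context. Passing recovery tests on these
synthetic libraries therefore demonstrates correctness of the statistics
and the pipeline plumbing, not robustness to every artefact of real
sequencing data.

## Preprocessing conventions

The trimmer looks for the adapter at the read's **3' end** (the small-RNA
3'-linker chemistry), allowing 10% mismatches over the overlap with a
minimum overlap of 3 nt, and truncates at the leftmost hit. Reads without
an adapter hit are discarded by default (`require_adapter = FALSE` for
pre-trimmed input). The quality rule is *mean* Phred strictly greater
than 20 over the trimmed insert — the aggregation is a declared choice,
configurable. Inserts outside 19–33 nt are discarded, mirroring the gel
size selection. Rejection reasons are reported per read with precedence
adapter → quality → size, and kept + discarded always equals input.

## Disambiguation

"Unambiguous" assignment of a read to EVE or virus is operationalised as
0-mismatch presence/absence against each reference: `virus_only`,
`eve_only`, `shared`, `unmapped` — exhaustive and mutually exclusive.
With this rule a sequencing error pushes a true read to `unmapped` rather
than into a wrong class, which is the conservative failure mode. The
per-fragment diagnostic-site density (EVE–virus differences per column)
is reported alongside so the classification power is visible: at 4%
divergence a 28-nt read has roughly a 2-in-3 chance of covering a
diagnostic site, so a substantial `shared` class is expected, not a
defect.

## Problem sizes and determinism

All randomness flows from a single integer seed; every generator
operation derives its RNG state from it, so a fixed configuration
reproduces byte-identical FASTA/FASTQ/TSV output (tested). The analysis
drivers use the default library sizes (20,000 reads per population, a
10.7 kb virus, 5 kb flanks); the knockout contrast uses twenty paired
simulations of 7,000 reads each, sizes chosen to give the recovery
statistics comfortable binomial margins. The test suite validates the
aligner against an exhaustive oracle at 10,000 reads on a 20 kb
reference and the overlap spectrum against a brute-force pair loop at
2,000 alignments.

## Worked example

```{r example}
library(evepirna)

cfg <- simulation_config(seed = 20260920L)
sim <- simulate_dataset(cfg)

# EVE structure from sequence alone
fragments <- discover_eve(sim$host_contig, sim$virus)
fragment_identity_report(fragments, sim$host_contig, sim$virus)$overall_identity

# ping-pong signature on the virus
va <- align_reads(sim$reads, sim$virus, max_mismatch = 1)
os <- overlap_spectrum(va)
attr(os, "ping_pong_z")

# 1U bias of the EVE-derived primary piRNAs
prim <- sim$reads[sim$labels$class == "primary_pirna", ]
ca <- align_reads(prim, sim$host_contig, max_mismatch = 1)
bias_fractions(nucleotide_profile(ca, prim, orientation = "sense",
                                  region = c(sim$eve_start, sim$eve_end)))
```

## Known limitations

* References are held in memory as plain strings; the design targets
  viral genomes and EVE loci, not chromosome-scale assemblies.
* No gapped alignment anywhere: an EVE with indel divergence would be
  recovered as split fragments rather than one gapped fragment.
* The shared read class is never probabilistically reassigned; no EM
  multi-mapping model is attempted.
* The ping-pong background window is fixed at \(d = 1..D_{max}\)
  (default 30); the choice is configurable but the default is the
  package's declared convention.
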