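---
title: "Methods: cleavage-site mapping, stall inference, and the forward simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cleavage-site mapping, stall inference, and the forward simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxcut)
```

## The model

A MazF-family toxin cleaves single-stranded RNA at a short sequence (and,
for tRNA-targeting members, structure) motif, leaving a 5'-hydroxyl end.
5'-OH-selected RNA-seq therefore sees two signals when such a toxin
attacks a tRNA:

1. **Primary cuts** inside the tRNA anticodon. A cut between anticodon
   bases 2 and 3 leaves the 5'-OH on anticodon base 3, which is mature
   position 36 — so every called tRNA site should report
   `gene_position = 36`.
2. **Secondary cuts** on mRNAs. Loss of the tRNA stalls ribosomes at its
   cognate codons; cellular RNases then cut the transcript on the 5' side
   of the stalled ribosome. The footprint geometry places the A-site codon
   at roughly the 15th nucleotide of the resulting 3' fragment, so aligned
   windows around these cuts show an AAA/AAG consensus near offset +15.

The proteomic consequence is codon-dependent: translation of genes rich in
the codon whose tRNA was destroyed (AAA, decoded only by the cleaved
tRNA-Lys-UUU when wobble is unavailable) drops in proportion to codon
count, while codon-poor genes keep translating.

## Pipeline stages and their parameters

**Trimming** (`trim_params`): adapter constant region (default the 26-nt
5' adapter `GTTCAGAGTTCTACAGTCCGACGATC`), `umi_len = 6`, trim to
`final_len = 20`, drop shorter inserts. Adapter recognition is an exact
match of the adapter's 3'-most 12 nt, which tolerates a 5'-truncated
adapter but no sequencing errors; reads without a match are dropped
because the UMI boundary cannot be located. These are deliberate,
oracle-checkable choices — the trimming operations, not any particular
trimming tool, are the specified computation.

**Mapping** (`build_index`, `map_and_count`): exact 20-mer matching on
both strands, the zero-mismatch seed policy of classical short-read
mappers. Reads matching no locus or more than one locus are discarded and
tallied; we prefer losing multi-mappers to assigning them arbitrarily,
because downstream thresholds act on per-position counts and must be
deterministic. The 5' position of a reverse-strand match is the *highest*
genome coordinate of the matched interval — the biological 5'-OH end. The
mapper is verified in the test suite against a naive all-offsets string
comparison on random genomes.

**Normalisation and fold change** (`fold_change_track`): counts are
scaled to reads per million mapped (rpm). Uninduced positions with a raw
count of 0 receive a pseudocount of 1 *before* normalisation (rpm-space
pseudocounts would give different folds), which floors the uninduced rpm
at `10^6 / total_uninduced` and caps attainable fold changes — a useful
property, since background-only positions can then never exceed a
10-fold threshold at realistic depths. Positions with induced count 0 get
fold change 0; the behaviour when the induced count is 0 but the
uninduced is positive is not otherwise constrained, and 0 (never called)
is the conservative completion.

**Calling** (`call_sites`): intragenic positions (`[start, end]`, the
feature's strand) with induced rpm ≥ 50 (tRNA) or ≥ 5 (mRNA) — inclusive,
"at least" — and fold change strictly > 10. Sites at a feature's first
base are kept; no interior-margin rule is imposed. Mature tRNA position is
the position within the annotated gene (the synthetic tRNAs are intronless
and carry no modelled CCA).

**Stall inference** (`detect_stalls`): mRNA sites whose sense-strand cut
context matches the toxin's own (U/C)U|U pattern are excluded as possible
direct toxin cuts; sequence context is the computable proxy for "similar
to the tRNA target" (the structural component of toxin recognition is not
computable from sequence alone, and sites too close to the gene 5' end to
check are retained with a flag). Windows are 50 nt of sense strand with
the 5'-OH base at index 26; the Lys codon is sought at fragment offsets
15, 14, 16, 13, 17 — ordered by distance from the canonical +15, first
match wins. The window is wider than the strictest reading of "at or near
+15" so that the *measured* modal offset can follow the true footprint
geometry rather than being clamped by the search; with the default
geometry the extra offsets are almost never used. The logo is a plain
positional frequency matrix: frequency is what the display encodes, and
enrichment statistics are out of scope. `stall_summary` counts each
transcript once (its highest-rpm site) because the proportion of interest
is over transcripts, not sites.

**Proteome** (`differential_translation`): proteins with < 15 total
spectral counts are dropped. Replicate libraries are scaled to the median
library size; log2FC = log2((Σ induced + 0.5) / (Σ uninduced + 0.5)) on
normalised sums (0.5 keeps ratios finite). The p-value is an exact
conditional binomial test of the protein's raw induced count against the
induced share of total library size, with Benjamini–Hochberg q-values and
significance at q ≤ 0.05. The upstream study's exact statistic (a
previously described analysis with local-fdr q-values) is not
reproducible from its description; the binomial-plus-BH substitution is
isolated behind this one function and keeps the same count filter and the
same significance rule. Note that depth normalisation identifies
*relative* abundance: when many proteins are genuinely suppressed, all
log2FCs shift up by a common composition offset, so effects should be
read as differences between codon classes, not absolute values.

## The forward simulator

`sim_config()` defaults define the simulated study conditions:

* **Reference**: one GC-rich contig (~36 kb), 47 tRNA genes of 76 nt — 46
  standard anticodons plus selenocysteine, with exactly two lysine
  isoacceptors (anticodons TTT and CTT at mature positions 34–36) — and 40
  CDSs of 200 codons on alternating strands. AAA and AAG codon counts per
  gene span 0–30 as independent permutations, so the two are uncorrelated
  by construction (this is what lets the analysis show AAA-specific and
  not AAG-specific suppression). CDS filler codons are drawn over
  {C,G,T} only, so every AAA/AAG trimer in a CDS is a deliberately
  planted lysine codon and ground truth is unambiguous; planted codons
  occupy alternating codon slots ≥ 9, keeping stall cuts strictly inside
  the CDS at every tested footprint offset.
* **Reads**: 20 000 background reads per condition (uniform 5' starts on
  feature sense strands, 10% intergenic on both strands) emulate ordinary
  5'-OH turnover; the in-vivo background abundance is not documented
  anywhere usable, so this is a package choice that leaves ~0.6 background
  reads per transcribed position — enough to exercise the pseudocount rule
  without letting background ever pass a 10-fold threshold. Induced
  libraries add Poisson(100) reads at each planted anticodon cut and
  Poisson(40) at each *chosen* stall site. A Lys codon's site is chosen
  with probability proportional to its class weight (default AAA:AAG =
  3:1, scaled so the larger is 1); read depth per chosen site is
  class-independent, so detection is class-symmetric and the expected AAA
  fraction of stalled transcripts is `wA·nA / (wA·nA + wG·nG)` — 0.75 at
  equal codon counts, the regime the analysis is meant to probe. Each read
  is adapter + 6-nt UMI + genomic sense sequence from the cut, post-adapter
  length uniform on 25–45 nt so the trim-to-20 rule always bites and a
  predictable fraction (length 25) is dropped short.
* **Proteome**: per-gene means log-uniform on 5–500 spectral counts;
  induced means are multiplied by `2^(aaa_effect · AAA_count)` with
  `aaa_effect = -0.2`, three replicates per condition, Poisson sampling.

All randomness derives from the single config seed (distinct fixed
offsets per output), so identical configs give byte-identical FASTQ and
TSV files.

**What the simulator does not emulate**: sequencing errors and quality
variation (qualities are constant, adapter matches exact), RNA secondary
structure and modification effects on library chemistry, rRNA/ncRNA
background classes, transcript boundaries (reads run into downstream
genomic sequence past a gene end), operonic structure, and replicate
variability beyond Poisson. Passing recovery tests therefore demonstrates
correctness of the computational rules under clean signal, not robustness
to those real-data artefacts.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere (the GFF and
  Bioconductor convention), including track TSVs; no internal conversion
  boundary exists.
* Ties in `classify_stall` resolve by the fixed search order
  (15, 14, 16, 13, 17); ties for a transcript's best stall site resolve to
  the first in position order; an all-tie rank-sum comparison reports
  p = 1.
* Contigs shorter than k warn and contribute nothing to the index;
  windows crossing a contig edge are dropped and tallied; zero-window
  logos, zero-mapped-read normalisation, all-zero count tables and
  single-replicate designs are errors, not silent results.
* Problem sizes throughout the tests (3–8 kb genomes for unit tests, the
  ~36 kb default simulation for recovery tests, 600 genes for the
  stall-proportion check) were chosen so the full suite runs in well under
  a minute while keeping every binomial check adequately powered.

## Known limitations

Exact-match mapping discards any read overlapping a genuine repeat;
fine for the synthetic reference, lossy on real genomes. The toxin-like
filter is sequence-only and will not exclude a structural toxin target
with a different cut context. The differential-translation statistic
treats summed counts as binomial draws, ignoring overdispersion between
replicates — adequate for Poisson-simulated counts, anticonservative for
noisy real spectral counts. The stall summary attributes one codon class
per transcript, which blurs mixed-class transcripts when several of their
sites are detected at comparable depth.
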