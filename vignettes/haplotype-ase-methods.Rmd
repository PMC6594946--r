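---
title: "Methods: haplotype-resolved allele-specific analysis at a rearranged locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-resolved allele-specific analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapase)
```

# The analysis in one paragraph

An enhancer-hijacking translocation inserts a multi-copy oncogene cassette
next to a strong enhancer on one of the two homologous alleles of a locus.
`hapase` resolves which allele, and what the regulatory consequences are,
by (i) phasing the locus's heterozygous SNPs from linked-read barcodes,
(ii) assigning reads of every assay — RNA, chromatin tags, bisulfite,
chromosome-conformation pairs — to a haplotype through those SNPs, and
(iii) quantifying enhancer-anchored chromatin contacts with explicit
handling of the multi-mapping caused by the cassette's near-identical
paralog family. Every component is exercised end to end on a synthetic
two-haplotype locus whose ground truth is known, which is how the package
tests itself.

# The synthetic locus

`build_genome()` constructs a deterministic diploid model. The default
geometry is a 10x scaled-down replica of the situation at an
IGH-DUX4-like locus, chosen once so that the whole pipeline runs in
seconds while preserving the *ratios* the analysis reasons about:

| feature | default | full-size counterpart |
|---|---|---|
| locus contig `chrL` | 30 kb | ~300 kb region |
| enhancer–promoter distance | 13.8 kb | ~140 kb |
| enhancer–cassette distance | 0.4 kb | ~4 kb |
| retained upstream (V-region-like) block | 12 kb | ~126 kb |
| cassette | 2 × 1.2 kb copies + 80 bp spacer | 2 × ~4.7 kb copies |
| het SNPs | 3 (wt A-A-A, rearranged T-G-G) | 3 |
| CpG island | 9 CpGs within ±45 bp of SNP 2 | 9 CpGs |

The wild-type haplotype (`hap_wt`) equals the reference plus its SNP
alleles; the rearranged haplotype (`hap_rearr`) additionally carries the
cassette insertion (and optionally a deletion). The global haplotype-label
flip is resolved by convention: `hap_wt` is the haplotype without the
cassette. A donor contig `chrD` carries the paralog family — the canonical
copy (the cassette's true source), a 4-substitution neighbour and a
12-substitution neighbour over 1 200 bp — so that each non-canonical copy
differs by at least one substitution and attribution is decidable. The CpG
island is written from a C-free filler alphabet with CpGs planted at fixed
offsets; this guarantees an exact CpG count and keeps the island's G/A SNP
from ever creating or destroying a CpG, at the cost of an unrealistic
local base composition (the methylation arithmetic is unaffected).

## What the simulators emulate — and what they do not

* `simulate_linked_reads()`: molecules drawn uniformly from the two
  haplotypes, all reads of a molecule sharing a barcode, SNP alleles
  faithful to the haplotype. Reads are reported in reference coordinates;
  cassette-internal reads are placed on the donor contig, as a real
  aligner would place them.
* `simulate_tag_reads()`: per-SNP read depth with wild-type probability
  `r/(1+r)` for allelic ratio `r`; stranded RNA reads carry a
  transcription-strand label.
* `simulate_bisulfite()`: original-top/original-bottom strands at 50:50;
  unmethylated cytosines convert with probability `conversion_rate`
  (default 0.993, a typical mitochondria-calibrated value); methylated
  island CpGs are protected; per-read methylation states are drawn from
  the per-haplotype truth.
* `simulate_contacts()`: background pairs with power-law distance decay
  (`d^-alpha`, default `alpha = 1`, sampled on [1 kb, L/2]); anchor-pair
  interactions added with Poisson counts around configured expectations;
  cassette-internal ends scattered uniformly across the paralog copies
  that are indistinguishable over the read span — the multi-mapping
  ambiguity that `multimapping_rescue()` exists to undo.

Not modelled: sequencing-quality profiles, PCR duplicates, indels,
restriction-fragment structure (contact ends are points, not fragments),
chimeric molecules, and barcode collisions. Passing tests therefore
demonstrate the *logic* of the analysis — allele assignment, filtering,
counting, rescue, the statistics — not robustness to every artefact of
real libraries.

# Phasing by greedy minimum error correction

The barcode-allele matrix reduces each (barcode, SNP) pair to `a`, `b`,
`conflict` or missing; the default purity of 1 makes any mixture a
conflict, and conflicts are dropped from scoring rather than
half-weighted — strictness is easier to reason about and to test.
Phasing is greedy MEC: the highest-coverage SNP seeds a phase set, and
each remaining SNP joins, in descending order of barcode-sharing weight,
in the orientation minimising contradicted entries. Ties in seeding and
extension break by coverage, then leftmost coordinate, so the algorithm
is deterministic without a seed. Disconnected SNPs start new phase sets;
an all-missing matrix yields singleton sets of quality 0. The per-SNP
quality is the supporting-minus-contradicting barcode margin against the
final phasing. The test suite compares the greedy result against an
exhaustive enumeration of all `2^(n-1)` phasings on small instances: the
greedy MEC can never be below the optimum, and equals it on noise-free
connected instances, where the switch error against truth is 0.

# Allele-specific statistics

The imbalance test is the exact one-tailed binomial tail
`p = P(X >= n_wt | n = n_wt + n_rearr, p = 0.5)`, computed by direct
summation of `dbinom` terms (no normal approximation); the direction is
fixed a priori toward the wild-type haplotype, with a two-tailed option
off by default. Stars follow 0.05/0.01/0.001. Fold with a zero
denominator is reported as `Inf`, never as a large float. No
multiple-testing correction is applied across SNPs and assays by default
(per-SNP stars are the convention here); a Bonferroni toggle exists.
Duplicate-flagged reads are excluded for tag assays and retained for long
reads; the default minimum base quality is 20 when qualities are present.

Bisulfite reads pass a conversion-strand informativeness filter before
haplotype assignment: C→T conversion on original-top reads collapses C/T
SNPs, G→A (in top-strand coordinates) on original-bottom reads collapses
G/A SNPs; only readable orientations are used, and the filter's counts
are conserved and reported. With conversion rate `c < 1` and truth `m`,
the expected estimate is `m + (1-m)(1-c)` — about +0.6% at `c = 0.993`
and `m = 0.1` — which the tests verify against simulation rather than
correct for.

# Contact quantification

Anchor-pair counting uses ≥1 bp overlap of read footprints with the two
anchors, requires the two ends to fall in *distinct* anchors (overlapping
anchors are an error, not a silent choice), is symmetric under end swap
(pairs are stored in canonical lexicographic order), and supports a union
over a set of anchors for the multi-copy array. Capture peak coverage is
the maximum per-base depth in a target window after removing other-ends
within ±500 bp of the viewpoint. Rescue realigns every family-mapped read
to the canonical region with a gap-free best-hit scan bounded at 2
mismatches (leftmost best hit on ties); rescued coverage can only grow.
Interaction folds report the float and the half-away-from-zero rounded
integer. Adjacency calls compare observed region-pair counts with a
distance-banded intra-contig expectation or a flat inter-contig constant,
at a default enrichment threshold of 5 and gated on copy-number
consistency.

In the end-to-end pipeline, the Hi-C/HiChIP interaction folds are
computed after subtracting a matched background-only simulation run at
the same seed. This is a property of the scaled-down locus: at 0.4 kb the
enhancer-cassette pair sits deep inside the distance-decay background,
proportionally much deeper than its full-size counterpart at ~4 kb, and
the uncorrected ratio would measure the background geometry rather than
the configured interaction strengths. Capture peak coverages are reported
raw.

# Expression

Multi-copy genes are quantified against a single representative locus:
the family copy matching the assembled cassette with fewest mismatches
(margin reported), with reads counted if they align within the mismatch
bound regardless of their placements elsewhere. FPKM is
`count × 10⁹ / (length × library size)`. Cohort summaries use the exact
paired *t* distribution one-tailed, Pearson's *r* with its *t*-transform
p-value, and a *t*-quantile confidence interval on the per-sample ratio;
identical input vectors give the null p of 0.5 and an undefined,
flagged *r*. The pipeline's cohort stage draws a correlated bivariate
lognormal (log-medians 145.4 and 661.9, spread 0.8, log-correlation
0.554), whose implied mean expression ratio of ~29% sits inside the
uncertainty of the cohort it emulates.

# Numerical and design choices

* Coordinates are 0-based half-open internally; VCF output is 1-based,
  BED/BEDPE/bedGraph 0-based. Barcodes travel as SAM-style `BX` values
  and are appended to FASTQ headers for round-tripping.
* The stand-in assembler is exact-k-overlap unitig construction
  (default `k = 31`), valid for the error-free regime only; it never
  joins across a branch point, so it forks at heterozygous sites and
  stops `k - 1` bases into a repeat. Real data should use a production
  assembler; the module's contract is recruitment, attribution and
  scaffolding.
* Attribution alignment is end-gap-free with unit mismatch cost and no
  gaps by default (family copies are equal-length in the model); a gapped
  mode is intentionally out of scope of the default path.
* Scaffold parts must abut exactly; gaps or overlaps without an explicit
  spacer part are an error, mirroring the manual-patch workflow where a
  reference segment bridges an unassemblable tandem repeat.
* Reads spanning an anchor boundary count by ≥1 bp overlap of their
  footprint; contact ends are points extended by the read length. The
  original analyses do not state a rule; this one is deterministic.
* Every simulator takes an explicit integer seed; the pipeline derives
  per-stage seeds from a single global seed, and identical configuration
  plus seed reproduces byte-identical outputs.

# Problem sizes

The shipped tests and the acceptance script run, per invocation: a 30 kb
diploid locus; 600–2 000 linked-read molecules; 200–2 000 tag reads per
SNP; 200 bisulfite reads over the CpG window (~50 informative reads per
haplotype per CpG); 20 000–100 000 contact pairs per assay; 100–2 000
seeded replicates for the statistical recovery suites. These sizes were
chosen as the smallest at which the binomial and Poisson sampling bounds
the tests assert are comfortably identifiable.

# Known limitations

* The greedy MEC phaser is exact only in the regimes the tests cover
  (small SNP panels, connected barcode graphs); it does not implement
  population or read-backed statistical phasing.
* The unitig assembler collapses perfect repeats longer than `k`; the
  two-copy cassette is therefore assembled as unitigs that stop at the
  repeat entry, and the scaffold step is how a full haplotype is put
  together.
* Contact simulation uses point ends and a single decay exponent; no
  fragment model, no matrix balancing, no TAD or loop calling.
* The methylation module reports per-site ratios only; differential
  statistics beyond the ratios are out of scope.
* Real-data I/O is intentionally minimal (plain SAM/VCF/BED/BEDPE text
  writers and readers for the package's own files); BAM ingestion should
  go through dedicated importers upstream of this package.
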