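---
title: "Counting mutant reads: the rafamp model and its assumptions"
author: "rafamp maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting mutant reads: the rafamp model and its assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rafamp)
```

## The measurement model

rafamp analyzes barcoded amplicon deep sequencing of B-RAF exons 11 and 15
in mixed cell populations, the setting of Langerhans cell histiocytosis
(LCH) granulomas where a mutant clone (CD1a+ dendritic cells) is diluted by
wild-type infiltrate. The core statistic is the **relative mutation
abundance** (RMA): the proportion of sequence reads at a locus that contain
the mutation,

$$\widehat{\mathrm{RMA}} = \frac{k}{n},$$

where $n$ is the read depth over the position and $k$ the number of reads
whose *event list* contains exactly the variant of interest. Membership is
event-based rather than per-base so that a sequencing error adjacent to a
hotspot never inflates the hotspot's count, and so that a 12-nt insertion
and a point substitution are counted on the same footing.

Uncertainty on the RMA uses the Wilson score interval
(`wilsonCI()`), which is well behaved at the small proportions this assay
cares about (an observed 5/500 gives roughly 0.4–2.3%).

## Detection as an exact binomial test

A variant is *detected* when its supporting count $k$ reaches the smallest
threshold $c$ satisfying

$$P\left[\,\mathrm{Bin}(n, e) \ge c\,\right] \le \alpha / m,$$

computed by exact tail enumeration (`detectionThreshold()`); no normal
approximation is used, because at $n e \approx 1\text{–}2$ the normal tail
is badly wrong. Here $e$ is the per-base background error probability
(default 0.002), $\alpha$ the per-site tail bound (default 0.001), and $m$
the Bonferroni factor — 1 in targeted mode (three exon-15 hotspots
interrogated individually) and the number of interrogated positions in
discovery mode. Calls also require a minimum depth (default 500×, the
assay's nominal coverage); hotspot evidence below that depth is reported
with a `lowDepth` flag rather than silently dropped, since some clinical
samples fall short of 500×.

The **limit of detection** (`estimateLOD()`) is the smallest true mutant
fraction $f$ (searched on a grid of $10^{-4}$) whose detection probability
$P[\mathrm{Bin}(n, f) \ge c]$ reaches the sensitivity goal (default 95%).
With all defaults the LOD at 1000× is 1.44%, inside the assay's stated
1–2% operating window, and it is non-increasing in depth. These defaults
were fixed once, as the package's operating point, together with the
simulator's error rates below.

## What the simulator emulates — and what it does not

`simulateSample()` emulates single-end pyrosequencing-style amplicon reads:
each read is `barcode (10 bp) + universal forward tag + insert + universal
reverse tag`, the insert being the reference amplicon or the
variant-spliced allele, drawn mutant independently with the sample's true
fraction. The error model has two components chosen to mirror flow-based
chemistry:

* per-base substitutions at `subRate` (default 0.002), uniformly to the
  three other bases;
* homopolymer length errors: each run of length $L \ge 2$ gains or loses
  one base with probability `homopolymerIndelRate` $\times (L-1)$
  (default 0.001), the characteristic pyrosequencing failure mode.

Reproducibility is per sample: each sample's stream is seeded from the
master seed and the sample identifier, so per-sample output is independent
of simulation order and identical seeds give byte-identical FASTQ output.

The simulator deliberately does **not** model flowgram intensities,
quality-value spectra (qualities are emitted as a constant Q40 symbol and
the caller is count-based), chimeric PCR products, strand effects, or
read-length attrition. Passing tests therefore demonstrate correctness of
the counting, alignment and decision machinery under a realistic error
*rate*, not robustness to every 454 artifact; true GS FLX error rates for
these amplicons were never published, so the defaults are calibrated, not
measured.

## Demultiplexing and trimming

Barcodes are matched anchored at the read start (the two-round PCR
construct guarantees this layout) within one mismatch by default. A read
tied between two barcodes is rejected rather than arbitrarily assigned —
with RMAs down to 1%, even rare cross-sample bleed would be visible. The
bundled 24-barcode panel keeps pairwise Hamming distance ≥ 3, which the
sample-sheet loader enforces (downgradeable to a warning for external
sheets). Trimming removes barcode + forward tag by length, and the reverse
tag by suffix match within one mismatch, flagging reads that end before it.

## Alignment and event extraction

Reads are aligned to their known amplicon (each sample's amplicon comes
from the sample sheet, so there is no multi-reference search) with a
semi-global affine-gap aligner written for this package: the read aligns
end-to-end, reference ends are free, and a gap of length $L$ costs
`gapOpen` $+ (L-1)\,$`gapExtend` (defaults +2/−3/−6/−1). The gap-open
penalty is high enough that the 12-nt insertion allele is recovered as a
single `I` run rather than a scatter of mismatches, which is what makes
insertion RMA well defined. CIGAR strings use `M` for match-or-mismatch;
mismatches are recovered by sequence comparison. Reads scoring below 0.6 ×
the perfect score are flagged unaligned and excluded from pileups — a
default guard for the RMA denominator, not a published value.

Two normalization conventions matter:

* **Indels are left-normalized.** The bundled 600DLAT insertion
  (GATCTAGCTACA after c.1797) is quasi-duplicative, so its 5′-most
  equivalent placement is anchor c.1787 with sequence TCTAGCTACAGA. All
  event comparison, tallying and hotspot matching happens on normalized
  events; in targeted mode an insertion is matched to a hotspot if the
  hotspot lies in the event's equivalent-placement interval.
* **Ties break toward the smallest reference coordinate**, making
  alignment output deterministic.

The aligner is verified against two independent oracles: exhaustive
enumeration of every alignment path on small instances, and a separately
written quadratic dynamic program on random instances up to length 200.

## Protein consequences

Substitutions annotate by direct codon arithmetic (c.1799 is offset 2 of
codon 600, etc.). In-frame insertions annotate by splicing the event into
the reference, translating both in frame, and diffing the proteins by
maximal common prefix: this names the 12-nt allele **600DLAT** — inserted
Asp occupying position 600, local motif TDLATV, i.e. effectively a V600D
with a trailing LATV — from *either* the 3′ anchored or the left-normalized
nucleotide representation. When an inserted peptide's first residue equals
the downstream reference residue the label rotates toward the C-terminus,
which is the convention that matches the published allele name. Frameshift
interpretation is out of scope and raises an error. The exact genomic
breakpoint of the insertion is not recoverable from published text; the
bundled allele places it between c.1797 and c.1798 with codons GAT CTA GCT
ACA, documented as a convention about the fixture, not a claim about the
patient chromosome. Similarly, the c.1795 A>G event is annotated purely as
a base change; the package never classifies transitions versus
transversions.

The reference fixture is a 90-nt CDS segment spanning codons 582–611 of
the B-RAF coding sequence, verified so that codon 599 = ACA, codon 600 =
GTG, and the two printed consequences (1795A>G → T599A, 1799T>A → V600E)
round-trip through translation. A second, abridged exon-11 P-loop segment
ships for pipeline completeness; no numeric result depends on its exact
codons.

## Compartment classification and cohort statistics

A variant profile across compartments classifies as:

* **germline** — detected in ≥ 1 blood compartment with its RMA interval
  overlapping the heterozygous band (default 0.35–0.65, chosen so the
  published 37–45% blood values count as "close to 50%"; configurable);
* **somatic** — detected in a lesional compartment while *every* assayed
  blood compartment is negative;
* **undetermined** — otherwise, in particular when no blood was assayed.
  The classifier deliberately stops at compartment level; heterozygosity
  of single cells is not assessed.

CD1a+ enrichment uses a two-sided Fisher exact test on supporting counts
(CD1a+ vs effluent), requiring a higher CD1a+ RMA and p < 0.05. Cohort
association tests are the Fisher exact test (mutation × multisystem
disease; the multisystem flag is derived from clinical-features text
mentioning hematological dysfunction) and the tie-corrected Kruskal–Wallis
test on age at diagnosis. Both are delegated to R's exact implementations
and cross-checked in the test suite against a full hypergeometric
enumeration (all 2×2 tables with total ≤ 30) and a 10⁴-permutation null.
The two-sided Fisher p is the point-probability sum, documented because
mid-p and doubling conventions differ. On the bundled cohort tables both
p-values exceed 0.05 (Fisher p = 1; Kruskal–Wallis H ≈ 0.54, p ≈ 0.46),
and with n = 16 these tests are descriptive, not powered.

The bundled compartment table records printed percentages, not read
counts; profiles built from it assume 1000× per compartment when an
interval is needed. Verdicts are insensitive to that choice across
500–5000×.

## Structure module

`residueEnvironment()` finds all residues with any heavy atom within 6 Å
(default) of any heavy atom of a focal residue — the minimum-atom-distance
criterion is the closest match to "residues surrounding", and hydrogens are
excluded since X-ray depositions rarely carry them. `contactReport()`
states whether the focal residue sits in a hydrophobic cluster (standard
aliphatic/aromatic set; Gly and Cys excluded by default), whether a
proposed mutant residue is carboxylate-charged and hence
cluster-disrupting (the codon-600 Glu/Asp pattern destabilizing the
inactive kinase conformation), and which polar contacts a
polar-to-hydrophobic mutation loses (the T599A pattern, losing Asp576 and
Asp594). Homology-model *generation* is out of scope: the module analyzes
any supplied coordinates, and the bundled file is a synthetic toy geometry
constructed for tests, clearly labelled as such. Verdicts depend only on
residue identities and the neighbor graph, verified by random rigid-body
motions at 10⁻⁶ Å tolerance.

## Numerical choices and problem sizes

* Exact binomial tails via `pbinom`; LOD grid 10⁻⁴; Wilson intervals at
  z = 1.96.
* Alignment on deduplicated inserts (error-free amplicon reads are heavily
  duplicated), which keeps the 16-sample, 1000× cohort under ~15 s on one
  core.
* Test and verification sizes, chosen as the package's own study sizes:
  the full cohort at 1000×, single-sample recoveries at 2000×, the
  law-of-large-numbers check at 10⁵ draws, null (type-I) batches of 25–60
  samples at 600×, and oracle batches of 30–100 random instances.
* Seeds: every stochastic step takes an explicit seed; per-sample streams
  derive from (seed, sample id).

## Known limitations

Single-orientation single-end reads only; no quality-aware calling; no
strand-bias or PCR-duplicate handling; deletion events are tallied and
reported in discovery mode but never interpreted at the protein level; the
classifier requires blood data to call germline, so lesion-only patients
remain undetermined by design; and the simulator's error rates are
calibrated to the assay's published operating point rather than measured
from raw flowgrams.
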