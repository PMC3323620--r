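# rafamp

Detection and quantification of B-RAF hotspot mutations from barcoded
amplicon deep sequencing of mixed cell populations.

## The problem

Langerhans cell histiocytosis (LCH) granulomas contain a minority
population of CD1a+ dendritic cells that may carry an activating B-RAF
mutation — classically the codon-600 Val→Glu substitution (c.1799 T>A,
V600E), but also rarer alleles such as a 12-nt in-frame insertion
(600DLAT) and a germ-line codon-599 variant (c.1795 A>G, T599A). Because
the mutant clone is diluted by wild-type infiltrate, bulk Sanger
sequencing misses it; deep amplicon sequencing of B-RAF exons 11 and 15 at
≥500× can quantify mutant clones down to a 1–2% **relative mutation
abundance** (RMA),

RMA = k / n,

the proportion of the *n* reads covering a locus whose extracted event
list contains the mutation (*k* of them). rafamp implements the full
analysis for this assay, for anyone who needs rare-variant quantification
from barcoded single-end amplicon reads:

* **simulate** — seeded pyrosequencing-style read simulation (barcode +
  universal tags + allele insert) with per-base substitution and
  homopolymer length errors;
* **demux** — anchored 10-bp barcode demultiplexing with mismatch
  tolerance and tie rejection, plus tag trimming;
* **align** — semi-global affine-gap alignment (Rcpp) that recovers the
  12-nt insertion as a single left-normalized event;
* **call** — count-based calling: RMA, Wilson intervals, exact-binomial
  detection thresholds P[Bin(n, e) ≥ c] ≤ α, and limits of detection at a
  stated sensitivity;
* **annotate** — codon-level consequences (V600E, T599A, 600DLAT with
  inserted peptide DLAT and local motif TDLATV);
* **cohort** — somatic-vs-germline classification across
  granuloma/CD1a+/effluent/blood compartments, CD1a+ enrichment tests,
  Fisher exact and Kruskal–Wallis cohort statistics, with the study's
  clinical and compartment tables bundled as fixtures;
* **structure** — residue-environment analysis of activation-segment
  mutants at a 6 Å heavy-atom cutoff (hydrophobic-cluster membership,
  charge disruption).

## Worked example

Simulate the 16-patient granuloma cohort at its published per-patient
mutant fractions (1000×, default error model), run the pipeline, and
summarize:

```r
library(rafamp)
amps  <- brafAmplicons()
cfg   <- simConfig(seed = 42)
specs <- granulomaSampleSpecs(depth = 1000)
run   <- simulateRun(specs, amps, errorModel(), cfg)
res   <- runPipeline(run$reads, sampleSheet(run$sheet), amps, cfg)
detectedCalls(res)[, c("sample", "cdsPos", "kind", "rma", "label")]
```

```
    sample cdsPos         kind        rma   label
  patient1   1799 substitution 0.12900000   V600E
  patient2   1799 substitution 0.28128128   V600E
  ...
 patient10   1787    insertion 0.10200000 600DLAT
 patient16   1795 substitution 0.45000000   T599A
```

Eleven of sixteen samples carry a detected variant; the recovered RMAs
track the simulated fractions (patient 1: 12.9% recovered at a true 13.5%;
patient 16: 45.0% at a true 44%). Note the 600DLAT call is anchored at
c.1787 — the left-normalized placement of the quasi-duplicative 12-nt
insertion — and still annotates to 600DLAT. The cohort summary:

```r
summarizeCohort()
```

```
Cohort: 11 of 16 patients carry a detected mutation
Alleles:
   600DLAT : 1
   T599A : 1
   V600E : 9
Verdicts:
  patient 1 : somatic
  ...
  patient 16 : germline
Fisher exact, mutation x multisystem: p = 1
Kruskal-Wallis, age at diagnosis: H = 0.542, p = 0.462
```

Patient 16's allele is germline (blood RMAs near 50%), patients with
wild-type blood are somatic, and neither disease extent nor age at
diagnosis associates with mutation status (both p > 0.05). The detection
limit at 1000× with defaults:

```r
estimateLOD(1000)
#> [1] 0.0144
```

i.e. 1.44%, inside the assay's 1–2% operating window. The structural
rationale for why codon-600 charge substitutions activate the kinase:

```r
env <- residueEnvironment(parsePDB(toyKinasePDB()), "A", 600)
contactReport(env, "GLU")
#> VAL600 -> GLU:
#>   hydrophobic cluster: TRUE
#>   cluster-disrupting (negative charge): TRUE
```

A thin command-line front-end over the same functions ships at
`inst/scripts/rafamp-pipeline.R` (subcommands `simulate`, `call`,
`cohort`, `structure`).

## Package layout

* `R/`, `src/` — implementation (S4 classes for amplicons, variants,
  consequences, pileups and compartment profiles; Rcpp aligner)
* `inst/extdata/` — reference amplicon FASTA, cohort tables (TSV), and a
  synthetic toy kinase PDB for the structure module
* `tests/testthat/` — unit, property and end-to-end tests, including
  independent brute-force oracles for the aligner and the exact tests
* `vignettes/rafamp-methods.Rmd` — the model, its assumptions, parameter
  defaults and limitations
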