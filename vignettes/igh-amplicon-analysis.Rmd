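---
title: "Calling intraorganismal haplotypes from deep amplicon sequencing"
author: "ighap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling intraorganismal haplotypes from deep amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ighap)
```

## The problem

Intraorganismal genetic heterogeneity (IGH) -- somatic mosaicism -- means a
single plant or animal carries more than one genotype across its cells. Deep
amplicon sequencing of one locus from bulk tissue can expose this: after
strict quality control, each distinct insert sequence above an abundance
threshold is treated as a *haplotype*, i.e. the genotype of some subset of
cells. `ighap` implements that entire analysis chain, plus a mosaic-population
read simulator so every stage can be validated against a known truth.

The chain is:

1. **Read QC** (`qualityTrim`, `matchPrimers`): 3'-anchored trimming of
   bases below Q20, then exact, end-anchored matching of both primers (with
   orientation rescue); anything less than a perfect primer match is
   discarded.
2. **Dereplication** (`dereplicate`): exact-string grouping into unique
   sequences with counts, ranks and proportions.
3. **Chimera removal** (`removeChimeras`): a de novo two-parent breakpoint
   test in the uchime tradition.
4. **Haplotype calling** (`callTissueHaplotypes`,
   `callSingleCellHaplotypes`): proportion > 1% for tissue libraries; top-10
   plus validity rules for single-cell libraries.
5. **Alignment and grouping** (`alignHaplotypes`, `njTree`):
   reference-anchored star alignment and neighbor-joining over p-distances.
6. **SNP statistics** (`callSnpSites`, `partitionByRegion`, `tstvSummary`,
   `snpDensity`): per-column site calling, transition/transversion
   classification, exon/intron partition, per-kilobase densities.
7. **Codon impact** (`spliceExons`, `translateCDS`, `codonEffect`,
   `collapseLevels`): synonymous versus nonsynonymous effects and the
   collapse of haplotype counts from genomic DNA to spliced exons to
   protein.

`runPipeline()` orchestrates all stages from a YAML config and writes a
machine-readable summary; `inst/scripts/ighap` exposes the same steps as a
command line.

## Haplotype calling rules and their parameters

**Proportion threshold (`minProp`, default 0.01).** A unique sequence is a
tissue haplotype iff its proportion of retained reads is *strictly* greater
than 1%. The strict inequality matters at the boundary: a proportion of
exactly 0.0100 is excluded, while 0.0182 counts as "over 1%". Proportions
are rounded half-up to four decimals (`roundHalfUp`) before comparison, so
printed values such as `Top1_52745_66819_0.7894` are reproduced digit for
digit; base R's round-half-even would print 0.78935 differently than the
field's conventional encoding.

**Single-cell rules (`topN`, default 10).** A single cell carries one
genotype, so minor variants are expected to be amplification or sequencing
artifacts. The top 10 unique sequences are kept for inspection; an entry is
a *valid* haplotype only if it clears the 1% threshold **and** survives the
singleton-site filter (`flagSingletonSiteErrors`): an entry whose every
difference from the rank-1 sequence occurs in a column where no other entry
differs is discarded as an error, even above 1%. This mirrors the
observation that a genuine low-frequency allele recurs across variants,
while a polymerase error is private.

**Chimera rule (`parentFactor`, default 2; `maxParents`, default 32).** A
candidate is chimeric iff two distinct equal-length parents, each at least
twice as abundant, explain it exactly as prefix + suffix at some breakpoint.
The 2x factor follows uchime's de novo convention (a chimera cannot out-amplify
its parents); the parent pool is capped at the 32 most abundant eligible
sequences per candidate, which keeps the scan linear in practice while real
chimera parents -- necessarily abundant templates -- remain in scope.
Flagged reads are removed **before** proportions are computed, so the 1%
threshold sees chimera-free totals.

## Alignment

`ClustalW`-style progressive alignment is unnecessary for same-locus
amplicons that differ by SNPs and rare short indels, and it is not
deterministic across versions. `ighap` instead uses a reference-anchored
star alignment: each haplotype is aligned globally to the anchor (rank-1
haplotype, or an explicit locus reference) by Needleman--Wunsch with affine
gaps at fixed scores -- match +1, mismatch -1, gap open -4, gap extend -1 (a
k-base gap costs 4 + (k-1)) -- and pairwise gaps are projected into shared
columns: an insertion against the anchor at offset *o* opens one shared
column block of the maximal insertion length seen at *o*. In the indel-free
case this is exact; with indels it is deterministic by construction.
Tie-breaking is fixed: the traceback prefers substitutions over gaps and
pushes gap runs leftmost. The kernel is compiled (Rcpp) and is verified in
the test suite against an independent top-down scoring oracle on short
strings.

Consequences worth knowing: a deletion inside a homopolymer or repeat is
placed at the leftmost equivalent position, which may differ from the
"true" simulated coordinate -- an alignment-theory ambiguity, not a defect.
Positional recovery tests therefore plant substitutions (unambiguous) and
test indels with controlled contexts.

## SNP sites and classes

Every alignment column with two or more distinct symbols among valid rows
yields a site: `transition` (A/G, T/C), `transversion` (A/T, A/C, G/T,
G/C), `multiallelic` (3+ bases; counted as one segregating site, with each
observed unordered pair contributing once to the Ts/Tv spectrum), or
`indel`. Maximal runs of gap columns affecting the same set of haplotypes
collapse into a single indel site -- an extended deletion is recorded as one
single-nucleotide deletion -- and runs split where the affected set changes.
Total SNPs = transitions + transversions + multiallelic + indel sites.

Densities are reported per kilobase of **ungapped reference** span (not
alignment length). Coordinates are 1-based closed intervals throughout, the
R/Bioconductor convention; an exon's first base is exonic, and insertion
columns inherit the region of the flanking reference base to the left.

## Codon impact

Exon intervals are lifted through the alignment anchor and spliced per
haplotype; minus-strand models are reverse-complemented. Translation uses
the standard genetic code (table 1), drops trailing partial codons, keeps
internal stops as `*` with a warning, and maps codons containing non-ACGT
symbols to `X`. A change is synonymous iff the two whole codons translate
identically. Haplotypes whose indels disrupt the frame (non-multiple-of-3
exonic indels, or gap runs spanning a splice boundary) are excluded from
exon/protein collapse and reported separately; with intron-confined
deletions -- the situation this package models -- that path is exercised
only by synthetic data. `collapseLevels` counts distinct sequences at the
DNA, spliced-exon and protein levels; the counts are provably monotone
(protein <= exon <= DNA) and the suite checks this on random sets.

## The simulator

`simulationConfig()` defaults describe the mosaic structure the analysis is
designed around: K = 5 haplotypes at frequencies 0.40/0.30/0.15/0.10/0.05
over a ~300 bp merged amplicon, substitution rates of 0.005/base in exons
and 0.02/base in introns (introns several-fold more variable than exons), a
two-fold transition bias (kappa = 2, i.e. a substitution is a transition
with probability 2/3), single-base deletions confined to introns at
0.002/base, 20,000 reads, 0.2% per-base error, and no chimeras unless
requested. Haplotype 1 is always the unmutated reference; other haplotypes
draw Poisson event counts per region and are rejection-sampled to be
pairwise distinct -- a mixture of K haplotypes means K different sequences.
Reads are `fwd + insert + reverseComplement(rev)` with i.i.d. errors
(uniform over the three alternatives) across the whole read, primers
included, so primer-region errors are rejected downstream exactly as on a
real run; qualities are flat at the Phred score of the error rate. All
randomness is confined to the simulator and is reproducible: the same seed
yields a byte-identical FASTQ.

What the simulator does **not** emulate: paired-end structure and overlap
merging (reads are emitted pre-merged), insertions, PCR-cycle-explicit
error accumulation, polymerase-specific error spectra, position-dependent
quality decay, and any claim about the true per-cell mutation process of a
real organism -- the rates are calibration knobs with field-plausible
defaults, not biology. Passing recovery tests therefore demonstrate the
pipeline's correctness under this error model, not robustness to every
artifact of real libraries.

## Numerical and design choices

- **Rounding:** proportions round half-up to 4 decimals; this is applied
  before thresholding so reported and thresholded values agree.
- **Trimming ambiguity:** "remove low-quality bases from the 3' to 5'
  ends" is read as a 3'-anchored scan (the standard Illumina quality-decay
  reading); `bothEnds = TRUE` applies the mirrored scan when wanted.
- **Threshold boundary:** exactly 1% is excluded (strict `>`), documented
  above.
- **Tie-breaks:** equal dereplication counts rank lexicographically by
  sequence; alignment ties prefer substitutions, then leftmost gaps --
  everything downstream is deterministic.
- **Frequency checks against truth:** per-base errors deflate every exact
  haplotype's read count by the same factor (1 - e)^L, so recovery tests
  compare frequencies renormalised over the valid calls, where the counts
  are conditionally multinomial in the true frequencies and a 3-binomial-SD
  band is exact.
- **Degenerate inputs:** empty trim results are kept until primer matching;
  an empty haplotype set warns rather than errors; one-entry sets produce
  single-leaf trees; a zero-transversion spectrum reports an infinite
  Ts/Tv ratio with an explicit flag.

## Problem sizes used by the test suite

Simulation-backed tests run at 2,000-20,000 reads over a 300 bp locus (a 90
bp intron between two stop-free exons), with 20-seed replicate loops for
the recovery properties; the Ts/Tv recovery uses an intron-only 6 kb locus
with ~650 planted substitutions. These sizes exercise every code path at
desk scale while keeping the default `R CMD check`-style run in minutes.

## Known limitations

- The chimera rule only considers equal-length parents and single
  breakpoints; multi-segment chimeras or length-changing artifacts pass.
- The singleton-site error filter assumes errors are private; two reads
  sharing the same polymerase error at high depth can defeat it.
- Indel placement inherits the leftmost-gap convention; positions inside
  repeats are canonical rather than historical.
- p-distance NJ grouping is descriptive (zero-length cherries = identical
  clusters), not a phylogenetic inference; no substitution model or
  bootstrap is offered.
- dN/dS estimation, nucleotide-diversity estimators (pi, theta) and
  haplotype networks are out of scope.
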