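---
title: "Curation methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncotier)
```

This vignette is the package's own account of the science it implements:
the models and rules, the parameters that matter, what the synthetic
cohort generator does and does not emulate, and the choices made where the
design was genuinely open.

## The curation model

The package treats tumor-board curation as a deterministic pipeline over
typed records. Somatic SNVs/indels enter with a gene symbol, a consequence
class and an exact variant spec (protein change or cDNA change as a
string); copy-number segments enter with observed bulk copy number; splice
junctions enter as unstranded read counts on 1-based intron boundaries.
Everything downstream is a pure function of these records plus a
`KnowledgeBase` object holding four tables: variant-level clinical
evidence, drug–gene associations, named gene sets and a pathway map.

### Tiering

`assignTier()` applies a strict precedence: exact-variant clinically
significant evidence in the study disease (Tier 1), the same in another
disease (Tier 2), otherwise a VUS in an actionable gene that has at least
one drug association (Tier 3), otherwise a VUS in a cancer-census gene
(Tier 4), otherwise unclassified. Two assumptions are worth making
explicit:

* **Evidence matching is exact-string**, after whitespace stripping and
  case folding — no HGVS parsing or coordinate liftover. Curated evidence
  names variants the way clinicians do (`R132H`, `V600E`), and string
  identity is the only match the evidence supports.
* **Tiers are disjoint by precedence.** A variant in a gene that is both
  actionable and census-listed can only be Tier 3, never Tier 4. Whether a
  curation program would allow overlap is unspecified in practice; forcing
  disjointness makes the classification a function.

The low-VAF rescue rule keeps sub-threshold calls alive when manual review
would: a variant with VAF < 0.15 is retained (flagged, not silently mixed
in) when its gene is in the cancer-census set and total depth is ≥ 40
reads; the boundary VAF of exactly 0.15 passes the main filter. Both
numbers are exposed as arguments.

### Expression outliers

The modified z-score divides the departure from the reference-cohort
median TPM by the reference **raw** median absolute deviation. The usual
1.4826 normal-consistency constant is deliberately omitted: the score is
used as a robust rank statistic against a skewed cohort, not as an
estimate of normal SDs. Consequences of this choice:

* A gene with zero reference MAD (typically unexpressed in every
  reference sample) gets an **undefined** score, not ±Inf. Returning
  infinity would rank dead genes as the strongest outliers.
* The score is invariant under a common positive rescaling of sample and
  reference (checked property-style in the tests), so TPM versus scaled
  TPM does not matter as long as both sides agree.

The outlier flag threshold |z| ≥ 2 is report-side highlighting only and
configurable; no pipeline decision consumes it.

### Splicing

PSI is computed by the literal ratio convention: alternative-event reads
divided by canonical-event reads, × 100. This ratio can exceed 100% and is
**not** the more common inclusion fraction alt/(alt+canonical); the
inclusion convention is available via `computePsi(..., convention =
"inclusion")` but the ratio is the default because it is the definition
the curation workflow used. Two anchoring decisions were open and are
resolved as follows:

* **Canonical denominator**: the read count of the single annotated
  junction sharing the event's donor site, falling back to the junction
  sharing its acceptor site. Donor sharing is the least ambiguous anchor
  when an event bypasses several introns.
* **Saturation**: zero canonical reads with positive alternative reads
  yields an undefined-high PSI; the event is still emitted, flagged
  `saturated`, because a fully penetrant skip (no canonical product at
  all) is the most biologically interesting case, not a division error.

Exon skipping is purely structural: a junction joining the 3′ end of exon
*i* to the 5′ start of exon *j* with *j* > *i* + 1 and ≥ 5 supporting
reads (the same floor as RNA variant sufficiency) skips exons *i*+1 …
*j*−1. DNA corroboration requires a deletion call spanning **all** skipped
exons; partial overlap does not corroborate.

### Copy number

Purity correction inverts the two-population mixture `observed = ρ·tumor +
(1−ρ)·2` and floors at zero; the inversion is exact wherever unfloored
(verified to 1e-9). Classification bands are conventions the source
workflow left unstated, fixed here as:

| class | rule | rationale |
|---|---|---|
| homozygous loss | corrected < 0.5 | both copies gone, ±0.5 tolerance |
| heterozygous loss | 0.5 ≤ cn < 1.5, or below the neutral band | one copy |
| neutral | within ploidy ± 0.5 | anchored at **sample ploidy**, not 2 |
| gain | above the neutral band, < 5 | |
| amplification | cn ≥ 5 | the 5-copy line separates first-class gains |
| focality | arm-level iff segment covers ≥ 50% of its arm | common convention, configurable |

Anchoring the neutral band at ploidy keeps hyperploid samples (ploidy up
to ~4) from being called gained genome-wide. Priority ranks follow the
curation preference: homozygous losses and high-copy focal amplifications
(rank 1) over other focal changes (rank 2) over arm-level gains and
heterozygous losses (rank 3); rank-3 findings can be dropped
(`includeLowPriority = FALSE`) to emulate stricter automated scopes that
do not consider < 5-copy gains or heterozygous losses targetable.

### Therapy matching

Only Tier 1–3 SNVs, rank-carrying CNVs and actionable SVs match drugs;
Tier-4-only findings never do. Scope compatibility is: `any_alteration`
matches everything, `gain`/`loss` match their copy classes,
`specific_variant` requires an exact spec match. Checkpoint inhibitors are
ordinary knowledge-base rows under the pseudo-gene key `TMB_HIGH`, which
keeps the matcher uniform. Open points resolved here:

* **Hypermutation threshold.** The workflow contrasted burdens of ~2000
  and ~6000 exonic SNVs against a cohort median of ~157 without stating a
  cutoff. The rule used is `count > max(1000, 5 × cohort median)`; both
  constants are arguments.
* **Conjunction.** The checkpoint option requires high burden **and** a
  disrupted MMR gene (truncating/splice-site SNV or homozygous loss in
  MSH2/MSH6/MLH1/PMS2/POLE). Either-alone is defensible; the conjunction
  matches the observed co-occurrence and is the conservative reading.
* **Combinations.** When ≥ 2 distinct genes with direct options fall in
  one pathway, one drug per gene (its best-evidence option,
  alphabetical tie-break) forms a combination; the rationale is
  `combination_parallel_arms` when two or more hit genes are tagged as
  parallel arms, `combination_same_pathway` otherwise.
* **Ranking** is stable: evidence level, then best-target tier, then drug
  name, preserving input order on full ties. No tumor-board judgment
  beyond evidence level is modeled — where the source workflow ranked
  e.g. one amplification over another on unpublished in-vitro grounds,
  this package does not attempt to reproduce it.

### Concordance

Call keys exist at three levels — variant (`GENE:SPEC`), gene, and drug
target — because published comparisons mix granularities without defining
keys; the default for panel comparison is variant-level, and curator
comparisons are meaningful at both variant and drug-target levels.
Germline miscalls are flagged only for panels lacking a matched normal
(matched-normal assays subtract germline by design), requiring germline
VAF ≥ 0.25 for confidence. Undefined sensitivity/PPV rows (empty truth or
test sets) are excluded from cohort means and counted separately; SD uses
the n−1 denominator because cohorts are small.

## The synthetic cohort generator

`simulateCohort()` emulates the statistical structure the analysis
assumes, with truth labels, so every stage is testable without external
data:

* purity from a truncated normal (mean 0.71, SD 0.16, bounds 0.15–0.95);
  ploidy normal around 2.03;
* exonic SNV burden lognormal with median 157 and sdlog 0.52 (chosen so
  the interquartile range is ≈ 110), plus a hypermutant component
  (expected 2 of 30 samples, counts uniform on 1500–6000, each carrying
  an MSH2 splice-donor disruption);
* curated variants planted by a tier mixture (3% Tier 1, 4% Tier 2, 48%
  Tier 3, 25% Tier 4, 20% unclassifiable), with Tier 1/2 specs drawn from
  the knowledge base and novel specs positioned to avoid colliding with
  any evidence row;
* TERT-promoter hotspot variants in ~60% of samples;
* recurrent CNVs as mixture-model observations: chr10 arm loss covering
  the PTEN analog (p = 0.7), EGFR-like focal amplification at 8–25 tumor
  copies (p = 0.5), CDKN2A-like focal homozygous loss (p = 0.4), plus
  Gaussian observation noise (SD 0.05 copies);
* DNA and RNA allele fractions drawn binomially at Poisson depths (means
  80 and 50) from a shared true VAF — so DNA–RNA correlation rises with
  depth, a property the tests check;
* spiked splice events: a mid-gene MET exon skip at PSI 30 and an
  EGFRvIII-like exon 1→8 junction with 32 reads accompanied by matching
  DEL records from two callers.

The generator runs on a bundled two-chromosome, 51-gene toy genome at
scaled coordinates (2.4 Mb chromosomes, 200-bp exons). Real-genome
coordinates, mutational signatures, subclonal structure, read-level data
and realistic linkage are **not** emulated; passing tests therefore
demonstrate the correctness of the curation logic and the statistical
recovery properties, not performance on real sequencing artifacts
(alignment error, FFPE damage, segmentation noise). All generators are
pure functions of (config, seed); the observer models (panel gene-space
masking with dropout and germline contamination; curator detection /
false-call sampling) are seeded the same way.

## Problem sizes and numerical choices

The test suite exercises each arithmetic operation against an independent
oracle (sort-based median/MAD, closed-form Pearson, element-wise set
loops, exon-pair enumeration) on 1000 random small instances each, checks
mixture inversion to 1e-9, recovers a curator detection probability of
0.71 within three standard errors over 200 simulated cases, and verifies
that tiering recovers 100% of planted tier labels on a 30-sample seeded
cohort (the acceptance bound is ≥ 99%). The default simulated cohorts used
throughout the tests are 3–30 samples (200 for the burden-distribution
check), which keeps the full suite around a minute on one CPU.

Degenerate inputs are handled explicitly rather than by propagating NaN:
zero-MAD genes, zero-canonical junctions, empty truth/test sets,
single-sample SDs and zero-width segments each return flagged undefined
values documented on the respective function.

## Interfaces

The package is a library: the exported functions (plus
`scripts/acceptance.R` for the headline numbers) are the entry points, and
every stage reads and writes plain TSV/VCF so a shell pipeline can be
assembled from `Rscript -e` one-liners if needed. Coordinates follow the
field's conventions throughout — VCF and junction tables 1-based, segments
and exon models 0-based half-open — and every reader validates them with
line-numbered errors.

## Known limitations

* Evidence matching cannot unify spelling variants of *variant* specs
  (only drug names have an alias map); a knowledge base with `R132H` and
  `Arg132His` rows would treat them as distinct.
* The pathway map is role-tagged but unordered; combination rationale
  distinguishes upstream/downstream/parallel arms, not signaling
  distance.
* PSI uses a single-junction canonical denominator; workflows that sum
  across all junctions of a skipped region will report smaller values for
  multi-intron events.
* CNV classification assumes one purity/ploidy per sample (no subclonal
  copy states) and consumes, never estimates, purity and ploidy.
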