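# oncotier

Tiered somatic-variant curation and therapy matching for tumor genomes.

`oncotier` re-implements, as a reusable R package, the analysis workflow an
expert tumor board applies to whole-genome plus RNA sequencing of tumors
(the bundled data model a 30-sample glioblastoma-like cohort). It is aimed
at clinical-genomics analysts and methods developers who need the curation
logic — tiering, RNA annotation, CNV prioritization, therapy matching,
call-set concordance — as testable, seedable code rather than a manual
protocol.

## What it computes

**Actionability tiers.** Somatic SNVs/indels are screened to candidate
classes (exonic, splice-site, promoter-window variants of promoter genes
such as *TERT*) and tiered against a clinical-evidence knowledge base with
precedence Tier 1 > 2 > 3 > 4:

- **Tier 1** — exact-variant evidence, clinically significant in the study
  disease;
- **Tier 2** — exact-variant evidence in another tumor type;
- **Tier 3** — VUS in an actionable gene with at least one associated drug;
- **Tier 4** — VUS in a cancer-census gene (recorded, never drug-matched).

Sub-threshold calls (VAF < 15%) in known cancer genes with ≥ 40 total reads
are rescued rather than dropped.

**RNA annotation.** Per-gene expression outliers use the modified z-score
against a reference cohort,

```
z = (TPM_sample − median_ref) / MAD_ref
```

with a *raw* median absolute deviation (no 1.4826 consistency constant).
Variant-level RNA support requires ≥ 5 total RNA reads; DNA–RNA agreement
is summarized by Pearson's *r* over sufficient pairs.

**Splicing.** Percent spliced in is the literal ratio
`PSI = 100 · alt_reads / canonical_reads`; unannotated junctions with
PSI > 10% in cancer-census genes become events, and junctions joining
non-adjacent exons (an EGFRvIII-like exon 1→8 junction skips exons 2–7) are
detected and corroborated against DNA deletion calls.

**Copy number.** Observed copy numbers are purity-corrected by inverting
the tumor/normal mixture, `cn_tumor = (cn_obs − 2(1 − ρ)) / ρ`, classified
(homozygous loss < 0.5 copies, heterozygous loss, ploidy-anchored neutral
band ± 0.5, gain, amplification ≥ 5 copies) with arm-level vs focal extent,
and ranked: homozygous losses and high-copy focal amplifications first,
focal gains/losses second, arm-level gains and heterozygous losses third.

**Therapies.** Tier 1–3 SNVs, prioritized CNVs and actionable SVs are
matched to drug–gene associations (with NCT trial identifiers) and ranked
by evidence level; co-occurring lesions in one pathway yield combination
options; hypermutant samples (exonic SNVs > max(1000, 5 × cohort median))
with a disrupted mismatch-repair gene receive checkpoint-inhibitor options.

**Concordance.** Call sets are compared as common / unique partitions with
germline-miscall audits for panels lacking matched normals, and as
sensitivity / PPV against a truth set, summarized per cohort.

A seeded synthetic-cohort generator (`simulateCohort()`) with observer
models for panels and automated curators makes every stage testable at desk
scale, and a bundled 30-sample curated-findings fixture (`table2Fixture()`)
carries the cohort's key variants, drug strings (spelling variants intact)
and trial identifiers.

## Worked example

```r
library(oncotier)
kb <- bundledKnowledgeBase()
co <- simulateCohort(cohortConfig(seed = 7, n_samples = 6L), kb = kb)
res <- curateCohort(co, kb)
cat(renderSampleReport(res[[2]])$text, sep = "\n")
```

```
== Sample S02 ==
purity 0.60 | ploidy 2.06 | exonic SNVs 421
findings: 13 (SNV 5, CNV 8, SV 0)
therapy options:
   1. MGMT:LOSS -> TEMOZOLOMIDE [approved_in_disease, direct_target]
   2. EGFR:GAIN+PTEN:A788K -> CETUXIMAB+EVEROLIMUS [approved_other_disease, combination_same_pathway]
   3. PTEN:A788K -> EVEROLIMUS [approved_other_disease, direct_target]
   ...
   8. IDH1:R132H -> AG120 [clinical_trial, direct_target]
```

The report ranks options by evidence level: the approved-in-disease
alkylator for the *MGMT* loss leads, the upstream-plus-downstream
RTK/PI3K/mTOR combination (*EGFR* gain + *PTEN* mutation) follows, and the
Tier 1 *IDH1* R132H variant maps to its mutant-IDH1 inhibitors at
trial-level evidence. DNA–RNA allele-fraction agreement for the same cohort:

```r
v <- cohortVariants(co)
suff <- v$rna_total >= 5
dnaRnaVafCorrelation(v$vaf[suff], v$rna_vaf[suff])
#> r = 0.630 over n = 42 variants
```

## Package tour

| Area | Entry points |
|---|---|
| Knowledge base | `loadKnowledgeBase()`, `bundledKnowledgeBase()`, `queryEvidence()`, `queryDrugs()`, `normalizeDrugName()` |
| I/O | `readSomaticVcf()`, `readCnvSegments()`, `readExpression()`, `readJunctions()`, `readGeneModel()`, `readSv()` (+ writers) |
| Tiering | `selectCandidates()`, `assignTier()`, `tierVariants()`, `rescueLowVaf()` |
| RNA | `modifiedZscore()`, `buildReferenceStats()`, `rnaVariantSupport()`, `dnaRnaVafCorrelation()` |
| Splicing | `computePsi()`, `callSpliceEvents()`, `detectExonSkipping()`, `corroborateWithSv()` |
| CNV/SV | `correctCopyNumber()`, `classifySegments()`, `genesInSegment()`, `prioritizeFindings()`, `svFindings()` |
| Therapy | `matchTherapies()`, `suggestCombinations()`, `applyHypermutationRule()`, `rankTherapies()`, `summarizeAssociationTypes()` |
| Concordance | `comparePanel()`, `sensitivityPpv()`, `summarizeCohort()` |
| Simulation | `cohortConfig()`, `simulateCohort()`, `observePanel()`, `observeCurator()`, `writeCohort()` |
| Reporting | `curateCohort()`, `renderSampleReport()` |

See `vignettes/curation-methods.Rmd` for the modeling choices and their
rationale.
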