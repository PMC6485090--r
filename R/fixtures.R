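#' The bundled 30-sample curated-findings fixture
#'
#' Loads the bundled per-sample key findings of the study cohort: each
#' sample's key therapeutic variants typed as SNV / copy gain / copy loss /
#' SV / mutation-burden flag, the associated drug strings verbatim
#' (spelling variants intact, so the normalizer is exercised), and the
#' clinical-trial registry identifiers verbatim. Hypermutant samples carry
#' their exonic SNV counts (1954 and 5881, against a cohort median of 157).
#' A small table of tier-exemplar SNVs (the recurrent Tier 1/2 variants:
#' IDH1 R132H, BRAF V600E, TP53 R175H/R273C, PIK3CA E542K) is included for
#' tier-rule checks.
#'
#' @return list with elements:
#'   \describe{
#'     \item{variants}{data.frame sample, gene, alteration_class
#'       (snv/gain/loss/sv/burden), variant_spec, consequence, focality.}
#'     \item{drugs}{data.frame sample, drugs (verbatim comma-joined cell),
#'       trials (space-joined registry ids).}
#'     \item{burden_counts}{named integer vector of exonic SNV counts for
#'       the burden-flagged samples.}
#'     \item{cohort_median_snvs}{cohort median exonic SNV count (157).}
#'     \item{tier_exemplars}{data.frame gene, variant_spec.}
#'   }
#' @export
table2Fixture <- function() {
  variants <- .readTsv(.extdata("table2", "table2_variants.tsv"))
  .requireCols(variants, c("sample", "gene", "alteration_class",
                           "variant_spec", "consequence", "focality"),
               "table2 variants")
  drugs <- .readTsv(.extdata("table2", "table2_drugs.tsv"))
  .requireCols(drugs, c("sample", "drugs", "trials"), "table2 drugs")
  nSamples <- length(unique(drugs$sample))
  if (nSamples != 30L)
    stop("fixture integrity: expected 30 samples, found ", nSamples,
         call. = FALSE)
  if (!all(unique(variants$sample) %in% drugs$sample))
    stop("fixture integrity: variant samples missing from drugs table",
         call. = FALSE)
  variants$gene <- .dotNA(variants$gene)
  variants$consequence <- .dotNA(variants$consequence)
  variants$focality <- .dotNA(variants$focality)
  burdenSamples <- variants$sample[variants$alteration_class == "burden"]
  counts <- stats::setNames(c(1954L, 5881L)[seq_along(burdenSamples)],
                            burdenSamples)
  list(variants = variants, drugs = drugs,
       burden_counts = counts, cohort_median_snvs = 157L,
       tier_exemplars = data.frame(
         gene = c("IDH1", "BRAF", "TP53", "TP53", "PIK3CA"),
         variant_spec = c("R132H", "V600E", "R175H", "R273C", "E542K"),
         stringsAsFactors = FALSE))
}

#' Distinct therapies named by the fixture's drug entries
#'
#' Splits every per-sample drug cell on commas and `/` (combination
#' entries), normalizes each name with [normalizeDrugName()] and counts the
#' distinct therapies across the cohort.
#'
#' @param fixture output of [table2Fixture()].
#' @param aliases alias map (default the bundled one).
#' @return list `therapies` (sorted character vector) and `n`.
#' @export
countFixtureTherapies <- function(fixture = table2Fixture(), aliases = NULL) {
  cells <- unlist(strsplit(fixture$drugs$drugs, ",", fixed = TRUE),
                  use.names = FALSE)
  entries <- splitDrugEntry(cells)
  entries <- entries[nzchar(entries)]
  norm <- sort(unique(normalizeDrugName(entries, aliases)))
  list(therapies = norm, n = length(norm))
}

#' Therapy-match the fixture cohort against a knowledge base
#'
#' Runs the full matching path over the fixture's typed findings: SNVs are
#' tiered with [tierVariants()], copy-number and SV rows are matched
#' directly, burden-flagged samples go through the hypermutation
#' checkpoint-inhibitor rule, and same-pathway combinations are suggested.
#'
#' @param fixture output of [table2Fixture()].
#' @param kb a [KnowledgeBase-class] (default the bundled one).
#' @param studyDisease disease defining Tier 1.
#' @return list `options` (ranked data.frame incl. combinations and
#'   checkpoint options), `findings` (the tiered findings table) and
#'   `samples_with_options` (character vector).
#' @export
matchFixtureTherapies <- function(fixture = table2Fixture(),
                                  kb = bundledKnowledgeBase(),
                                  studyDisease = "glioblastoma") {
  f <- fixture$variants
  findings <- data.frame(sample_id = f$sample, gene = f$gene,
                         alteration_class = f$alteration_class,
                         variant_spec = f$variant_spec,
                         consequence = f$consequence,
                         stringsAsFactors = FALSE)
  isSnv <- findings$alteration_class == "snv"
  findings$tier <- NA_integer_
  if (any(isSnv))
    findings$tier[isSnv] <- tierVariants(findings[isSnv, , drop = FALSE],
                                         kb, studyDisease)$tier
  # fixture CNVs are curated key findings: focal events rank ahead of
  # arm-level ones
  findings$priority_rank <- ifelse(
    findings$alteration_class %in% c("gain", "loss"),
    ifelse(!is.na(f$focality) & f$focality == "arm_level", 3L, 2L),
    NA_integer_)
  opts <- matchTherapies(findings, kb)
  combos <- suggestCombinations(opts, findings, kb)
  hyperOpts <- list()
  for (sid in names(fixture$burden_counts)) {
    b <- mutationBurden(sid, fixture$burden_counts[[sid]], findings, kb)
    hyperOpts[[sid]] <- applyHypermutationRule(b, fixture$cohort_median_snvs,
                                               kb)
  }
  all <- rbind(opts, combos, do.call(rbind, hyperOpts))
  all <- rankTherapies(all)
  list(options = all, findings = findings,
       samples_with_options = sort(unique(all$sample_id)))
}
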