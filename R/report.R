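#' Run the full curation pipeline over a cohort
#'
#' Per sample: candidate selection and low-VAF rescue, tier assignment,
#' purity-corrected CNV classification and prioritization, splice-event
#' calling with SV corroboration, expression outlier annotation, therapy
#' matching (direct targets, same-pathway combinations, hypermutation
#' checkpoint rule) and ranking.
#'
#' @param cohort a [TumorCohort-class].
#' @param kb a [KnowledgeBase-class].
#' @param model gene model (default [toyGeneModel()]).
#' @param arms arm table (default [toyArmTable()]).
#' @param studyDisease disease defining Tier 1.
#' @return named list of per-sample result lists (see
#'   [renderSampleReport()]).
#' @export
curateCohort <- function(cohort, kb = bundledKnowledgeBase(),
                         model = toyGeneModel(), arms = toyArmTable(),
                         studyDisease = "glioblastoma") {
  samples <- cohortSamples(cohort)
  census <- kbGeneSet(kb, "cancer_census")
  actionable <- kbGeneSet(kb, "actionable_genes")
  variants <- cohortVariants(cohort)
  segments <- cohortSegments(cohort)
  junctions <- cohortJunctions(cohort)
  svRec <- cohortSv(cohort)
  refStats <- buildReferenceStats(referenceExpression(cohort))
  cohortMedian <- stats::median(samples$exonic_snv_count)

  out <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[[i]]
    sv <- variants[variants$sample_id == sid, , drop = FALSE]
    cand <- selectCandidates(sv, model)
    part <- suppressMessages(rescueLowVaf(cand, census))
    kept <- rbind(part$pass_main, part$rescued)
    tiered <- tierVariants(kept, kb, studyDisease)

    seg <- segments[segments$sample_id == sid, , drop = FALSE]
    cls <- if (nrow(seg) > 0L)
      classifySegments(seg, samples$purity[[i]], samples$ploidy[[i]],
                       arms, model) else seg
    prio <- if (nrow(seg) > 0L) prioritizeFindings(cls) else cls

    jx <- junctions[junctions$sample_id == sid, , drop = FALSE]
    splice <- callSpliceEvents(jx, model, census)
    splice <- corroborateWithSv(splice,
                                svRec[svRec$sample_id == sid, , drop = FALSE],
                                model)

    exprAnn <- expressionAnnotation(cohortExpression(cohort)[, sid],
                                    refStats)

    findings <- .assembleFindings(sid, tiered, prio, svRec, actionable,
                                  model)
    opts <- matchTherapies(findings, kb)
    combos <- suggestCombinations(opts, findings, kb)
    burden <- mutationBurden(sid, samples$exonic_snv_count[[i]], findings,
                             kb)
    hyper <- applyHypermutationRule(burden, cohortMedian, kb)
    options <- rankTherapies(rbind(opts, combos, hyper))

    out[[sid]] <- list(
      sample = as.list(samples[i, ]),
      findings = findings, tiered_variants = tiered, cnv = prio,
      splice_events = splice,
      expression_outliers = exprAnn[exprAnn$outlier, , drop = FALSE],
      burden = burden, therapy_options = options,
      provenance = list(study_disease = studyDisease,
                        seed = cohort@config$seed %||% NA,
                        kb_evidence_n = nrow(kbEvidence(kb)),
                        kb_drug_n = nrow(kbDrugs(kb))))
  }
  out
}

.assembleFindings <- function(sid, tiered, prio, svRec, actionable, model) {
  parts <- list()
  if (nrow(tiered) > 0L)
    parts$snv <- data.frame(sample_id = sid, gene = tiered$gene,
                            alteration_class = "snv",
                            variant_spec = tiered$variant_spec,
                            consequence = tiered$consequence,
                            tier = tiered$tier, priority_rank = NA_integer_,
                            copy_class = NA_character_,
                            stringsAsFactors = FALSE)
  if (nrow(prio) > 0L) {
    cnvClass <- ifelse(prio$copy_class %in%
                         c("gain", "focal_amplification"), "gain", "loss")
    cnvRows <- list()
    for (k in seq_len(nrow(prio))) {
      genes <- intersect(strsplit(prio$genes_hit[[k]], ";", fixed = TRUE)[[1]],
                         actionable)
      if (length(genes) == 0L) next
      cnvRows[[length(cnvRows) + 1L]] <- data.frame(
        sample_id = sid, gene = genes, alteration_class = cnvClass[[k]],
        variant_spec = cnvClass[[k]], consequence = NA_character_,
        tier = NA_integer_, priority_rank = prio$priority_rank[[k]],
        copy_class = prio$copy_class[[k]], stringsAsFactors = FALSE)
    }
    if (length(cnvRows) > 0L) parts$cnv <- do.call(rbind, cnvRows)
  }
  svF <- svFindings(svRec[svRec$sample_id == sid, , drop = FALSE],
                    actionable)
  if (nrow(svF) > 0L) {
    svF <- svF[!duplicated(svF[, c("gene", "sv_type")]), , drop = FALSE]
    parts$sv <- data.frame(sample_id = sid, gene = svF$gene,
                           alteration_class = "sv",
                           variant_spec = ifelse(svF$gene == "EGFR" &
                                                   svF$sv_type == "DEL",
                                                 "VIII", svF$sv_type),
                           consequence = NA_character_, tier = NA_integer_,
                           priority_rank = svF$priority_rank,
                           copy_class = NA_character_,
                           stringsAsFactors = FALSE)
  }
  if (length(parts) == 0L)
    return(data.frame(sample_id = character(), gene = character(),
                      alteration_class = character(),
                      variant_spec = character(), consequence = character(),
                      tier = integer(), priority_rank = integer(),
                      copy_class = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, parts)
  out <- out[!duplicated(out[, c("gene", "alteration_class",
                                 "variant_spec")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render a per-sample tumor-board-style report
#'
#' Deterministic serialization of one sample's pipeline results to JSON
#' (canonical form) and a human-readable text block. Errors if a pipeline
#' stage is missing from the results.
#'
#' @param result one element of [curateCohort()]'s return value.
#' @return list with `json` (character scalar) and `text` (character
#'   vector of lines).
#' @export
renderSampleReport <- function(result) {
  needed <- c("sample", "findings", "cnv", "splice_events", "burden",
              "therapy_options", "provenance")
  missing <- setdiff(needed, names(result))
  if (length(missing) > 0L)
    stop("missing pipeline stage(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  json <- jsonlite::toJSON(
    list(schema_version = "1.0", sample = result$sample,
         findings = result$findings, cnv = result$cnv,
         splice_events = result$splice_events, burden = result$burden,
         therapy_options = result$therapy_options,
         provenance = result$provenance),
    auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows")
  s <- result$sample
  opts <- result$therapy_options
  text <- c(
    sprintf("== Sample %s ==", s$sample_id),
    sprintf("purity %.2f | ploidy %.2f | exonic SNVs %d%s", s$purity,
            s$ploidy, s$exonic_snv_count,
            if (isTRUE(s$hypermutant)) " [hypermutant]" else ""),
    sprintf("findings: %d (SNV %d, CNV %d, SV %d)", nrow(result$findings),
            sum(result$findings$alteration_class == "snv"),
            sum(result$findings$alteration_class %in% c("gain", "loss")),
            sum(result$findings$alteration_class == "sv")),
    "therapy options:",
    if (nrow(opts) == 0L) "  (none)" else
      sprintf("  %2d. %s -> %s [%s, %s]", opts$rank, opts$targets,
              opts$drugs, opts$evidence_level, opts$rationale))
  list(json = as.character(json), text = text)
}
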