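#' @import methods
NULL

.EVIDENCE_COLS <- c("gene", "variant_spec", "disease", "significance", "source_id")
.DRUG_COLS <- c("gene", "variant_scope", "variant_spec", "drug",
                "evidence_level", "trial_ids", "disease")
.SIGNIFICANCE_LEVELS <- c("clinically_significant", "resistance", "unknown")
.VARIANT_SCOPES <- c("any_alteration", "gain", "loss", "specific_variant")
.EVIDENCE_LEVELS <- c("approved_in_disease", "approved_other_disease",
                      "clinical_trial", "preclinical")
.PATHWAY_ROLES <- c("upstream", "downstream", "parallel_arm")

#' Clinical-evidence knowledge base
#'
#' Container for the three knowledge bases the curation pipeline consults:
#' variant-level clinical evidence (CIViC-style), drug--gene associations with
#' registry trial identifiers, and named gene sets (actionable genes, cancer
#' census genes, mismatch-repair genes, panel gene spaces), plus a pathway map
#' used for combination-therapy logic and a drug-name alias table.
#'
#' Use [loadKnowledgeBase()] or [bundledKnowledgeBase()] to construct one;
#' access the slots through [kbEvidence()], [kbDrugs()], [kbGeneSet()],
#' [kbPathways()] and [kbAliases()].
#'
#' @slot evidence data.frame of evidence entries (gene, variant_spec, disease,
#'   significance, source_id).
#' @slot drugs data.frame of drug--gene associations (gene, variant_scope,
#'   variant_spec, drug, evidence_level, trial_ids, disease).
#' @slot geneSets named list of uppercase gene-symbol character vectors.
#' @slot pathways data.frame (pathway, gene, role) with one role per gene per
#'   pathway; roles are upstream / downstream / parallel_arm.
#' @slot aliases named character vector mapping normalized misspellings to
#'   canonical normalized drug names.
#' @exportClass KnowledgeBase
setClass("KnowledgeBase",
  representation(evidence = "data.frame", drugs = "data.frame",
                 geneSets = "list", pathways = "data.frame",
                 aliases = "character"))

setValidity("KnowledgeBase", function(object) {
  msgs <- character()
  ev <- object@evidence
  dr <- object@drugs
  if (!all(.EVIDENCE_COLS %in% names(ev)))
    msgs <- c(msgs, "evidence lacks required columns")
  else {
    if (any(!nzchar(ev$gene)) || any(!nzchar(ev$variant_spec)) ||
        any(!nzchar(ev$disease)))
      msgs <- c(msgs, "evidence has empty gene/variant_spec/disease")
    if (!all(ev$significance %in% .SIGNIFICANCE_LEVELS))
      msgs <- c(msgs, "evidence significance outside allowed values")
  }
  if (!all(.DRUG_COLS %in% names(dr)))
    msgs <- c(msgs, "drugs lacks required columns")
  else {
    if (!all(dr$evidence_level %in% .EVIDENCE_LEVELS))
      msgs <- c(msgs, "drugs evidence_level outside the four ordered levels")
    if (!all(dr$variant_scope %in% .VARIANT_SCOPES))
      msgs <- c(msgs, "drugs variant_scope outside allowed values")
    ids <- unlist(strsplit(dr$trial_ids[!is.na(dr$trial_ids)], ";"),
                  use.names = FALSE)
    bad <- ids[!grepl("^NCT[0-9]+$", ids)]
    if (length(bad) > 0L)
      msgs <- c(msgs, paste0("malformed trial id(s): ",
                             paste(unique(bad), collapse = ", ")))
    key <- paste(dr$gene, dr$variant_spec, dr$disease, dr$drug)
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate (gene, variant_spec, disease, drug) rows")
  }
  for (nm in names(object@geneSets)) {
    g <- object@geneSets[[nm]]
    if (anyDuplicated(g)) msgs <- c(msgs, paste0("gene set ", nm, " has duplicates"))
    if (!identical(g, toupper(g)))
      msgs <- c(msgs, paste0("gene set ", nm, " not uppercase-normalized"))
  }
  pw <- object@pathways
  if (nrow(pw) > 0L) {
    if (!all(c("pathway", "gene", "role") %in% names(pw)))
      msgs <- c(msgs, "pathways lacks required columns")
    else {
      if (!all(pw$role %in% .PATHWAY_ROLES))
        msgs <- c(msgs, "pathway role outside allowed values")
      if (anyDuplicated(paste(pw$pathway, pw$gene)))
        msgs <- c(msgs, "gene appears with more than one role in a pathway")
    }
  }
  if (length(msgs) == 0L) TRUE else msgs
})

#' @describeIn KnowledgeBase compact summary of KB contents
#' @param object a `KnowledgeBase`
#' @export
setMethod("show", "KnowledgeBase", function(object) {
  cat("KnowledgeBase\n")
  cat("  evidence entries :", nrow(object@evidence), "\n")
  cat("  drug associations:", nrow(object@drugs),
      sprintf("(%d genes, %d drugs)\n",
              length(unique(object@drugs$gene)),
              length(unique(object@drugs$drug))))
  cat("  gene sets        :",
      paste(sprintf("%s[%d]", names(object@geneSets),
                    lengths(object@geneSets)), collapse = " "), "\n")
  cat("  pathways         :",
      length(unique(object@pathways$pathway)), "\n")
})

#' Tumor cohort container
#'
#' Holds a simulated (or ingested) multi-sample tumor cohort: per-sample
#' metadata (purity, ploidy, exonic SNV burden), somatic and germline variant
#' tables, copy-number segments, splice-junction counts, a gene-by-sample TPM
#' matrix, and a reference-cohort TPM matrix for expression outlier scoring.
#' Simulated cohorts additionally carry truth columns (intended tier, intended
#' copy class, true PSI) used for pipeline validation.
#'
#' @slot samples data.frame: sample_id, purity, ploidy, exonic_snv_count,
#'   hypermutant.
#' @slot variants data.frame of somatic SNV/indel records (1-based positions).
#' @slot germline data.frame of germline calls per sample.
#' @slot segments data.frame of copy-number segments (0-based half-open).
#' @slot junctions data.frame of splice-junction read counts (1-based intron
#'   boundaries).
#' @slot sv data.frame of structural-variant records.
#' @slot expression gene x sample TPM matrix.
#' @slot referenceExpression gene x reference-sample TPM matrix.
#' @slot spliceTruth data.frame of spiked splice events (simulated cohorts).
#' @slot config the list of generator settings the cohort was built from.
#' @exportClass TumorCohort
setClass("TumorCohort",
  representation(samples = "data.frame", variants = "data.frame",
                 germline = "data.frame", segments = "data.frame",
                 junctions = "data.frame", sv = "data.frame",
                 expression = "matrix",
                 referenceExpression = "matrix", spliceTruth = "data.frame",
                 config = "list"))

setValidity("TumorCohort", function(object) {
  msgs <- character()
  s <- object@samples
  if (nrow(s) > 0L) {
    if (anyDuplicated(s$sample_id)) msgs <- c(msgs, "duplicate sample ids")
    if (any(s$purity <= 0 | s$purity > 1)) msgs <- c(msgs, "purity outside (0, 1]")
  }
  v <- object@variants
  if (nrow(v) > 0L && any(v$vaf < 0 | v$vaf > 1, na.rm = TRUE))
    msgs <- c(msgs, "variant VAF outside [0, 1]")
  if (length(msgs) == 0L) TRUE else msgs
})

#' @describeIn TumorCohort compact summary of cohort contents
#' @param object a `TumorCohort`
#' @export
setMethod("show", "TumorCohort", function(object) {
  cat("TumorCohort with", nrow(object@samples), "samples\n")
  cat("  somatic variants :", nrow(object@variants), "\n")
  cat("  germline calls   :", nrow(object@germline), "\n")
  cat("  CNV segments     :", nrow(object@segments), "\n")
  cat("  splice junctions :", nrow(object@junctions), "\n")
  cat("  expression       :", nrow(object@expression), "genes x",
      ncol(object@expression), "samples (reference n =",
      ncol(object@referenceExpression), ")\n")
})

#' @rdname kbAccessors
#' @export
setGeneric("kbEvidence", function(kb) standardGeneric("kbEvidence"))
#' @rdname kbAccessors
#' @export
setGeneric("kbDrugs", function(kb) standardGeneric("kbDrugs"))
#' @rdname kbAccessors
#' @export
setGeneric("kbGeneSet", function(kb, name) standardGeneric("kbGeneSet"))
#' @rdname kbAccessors
#' @export
setGeneric("kbPathways", function(kb) standardGeneric("kbPathways"))
#' @rdname kbAccessors
#' @export
setGeneric("kbAliases", function(kb) standardGeneric("kbAliases"))

#' Knowledge-base accessors
#'
#' Read access to the slots of a [KnowledgeBase-class] object.
#'
#' @param kb a `KnowledgeBase`
#' @param name gene-set name, e.g. `"actionable_genes"`, `"cancer_census"`,
#'   `"mmr_genes"`
#' @return `kbEvidence`/`kbDrugs`/`kbPathways` return data.frames;
#'   `kbGeneSet` a character vector of gene symbols; `kbAliases` a named
#'   character vector.
#' @name kbAccessors
NULL

#' @rdname kbAccessors
setMethod("kbEvidence", "KnowledgeBase", function(kb) kb@evidence)
#' @rdname kbAccessors
setMethod("kbDrugs", "KnowledgeBase", function(kb) kb@drugs)
#' @rdname kbAccessors
setMethod("kbGeneSet", "KnowledgeBase", function(kb, name) {
  if (!name %in% names(kb@geneSets))
    stop("unknown gene set: ", name, " (have: ",
         paste(names(kb@geneSets), collapse = ", "), ")", call. = FALSE)
  kb@geneSets[[name]]
})
#' @rdname kbAccessors
setMethod("kbPathways", "KnowledgeBase", function(kb) kb@pathways)
#' @rdname kbAccessors
setMethod("kbAliases", "KnowledgeBase", function(kb) kb@aliases)

#' @rdname cohortAccessors
#' @export
setGeneric("cohortSamples", function(x) standardGeneric("cohortSamples"))
#' @rdname cohortAccessors
#' @export
setGeneric("cohortVariants", function(x) standardGeneric("cohortVariants"))
#' @rdname cohortAccessors
#' @export
setGeneric("cohortGermline", function(x) standardGeneric("cohortGermline"))
#' @rdname cohortAccessors
#' @export
setGeneric("cohortSegments", function(x) standardGeneric("cohortSegments"))
#' @rdname cohortAccessors
#' @export
setGeneric("cohortJunctions", function(x) standardGeneric("cohortJunctions"))
#' @rdname cohortAccessors
#' @export
setGeneric("cohortSv", function(x) standardGeneric("cohortSv"))
#' @rdname cohortAccessors
#' @export
setGeneric("cohortExpression", function(x) standardGeneric("cohortExpression"))
#' @rdname cohortAccessors
#' @export
setGeneric("referenceExpression", function(x) standardGeneric("referenceExpression"))

#' Tumor-cohort accessors
#'
#' Read access to the tables of a [TumorCohort-class] object.
#'
#' @param x a `TumorCohort`
#' @return the corresponding slot (data.frame or matrix).
#' @name cohortAccessors
NULL

#' @rdname cohortAccessors
setMethod("cohortSamples", "TumorCohort", function(x) x@samples)
#' @rdname cohortAccessors
setMethod("cohortVariants", "TumorCohort", function(x) x@variants)
#' @rdname cohortAccessors
setMethod("cohortGermline", "TumorCohort", function(x) x@germline)
#' @rdname cohortAccessors
setMethod("cohortSegments", "TumorCohort", function(x) x@segments)
#' @rdname cohortAccessors
setMethod("cohortJunctions", "TumorCohort", function(x) x@junctions)
#' @rdname cohortAccessors
setMethod("cohortSv", "TumorCohort", function(x) x@sv)
#' @rdname cohortAccessors
setMethod("cohortExpression", "TumorCohort", function(x) x@expression)
#' @rdname cohortAccessors
setMethod("referenceExpression", "TumorCohort", function(x) x@referenceExpression)
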