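.EXONIC_CLASSES <- c("missense", "nonsense", "frameshift", "inframe_indel")

#' Select candidate variants for curation
#'
#' Keeps the variant classes the curation workflow reviews: exonic
#' protein-altering variants, splice-site variants, and promoter variants of
#' configured promoter genes (default TERT) falling within a window upstream
#' of the transcription start site. Synonymous variants are excluded by
#' default. A `candidate_class` column (exonic / splice_site / promoter) is
#' added.
#'
#' @param variants somatic variant data.frame (needs chrom, pos, gene,
#'   consequence).
#' @param model exon-level gene model (see [readGeneModel()]), used to locate
#'   promoter windows.
#' @param promoterGenes genes whose promoter windows are screened.
#' @param promoterWindow window size in bp upstream of the TSS (default 1000).
#' @param includeSynonymous keep synonymous variants as exonic candidates.
#' @return the retained rows with a `candidate_class` column.
#' @export
selectCandidates <- function(variants, model, promoterGenes = "TERT",
                             promoterWindow = 1000L,
                             includeSynonymous = FALSE) {
  if (nrow(variants) == 0L) {
    variants$candidate_class <- character(0)
    return(variants)
  }
  exonic <- .EXONIC_CLASSES
  if (includeSynonymous) exonic <- c(exonic, "synonymous")
  cls <- rep(NA_character_, nrow(variants))
  cls[variants$consequence %in% exonic] <- "exonic"
  cls[variants$consequence == "splice_site"] <- "splice_site"

  # promoter window: [TSS - window, TSS) in 1-based coordinates, strand-aware
  for (g in toupper(promoterGenes)) {
    ex <- model[toupper(model$gene) == g, , drop = FALSE]
    if (nrow(ex) == 0L) next
    strand <- ex$strand[[1L]]
    if (strand == "+") {
      tss1 <- min(ex$start) + 1L
      lo <- tss1 - promoterWindow; hi <- tss1 - 1L
    } else {
      tss1 <- max(ex$end)
      lo <- tss1 + 1L; hi <- tss1 + promoterWindow
    }
    inWin <- variants$chrom == ex$chrom[[1L]] &
      variants$pos >= lo & variants$pos <= hi
    cls[inWin & is.na(cls)] <- "promoter"
  }
  cls[is.na(cls) & variants$consequence == "promoter" &
        toupper(variants$gene) %in% toupper(promoterGenes)] <- "promoter"
  out <- variants[!is.na(cls), , drop = FALSE]
  out$candidate_class <- cls[!is.na(cls)]
  rownames(out) <- NULL
  out
}

#' Assign an actionability tier to one variant
#'
#' Deterministic precedence Tier 1 > 2 > 3 > 4 > none:
#' \describe{
#'   \item{Tier 1}{exact-variant evidence, clinically significant, in the
#'     study disease.}
#'   \item{Tier 2}{exact-variant clinically significant evidence in another
#'     disease.}
#'   \item{Tier 3}{no exact-variant evidence, but the gene is in the
#'     actionable set and carries at least one drug association (a VUS in an
#'     actionable gene).}
#'   \item{Tier 4}{otherwise, the gene is in the cancer-census set.}
#' }
#' All matching evidence rows are returned as supporting references; the tier
#' comes from the best row.
#'
#' @param gene gene symbol.
#' @param variantSpec exact variant spec.
#' @param kb a [KnowledgeBase-class].
#' @param studyDisease disease label defining Tier 1 (default
#'   `"glioblastoma"`).
#' @return list with `tier` (integer 1--4 or `NA` for none) and
#'   `evidence` (data.frame of supporting evidence rows).
#' @export
assignTier <- function(gene, variantSpec, kb,
                       studyDisease = "glioblastoma") {
  ev <- queryEvidence(kb, gene, variantSpec, studyDisease)
  sig <- ev[ev$significance == "clinically_significant", , drop = FALSE]
  g <- .normGene(gene)
  tier <- if (nrow(sig) > 0L && any(sig$same_disease)) 1L
  else if (nrow(sig) > 0L) 2L
  else if (g %in% kbGeneSet(kb, "actionable_genes") &&
           nrow(kb@drugs[kb@drugs$gene == g, ]) > 0L) 3L
  else if (g %in% kbGeneSet(kb, "cancer_census")) 4L
  else NA_integer_
  list(tier = tier, evidence = ev)
}

#' Tier a table of variants
#'
#' Vectorized wrapper around [assignTier()]: adds `tier` and `evidence_refs`
#' (`;`-joined source ids of matching evidence rows) columns.
#'
#' @param variants data.frame with gene and variant_spec columns.
#' @inheritParams assignTier
#' @return `variants` with `tier` and `evidence_refs` columns.
#' @export
tierVariants <- function(variants, kb, studyDisease = "glioblastoma") {
  n <- nrow(variants)
  tier <- integer(n); refs <- character(n)
  for (i in seq_len(n)) {
    a <- assignTier(variants$gene[[i]], variants$variant_spec[[i]], kb,
                    studyDisease)
    tier[[i]] <- if (is.na(a$tier)) NA_integer_ else a$tier
    refs[[i]] <- if (nrow(a$evidence) > 0L)
      paste(a$evidence$source_id, collapse = ";") else NA_character_
  }
  variants$tier <- tier
  variants$evidence_refs <- refs
  variants
}

#' Low-VAF rescue for known cancer genes
#'
#' Variants at or above the VAF threshold pass; sub-threshold variants in a
#' known cancer gene with adequate total read depth are rescued (flagged)
#' rather than dropped, mirroring manual review of low-VAF calls in cancer
#' genes; the rest are dropped. The three outputs partition the input.
#'
#' @param variants data.frame with gene, vaf and depth columns.
#' @param cancerGenes character vector of cancer gene symbols (typically
#'   `kbGeneSet(kb, "cancer_census")`).
#' @param vafThreshold VAF below which a variant needs rescue (default 0.15;
#'   a VAF of exactly the threshold passes).
#' @param minDepth minimum total read count for rescue (default 40).
#' @return list with data.frames `pass_main`, `rescued` (with
#'   `rescue_flag = TRUE`) and `dropped`.
#' @export
rescueLowVaf <- function(variants, cancerGenes, vafThreshold = 0.15,
                         minDepth = 40L) {
  pass <- variants$vaf >= vafThreshold
  resc <- !pass & .normGene(variants$gene) %in% .normGene(cancerGenes) &
    variants$depth >= minDepth
  drop <- !pass & !resc
  out <- list(pass_main = variants[pass, , drop = FALSE],
              rescued = variants[resc, , drop = FALSE],
              dropped = variants[drop, , drop = FALSE])
  out$pass_main$rescue_flag <- rep(FALSE, nrow(out$pass_main))
  out$rescued$rescue_flag <- rep(TRUE, nrow(out$rescued))
  message(sprintf("VAF filter: %d pass, %d rescued (cancer gene, depth >= %d), %d dropped",
                  sum(pass), sum(resc), minDepth, sum(drop)))
  out
}
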