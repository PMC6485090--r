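.LEVEL_ORDER <- stats::setNames(seq_along(.EVIDENCE_LEVELS), .EVIDENCE_LEVELS)

# chemotherapies / immunotherapies, excluded when emulating a
# molecularly-targeted-only scope
.NON_TARGETED <- c("TEMOZOLOMIDE", "DOCETAXEL", "PACLITAXEL",
                   "PEMBROLIZUMAB", "NIVOLUMAB", "RINDOPEPIMUT", "CART")

.emptyOptions <- function() {
  data.frame(sample_id = character(), drugs = character(),
             targets = character(), target_gene = character(),
             target_class = character(), target_tier = integer(),
             target_consequence = character(), evidence_level = character(),
             trial_ids = character(), rationale = character(),
             stringsAsFactors = FALSE)
}

#' Match findings to therapy options
#'
#' For every tiered SNV/indel (Tiers 1--3), prioritized CNV and actionable
#' SV finding, emits one therapy option per compatible drug association in
#' the knowledge base. Tier-4-only findings emit nothing (VUS in census
#' genes are recorded but not matched to drugs). Duplicate
#' (sample, drug, target) triples are collapsed.
#'
#' @param findings data.frame with columns sample_id, gene,
#'   alteration_class (`snv`/`gain`/`loss`/`sv`/`burden`), variant_spec and
#'   optionally tier (SNVs), priority_rank (CNVs), consequence.
#' @param kb a [KnowledgeBase-class].
#' @param restrictTargeted drop chemotherapy/immunotherapy options, keeping
#'   only molecularly targeted drugs (default FALSE).
#' @return options data.frame (one row per drug--target association) with
#'   rationale `"direct_target"`. Burden rows are ignored here; see
#'   [applyHypermutationRule()].
#' @export
matchTherapies <- function(findings, kb, restrictTargeted = FALSE) {
  opts <- list()
  for (i in seq_len(nrow(findings))) {
    f <- findings[i, ]
    cls <- f$alteration_class
    if (cls == "burden") next
    if (cls == "snv") {
      tier <- if ("tier" %in% names(findings)) f$tier else NA_integer_
      if (is.na(tier) || tier > 3L) next
    }
    if (cls %in% c("gain", "loss") && "priority_rank" %in% names(findings) &&
        is.na(f$priority_rank)) next
    dr <- queryDrugs(kb, f$gene, cls, f$variant_spec)
    if (nrow(dr) == 0L) next
    target <- paste0(.normGene(f$gene), ":",
                     .normSpec(f$variant_spec %||% cls))
    opts[[length(opts) + 1L]] <- data.frame(
      sample_id = f$sample_id, drugs = dr$drug, targets = target,
      target_gene = .normGene(f$gene), target_class = cls,
      target_tier = if ("tier" %in% names(findings)) f$tier else NA_integer_,
      target_consequence = if ("consequence" %in% names(findings))
        f$consequence else NA_character_,
      evidence_level = dr$evidence_level, trial_ids = dr$trial_ids,
      rationale = "direct_target", stringsAsFactors = FALSE)
  }
  if (length(opts) == 0L) return(.emptyOptions())
  out <- do.call(rbind, opts)
  if (restrictTargeted) out <- out[!out$drugs %in% .NON_TARGETED, ,
                                   drop = FALSE]
  out <- out[!duplicated(out[, c("sample_id", "drugs", "targets")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Suggest same-pathway combination therapies
#'
#' When two or more distinct genes with direct therapy options fall in one
#' pathway of the knowledge base's pathway map (e.g. an upstream RTK gain
#' plus a downstream suppressor loss), a combination option pairing one drug
#' per finding is emitted. The rationale is `combination_same_pathway` when
#' the hit genes span upstream and downstream roles, and
#' `combination_parallel_arms` when two or more hit genes are parallel arms
#' of the pathway.
#'
#' @param options direct-target options from [matchTherapies()].
#' @param findings the findings table the options were matched from.
#' @param kb a [KnowledgeBase-class].
#' @return data.frame of combination options (drugs joined with `"+"`),
#'   possibly empty.
#' @export
suggestCombinations <- function(options, findings, kb) {
  pw <- kbPathways(kb)
  combos <- list()
  direct <- options[options$rationale == "direct_target", , drop = FALSE]
  for (sid in unique(direct$sample_id)) {
    so <- direct[direct$sample_id == sid, , drop = FALSE]
    for (p in unique(pw$pathway)) {
      members <- pw[pw$pathway == p, , drop = FALSE]
      hitGenes <- intersect(members$gene, unique(so$target_gene))
      if (length(hitGenes) < 2L) next
      pick <- lapply(hitGenes, function(g) {
        cand <- so[so$target_gene == g, , drop = FALSE]
        cand <- cand[order(.LEVEL_ORDER[cand$evidence_level], cand$drugs,
                           method = "radix"), , drop = FALSE]
        cand[1L, ]
      })
      pick <- do.call(rbind, pick)
      roles <- members$role[match(hitGenes, members$gene)]
      rationale <- if (sum(roles == "parallel_arm") >= 2L)
        "combination_parallel_arms" else "combination_same_pathway"
      trials <- unique(unlist(strsplit(pick$trial_ids[!is.na(pick$trial_ids)],
                                       ";")))
      combos[[length(combos) + 1L]] <- data.frame(
        sample_id = sid, drugs = paste(pick$drugs, collapse = "+"),
        targets = paste(pick$targets, collapse = "+"),
        target_gene = paste(hitGenes, collapse = "+"),
        target_class = "combination",
        target_tier = suppressWarnings(min(pick$target_tier, na.rm = TRUE)),
        target_consequence = NA_character_,
        evidence_level = .EVIDENCE_LEVELS[[
          max(.LEVEL_ORDER[pick$evidence_level])]],
        trial_ids = if (length(trials)) paste(sort(trials), collapse = ";")
                    else NA_character_,
        rationale = rationale, stringsAsFactors = FALSE)
    }
  }
  if (length(combos) == 0L) return(.emptyOptions())
  out <- do.call(rbind, combos)
  out$target_tier[!is.finite(out$target_tier)] <- NA_integer_
  rownames(out) <- NULL
  out
}

#' Mutation burden of a sample
#'
#' Summarizes the exonic SNV burden and the sample's mismatch-repair (MMR)
#' status. An MMR hit is any SNV/indel finding with a truncating or
#' splice-disrupting consequence (nonsense, frameshift, splice_site), or a
#' homozygous loss, in an MMR-set gene.
#'
#' @param sampleId sample identifier.
#' @param exonicSnvCount exonic SNV count of the sample.
#' @param findings the sample's findings table (may be empty).
#' @param kb a [KnowledgeBase-class] with an `mmr_genes` gene set.
#' @return list sample_id, exonic_snv_count, mmr_hits (character vector of
#'   gene symbols).
#' @export
mutationBurden <- function(sampleId, exonicSnvCount, findings, kb) {
  mmr <- kbGeneSet(kb, "mmr_genes")
  f <- findings[findings$sample_id == sampleId, , drop = FALSE]
  hitSnv <- f$alteration_class == "snv" &
    (f$consequence %||% NA) %in% c("nonsense", "frameshift", "splice_site") &
    .normGene(f$gene) %in% mmr
  hitLoss <- f$alteration_class == "loss" & .normGene(f$gene) %in% mmr &
    ("copy_class" %in% names(f) & (f$copy_class %||% "") == "homozygous_loss")
  list(sample_id = sampleId, exonic_snv_count = exonicSnvCount,
       mmr_hits = unique(.normGene(f$gene[hitSnv | hitLoss])))
}

#' Hypermutation checkpoint-inhibitor rule
#'
#' A sample is hypermutant when its exonic SNV count exceeds
#' `max(absoluteFloor, foldOverMedian * cohortMedian)`. A hypermutant sample
#' with at least one disrupted MMR gene receives a checkpoint-inhibitor
#' option (drug associations under the knowledge base's `TMB_HIGH` key) with
#' rationale `hypermutation_checkpoint`; both conditions are required.
#'
#' @param burden output of [mutationBurden()].
#' @param cohortMedian median exonic SNV count over the cohort.
#' @param kb a [KnowledgeBase-class].
#' @param absoluteFloor absolute count floor (default 1000).
#' @param foldOverMedian fold over the cohort median (default 5).
#' @return options data.frame (zero rows when the rule does not fire).
#' @export
applyHypermutationRule <- function(burden, cohortMedian, kb,
                                   absoluteFloor = 1000,
                                   foldOverMedian = 5) {
  threshold <- max(absoluteFloor, foldOverMedian * cohortMedian)
  hyper <- burden$exonic_snv_count > threshold
  if (!hyper || length(burden$mmr_hits) == 0L) return(.emptyOptions())
  dr <- queryDrugs(kb, "TMB_HIGH", "expression")
  if (nrow(dr) == 0L) return(.emptyOptions())
  data.frame(
    sample_id = burden$sample_id, drugs = dr$drug,
    targets = paste0("TMB_HIGH:", burden$exonic_snv_count),
    target_gene = "TMB_HIGH", target_class = "burden",
    target_tier = NA_integer_, target_consequence = NA_character_,
    evidence_level = dr$evidence_level, trial_ids = dr$trial_ids,
    rationale = "hypermutation_checkpoint", stringsAsFactors = FALSE)
}

#' Rank therapy options
#'
#' Stable sort by evidence level (approved in the study disease first, then
#' approved in another disease, clinical trial, preclinical), then by the
#' tier of the best target (unknown tiers last), then alphabetically by
#' drug; ties keep input order.
#'
#' @param options options data.frame.
#' @return reordered options with a `rank` column (1 = strongest).
#' @export
rankTherapies <- function(options) {
  if (nrow(options) == 0L) { options$rank <- integer(0); return(options) }
  tier <- options$target_tier
  tier[is.na(tier)] <- 99L
  ord <- order(.LEVEL_ORDER[options$evidence_level], tier, options$drugs,
               method = "radix")
  out <- options[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Distribution of therapy associations over finding types
#'
#' Fraction of direct therapy associations attributable to SNVs, CNVs,
#' indels and SVs. SNV targets with frameshift or in-frame indel
#' consequences count as indels; burden-driven (checkpoint) options are
#' untyped and excluded from the denominator.
#'
#' @param options options data.frame from [matchTherapies()] (and friends).
#' @return named numeric vector (SNV, CNV, Indel, SV) summing to 1 over
#'   typed associations, with attributes `n` (typed association count) and
#'   `empty` (TRUE when there are none; all fractions 0).
#' @export
summarizeAssociationTypes <- function(options) {
  type <- rep(NA_character_, nrow(options))
  isIndel <- options$target_class == "snv" &
    options$target_consequence %in% c("frameshift", "inframe_indel")
  type[options$target_class == "snv"] <- "SNV"
  type[isIndel] <- "Indel"
  type[options$target_class %in% c("gain", "loss")] <- "CNV"
  type[options$target_class == "sv"] <- "SV"
  type <- type[!is.na(type)]
  out <- c(SNV = 0, CNV = 0, Indel = 0, SV = 0)
  if (length(type) > 0L) {
    tab <- table(factor(type, levels = names(out)))
    out <- as.numeric(tab) / length(type)
    names(out) <- c("SNV", "CNV", "Indel", "SV")
  }
  attr(out, "n") <- length(type)
  attr(out, "empty") <- length(type) == 0L
  out
}
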