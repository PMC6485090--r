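#' @importFrom GenomicRanges GRanges findOverlaps width pintersect
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Purity-corrected copy number
#'
#' Inverts the two-population mixture `observed = purity * tumor +
#' (1 - purity) * normal` to recover the tumor copy number:
#' `corrected = (observed - normal * (1 - purity)) / purity`, floored at 0.
#'
#' @param observedCn observed (bulk) copy number, >= 0.
#' @param purity tumor purity in (0, 1].
#' @param normalCn copy number of admixed normal cells (default 2).
#' @return corrected tumor copy number (vectorized).
#' @examples
#' correctCopyNumber(4, 0.5)   # 6
#' @export
correctCopyNumber <- function(observedCn, purity, normalCn = 2) {
  if (any(purity <= 0 | purity > 1))
    stop("purity must be in (0, 1]", call. = FALSE)
  pmax(0, (observedCn - normalCn * (1 - purity)) / purity)
}

.segGRanges <- function(chrom, start, end) {
  # 0-based half-open -> IRanges 1-based closed
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
}

.geneSpans <- function(model) {
  genes <- unique(model$gene)
  do.call(rbind, lapply(genes, function(g) {
    ex <- model[model$gene == g, , drop = FALSE]
    data.frame(gene = g, chrom = ex$chrom[[1L]], start = min(ex$start),
               end = max(ex$end), stringsAsFactors = FALSE)
  }))
}

#' Genes overlapping a genomic segment
#'
#' Intervals are 0-based half-open; a gene is reported on >= 1 bp overlap,
#' so a segment ending exactly at a gene's start does not include it.
#'
#' @param chrom,start,end segment interval (0-based half-open).
#' @param model exon-level gene model.
#' @return character vector of gene symbols.
#' @export
genesInSegment <- function(chrom, start, end, model) {
  if (end <= start) return(character(0))
  spans <- .geneSpans(model)
  spans <- spans[spans$chrom == chrom, , drop = FALSE]
  if (nrow(spans) == 0L) return(character(0))
  hits <- GenomicRanges::findOverlaps(
    .segGRanges(chrom, start, end),
    .segGRanges(spans$chrom, spans$start, spans$end))
  spans$gene[S4Vectors::subjectHits(hits)]
}

.copyClass <- function(cn, ploidy, ampThreshold = 5, band = 0.5) {
  ifelse(cn < 0.5, "homozygous_loss",
  ifelse(cn < 1.5, "heterozygous_loss",
  ifelse(cn >= ampThreshold, "focal_amplification",
  ifelse(abs(cn - ploidy) <= band, "neutral",
  ifelse(cn > ploidy, "gain", "heterozygous_loss")))))
}

#' Classify copy-number segments
#'
#' Purity-corrects each segment's copy number, assigns a copy class
#' (homozygous loss < 0.5 copies; heterozygous loss < 1.5 or below the
#' ploidy-anchored neutral band; neutral within ploidy +/- 0.5;
#' gain above the band; amplification at >= 5 copies), determines focality
#' (arm-level when the segment covers at least half of its chromosome arm),
#' intersects with the gene model, and assigns the priority rank:
#' rank 1 = homozygous loss or high-copy amplification, rank 2 = other focal
#' gains/losses, rank 3 = arm-level gains and heterozygous losses; neutral
#' segments are unranked. Anchoring the neutral band at the sample ploidy
#' keeps hyperploid genomes from being called gained genome-wide.
#'
#' @param segments data.frame of segments (see [readCnvSegments()]).
#' @param purity tumor purity in (0, 1].
#' @param ploidy sample ploidy anchoring the neutral band (default 2).
#' @param arms chromosome-arm table (chrom, start, end, arm), e.g.
#'   [toyArmTable()].
#' @param model exon-level gene model for the genes-hit annotation.
#' @param ampThreshold copies at or above which a segment is an
#'   amplification (default 5).
#' @param neutralBand half-width of the copy-neutral band (default 0.5).
#' @param armFraction fraction of an arm a segment must cover to be
#'   arm-level (default 0.5).
#' @return `segments` with corrected_cn, copy_class, focality, genes_hit
#'   (`;`-joined) and priority_rank (NA for neutral) columns.
#' @export
classifySegments <- function(segments, purity, ploidy = 2, arms, model,
                             ampThreshold = 5, neutralBand = 0.5,
                             armFraction = 0.5) {
  n <- nrow(segments)
  corrected <- correctCopyNumber(segments$observed_cn, purity)
  cls <- .copyClass(corrected, ploidy, ampThreshold, neutralBand)
  focality <- character(n); genesHit <- character(n)
  for (i in seq_len(n)) {
    seg <- segments[i, ]
    armRows <- arms[arms$chrom == seg$chrom, , drop = FALSE]
    ov <- pmin(seg$end, armRows$end) - pmax(seg$start, armRows$start)
    if (nrow(armRows) == 0L || all(ov <= 0)) {
      focality[[i]] <- "focal"
    } else {
      k <- which.max(ov)
      frac <- ov[[k]] / (armRows$end[[k]] - armRows$start[[k]])
      focality[[i]] <- if (frac >= armFraction) "arm_level" else "focal"
    }
    genesHit[[i]] <- paste(genesInSegment(seg$chrom, seg$start, seg$end,
                                          model), collapse = ";")
  }
  rank <- ifelse(cls %in% c("homozygous_loss", "focal_amplification"), 1L,
          ifelse(cls == "neutral", NA_integer_,
          ifelse(focality == "focal", 2L, 3L)))
  segments$corrected_cn <- corrected
  segments$copy_class <- cls
  segments$focality <- focality
  segments$genes_hit <- genesHit
  segments$priority_rank <- rank
  segments
}

#' Order classified CNV findings by priority
#'
#' Stable sort by priority rank, then by decreasing departure from the
#' diploid state `|corrected_cn - 2|`. Neutral (unranked) segments are
#' dropped. Rank-3 findings (arm-level gains, heterozygous losses) are kept
#' by default --- the curation behavior that also reports lower-copy
#' changes --- and dropped with `includeLowPriority = FALSE` to emulate a
#' stricter automated scope.
#'
#' @param classified output of [classifySegments()].
#' @param includeLowPriority keep rank-3 findings (default TRUE).
#' @return reordered subset of `classified`.
#' @export
prioritizeFindings <- function(classified, includeLowPriority = TRUE) {
  keep <- !is.na(classified$priority_rank)
  if (!includeLowPriority) keep <- keep & classified$priority_rank < 3L
  out <- classified[keep, , drop = FALSE]
  ord <- order(out$priority_rank, -abs(out$corrected_cn - 2),
               method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach actionable structural variants as rank-1 findings
#'
#' Intragenic deletions and fusions disrupting or activating an actionable
#' gene are carried alongside CNV findings at the top priority rank (such
#' events drove therapy options for EGFRvIII-like alterations).
#'
#' @param svRecords SV data.frame (see [readSv()]).
#' @param actionableGenes character vector of actionable gene symbols.
#' @return data.frame sample_id, gene, sv_type, priority_rank (1).
#' @export
svFindings <- function(svRecords, actionableGenes) {
  if (nrow(svRecords) == 0L)
    return(data.frame(sample_id = character(), gene = character(),
                      sv_type = character(), priority_rank = integer(),
                      stringsAsFactors = FALSE))
  genes <- strsplit(svRecords$genes_hit, ";", fixed = TRUE)
  out <- data.frame(
    sample_id = rep(svRecords$sample_id, lengths(genes)),
    gene = .normGene(unlist(genes, use.names = FALSE)),
    sv_type = rep(svRecords$sv_type, lengths(genes)),
    stringsAsFactors = FALSE)
  out <- out[out$gene %in% .normGene(actionableGenes), , drop = FALSE]
  out$priority_rank <- rep(1L, nrow(out))
  rownames(out) <- NULL
  out
}
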