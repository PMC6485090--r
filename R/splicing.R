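#' Percent spliced in (PSI)
#'
#' The literal ratio of reads supporting an unannotated alternative splicing
#' event to reads supporting the annotated (canonical) event, as a percent:
#' `psi = 100 * alt / canonical`. Note this convention can exceed 100% (it is
#' not `alt / (alt + canonical)`; see [callSpliceEvents()] for the inclusion
#' convention switch). With zero canonical reads but positive alternative
#' reads the ratio is undefined-high and flagged `saturated`; with both
#' counts zero there is no event and psi is `NA`.
#'
#' @param altReads reads supporting the unannotated event (>= 0).
#' @param canonicalReads reads supporting the annotated event (>= 0).
#' @param convention `"ratio"` (default, alt/canonical) or `"inclusion"`
#'   (alt/(alt+canonical)).
#' @return list with numeric `psi` (percent) and logical `saturated`.
#' @examples
#' computePsi(5, 50)$psi    # 10
#' @export
computePsi <- function(altReads, canonicalReads, convention = c("ratio", "inclusion")) {
  convention <- match.arg(convention)
  if (any(altReads < 0) || any(canonicalReads < 0))
    stop("read counts must be >= 0", call. = FALSE)
  denom <- if (convention == "ratio") canonicalReads
           else altReads + canonicalReads
  psi <- 100 * altReads / denom
  saturated <- denom == 0 & altReads > 0
  psi[saturated] <- NA_real_
  psi[denom == 0 & altReads == 0] <- NA_real_
  list(psi = psi, saturated = saturated)
}

# coordinate-sorted exons of one gene
.geneExons <- function(model, gene) {
  ex <- model[toupper(model$gene) == toupper(gene), , drop = FALSE]
  ex[order(ex$start), , drop = FALSE]
}

#' Annotated (adjacent-exon) junctions of a gene model
#'
#' One row per intron: 1-based first/last intronic base flanked by
#' consecutive exons in coordinate order.
#'
#' @param model exon-level gene model.
#' @return data.frame gene, chrom, donor_pos, acceptor_pos.
#' @export
annotatedJunctions <- function(model) {
  out <- lapply(unique(model$gene), function(g) {
    ex <- .geneExons(model, g)
    if (nrow(ex) < 2L) return(NULL)
    i <- seq_len(nrow(ex) - 1L)
    data.frame(gene = g, chrom = ex$chrom[[1L]],
               donor_pos = ex$end[i] + 1L,       # first intronic base
               acceptor_pos = ex$start[i + 1L],  # last intronic base
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

.geneForJunction <- function(model, chrom, donor, acceptor) {
  spans <- do.call(rbind, lapply(unique(model$gene), function(g) {
    ex <- model[model$gene == g, , drop = FALSE]
    data.frame(gene = g, chrom = ex$chrom[[1L]],
               start = min(ex$start), end = max(ex$end))
  }))
  hit <- spans$chrom == chrom & donor > spans$start & acceptor <= spans$end
  if (!any(hit)) NA_character_ else spans$gene[which(hit)[1L]]
}

.skippedExons <- function(ex, donor, acceptor) {
  i <- match(donor, ex$end + 1L)        # donor anchored at 3' end of exon i
  j <- match(acceptor, ex$start)        # acceptor at 5' start of exon j
  if (is.na(i) || is.na(j) || j <= i + 1L) return(integer(0))
  ex$exon_number[(i + 1L):(j - 1L)]
}

#' Call alternative splice events from junction counts
#'
#' Junctions that do not match any annotated intron of their gene are
#' unannotated. The canonical denominator is the read count (same sample) of
#' the annotated junction sharing the event's donor site, falling back to the
#' annotated junction sharing its acceptor site. Events are emitted when the
#' PSI exceeds the threshold (strictly) or is saturated, and the gene is in
#' the cancer-census set. When both junction ends align to exon boundaries
#' the skipped exon numbers are recorded.
#'
#' @param junctions junction data.frame (see [readJunctions()]).
#' @param model exon-level gene model.
#' @param censusGenes character vector of cancer-census gene symbols.
#' @param minPsiPercent PSI threshold in percent (default 10; events at
#'   exactly the threshold are not emitted).
#' @param convention PSI convention, see [computePsi()].
#' @return data.frame of splice events: sample_id, gene, donor_pos,
#'   acceptor_pos, alt_reads, canonical_reads, psi, saturated, skipped_exons
#'   (`;`-joined), sv_corroborated (initialized FALSE).
#' @export
callSpliceEvents <- function(junctions, model, censusGenes,
                             minPsiPercent = 10, convention = "ratio") {
  annot <- annotatedJunctions(model)
  censusGenes <- toupper(censusGenes)
  events <- list()
  nOrphan <- 0L
  for (i in seq_len(nrow(junctions))) {
    jx <- junctions[i, ]
    g <- .geneForJunction(model, jx$chrom, jx$donor_pos, jx$acceptor_pos)
    if (is.na(g)) { nOrphan <- nOrphan + 1L; next }
    ga <- annot[annot$gene == g, , drop = FALSE]
    isAnnot <- any(ga$donor_pos == jx$donor_pos &
                     ga$acceptor_pos == jx$acceptor_pos)
    if (isAnnot || jx$read_count == 0) next
    # canonical junction sharing the donor, else the acceptor
    canDonor <- ga[ga$donor_pos == jx$donor_pos, , drop = FALSE]
    canAcc <- ga[ga$acceptor_pos == jx$acceptor_pos, , drop = FALSE]
    can <- if (nrow(canDonor) > 0L) canDonor[1L, ] else
           if (nrow(canAcc) > 0L) canAcc[1L, ] else NULL
    canonicalReads <- if (is.null(can)) 0 else {
      m <- junctions$sample_id == jx$sample_id &
        junctions$chrom == can$chrom &
        junctions$donor_pos == can$donor_pos &
        junctions$acceptor_pos == can$acceptor_pos
      if (any(m)) sum(junctions$read_count[m]) else 0
    }
    p <- computePsi(jx$read_count, canonicalReads, convention)
    if (!(toupper(g) %in% censusGenes)) next
    if (!p$saturated && (is.na(p$psi) || p$psi <= minPsiPercent)) next
    skipped <- .skippedExons(.geneExons(model, g), jx$donor_pos,
                             jx$acceptor_pos)
    events[[length(events) + 1L]] <- data.frame(
      sample_id = jx$sample_id, gene = g, donor_pos = jx$donor_pos,
      acceptor_pos = jx$acceptor_pos, alt_reads = jx$read_count,
      canonical_reads = canonicalReads, psi = p$psi, saturated = p$saturated,
      skipped_exons = paste(skipped, collapse = ";"),
      sv_corroborated = FALSE, stringsAsFactors = FALSE)
  }
  if (nOrphan > 0L)
    warning(nOrphan, " junction(s) outside every modeled gene skipped",
            call. = FALSE)
  if (length(events) == 0L)
    return(data.frame(sample_id = character(), gene = character(),
                      donor_pos = integer(), acceptor_pos = integer(),
                      alt_reads = numeric(), canonical_reads = numeric(),
                      psi = numeric(), saturated = logical(),
                      skipped_exons = character(), sv_corroborated = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Detect exon-skipping junctions in one gene
#'
#' Any junction connecting the 3' end of exon *i* to the 5' start of exon
#' *j* with *j* > *i* + 1 (in coordinate order) and read support at or above
#' the floor yields an event whose skipped exons are *i*+1 .. *j*-1 --- the
#' pattern of EGFRvIII-like intragenic deletions read out from RNA junctions.
#'
#' @param junctions junction data.frame.
#' @param model exon-level gene model.
#' @param gene gene symbol to scan.
#' @param minReads junction read-support floor (default 5, the RNA
#'   sufficiency precedent).
#' @return data.frame like [callSpliceEvents()] (psi columns NA; one row per
#'   skipping junction).
#' @export
detectExonSkipping <- function(junctions, model, gene, minReads = 5L) {
  ex <- .geneExons(model, gene)
  events <- list()
  for (i in seq_len(nrow(junctions))) {
    jx <- junctions[i, ]
    if (jx$chrom != ex$chrom[[1L]] || jx$read_count < minReads) next
    skipped <- .skippedExons(ex, jx$donor_pos, jx$acceptor_pos)
    if (length(skipped) == 0L) next
    events[[length(events) + 1L]] <- data.frame(
      sample_id = jx$sample_id, gene = ex$gene[[1L]],
      donor_pos = jx$donor_pos, acceptor_pos = jx$acceptor_pos,
      alt_reads = jx$read_count, canonical_reads = NA_real_,
      psi = NA_real_, saturated = FALSE,
      skipped_exons = paste(skipped, collapse = ";"),
      sv_corroborated = FALSE, stringsAsFactors = FALSE)
  }
  if (length(events) == 0L)
    return(data.frame(sample_id = character(), gene = character(),
                      donor_pos = integer(), acceptor_pos = integer(),
                      alt_reads = numeric(), canonical_reads = numeric(),
                      psi = numeric(), saturated = logical(),
                      skipped_exons = character(), sv_corroborated = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Corroborate splice events with DNA structural variants
#'
#' An exon-skipping event is corroborated when a DNA deletion call in the
#' same sample spans all of its skipped exons (full-span containment;
#' partial overlap does not corroborate).
#'
#' @param events splice-event data.frame with `skipped_exons`.
#' @param svRecords SV data.frame (see [readSv()]).
#' @param model exon-level gene model (to locate skipped-exon coordinates).
#' @return `events` with `sv_corroborated` updated.
#' @export
corroborateWithSv <- function(events, svRecords, model) {
  if (nrow(events) == 0L) return(events)
  for (i in seq_len(nrow(events))) {
    skipped <- suppressWarnings(
      as.integer(strsplit(events$skipped_exons[[i]], ";")[[1]]))
    skipped <- skipped[!is.na(skipped)]
    if (length(skipped) == 0L) next
    ex <- .geneExons(model, events$gene[[i]])
    ex <- ex[ex$exon_number %in% skipped, , drop = FALSE]
    if (nrow(ex) == 0L) next
    dels <- svRecords[svRecords$sv_type == "DEL" &
                        svRecords$sample_id == events$sample_id[[i]] &
                        svRecords$chrom_a == ex$chrom[[1L]] &
                        svRecords$chrom_b == ex$chrom[[1L]], , drop = FALSE]
    if (nrow(dels) == 0L) next
    lo <- pmin(dels$pos_a, dels$pos_b); hi <- pmax(dels$pos_a, dels$pos_b)
    covers <- lo <= min(ex$start) + 1L & hi >= max(ex$end)
    events$sv_corroborated[[i]] <- any(covers)
  }
  events
}
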