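#' Modified z-score of expression against a reference cohort
#'
#' `z = (tpm - median_tpm) / mad_tpm`, where the median and MAD are taken per
#' gene over the reference cohort and the MAD is raw (no 1.4826
#' normal-consistency constant). When the reference MAD is zero the score is
#' undefined (`NA`), not infinite: a constant reference gene cannot support
#' outlier calls.
#'
#' @param tpm sample TPM value(s), non-negative.
#' @param medianTpm reference cohort median TPM.
#' @param madTpm reference cohort raw median absolute deviation (>= 0).
#' @return numeric z (NA where `madTpm == 0`).
#' @examples
#' modifiedZscore(5, 3, 1)   # 2
#' @export
modifiedZscore <- function(tpm, medianTpm, madTpm) {
  if (any(tpm < 0, na.rm = TRUE))
    stop("negative TPM", call. = FALSE)
  if (any(madTpm < 0, na.rm = TRUE))
    stop("MAD must be >= 0", call. = FALSE)
  z <- (tpm - medianTpm) / madTpm
  z[madTpm == 0] <- NA_real_
  z
}

#' Per-gene reference statistics (median and raw MAD of TPM)
#'
#' @param expression gene x sample TPM matrix with at least two samples.
#' @return data.frame gene, median_tpm, mad_tpm, cohort_n.
#' @export
buildReferenceStats <- function(expression) {
  if (ncol(expression) < 2L)
    stop("reference cohort needs >= 2 samples (MAD degenerate)", call. = FALSE)
  med <- apply(expression, 1L, stats::median)
  mad <- apply(expression, 1L, stats::mad, constant = 1)
  data.frame(gene = rownames(expression), median_tpm = unname(med),
             mad_tpm = unname(mad), cohort_n = ncol(expression),
             stringsAsFactors = FALSE)
}

#' Score a sample's expression against reference statistics
#'
#' @param tpm named vector (or one-sample matrix column) of TPM per gene.
#' @param refStats output of [buildReferenceStats()].
#' @param outlierZ absolute z at or beyond which a gene is flagged as an
#'   expression outlier in reports (default 2; reporting-only).
#' @return data.frame gene, tpm, z, outlier.
#' @export
expressionAnnotation <- function(tpm, refStats, outlierZ = 2) {
  i <- match(refStats$gene, names(tpm))
  keep <- !is.na(i)
  rs <- refStats[keep, , drop = FALSE]
  v <- unname(tpm[i[keep]])
  z <- modifiedZscore(v, rs$median_tpm, rs$mad_tpm)
  data.frame(gene = rs$gene, tpm = v, z = z,
             outlier = !is.na(z) & abs(z) >= outlierZ,
             stringsAsFactors = FALSE)
}

#' RNA support for a DNA variant
#'
#' Computes the RNA VAF at a variant locus and flags whether coverage is
#' sufficient (default: at least 5 total RNA reads) for use in DNA--RNA
#' concordance analyses.
#'
#' @param rnaAltReads alternate-allele RNA read count.
#' @param rnaTotalReads total RNA read count at the locus.
#' @param minReads sufficiency floor (default 5).
#' @return list rna_alt_reads, rna_total_reads, rna_vaf (NA when total is 0),
#'   sufficient.
#' @export
rnaVariantSupport <- function(rnaAltReads, rnaTotalReads, minReads = 5L) {
  if (rnaAltReads < 0 || rnaTotalReads < 0)
    stop("read counts must be >= 0", call. = FALSE)
  if (rnaAltReads > rnaTotalReads)
    stop("alt reads exceed total reads", call. = FALSE)
  list(rna_alt_reads = rnaAltReads, rna_total_reads = rnaTotalReads,
       rna_vaf = if (rnaTotalReads > 0) rnaAltReads / rnaTotalReads
                 else NA_real_,
       sufficient = rnaTotalReads >= minReads)
}

#' DNA--RNA VAF correlation
#'
#' Pearson correlation between DNA and RNA variant allele fractions over
#' variants with sufficient RNA coverage. The p-value uses the usual
#' t-approximation and is reported for context only.
#'
#' @param dnaVaf,rnaVaf numeric vectors of paired allele fractions (already
#'   filtered to sufficient coverage).
#' @return list r, n, p_value; `r` is NA (flagged undefined) with fewer than
#'   3 pairs or zero variance in either vector.
#' @export
dnaRnaVafCorrelation <- function(dnaVaf, rnaVaf) {
  stopifnot(length(dnaVaf) == length(rnaVaf))
  keep <- !is.na(dnaVaf) & !is.na(rnaVaf)
  x <- dnaVaf[keep]; y <- rnaVaf[keep]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, n = n, p_value = NA_real_))
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(r = r, n = n, p_value = p)
}
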