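#' @importFrom vcfR read.vcfR
NULL

.CONSEQUENCES <- c("missense", "nonsense", "frameshift", "inframe_indel",
                   "splice_site", "promoter", "synonymous", "other")

.consequenceMap <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      df <- .readTsv(.extdata("consequence_map.tsv"))
      cache <<- stats::setNames(df$consequence, df$snpeff_term)
    }
    cache
  }
})

#' Map SnpEff-style consequence terms to the pipeline's classes
#'
#' @param terms character vector of SnpEff effect terms
#'   (e.g. `"missense_variant"`, `"stop_gained"`). Terms already in the
#'   pipeline's own vocabulary pass through. Unmapped terms become `"other"`
#'   with a warning.
#' @return character vector of consequence classes.
#' @export
mapConsequence <- function(terms) {
  m <- .consequenceMap()
  out <- unname(m[terms])
  passthrough <- is.na(out) & terms %in% .CONSEQUENCES
  out[passthrough] <- terms[passthrough]
  if (anyNA(out)) {
    warning("unmapped consequence term(s) set to 'other': ",
            paste(unique(terms[is.na(out)]), collapse = ", "), call. = FALSE)
    out[is.na(out)] <- "other"
  }
  out
}

.parseAnn <- function(info) {
  # SnpEff ANN subfields: Allele|Effect|Impact|Gene|...|HGVS.c|HGVS.p|...
  ann <- sub(".*ANN=([^;]*).*", "\\1", info)
  ann[!grepl("ANN=", info)] <- NA_character_
  first <- vapply(strsplit(ann, ",", fixed = TRUE),
                  function(x) if (length(x)) x[[1]] else NA_character_,
                  character(1))
  fields <- strsplit(first, "|", fixed = TRUE)
  pick <- function(i) vapply(fields, function(f)
    if (length(f) >= i && nzchar(f[[i]])) f[[i]] else NA_character_,
    character(1))
  hgvsp <- sub("^p\\.", "", pick(11L))
  spec <- ifelse(is.na(hgvsp), sub("^c\\.", "c.", pick(10L)), hgvsp)
  list(effect = pick(2L), gene = pick(4L), spec = spec)
}

.numFirst <- function(x) suppressWarnings(
  as.numeric(vapply(strsplit(x, ",", fixed = TRUE),
                    function(p) if (length(p)) p[[1]] else NA_character_,
                    character(1))))

#' Read a somatic (or germline) VCF
#'
#' Parses a single-sample VCF 4.x into a variant table. Positions stay
#' 1-based; multiallelic sites are split into one record per alternate
#' allele. VAF is taken from the `AF` FORMAT tag when present, otherwise
#' derived from `AD` (alt / sum); depth from `DP`, otherwise the `AD` sum.
#' Gene, consequence and variant spec are parsed from a SnpEff-style `ANN`
#' INFO field when present. Records with no usable VAF source are skipped
#' with a warning giving the count.
#'
#' @param path VCF file.
#' @param sampleId sample identifier; defaults to the VCF genotype column
#'   name.
#' @return data.frame with columns sample_id, chrom, pos, ref, alt, gene,
#'   variant_spec, consequence, vaf, depth.
#' @export
readSomaticVcf <- function(path, sampleId = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  empty <- data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      gene = character(), variant_spec = character(),
                      consequence = character(), vaf = numeric(),
                      depth = integer(), stringsAsFactors = FALSE)
  if (is.null(fix) || nrow(fix) == 0L) return(empty)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L)
    stop("VCF has no genotype column: ", path, call. = FALSE)
  if (is.null(sampleId)) sampleId <- colnames(gt)[2L]
  fmt <- strsplit(gt[, 1L], ":", fixed = TRUE)
  val <- strsplit(gt[, 2L], ":", fixed = TRUE)
  getTag <- function(i, tag) {
    j <- match(tag, fmt[[i]])
    if (is.na(j) || j > length(val[[i]])) NA_character_ else val[[i]][[j]]
  }
  ann <- .parseAnn(fix[, "INFO"])
  rows <- vector("list", nrow(fix))
  skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    adStr <- getTag(i, "AD")
    afStr <- getTag(i, "AF")
    dpStr <- getTag(i, "DP")
    ad <- if (is.na(adStr)) NULL else
      suppressWarnings(as.numeric(strsplit(adStr, ",", fixed = TRUE)[[1]]))
    af <- if (is.na(afStr)) NULL else
      suppressWarnings(as.numeric(strsplit(afStr, ",", fixed = TRUE)[[1]]))
    depth <- if (!is.na(dpStr)) suppressWarnings(as.numeric(dpStr))
             else if (!is.null(ad)) sum(ad) else NA_real_
    for (k in seq_along(alts)) {
      vaf <- if (!is.null(af) && length(af) >= k) af[[k]]
             else if (!is.null(ad) && length(ad) >= k + 1L && sum(ad) > 0)
               ad[[k + 1L]] / sum(ad)
             else NA_real_
      if (is.na(vaf)) { skipped <- skipped + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sampleId, chrom = fix[i, "CHROM"],
        pos = as.integer(fix[i, "POS"]), ref = fix[i, "REF"],
        alt = alts[[k]], gene = ann$gene[[i]],
        variant_spec = ann$spec[[i]],
        consequence = if (is.na(ann$effect[[i]])) NA_character_
                      else mapConsequence(ann$effect[[i]]),
        vaf = vaf,
        depth = as.integer(round(depth)),
        stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0L)
    warning(skipped, " record(s) without AF or AD skipped in ", path,
            call. = FALSE)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname readSomaticVcf
#' @export
readGermlineVcf <- readSomaticVcf

#' Write a variant table as a single-sample VCF 4.2
#'
#' Inverse of [readSomaticVcf()]: emits `AD:DP:AF` genotype fields and a
#' SnpEff-style `ANN` INFO entry carrying gene, consequence and variant spec,
#' so read-write-read round-trips the typed records.
#'
#' @param variants data.frame as returned by [readSomaticVcf()] (one sample).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSomaticVcf <- function(variants, path) {
  sid <- unique(variants$sample_id)
  if (length(sid) > 1L)
    stop("writeSomaticVcf writes one sample per file; got ",
         length(sid), call. = FALSE)
  if (length(sid) == 0L) sid <- "SAMPLE"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: 'Allele|Annotation|Impact|Gene_Name|Gene_ID|Feature_Type|Feature_ID|Biotype|Rank|HGVS.c|HGVS.p'\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sid)),
    con)
  if (nrow(variants) > 0L) {
    depth <- as.integer(variants$depth)
    altReads <- as.integer(round(variants$vaf * depth))
    ann <- sprintf("ANN=%s|%s|MODERATE|%s|%s|transcript|%s.1|protein_coding|1/1|c.?|p.%s",
                   variants$alt,
                   ifelse(is.na(variants$consequence), "", variants$consequence),
                   ifelse(is.na(variants$gene), "", variants$gene),
                   ifelse(is.na(variants$gene), "", variants$gene),
                   ifelse(is.na(variants$gene), "", variants$gene),
                   ifelse(is.na(variants$variant_spec), "?",
                          variants$variant_spec))
    gtv <- sprintf("%d,%d:%d:%.6g", depth - altReads, altReads, depth,
                   variants$vaf)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tAD:DP:AF\t%s",
                       variants$chrom, as.integer(variants$pos),
                       variants$ref, variants$alt, ann, gtv), con)
  }
  invisible(path)
}

#' Read copy-number segments
#'
#' Segments use the BED convention: 0-based half-open intervals. Validates
#' `start < end` and `observed_cn >= 0`, reporting the offending line number.
#'
#' @param path TSV with columns sample_id, chrom, start, end, observed_cn and
#'   optionally allele_cn (`"a|b"` or `"."`).
#' @return validated data.frame of segments.
#' @export
readCnvSegments <- function(path) {
  df <- .readTsv(path)
  .requireCols(df, c("sample_id", "chrom", "start", "end", "observed_cn"),
               "cnv segments")
  bad <- which(!(df$start < df$end))
  if (length(bad) > 0L)
    stop("segment start must be < end; line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  bad <- which(df$observed_cn < 0)
  if (length(bad) > 0L)
    stop("observed_cn must be >= 0; line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  if (is.null(df$allele_cn)) df$allele_cn <- NA_character_
  df$allele_cn <- .dotNA(df$allele_cn)
  df
}

#' @rdname readCnvSegments
#' @param segments data.frame of segments.
#' @export
writeCnvSegments <- function(segments, path) {
  seg <- segments[, intersect(c("sample_id", "chrom", "start", "end",
                                "observed_cn", "allele_cn"), names(segments))]
  if (!is.null(seg$allele_cn)) seg$allele_cn[is.na(seg$allele_cn)] <- "."
  .writeTsv(seg, path)
}

#' Read / write a gene-by-sample TPM table
#'
#' The TSV holds a `gene` column followed by one column per sample; values
#' are non-negative TPM.
#'
#' @param path TSV file.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
readExpression <- function(path) {
  df <- .readTsv(path)
  .requireCols(df, "gene", "expression")
  if (anyDuplicated(df$gene)) stop("duplicate gene symbols in ", path,
                                   call. = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  rownames(m) <- df$gene
  if (any(m < 0)) stop("negative TPM in ", path, call. = FALSE)
  m
}

#' @rdname readExpression
#' @param tpm gene x sample matrix.
#' @export
writeExpression <- function(tpm, path) {
  .writeTsv(data.frame(gene = rownames(tpm), tpm, check.names = FALSE), path)
}

#' Read / write splice-junction read counts
#'
#' Junctions are stored unstranded with 1-based intron boundary coordinates
#' (first and last intronic base, STAR `SJ.out.tab` style), requiring
#' `donor_pos < acceptor_pos` and `read_count >= 0`.
#'
#' @param path TSV with columns sample_id, chrom, donor_pos, acceptor_pos,
#'   read_count.
#' @return validated data.frame.
#' @export
readJunctions <- function(path) {
  df <- .readTsv(path)
  .requireCols(df, c("sample_id", "chrom", "donor_pos", "acceptor_pos",
                     "read_count"), "junctions")
  bad <- which(!(df$donor_pos < df$acceptor_pos))
  if (length(bad) > 0L)
    stop("donor_pos must be < acceptor_pos; line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  bad <- which(df$read_count < 0)
  if (length(bad) > 0L)
    stop("read_count must be >= 0; line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  df
}

#' @rdname readJunctions
#' @param junctions data.frame of junction rows.
#' @export
writeJunctions <- function(junctions, path) .writeTsv(junctions, path)

#' Read / write an exon-level gene model
#'
#' Exons use BED-style 0-based half-open coordinates. Per gene, exons must be
#' non-overlapping and `exon_number` must run consecutively from 1 in strand
#' order (so numbering descends along the chromosome for minus-strand genes).
#'
#' @param path TSV with columns gene, chrom, strand, exon_number, start, end.
#' @return validated data.frame.
#' @export
readGeneModel <- function(path) {
  df <- .readTsv(path)
  .requireCols(df, c("gene", "chrom", "strand", "exon_number", "start", "end"),
               "gene model")
  validateGeneModel(df)
  df
}

#' @rdname readGeneModel
#' @param model gene-model data.frame.
#' @export
writeGeneModel <- function(model, path) .writeTsv(model, path)

#' @rdname readGeneModel
#' @export
validateGeneModel <- function(model) {
  for (g in unique(model$gene)) {
    ex <- model[model$gene == g, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (any(ex$end[-nrow(ex)] > ex$start[-1L]))
      stop("overlapping exons in gene ", g, call. = FALSE)
    strand <- ex$strand[[1L]]
    num <- if (strand == "+") ex$exon_number else rev(ex$exon_number)
    if (!identical(as.integer(num), seq_len(nrow(ex))))
      stop("exon_number not consecutive from 1 in strand order for gene ", g,
           call. = FALSE)
  }
  invisible(model)
}

#' Read / write structural-variant records
#'
#' Breakpoints are 1-based; `sv_type` is one of DEL, DUP, INV, TRA, fusion;
#' `genes_hit` is a `;`-separated symbol list.
#'
#' @param path TSV with columns sample_id, chrom_a, pos_a, strand_a, chrom_b,
#'   pos_b, strand_b, sv_type, genes_hit, caller.
#' @return validated data.frame.
#' @export
readSv <- function(path) {
  df <- .readTsv(path)
  .requireCols(df, c("sample_id", "chrom_a", "pos_a", "strand_a", "chrom_b",
                     "pos_b", "strand_b", "sv_type", "genes_hit", "caller"),
               "structural variants")
  ok <- df$sv_type %in% c("DEL", "DUP", "INV", "TRA", "fusion")
  if (!all(ok))
    stop("invalid sv_type at line(s) ",
         paste(which(!ok) + 1L, collapse = ", "), " of ", path, call. = FALSE)
  df
}

#' @rdname readSv
#' @param sv data.frame of SV records.
#' @export
writeSv <- function(sv, path) .writeTsv(sv, path)

#' Bundled desk-scale genome model
#'
#' A compact two-chromosome genome (chr7, chr10; 2.4 Mb each) with 51 toy
#' genes at scaled coordinates, including analogs of the recurrent
#' glioblastoma genes (EGFR, PTEN, CDKN2A, MSH2, TERT, ...) and a pool of
#' decoy genes outside every knowledge-base gene set. `toyArmTable()` returns
#' the matching chromosome-arm table (p/q split at 1.2 Mb).
#'
#' @return `toyGeneModel()`: exon-level gene model data.frame (0-based
#'   half-open); `toyArmTable()`: data.frame chrom, start, end, arm.
#' @export
toyGeneModel <- function() readGeneModel(.extdata("genome", "toy_gene_model.tsv"))

#' @rdname toyGeneModel
#' @export
toyArmTable <- function() {
  df <- .readTsv(.extdata("genome", "toy_arms.tsv"))
  .requireCols(df, c("chrom", "start", "end", "arm"), "arm table")
  df
}
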