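writeVcfLines <- function(lines, path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    lines), path)
  path
}

test_that("VAF is derived from AD when no AF tag is present", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeVcfLines("chr7\t100\t.\tA\tG\t.\tPASS\t.\tAD:DP\t60,40:100", f)
  v <- suppressWarnings(readSomaticVcf(f))
  expect_equal(v$vaf, 0.4)
  expect_equal(v$depth, 100L)
  expect_equal(v$pos, 100L)   # stays 1-based
})

test_that("VCF with zero variant lines yields an empty typed table", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeVcfLines(character(), f)
  v <- suppressWarnings(readSomaticVcf(f))
  expect_equal(nrow(v), 0L)
  expect_true(all(c("vaf", "depth", "gene") %in% names(v)))
})

test_that("multiallelic sites split into one record per alternate allele", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeVcfLines("chr7\t200\t.\tA\tC,T\t.\tPASS\t.\tAD:DP\t50,30,20:100", f)
  v <- readSomaticVcf(f)
  expect_equal(nrow(v), 2L)
  expect_equal(v$alt, c("C", "T"))
  expect_equal(v$vaf, c(0.3, 0.2))
})

test_that("records without any VAF source are skipped with a warning", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeVcfLines(c("chr7\t100\t.\tA\tG\t.\tPASS\t.\tDP\t100",
                  "chr7\t200\t.\tC\tT\t.\tPASS\t.\tAD:DP\t60,40:100"), f)
  expect_warning(v <- readSomaticVcf(f), "skipped")
  expect_equal(nrow(v), 1L)
  expect_equal(v$pos, 200L)
})

test_that("somatic VCF write -> read round-trips the typed records", {
  v0 <- rbind(variantRow("EGFR", "A289V", vaf = 0.35, depth = 200L,
                         chrom = "chr7", pos = 1234L),
              variantRow("MSH2", "c.366+1G>A", vaf = 0.10, depth = 60L,
                         consequence = "splice_site", chrom = "chr10",
                         pos = 777L))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeSomaticVcf(v0, f)
  v1 <- readSomaticVcf(f)
  expect_equal(v1$gene, v0$gene)
  expect_equal(v1$variant_spec, v0$variant_spec)
  expect_equal(v1$consequence, v0$consequence)
  expect_equal(v1$vaf, v0$vaf, tolerance = 1e-5)
  expect_equal(v1$depth, v0$depth)
  expect_equal(v1$pos, v0$pos)
  # read -> write -> read is then the identity on the typed records
  f2 <- withr::local_tempfile(fileext = ".vcf")
  writeSomaticVcf(v1, f2)
  expect_equal(readSomaticVcf(f2), v1, tolerance = 1e-9)
})

test_that("segment reader enforces BED conventions with line numbers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  seg <- data.frame(sample_id = "S1", chrom = "chr10", start = 0L,
                    end = 135000000L, observed_cn = 1.0)
  writeCnvSegments(seg, f)
  s <- readCnvSegments(f)
  expect_equal(s$observed_cn, 1.0)
  bad <- seg; bad$end <- 0L
  writeCnvSegments(bad, f)
  expect_error(readCnvSegments(f), "line")
  bad <- seg; bad$observed_cn <- -1
  writeCnvSegments(bad, f)
  expect_error(readCnvSegments(f), "observed_cn")
})

test_that("junction reader keeps zero-read rows and validates ordering", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeJunctions(junctionRow(100L, 500L, 0L), f)
  j <- readJunctions(f)
  expect_equal(j$read_count, 0L)   # retained; never supports an event
  writeJunctions(junctionRow(500L, 100L, 5L), f)
  expect_error(readJunctions(f), "donor_pos")
})

test_that("expression and gene-model tables round-trip", {
  m <- matrix(c(0, 10, 5.5, 2), nrow = 2,
              dimnames = list(c("EGFR", "PTEN"), c("S1", "S2")))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeExpression(m, f)
  expect_equal(readExpression(f), m)

  model <- rbind(toyGene("GPLUS", nExons = 4L),
                 toyGene("GMINUS", start = 50000L, nExons = 3L,
                         strand = "-"))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeGeneModel(model, f2)
  expect_equal(readGeneModel(f2), model)
  badModel <- toyGene("G1", nExons = 3L)
  badModel$exon_number <- c(1L, 3L, 2L)
  expect_error(validateGeneModel(badModel), "consecutive")
})

test_that("SV reader validates sv_type and round-trips genes_hit", {
  sv <- data.frame(sample_id = "S1", chrom_a = "chr7", pos_a = 55100000L,
                   strand_a = "+", chrom_b = "chr7", pos_b = 55200000L,
                   strand_b = "+", sv_type = "DEL", genes_hit = "EGFR",
                   caller = "delly", stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSv(sv, f)
  expect_equal(readSv(f), sv)
  sv$sv_type <- "WEIRD"
  writeSv(sv, f)
  expect_error(readSv(f), "sv_type")
})

test_that("SnpEff consequence terms map onto the pipeline vocabulary", {
  expect_equal(mapConsequence(c("missense_variant", "stop_gained",
                                "splice_donor_variant")),
               c("missense", "nonsense", "splice_site"))
  expect_warning(out <- mapConsequence("totally_new_term"), "unmapped")
  expect_equal(out, "other")
})
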