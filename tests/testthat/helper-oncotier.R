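# Build a KnowledgeBase from in-code data.frames by writing temp TSVs and
# going through the loader (so tests exercise the same validation path).
kbFromDfs <- function(evidence = NULL, drugs = NULL, geneSets = NULL,
                      pathways = NULL, aliases = NULL) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  if (is.null(evidence))
    evidence <- data.frame(gene = character(), variant_spec = character(),
                           disease = character(), significance = character(),
                           source_id = character())
  if (is.null(drugs))
    drugs <- data.frame(gene = character(), variant_scope = character(),
                        variant_spec = character(), drug = character(),
                        evidence_level = character(), trial_ids = character(),
                        disease = character())
  if (is.null(geneSets))
    geneSets <- data.frame(set_name = character(), gene = character())
  if (is.null(pathways))
    pathways <- data.frame(pathway = character(), gene = character(),
                           role = character())
  write.table(evidence, file.path(dir, "evidence.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(drugs, file.path(dir, "drugs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(geneSets, file.path(dir, "gene_sets.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(pathways, file.path(dir, "pathways.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(aliases))
    write.table(aliases, file.path(dir, "drug_aliases.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  loadKnowledgeBase(dir)
}

evidenceRow <- function(gene, spec, disease, sig = "clinically_significant",
                        src = "test") {
  data.frame(gene = gene, variant_spec = spec, disease = disease,
             significance = sig, source_id = src, stringsAsFactors = FALSE)
}

drugRow <- function(gene, scope, drug, spec = ".",
                    level = "clinical_trial", trials = "NCT00000001",
                    disease = ".") {
  data.frame(gene = gene, variant_scope = scope, variant_spec = spec,
             drug = drug, evidence_level = level, trial_ids = trials,
             disease = disease, stringsAsFactors = FALSE)
}

geneSetRows <- function(name, genes) {
  data.frame(set_name = name, gene = genes, stringsAsFactors = FALSE)
}

# a small plus-strand gene with nExons 200-bp exons / 800-bp introns
toyGene <- function(gene = "GENE1", chrom = "chrT", start = 10000L,
                    nExons = 5L, strand = "+") {
  starts <- start + (seq_len(nExons) - 1L) * 1000L
  num <- if (strand == "+") seq_len(nExons) else rev(seq_len(nExons))
  data.frame(gene = gene, chrom = chrom, strand = strand,
             exon_number = num, start = starts, end = starts + 200L,
             stringsAsFactors = FALSE)
}

junctionRow <- function(donor, acceptor, reads, sample = "S1",
                        chrom = "chrT") {
  data.frame(sample_id = sample, chrom = chrom, donor_pos = donor,
             acceptor_pos = acceptor, read_count = reads,
             stringsAsFactors = FALSE)
}

variantRow <- function(gene, spec, sample = "S1", vaf = 0.4, depth = 100L,
                       consequence = "missense", chrom = "chrT",
                       pos = 10050L) {
  data.frame(sample_id = sample, chrom = chrom, pos = pos, ref = "A",
             alt = "T", gene = gene, variant_spec = spec,
             consequence = consequence, vaf = vaf, depth = depth,
             stringsAsFactors = FALSE)
}

# sort-based oracles, independent of stats::median / stats::mad
oracleMedian <- function(x) {
  s <- sort(x); n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) %/% 2L] else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
}
oracleMad <- function(x) oracleMedian(abs(x - oracleMedian(x)))

oraclePearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}
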