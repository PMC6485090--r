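therapyKb <- function() {
  kbFromDfs(
    evidence = evidenceRow("IDH1", "R132H", "glioblastoma"),
    drugs = rbind(
      drugRow("EGFR", "gain", "Cetuximab", level = "approved_other_disease"),
      drugRow("EGFR", "gain", "ABT-414"),
      drugRow("PTEN", "loss", "Everolimus", level = "approved_other_disease"),
      drugRow("MET", "gain", "INC280"),
      drugRow("PIK3R1", "any_alteration", "BKM120"),
      drugRow("TMB_HIGH", "any_alteration", "Pembrolizumab",
              level = "approved_other_disease"),
      drugRow("TMB_HIGH", "any_alteration", "Nivolumab",
              level = "approved_other_disease")),
    geneSets = rbind(
      geneSetRows("actionable_genes", c("EGFR", "PTEN", "MET", "PIK3R1")),
      geneSetRows("cancer_census",
                  c("EGFR", "PTEN", "MET", "PIK3R1", "TP53", "MSH2")),
      geneSetRows("mmr_genes", "MSH2")),
    pathways = data.frame(
      pathway = "RTK_PI3K_MTOR",
      gene = c("EGFR", "MET", "PIK3R1", "PTEN"),
      role = c("upstream", "upstream", "downstream", "downstream")))
}

findingRow <- function(sample, gene, cls, spec, tier = NA_integer_,
                       rank = NA_integer_, consequence = NA_character_) {
  data.frame(sample_id = sample, gene = gene, alteration_class = cls,
             variant_spec = spec, consequence = consequence, tier = tier,
             priority_rank = rank, stringsAsFactors = FALSE)
}

test_that("therapy matching covers tiers 1-3, CNVs and SVs but not tier-4-only findings", {
  kb <- therapyKb()
  f <- rbind(
    findingRow("GBMx", "EGFR", "gain", "gain", rank = 1L),
    findingRow("GBMx", "TP53", "snv", "R999Q", tier = 4L),
    findingRow("GBMx", "PIK3R1", "snv", "K567E", tier = 3L,
               consequence = "missense"))
  opts <- matchTherapies(f, kb)
  expect_setequal(opts$drugs[opts$target_gene == "EGFR"],
                  c("CETUXIMAB", "ABT414"))
  expect_true("BKM120" %in% opts$drugs)
  expect_false("TP53" %in% opts$target_gene)   # tier-4-only: nothing
  expect_equal(nrow(matchTherapies(f[0, ], kb)), 0L)
  # all emitted drugs exist in the KB (closed world)
  expect_true(all(opts$drugs %in% kbDrugs(kb)$drug))
})

test_that("matching is monotone in the knowledge base", {
  kb <- therapyKb()
  f <- rbind(findingRow("GBMx", "EGFR", "gain", "gain", rank = 1L),
             findingRow("GBMx", "PTEN", "loss", "loss", rank = 3L))
  before <- matchTherapies(f, kb)
  kb2 <- kbFromDfs(
    drugs = rbind(kbDrugs(kb)[, oncotier:::.DRUG_COLS],
                  drugRow("EGFR", "gain", "BrandNewDrug")),
    geneSets = rbind(
      geneSetRows("actionable_genes", kbGeneSet(kb, "actionable_genes")),
      geneSetRows("cancer_census", kbGeneSet(kb, "cancer_census"))))
  after <- matchTherapies(f, kb2)
  key <- function(o) paste(o$sample_id, o$drugs, o$targets)
  expect_true(all(key(before) %in% key(after)))
  expect_true("BRANDNEWDRUG" %in% after$drugs)
})

test_that("same-pathway combinations pair one drug per finding", {
  kb <- therapyKb()
  f <- rbind(findingRow("GBM24x", "EGFR", "gain", "gain", rank = 1L),
             findingRow("GBM24x", "PTEN", "loss", "loss", rank = 3L))
  opts <- matchTherapies(f, kb)
  combos <- suggestCombinations(opts, f, kb)
  expect_equal(nrow(combos), 1L)
  expect_equal(combos$rationale, "combination_same_pathway")
  drugs <- strsplit(combos$drugs, "+", fixed = TRUE)[[1]]
  expect_setequal(drugs, c("CETUXIMAB", "EVEROLIMUS"))
  # three-way pathway hit pairs a PI3K and a MET inhibitor
  f3 <- rbind(f, findingRow("GBM24x", "MET", "gain", "gain", rank = 2L),
              findingRow("GBM24x", "PIK3R1", "snv", "K567E", tier = 3L))
  combos3 <- suggestCombinations(matchTherapies(f3, kb), f3, kb)
  d3 <- strsplit(combos3$drugs, "+", fixed = TRUE)[[1]]
  expect_true(all(c("INC280", "BKM120") %in% d3))
  # a single finding in the pathway yields no combination
  single <- findingRow("GBMy", "EGFR", "gain", "gain", rank = 1L)
  expect_equal(nrow(suggestCombinations(matchTherapies(single, kb), single,
                                        kb)), 0L)
  # combination drugs always target genes of one pathway
  pw <- kbPathways(kb)
  for (i in seq_len(nrow(combos3))) {
    genes <- strsplit(combos3$target_gene[i], "+", fixed = TRUE)[[1]]
    expect_true(any(vapply(split(pw$gene, pw$pathway),
                           function(g) all(genes %in% g), logical(1))))
  }
})

test_that("hypermutation rule requires both high burden and an MMR hit", {
  kb <- therapyKb()
  mmrFinding <- findingRow("GBM8x", "MSH2", "snv", "c.366+1G>A", tier = 4L,
                           consequence = "splice_site")
  b <- mutationBurden("GBM8x", 1954L, mmrFinding, kb)
  expect_equal(b$mmr_hits, "MSH2")
  opt <- applyHypermutationRule(b, cohortMedian = 157, kb)
  expect_setequal(opt$drugs, c("PEMBROLIZUMAB", "NIVOLUMAB"))
  expect_equal(unique(opt$rationale), "hypermutation_checkpoint")
  # median burden never fires
  bMed <- mutationBurden("GBMy", 157L, mmrFinding, kb)
  expect_equal(nrow(applyHypermutationRule(bMed, 157, kb)), 0L)
  # extreme burden without an MMR hit does not fire either
  bNoMmr <- mutationBurden("GBMz", 5881L, mmrFinding[0, ], kb)
  expect_equal(nrow(applyHypermutationRule(bNoMmr, 157, kb)), 0L)
  # missense in an MMR gene is not a disruption
  miss <- findingRow("GBMw", "MSH2", "snv", "A100V", tier = 4L,
                     consequence = "missense")
  expect_equal(length(mutationBurden("GBMw", 2000L, miss, kb)$mmr_hits), 0L)
})

test_that("ranking orders by evidence level then tier then drug, stably", {
  o <- data.frame(
    sample_id = "S", drugs = c("ZDRUG", "ADRUG", "MDRUG", "MDRUG2"),
    targets = "T", target_gene = "G", target_class = "snv",
    target_tier = c(3L, 1L, 3L, 3L), target_consequence = NA_character_,
    evidence_level = c("clinical_trial", "clinical_trial",
                       "approved_in_disease", "clinical_trial"),
    trial_ids = NA_character_, rationale = "direct_target",
    stringsAsFactors = FALSE)
  r <- rankTherapies(o)
  expect_equal(r$drugs, c("MDRUG", "ADRUG", "MDRUG2", "ZDRUG"))
  expect_equal(r$rank, 1:4)
  # equal keys preserve input order (stability)
  oEq <- o; oEq$evidence_level <- "clinical_trial"; oEq$target_tier <- 3L
  oEq$drugs <- "SAME"
  expect_equal(rankTherapies(oEq)$targets, oEq$targets)
  expect_equal(nrow(rankTherapies(o[0, ])), 0L)
})

test_that("association-type distribution counts SNV/CNV/Indel/SV fractions", {
  mk <- function(cls, cons = NA_character_) data.frame(
    sample_id = "S", drugs = "D", targets = "T", target_gene = "G",
    target_class = cls, target_tier = NA_integer_,
    target_consequence = cons, evidence_level = "clinical_trial",
    trial_ids = NA_character_, rationale = "direct_target",
    stringsAsFactors = FALSE)
  o <- rbind(mk("snv", "missense"), mk("snv", "missense"), mk("gain"),
             mk("sv"))
  d <- summarizeAssociationTypes(o)
  expect_equal(as.numeric(d), c(0.5, 0.25, 0, 0.25))
  expect_equal(sum(d), 1)
  # frameshift SNVs count as indels
  d2 <- summarizeAssociationTypes(rbind(mk("snv", "frameshift")))
  expect_equal(as.numeric(d2["Indel"]), 1)
  dEmpty <- summarizeAssociationTypes(mk("snv")[0, ])
  expect_true(attr(dEmpty, "empty"))
  expect_equal(as.numeric(dEmpty), c(0, 0, 0, 0))
})
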