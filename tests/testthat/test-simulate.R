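test_that("config validation rejects infeasible settings and demands a seed", {
  expect_error(cohortConfig(), "seed")
  expect_error(cohortConfig(seed = 1, hypermutant_fraction = 1.5), "\\[0, 1\\]")
  expect_error(cohortConfig(seed = 1, purity_bounds = c(0.9, 0.2)), "ordered")
  expect_error(cohortConfig(seed = 1,
                            tier_mix = c(tier1 = 1, tier2 = 1, tier3 = 0,
                                         tier4 = 0, none = 0)), "sum to 1")
})

test_that("simulation is deterministic given the seed", {
  cfg <- cohortConfig(seed = 42, n_samples = 6L)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(cohortVariants(a), cohortVariants(b))
  expect_identical(cohortSegments(a), cohortSegments(b))
  expect_identical(cohortExpression(a), cohortExpression(b))
  c2 <- simulateCohort(cohortConfig(seed = 43, n_samples = 6L))
  expect_false(identical(cohortVariants(a), cohortVariants(c2)))
})

test_that("degenerate purity spread collapses all samples to the mean", {
  cfg <- cohortConfig(seed = 7, n_samples = 5L, purity_sd = 0)
  co <- simulateCohort(cfg)
  expect_equal(cohortSamples(co)$purity, rep(0.71, 5))
})

test_that("burden distribution tracks the configured median at scale", {
  cfg <- cohortConfig(seed = 11, n_samples = 200L,
                      hypermutant_fraction = 2 / 30)
  co <- simulateCohort(cfg)
  s <- cohortSamples(co)
  med <- median(s$exonic_snv_count[!s$hypermutant])
  expect_lt(abs(med - 157) / 157, 0.2)
  expect_true(all(s$exonic_snv_count[s$hypermutant] >= 1500))
  expect_equal(sum(s$hypermutant), round(200 * 2 / 30))
})

test_that("simulated cohorts carry recoverable structure", {
  co <- simulateCohort(cohortConfig(seed = 3, n_samples = 10L))
  v <- cohortVariants(co)
  expect_true(all(v$vaf >= 0 & v$vaf <= 1))
  expect_true(all(v$depth >= 1))
  # hypermutants carry the MMR splice-site disruption
  hyper <- cohortSamples(co)$sample_id[cohortSamples(co)$hypermutant]
  for (sid in hyper)
    expect_true(any(v$sample_id == sid & v$gene == "MSH2" &
                      v$consequence == "splice_site"))
  # spiked EGFR skipping events come with corroborating DEL calls
  st <- co@spliceTruth
  if (nrow(st) > 0L && any(st$gene == "EGFR")) {
    svs <- cohortSv(co)
    for (sid in st$sample_id[st$gene == "EGFR"])
      expect_true(any(svs$sample_id == sid & svs$sv_type == "DEL"))
  }
})

test_that("a written cohort round-trips through the ingest readers", {
  co <- simulateCohort(cohortConfig(seed = 13, n_samples = 3L))
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  sid <- cohortSamples(co)$sample_id[1]
  v0 <- cohortVariants(co)
  v0 <- v0[v0$sample_id == sid, ]
  v1 <- readSomaticVcf(file.path(dir, paste0(sid, ".somatic.vcf")))
  expect_equal(nrow(v1), nrow(v0))
  expect_equal(v1$gene, v0$gene)
  expect_equal(v1$variant_spec, v0$variant_spec)
  expect_equal(v1$vaf, v0$vaf, tolerance = 1e-5)
  seg <- readCnvSegments(file.path(dir, "segments.tsv"))
  expect_equal(nrow(seg), nrow(cohortSegments(co)))
  jx <- readJunctions(file.path(dir, "junctions.tsv"))
  expect_equal(nrow(jx), nrow(cohortJunctions(co)))
  expr <- readExpression(file.path(dir, "tpm.tsv"))
  expect_equal(expr, cohortExpression(co))
})

test_that("panel observer masks, drops and contaminates as configured", {
  truth <- data.frame(gene = c("EGFR", "PTEN", "DECOY01"),
                      variant_spec = c("A289V", "R130*", "G1R"),
                      stringsAsFactors = FALSE)
  germ <- data.frame(gene = "DECOY02", variant_spec = "G5R", vaf = 0.5,
                     stringsAsFactors = FALSE)
  # full gene space, no dropout: panel equals the truth set
  obs <- observerConfig(panel_genes = truth$gene, dropout_prob = 0,
                        germline_contamination_rate = 0, seed = 1)
  ps <- observePanel("c", truth, germ, obs)
  expect_setequal(ps$calls, normalizeCall(truth$gene, truth$variant_spec,
                                          keyLevel = "variant"))
  # zero contamination -> never a germline miscall downstream
  expect_false(any(grepl("DECOY02", ps$calls)))
  # gene-space masking
  obs2 <- observerConfig(panel_genes = "EGFR", dropout_prob = 0, seed = 1)
  expect_equal(observePanel("c", truth, germ, obs2)$calls, "EGFR:A289V")
  # contamination without a matched normal is a seeded binomial draw
  germMany <- data.frame(gene = sprintf("DECOY%02d", 1:10),
                         variant_spec = sprintf("G%dR", 1:10), vaf = 0.5,
                         stringsAsFactors = FALSE)
  obs3 <- observerConfig(panel_genes = character(),
                         matched_normal_used = FALSE, dropout_prob = 0,
                         germline_contamination_rate = 0.3, seed = 99)
  got <- observePanel("c", truth[0, ], germMany, obs3)
  expected <- withr::with_seed(99, {
    runif(0)  # mirror the dropout draw on zero truth calls
    sum(runif(10) < 0.3)
  })
  expect_equal(length(got$calls), expected)
  expect_identical(observePanel("c", truth[0, ], germMany, obs3)$calls,
                   got$calls)
})

test_that("curator observer obeys detection extremes and rejects bad decoys", {
  truth <- callSet("c", sprintf("K%02d", 1:10))
  decoys <- sprintf("D%02d", 1:10)
  all <- observeCurator(truth, 1, 0, decoys, seed = 5)
  r <- sensitivityPpv(truth, all)
  expect_equal(c(r$sensitivity, r$ppv), c(1, 1))
  none <- observeCurator(truth, 0, 0, decoys, seed = 5)
  expect_equal(sensitivityPpv(truth, none)$sensitivity, 0)
  expect_error(observeCurator(truth, 0.5, 0.1, c("K01", decoys), 5),
               "overlap")
})
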