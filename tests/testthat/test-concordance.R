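test_that("call keys normalize at variant, gene and drug-target level", {
  expect_equal(normalizeCall("EGFR", "A289V", keyLevel = "variant"),
               "EGFR:A289V")
  expect_equal(normalizeCall("egfr ", keyLevel = "gene"), "EGFR")
  # a point mutation and a gain of the same gene stay distinct
  expect_false(normalizeCall("EGFR", "A289V", keyLevel = "variant") ==
                 normalizeCall("EGFR", "gain", keyLevel = "variant"))
  expect_equal(normalizeCall(drug = "cetuximab", keyLevel = "drug_target"),
               "CETUXIMAB")
  expect_error(normalizeCall("EGFR", keyLevel = "variant"), "variantSpec")
})

test_that("panel comparison performs the common/unique/germline set algebra", {
  wgs <- callSet("case1", c("G1", "G2", "G3"), "wgs")
  panel <- callSet("case1", c("G2", "G4"), "panel", matchedNormal = FALSE)
  cmp <- comparePanel(wgs, panel, germlineKeys = "G4")
  expect_equal(cmp$common, "G2")
  expect_setequal(cmp$wgs_unique, c("G1", "G3"))
  expect_equal(cmp$panel_unique, "G4")
  expect_equal(cmp$germline_miscalls, "G4")
  # identical sets: all common
  same <- comparePanel(wgs, callSet("case1", wgs$calls, "panel",
                                    matchedNormal = FALSE))
  expect_equal(length(same$wgs_unique), 0L)
  expect_equal(length(same$panel_unique), 0L)
  # matched-normal panels are not germline-audited
  mnPanel <- callSet("case1", c("G2", "G4"), "panel", matchedNormal = TRUE)
  expect_equal(length(comparePanel(wgs, mnPanel,
                                   germlineKeys = "G4")$germline_miscalls),
               0L)
  expect_error(comparePanel(wgs, callSet("case2", "G1")), "different cases")
})

test_that("gene-space restriction moves off-space calls aside", {
  wgs <- callSet("c", c("EGFR:A289V", "TERT:C.-124C>T"))
  panel <- callSet("c", "EGFR:A289V")
  cmp <- comparePanel(wgs, panel, panelGeneSpace = "EGFR")
  expect_equal(cmp$common, "EGFR:A289V")
  expect_equal(length(cmp$wgs_unique), 0L)
  expect_equal(cmp$off_space_wgs_unique, "TERT:C.-124C>T")
})

test_that("partition identities hold on random call sets", {
  withr::with_seed(23, {
    pool <- sprintf("G%02d", 1:30)
    for (rep in 1:50) {
      a <- callSet("c", sample(pool, sample(0:20, 1)))
      b <- callSet("c", sample(pool, sample(0:20, 1)), matchedNormal = FALSE)
      cmp <- comparePanel(a, b, germlineKeys = sample(pool, 5))
      expect_equal(length(cmp$common) + length(cmp$wgs_unique),
                   length(a$calls))
      expect_equal(length(cmp$common) + length(cmp$panel_unique),
                   length(b$calls))
      expect_true(all(cmp$germline_miscalls %in% b$calls))
    }
  })
})

test_that("sensitivity and PPV follow the truth-set formulas with degenerate flags", {
  truth <- callSet("c", c("A", "B", "C", "D"))
  test <- callSet("c", c("A", "B", "E"))
  r <- sensitivityPpv(truth, test)
  expect_equal(r$sensitivity, 0.5)
  expect_equal(r$ppv, 2 / 3, tolerance = 1e-9)
  perfect <- sensitivityPpv(truth, callSet("c", truth$calls))
  expect_equal(c(perfect$sensitivity, perfect$ppv), c(1, 1))
  degen <- sensitivityPpv(truth, callSet("c", character()))
  expect_equal(degen$sensitivity, 0)
  expect_true(is.na(degen$ppv))
  noTruth <- sensitivityPpv(callSet("c", character()), test)
  expect_true(is.na(noTruth$sensitivity))
})

test_that("sensitivity/PPV duality holds for arbitrary set pairs", {
  withr::with_seed(29, {
    pool <- sprintf("K%02d", 1:25)
    for (rep in 1:50) {
      a <- callSet("c", sample(pool, sample(1:15, 1)))
      b <- callSet("c", sample(pool, sample(1:15, 1)))
      expect_equal(sensitivityPpv(a, b)$sensitivity,
                   sensitivityPpv(b, a)$ppv)
    }
  })
})

test_that("cohort summary computes means, SDs and actionability gain", {
  rows <- list(list(case_id = "a", sensitivity = 0.6, ppv = 0.9),
               list(case_id = "b", sensitivity = 0.8, ppv = NA_real_))
  s <- summarizeCohort(rows)
  expect_equal(s$mean_sensitivity, 0.7)
  expect_equal(s$sd_sensitivity, sd(c(0.6, 0.8)), tolerance = 1e-9)
  expect_equal(s$n_undefined_ppv, 1L)       # undefined excluded from means
  expect_equal(s$mean_ppv, 0.9)
  single <- summarizeCohort(rows[1])
  expect_true(is.na(single$sd_sensitivity))  # n-1 policy flagged
  # panel flavor: 18 of 20 cases with >= 1 WGS-unique call -> gain 0.90
  panelRows <- lapply(1:20, function(i) {
    list(case_id = paste0("c", i),
         common = c("x", "y"),
         wgs_unique = if (i <= 18) sprintf("u%d", seq_len((i %% 4) + 1))
                      else character(),
         panel_unique = character(), germline_miscalls = character())
  })
  ps <- summarizeCohort(panelRows)
  expect_equal(ps$actionability_gain_rate, 0.9)
  expect_equal(ps$median_common, 2)
  tab <- panelComparisonTable(panelRows)
  expect_equal(nrow(tab), 80L)
  expect_equal(sum(tab$count[tab$category == "common"]), 40L)
  expect_error(summarizeCohort(list()), "no comparison rows")
})
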