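test_that("purity correction inverts the tumor/normal mixture", {
  expect_equal(correctCopyNumber(4, 0.5), 6)
  expect_equal(correctCopyNumber(3.2, 1), 3.2)        # pure tumor: identity
  expect_equal(correctCopyNumber(1, 0.5), 0)          # floored at 0
  expect_error(correctCopyNumber(2, 0), "purity")
  expect_error(correctCopyNumber(2, 1.2), "purity")
})

test_that("re-mixing a corrected copy number recovers the observation", {
  withr::with_seed(5, {
    for (rep in 1:50) {
      p <- runif(1, 0.05, 1); obs <- runif(1, 0, 12)
      corr <- correctCopyNumber(obs, p)
      if (corr > 0) {   # unfloored
        remixed <- p * corr + (1 - p) * 2
        expect_equal(remixed, obs, tolerance = 1e-9)
      }
    }
  })
})

test_that("segment classification matches the copy-class and focality rules", {
  model <- toyGeneModel(); arms <- toyArmTable()
  ptenSpan <- model[model$gene == "PTEN", ]
  seg <- data.frame(
    sample_id = "S1", chrom = c("chr10", ptenSpan$chrom[1], "chr7", "chr7"),
    start = c(0L, 0L, 20000L, 100000L),
    end = c(1200000L, 1200000L, 120000L, 160000L),
    observed_cn = c(1.0, 1.0, 0.0, 2.0),
    stringsAsFactors = FALSE)
  # purity 1 so observed == tumor copies
  cls <- classifySegments(seg[c(1, 3, 4), ], purity = 1, ploidy = 2,
                          arms = arms, model = model)
  expect_equal(cls$copy_class, c("heterozygous_loss", "homozygous_loss",
                                 "neutral"))
  expect_equal(cls$focality[1:2], c("arm_level", "focal"))
  expect_true("PTEN" %in% strsplit(cls$genes_hit[1], ";")[[1]])
  expect_equal(cls$priority_rank, c(3L, 1L, NA_integer_))
  # high-copy focal amplification is rank 1
  amp <- data.frame(sample_id = "S1", chrom = "chr7", start = 10000L,
                    end = 60000L, observed_cn = 12, stringsAsFactors = FALSE)
  ca <- classifySegments(amp, 1, 2, arms, model)
  expect_equal(ca$copy_class, "focal_amplification")
  expect_equal(ca$priority_rank, 1L)
})

test_that("the neutral band follows sample ploidy", {
  arms <- toyArmTable(); model <- toyGeneModel()
  seg <- data.frame(sample_id = "S1", chrom = "chr7", start = 0L,
                    end = 1200000L, observed_cn = 4, stringsAsFactors = FALSE)
  hyper <- classifySegments(seg, 1, ploidy = 4, arms, model)
  expect_equal(hyper$copy_class, "neutral")   # not genome-wide gain
  diploid <- classifySegments(seg, 1, ploidy = 2, arms, model)
  expect_equal(diploid$copy_class, "gain")
})

test_that("classification is monotone in corrected copy number", {
  classOrder <- c(homozygous_loss = 1, heterozygous_loss = 2, neutral = 3,
                  gain = 4, focal_amplification = 5)
  cls <- oncotier:::.copyClass(seq(0, 8, by = 0.1), ploidy = 2)
  expect_true(all(diff(classOrder[cls]) >= 0))
})

test_that("gene overlap respects half-open interval conventions", {
  model <- toyGeneModel()
  pten <- model[model$gene == "PTEN", ]
  chrom <- pten$chrom[1]; s <- min(pten$start); e <- max(pten$end)
  expect_true("PTEN" %in% genesInSegment(chrom, s, e, model))
  expect_true("PTEN" %in% genesInSegment(chrom, 0L, 1200000L, model))
  expect_equal(genesInSegment(chrom, s, s, model), character(0))  # zero-width
  # a segment ending exactly at the gene start excludes it
  expect_false("PTEN" %in% genesInSegment(chrom, s - 1000L, s, model))
  expect_true("PTEN" %in% genesInSegment(chrom, s - 1000L, s + 1L, model))
})

test_that("prioritization orders by rank then magnitude and is a permutation", {
  model <- toyGeneModel(); arms <- toyArmTable()
  seg <- data.frame(
    sample_id = "S1", chrom = "chr7",
    start = c(10000L, 0L, 200000L, 0L),
    end = c(60000L, 1200000L, 260000L, 1150000L),
    observed_cn = c(20, 3, 0, 2), stringsAsFactors = FALSE)
  cls <- classifySegments(seg, 1, 2, arms, model)
  prio <- prioritizeFindings(cls)
  # EGFR-like focal cn 20 first, then the focal homozygous loss
  expect_equal(prio$observed_cn[1:2], c(20, 0))
  expect_equal(prio$priority_rank, sort(prio$priority_rank))
  # permutation of rank-eligible inputs
  eligible <- cls[!is.na(cls$priority_rank), ]
  expect_setequal(paste(prio$start, prio$end),
                  paste(eligible$start, eligible$end))
  # stricter scope drops rank-3 arm-level gains / het losses
  strict <- prioritizeFindings(cls, includeLowPriority = FALSE)
  expect_true(all(strict$priority_rank < 3L))
  expect_equal(nrow(prioritizeFindings(cls[0, ])), 0L)
})

test_that("actionable SVs are attached as rank-1 findings", {
  sv <- data.frame(sample_id = "S1", chrom_a = "chr7", pos_a = 10L,
                   strand_a = "+", chrom_b = "chr7", pos_b = 20L,
                   strand_b = "+", sv_type = "DEL",
                   genes_hit = "EGFR;DECOY01", caller = "delly",
                   stringsAsFactors = FALSE)
  f <- svFindings(sv, c("EGFR"))
  expect_equal(f$gene, "EGFR")
  expect_equal(f$priority_rank, 1L)
})
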