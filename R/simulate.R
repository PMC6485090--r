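#' @importFrom withr with_seed
#' @importFrom stats rnorm rlnorm rpois rbinom runif median
NULL

#' Cohort generator settings
#'
#' Builds and validates the configuration for [simulateCohort()]. The
#' defaults encode the statistical structure of a 30-sample GBM-like study
#' cohort: tumor purity from a truncated normal (mean 0.71, SD 0.16, bounds
#' 0.15--0.95); exonic SNV burden lognormal around a median of 157 with a
#' rare hypermutant component (2 of 30 samples, counts spanning roughly
#' 1500--6000); a tier-mixture over planted curated variants; recurrent CNV
#' events (chr10 arm loss covering PTEN, EGFR-like focal amplification,
#' CDKN2A-like focal homozygous loss); paired DNA/RNA variant allele
#' fractions drawn binomially from a shared true VAF; TERT-promoter hotspot
#' variants in roughly 60% of samples; and spiked alternative-splicing
#' events (a mid-gene MET exon skip, an EGFRvIII-like exon 2--7 skip with
#' corroborating DNA deletion).
#'
#' @param seed integer seed; mandatory, all randomness derives from it.
#' @param n_samples cohort size.
#' @param purity_mean,purity_sd,purity_bounds truncated-normal purity model.
#' @param ploidy_mean,ploidy_sd,ploidy_min ploidy model.
#' @param snv_median,snv_sdlog lognormal exonic-SNV burden model
#'   (meanlog = log(snv_median)).
#' @param hypermutant_fraction expected fraction of hypermutant samples.
#' @param hypermutant_range uniform count range for hypermutant burdens.
#' @param tier_mix named probabilities (tier1, tier2, tier3, tier4, none)
#'   for planted curated variants.
#' @param n_curated_mean Poisson mean of curated variants per sample.
#' @param tert_promoter_prob probability a sample carries a TERT-promoter
#'   hotspot variant.
#' @param p_arm_loss,p_focal_amp,p_hom_loss per-sample probabilities of the
#'   chr10 arm-loss, EGFR focal-amplification and CDKN2A homozygous-loss
#'   events.
#' @param dna_depth,rna_depth Poisson means of DNA and RNA read depth.
#' @param p_met_skip,met_skip_psi,p_egfr_viii,egfr_viii_reads splice-spike
#'   settings.
#' @param n_germline germline het variants per sample.
#' @param reference_n reference expression cohort size (default 169).
#' @return validated list of class `cohort_config`.
#' @export
cohortConfig <- function(seed,
                         n_samples = 30L,
                         purity_mean = 0.71, purity_sd = 0.16,
                         purity_bounds = c(0.15, 0.95),
                         ploidy_mean = 2.03, ploidy_sd = 0.2,
                         ploidy_min = 1.5,
                         snv_median = 157, snv_sdlog = 0.52,
                         hypermutant_fraction = 2 / 30,
                         hypermutant_range = c(1500, 6000),
                         tier_mix = c(tier1 = 0.03, tier2 = 0.04,
                                      tier3 = 0.48, tier4 = 0.25,
                                      none = 0.20),
                         n_curated_mean = 8,
                         tert_promoter_prob = 19 / 33,
                         p_arm_loss = 0.7, p_focal_amp = 0.5,
                         p_hom_loss = 0.4,
                         dna_depth = 80, rna_depth = 50,
                         p_met_skip = 0.15, met_skip_psi = 30,
                         p_egfr_viii = 0.1, egfr_viii_reads = 32,
                         n_germline = 20L, reference_n = 169L) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("seed is mandatory", call. = FALSE)
  probs <- c(hypermutant_fraction, tier_mix, tert_promoter_prob,
             p_arm_loss, p_focal_amp, p_hom_loss, p_met_skip, p_egfr_viii)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (purity_bounds[1] >= purity_bounds[2] ||
      hypermutant_range[1] >= hypermutant_range[2])
    stop("bounds must be ordered", call. = FALSE)
  if (abs(sum(tier_mix) - 1) > 1e-8)
    stop("tier_mix must sum to 1", call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lo && x <= hi) break
    }
    out[i] <- x
  }
  out
}

.randSpec <- function() sprintf("%s%d%s",
                                sample(c("A", "G", "L", "P", "S", "T"), 1),
                                sample(700:1500, 1),
                                sample(c("V", "M", "R", "K", "D"), 1))

.BASES <- c("A", "C", "G", "T")

.plantVariant <- function(sampleId, gene, spec, consequence, trueTier,
                          model, purity, dnaDepth, rnaDepth) {
  ex <- .geneExons(model, gene)
  k <- sample(nrow(ex), 1)
  pos <- sample((ex$start[k] + 1L):ex$end[k], 1)   # 1-based within exon
  ref <- sample(.BASES, 1)
  alt <- sample(setdiff(.BASES, ref), 1)
  trueVaf <- purity / 2 * stats::runif(1, 0.5, 1)
  depth <- max(1L, stats::rpois(1, dnaDepth))
  altReads <- stats::rbinom(1, depth, trueVaf)
  rnaTot <- stats::rpois(1, rnaDepth)
  rnaAlt <- if (rnaTot > 0) stats::rbinom(1, rnaTot, trueVaf) else 0L
  data.frame(sample_id = sampleId, chrom = ex$chrom[[1]], pos = pos,
             ref = ref, alt = alt, gene = gene, variant_spec = spec,
             consequence = consequence, true_tier = trueTier,
             true_vaf = trueVaf, depth = depth,
             alt_reads = altReads, vaf = altReads / depth,
             rna_total = rnaTot, rna_alt = rnaAlt,
             rna_vaf = if (rnaTot > 0) rnaAlt / rnaTot else NA_real_,
             stringsAsFactors = FALSE)
}

#' Simulate a GBM-like tumor cohort
#'
#' Generates a complete desk-scale cohort with known truth: per-sample
#' purity, ploidy and exonic SNV burden; curated somatic variants planted
#' with intended tiers against the knowledge base (Tier 1/2 specs taken
#' from evidence rows, Tier 3 novel specs in actionable genes, Tier 4 in
#' census-only genes, plus unclassifiable decoys); germline het calls;
#' copy-number segments with intended copy classes; splice junctions with
#' spiked skipping events and corroborating SV deletions; and gene
#' expression for the cohort plus a reference cohort. DNA and RNA allele
#' fractions are binomial draws from a shared true VAF. Deterministic given
#' the config seed.
#'
#' @param config a [cohortConfig()].
#' @param kb knowledge base used for planting (default
#'   [bundledKnowledgeBase()]).
#' @param model gene model (default [toyGeneModel()]).
#' @param studyDisease disease defining Tier 1 (default `"glioblastoma"`).
#' @return a [TumorCohort-class] with truth columns.
#' @export
simulateCohort <- function(config, kb = bundledKnowledgeBase(),
                           model = toyGeneModel(),
                           studyDisease = "glioblastoma") {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, .simulateCohortImpl(config, kb, model,
                                                    studyDisease))
}

.simulateCohortImpl <- function(cfg, kb, model, studyDisease) {
  ev <- kbEvidence(kb)
  snvSpec <- grepl("^[A-Z][0-9]+", ev$variant_spec)
  sigEv <- ev[ev$significance == "clinically_significant" & snvSpec, ,
              drop = FALSE]
  sameDis <- sigEv$disease == tolower(studyDisease)
  tier1Pool <- sigEv[sameDis, c("gene", "variant_spec")]
  tier2Pool <- sigEv[!sameDis &
                       !paste(sigEv$gene, sigEv$variant_spec) %in%
                         paste(tier1Pool$gene, tier1Pool$variant_spec),
                     c("gene", "variant_spec")]
  actionable <- kbGeneSet(kb, "actionable_genes")
  withDrugs <- unique(kbDrugs(kb)$gene)
  tier3Genes <- intersect(intersect(actionable, withDrugs),
                          unique(model$gene))
  tier4Genes <- intersect(setdiff(kbGeneSet(kb, "cancer_census"), actionable),
                          unique(model$gene))
  noneGenes <- grep("^DECOY", unique(model$gene), value = TRUE)

  n <- cfg$n_samples
  sampleIds <- sprintf("S%02d", seq_len(n))
  purity <- .rtruncnorm(n, cfg$purity_mean, cfg$purity_sd,
                        cfg$purity_bounds[1], cfg$purity_bounds[2])
  ploidy <- pmax(cfg$ploidy_min, stats::rnorm(n, cfg$ploidy_mean,
                                              cfg$ploidy_sd))
  nHyper <- round(cfg$hypermutant_fraction * n)
  hyper <- seq_len(n) %in% sample(n, nHyper)
  burden <- round(stats::rlnorm(n, log(cfg$snv_median), cfg$snv_sdlog))
  burden[hyper] <- round(stats::runif(sum(hyper), cfg$hypermutant_range[1],
                                      cfg$hypermutant_range[2]))

  samples <- data.frame(sample_id = sampleIds, purity = purity,
                        ploidy = ploidy, exonic_snv_count = as.integer(burden),
                        hypermutant = hyper, stringsAsFactors = FALSE)

  tiers <- names(cfg$tier_mix)
  variants <- list(); germline <- list(); segments <- list()
  junctions <- list(); svRecords <- list(); spliceTruth <- list()
  annot <- annotatedJunctions(model)
  tertExists <- "TERT" %in% model$gene

  for (i in seq_len(n)) {
    sid <- sampleIds[i]
    nVar <- max(1L, stats::rpois(1, cfg$n_curated_mean))
    draw <- sample(tiers, nVar, replace = TRUE, prob = cfg$tier_mix)
    for (d in draw) {
      if (d == "tier1" && nrow(tier1Pool) > 0L) {
        r <- tier1Pool[sample(nrow(tier1Pool), 1), ]
        v <- .plantVariant(sid, r$gene, r$variant_spec, "missense", 1L,
                           model, purity[i], cfg$dna_depth, cfg$rna_depth)
      } else if (d == "tier2" && nrow(tier2Pool) > 0L) {
        r <- tier2Pool[sample(nrow(tier2Pool), 1), ]
        v <- .plantVariant(sid, r$gene, r$variant_spec, "missense", 2L,
                           model, purity[i], cfg$dna_depth, cfg$rna_depth)
      } else if (d == "tier3") {
        v <- .plantVariant(sid, sample(tier3Genes, 1), .randSpec(),
                           sample(c("missense", "nonsense", "frameshift"), 1,
                                  prob = c(0.7, 0.15, 0.15)),
                           3L, model, purity[i], cfg$dna_depth,
                           cfg$rna_depth)
      } else if (d == "tier4") {
        v <- .plantVariant(sid, sample(tier4Genes, 1), .randSpec(),
                           "missense", 4L, model, purity[i], cfg$dna_depth,
                           cfg$rna_depth)
      } else {
        v <- .plantVariant(sid, sample(noneGenes, 1), .randSpec(),
                           "missense", NA_integer_, model, purity[i],
                           cfg$dna_depth, cfg$rna_depth)
      }
      variants[[length(variants) + 1L]] <- v
    }
    if (hyper[i]) {
      # hypermutants carry the MMR splice-donor disruption
      variants[[length(variants) + 1L]] <-
        .plantVariant(sid, "MSH2", "c.366+1G>A", "splice_site", 4L, model,
                      purity[i], cfg$dna_depth, cfg$rna_depth)
    }
    if (tertExists && stats::runif(1) < cfg$tert_promoter_prob) {
      ex <- .geneExons(model, "TERT")
      tss1 <- if (ex$strand[[1]] == "+") min(ex$start) + 1L else max(ex$end)
      pos <- if (ex$strand[[1]] == "+") tss1 - 124L else tss1 + 124L
      variants[[length(variants) + 1L]] <- data.frame(
        sample_id = sid, chrom = ex$chrom[[1]], pos = pos, ref = "G",
        alt = "A", gene = "TERT", variant_spec = "c.-124C>T",
        consequence = "promoter", true_tier = NA_integer_,
        true_vaf = purity[i] / 2, depth = 60L, alt_reads = 20L,
        vaf = 1 / 3, rna_total = 0L, rna_alt = 0L, rna_vaf = NA_real_,
        stringsAsFactors = FALSE)
    }

    # germline het calls in decoy genes
    for (k in seq_len(cfg$n_germline)) {
      g <- sample(noneGenes, 1)
      ex <- .geneExons(model, g)
      j <- sample(nrow(ex), 1)
      pos <- sample((ex$start[j] + 1L):ex$end[j], 1)
      dep <- max(1L, stats::rpois(1, 40))
      altR <- stats::rbinom(1, dep, 0.5)
      germline[[length(germline) + 1L]] <- data.frame(
        sample_id = sid, chrom = ex$chrom[[1]], pos = pos,
        ref = sample(.BASES, 1), alt = sample(.BASES, 1),
        gene = g, variant_spec = sprintf("G%dR", pos %% 997L),
        vaf = altR / dep, stringsAsFactors = FALSE)
    }

    # copy-number segments: observed = purity * tumor + (1 - purity) * 2
    mix <- function(tumorCn) pmax(0, purity[i] * tumorCn +
                                    (1 - purity[i]) * 2 +
                                    stats::rnorm(1, 0, 0.05))
    base <- round(ploidy[i])
    addSeg <- function(chrom, start, end, tumorCn, class, focality) {
      segments[[length(segments) + 1L]] <<- data.frame(
        sample_id = sid, chrom = chrom, start = start, end = end,
        observed_cn = mix(tumorCn), true_class = class,
        true_focality = focality, stringsAsFactors = FALSE)
    }
    egfr <- .geneSpans(model); rownames(egfr) <- egfr$gene
    armLoss <- stats::runif(1) < cfg$p_arm_loss
    focalAmp <- stats::runif(1) < cfg$p_focal_amp
    homLoss <- stats::runif(1) < cfg$p_hom_loss
    addSeg("chr7", 0L, 1200000L,
           if (focalAmp) base else base, "neutral", NA)
    if (focalAmp) {
      sp <- egfr["EGFR", ]
      addSeg(sp$chrom, max(0L, sp$start - 30000L), sp$end + 30000L,
             stats::runif(1, 8, 25), "focal_amplification", "focal")
    }
    if (armLoss) {
      addSeg("chr10", 0L, 1200000L, 1, "heterozygous_loss", "arm_level")
    } else {
      addSeg("chr10", 0L, 1200000L, base, "neutral", NA)
    }
    if (homLoss) {
      sp <- egfr["CDKN2A", ]
      addSeg(sp$chrom, max(0L, sp$start - 20000L), sp$end + 20000L, 0,
             "homozygous_loss", "focal")
    }

    # canonical junctions for the splice-modeled genes, plus spikes
    spliceGenes <- intersect(c("MET", "EGFR", "PTEN", "TP53"), annot$gene)
    for (g in spliceGenes) {
      ga <- annot[annot$gene == g, , drop = FALSE]
      junctions[[length(junctions) + 1L]] <- data.frame(
        sample_id = sid, chrom = ga$chrom, donor_pos = ga$donor_pos,
        acceptor_pos = ga$acceptor_pos,
        read_count = stats::rpois(nrow(ga), 100),
        stringsAsFactors = FALSE)
    }
    if (stats::runif(1) < cfg$p_met_skip && "MET" %in% model$gene) {
      ex <- .geneExons(model, "MET")
      mid <- floor(nrow(ex) / 2)
      canonical <- 100
      alt <- round(cfg$met_skip_psi / 100 * canonical)
      junctions[[length(junctions) + 1L]] <- data.frame(
        sample_id = sid, chrom = ex$chrom[[1]],
        donor_pos = ex$end[mid - 1L] + 1L, acceptor_pos = ex$start[mid + 1L],
        read_count = alt, stringsAsFactors = FALSE)
      spliceTruth[[length(spliceTruth) + 1L]] <- data.frame(
        sample_id = sid, gene = "MET", donor_pos = ex$end[mid - 1L] + 1L,
        acceptor_pos = ex$start[mid + 1L], true_psi = cfg$met_skip_psi,
        skipped_exons = paste(ex$exon_number[mid], collapse = ";"),
        stringsAsFactors = FALSE)
    }
    if (stats::runif(1) < cfg$p_egfr_viii && "EGFR" %in% model$gene) {
      ex <- .geneExons(model, "EGFR")
      j <- min(8L, nrow(ex))
      junctions[[length(junctions) + 1L]] <- data.frame(
        sample_id = sid, chrom = ex$chrom[[1]],
        donor_pos = ex$end[1L] + 1L, acceptor_pos = ex$start[j],
        read_count = cfg$egfr_viii_reads, stringsAsFactors = FALSE)
      spliceTruth[[length(spliceTruth) + 1L]] <- data.frame(
        sample_id = sid, gene = "EGFR", donor_pos = ex$end[1L] + 1L,
        acceptor_pos = ex$start[j], true_psi = NA_real_,
        skipped_exons = paste(ex$exon_number[2:(j - 1L)], collapse = ";"),
        stringsAsFactors = FALSE)
      for (caller in c("delly", "breakdancer")) {
        svRecords[[length(svRecords) + 1L]] <- data.frame(
          sample_id = sid, chrom_a = ex$chrom[[1]],
          pos_a = ex$start[2L] - 50L, strand_a = "+",
          chrom_b = ex$chrom[[1]], pos_b = ex$end[j - 1L] + 50L,
          strand_b = "+", sv_type = "DEL", genes_hit = "EGFR",
          caller = caller, stringsAsFactors = FALSE)
      }
    }
  }

  genes <- unique(model$gene)
  meanlog <- stats::runif(length(genes), 0, 4)
  refExpr <- matrix(stats::rlnorm(length(genes) * cfg$reference_n,
                                  meanlog, 0.5),
                    nrow = length(genes),
                    dimnames = list(genes, sprintf("REF%03d",
                                                   seq_len(cfg$reference_n))))
  expr <- matrix(stats::rlnorm(length(genes) * n, meanlog, 0.5),
                 nrow = length(genes), dimnames = list(genes, sampleIds))

  .bind <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  methods::new("TumorCohort",
    samples = samples,
    variants = .bind(variants, data.frame()),
    germline = .bind(germline, data.frame()),
    segments = .bind(segments, data.frame()),
    junctions = .bind(junctions, data.frame()),
    sv = .bind(svRecords, data.frame()),
    expression = expr, referenceExpression = refExpr,
    spliceTruth = .bind(spliceTruth, data.frame()),
    config = unclass(cfg))
}

#' Observer settings for panels and automated curators
#'
#' @param panel_genes character vector: the panel's gene space.
#' @param matched_normal_used does the panel sequence a matched normal?
#' @param dropout_prob probability a truth call inside the gene space is
#'   missed (low-VAF dropout).
#' @param germline_contamination_rate probability a germline variant is
#'   emitted as somatic when no matched normal is used.
#' @param detect_prob automated-curator detection probability per truth
#'   call.
#' @param false_call_rate automated-curator probability of emitting a decoy
#'   call.
#' @param seed observer seed.
#' @return validated list of class `observer_config`.
#' @export
observerConfig <- function(panel_genes = character(),
                           matched_normal_used = TRUE,
                           dropout_prob = 0.1,
                           germline_contamination_rate = 0,
                           detect_prob = 0.71, false_call_rate = 0.2,
                           seed = 1L) {
  p <- c(dropout_prob, germline_contamination_rate, detect_prob,
         false_call_rate)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]",
                               call. = FALSE)
  structure(list(panel_genes = .normGene(panel_genes),
                 matched_normal_used = matched_normal_used,
                 dropout_prob = dropout_prob,
                 germline_contamination_rate = germline_contamination_rate,
                 detect_prob = detect_prob, false_call_rate = false_call_rate,
                 seed = seed),
            class = "observer_config")
}

#' Simulate a targeted panel observing a sample's truth calls
#'
#' Truth calls are masked to the panel's gene space and each surviving call
#' is dropped with the dropout probability; when the panel has no matched
#' normal, each confident germline variant (VAF >= 0.25) is added as a
#' somatic miscall with the contamination rate. Deterministic given the
#' observer seed.
#'
#' @param caseId case identifier.
#' @param truthVariants data.frame with gene and variant_spec columns (the
#'   sample's true somatic calls).
#' @param germlineVariants data.frame with gene, variant_spec, vaf.
#' @param observer an [observerConfig()].
#' @return a [callSet()] with `matched_normal_used` taken from the observer.
#' @export
observePanel <- function(caseId, truthVariants, germlineVariants, observer) {
  stopifnot(inherits(observer, "observer_config"))
  withr::with_seed(observer$seed, {
    keys <- normalizeCall(truthVariants$gene, truthVariants$variant_spec,
                          keyLevel = "variant")
    inSpace <- .normGene(truthVariants$gene) %in% observer$panel_genes
    keys <- keys[inSpace]
    kept <- keys[stats::runif(length(keys)) >= observer$dropout_prob]
    contam <- character()
    if (!observer$matched_normal_used &&
        observer$germline_contamination_rate > 0 &&
        nrow(germlineVariants) > 0L) {
      conf <- germlineVariants[germlineVariants$vaf >= 0.25, , drop = FALSE]
      if (nrow(conf) > 0L) {
        take <- stats::runif(nrow(conf)) < observer$germline_contamination_rate
        contam <- normalizeCall(conf$gene[take], conf$variant_spec[take],
                                keyLevel = "variant")
      }
    }
    callSet(caseId, c(kept, contam), source = "panel",
            matchedNormal = observer$matched_normal_used)
  })
}

#' Simulate an automated curator observing a truth call set
#'
#' Each truth call is detected with probability `detectProb`; each decoy in
#' the (truth-disjoint) decoy pool is emitted as a false call with
#' probability `falseCallRate`. Deterministic given the seed.
#'
#' @param truth a [callSet()] of truth calls.
#' @param detectProb per-call detection probability.
#' @param falseCallRate per-decoy false-call probability.
#' @param decoyPool character vector of keys disjoint from the truth calls.
#' @param seed integer seed.
#' @return a [callSet()] labeled `"automated_curator"`.
#' @export
observeCurator <- function(truth, detectProb, falseCallRate, decoyPool,
                           seed) {
  if (length(intersect(truth$calls, decoyPool)) > 0L)
    stop("decoy pool overlaps truth calls", call. = FALSE)
  withr::with_seed(seed, {
    kept <- truth$calls[stats::runif(length(truth$calls)) < detectProb]
    false <- decoyPool[stats::runif(length(decoyPool)) < falseCallRate]
    callSet(truth$case_id, c(kept, false), source = "automated_curator")
  })
}

#' Write a simulated cohort to disk in the standard input formats
#'
#' One somatic and one germline VCF per sample, segment/junction/SV TSVs,
#' the TPM tables and the gene model --- the same formats the ingest readers
#' consume, so a simulated cohort can round-trip through files.
#'
#' @param cohort a [TumorCohort-class].
#' @param dir output directory.
#' @param model gene model to write alongside (default [toyGeneModel()]).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir, model = toyGeneModel()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- cohortVariants(cohort); g <- cohortGermline(cohort)
  for (sid in cohortSamples(cohort)$sample_id) {
    sv <- v[v$sample_id == sid, , drop = FALSE]
    writeSomaticVcf(sv, file.path(dir, paste0(sid, ".somatic.vcf")))
    gl <- g[g$sample_id == sid, , drop = FALSE]
    gl$depth <- 40L; gl$consequence <- NA_character_
    writeSomaticVcf(gl, file.path(dir, paste0(sid, ".germline.vcf")))
  }
  writeCnvSegments(cohortSegments(cohort), file.path(dir, "segments.tsv"))
  writeJunctions(cohortJunctions(cohort), file.path(dir, "junctions.tsv"))
  if (nrow(cohortSv(cohort)) > 0L)
    writeSv(cohortSv(cohort), file.path(dir, "sv.tsv"))
  writeExpression(cohortExpression(cohort), file.path(dir, "tpm.tsv"))
  writeExpression(referenceExpression(cohort),
                  file.path(dir, "reference_tpm.tsv"))
  writeGeneModel(model, file.path(dir, "gene_model.tsv"))
  .writeTsv(cohortSamples(cohort), file.path(dir, "samples.tsv"))
  invisible(dir)
}
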