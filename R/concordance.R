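#' Normalize call keys for concordance analysis
#'
#' Builds canonical call keys at one of three granularities:
#' `variant` (`GENE:SPEC`, so a point mutation and a copy gain of the same
#' gene stay distinct), `gene` (all alterations of a gene collapse to the
#' symbol), or `drug_target` (normalized drug names, for comparing
#' recommended therapies).
#'
#' @param gene gene symbols (ignored for `drug_target`).
#' @param variantSpec variant specs (required for `variant` level).
#' @param drug drug names (required for `drug_target` level).
#' @param keyLevel `"variant"`, `"gene"` or `"drug_target"`.
#' @return character vector of canonical keys.
#' @export
normalizeCall <- function(gene = NULL, variantSpec = NULL, drug = NULL,
                          keyLevel = c("variant", "gene", "drug_target")) {
  keyLevel <- match.arg(keyLevel)
  switch(keyLevel,
    variant = {
      if (is.null(gene) || is.null(variantSpec))
        stop("variant-level keys need gene and variantSpec", call. = FALSE)
      paste0(.normGene(gene), ":", .normSpec(variantSpec))
    },
    gene = {
      if (is.null(gene)) stop("gene-level keys need gene", call. = FALSE)
      .normGene(gene)
    },
    drug_target = {
      if (is.null(drug)) stop("drug_target keys need drug", call. = FALSE)
      normalizeDrugName(drug)
    })
}

#' A call set for concordance comparison
#'
#' @param caseId case identifier.
#' @param calls character vector of normalized call keys (deduplicated).
#' @param source label of the calling source.
#' @param matchedNormal whether the assay used a matched normal (panels
#'   without one are audited for germline miscalls).
#' @return list of class `call_set`.
#' @export
callSet <- function(caseId, calls, source = "unknown", matchedNormal = TRUE) {
  structure(list(case_id = caseId, calls = unique(as.character(calls)),
                 source = source, matched_normal_used = matchedNormal),
            class = "call_set")
}

#' Compare a WGS call set against a targeted-panel call set
#'
#' Computes the common / WGS-unique / panel-unique partition at a fixed key
#' level, optionally restricting the WGS set to the panel's gene space
#' (off-space WGS-unique calls are then reported separately). Panel calls
#' whose keys appear in the case's germline call set are flagged as germline
#' miscalls --- but only when the panel lacks a matched normal, since
#' matched-normal assays subtract germline variation by design.
#'
#' @param wgs,panel `call_set` objects for the same case.
#' @param germlineKeys character vector of the case's germline call keys
#'   (already filtered to confident germline VAF).
#' @param panelGeneSpace optional character vector of panel genes; WGS keys
#'   whose gene prefix is outside it are moved to `off_space_wgs_unique`.
#' @return list: case_id, common, wgs_unique, panel_unique,
#'   germline_miscalls, off_space_wgs_unique (character vectors of keys).
#' @export
comparePanel <- function(wgs, panel, germlineKeys = character(),
                         panelGeneSpace = NULL) {
  if (!identical(wgs$case_id, panel$case_id))
    stop("call sets are for different cases: ", wgs$case_id, " vs ",
         panel$case_id, call. = FALSE)
  wgsCalls <- wgs$calls
  offSpace <- character()
  if (!is.null(panelGeneSpace)) {
    genePart <- sub(":.*$", "", wgsCalls)
    inSpace <- genePart %in% .normGene(panelGeneSpace)
    offSpace <- wgsCalls[!inSpace]
    wgsCalls <- wgsCalls[inSpace]
  }
  common <- intersect(wgsCalls, panel$calls)
  wgsUnique <- setdiff(wgsCalls, panel$calls)
  panelUnique <- setdiff(panel$calls, wgsCalls)
  miscalls <- if (isFALSE(panel$matched_normal_used))
    intersect(panel$calls, germlineKeys) else character()
  list(case_id = wgs$case_id, common = common, wgs_unique = wgsUnique,
       panel_unique = panelUnique, germline_miscalls = miscalls,
       off_space_wgs_unique = offSpace)
}

#' Sensitivity and PPV of a test call set against a truth set
#'
#' `sensitivity = |truth \\* test| / |truth|`; `ppv = |truth \\* test| /
#' |test|` (intersections). An empty truth set leaves sensitivity undefined
#' (`NA`); an empty test set gives sensitivity 0 and undefined PPV.
#' Undefined rows are flagged and later excluded from cohort means.
#'
#' @param truth,test `call_set` objects for the same case.
#' @return list case_id, sensitivity, ppv, truth_n, test_n, tp.
#' @export
sensitivityPpv <- function(truth, test) {
  if (!identical(truth$case_id, test$case_id))
    stop("call sets are for different cases", call. = FALSE)
  tp <- length(intersect(truth$calls, test$calls))
  truthN <- length(truth$calls); testN <- length(test$calls)
  list(case_id = truth$case_id,
       sensitivity = if (truthN > 0L) tp / truthN else NA_real_,
       ppv = if (testN > 0L) tp / testN else NA_real_,
       truth_n = truthN, test_n = testN, tp = tp)
}

#' Cohort summary of concordance comparisons
#'
#' For curator comparisons (a list of [sensitivityPpv()] rows): the mean and
#' SD (n-1 denominator) of sensitivity and PPV over cases where they are
#' defined, plus the count of undefined rows.
#'
#' For panel comparisons (a list of [comparePanel()] rows): the
#' actionability-gain rate (fraction of cases with at least one WGS-unique
#' call) and the median/IQR of per-case common, WGS-unique and panel-unique
#' counts.
#'
#' @param rows list of comparison rows of one kind.
#' @return named list of summary statistics.
#' @export
summarizeCohort <- function(rows) {
  if (length(rows) == 0L) stop("no comparison rows", call. = FALSE)
  if (!is.null(rows[[1]]$sensitivity)) {
    sens <- vapply(rows, `[[`, numeric(1), "sensitivity")
    ppv <- vapply(rows, `[[`, numeric(1), "ppv")
    .ms <- function(x) {
      x <- x[!is.na(x)]
      list(mean = mean(x),
           sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
           n = length(x))
    }
    s <- .ms(sens); p <- .ms(ppv)
    list(kind = "curator",
         mean_sensitivity = s$mean, sd_sensitivity = s$sd,
         n_sensitivity = s$n, n_undefined_sensitivity = sum(is.na(sens)),
         mean_ppv = p$mean, sd_ppv = p$sd, n_ppv = p$n,
         n_undefined_ppv = sum(is.na(ppv)))
  } else if (!is.null(rows[[1]]$wgs_unique)) {
    nWgsU <- vapply(rows, function(r) length(r$wgs_unique), integer(1))
    nCommon <- vapply(rows, function(r) length(r$common), integer(1))
    nPanelU <- vapply(rows, function(r) length(r$panel_unique), integer(1))
    nGerm <- vapply(rows, function(r) length(r$germline_miscalls), integer(1))
    list(kind = "panel",
         n_cases = length(rows),
         actionability_gain_rate = mean(nWgsU >= 1L),
         median_wgs_unique = stats::median(nWgsU),
         iqr_wgs_unique = stats::IQR(nWgsU),
         median_common = stats::median(nCommon),
         iqr_common = stats::IQR(nCommon),
         median_panel_unique = stats::median(nPanelU),
         iqr_panel_unique = stats::IQR(nPanelU),
         total_germline_miscalls = sum(nGerm))
  } else stop("unrecognized comparison rows", call. = FALSE)
}

#' Long-format per-case comparison table
#'
#' Export helper: one row per (case, category) count, matching the
#' common / unique / germline-miscall accounting used in panel-comparison
#' heatmaps.
#'
#' @param rows list of [comparePanel()] results.
#' @return data.frame case_id, category, count.
#' @export
panelComparisonTable <- function(rows) {
  do.call(rbind, lapply(rows, function(r) {
    data.frame(case_id = r$case_id,
               category = c("common", "wgs_unique", "panel_unique",
                            "germline_miscall"),
               count = c(length(r$common), length(r$wgs_unique),
                         length(r$panel_unique),
                         length(r$germline_miscalls)),
               stringsAsFactors = FALSE)
  }))
}
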