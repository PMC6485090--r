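#' Normalize a drug name
#'
#' Collapses the spelling variants that clinical tables accumulate: the name
#' is case-folded to upper case, hyphens and whitespace are removed, and a
#' misspelling alias map is applied (the bundled map reconciles e.g.
#' `"Afatnib"` with `"Afatanib"` and `"ABT41"` with `"ABT414"`). Combination
#' entries joined by `"/"` should be split with [splitDrugEntry()] before
#' calling this. The function is idempotent and pure.
#'
#' @param raw character vector of raw drug names.
#' @param aliases named character vector mapping normalized misspellings to
#'   canonical normalized names; defaults to the bundled alias map.
#' @return character vector of normalized names.
#' @examples
#' normalizeDrugName(c("ABT-414", "abt414", "Afatnib"))
#' @export
normalizeDrugName <- function(raw, aliases = NULL) {
  if (is.null(aliases)) aliases <- bundledDrugAliases()
  x <- gsub("[-[:space:]]", "", toupper(trimws(as.character(raw))))
  hit <- match(x, names(aliases))
  x[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  x
}

#' Split a combination drug entry
#'
#' Entries such as `"RG7112/RG7388"` or `"Temsirolimus/Docetaxel"` denote two
#' drugs; this splits them on `"/"` and trims whitespace.
#'
#' @param entry character vector of drug cell entries.
#' @return character vector with one element per drug.
#' @export
splitDrugEntry <- function(entry) {
  trimws(unlist(strsplit(as.character(entry), "/", fixed = TRUE),
                use.names = FALSE))
}

#' @rdname bundledKnowledgeBase
#' @export
bundledDrugAliases <- function() {
  df <- .readTsv(.extdata("kb", "drug_aliases.tsv"))
  .requireCols(df, c("alias", "canonical"), "drug_aliases")
  stats::setNames(toupper(df$canonical), toupper(df$alias))
}

.loadGeneSets <- function(path) {
  df <- .readTsv(path)
  .requireCols(df, c("set_name", "gene"), "gene_sets")
  sets <- split(.normGene(df$gene), df$set_name)
  lapply(sets, function(g) sort(unique(g)))
}

.normalizeTrialIds <- function(ids) {
  if (is.na(ids) || !nzchar(ids) || ids == ".") return(NA_character_)
  parts <- toupper(gsub("[[:space:]]", "", strsplit(ids, ";", fixed = TRUE)[[1]]))
  paste(parts, collapse = ";")
}

#' Load a knowledge base from TSV files
#'
#' Reads and validates the four knowledge-base tables (clinical evidence,
#' drug--gene associations, gene sets, pathway map) plus the drug-name alias
#' map, normalizes gene symbols (upper case), variant specs (whitespace
#' stripped, upper case) and drug names (via [normalizeDrugName()]),
#' collapses duplicate rows, and returns a validated [KnowledgeBase-class].
#'
#' @param dir directory holding `evidence.tsv`, `drugs.tsv`, `gene_sets.tsv`,
#'   `pathways.tsv` and optionally `drug_aliases.tsv`. Ignored when `paths`
#'   is given.
#' @param paths named list overriding individual file paths (roles:
#'   `evidence`, `drugs`, `gene_sets`, `pathways`, `aliases`).
#' @return a [KnowledgeBase-class] object.
#' @seealso [bundledKnowledgeBase()], [writeKnowledgeBase()]
#' @export
loadKnowledgeBase <- function(dir = NULL, paths = list()) {
  if (!is.null(dir)) {
    default <- list(evidence = file.path(dir, "evidence.tsv"),
                    drugs = file.path(dir, "drugs.tsv"),
                    gene_sets = file.path(dir, "gene_sets.tsv"),
                    pathways = file.path(dir, "pathways.tsv"),
                    aliases = file.path(dir, "drug_aliases.tsv"))
    for (nm in names(default))
      if (is.null(paths[[nm]])) paths[[nm]] <- default[[nm]]
  }
  for (nm in c("evidence", "drugs", "gene_sets", "pathways"))
    if (is.null(paths[[nm]]))
      stop("no path for knowledge-base role: ", nm, call. = FALSE)

  aliases <- if (!is.null(paths$aliases) && file.exists(paths$aliases)) {
    df <- .readTsv(paths$aliases)
    .requireCols(df, c("alias", "canonical"), "drug_aliases")
    stats::setNames(toupper(df$canonical), toupper(df$alias))
  } else character()

  ev <- .readTsv(paths$evidence)
  .requireCols(ev, .EVIDENCE_COLS, "evidence")
  ev$gene <- .normGene(ev$gene)
  ev$variant_spec <- .normSpec(ev$variant_spec)
  ev$disease <- tolower(trimws(ev$disease))
  ev <- ev[!duplicated(ev[, .EVIDENCE_COLS]), , drop = FALSE]
  rownames(ev) <- NULL

  dr <- .readTsv(paths$drugs)
  .requireCols(dr, .DRUG_COLS, "drugs")
  dr$gene <- .normGene(dr$gene)
  dr$variant_spec <- .normSpec(.dotNA(dr$variant_spec))
  dr$drug <- normalizeDrugName(dr$drug, aliases)
  dr$disease <- tolower(trimws(.dotNA(dr$disease)))
  dr$trial_ids <- vapply(.dotNA(dr$trial_ids), .normalizeTrialIds,
                         character(1), USE.NAMES = FALSE)
  badTrial <- which(!is.na(dr$trial_ids) &
                      !grepl("^NCT[0-9]+(;NCT[0-9]+)*$", dr$trial_ids))
  if (length(badTrial) > 0L)
    stop("malformed trial id(s) in drugs table, row(s): ",
         paste(badTrial, collapse = ", "), call. = FALSE)
  key <- paste(dr$gene, dr$variant_spec, dr$disease, dr$drug, dr$variant_scope)
  if (anyDuplicated(key)) {
    # collapse case-variant duplicates, taking the union of their trials
    keep <- !duplicated(key)
    trialUnion <- vapply(split(dr$trial_ids, key), function(t) {
      t <- unique(unlist(strsplit(t[!is.na(t)], ";")))
      if (length(t) == 0L) NA_character_ else paste(sort(t), collapse = ";")
    }, character(1))
    dr <- dr[keep, , drop = FALSE]
    dr$trial_ids <- unname(trialUnion[paste(dr$gene, dr$variant_spec,
                                            dr$disease, dr$drug,
                                            dr$variant_scope)])
  }
  rownames(dr) <- NULL

  sets <- .loadGeneSets(paths$gene_sets)

  pw <- .readTsv(paths$pathways)
  .requireCols(pw, c("pathway", "gene", "role"), "pathways")
  pw$gene <- .normGene(pw$gene)

  methods::new("KnowledgeBase", evidence = ev, drugs = dr, geneSets = sets,
               pathways = pw, aliases = aliases)
}

#' The bundled glioblastoma knowledge base
#'
#' Loads the knowledge base shipped with the package: variant-level clinical
#' evidence for the study disease (glioblastoma) and other tumor types,
#' drug--gene associations with trial identifiers covering the cohort's
#' recurrent targets (EGFR, PTEN, CDKN2A, MET, ...), the actionable-gene and
#' cancer-census gene sets, a mismatch-repair gene set, a 15-gene panel space,
#' and the RTK/PI3K/mTOR, RB, p53 and RAS/MAPK pathway maps.
#' `bundledDrugAliases()` returns the misspelling alias map alone.
#'
#' @return a [KnowledgeBase-class] object.
#' @examples
#' kb <- bundledKnowledgeBase()
#' kb
#' @export
bundledKnowledgeBase <- function() {
  loadKnowledgeBase(dir = .extdata("kb"))
}

#' Serialize a knowledge base back to TSV
#'
#' Writes the four knowledge-base tables (plus the alias map when present) in
#' the same schema [loadKnowledgeBase()] reads, so that load-write-load is an
#' identity.
#'
#' @param kb a [KnowledgeBase-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeKnowledgeBase <- function(kb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .writeTsv(kb@evidence, file.path(dir, "evidence.tsv"))
  dr <- kb@drugs
  dr$variant_spec[is.na(dr$variant_spec)] <- "."
  dr$trial_ids[is.na(dr$trial_ids)] <- "."
  dr$disease[is.na(dr$disease)] <- "."
  .writeTsv(dr, file.path(dir, "drugs.tsv"))
  sets <- kb@geneSets
  .writeTsv(data.frame(set_name = rep(names(sets), lengths(sets)),
                       gene = unlist(sets, use.names = FALSE)),
            file.path(dir, "gene_sets.tsv"))
  .writeTsv(kb@pathways, file.path(dir, "pathways.tsv"))
  if (length(kb@aliases) > 0L)
    .writeTsv(data.frame(alias = names(kb@aliases),
                         canonical = unname(kb@aliases)),
              file.path(dir, "drug_aliases.tsv"))
  invisible(dir)
}

#' Query variant-level clinical evidence
#'
#' Exact-match lookup of evidence rows for a (gene, variant spec) pair, split
#' into same-disease and other-disease matches. Disease labels are compared
#' case-insensitively; the tier rules treat same-disease clinically
#' significant evidence as Tier 1 and other-disease evidence as Tier 2.
#'
#' @param kb a [KnowledgeBase-class].
#' @param gene gene symbol.
#' @param variantSpec exact variant spec (protein change, `"amplification"`,
#'   `"loss"`, ...).
#' @param disease study disease label (default `"glioblastoma"`).
#' @return data.frame of matching evidence rows with a logical
#'   `same_disease` column; zero rows when nothing matches.
#' @export
queryEvidence <- function(kb, gene, variantSpec, disease = "glioblastoma") {
  ev <- kb@evidence
  hit <- ev[ev$gene == .normGene(gene) &
              ev$variant_spec == .normSpec(variantSpec), , drop = FALSE]
  hit$same_disease <- hit$disease == tolower(trimws(disease))
  rownames(hit) <- NULL
  hit
}

#' Query drug--gene associations
#'
#' Returns drug associations for a gene whose `variant_scope` is compatible
#' with the observed alteration class: `any_alteration` matches every class,
#' `gain`/`loss` match copy-number gains/losses, and `specific_variant`
#' requires an exact variant-spec match (SNV/indel or SV specs such as
#' `"VIII"`).
#'
#' @param kb a [KnowledgeBase-class].
#' @param gene gene symbol.
#' @param alterationClass one of `"snv"`, `"gain"`, `"loss"`, `"sv"`,
#'   `"expression"`.
#' @param variantSpec optional exact spec, consulted for
#'   `specific_variant`-scoped rows.
#' @return data.frame of matching drug-association rows (possibly empty).
#' @export
queryDrugs <- function(kb, gene, alterationClass, variantSpec = NULL) {
  allowed <- c("snv", "gain", "loss", "sv", "expression")
  if (length(alterationClass) != 1L || !alterationClass %in% allowed)
    stop("alterationClass must be one of: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  dr <- kb@drugs
  dr <- dr[dr$gene == .normGene(gene), , drop = FALSE]
  if (nrow(dr) == 0L) return(dr)
  spec <- if (is.null(variantSpec)) NA_character_ else .normSpec(variantSpec)
  ok <- dr$variant_scope == "any_alteration" |
    (dr$variant_scope == "gain" & alterationClass == "gain") |
    (dr$variant_scope == "loss" & alterationClass == "loss") |
    (dr$variant_scope == "specific_variant" & !is.na(spec) &
       !is.na(dr$variant_spec) & dr$variant_spec == spec &
       alterationClass %in% c("snv", "sv"))
  out <- dr[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}
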