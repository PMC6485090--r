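#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.normGene <- function(x) toupper(trimws(as.character(x)))

# variant specs ("R132H", "c.366+1G>A", "amplification") are compared as
# whitespace-stripped upper-case strings; no HGVS parsing
.normSpec <- function(x) gsub("[[:space:]]", "", toupper(as.character(x)))

.readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.requireCols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stop(what, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(df)
}

.extdata <- function(...) {
  path <- system.file("extdata", ..., package = "oncotier", mustWork = FALSE)
  if (!nzchar(path)) stop("bundled file not found: ",
                          file.path(...), call. = FALSE)
  path
}

# dot-as-NA convention used by the bundled TSVs
.dotNA <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "." | x == "")] <- NA_character_
  x
}
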