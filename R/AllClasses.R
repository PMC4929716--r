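#' @import methods
NULL

## Canonical field roles of an annotated variant table. The first seven are
## mandatory; frequency and score columns may be absent from a given export.
.MANDATORY_ROLES <- c("chrom", "start", "end", "ref", "alt",
                      "func_region", "gene", "exonic_func")
.OPTIONAL_ROLES  <- c("freq_1kgp", "freq_esp6500", "gerp", "fathmm")
.ALL_ROLES       <- c(.MANDATORY_ROLES, .OPTIONAL_ROLES)
.NUMERIC_ROLES   <- c("start", "end", .OPTIONAL_ROLES)

#' AnnotationSchema: map raw table headers to canonical field roles
#'
#' An `AnnotationSchema` records, for a particular tab-delimited annotation
#' export, which raw column header plays each canonical role (chromosome,
#' position, gene symbol, functional class, population frequencies,
#' conservation and pathogenicity scores), together with the dialect the
#' table was written in and the token that encodes a missing value.
#'
#' @slot columnOf Named character vector mapping canonical role names to raw
#'   header strings. Roles `chrom`, `start`, `end`, `ref`, `alt`,
#'   `func_region`, `gene`, `exonic_func` are mandatory; `freq_1kgp`,
#'   `freq_esp6500`, `gerp`, `fathmm` are optional.
#' @slot dialect Either `"wannovar_multianno"` (headers resolved through the
#'   built-in alias table) or `"generic"` (user-supplied column map).
#' @slot missingToken String written in a cell when the value is absent
#'   (default `"."`, the ANNOVAR convention). Empty cells are always treated
#'   as missing as well.
#'
#' @seealso [detectSchema()], [annotationSchema()], [readVariantTable()]
#' @export
setClass("AnnotationSchema",
  representation(columnOf = "character",
                 dialect = "character",
                 missingToken = "character"),
  prototype(columnOf = character(), dialect = "generic", missingToken = "."))

setValidity("AnnotationSchema", function(object) {
  msgs <- character()
  roles <- names(object@columnOf)
  if (is.null(roles) && length(object@columnOf) > 0)
    msgs <- c(msgs, "columnOf must be a named character vector")
  bad <- setdiff(roles, .ALL_ROLES)
  if (length(bad))
    msgs <- c(msgs, paste0("unknown role(s): ", paste(bad, collapse = ", ")))
  if (anyDuplicated(roles))
    msgs <- c(msgs, "each role may map to at most one raw header")
  if (anyDuplicated(object@columnOf))
    msgs <- c(msgs, "two roles map to the same raw header")
  miss <- setdiff(.MANDATORY_ROLES, roles)
  if (length(miss))
    msgs <- c(msgs, paste0("mandatory role(s) unmapped: ",
                           paste(miss, collapse = ", ")))
  if (length(object@dialect) != 1L ||
      !object@dialect %in% c("wannovar_multianno", "generic"))
    msgs <- c(msgs, "dialect must be 'wannovar_multianno' or 'generic'")
  if (length(object@missingToken) != 1L || !nzchar(object@missingToken))
    msgs <- c(msgs, "missingToken must be a single non-empty string")
  if (length(msgs)) msgs else TRUE
})

#' VariantTable: an ordered collection of annotated variant records
#'
#' One row per variant, in file order, with canonical columns `chrom`,
#' `start`, `end`, `ref`, `alt`, `func_region`, `gene`, `exonic_func`,
#' `freq_1kgp`, `freq_esp6500`, `gerp`, `fathmm` plus any unmapped
#' passthrough columns from the source table. Missing values are `NA` —
#' a distinct state, never coerced to 0 or a sentinel — and every filter
#' treats them explicitly. Coordinates are 1-based and end-inclusive, as
#' emitted by ANNOVAR; no conversion is performed.
#'
#' @slot variants `data.frame` holding the records; canonical columns first,
#'   passthrough extras after.
#' @slot schema The [AnnotationSchema-class] the table was read with (used to
#'   reproduce raw headers on output).
#'
#' @seealso [readVariantTable()], [writeShortlist()], [runCascade()]
#' @export
setClass("VariantTable",
  representation(variants = "data.frame", schema = "AnnotationSchema"))

setValidity("VariantTable", function(object) {
  df <- object@variants
  msgs <- character()
  need <- setdiff(.MANDATORY_ROLES, names(df))
  if (length(need))
    return(paste0("missing canonical column(s): ", paste(need, collapse = ", ")))
  for (cn in intersect(.NUMERIC_ROLES, names(df)))
    if (!is.numeric(df[[cn]]))
      msgs <- c(msgs, paste0("column '", cn, "' must be numeric"))
  if (!length(msgs) && nrow(df)) {
    if (anyNA(df$start) || anyNA(df$end))
      msgs <- c(msgs, "start/end must be present on every record")
    else if (any(df$start > df$end))
      msgs <- c(msgs, "start must be <= end on every record")
    for (fc in c("freq_1kgp", "freq_esp6500")) {
      v <- df[[fc]]
      if (!is.null(v) && any(!is.na(v) & (v < 0 | v > 1)))
        msgs <- c(msgs, paste0(fc, " must lie in [0, 1] when present"))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' FilterConfig: thresholds and missing-value policies for the cascade
#'
#' Holds every tunable of filtration steps 1-6. Defaults implement the
#' published rules: keep exonic records; remove synonymous and nonframeshift
#' classes; remove records with population frequency strictly above 1% in
#' the 1000 Genomes Project or ESP6500 (at-or-below 1% is rare and kept);
#' remove records with negative GERP (conservation) score; remove records
#' with FATHMM score strictly above 1.0. Records missing a frequency or
#' score are kept by default at every step — variants with no available
#' frequency data are prioritized, and indels carry no GERP/FATHMM score
#' yet must survive to the shortlist.
#'
#' @slot exonicKeep Character set of `func_region` values kept at step 1.
#' @slot includeSplicing If `TRUE`, `"splicing"` is added to `exonicKeep`.
#' @slot exonicFuncRemove Character set of `exonic_func` classes removed at
#'   step 2.
#' @slot freqThreshold1kgp,freqThresholdEsp Rarity thresholds as fractions in
#'   \[0, 1\]; a record is removed when its frequency is present and strictly
#'   greater than the threshold.
#' @slot keepMissingFreq,keepMissingGerp,keepMissingFathmm Whether records
#'   missing the respective value pass that step.
#' @slot gerpMin Keep when `gerp >= gerpMin`; the default 0 removes exactly
#'   the negative (non-conserved) scores.
#' @slot fathmmMax Keep when `fathmm <= fathmmMax`; default 1.0, strict
#'   preset -1.5.
#'
#' @seealso [filterConfig()], [runCascade()]
#' @export
setClass("FilterConfig",
  representation(exonicKeep = "character",
                 includeSplicing = "logical",
                 exonicFuncRemove = "character",
                 freqThreshold1kgp = "numeric",
                 freqThresholdEsp = "numeric",
                 keepMissingFreq = "logical",
                 gerpMin = "numeric",
                 keepMissingGerp = "logical",
                 fathmmMax = "numeric",
                 keepMissingFathmm = "logical"),
  prototype(exonicKeep = c("exonic", "exonic;splicing"),
            includeSplicing = FALSE,
            exonicFuncRemove = c("synonymous SNV",
                                 "nonframeshift insertion",
                                 "nonframeshift deletion",
                                 "nonframeshift substitution"),
            freqThreshold1kgp = 0.01,
            freqThresholdEsp = 0.01,
            keepMissingFreq = TRUE,
            gerpMin = 0,
            keepMissingGerp = TRUE,
            fathmmMax = 1.0,
            keepMissingFathmm = TRUE))

setValidity("FilterConfig", function(object) {
  msgs <- character()
  for (s in c("freqThreshold1kgp", "freqThresholdEsp")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msgs <- c(msgs, paste0(s, " must be a single value in [0, 1]"))
  }
  for (s in c("gerpMin", "fathmmMax")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msgs <- c(msgs, paste0(s, " must be a single finite value"))
  }
  for (s in c("includeSplicing", "keepMissingFreq", "keepMissingGerp",
              "keepMissingFathmm")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v))
      msgs <- c(msgs, paste0(s, " must be TRUE or FALSE"))
  }
  if (!length(object@exonicKeep))
    msgs <- c(msgs, "exonicKeep must be non-empty")
  if (length(msgs)) msgs else TRUE
})

#' CascadeReport: per-step surviving-record ledger
#'
#' The stepwise attrition record of a cascade run: an ordered list of step
#' labels and, for each, the number of records surviving that step.
#' `counts()` has one more element than there are steps — element 1 is the
#' input size — and is non-increasing; `removed()` is its successive
#' difference.
#'
#' @slot stepLabels Character vector of step descriptions, beginning with
#'   the input row.
#' @slot counts Integer vector of surviving-record counts, aligned with
#'   `stepLabels`.
#'
#' @seealso [runCascade()], [writeCascadeReport()]
#' @export
setClass("CascadeReport",
  representation(stepLabels = "character", counts = "integer"))

setValidity("CascadeReport", function(object) {
  msgs <- character()
  if (length(object@stepLabels) != length(object@counts))
    msgs <- c(msgs, "stepLabels and counts must have equal length")
  if (length(object@counts)) {
    if (anyNA(object@counts) || any(object@counts < 0))
      msgs <- c(msgs, "counts must be non-negative integers")
    else if (is.unsorted(rev(object@counts)))
      msgs <- c(msgs, "counts must be non-increasing")
  }
  if (length(msgs)) msgs else TRUE
})

#' GeneDiseaseMap: gene symbol to known-disorder lookup
#'
#' A local stand-in for OMIM-genemap-like or DISEASES-export-like lookups:
#' each entry links an upper-cased gene symbol to one disorder description
#' string with a source tag. Duplicate (gene, disorder) pairs are collapsed
#' on load.
#'
#' @slot entries `data.frame` with character columns `gene`, `disorder`,
#'   `source`.
#'
#' @seealso [readGeneDiseaseMap()], [matchDiseases()]
#' @export
setClass("GeneDiseaseMap", representation(entries = "data.frame"))

setValidity("GeneDiseaseMap", function(object) {
  df <- object@entries
  need <- setdiff(c("gene", "disorder", "source"), names(df))
  if (length(need))
    return(paste0("entries must have column(s): ", paste(need, collapse = ", ")))
  if (nrow(df)) {
    if (anyNA(df$gene) || any(!nzchar(df$gene)))
      return("gene symbols must be non-empty")
    if (anyNA(df$disorder) || any(!nzchar(trimws(df$disorder))))
      return("disorder descriptions must be non-empty")
    if (any(df$gene != toupper(df$gene)))
      return("gene symbols must be upper-cased")
    if (anyDuplicated(df[c("gene", "disorder")]))
      return("(gene, disorder) pairs must be unique")
  }
  TRUE
})
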