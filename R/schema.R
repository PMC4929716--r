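## wANNOVAR/ANNOVAR header names drifted across releases; this alias table
## covers the common spellings of both the "exome summary" and "genome
## summary" exports. Resolution is case-insensitive.
.WANNOVAR_ALIASES <- list(
  chrom        = c("Chr"),
  start        = c("Start"),
  end          = c("End"),
  ref          = c("Ref"),
  alt          = c("Alt"),
  func_region  = c("Func.refGene", "Func.refgene", "Func.knownGene"),
  gene         = c("Gene.refGene", "Gene.refgene", "Gene.knownGene"),
  exonic_func  = c("ExonicFunc.refGene", "ExonicFunc.refgene",
                   "ExonicFunc.knownGene"),
  freq_1kgp    = c("1000g2015aug_all", "1000g2014oct_all", "1000G_ALL",
                   "1000g_all"),
  freq_esp6500 = c("esp6500siv2_all", "esp6500si_all", "ESP6500_ALL"),
  gerp         = c("GERP++_RS", "gerp++gt2", "GERP_RS"),
  fathmm       = c("FATHMM_score", "FATHMM")
)

#' Construct an AnnotationSchema
#'
#' Build a schema by hand, typically for a `"generic"` table whose headers
#' are not in the wANNOVAR dialect. For wANNOVAR-style exports use
#' [detectSchema()], which resolves headers through the built-in alias
#' table.
#'
#' @param columnOf Named character vector: canonical role -> raw header.
#'   Mandatory roles: `chrom`, `start`, `end`, `ref`, `alt`, `func_region`,
#'   `gene`, `exonic_func`; optional: `freq_1kgp`, `freq_esp6500`, `gerp`,
#'   `fathmm`.
#' @param dialect `"generic"` or `"wannovar_multianno"`.
#' @param missingToken Token encoding a missing value (default `"."`).
#' @return An [AnnotationSchema-class].
#' @examples
#' annotationSchema(c(chrom = "chromosome", start = "pos", end = "pos_end",
#'                    ref = "REF", alt = "ALT", func_region = "region",
#'                    gene = "symbol", exonic_func = "effect"))
#' @export
annotationSchema <- function(columnOf, dialect = "generic",
                             missingToken = ".") {
  new("AnnotationSchema", columnOf = columnOf, dialect = dialect,
      missingToken = missingToken)
}

#' Detect the annotation schema of a header row
#'
#' Resolves each header against the built-in wANNOVAR alias table
#' (case-insensitive). When all eight mandatory roles resolve, a
#' `wannovar_multianno` schema is returned with whatever optional roles were
#' also found; otherwise an error names every unresolved mandatory role.
#'
#' @param headerRow Character vector of raw column headers (whitespace is
#'   stripped before matching).
#' @param missingToken Missing-value token to record in the schema.
#' @return An [AnnotationSchema-class] with `dialect = "wannovar_multianno"`.
#' @examples
#' detectSchema(c("Chr", "Start", "End", "Ref", "Alt", "Func.refGene",
#'                "Gene.refGene", "ExonicFunc.refGene", "1000g2015aug_all",
#'                "esp6500siv2_all", "GERP++_RS", "FATHMM_score"))
#' @export
detectSchema <- function(headerRow, missingToken = ".") {
  if (!length(headerRow))
    stop("header row is empty", call. = FALSE)
  headers <- trimws(headerRow)
  dup <- unique(headers[duplicated(headers)])
  if (length(dup))
    stop("duplicate header(s): ", paste(dup, collapse = ", "), call. = FALSE)
  lowered <- tolower(headers)
  columnOf <- character()
  for (role in names(.WANNOVAR_ALIASES)) {
    hit <- which(lowered %in% tolower(.WANNOVAR_ALIASES[[role]]))
    if (length(hit))
      columnOf[[role]] <- headers[hit[1L]]
  }
  unresolved <- setdiff(.MANDATORY_ROLES, names(columnOf))
  if (length(unresolved))
    stop("cannot detect schema; unresolved mandatory role(s): ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  annotationSchema(columnOf, dialect = "wannovar_multianno",
                   missingToken = missingToken)
}

#' Read or write a schema / column map as YAML
#'
#' The YAML layout has keys `dialect`, `missing_token` and a `columns`
#' mapping of canonical role to raw header, so a user can supply a column
#' map for any generic tab-delimited export without code changes.
#'
#' @param path YAML file path.
#' @return `readSchema()` returns an [AnnotationSchema-class];
#'   `writeSchema()` returns `path` invisibly.
#' @export
readSchema <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$columns))
    stop("schema YAML must contain a 'columns' mapping", call. = FALSE)
  annotationSchema(unlist(doc$columns),
                   dialect = if (is.null(doc$dialect)) "generic"
                             else doc$dialect,
                   missingToken = if (is.null(doc$missing_token)) "."
                                  else doc$missing_token)
}

#' @rdname readSchema
#' @param schema An [AnnotationSchema-class] to serialize.
#' @export
writeSchema <- function(schema, path) {
  stopifnot(is(schema, "AnnotationSchema"))
  yaml::write_yaml(list(dialect = schema@dialect,
                        missing_token = schema@missingToken,
                        columns = as.list(schema@columnOf)),
                   path)
  invisible(path)
}
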