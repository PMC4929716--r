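#' Construct a gene-disease map from a data.frame
#'
#' @param entries `data.frame` with columns `gene`, `disorder` and
#'   optionally `source`. Symbols are upper-cased, disorder whitespace is
#'   normalized, and duplicate (gene, disorder) pairs are collapsed.
#' @return A [GeneDiseaseMap-class].
#' @export
geneDiseaseMap <- function(entries = data.frame(gene = character(),
                                                disorder = character(),
                                                source = character())) {
  if (is.null(entries$source)) entries$source <- "custom"
  df <- data.frame(gene = toupper(trimws(as.character(entries$gene))),
                   disorder = gsub("[[:space:]]+", " ",
                                   trimws(as.character(entries$disorder))),
                   source = as.character(entries$source),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df[c("gene", "disorder")]), , drop = FALSE]
  rownames(df) <- NULL
  new("GeneDiseaseMap", entries = df)
}

#' Load gene-disease tables
#'
#' Reads one or more local 2+-column TSV files (gene symbol, disorder
#' description, optional source tag) — the layout of an OMIM-genemap-like
#' or DISEASES-export-like download — and unions them into one
#' [GeneDiseaseMap-class]. Symbols are upper-cased; duplicate
#' (gene, disorder) pairs across files are deduplicated. Lines starting
#' with `#` are ignored.
#'
#' @param paths One or more TSV file paths.
#' @param defaultSource Source tag recorded for rows lacking a third column.
#' @return A [GeneDiseaseMap-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("KCNA2\tepileptic encephalopathy\tomim",
#'              "KCNA2\tataxia\tomim"), f)
#' map <- readGeneDiseaseMap(f)
#' length(map)   # 1 gene, 2 disorders
#' @export
readGeneDiseaseMap <- function(paths, defaultSource = "custom") {
  all <- lapply(paths, function(path) {
    if (!file.exists(path))
      stop("cannot read '", path, "': no such file", call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
    lineNo <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) {
      warning("'", path, "' contains no gene-disease rows", call. = FALSE)
      return(data.frame(gene = character(), disorder = character(),
                        source = character(), stringsAsFactors = FALSE))
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 2L |
                   !nzchar(trimws(vapply(parts, `[`, "", 1L))) |
                   !nzchar(trimws(vapply(parts, function(p) p[2L], ""))))
    if (length(bad))
      stop("'", path, "' line ", lineNo[bad[1L]],
           ": expected at least 2 tab-delimited fields (gene, disorder)",
           call. = FALSE)
    data.frame(
      gene = vapply(parts, `[`, "", 1L),
      disorder = vapply(parts, `[`, "", 2L),
      source = vapply(parts, function(p)
        if (length(p) >= 3L && nzchar(trimws(p[3L]))) trimws(p[3L])
        else defaultSource, ""),
      stringsAsFactors = FALSE)
  })
  geneDiseaseMap(do.call(rbind, all))
}

## Case-insensitive word-boundary match of one query term in descriptions.
.termMatches <- function(term, descriptions) {
  re <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", term), "\\b")
  grepl(re, descriptions, ignore.case = TRUE, perl = TRUE)
}

#' Match surviving genes against a disease-keyword query
#'
#' The disease-linking step: every gene symbol of each record (multi-gene
#' cells are split on `";"`/`","`) is looked up in the map, and each query
#' term is matched as a case-insensitive, word-boundary substring of the
#' linked disorder descriptions — so `"ataxia"` matches
#' `"spinocerebellar ataxia"`, but `"epilepsy"` does not match
#' `"epileptic"`. The score of a record is the number of distinct query
#' terms matched across all its genes' disorders. Records are annotated,
#' never removed; pruning to disorder-linked records is the caller's
#' opt-in (see `drop_unmatched` in [vsRun()]).
#'
#' @param x A [VariantTable-class] (typically step-6 survivors).
#' @param map A [GeneDiseaseMap-class].
#' @param queryTerms Character vector of disease keywords (case ignored);
#'   may be empty, in which case every record scores 0.
#' @return A `data.frame` aligned with the records of `x`, columns:
#'   `score` (integer, distinct matched terms), `matched_terms`,
#'   `matched_disorders` (both `"; "`-joined, sorted, `""` when none) and
#'   `any_disorder` (whether any gene of the record has any disorder in the
#'   map at all).
#' @examples
#' map <- geneDiseaseMap(data.frame(
#'   gene = c("KCNA2", "KCNA2"),
#'   disorder = c("ataxia", "epileptic encephalopathy")))
#' tab <- makeVariantTable(list(stratumSpec(1, genePool = "KCNA2")), seed = 1)
#' matchDiseases(tab$table, map, c("ataxia", "epilepsy"))$score  # 1
#' @export
matchDiseases <- function(x, map, queryTerms = character()) {
  stopifnot(is(x, "VariantTable"), is(map, "GeneDiseaseMap"))
  queryTerms <- unique(tolower(trimws(queryTerms)))
  queryTerms <- queryTerms[nzchar(queryTerms)]
  ent <- map@entries
  symbols <- splitGeneSymbols(x@variants$gene)

  res <- lapply(symbols, function(sy) {
    hits <- ent[ent$gene %in% sy, , drop = FALSE]
    if (!nrow(hits))
      return(list(score = 0L, terms = character(), disorders = character(),
                  any = FALSE))
    mt <- character(); md <- character()
    for (term in queryTerms) {
      m <- .termMatches(term, hits$disorder)
      if (any(m)) {
        mt <- c(mt, term)
        md <- c(md, hits$disorder[m])
      }
    }
    list(score = length(mt), terms = sort(unique(mt)),
         disorders = sort(unique(md)), any = TRUE)
  })
  data.frame(
    score = vapply(res, function(r) r$score, integer(1L)),
    matched_terms = vapply(res, function(r)
      paste(r$terms, collapse = "; "), character(1L)),
    matched_disorders = vapply(res, function(r)
      paste(r$disorders, collapse = "; "), character(1L)),
    any_disorder = vapply(res, function(r) r$any, logical(1L)),
    stringsAsFactors = FALSE)
}

#' Rank a shortlist by disease-match score
#'
#' Stable sort: descending by score, ties broken by original table order,
#' so with no matches at all the input order is preserved and the
#' hypothesis-free shortlist is unchanged.
#'
#' @param x A [VariantTable-class].
#' @param matches Match annotation from [matchDiseases()], aligned with `x`.
#' @return A list with `table` (the reordered [VariantTable-class]) and
#'   `matches` (the annotation reordered to match).
#' @export
rankShortlist <- function(x, matches) {
  stopifnot(is(x, "VariantTable"), nrow(matches) == length(x))
  ord <- order(-matches$score, seq_len(length(x)))
  list(table = x[ord],
       matches = matches[ord, , drop = FALSE])
}
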