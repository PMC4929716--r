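## Strict numeric syntax: decimal point ".", optional sign/exponent, no
## thousands separators, no locale dependence.
.NUMERIC_RE <- "^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$"

## Split a line on tabs without losing trailing empty fields.
.splitTabs <- function(lines) {
  parts <- strsplit(paste0(lines, "\x01"), "\t", fixed = TRUE)
  lapply(parts, function(p) {
    p[length(p)] <- sub("\x01$", "", p[length(p)])
    p
  })
}

.parseNumericColumn <- function(cells, colname, lenient, warnings) {
  out <- rep(NA_real_, length(cells))
  present <- !is.na(cells)
  ok <- grepl(.NUMERIC_RE, cells[present])
  if (any(!ok)) {
    bad <- cells[present][!ok]
    if (!lenient)
      stop("column '", colname, "': unparseable numeric value(s): ",
           paste(utils::head(unique(bad), 3L), collapse = ", "),
           call. = FALSE)
    warnings$n <- warnings$n + sum(!ok)
  }
  vals <- rep(NA_real_, sum(present))
  vals[ok] <- as.numeric(cells[present][ok])
  out[present] <- vals
  out
}

#' Read an annotated variant table
#'
#' Parses a tab-delimited annotated variant table (one header row, one row
#' per variant) into a [VariantTable-class]. With `schema = NULL` the header
#' is resolved through [detectSchema()]; otherwise the supplied schema's
#' raw headers are matched against the file. Cells equal to the schema's
#' missing token, or empty, parse to `NA`. Numeric fields that fail to parse
#' raise an error unless `lenient = TRUE`, which converts them to `NA` and
#' reports the count in a warning.
#'
#' @param path Path to the tab-delimited file.
#' @param schema An [AnnotationSchema-class], or `NULL` to auto-detect.
#' @param lenient If `TRUE`, malformed numeric cells become `NA` with a
#'   single summarising warning instead of an error.
#' @return A [VariantTable-class]; records in file order, canonical columns
#'   first, unmapped columns passed through after them.
#' @examples
#' tab <- makeVariantTable(list(stratumSpec(3)), seed = 1)
#' path <- tempfile(fileext = ".tsv")
#' writeShortlist(tab$table, path = path)
#' vt <- readVariantTable(path)
#' length(vt)
#' @export
readVariantTable <- function(path, schema = NULL, lenient = FALSE) {
  if (!file.exists(path))
    stop("cannot read '", path, "': no such file", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (!length(lines))
    stop("'", path, "' is empty: expected a header row", call. = FALSE)
  fields <- .splitTabs(lines)
  header <- trimws(fields[[1L]])
  if (is.null(schema))
    schema <- detectSchema(header)
  missingHeaders <- setdiff(unname(schema@columnOf), header)
  if (length(missingHeaders))
    stop("schema header(s) not found in file: ",
         paste(missingHeaders, collapse = ", "), call. = FALSE)

  ncol <- length(header)
  widths <- lengths(fields)
  bad <- which(widths[-1L] != ncol) + 1L
  if (length(bad))
    stop("line ", bad[1L], ": expected ", ncol, " tab-delimited field(s), got ",
         widths[bad[1L]], call. = FALSE)

  body <- fields[-1L]
  cols <- if (length(body)) {
    m <- matrix(unlist(body, use.names = FALSE), nrow = ncol)
    lapply(seq_len(ncol), function(j) m[j, ])
  } else {
    rep(list(character()), ncol)
  }
  names(cols) <- header
  cols <- lapply(cols, function(v) {
    v <- trimws(v)
    v[v == schema@missingToken | v == ""] <- NA_character_
    v
  })

  warnings <- new.env()
  warnings$n <- 0L
  df <- data.frame(row.names = seq_along(body))
  for (role in .ALL_ROLES) {
    if (!role %in% names(schema@columnOf)) {
      if (role %in% .OPTIONAL_ROLES) df[[role]] <- NA_real_
      next
    }
    raw <- cols[[schema@columnOf[[role]]]]
    df[[role]] <- if (role %in% .NUMERIC_ROLES)
      .parseNumericColumn(raw, schema@columnOf[[role]], lenient, warnings)
    else raw
  }
  if (warnings$n > 0L)
    warning(warnings$n, " malformed numeric cell(s) converted to missing",
            call. = FALSE)
  for (role in c("start", "end"))
    if (anyNA(df[[role]]))
      stop("column '", schema@columnOf[[role]],
           "': positions must be present on every row", call. = FALSE)

  extras <- setdiff(header, unname(schema@columnOf))
  for (e in extras) df[[e]] <- cols[[e]]
  rownames(df) <- NULL
  new("VariantTable", variants = df, schema = schema)
}

## Deterministic, locale-independent rendering of a numeric column:
## shortest decimal string that parses back to exactly the same double, so
## write -> read is the identity and output is byte-stable.
.formatNumeric <- function(v, missingToken) {
  vapply(v, function(x) {
    if (is.na(x)) return(missingToken)
    for (d in 1:17) {
      s <- format(x, digits = d, scientific = FALSE, trim = TRUE)
      if (as.numeric(s) == x) return(s)
    }
    s
  }, character(1L))
}

#' Write a variant shortlist
#'
#' Serializes records back to tab-delimited text using the schema's raw
#' headers: canonical columns first, passthrough extras after, missing
#' values rendered as the schema's missing token. Output is byte-stable for
#' identical input. When a disease-match annotation (from
#' [matchDiseases()]) is supplied, columns `disease_score`,
#' `matched_terms` and `matched_disorders` are appended.
#'
#' @param x A [VariantTable-class].
#' @param ranks Optional per-record disease-match `data.frame` as returned
#'   by [matchDiseases()], aligned with the records of `x`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeShortlist <- function(x, ranks = NULL, path) {
  stopifnot(is(x, "VariantTable"))
  df <- x@variants
  sch <- x@schema
  if (!is.null(ranks) && nrow(ranks) != nrow(df))
    stop("ranks must align with records (", nrow(df), " row(s))",
         call. = FALSE)

  roles <- intersect(.ALL_ROLES, names(sch@columnOf))
  outHeaders <- unname(sch@columnOf[roles])
  outCols <- lapply(roles, function(role) {
    v <- df[[role]]
    if (is.numeric(v)) {
      if (role %in% c("start", "end"))
        .formatNumeric(as.integer(v), sch@missingToken)
      else .formatNumeric(v, sch@missingToken)
    } else {
      v[is.na(v)] <- sch@missingToken
      v
    }
  })
  extras <- setdiff(names(df), .ALL_ROLES)
  for (e in extras) {
    v <- df[[e]]
    v[is.na(v)] <- sch@missingToken
    outHeaders <- c(outHeaders, e)
    outCols <- c(outCols, list(v))
  }
  if (!is.null(ranks)) {
    outHeaders <- c(outHeaders, "disease_score", "matched_terms",
                    "matched_disorders")
    blank <- function(v) { v[is.na(v) | v == ""] <- sch@missingToken; v }
    outCols <- c(outCols,
                 list(as.character(ranks$score),
                      blank(ranks$matched_terms),
                      blank(ranks$matched_disorders)))
  }

  conn <- file(path, open = "wb")  # binary: byte-stable line endings
  on.exit(close(conn))
  lines <- c(paste(outHeaders, collapse = "\t"),
             if (nrow(df)) do.call(paste, c(outCols, sep = "\t")))
  writeLines(lines, conn, sep = "\n")
  invisible(path)
}

#' Split a gene cell into its symbol set
#'
#' ANNOVAR emits multiple symbols at gene boundaries separated by `";"` or
#' `","`; the cell is preserved verbatim in output but split into a symbol
#' set for disease matching.
#'
#' @param gene Character vector of gene cells.
#' @return List of character vectors (upper-cased, trimmed symbols).
#' @export
splitGeneSymbols <- function(gene) {
  lapply(strsplit(as.character(gene), "[;,]"), function(s) {
    s <- toupper(trimws(s))
    s[nzchar(s)]
  })
}
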