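#' @importFrom S4Vectors isSingleString
NULL

## ---- generics -------------------------------------------------------------

#' Extract the records of a VariantTable as a data.frame
#' @param x A [VariantTable-class].
#' @return A `data.frame`, canonical columns first, passthrough extras after.
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' Schema accessor
#' @param x A [VariantTable-class] or [AnnotationSchema-class].
#' @return The [AnnotationSchema-class] associated with `x`.
#' @export
setGeneric("schema", function(x) standardGeneric("schema"))

#' Surviving-count ledger of a cascade report
#' @param x A [CascadeReport-class].
#' @return Named integer vector of surviving counts, input size first.
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' Per-step removed counts of a cascade report
#' @param x A [CascadeReport-class].
#' @return Integer vector: records removed at each step (0 for the input row).
#' @export
setGeneric("removed", function(x) standardGeneric("removed"))

#' Step labels of a cascade report
#' @param x A [CascadeReport-class].
#' @return Character vector of step descriptions.
#' @export
setGeneric("stepLabels", function(x) standardGeneric("stepLabels"))

#' Entries of a gene-disease map
#' @param x A [GeneDiseaseMap-class].
#' @return `data.frame` with columns `gene`, `disorder`, `source`.
#' @export
setGeneric("diseaseEntries", function(x) standardGeneric("diseaseEntries"))

#' Coerce variant records to a GRanges
#'
#' Positions are ANNOVAR-style 1-based end-inclusive, which matches the
#' `GRanges` convention directly; canonical annotation columns become
#' metadata columns.
#'
#' @param x A [VariantTable-class].
#' @return A [GenomicRanges::GRanges] with one range per record.
#' @export
setGeneric("asGRanges", function(x) standardGeneric("asGRanges"))

## ---- methods --------------------------------------------------------------

#' @describeIn VariantTable Records as a data.frame.
#' @param x,object A `VariantTable`.
#' @export
setMethod("variants", "VariantTable", function(x) x@variants)

#' @describeIn VariantTable The schema the table was read with.
#' @export
setMethod("schema", "VariantTable", function(x) x@schema)

#' @describeIn VariantTable Number of records.
#' @export
setMethod("length", "VariantTable", function(x) nrow(x@variants))

#' @describeIn VariantTable Subset records (row indices), preserving order
#'   semantics of `[`.
#' @param i Row index vector.
#' @param j,drop Ignored (row subsetting only).
#' @param ... Ignored.
#' @export
setMethod("[", "VariantTable", function(x, i, j, ..., drop = FALSE) {
  df <- x@variants[i, , drop = FALSE]
  rownames(df) <- NULL
  initialize(x, variants = df)
})

#' @describeIn VariantTable Compact display.
#' @export
setMethod("show", "VariantTable", function(object) {
  df <- object@variants
  cat("VariantTable with", nrow(df), "record(s) [dialect:",
      object@schema@dialect, "]\n")
  extras <- setdiff(names(df), .ALL_ROLES)
  mapped <- intersect(.ALL_ROLES, names(df))
  cat("  mapped fields:", paste(mapped, collapse = ", "), "\n")
  if (length(extras))
    cat("  passthrough:", paste(extras, collapse = ", "), "\n")
  if (nrow(df)) {
    print(utils::head(df[, mapped, drop = FALSE], 5L))
    if (nrow(df) > 5L) cat("  ...", nrow(df) - 5L, "more record(s)\n")
  }
  invisible(NULL)
})

#' @describeIn AnnotationSchema Compact display.
#' @param object An `AnnotationSchema`.
#' @export
setMethod("show", "AnnotationSchema", function(object) {
  cat("AnnotationSchema [dialect:", object@dialect,
      "| missing token:", dQuote(object@missingToken), "]\n")
  for (r in .ALL_ROLES) {
    raw <- if (r %in% names(object@columnOf)) object@columnOf[[r]]
           else "<unmapped>"
    cat(sprintf("  %-13s <- %s\n", r, raw))
  }
  invisible(NULL)
})

#' @describeIn CascadeReport Surviving counts (input size first).
#' @export
setMethod("counts", "CascadeReport", function(x) {
  stats::setNames(x@counts, x@stepLabels)
})

#' @describeIn CascadeReport Removed counts per step.
#' @export
setMethod("removed", "CascadeReport", function(x) {
  if (!length(x@counts)) return(integer())
  c(0L, -diff(x@counts))
})

#' @describeIn CascadeReport Step labels.
#' @export
setMethod("stepLabels", "CascadeReport", function(x) x@stepLabels)

#' @describeIn CascadeReport Display as an attrition table.
#' @param object A `CascadeReport`.
#' @export
setMethod("show", "CascadeReport", function(object) {
  cat("CascadeReport:", length(object@counts) - 1L, "step(s)\n")
  print(as(object, "data.frame"))
  invisible(NULL)
})

#' Cascade report as a data.frame (step, surviving, removed)
#' @name CascadeReport-coerce
#' @aliases coerce,CascadeReport,data.frame-method
setAs("CascadeReport", "data.frame", function(from) {
  data.frame(step = from@stepLabels,
             surviving = from@counts,
             removed = removed(from),
             stringsAsFactors = FALSE)
})

#' @describeIn GeneDiseaseMap Entries as a data.frame.
#' @param x,object A `GeneDiseaseMap`.
#' @export
setMethod("diseaseEntries", "GeneDiseaseMap", function(x) x@entries)

#' @describeIn GeneDiseaseMap Number of distinct genes.
#' @export
setMethod("length", "GeneDiseaseMap", function(x) {
  length(unique(x@entries$gene))
})

#' @describeIn GeneDiseaseMap Compact display.
#' @export
setMethod("show", "GeneDiseaseMap", function(object) {
  cat("GeneDiseaseMap:", nrow(object@entries), "entry(ies) across",
      length(object), "gene(s); sources:",
      paste(unique(object@entries$source), collapse = ", "), "\n")
  invisible(NULL)
})

#' @describeIn VariantTable Records as a `GRanges` (1-based, end-inclusive).
#' @export
setMethod("asGRanges", "VariantTable", function(x) {
  df <- x@variants
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end))
  meta <- df[, setdiff(names(df), c("chrom", "start", "end")), drop = FALSE]
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(meta)
  gr
})
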