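## End-to-end pipeline entry points. These back the command-line script in
## inst/scripts/variantsieve; all behaviour lives here so it is testable.

.msg <- function(verbose, ...) if (verbose) message(...)

#' Run the full filtration and prioritization pipeline
#'
#' Reads an annotated variant table, applies the six-step filtration
#' cascade, optionally links surviving genes to known disorders and ranks
#' by keyword relevance, and writes the shortlist, the stepwise attrition
#' report (TSV and JSON) and a run manifest into `outDir`. With no disease
#' map the disorder-linking step is skipped with a notice and the
#' shortlist is the step-6 survivor set in input order.
#'
#' @param input Path to the annotated variant table.
#' @param outDir Output directory (created if absent).
#' @param config A [FilterConfig-class] (see [filterConfig()]), or the path
#'   to a YAML configuration file.
#' @param schema Optional [AnnotationSchema-class] or schema YAML path; by
#'   default the table header is auto-detected.
#' @param diseaseMaps Character vector of gene-disease TSV paths (may be
#'   empty).
#' @param queryTerms Disease keywords for [matchDiseases()].
#' @param dropUnmatched If `TRUE`, records whose genes have no disorder
#'   annotation at all are removed at the disorder-linking step (the
#'   opt-in attrition mode); default is annotate-and-rank only.
#' @param lenient Passed to [readVariantTable()].
#' @param verbose Log per-step counts to stderr.
#' @return Invisibly, a list: `shortlist` ([VariantTable-class]),
#'   `matches`, `report` ([CascadeReport-class]), `paths` (named output
#'   paths), `manifest`.
#' @export
vsRun <- function(input, outDir, config = filterConfig(), schema = NULL,
                  diseaseMaps = character(), queryTerms = character(),
                  dropUnmatched = FALSE, lenient = FALSE, verbose = TRUE) {
  if (is.character(config)) config <- readFilterConfig(config)
  if (is.character(schema)) schema <- readSchema(schema)
  stopifnot(is(config, "FilterConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  vt <- readVariantTable(input, schema = schema, lenient = lenient)
  res <- runCascade(vt, config)
  report <- res$report
  shortlist <- res$survivors

  matches <- NULL
  if (length(diseaseMaps)) {
    map <- readGeneDiseaseMap(diseaseMaps)
    matches <- matchDiseases(shortlist, map, queryTerms)
    if (dropUnmatched) {
      keep <- matches$any_disorder
      shortlist <- shortlist[keep]
      matches <- matches[keep, , drop = FALSE]
    }
    report <- .appendDiseaseStep(report, length(shortlist))
    ranked <- rankShortlist(shortlist, matches)
    shortlist <- ranked$table
    matches <- ranked$matches
  } else {
    .msg(verbose,
         "no disease map supplied; disorder-linking step skipped, ",
         "shortlist = step-6 survivors")
  }
  for (i in seq_along(stepLabels(report)))
    .msg(verbose, stepLabels(report)[i], ": ", counts(report)[i])

  paths <- c(shortlist = file.path(outDir, "shortlist.tsv"),
             report_tsv = file.path(outDir, "cascade_report.tsv"),
             report_json = file.path(outDir, "cascade_report.json"),
             manifest = file.path(outDir, "run_manifest.json"))
  writeShortlist(shortlist, ranks = matches, path = paths[["shortlist"]])
  writeCascadeReport(report, paths[["report_tsv"]], "tsv")
  writeCascadeReport(report, paths[["report_json"]], "json")

  manifest <- list(
    tool = "VariantSieve",
    version = as.character(utils::packageVersion("VariantSieve")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input = normalizePath(input),
    disease_maps = as.character(diseaseMaps),
    query_terms = as.character(queryTerms),
    drop_unmatched = dropUnmatched,
    lenient = lenient,
    config = configAsList(config),
    step_counts = stats::setNames(as.list(unname(counts(report))),
                                  stepLabels(report)),
    outputs = as.list(paths))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(shortlist = shortlist, matches = matches, report = report,
                 paths = paths, manifest = manifest))
}

#' Emit a synthetic fixture table and its expectation ledger
#'
#' @param profile Name of a builtin profile (`"exome-mini"`, ~5 573 rows;
#'   `"exome-micro"`, ~557 rows) or the path to a YAML stratum
#'   specification (a list of stratum entries using the [stratumSpec()]
#'   argument names).
#' @param seed Integer seed; identical seeds give byte-identical files.
#' @param outDir Output directory.
#' @param spike Plant a [spikeInVariant()] record (default `TRUE`).
#' @return Invisibly, the [makeVariantTable()] result plus the written
#'   paths (`table.tsv`, `ledger.json`, `disease_map.tsv`).
#' @export
vsSimulate <- function(profile, seed, outDir, spike = TRUE) {
  strata <- if (file.exists(profile)) {
    doc <- yaml::read_yaml(profile)
    lapply(doc$strata, function(s) do.call(stratumSpec, s))
  } else if (profile %in% names(.SIM_PROFILES)) {
    .SIM_PROFILES[[profile]]()
  } else {
    stop("unknown profile '", profile, "'; builtin profiles: ",
         paste(names(.SIM_PROFILES), collapse = ", "), call. = FALSE)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tablePath <- file.path(outDir, "table.tsv")
  sim <- makeVariantTable(strata, seed = seed, path = tablePath,
                          spike = if (spike) spikeInVariant() else NULL)
  mapPath <- file.path(outDir, "disease_map.tsv")
  gd <- makeGeneDiseaseMap(.EXOME_DISEASE_GENES, disordersPerGene = 2L,
                           vocabulary = exomeMiniDiseaseVocabulary(),
                           seed = seed, path = mapPath)
  if (spike) {
    # dedicated disorder entry so the spike-in gene is disease-linked and,
    # under spikeInQueryTerms(), strictly out-scores every other gene
    gd$map <- geneDiseaseMap(rbind(
      diseaseEntries(gd$map),
      data.frame(gene = .SPIKE_GENE, disorder = .SPIKE_DISORDER,
                 source = "custom", stringsAsFactors = FALSE)))
    ent <- diseaseEntries(gd$map)
    conn <- file(mapPath, open = "wb")
    writeLines(paste(ent$gene, ent$disorder, ent$source, sep = "\t"),
               conn, sep = "\n")
    close(conn)
  }
  ledgerPath <- file.path(outDir, "ledger.json")
  jsonlite::write_json(sim$ledger, ledgerPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(sim, list(map = gd$map,
                        paths = c(table = tablePath, ledger = ledgerPath,
                                  disease_map = mapPath))))
}

#' Validate a variant table against its (detected or supplied) schema
#'
#' Schema check only: parses the header, resolves the schema, checks every
#' row's column count and numeric syntax, and reports the record count.
#' Nothing is written.
#'
#' @inheritParams vsRun
#' @return Invisibly, a list with `schema` and `n_records`.
#' @export
vsValidate <- function(input, schema = NULL, verbose = TRUE) {
  if (is.character(schema)) schema <- readSchema(schema)
  vt <- readVariantTable(input, schema = schema)
  .msg(verbose, "OK: ", length(vt), " record(s), dialect ",
       schema(vt)@dialect)
  invisible(list(schema = schema(vt), n_records = length(vt)))
}

#' Re-render the attrition report recorded in a run manifest
#'
#' @param manifestPath Path to a `run_manifest.json` written by [vsRun()].
#' @return The recorded step counts as a `data.frame` (step, surviving),
#'   printed to stdout.
#' @export
vsReport <- function(manifestPath) {
  man <- jsonlite::read_json(manifestPath)
  df <- data.frame(step = names(man$step_counts),
                   surviving = as.integer(unlist(man$step_counts)),
                   stringsAsFactors = FALSE)
  print(df, right = FALSE)
  invisible(df)
}

#' Cross-check a variant table against the VCF it was annotated from
#'
#' Provenance check only: compares the record count of the annotated table
#' with the record count of the VCF (the annotation table is expected to
#' have one row per VCF record for row-per-variant exports). The VCF is
#' never used for annotation.
#'
#' @param x A [VariantTable-class].
#' @param vcfPath Path to a VCF 4.x file.
#' @return List with `table_records`, `vcf_records` and `consistent`.
#' @export
crossCheckVcf <- function(x, vcfPath) {
  stopifnot(is(x, "VariantTable"))
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("crossCheckVcf requires the vcfR package", call. = FALSE)
  vcf <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  nv <- nrow(vcf@fix)
  list(table_records = length(x), vcf_records = nv,
       consistent = length(x) == nv)
}
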