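#' Build a filter configuration
#'
#' Returns a [FilterConfig-class] holding every threshold, keep-set and
#' missing-value policy of cascade steps 1-6. Two named presets are
#' provided: `"default"` uses the FATHMM cutoff of 1.0 (remove scores
#' strictly greater than 1.0), and `"strict"` lowers it to -1.5, the more
#' conservative cutoff recommended for broad use; the presets differ in
#' nothing else. Any field can then be overridden individually.
#'
#' @param preset `"default"` or `"strict"`.
#' @param exonicKeep `func_region` values kept at step 1.
#' @param includeSplicing Add `"splicing"` to the step-1 keep-set.
#' @param exonicFuncRemove `exonic_func` classes removed at step 2.
#' @param freqThreshold1kgp,freqThresholdEsp Rarity thresholds (fractions);
#'   a record is removed when its frequency is present and strictly above
#'   the threshold, so frequency at exactly the threshold is kept.
#' @param keepMissingFreq,keepMissingGerp,keepMissingFathmm Keep records
#'   whose respective value is missing.
#' @param gerpMin Keep records with `gerp >= gerpMin` (default 0: only
#'   negative, non-conserved scores are removed).
#' @param fathmmMax Keep records with `fathmm <= fathmmMax`.
#' @return A validated [FilterConfig-class].
#' @examples
#' filterConfig()
#' filterConfig(preset = "strict")@fathmmMax   # -1.5
#' filterConfig(includeSplicing = TRUE)
#' @export
filterConfig <- function(preset = c("default", "strict"),
                         exonicKeep = NULL, includeSplicing = NULL,
                         exonicFuncRemove = NULL,
                         freqThreshold1kgp = NULL, freqThresholdEsp = NULL,
                         keepMissingFreq = NULL,
                         gerpMin = NULL, keepMissingGerp = NULL,
                         fathmmMax = NULL, keepMissingFathmm = NULL) {
  preset <- match.arg(preset)
  cfg <- new("FilterConfig")
  if (preset == "strict") cfg@fathmmMax <- -1.5
  override <- list(exonicKeep = exonicKeep, includeSplicing = includeSplicing,
                   exonicFuncRemove = exonicFuncRemove,
                   freqThreshold1kgp = freqThreshold1kgp,
                   freqThresholdEsp = freqThresholdEsp,
                   keepMissingFreq = keepMissingFreq, gerpMin = gerpMin,
                   keepMissingGerp = keepMissingGerp, fathmmMax = fathmmMax,
                   keepMissingFathmm = keepMissingFathmm)
  for (nm in names(override))
    if (!is.null(override[[nm]]))
      slot(cfg, nm) <- override[[nm]]
  validObject(cfg)
  cfg
}

#' Serialize a filter configuration to / from YAML
#'
#' The YAML layout uses the slot names verbatim under a top-level `filters`
#' key, so a configuration file round-trips exactly and a run manifest can
#' embed the resolved configuration.
#'
#' @param path YAML file path.
#' @return `readFilterConfig()` returns a [FilterConfig-class];
#'   `writeFilterConfig()` returns `path` invisibly.
#' @export
readFilterConfig <- function(path) {
  doc <- yaml::read_yaml(path)
  flt <- if (!is.null(doc$filters)) doc$filters else doc
  cfg <- new("FilterConfig")
  for (nm in intersect(names(flt), slotNames("FilterConfig"))) {
    v <- flt[[nm]]
    if (is.list(v)) v <- unlist(v)
    slot(cfg, nm) <- if (is.character(slot(cfg, nm))) as.character(v)
                     else if (is.logical(slot(cfg, nm))) as.logical(v)
                     else as.numeric(v)
  }
  validObject(cfg)
  cfg
}

#' @rdname readFilterConfig
#' @param config A [FilterConfig-class].
#' @export
writeFilterConfig <- function(config, path) {
  yaml::write_yaml(list(filters = configAsList(config)), path)
  invisible(path)
}

#' Filter configuration as a plain named list
#' @param config A [FilterConfig-class].
#' @return Named list of every slot (used for manifests and YAML output).
#' @export
configAsList <- function(config) {
  stopifnot(is(config, "FilterConfig"))
  out <- lapply(slotNames("FilterConfig"), function(s) slot(config, s))
  stats::setNames(out, slotNames("FilterConfig"))
}

## ---- vectorized keep-predicates ------------------------------------------
## Each returns a logical keep-mask over the rows of a variants data.frame.
## Missing (NA) is a distinct state handled explicitly, never compared
## numerically.

.effectiveExonicKeep <- function(config) {
  if (config@includeSplicing) union(config@exonicKeep, "splicing")
  else config@exonicKeep
}

.keepExonic <- function(df, config) {
  df$func_region %in% .effectiveExonicKeep(config)
}

.keepFunctionalClass <- function(df, config) {
  ef <- df$exonic_func
  is.na(ef) | !(ef %in% config@exonicFuncRemove)
}

.keepFrequency <- function(df, which, config) {
  v <- if (which == "kgp") df$freq_1kgp else df$freq_esp6500
  thr <- if (which == "kgp") config@freqThreshold1kgp
         else config@freqThresholdEsp
  ifelse(is.na(v), config@keepMissingFreq, v <= thr)
}

.keepGerp <- function(df, config) {
  ifelse(is.na(df$gerp), config@keepMissingGerp, df$gerp >= config@gerpMin)
}

.keepFathmm <- function(df, config) {
  ifelse(is.na(df$fathmm), config@keepMissingFathmm,
         df$fathmm <= config@fathmmMax)
}

## ---- step filters ---------------------------------------------------------

#' Cascade step filters
#'
#' Each filter keeps the records satisfying one step's rule, preserving
#' record order; records are never reordered or modified. The rules are:
#'
#' * `filterExonic()` — step 1: keep records whose `func_region` is in the
#'   configured keep-set (`exonic` and `exonic;splicing` by default;
#'   `splicing` too when `includeSplicing` is on).
#' * `filterFunctionalClass()` — step 2: remove synonymous SNVs and
#'   nonframeshift indel/substitution classes; frameshift indels, stopgain,
#'   stoploss, nonsynonymous SNVs and records with missing or `"unknown"`
#'   class are kept.
#' * `filterFrequency()` — steps 3 (1000 Genomes) and 4 (ESP6500): remove
#'   records whose frequency is present and strictly greater than the
#'   threshold; a frequency at or below the threshold is rare and kept, and
#'   records with no frequency data are kept (prioritized) by default.
#' * `filterGerp()` — step 5: remove records whose GERP conservation score
#'   is present and below `gerpMin` (default 0: negatives removed, zero
#'   kept); missing scores (e.g. indels) are kept by default.
#' * `filterFathmm()` — step 6: remove records whose FATHMM score is
#'   present and strictly greater than `fathmmMax` (default 1.0, strict
#'   preset -1.5); missing scores kept by default.
#'
#' @param x A [VariantTable-class].
#' @param config A [FilterConfig-class].
#' @param which For `filterFrequency()`: `"kgp"` (1000 Genomes) or `"esp"`
#'   (ESP6500).
#' @param threshold For `filterFrequency()`: optional override of the
#'   configured threshold (fraction in \[0, 1\]).
#' @return A [VariantTable-class] of surviving records, order preserved.
#' @seealso [runCascade()] for the fixed-order composition with attrition
#'   accounting.
#' @export
filterExonic <- function(x, config = filterConfig()) {
  x[.keepExonic(x@variants, config)]
}

#' @rdname filterExonic
#' @export
filterFunctionalClass <- function(x, config = filterConfig()) {
  x[.keepFunctionalClass(x@variants, config)]
}

#' @rdname filterExonic
#' @export
filterFrequency <- function(x, which = c("kgp", "esp"), threshold = NULL,
                            config = filterConfig()) {
  which <- match.arg(which)
  if (!is.null(threshold)) {
    stopifnot(length(threshold) == 1L, threshold >= 0, threshold <= 1)
    if (which == "kgp") config@freqThreshold1kgp <- threshold
    else config@freqThresholdEsp <- threshold
  }
  x[.keepFrequency(x@variants, which, config)]
}

#' @rdname filterExonic
#' @export
filterGerp <- function(x, config = filterConfig()) {
  x[.keepGerp(x@variants, config)]
}

#' @rdname filterExonic
#' @export
filterFathmm <- function(x, config = filterConfig()) {
  x[.keepFathmm(x@variants, config)]
}

.STEP_LABELS <- c(
  "Total number of variants in input",
  "STEP 1: Variants assigned to exonic regions",
  "STEP 2: Synonymous and nonframeshift variants removed",
  "STEP 3: Variants with frequency > threshold in 1KGP removed",
  "STEP 4: Variants with frequency > threshold in ESP6500 removed",
  "STEP 5: Variants with GERP score below minimum removed",
  "STEP 6: Variants with FATHMM score above cutoff removed")

.DISEASE_STEP_LABEL <- "STEP 7: Variants linked to relevant diseases"

#' Run the filtration cascade (steps 1-6)
#'
#' Applies the six record-level filters in their fixed order — exonic
#' restriction, functional-class removal, 1000 Genomes rarity, ESP6500
#' rarity, GERP conservation, FATHMM pathogenicity — and records the
#' per-step attrition. Steps 2-6 are pure per-record predicates, so the
#' surviving set equals the intersection of the per-filter keep-sets; only
#' the intermediate counts depend on the order.
#'
#' @param x A [VariantTable-class].
#' @param config A [FilterConfig-class].
#' @return A list with elements `survivors` (a [VariantTable-class], order
#'   preserved) and `report` (a [CascadeReport-class] whose first count is
#'   the input size).
#' @examples
#' sim <- makeVariantTable(list(
#'   stratumSpec(5, funcRegion = "exonic", exonicFunc = "nonsynonymous SNV",
#'               gerp = 4, fathmm = -2),
#'   stratumSpec(5, funcRegion = "exonic", exonicFunc = "synonymous SNV")),
#'   seed = 1)
#' res <- runCascade(sim$table)
#' counts(res$report)
#' @export
runCascade <- function(x, config = filterConfig()) {
  stopifnot(is(x, "VariantTable"), is(config, "FilterConfig"))
  validObject(config)
  steps <- list(
    function(v) filterExonic(v, config),
    function(v) filterFunctionalClass(v, config),
    function(v) filterFrequency(v, "kgp", config = config),
    function(v) filterFrequency(v, "esp", config = config),
    function(v) filterGerp(v, config),
    function(v) filterFathmm(v, config))
  n <- integer(length(steps) + 1L)
  n[1L] <- length(x)
  cur <- x
  for (i in seq_along(steps)) {
    cur <- steps[[i]](cur)
    n[i + 1L] <- length(cur)
  }
  list(survivors = cur,
       report = new("CascadeReport", stepLabels = .STEP_LABELS, counts = n))
}

## Append the disease-linking attrition row to a 6-step report.
.appendDiseaseStep <- function(report, count) {
  new("CascadeReport",
      stepLabels = c(report@stepLabels, .DISEASE_STEP_LABEL),
      counts = c(report@counts, as.integer(count)))
}

#' Write a cascade report
#'
#' @param report A [CascadeReport-class].
#' @param path Output path.
#' @param format `"tsv"` (columns step / surviving / removed) or `"json"`.
#' @return `path`, invisibly.
#' @export
writeCascadeReport <- function(report, path, format = c("tsv", "json")) {
  stopifnot(is(report, "CascadeReport"))
  format <- match.arg(format)
  df <- as(report, "data.frame")
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
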