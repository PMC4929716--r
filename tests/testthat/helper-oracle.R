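# Independent brute-force oracle: one scalar keep-predicate per record,
# the conjunction of all six step rules, written directly from the rule
# statements and sharing no code with the package's engine.

oracleKeepRow <- function(funcRegion, exonicFunc, f1k, fesp, gerp, fathmm,
                          cfg) {
  keepRegions <- cfg@exonicKeep
  if (cfg@includeSplicing) keepRegions <- c(keepRegions, "splicing")
  if (!(funcRegion %in% keepRegions)) return(FALSE)
  if (!is.na(exonicFunc) && exonicFunc %in% cfg@exonicFuncRemove)
    return(FALSE)
  if (is.na(f1k)) { if (!cfg@keepMissingFreq) return(FALSE) }
  else if (f1k > cfg@freqThreshold1kgp) return(FALSE)
  if (is.na(fesp)) { if (!cfg@keepMissingFreq) return(FALSE) }
  else if (fesp > cfg@freqThresholdEsp) return(FALSE)
  if (is.na(gerp)) { if (!cfg@keepMissingGerp) return(FALSE) }
  else if (gerp < cfg@gerpMin) return(FALSE)
  if (is.na(fathmm)) { if (!cfg@keepMissingFathmm) return(FALSE) }
  else if (fathmm > cfg@fathmmMax) return(FALSE)
  TRUE
}

oracleSurvivors <- function(df, cfg) {
  which(vapply(seq_len(nrow(df)), function(i)
    oracleKeepRow(df$func_region[i], df$exonic_func[i], df$freq_1kgp[i],
                  df$freq_esp6500[i], df$gerp[i], df$fathmm[i], cfg),
    logical(1)))
}

# Random canonical variant data.frame with a broad mix of regions, classes
# and missing strata; independent of the package's stratumSpec generator.
randomVariantFrame <- function(n) {
  regions <- c("exonic", "exonic", "exonic;splicing", "splicing", "intronic",
               "intergenic", "UTR5", "UTR3", "ncRNA_exonic")
  classes <- c("nonsynonymous SNV", "synonymous SNV", "stopgain", "stoploss",
               "frameshift insertion", "frameshift deletion",
               "nonframeshift insertion", "nonframeshift deletion",
               "nonframeshift substitution", "unknown", NA)
  maybe <- function(vals, pMissing = 0.3) {
    vals[runif(n) < pMissing] <- NA_real_
    vals
  }
  start <- sample.int(1e6L, n, replace = TRUE)
  data.frame(
    chrom = as.character(sample(c(1:22, "X"), n, replace = TRUE)),
    start = as.numeric(start),
    end = as.numeric(start),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T", "-"), n, replace = TRUE),
    func_region = sample(regions, n, replace = TRUE),
    gene = sample(paste0("G", 1:25), n, replace = TRUE),
    exonic_func = sample(classes, n, replace = TRUE),
    freq_1kgp = maybe(runif(n) ^ 3),          # skew toward rare
    freq_esp6500 = maybe(runif(n) ^ 3),
    gerp = maybe(runif(n, -8, 8)),
    fathmm = maybe(runif(n, -6, 6)),
    stringsAsFactors = FALSE)
}

wannovarSchema <- function() {
  detectSchema(c("Chr", "Start", "End", "Ref", "Alt", "Func.refGene",
                 "Gene.refGene", "ExonicFunc.refGene", "1000g2015aug_all",
                 "esp6500siv2_all", "GERP++_RS", "FATHMM_score"))
}

randomVariantTable <- function(n) {
  new("VariantTable", variants = randomVariantFrame(n),
      schema = wannovarSchema())
}

randomFilterConfig <- function() {
  filterConfig(
    includeSplicing = runif(1) < 0.5,
    freqThreshold1kgp = runif(1, 0, 0.05),
    freqThresholdEsp = runif(1, 0, 0.05),
    keepMissingFreq = runif(1) < 0.7,
    gerpMin = runif(1, -2, 2),
    keepMissingGerp = runif(1) < 0.7,
    fathmmMax = runif(1, -3, 3),
    keepMissingFathmm = runif(1) < 0.7)
}

# Minimal wannovar-dialect table writer for fixtures, independent of
# writeShortlist().
writeRawTable <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

wannovarHeader <- paste(c("Chr", "Start", "End", "Ref", "Alt",
                          "Func.refGene", "Gene.refGene",
                          "ExonicFunc.refGene", "1000g2015aug_all",
                          "esp6500siv2_all", "GERP++_RS", "FATHMM_score"),
                        collapse = "\t")

wannovarRow <- function(chrom = "1", start = 100, end = start, ref = "A",
                        alt = "G", region = "exonic", gene = "GENE1",
                        efunc = "nonsynonymous SNV", f1k = ".", fesp = ".",
                        gerp = ".", fathmm = ".") {
  paste(chrom, start, end, ref, alt, region, gene, efunc, f1k, fesp, gerp,
        fathmm, sep = "\t")
}
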