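## Synthetic annotated-variant tables with fully known composition, so that
## every cascade count is predictable and the engine can be checked against
## an independently computed ledger.

.DEFAULT_GENE_POOL <- paste0("GENE", sprintf("%03d", 1:40))

#' Specify one stratum of a synthetic variant table
#'
#' A stratum is a block of `n` rows sharing one functional-region class,
#' one exonic functional class, and one generating rule per numeric
#' annotation. Numeric rules are: `NA` — the value is missing on every row;
#' a single number — that fixed value on every row; a length-2 numeric —
#' values drawn uniformly from that closed range.
#'
#' @param n Row count (>= 0).
#' @param funcRegion `func_region` value for every row (e.g. `"exonic"`,
#'   `"intronic"`, `"splicing"`).
#' @param exonicFunc `exonic_func` class, or `NA` for missing.
#' @param freq1kgp,freqEsp Population-frequency rule; ranges must lie in
#'   \[0, 1\].
#' @param gerp,fathmm Score rules.
#' @param genePool Gene symbols sampled uniformly for the rows.
#' @return A `stratumSpec` list, consumed by [makeVariantTable()].
#' @examples
#' stratumSpec(10, funcRegion = "intronic", exonicFunc = NA)
#' stratumSpec(5, freq1kgp = c(0.02, 0.5), gerp = 3, fathmm = -2)
#' @export
stratumSpec <- function(n, funcRegion = "exonic",
                        exonicFunc = "nonsynonymous SNV",
                        freq1kgp = NA, freqEsp = NA,
                        gerp = NA, fathmm = NA,
                        genePool = .DEFAULT_GENE_POOL) {
  stopifnot(length(n) == 1L, !is.na(n), n >= 0)
  checkRule <- function(v, nm, lo = -Inf, hi = Inf) {
    if (length(v) == 1L && is.na(v)) return(invisible())
    if (!is.numeric(v) || length(v) > 2L || anyNA(v))
      stop("stratum rule '", nm,
           "' must be NA, one number, or a length-2 range", call. = FALSE)
    if (length(v) == 2L && v[1L] > v[2L])
      stop("stratum rule '", nm, "' range is not well-ordered", call. = FALSE)
    if (any(v < lo | v > hi))
      stop("stratum rule '", nm, "' must lie in [", lo, ", ", hi, "]",
           call. = FALSE)
  }
  checkRule(freq1kgp, "freq1kgp", 0, 1)
  checkRule(freqEsp, "freqEsp", 0, 1)
  checkRule(gerp, "gerp")
  checkRule(fathmm, "fathmm")
  stopifnot(length(genePool) >= 1L)
  structure(list(n = as.integer(n), funcRegion = funcRegion,
                 exonicFunc = exonicFunc, freq1kgp = freq1kgp,
                 freqEsp = freqEsp, gerp = gerp, fathmm = fathmm,
                 genePool = genePool),
            class = "stratumSpec")
}

.drawValues <- function(rule, n) {
  if (length(rule) == 1L && is.na(rule)) rep(NA_real_, n)
  else if (length(rule) == 1L) rep(as.numeric(rule), n)
  else stats::runif(n, rule[1L], rule[2L])
}

.BASES <- c("A", "C", "G", "T")

.stratumRows <- function(spec) {
  n <- spec$n
  if (n == 0L)
    return(NULL)
  ef <- spec$exonicFunc
  chrom <- as.character(sample(c(1:22, "X"), n, replace = TRUE))
  start <- sample.int(5e7L, n, replace = TRUE) + 1e4L
  ref <- sample(.BASES, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1L),
                character(1L), USE.NAMES = FALSE)
  end <- start
  if (!is.na(ef) && grepl("insertion", ef)) {
    ref <- rep("-", n)
    alt <- vapply(seq_len(n), function(i)
      paste(sample(.BASES, sample(1:4, 1L), replace = TRUE), collapse = ""),
      character(1L))
  } else if (!is.na(ef) && grepl("deletion", ef)) {
    len <- sample(1:4, n, replace = TRUE)
    ref <- vapply(len, function(l)
      paste(sample(.BASES, l, replace = TRUE), collapse = ""), character(1L))
    alt <- rep("-", n)
    end <- start + len - 1L
  }
  data.frame(chrom = chrom, start = as.numeric(start), end = as.numeric(end),
             ref = ref, alt = alt,
             func_region = rep(spec$funcRegion, n),
             gene = sample(spec$genePool, n, replace = TRUE),
             exonic_func = if (is.na(ef)) NA_character_ else rep(ef, n),
             freq_1kgp = .drawValues(spec$freq1kgp, n),
             freq_esp6500 = .drawValues(spec$freqEsp, n),
             gerp = .drawValues(spec$gerp, n),
             fathmm = .drawValues(spec$fathmm, n),
             stringsAsFactors = FALSE)
}

.SPIKE_GENE <- "KCNA2"
.SPIKE_DISORDER <- "refractory ataxia with myoclonic epilepsy"

#' Query keywords tailored to the spike-in record's disorder
#'
#' The spike-in gene carries one dedicated disorder description
#' (`"refractory ataxia with myoclonic epilepsy"`) in maps emitted by
#' [vsSimulate()]; these four keywords all occur in it, and `"refractory"`
#' occurs in no phrase of [exomeMiniDiseaseVocabulary()], so under this
#' query the spike-in always out-scores every other gene strictly.
#'
#' @return Character vector of disease keywords.
#' @export
spikeInQueryTerms <- function() {
  c("refractory", "ataxia", "myoclonic", "epilepsy")
}

#' A causal-like spike-in record
#'
#' One designated record built to survive every step: exonic,
#' nonsynonymous, no population-frequency data (prioritized as rare),
#' strongly conserved position (high GERP) and a damaging FATHMM score,
#' on a gene intended to be disease-linked in the accompanying map.
#'
#' @param gene Gene symbol of the planted record.
#' @param chrom,start Locus of the planted record.
#' @return A one-row `data.frame` in canonical column layout.
#' @export
spikeInVariant <- function(gene = .SPIKE_GENE, chrom = "1",
                           start = 111949111) {
  data.frame(chrom = chrom, start = as.numeric(start),
             end = as.numeric(start), ref = "G", alt = "A",
             func_region = "exonic", gene = gene,
             exonic_func = "nonsynonymous SNV",
             freq_1kgp = NA_real_, freq_esp6500 = NA_real_,
             gerp = 5.49, fathmm = -3.47,
             stringsAsFactors = FALSE)
}

## Independent per-row cascade: scalar re-statement of every step rule,
## evaluated row by row. This is the ledger oracle the vectorized engine is
## checked against; keep it free of the .keep* helpers in filters.R.
.rowSurvivesStep <- function(row, step, config) {
  switch(step,
    exonic = {
      keep <- config@exonicKeep
      if (config@includeSplicing) keep <- c(keep, "splicing")
      row$func_region %in% keep
    },
    func_class = {
      if (is.na(row$exonic_func)) TRUE
      else !(row$exonic_func %in% config@exonicFuncRemove)
    },
    kgp = {
      if (is.na(row$freq_1kgp)) config@keepMissingFreq
      else row$freq_1kgp <= config@freqThreshold1kgp
    },
    esp = {
      if (is.na(row$freq_esp6500)) config@keepMissingFreq
      else row$freq_esp6500 <= config@freqThresholdEsp
    },
    gerp = {
      if (is.na(row$gerp)) config@keepMissingGerp
      else row$gerp >= config@gerpMin
    },
    fathmm = {
      if (is.na(row$fathmm)) config@keepMissingFathmm
      else row$fathmm <= config@fathmmMax
    })
}

.CASCADE_STEP_IDS <- c("exonic", "func_class", "kgp", "esp", "gerp", "fathmm")

#' Row-by-row cascade oracle
#'
#' Evaluates every step rule independently, one record at a time, and
#' reports per-step surviving counts and the final survivor row indices.
#' [makeVariantTable()] uses it to compute the expectation ledger for a
#' generated table; it is deliberately a separate code path from the
#' vectorized engine in [runCascade()], so the two can check each other.
#'
#' @param df Canonical variants `data.frame` (as from `variants(x)`).
#' @param config A [FilterConfig-class].
#' @return List with `counts` (integer, input size first, one entry per
#'   step after) and `survivors` (row indices surviving all six steps).
#' @export
rowwiseCascade <- function(df, config = filterConfig()) {
  alive <- rep(TRUE, nrow(df))
  countAfter <- integer(length(.CASCADE_STEP_IDS))
  for (s in seq_along(.CASCADE_STEP_IDS)) {
    for (i in which(alive))
      alive[i] <- .rowSurvivesStep(df[i, , drop = FALSE],
                                   .CASCADE_STEP_IDS[s], config)
    countAfter[s] <- sum(alive)
  }
  list(counts = c(nrow(df), countAfter), survivors = which(alive))
}

#' Generate a synthetic annotated variant table with an expectation ledger
#'
#' Realizes each stratum, reproducibly shuffles the rows, optionally plants
#' a spike-in record, and computes the expected per-step surviving counts
#' by an independent row-by-row pass over the emitted rows
#' ([rowwiseCascade()]). Identical `(strata, seed)` produce byte-identical
#' output files.
#'
#' @param strata Non-empty list of [stratumSpec()] objects.
#' @param seed Integer seed controlling every random draw.
#' @param path Optional output path; when given, the table is written in
#'   the wANNOVAR multianno dialect via [writeShortlist()].
#' @param config [FilterConfig-class] used for the expectation ledger.
#' @param spike Optional one-row `data.frame` from [spikeInVariant()],
#'   inserted at a seed-determined position.
#' @return A list: `table` (a [VariantTable-class]), `ledger` (a list with
#'   `step_labels`, `expected_counts`, `survivor_rows`, `spike_row`), and
#'   `path` (or `NULL`).
#' @examples
#' sim <- makeVariantTable(list(
#'   stratumSpec(40, funcRegion = "exonic", gerp = 3, fathmm = -1),
#'   stratumSpec(60, funcRegion = "intronic", exonicFunc = NA)), seed = 7)
#' sim$ledger$expected_counts
#' @export
makeVariantTable <- function(strata, seed, path = NULL,
                             config = filterConfig(), spike = NULL) {
  if (!length(strata))
    stop("strata must be a non-empty list of stratumSpec objects",
         call. = FALSE)
  if (!all(vapply(strata, inherits, logical(1L), "stratumSpec")))
    stop("every stratum must be built with stratumSpec()", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  df <- do.call(rbind, lapply(strata, .stratumRows))
  if (is.null(df))
    df <- .stratumRows(stratumSpec(0))
  df <- if (is.null(df)) spikeInVariant()[0, ] else df
  df <- df[sample.int(nrow(df)), , drop = FALSE]
  spikeRow <- NA_integer_
  if (!is.null(spike)) {
    pos <- if (nrow(df)) sample.int(nrow(df) + 1L, 1L) else 1L
    df <- rbind(df[seq_len(pos - 1L), , drop = FALSE], spike,
                df[seq(pos, length.out = nrow(df) - pos + 1L), ,
                   drop = FALSE])
    spikeRow <- pos
  }
  rownames(df) <- NULL

  sch <- detectSchema(c("Chr", "Start", "End", "Ref", "Alt", "Func.refGene",
                        "Gene.refGene", "ExonicFunc.refGene",
                        "1000g2015aug_all", "esp6500siv2_all", "GERP++_RS",
                        "FATHMM_score"))
  vt <- new("VariantTable", variants = df, schema = sch)
  oracle <- rowwiseCascade(df, config)
  ledger <- list(step_labels = .STEP_LABELS,
                 expected_counts = oracle$counts,
                 survivor_rows = oracle$survivors,
                 spike_row = spikeRow)
  if (!is.null(path)) writeShortlist(vt, path = path)
  list(table = vt, ledger = ledger, path = path)
}

#' Generate a synthetic gene-disease map with a match ledger
#'
#' Builds a deterministic gene-disease TSV-shaped map by sampling disorder
#' phrases from a vocabulary, and (when `queryTerms` is given) records
#' which genes match which query keywords, computed by a direct scan of
#' the emitted entries.
#'
#' @param genes Character vector of gene symbols (may be empty).
#' @param disordersPerGene Disorders sampled per gene (without replacement
#'   when the vocabulary allows).
#' @param vocabulary Non-empty character vector of disorder phrases.
#' @param seed Integer seed.
#' @param path Optional TSV output path (columns gene, disorder, source).
#' @param queryTerms Optional keywords for the match ledger.
#' @return A list: `map` (a [GeneDiseaseMap-class]), `ledger` (`data.frame`
#'   gene / matched_terms / score, or `NULL` without `queryTerms`), and
#'   `path`.
#' @export
makeGeneDiseaseMap <- function(genes, disordersPerGene = 2L, vocabulary,
                               seed, path = NULL, queryTerms = NULL) {
  if (!length(vocabulary))
    stop("vocabulary must be non-empty", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  entries <- if (length(genes)) {
    do.call(rbind, lapply(genes, function(g) {
      k <- min(disordersPerGene, length(vocabulary))
      data.frame(gene = g,
                 disorder = sample(vocabulary, k,
                                   replace = disordersPerGene > length(vocabulary)),
                 source = "custom", stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(gene = character(), disorder = character(),
               source = character(), stringsAsFactors = FALSE)
  }
  map <- geneDiseaseMap(entries)

  ledger <- NULL
  if (!is.null(queryTerms)) {
    ent <- diseaseEntries(map)
    genesU <- unique(ent$gene)
    ledger <- do.call(rbind, c(list(
      data.frame(gene = character(), matched_terms = character(),
                 score = integer(), stringsAsFactors = FALSE)),
      lapply(genesU, function(g) {
        desc <- ent$disorder[ent$gene == g]
        hit <- vapply(tolower(queryTerms), function(tm)
          any(.termMatches(tm, desc)), logical(1L))
        data.frame(gene = g,
                   matched_terms = paste(sort(names(hit)[hit]),
                                         collapse = "; "),
                   score = sum(hit), stringsAsFactors = FALSE)
      })))
  }
  if (!is.null(path)) {
    ent <- diseaseEntries(map)
    conn <- file(path, open = "wb")
    writeLines(paste(ent$gene, ent$disorder, ent$source, sep = "\t"),
               conn, sep = "\n")
    close(conn)
  }
  list(map = map, ledger = ledger, path = path)
}

## ---- builtin simulation profiles -----------------------------------------

## Disease-linked gene pool for simulated full-pass strata. The spike-in
## gene is deliberately not in it, so a planted record is the only carrier
## of its gene and ranking checks are unambiguous.
.EXOME_DISEASE_GENES <- c("FBXO7", "PARK2", "SLC1A4", "SNCA",
                          "LRRK2", "PINK1", "ATM", "CACNA1A", "SETX")

#' Built-in "exome-mini" simulation profile
#'
#' An exome-shaped attrition profile: strata sized so that a typical
#' whole-exome's stepwise attrition (tens of thousands of variants down to
#' a few hundred candidates) is reproduced at roughly 1:10 scale with
#' ~5 500 rows at `scale = 1`. Strata cover non-exonic rows, synonymous and
#' nonframeshift classes, common variants in each frequency database
#' (including rows missing one frequency), non-conserved rows, tolerated
#' (high-FATHMM) rows, frameshift indels with no scores, and a small
#' full-pass block on disease-linked genes plus one full-pass row on an
#' unlinked gene (so the disorder-linking step has a visible attrition).
#'
#' @param scale Multiplier on every stratum size (default 1, ~5 573 rows).
#' @return List of [stratumSpec()] objects for [makeVariantTable()].
#' @seealso [exomeMiniDiseaseVocabulary()] for a matching disorder
#'   vocabulary.
#' @export
exomeMiniProfile <- function(scale = 1) {
  k <- function(n) max(0L, as.integer(round(n * scale)))
  dg <- .EXOME_DISEASE_GENES
  list(
    stratumSpec(k(2600), funcRegion = "intronic", exonicFunc = NA),
    stratumSpec(k(700), funcRegion = "intergenic", exonicFunc = NA),
    stratumSpec(k(300), funcRegion = "UTR3", exonicFunc = NA),
    stratumSpec(k(860), exonicFunc = "synonymous SNV",
                freq1kgp = c(0, 0.6), freqEsp = c(0, 0.6),
                gerp = c(-6, 6), fathmm = c(-4, 4)),
    stratumSpec(k(100), exonicFunc = "nonframeshift insertion"),
    stratumSpec(k(66), exonicFunc = "nonframeshift deletion"),
    stratumSpec(k(790), exonicFunc = "nonsynonymous SNV",
                freq1kgp = c(0.011, 0.6), freqEsp = c(0, 0.6),
                gerp = c(-6, 6), fathmm = c(-4, 4)),
    stratumSpec(k(29), exonicFunc = "stopgain", freq1kgp = c(0.02, 0.3),
                gerp = c(0, 5), fathmm = NA),
    stratumSpec(k(36), exonicFunc = "nonsynonymous SNV",
                freq1kgp = c(0, 0.01), freqEsp = c(0.011, 0.5),
                gerp = c(-6, 6), fathmm = c(-4, 4)),
    stratumSpec(k(20), exonicFunc = "nonsynonymous SNV",
                freq1kgp = NA, freqEsp = c(0, 0.01),
                gerp = c(-6, -0.01), fathmm = c(-4, 4)),
    stratumSpec(k(40), exonicFunc = "nonsynonymous SNV",
                freq1kgp = c(0, 0.01), freqEsp = NA,
                gerp = c(0, 6), fathmm = c(1.01, 5)),
    stratumSpec(k(6), exonicFunc = "stoploss", freq1kgp = NA, freqEsp = NA,
                gerp = c(0, 6), fathmm = c(1.01, 5)),
    stratumSpec(k(15), exonicFunc = "nonsynonymous SNV",
                freq1kgp = NA, freqEsp = NA, gerp = c(0, 6),
                fathmm = c(-4, 1), genePool = dg),
    stratumSpec(k(6), exonicFunc = "frameshift deletion",
                freq1kgp = NA, freqEsp = NA, gerp = NA, fathmm = NA,
                genePool = dg),
    stratumSpec(k(4), exonicFunc = "stopgain", freq1kgp = c(0, 0.005),
                freqEsp = c(0, 0.005), gerp = c(2, 6), fathmm = NA,
                genePool = dg),
    stratumSpec(k(1), exonicFunc = "nonsynonymous SNV",
                freq1kgp = NA, freqEsp = NA, gerp = c(1, 5),
                fathmm = c(-3, -1), genePool = "ORPHN1")
  )
}

#' Disorder vocabulary matching the exome-mini profile
#'
#' Disorder phrases for [makeGeneDiseaseMap()] such that the disease genes
#' of [exomeMiniProfile()] can be linked to neurological disorders while
#' the deliberate `ORPHN1` full-pass row stays unlinked.
#'
#' @return Character vector of disorder description phrases.
#' @export
exomeMiniDiseaseVocabulary <- function() {
  c("early-onset parkinson disease",
    "parkinson disease, autosomal recessive",
    "epileptic encephalopathy, early infantile",
    "spinocerebellar ataxia",
    "ataxia with myoclonic epilepsy",
    "intellectual disability and microcephaly",
    "spastic tetraplegia and seizures",
    "dystonia with brain iron accumulation")
}

.SIM_PROFILES <- list(
  "exome-mini" = function() exomeMiniProfile(1),
  "exome-micro" = function() exomeMiniProfile(0.1)
)
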