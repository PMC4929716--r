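makeVT <- function(...) {
  # build a VariantTable from per-record named lists
  rows <- list(...)
  base <- function(i, r) {
    data.frame(chrom = "1", start = i * 100, end = i * 100, ref = "A",
               alt = "G",
               func_region = as.character(r$region %||% "exonic"),
               gene = as.character(r$gene %||% "GENE1"),
               exonic_func = as.character(r$efunc %||% "nonsynonymous SNV"),
               freq_1kgp = as.numeric(r$f1k %||% NA_real_),
               freq_esp6500 = as.numeric(r$fesp %||% NA_real_),
               gerp = as.numeric(r$gerp %||% NA_real_),
               fathmm = as.numeric(r$fathmm %||% NA_real_),
               stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, lapply(seq_along(rows), function(i) base(i, rows[[i]])))
  new("VariantTable", variants = df, schema = wannovarSchema())
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("exonic restriction keeps exactly the configured region classes", {
  vt <- makeVT(list(region = "exonic"), list(region = "exonic;splicing"),
               list(region = "intergenic"), list(region = "splicing"),
               list(region = "intronic"))
  kept <- variants(filterExonic(vt))$func_region
  expect_equal(kept, c("exonic", "exonic;splicing"))

  withSpl <- filterExonic(vt, filterConfig(includeSplicing = TRUE))
  expect_equal(variants(withSpl)$func_region,
               c("exonic", "exonic;splicing", "splicing"))
})

test_that("functional-class step removes synonymous and nonframeshift only", {
  classes <- c("synonymous SNV", "nonframeshift insertion",
               "nonframeshift deletion", "nonframeshift substitution",
               "nonsynonymous SNV", "frameshift deletion",
               "frameshift insertion", "stopgain", "stoploss", "unknown", NA)
  vt <- do.call(makeVT, lapply(classes, function(cl) list(efunc = cl)))
  surv <- variants(filterFunctionalClass(vt))$exonic_func
  expect_setequal(surv[!is.na(surv)],
                  c("nonsynonymous SNV", "frameshift deletion",
                    "frameshift insertion", "stopgain", "stoploss",
                    "unknown"))
  expect_true(anyNA(surv))    # missing class is kept
})

test_that("frequency steps: rare is at-or-below threshold; missing is kept", {
  vt <- makeVT(list(f1k = 0.02), list(f1k = 0.01), list(f1k = NA),
               list(f1k = 0.0099), list(f1k = 0.0100001))
  surv <- variants(filterFrequency(vt, "kgp"))$freq_1kgp
  expect_equal(surv, c(0.01, NA, 0.0099))

  # the two databases are filtered independently
  vt2 <- makeVT(list(f1k = 0.001, fesp = 0.2), list(f1k = 0.2, fesp = 0.001))
  expect_equal(variants(filterFrequency(vt2, "esp"))$freq_esp6500, 0.001)
  expect_equal(variants(filterFrequency(vt2, "kgp"))$freq_1kgp, 0.001)

  # explicit threshold override
  expect_equal(length(filterFrequency(vt, "kgp", threshold = 0.05)), 5L)

  # drop-missing policy
  noMiss <- filterFrequency(vt, "kgp",
                            config = filterConfig(keepMissingFreq = FALSE))
  expect_false(anyNA(variants(noMiss)$freq_1kgp))
})

test_that("GERP step removes negative scores; zero and missing survive", {
  vt <- makeVT(list(gerp = -1.2), list(gerp = 0), list(gerp = NA),
               list(gerp = 5.3), list(gerp = -1e-9))
  surv <- variants(filterGerp(vt))$gerp
  expect_equal(surv, c(0, NA, 5.3))
})

test_that("FATHMM step removes scores strictly above the cutoff", {
  vt <- makeVT(list(fathmm = 2.5), list(fathmm = 1.0), list(fathmm = NA),
               list(fathmm = -3.0), list(fathmm = 1.0 + 1e-9))
  surv <- variants(filterFathmm(vt))$fathmm
  expect_equal(surv, c(1.0, NA, -3.0))

  # a clearly damaging (negative) score survives both presets
  strict <- filterFathmm(vt, filterConfig(preset = "strict"))
  expect_true(-3.0 %in% variants(strict)$fathmm)
  expect_false(1.0 %in% variants(strict)$fathmm)
})

test_that("runCascade applies the fixed order with attrition accounting", {
  empty <- randomVariantTable(0)
  res0 <- runCascade(empty)
  expect_equal(unname(counts(res0$report)), rep(0L, 7))
  expect_equal(length(res0$survivors), 0L)

  one <- makeVT(list(region = "exonic", efunc = "nonsynonymous SNV",
                     f1k = 0.001, fesp = NA, gerp = 3, fathmm = -2))
  res1 <- runCascade(one)
  expect_equal(unname(counts(res1$report)), rep(1L, 7))

  # a known mixed table: 2 intronic, 1 synonymous, 1 common, 1 full pass
  vt <- makeVT(list(region = "intronic"), list(region = "intronic"),
               list(efunc = "synonymous SNV"),
               list(f1k = 0.2),
               list(gerp = 4, fathmm = 0.5))
  res <- runCascade(vt)
  expect_equal(unname(counts(res$report)), c(5L, 3L, 2L, 1L, 1L, 1L, 1L))
  expect_equal(unname(removed(res$report)), c(0L, 2L, 1L, 1L, 0L, 0L, 0L))
})

test_that("cascade survivors equal brute-force predicate conjunction", {
  set.seed(501)
  for (rep in 1:25) {
    vt <- randomVariantTable(sample(10:200, 1))
    cfg <- randomFilterConfig()
    res <- runCascade(vt, cfg)
    expect_identical(variants(res$survivors),
                     variants(vt[oracleSurvivors(variants(vt), cfg)]))
  }
})

test_that("cascade counts are non-increasing and the run is idempotent", {
  set.seed(502)
  for (rep in 1:20) {
    vt <- randomVariantTable(sample(5:150, 1))
    cfg <- randomFilterConfig()
    res <- runCascade(vt, cfg)
    n <- unname(counts(res$report))
    expect_true(all(diff(n) <= 0))
    again <- runCascade(res$survivors, cfg)
    expect_identical(variants(again$survivors), variants(res$survivors))
    expect_equal(unname(counts(again$report)),
                 rep(length(res$survivors), 7L))
  }
})

test_that("steps 2-6 commute in the final survivor set", {
  set.seed(503)
  stepFns <- list(filterFunctionalClass,
                  function(v, c) filterFrequency(v, "kgp", config = c),
                  function(v, c) filterFrequency(v, "esp", config = c),
                  filterGerp, filterFathmm)
  for (rep in 1:15) {
    vt <- randomVariantTable(80)
    cfg <- randomFilterConfig()
    ref <- variants(runCascade(vt, cfg)$survivors)
    perm <- sample(5)
    cur <- filterExonic(vt, cfg)
    for (k in perm) cur <- stepFns[[k]](cur, cfg)
    expect_identical(variants(cur), ref)
  }
})

test_that("keeping fewer missing values never increases survivors", {
  set.seed(504)
  for (rep in 1:15) {
    vt <- randomVariantTable(100)
    base <- filterConfig(keepMissingFreq = TRUE, keepMissingGerp = TRUE,
                         keepMissingFathmm = TRUE)
    nBase <- length(runCascade(vt, base)$survivors)
    for (fld in c("keepMissingFreq", "keepMissingGerp",
                  "keepMissingFathmm")) {
      cfg <- base
      slot(cfg, fld) <- FALSE
      expect_lte(length(runCascade(vt, cfg)$survivors), nBase)
    }
  }
})

test_that("relaxing any threshold never decreases survivors", {
  set.seed(505)
  for (rep in 1:15) {
    vt <- randomVariantTable(100)
    cfg <- randomFilterConfig()
    n0 <- length(runCascade(vt, cfg)$survivors)
    up <- cfg; up@freqThreshold1kgp <- min(1, up@freqThreshold1kgp + 0.02)
    expect_gte(length(runCascade(vt, up)$survivors), n0)
    up2 <- cfg; up2@freqThresholdEsp <- min(1, up2@freqThresholdEsp + 0.02)
    expect_gte(length(runCascade(vt, up2)$survivors), n0)
    lo <- cfg; lo@gerpMin <- lo@gerpMin - 1.5
    expect_gte(length(runCascade(vt, lo)$survivors), n0)
    hi <- cfg; hi@fathmmMax <- hi@fathmmMax + 1.5
    expect_gte(length(runCascade(vt, hi)$survivors), n0)
  }
})

test_that("filter configuration validates, presets differ only in FATHMM", {
  expect_error(filterConfig(freqThreshold1kgp = 1.2), "\\[0, 1\\]")
  expect_error(filterConfig(fathmmMax = Inf), "finite")

  d <- filterConfig()
  s <- filterConfig(preset = "strict")
  for (sl in slotNames("FilterConfig")) {
    if (sl == "fathmmMax") next
    expect_identical(slot(d, sl), slot(s, sl), label = sl)
  }
  expect_equal(d@fathmmMax, 1.0)
  expect_equal(s@fathmmMax, -1.5)
})

test_that("filter configuration round-trips through YAML", {
  cfg <- filterConfig(preset = "strict", includeSplicing = TRUE,
                      freqThreshold1kgp = 0.005, keepMissingGerp = FALSE)
  path <- tempfile(fileext = ".yaml")
  writeFilterConfig(cfg, path)
  back <- readFilterConfig(path)
  for (sl in slotNames("FilterConfig"))
    expect_identical(slot(back, sl), slot(cfg, sl), label = sl)
})

test_that("cascade report serializes to TSV and JSON", {
  res <- runCascade(randomVariantTable(50))
  tsv <- tempfile(fileext = ".tsv")
  writeCascadeReport(res$report, tsv, "tsv")
  df <- read.delim(tsv)
  expect_equal(df$surviving, unname(counts(res$report)))
  expect_equal(df$removed, unname(removed(res$report)))

  js <- tempfile(fileext = ".json")
  writeCascadeReport(res$report, js, "json")
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$surviving, unname(counts(res$report)))
})
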