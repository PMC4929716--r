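test_that("detectSchema resolves wANNOVAR headers, case-insensitively", {
  full <- c("Chr", "Start", "End", "Ref", "Alt", "Func.refGene",
            "Gene.refGene", "ExonicFunc.refGene", "1000g2015aug_all",
            "esp6500siv2_all", "GERP++_RS", "FATHMM_score")
  sch <- detectSchema(full)
  expect_s4_class(sch, "AnnotationSchema")
  expect_identical(sch@dialect, "wannovar_multianno")
  expect_setequal(names(sch@columnOf),
                  c("chrom", "start", "end", "ref", "alt", "func_region",
                    "gene", "exonic_func", "freq_1kgp", "freq_esp6500",
                    "gerp", "fathmm"))
  expect_identical(sch@columnOf[["freq_1kgp"]], "1000g2015aug_all")

  # alias drift across releases and case changes still resolve
  sch2 <- detectSchema(c("CHR", "start", "END", "ref", "alt",
                         "Func.knownGene", "Gene.knownGene",
                         "ExonicFunc.knownGene", "1000G_ALL",
                         "esp6500si_all", "GERP_RS", "FATHMM"))
  expect_identical(unname(sch2@columnOf[["gene"]]), "Gene.knownGene")
  expect_identical(unname(sch2@columnOf[["freq_esp6500"]]), "esp6500si_all")
})

test_that("detectSchema handles the minimal mandatory set and failures", {
  sch <- detectSchema(c("Chr", "Start", "End", "Ref", "Alt", "Func.refGene",
                        "Gene.refGene", "ExonicFunc.refGene"))
  expect_setequal(names(sch@columnOf),
                  c("chrom", "start", "end", "ref", "alt", "func_region",
                    "gene", "exonic_func"))

  err <- tryCatch(detectSchema(c("foo", "bar")), error = identity)
  expect_s3_class(err, "error")
  for (role in c("chrom", "start", "end", "ref", "alt", "func_region",
                 "gene", "exonic_func"))
    expect_match(conditionMessage(err), role, fixed = TRUE)

  expect_error(detectSchema(c("Chr", "Chr", "Start")), "duplicate")
  expect_error(detectSchema(character()), "empty")
})

test_that("readVariantTable parses rows, missing tokens and empty tables", {
  path <- writeRawTable(c(
    wannovarHeader,
    wannovarRow(start = 100, f1k = "0.05", gerp = "2.1", fathmm = "-1.2"),
    wannovarRow(start = 200, f1k = ".", fesp = "0.001"),
    wannovarRow(start = 300, region = "intronic", efunc = ".")))
  vt <- readVariantTable(path)
  expect_equal(length(vt), 3L)
  df <- variants(vt)
  expect_equal(df$start, c(100, 200, 300))          # file order preserved
  expect_equal(df$freq_1kgp, c(0.05, NA, NA))
  expect_true(is.na(df$exonic_func[3]))
  expect_equal(df$freq_esp6500[2], 0.001)

  empty <- readVariantTable(writeRawTable(wannovarHeader))
  expect_equal(length(empty), 0L)
  expect_s4_class(empty, "VariantTable")
})

test_that("read errors cite the problem precisely", {
  expect_error(readVariantTable(tempfile()), "no such file")
  bad <- writeRawTable(c(wannovarHeader, wannovarRow(),
                         "1\t100\t100\tA\tG"))
  expect_error(readVariantTable(bad), "line 3")
  expect_error(readVariantTable(bad), "expected 12")

  nonnum <- writeRawTable(c(wannovarHeader,
                            wannovarRow(gerp = "conserved")))
  expect_error(readVariantTable(nonnum), "GERP\\+\\+_RS")
  expect_warning(vt <- readVariantTable(nonnum, lenient = TRUE),
                 "1 malformed")
  expect_true(is.na(variants(vt)$gerp[1]))
})

test_that("numeric parsing is strict and locale-independent", {
  path <- writeRawTable(c(wannovarHeader,
                          wannovarRow(f1k = "1,000")))  # thousands separator
  expect_error(readVariantTable(path), "unparseable")
  path2 <- writeRawTable(c(wannovarHeader,
                           wannovarRow(f1k = "1e-3", gerp = "-0.5")))
  df <- variants(readVariantTable(path2))
  expect_equal(df$freq_1kgp, 0.001)
  expect_equal(df$gerp, -0.5)
})

test_that("generic schemas map arbitrary headers and round-trip as YAML", {
  sch <- annotationSchema(c(chrom = "chromosome", start = "pos",
                            end = "pos_to", ref = "REF", alt = "ALT",
                            func_region = "region", gene = "symbol",
                            exonic_func = "effect", fathmm = "patho_score"),
                          missingToken = "NA")
  path <- writeRawTable(c(
    paste(c("chromosome", "pos", "pos_to", "REF", "ALT", "region", "symbol",
            "effect", "patho_score", "note"), collapse = "\t"),
    paste(c("7", "5000", "5000", "C", "T", "exonic", "ABC1",
            "nonsynonymous SNV", "NA", "checkme"), collapse = "\t")))
  vt <- readVariantTable(path, schema = sch)
  df <- variants(vt)
  expect_true(is.na(df$fathmm[1]))
  expect_true(is.na(df$freq_1kgp[1]))       # unmapped optional role
  expect_identical(df$note, "checkme")      # passthrough preserved

  yml <- tempfile(fileext = ".yaml")
  writeSchema(sch, yml)
  sch2 <- readSchema(yml)
  expect_identical(sch2@columnOf, sch@columnOf)
  expect_identical(sch2@missingToken, "NA")
})

test_that("write -> read round-trips mapped fields, order and extras", {
  set.seed(401)
  vt <- randomVariantTable(120)
  path <- tempfile(fileext = ".tsv")
  writeShortlist(vt, path = path)
  back <- readVariantTable(path)
  expect_identical(variants(back), variants(vt))

  # byte-stability: identical input writes identical bytes
  path2 <- tempfile(fileext = ".tsv")
  writeShortlist(vt, path = path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))

  # empty collection -> header-only file
  epath <- tempfile(fileext = ".tsv")
  writeShortlist(vt[integer(0)], path = epath)
  expect_equal(length(readLines(epath)), 1L)
})

test_that("gene cells split into symbol sets but are preserved verbatim", {
  syms <- splitGeneSymbols(c("GENE1;GENE2", "a,b", "SOLO", "x ; y"))
  expect_equal(syms[[1]], c("GENE1", "GENE2"))
  expect_equal(syms[[2]], c("A", "B"))
  expect_equal(syms[[4]], c("X", "Y"))

  path <- writeRawTable(c(wannovarHeader, wannovarRow(gene = "NPHP1;MALL")))
  vt <- readVariantTable(path)
  out <- tempfile(fileext = ".tsv")
  writeShortlist(vt, path = out)
  expect_match(readLines(out)[2], "NPHP1;MALL", fixed = TRUE)
})

test_that("VariantTable validity rejects inconsistent records", {
  df <- variants(randomVariantTable(5))
  df$start[2] <- df$end[2] + 10
  expect_error(new("VariantTable", variants = df, schema = wannovarSchema()),
               "start must be <= end")
  df2 <- variants(randomVariantTable(5))
  df2$freq_1kgp[1] <- 1.5
  expect_error(new("VariantTable", variants = df2,
                   schema = wannovarSchema()), "\\[0, 1\\]")
})

test_that("VCF cross-check compares record counts only", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "1\t100\t.\tA\tG\t50\tPASS\t.",
    "1\t200\t.\tC\tT\t50\tPASS\t.",
    "1\t300\t.\tG\tA\t50\tPASS\t."), vcf)
  path <- writeRawTable(c(wannovarHeader, wannovarRow(start = 100),
                          wannovarRow(start = 200),
                          wannovarRow(start = 300)))
  vt <- readVariantTable(path)
  chk <- crossCheckVcf(vt, vcf)
  expect_true(chk$consistent)
  expect_equal(chk$vcf_records, 3L)
  expect_false(crossCheckVcf(vt[1:2], vcf)$consistent)
})
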