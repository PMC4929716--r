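# VariantSieve

Rule-based filtration and prioritization of annotated whole-exome variants.

A single whole-exome sequencing (WES) run typically yields 50,000–100,000
called variants, of which at most a handful are plausible causes of a rare
Mendelian disorder. VariantSieve is for wet-lab groups and small genetics
labs who have an annotated variant table in hand — the tab-delimited export
of ANNOVAR or wANNOVAR — and need a short, defensible candidate list
without a hypothesis about inheritance mode or phenotype: the cascade is
deliberately *hypothesis-free*, so it works even when affection status and
pedigree structure are unclear.

## The filtration cascade

Starting from one row per annotated variant, seven steps are applied in a
fixed order; each step is a pure per-record rule, and the per-step
attrition is recorded:

1. **Exonic restriction** — keep records with
   `Func ∈ {exonic, exonic;splicing}` (optionally also `splicing`).
2. **Functional class** — remove `synonymous SNV` and the
   `nonframeshift insertion/deletion/substitution` classes. Frameshift
   indels, stopgain/stoploss, nonsynonymous SNVs and unknown classes are
   kept: codon substitutions that leave the amino acid unchanged are
   unlikely to underlie rare disease.
3. **1000 Genomes rarity** — remove records with 1KGP allele frequency
   *f* > 0.01. A variant at 1% or less is considered rare; records with
   *no* frequency data are kept (prioritized).
4. **ESP6500 rarity** — the same rule against the NHLBI Exome Sequencing
   Project frequencies.
5. **Conservation** — remove records with negative GERP score (GERP > 0
   indicates an evolutionarily conserved position; 0 is not negative and
   is kept). Records without a score — e.g. indels — are kept.
6. **Pathogenicity** — remove records with FATHMM score strictly greater
   than the cutoff (default 1.0; a `strict` preset uses −1.5). Negative
   FATHMM predicts intolerance to the substitution.
7. **Disease linking** — each surviving gene is looked up in local
   gene→disorder tables (OMIM-genemap-like or DISEASES-export-like TSVs)
   and scored by how many of the user's disease keywords occur — as
   case-insensitive, word-boundary matches — in its linked disorder
   descriptions. Records are ranked by that score (stably; ties keep
   input order); removal of disorder-free records is opt-in
   (`dropUnmatched`).

Missing values are a first-class state throughout: a `"."` cell never
compares equal to any number, and every keep-missing policy is a
configuration flag.

Because the published stepwise counts of such cascades derive from private
patient exomes and version-pinned annotation databases, the package ships
a synthetic-table generator (`stratumSpec()`, `makeVariantTable()`) whose
output has analytically known composition — every filter count is
predictable from the strata, so the whole pipeline is testable offline.

## Worked example

Simulate an exome-shaped table (~5,600 rows with a planted causal-like
record), run the cascade, link diseases and rank:

```r
library(VariantSieve)

sim <- vsSimulate("exome-mini", seed = 7, outDir = "sim")
res <- vsRun(sim$paths[["table"]], "out",
             diseaseMaps = sim$paths[["disease_map"]],
             queryTerms = spikeInQueryTerms(), dropUnmatched = TRUE)
res$report
```

```
CascadeReport: 7 step(s)
                                                            step surviving removed
1                              Total number of variants in input      5574       0
2                    STEP 1: Variants assigned to exonic regions      1974    3600
3          STEP 2: Synonymous and nonframeshift variants removed       948    1026
4    STEP 3: Variants with frequency > threshold in 1KGP removed       129     819
5 STEP 4: Variants with frequency > threshold in ESP6500 removed        93      36
6         STEP 5: Variants with GERP score below minimum removed        73      20
7        STEP 6: Variants with FATHMM score above cutoff removed        27      46
8                   STEP 7: Variants linked to relevant diseases        26       1
```

5,574 simulated variants are reduced to a 26-record shortlist: 3,600
non-exonic rows fall at step 1, 1,026 synonymous/nonframeshift rows at
step 2, 855 common variants at the two frequency steps, 20 non-conserved
and 46 FATHMM-tolerated rows at steps 5–6, and one record on a gene with
no disorder annotation at step 7. The planted causal-like record ranks
first — it matches all four query keywords, while the best other gene
matches one:

```r
head(cbind(variants(res$shortlist)[, c("chrom", "start", "gene", "exonic_func")],
           res$matches[, c("score", "matched_terms")]), 3)
#>    chrom     start    gene         exonic_func score                           matched_terms
#> 22     1 111949111   KCNA2   nonsynonymous SNV     4 ataxia; epilepsy; myoclonic; refractory
#> 1     10  45573487 CACNA1A   nonsynonymous SNV     1                                  ataxia
#> 3      2  24900407    SETX frameshift deletion     1                                  ataxia
```

`vsRun()` also writes `shortlist.tsv`, `cascade_report.tsv/.json` and a
`run_manifest.json` recording every threshold used. Real wANNOVAR exports
are read the same way (`readVariantTable("multianno.txt")`); generic TSVs
need only a column map (`annotationSchema()` / a YAML schema file). A thin
command-line front end is installed at
`system.file("scripts", "variantsieve", package = "VariantSieve")` with
subcommands `run`, `simulate`, `validate` and `report`.

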