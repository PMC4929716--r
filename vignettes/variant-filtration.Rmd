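---
title: "Methods: the VariantSieve filtration cascade"
author: "VariantSieve authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the VariantSieve filtration cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The procedure and its assumptions

VariantSieve prioritizes candidate disease-causing variants from annotated
whole-exome tables by a fixed cascade of per-record rules rather than by a
statistical model. The underlying assumptions are the standard ones for
rare Mendelian disease:

* the causal variant alters a protein product, so non-exonic records and
  codon substitutions that leave the amino acid unchanged can be discarded;
* the causal variant is rare, so anything seen above 1% allele frequency
  in either of two population references (1000 Genomes Project, NHLBI
  ESP6500) is background;
* the causal variant hits a functionally constrained position, so
  non-conserved sites (negative GERP) and substitutions predicted
  tolerated (high FATHMM) can be dropped;
* genes already linked to disorders resembling the patient's presentation
  deserve the top of the list, but absence of such a link is weak evidence
  — hence disease linking *annotates and ranks* by default and removes
  only on request.

The approach is deliberately hypothesis-free: no inheritance model,
genotype segregation, phenotype-similarity ontology or pathway expansion
is used, so the cascade applies even when pedigree and phenotype data are
thin. That is also its limitation: it cannot exploit trio information or
compound heterozygosity, and a causal variant that is synonymous,
common-in-reference, or scored tolerated by FATHMM will be lost.

Each step is a pure predicate on one record. Consequently the survivor
set equals the intersection of the per-step keep-sets; only the
intermediate attrition counts depend on step order, which is why the order
is fixed (it mirrors the order in which an analyst reads the report) and
why `runCascade()` may legally be replaced by a single conjunctive pass.

## Tunable parameters

| Parameter | Default | Units / domain | Rationale |
|---|---|---|---|
| `exonicKeep` | `exonic`, `exonic;splicing` | region classes | protein-altering territory |
| `includeSplicing` | off | flag | whether bare `splicing` rows count as exonic is genuinely ambiguous in practice; exposed as a switch |
| `exonicFuncRemove` | synonymous SNV, nonframeshift ins/del/sub | ANNOVAR classes | classes unlikely to cause rare disease |
| `freqThreshold1kgp`, `freqThresholdEsp` | 0.01 | allele-frequency fraction | at-or-below 1% is "rare"; removal requires frequency **strictly above** the threshold |
| `gerpMin` | 0 | GERP rejected-substitution score | scores > 0 indicate conservation; removal targets *negative* scores, so 0 is kept |
| `fathmmMax` | 1.0 (`strict`: −1.5) | FATHMM score | see below |
| `keepMissingFreq/Gerp/Fathmm` | on | flags | missing is informative, not zero |

**The FATHMM cutoff.** Two defensible cutoffs exist: −1.5 (the score's
conventional damaging threshold, high discriminative power) and 1.0 (a
relaxed value that avoids discarding known causal missense variants that
score between −1.5 and 1.0). The package defaults to 1.0 — the value that
keeps sensitivity high on known-positive exomes — and exposes −1.5 as the
`strict` preset. The presets differ in `fathmmMax` only, so strict
survivors are always a subset of default survivors; the test suite and the
acceptance script verify both properties.

**Missing-value policy.** The rarity rule explicitly prioritizes variants
with no available frequency data; the package generalizes that reading to
GERP and FATHMM, because frameshift indels — prime candidates — carry
neither score and would otherwise silently vanish between steps 5 and 6.
Each `keepMissing*` flag can be turned off; doing so can only shrink the
survivor set (a law checked over 200 random configurations).

## Boundary semantics and numerical choices

* Frequency: keep iff `f <= threshold` ("1% or less is rare"). A record at
  exactly 0.01 survives; 0.0100001 does not.
* GERP: keep iff `score >= gerpMin`; at the default 0 this removes exactly
  the negative scores, and 0.0 itself survives.
* FATHMM: keep iff `score <= fathmmMax`; removal is strict (`> 1.0`), so
  a score of exactly 1.0 survives.
* Ranking ties: `rankShortlist()` sorts stably, descending by the integer
  match score with ties in original table order — with an empty query the
  shortlist order is the input order.
* Coordinates are 1-based end-inclusive (the ANNOVAR convention) and are
  never remapped; the tool filters rows, it does not re-call or re-align.
* Numeric cells are parsed with a strict, locale-independent grammar
  (decimal point, optional sign/exponent, no thousands separators);
  malformed numerics are an error unless `lenient = TRUE` converts them to
  missing with a counted warning. On output, numbers are written as the
  shortest decimal string that parses back to the identical double, which
  makes write→read the identity and output byte-stable.
* Degenerate inputs: a header-only table yields an empty `VariantTable`
  that passes through every step with all counts 0; empty strata, empty
  gene lists and empty query sets are all legal and tested.

## Disease linking

No matching algorithm is prescribed by the cascade's design beyond
"related or similar disorders", so the package implements the simplest
faithful reading: a query keyword matches a disorder description when it
occurs as a case-insensitive, word-boundary substring ("ataxia" matches
"spinocerebellar ataxia"; "epilepsy" does not match "epileptic"), and a
record's score is the number of distinct keywords matched across all of
its gene symbols' disorders. Multi-gene cells (`GENE1;GENE2`) are split
for lookup but preserved verbatim in output. Anything semantic — ontology
traversal, phenotype similarity — is out of scope by design, since the
cascade positions itself against phenotype-driven prioritization.

Whether disorder-free records should be *removed* or merely ranked last is
ambiguous in practice (observed attrition at this step is small but
nonzero); both behaviours are provided, with annotate-and-rank as the
hypothesis-free default and `dropUnmatched` as the opt-in pruning mode.
OMIM licensing forbids redistribution, so gene–disease tables are consumed
as user-supplied local TSVs (gene, disorder, optional source) and the
package ships only synthetic maps.

## What the synthetic generator emulates — and what it does not

`makeVariantTable()` realizes user-declared strata: blocks of rows sharing
a region class, a functional class, and per-field rules (missing / fixed
value / uniform range), shuffled reproducibly under one seed. The
expectation ledger is computed by `rowwiseCascade()`, a deliberately
separate row-by-row evaluation of each rule, so the vectorized engine and
the ledger check each other; the test suite adds a third, independent
conjunction oracle of its own.

The built-in `exome-mini` profile (~5,574 rows) reproduces the *shape* of
a real exome's attrition — tens of thousands of variants collapsing to a
few dozen candidates — at roughly 1:10 scale, including strata that only
exist to exercise edge behaviour: frameshift indels with no scores, rows
missing one frequency but not the other, and one full-pass row on a gene
absent from the disease map. A planted "spike-in" record (exonic,
nonsynonymous, frequency-missing, GERP 5.49, FATHMM −3.47, on a
disease-linked gene) is the desk-scale analogue of a known causal mutation
and must survive every step and rank first.

The generator does **not** simulate reads, genotypes, annotation error,
linkage between fields (real frequency and conservation are correlated),
or a realistic allele-frequency spectrum; strata are i.i.d. uniform within
their declared ranges. Passing tests therefore demonstrate that the
implementation applies its stated rules exactly — not that those rules are
optimal on real exomes, where database version drift and annotation
quality dominate.

## Problem sizes used by the tests and acceptance script

The suite checks the ledger on the full `exome-mini` profile (~5,574
rows) and many smaller profiles; engine–oracle equivalence on 1,000 random
tables of up to 200 rows; and the cascade laws (monotone attrition,
idempotence, commutativity of the record-level steps, missing-toggle and
threshold monotonicity, I/O round-trip) on 200 random configurations.
The acceptance script re-runs the full pipeline on `exome-mini`, 300
random stratified tables against the row-by-row oracle, and the boundary
and preset checks; all sizes were chosen so the entire run completes in
well under a minute on one CPU while still exercising every stratum type.
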