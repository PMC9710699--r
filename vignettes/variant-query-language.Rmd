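---
title: "Filtering annotated VCF cohorts with VQL: model, semantics, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtering annotated VCF cohorts with VQL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(variantql)
```

# The problem

After alignment, variant calling and annotation, a sequencing analysis
ends with a large annotated VCF: tens of thousands to millions of rows,
one per site, with per-sample genotype columns and per-transcript
functional annotations packed into the `ANN` (SnpEff) or `CSQ` (VEP)
INFO field. The analytical task that remains — *find the variants
homozygous in the affected individuals, absent from the controls, and
predicted damaging* — is conceptually a relational query, but VCF is not
a relational format: alleles are multi-valued per row, annotations are
multi-valued per allele, and genotypes are a matrix folded into text.

`variantql` normalizes this structure once at import and then lets the
user express filters in VQL, a small SQL-like language purpose-built for
variant filtering. Everything is computed locally in an embedded store;
no server, no network, no species assumptions.

# Data model

Import decomposes each VCF record into:

* **variants** — one row per `(chrom, pos, ref, alt)`; exactly one ALT
  per row. Multi-allelic records are split, which makes the identity
  tuple a primary key and annotation–allele matching unambiguous. `QUAL`
  is `qual`, INFO `DP` is additionally exposed as the core field
  `depth`, other INFO fields keep their (lowercased) names. Positions
  are 1-based, as in the VCF.
* **annotations** — one row per transcript-level annotation entry,
  linked to its variant. Column names are normalized so SnpEff and VEP
  output answer the same queries: `Annotation`/`Consequence` →
  `consequence`, `Annotation_Impact`/`IMPACT` → `impact`,
  `Gene_Name`/`SYMBOL` → `gene`, `Feature_ID`/`Feature` → `transcript`.
  VEP's `Gene` column (an Ensembl gene *identifier*, not a symbol) is
  mapped to `gene_id` to avoid colliding with `gene`.
* **genotypes** — one row per `(variant, sample)`, with the genotype
  recoded as a dosage code: −1 unknown, 0 hom-ref, 1 het, 2 hom-alt.
  The code counts how many of the sample's called alleles equal the
  row's ALT; phase is ignored; a haploid call is treated as homozygous;
  any missing allele (`.`) makes the whole call unknown. Calls with
  ploidy above two collapse onto the same three informative levels
  (none / some / all alleles alternate). This is the minimal encoding
  that supports every count the queries need.
* **samples** — names from the `#CHROM` line, joined to the optional
  PED pedigree (phenotype 2 = case, 1 = control, 0/−9 = unknown and
  excluded from both case and control aggregates).

## Materialized genotype counts

With the pedigree loaded, ten per-variant aggregates are computed at
import time: `count_hom/het/ref/var` over all samples and
`case_*` / `control_*` over phenotype-2 / phenotype-1 samples, unknown
genotypes counting nowhere. Materializing at import (rather than
computing per query) means a cohort filter such as

```sql
WHERE case_count_hom = 3 AND control_count_hom = 0
```

is an ordinary indexed field comparison, which is exactly how users
reason about it. The cost — aggregates must be recomputed on re-import —
is irrelevant in a write-once/query-many workflow.

# VQL semantics

## Grammar and precedence

```
statement := select | create | drop | import_wordset
select    := SELECT fieldlist FROM source [WHERE expr]
             [ORDER BY field [ASC|DESC], ...] [LIMIT n [OFFSET m]]
create    := CREATE name FROM source [WHERE expr] [INTERSECT 'file.bed']
           | CREATE name = a & b | a "|" b | a - b
field     := name | ann.name | samples['SAMPLE'].name
expr      := comparisons (=, !=, <, <=, >, >=, IN (...), NOT IN (...),
             ~ 'regex', IN WORDSET 'w', IS [NOT] NULL)
             combined with NOT > AND > OR, parentheses override
```

Keywords are case-insensitive; identifiers are lowercased; string
literals are single-quoted. Typographic quotes (`‘ ’ “ ”`) are accepted
as equivalent to straight ones, because queries are routinely pasted
from formatted documents. The published form of this query language
never prints a CREATE or set-operation statement, so that part of the
grammar is this package's own dialect (as is
`IMPORT WORDSET 'file' AS name`); it is kept deliberately minimal.
`parse_vql()` and `serialize_ast()` are mutually inverse on ASTs: the
canonical serialization re-parses to a structurally identical tree, and
the test suite enforces this on hundreds of generated ASTs.

## Name resolution

Bare field names resolve against the core/INFO namespace first, then
the annotation namespace. Hence `impact` and `ann.impact` denote the
same column (there is no core field `impact`), which lets terse cohort
queries and fully qualified ones coexist. `chr` is an alias for
`chrom`. Sample fields always require the explicit
`samples['NAME'].field` form.

## Row multiplicity

A query whose *select list* references `ann.*` fields returns one row
per (variant, matching annotation) — a variant with two qualifying
transcripts appears twice. A query that references annotations only in
the *filter* treats the predicate existentially ("some annotation
matches") and returns one row per variant. This mirrors how annotation
tools themselves behave (`ANN[*]` quantifiers) and is the semantics the
brute-force oracle implements independently.

## Missing values

Comparisons, `IN`, and regexes against a missing value are `FALSE`;
`IS NULL` / `IS NOT NULL` test missingness explicitly. The logic is
two-valued throughout — `NOT (gene = 'X')` on a missing `gene` is
therefore `TRUE`, while `gene != 'X'` is `FALSE`. This is deliberately
not SQL's three-valued NULL logic: for end-user filtering, predictable
two-valued behaviour was judged less surprising, and the rule is
enforced identically in the vectorized engine and the reference
evaluator. Variants with no annotations at all join a single all-missing
annotation context, so `ann.gene IS NULL` can find them.

Regular expressions (`~`) use unanchored, case-sensitive matching —
the smallest-surprise reading of "the field matches this pattern".

# Two execution paths, one semantics

`compile_select()` turns a validated AST into a declarative plan
executed by `execute_plan()` with vectorized `data.table` operations:
selection subset → annotation left-join (only when needed) → one column
per referenced `samples['S'].field` → vectorized filter mask →
per-variant deduplication (unless annotation columns are selected) →
stable radix sort → LIMIT/OFFSET.

`oracle_query()` answers the same question by looping variant-by-variant
and annotation-by-annotation, calling the scalar, recursive
`evaluate_filter()` on each context, and assembling rows with plain base
R. The two paths share the row-semantics *definition* but no evaluation
code; their exact agreement over randomized stores and queries is the
package's central acceptance property. (The oracle caches its
per-variant contexts per store — a pure representation change that
leaves the evaluation semantics untouched.)

# Trio transmission filters

`transmission_filter(mode, child, father, mother)` returns an ordinary
filter tree:

* *de novo*: child `gt ∈ {1,2}`, father `= 0`, mother `= 0`;
* *autosomal recessive*: child `= 2`, father `= 1`, mother `= 1`;
* *dominant*: child `gt ∈ {1,2}` and at least one parent `gt ∈ {1,2}`.

These are the standard Mendelian rules; the feature's source names the
modes but not the formulas, so the definitions are documented here as
this package's own. Two consequences worth knowing:

* unknown genotypes (−1) fail every clause, so a variant with a missing
  parental call is never reported — conservative by design;
* the recessive genotype pattern (2,1,1) *necessarily* also satisfies
  the dominant rule, so the three modes are not mutually exclusive
  (de novo is disjoint from both others). Parental phenotype is
  deliberately ignored in the dominant rule.

# BED, wordsets, selections

* BED intervals are 0-based half-open; a variant is kept iff
  `pos − 1 ∈ [start, end)` on the same chromosome. Only the variant
  *start* position is tested, not the REF span — deletion spans
  crossing an interval boundary are not counted as overlapping. The
  source material does not define span semantics; position-only is the
  documented choice here.
* Chromosome names are harmonized before comparison by stripping a
  leading `chr` from both sides (a store-level policy, `chr_prefix`,
  settable to `keep`), because mixed `chr7`/`7` inputs are common.
* Named selections are persisted sets of variant identities with the
  creating expression recorded as provenance; `variants` is the
  reserved selection of everything imported. Set operations are exact
  set algebra on identity tuples.
* Wordsets are named string sets (typically gene symbols) loaded from
  one-term-per-line files; `gene IN WORDSET 'panel'` is a membership
  test with preserved case.

# The synthetic-data generators

The fixtures module is first-class, tested code. What it emulates — and
what it does not:

* `generate_cohort()` draws a cohort of the shape used in case/control
  filtering. Defaults state that world: 17 samples of which 3 are
  cases; 200 variants; impact mix 5% HIGH, 25% MODERATE, 35% LOW, 35%
  MODIFIER (severe annotations are rare, as in real exomes); 10%
  multi-allelic sites; 2% missing genotypes; allele frequencies uniform
  on [0.05, 0.5]. Genotypes are drawn independently per sample —
  there is **no** linkage, population structure, Hardy–Weinberg
  calibration or allele-frequency spectrum. A green test on these
  fixtures establishes that the *bookkeeping* (decomposition, counting,
  querying) is exact, not that the package has been exercised against
  population-genetic realism.
* `generate_snpsift_case()` plants one HIGH-impact CFTR stop-gain,
  homozygous in all 3 cases and in no control, among 220 decoys built
  in three classes, each violating exactly one clause of the cohort
  query (wrong case-homozygote count / a homozygous control / only
  LOW-MODIFIER annotations). The expected answer is known by
  construction — the engine is never consulted to produce it.
* `generate_trio()` enumerates all 64 genotype combinations of
  (child, father, mother) over {−1,0,1,2} and emits one variant per
  combination; the expected keys are the combinations satisfying the
  requested mode, computed from the combination table directly.

Same seed, same bytes: generators run under a private, restored RNG
state.

# Numerical and degenerate-input choices

* Duplicate `(chrom, pos, ref, alt)` rows after decomposition are
  skipped with a warning (first occurrence wins).
* `ALT = '.'` records are skipped with a warning; symbolic/breakend
  ALTs are out of scope and skipped likewise.
* Annotation entries whose allele matches no ALT of their record (a
  real phenomenon: SnpEff's indel allele notation differs from the VCF
  spelling) attach to *all* sibling variants of that record, with a
  warning — over-attachment was preferred to silent loss.
* Annotation entries shorter than the declared Format are right-padded
  with missing values and kept; extra positions are dropped. Nothing in
  annotation parsing is fatal.
* `Number=A` INFO fields are sliced per ALT; `Number=R/G` fields are
  carried unsliced as strings (documented limitation).
* Without `ORDER BY`, result order is the store's import order —
  stable, but unspecified; tests only assert order under explicit
  `ORDER BY`.
* Ties under `ORDER BY` keep store order (stable radix sort).

# Known limitations

* No GROUP BY/aggregation or JOIN syntax in VQL; no compound-het
  phasing analysis; no structural variants, breakends, or liftover.
* The store is single-writer; persistence is a single file reopened
  with `open_store()`.
* String literals cannot contain quote characters (the lexer has no
  escape syntax).
* CSV is the only export format.
* The embedded store is implemented over in-memory `data.table` tables
  persisted to one file, not an SQL engine; the module's contract
  (normalized tables, selections, wordsets, materialized aggregates,
  single-file persistence) is unchanged by this choice, and all of its
  operations are tested against independent oracles.
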