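# variantql

Filtering a multi-sample, annotated VCF down to a handful of candidate
variants is the last step of most rare-disease and cohort sequencing
analyses, and it is usually done either in a spreadsheet (painfully) or
with ad-hoc command lines. `variantql` is an R package that makes this
step reproducible and scriptable: it imports annotated VCF files
(SnpEff `ANN` or VEP `CSQ` annotations) together with an optional PED
pedigree into an embedded, normalized variant store, and filters them
with **VQL**, a compact SQL-like *variant query language*:

```sql
SELECT chr, pos, ann.consequence, samples['NA1223'].gt
FROM variants
WHERE ann.gene = 'CFTR' AND ann.impact = 'HIGH'
```

It is intended for geneticists and bioinformaticians who receive
annotated VCFs from an upstream pipeline and need transparent, auditable
filters — without a database server, a GUI, or any species-specific
assumptions.

## What it does

* **Import** — VCF 4.x (plain or gzip). Multi-allelic records are
  decomposed to one row per ALT allele so `(chrom, pos, ref, alt)` is a
  primary key; genotypes are recoded as dosage codes
  (−1 unknown / 0 hom-ref / 1 het / 2 hom-alt); `Number=A` INFO fields
  are sliced per allele; SnpEff/VEP annotation columns are normalized to
  common names (`ann.gene`, `ann.impact`, `ann.consequence`,
  `ann.transcript`) so the same query works against both annotators.
* **Pedigree-aware genotype counts** — with a PED file, every variant
  gets materialized aggregates (`count_hom`, `count_het`, `count_var`,
  `case_count_hom`, `control_count_hom`, …) over affected (phenotype 2)
  and unaffected (phenotype 1) samples, so cohort filters are plain
  field comparisons.
* **VQL** — `SELECT`/`FROM`/`WHERE` with `AND`/`OR`/`NOT`, comparison
  operators, `IN (...)`, regular expressions (`gene ~ '^CF'`),
  `IN WORDSET`, `IS NULL`, `ORDER BY`, `LIMIT`/`OFFSET`; `CREATE` for
  named selections from filters, set operations (`a & b`, `a | b`,
  `a - b`) or BED intersection; wordset import. Typographic (curly)
  quotes are accepted, so queries pasted from papers and word processors
  parse.
* **Trio analysis** — `transmission_filter()` builds standard Mendelian
  de novo / autosomal-recessive / dominant filters over
  `samples['CHILD'].gt` et al.
* **Export** — RFC 4180 CSV, plus a full command-line interface
  (`inst/cli/variantql`) mirroring the library.
* **Synthetic data** — deterministic generators for annotated
  VCF/PED/BED fixtures (`generate_cohort()`, `generate_snpsift_case()`,
  `generate_trio()`), so everything is testable offline.

## Worked example: cohort case/control analysis

A 17-individual cohort in which 3 affected individuals share a
homozygous nonsense mutation in *CFTR*. The fixture generator plants
that variant among 220 decoys, each of which violates at least one
clause of the query:

```r
library(variantql)

fx <- generate_snpsift_case()          # vcf + ped + known answer
st <- variant_store()
import_vcf(fx$vcf, ped = fx$ped, store = st)
#> Imported 221 VCF record(s): 221 variant(s), 221 annotation(s),
#>   17 sample(s), 3757 genotype(s)

vql_exec(st, "SELECT chr, pos FROM variants
              WHERE case_count_hom=3 AND control_count_hom=0
                AND impact IN ('HIGH', 'MODERATE')")
#>     chrom     pos
#> 1:      7 1195763
```

Exactly one variant survives — the planted one (`fx$expected_site` is
`"7:1195763"`). The same set is returned by
`snpsift_case_control_filter()`, an independently coded streaming filter
over the raw VCF text that mimics the per-record case/control semantics
of SnpSift-style tools; the store-backed query and the streaming scan
agree.

Transcript-level columns put one row per matching annotation in the
result:

```r
vql_exec(st, "SELECT chr, pos, ann.consequence, samples['S01'].gt
              FROM variants WHERE ann.gene = 'CFTR' AND ann.impact = 'HIGH'")
#>     chrom     pos ann.consequence samples['S01'].gt
#> 1:      7 1195763     stop_gained                 2
```

(`gt = 2`: sample S01 is homozygous for the alternate allele.)

## Command line

```sh
variantql import cohort.vcf cohort.ped --store cohort.vstore
variantql exec "SELECT chr, pos FROM variants WHERE ann.impact = 'HIGH'" \
  --store cohort.vstore --csv high.csv
variantql trio --mode denovo --child KID --father DAD --mother MOM \
  --store trio.vstore
variantql fixtures generate snpsift --out-vcf demo.vcf --out-ped demo.ped
```

Exit codes: 0 success, 1 validation error, 2 usage or VQL syntax error.

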