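# varsieve

Consecutive filtering of exome variants for disease-gene prioritization.

Whole-exome sequencing of a family with a suspected Mendelian disorder
yields tens of thousands of variants per individual; the causal mutation
has to be fished out of that background with a handful of samples.
`varsieve` implements the standard consecutive-filtering strategy for this
problem as an offline R package and command-line tool: every filter is a
pure intersective set operation on a multi-sample variant table, applied
in sequence, with the surviving-record count recorded after each step.

## The model

**Segregation filter.** Any pedigree and inheritance model is expressed as
a *segregation pattern*: for each constrained sample *s*, a non-empty
allowed set *A(s)* ⊆ {0/0, 0/1, 1/1} of genotype classes, plus a tolerance
*N* for missing calls. A record survives iff

* every constrained sample's genotype is in its allowed set **or** is
  missing (`./.`), and
* at most *N* constrained samples are missing.

Presets compile the classical models to patterns — e.g. autosomal
recessive on a trio with an unaffected sibling: parents {0/1} (obligate
carriers), affected {1/1}, unaffected {0/0, 0/1}; dominant with complete
or incomplete penetrance; de novo (parents {0/0}); and case-control
designs (e.g. cases {1/1} vs controls {0/0, 0/1} for a recessive
loss-of-function allele). By construction the retained configurations
exclude Mendelian inconsistencies for the recessive model. Off-model
genotype classes (multi-allelic indices, half-calls) never match and never
count as missing.

**Annotation-driven filters.** A local tab-delimited annotation table
(gene, per-transcript Sequence Ontology consequence terms, dbSNP id,
per-population minor allele frequencies for 1000 Genomes — ALL/EUR/ASN/
AFR/AMR — and ESP, SIFT/PolyPhen scores, phenotype strings) drives three
more filters: consequence type (any-transcript match against an allowed
term set), minor allele frequency (survive iff max MAF over the selected
study/population columns < threshold; unannotated variants are treated as
novel and pass), and gene lists. A region filter restricts to 1-based
inclusive `chrom:start-end` intervals. Population MAFs derive from
genotype counts by the folded closed form

    p = (n_het + 2 n_hom_alt) / (2 n_total),   MAF = min(p, 1 − p) ∈ [0, 0.5]

and a variant hitting several transcripts displays the most deleterious
damaging score (minimum SIFT, maximum PolyPhen).

A built-in simulator (`simulate_family()`) generates family VCFs with a
planted causal variant under any of the models, Hardy–Weinberg background
variation, configurable missingness and Mendelian-error rates, and a
matching annotation table plus truth file — so the whole cascade is
testable without any downloads.

## Worked example

The package ships a 10-record demonstration VCF for the classic family of
four (two unaffected parents, affected proband, unaffected sibling) and a
matching annotation table:

```r
library(varsieve)

vcf <- system.file("extdata", "trio_demo.vcf", package = "varsieve")
ann <- system.file("extdata", "trio_demo.annotations.tsv", package = "varsieve")

variants <- read_vcf(vcf)
store    <- read_annotations(ann)
ped      <- default_trio_sib()

res <- run_cascade(variants, store, list(
  segregation = pattern_recessive(ped),
  consequence = c("missense_variant", "stop_lost"),
  frequency   = list(threshold = 0.01)
))
res
#> # Filter cascade: 3 step(s)
#>    input        10
#>    segregation  2
#>    consequence  1
#>    frequency    1
```

Of the ten records, two are compatible with recessive segregation
(carrier parents 0/1, affected 1/1, unaffected 0/0 or 0/1); one of those
is a missense change; and that one carries no population MAF (a novel
variant), so it survives the frequency cut:

```r
res$rows[, c("position", "change", "gene", "rs_id", "consequence",
             "sift", "polyphen")]
#> # A tibble: 1 × 7
#>   position change gene  rs_id consequence       sift polyphen
#> 1 1:1000   A>G    BCKDK rs1   missense_variant  0.02     0.97
```

The SIFT score 0.02 (low = damaging) and PolyPhen 0.97 (high = damaging)
mark the surviving candidate as predicted deleterious. `tidy(res)` gives
the per-step funnel as a tibble, `glance(res)` a one-row summary, and
`autoplot(res)` the funnel as a ggplot. `summarize_variants(variants,
store)` reports the roster, SNV/indel counts and the consequence-type
distribution. Results export with `write_variant_csv(res$rows, "out.csv",
columns = ...)` with the same column selection the interactive tools
offer.

The same run from a shell:

```sh
Rscript inst/cli/varsieve.R filter \
  --vcf inst/extdata/trio_demo.vcf \
  --annotations inst/extdata/trio_demo.annotations.tsv \
  --ped fam.ped --model recessive \
  --consequence missense_variant,stop_lost --maf-threshold 0.01 \
  --out-csv out.csv --out-report report.json
```

`report.json` records the per-step counts and the full effective
configuration, so any run can be reproduced from its report alone.
Subcommands `summary` and `simulate` print data-set statistics and write
synthetic family fixtures.

## Scope

`varsieve` starts from called variants (VCF) and a local annotation
table: it performs no variant calling, QC or alignment, no liftover, no
compound-heterozygote or per-gene aggregation, and no live queries to
annotation services. Indels are accepted as-is and assumed normalized.
See `vignette("filtering-model")` for the model, its assumptions and the
design decisions.
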