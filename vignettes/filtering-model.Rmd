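---
title: "The varsieve filtering model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The varsieve filtering model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varsieve)
```

## The problem

Exome studies of rare familial disease produce a multi-sample VCF with
tens of thousands of candidate variants and only a handful of
individuals. Statistical association is hopeless at that sample size;
instead, candidates are winnowed by *consecutive filtering*: each filter
encodes one piece of prior knowledge (how the disease segregates in the
family, which molecular consequences are plausible, how common the allele
is in reference populations, which regions or genes are implicated) and
removes the variants incompatible with it. `varsieve` implements this
strategy as a set of pure, composable filters over a tidy variant table.

## Genotype model

Every call is reduced to one of five classes: `0/0`, `0/1`, `1/1`, `./.`
(missing — low quality or coverage) and `other`. Phase marks are ignored
(`0|1` ≡ `0/1`): segregation constraints here are zygosity constraints,
and none of the supported models distinguishes parental origin.
Multi-allelic records are split into one biallelic record per ALT allele;
genotype indices that do not refer to {REF, that ALT} — and half-calls —
become `other` for that record. `other` never satisfies an allowed set and
never counts as missing, because the filtering model is strictly
biallelic: treating an off-model call as missing would silently spend the
user's missing-call budget on records the model cannot describe. Indels
are accepted as-is and assumed left-aligned/normalized upstream.

## The segregation filter

A segregation pattern assigns each constrained sample a non-empty allowed
subset of {`0/0`, `0/1`, `1/1`} and fixes a missing-call tolerance
`max_missing`. Filtering proceeds in two stages: records where every
constrained sample either fulfils its zygosity criterion *or* is missing
are collected first, and of those only the records with `max_missing` or
fewer missing constrained samples are kept. Unconstrained samples are
ignored entirely, including for the missing count. This makes the
survivor set weakly monotone in `max_missing`, which the tests verify
exhaustively.

The pattern is the single source of truth; inheritance-model presets are
conveniences that compile a pedigree into one:

* **Autosomal recessive** — affected {`1/1`}, unaffected {`0/0`, `0/1`},
  and parents of an affected individual intersected with {`0/1`}
  (obligate carriers). Conflicting roles are resolved by set
  intersection; an empty intersection (e.g. an affected parent of an
  affected child under this model) is reported as a model/pedigree
  inconsistency rather than silently relaxed.
* **Autosomal dominant** — affected {`0/1`, `1/1`}; unaffected {`0/0`}
  under complete penetrance. Under *incomplete* penetrance the unaffected
  are relaxed to all three called classes. They remain constrained — so
  their missing calls still count against the tolerance — which matches
  the intuition that the sample is part of the design even if its
  phenotype is uninformative. Relaxation is monotone: no allowed set ever
  shrinks.
* **De novo** — both parents of each affected individual {`0/0`},
  affected {`0/1`, `1/1`}, and unaffected full siblings {`0/0`} (they
  cannot have inherited an allele neither parent carries).
* **Case-control** — unrelated samples: recessive gives cases {`1/1`} vs
  controls {`0/0`, `0/1`} (the loss-of-function configuration), dominant
  gives cases {`0/1`, `1/1`} vs controls {`0/0`}.

For the recessive preset the retained configurations are exactly the
Mendelian-consistent ones, which the tests confirm by exhaustive
enumeration of all 27 called trio vectors. The dominant preset is
deliberately looser: with an affected child {`0/1`,`1/1`} and one parent
{`0/0`}, the child's `1/1` cell is transmission-impossible but still
allowed — per-sample set constraints cannot express cross-sample allele
accounting, and tightening the preset beyond the model definition would
reject legitimate configurations in larger pedigrees. Users who want the
stricter behaviour can write the pattern directly.

Compound heterozygosity is out of scope by construction: the filter is
per-site, and a compound-het model needs joint reasoning over pairs of
sites per gene.

## Annotation-driven filters

Annotations come from a local TSV (schema in `?read_annotations`) rather
than live services, keeping every run offline and reproducible; an
Ensembl VEP or CellBase export can be reshaped into the schema. Three
filters consume it:

* **Consequence type** — any-transcript semantics: a variant survives if
  *any* of its transcript-level Sequence Ontology terms is allowed.
  Legacy labels ("non-synonymous", "stop lost") are aliased to SO terms;
  anything outside the controlled vocabulary is an error rather than a
  silent non-match. The conventional starting set for severe effects is
  `missense_variant` + `stop_lost`.
* **Allelic frequency** — survive iff the *maximum* MAF over the selected
  study/population columns (1000 Genomes ALL/EUR/ASN/AFR/AMR; ESP) is
  *strictly below* the threshold. A variant with no MAF annotation in any
  selected column is treated as novel and passes. Both choices are the
  conservative prioritization reading: strict-less keeps "exactly at
  threshold" out, max-across-populations discards a variant common in
  *any* selected ancestry, and novelty is evidence for — not against — a
  rare-disease candidate. Thresholds live in [0, 0.5] because MAFs are
  folded.
* **Gene list** — case-insensitive exact match; a variant annotated to
  several genes (pipe-separated in display) survives if any is listed.

The region filter needs no annotation: 1-based inclusive intervals on
both endpoints, matching VCF coordinates throughout the package (no 0-based
conversions anywhere).

MAFs derive from genotype counts by
`p = (n_het + 2 n_hom_alt) / (2 n_total)` folded to `min(p, 1 − p)`; the
fold makes the value symmetric under swapping the reference/alternative
roles, and degenerate monomorphic counts give 0. A zero total is a domain
error. When a variant has several damaging-score annotations across
transcripts, the displayed value is the most deleterious: minimum for
SIFT (low = damaging), maximum for PolyPhen (high = damaging);
aggregation is over all transcript effects of the record. Score vectors
that are all-NA aggregate to NA; an empty score set is an error.

## The cascade

`run_cascade()` applies the configured filters in declared order and
records survivors after each step. Every filter is intersective (output ⊆
input, no reordering, no duplication), so the *final* set is invariant
under permutation of the steps — a property the tests check explicitly —
while the per-step funnel depends on the order and is the per-run report
(`tidy()`, `glance()`, `autoplot()`). Annotation is strictly additive and
happens once, before filtering. Re-running with different settings
replaces the interactive tools' re-search loop; `cmd_filter()` writes a
JSON report carrying the per-step counts plus the full effective
configuration, which round-trips to an identical run.

## What the simulator emulates — and what it does not

`simulate_family()` exists so the full cascade is testable end-to-end
with known truth. It emulates:

* background variants in Hardy–Weinberg equilibrium in founders, with
  Mendelian transmission down the pedigree (one allele drawn per parent);
* background allele frequencies from a 50/50 mixture of uniform(0.0005,
  0.01) and uniform(0.01, 0.5) — rare and common variants in equal
  measure, so the MAF filter has something to do in both regimes;
* a planted causal variant whose genotypes are set by the chosen model
  (recessive: parents `0/1`, affected `1/1`, unaffected drawn from
  {`0/0`, `0/1`});
* per-genotype missingness and Mendelian-error corruption at configurable
  rates. Both default to background variants only, keeping the truth
  record clean; `corrupt_causal = TRUE` extends them to the causal record
  to exercise the missing-tolerance path. The recorded truth always holds
  the clean planted genotypes;
* a matching annotation table: one gene per five consecutive variants,
  one or two transcript effects with consequence terms drawn from a
  realistic exome mix (≈30% intronic, 20% missense, 15% synonymous,
  UTR/splice/upstream/downstream making up the rest, 2% stop-gain),
  population MAF columns equal to the folded generating frequency with
  per-population jitter, ~5% of variants left unannotated as novel, and
  damaging scores on missense hits. The causal variant gets a
  configurable consequence (default missense) and MAF (default novel).

It does **not** emulate linkage disequilibrium or haplotype structure,
genotyping-error covariance with depth or batch, sequencing reads, indel
mis-normalization, or population substructure. Passing tests on this
generator therefore demonstrate the *filtering semantics* — segregation
logic, tolerance accounting, threshold behaviour, format round-trips —
not calling accuracy or real-data error profiles. Positions are assigned
sequentially on a synthetic contig, so nothing depends on a genome build.

All simulation is seeded and byte-reproducible: the same configuration
and seed give identical VCF, TSV and truth files.

## Numerical and degenerate-input choices

* MAF comparison strict (`<`); values written to TSV with `%.17g` so
  doubles round-trip exactly.
* Duplicate `(chrom, pos, ref, alt)` keys: an error in the annotation
  store (ambiguous join), a dropped-with-warning duplicate in VCF input.
* Header-only VCF parses to a zero-record table with the correct roster;
  empty tables pass through every filter and summarize to zero counts.
* Records lacking a GT field become missing for all samples, with one
  warning per file.
* Pattern validation reports *all* violations at once (unknown samples,
  empty sets, tolerance exceeding the constrained-sample count), not just
  the first.

## Problem sizes

The validation suite enumerates all `4^n` genotype-class vectors for
patterns over 3–5 samples (200 random patterns against an independently
written brute-force oracle), and runs 20 simulated families of 10,000
background variants each for causal-variant recovery — sizes chosen so
the exhaustive checks stay exact while a full run remains comfortable on
a laptop. Real exomes (30,000–50,000 variants, any pedigree size) are
well within the engine's vectorized path.

## Known limitations

* Per-site filtering only: no compound-heterozygote, no per-gene burden.
* X-linked presets are not provided (sex-aware allowed sets can be
  written manually per sample).
* The VCF reader interprets only the GT subfield; qualities, depths and
  INFO fields are ignored rather than used for adaptive missingness.
* Annotation quality is whatever the local table contains; the package
  computes no effect predictions of its own.
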