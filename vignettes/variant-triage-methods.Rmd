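---
title: "Three-tier triage of annotated germline variants: methods and design"
author: "VariantTriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-tier triage of annotated germline variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VariantTriage)
```

## The problem

Proactive genomic screening of healthy individuals produces tens of
thousands of annotated germline variants per exome or genome, of which a
handful are worth communicating: recessive carrier alleles, actionable
cardiovascular and cancer predispositions, clinically validated
pharmacogenetic alleles, and rare loss-of-function variants that deserve
future reassessment. `VariantTriage` implements a reproducible three-tier
filtering protocol that turns annotated variant tables — VCF or delimited
platform exports — into a two-part clinical-style report: a concise main
report for actionable findings, and a tabulated annex listing every
selected variant with its full evidence.

The three tiers are:

* **Tier A (variant-centric).** Select variants whose ClinVar aggregate
  interpretation signature carries at least one submission labelled
  pathogenic, likely pathogenic, protective, risk factor or drug response.
* **Tier B (gene-centric).** Restrict to virtual gene panels and keep
  variants that classify pathogenic / likely pathogenic under the ACMG/AMP
  evidence-combination rules *or* reach a damaging consensus across nine
  in-silico deleteriousness predictors.
* **Tier C (VUS-centric).** Forward rare nonsense/frameshift (and
  canonical splice-site) variants of uncertain significance in
  medium/high-penetrance genes to the annex, without interpretation.

Everything runs twice: once over all detected variants and once over the
high-confidence subset retained by the quality rules, with every record
carrying its confidence label.

## The ClinVar aggregate signature

Annotation platforms summarize submitter interpretations per variant as a
tally string such as `Pathogenic(4);Risk factor(4);Benign(1)`.
`parseClinvarSignature()` parses this format case-insensitively, folds
spelling variants (`Drug-response` → `Drug response`), buckets unknown
labels into `Other` with a warning, and sums repeated classes.
`formatClinvarSignature()` renders counts in a fixed canonical order
(descending clinical severity, then the non-Mendelian classes), so
`parse(format(x))` is the identity and reports diff cleanly.

A deliberate property of Tier A is that a *single* qualifying submission
triggers candidacy even against a benign majority — a long-QT potassium
channel allele with five benign and one pathogenic submission is still
selected, but flagged (`conflict`) so the report shows the disagreement.

## Quality model

```{r}
qualityThresholds()
```

High-confidence retention requires, with strict inequalities exactly as the
protocol states them: quality score > 100, read depth > 10,
quality-by-depth > 10, and detection by at least two distinct variant
callers. Any absent metric fails the test. Alleles supported by more than
25% of covering reads are heterozygous; the homozygous cutoff (≥ 0.75) is
this package's choice — common practice, configurable — because the
protocol defines only the heterozygous lower bound. Fractions at or below
25% are labelled `low_fraction` and excluded from the high-confidence pass
but retained in the all-variants pass. When an export carries no caller
provenance at all, the concordance rule is skipped with a warning rather
than discarding the whole table.

## ACMG automation boundary

Only six evidence criteria are derivable from annotations alone, and only
those are auto-assigned:

| code | rule | default |
|------|------|---------|
| PVS1 | null consequence in a gene with an established LoF mechanism | LoF gene list; defaults to the panel union |
| PM2  | absent from population controls, or below cutoff | max AF < 1e-4 |
| PP3 / BP4 | predictor consensus damaging / tolerated | see below |
| BA1  | stand-alone benign frequency | max AF > 0.05 |
| BS1  | strong benign frequency | max AF > 0.01 |

The remaining 22 criteria need curated knowledge (segregation, functional
assays, de novo status) that no annotation table supplies; they are
accepted as *supplied* inputs per variant and merged in. This is an honest
automation boundary, not a simplification of the combination rules.

`combineAcmg()` implements the full published combination table over
evidence counts. Conditions such as "1 moderate and 1 supporting" are read
as *at least*: extra evidence of the same strength never weakens a class.
When a pathogenic-side and a benign-side rule fire together the result is
`vus` (conflicting evidence), as is an empty criteria set. The test suite
checks the combiner against an independently written scalar transcription
of the rule table over all 21,600 evidence-count vectors with per-class
counts capped at the vocabulary sizes.

## Predictor consensus

```{r}
defaultPredictorTable()
```

Nine predictors vote; each predictor's published cutoff is the default and
every threshold is configurable. A categorical call (e.g. MutationTaster
`A`/`D`) takes precedence over a raw score. Absent predictors are excluded
from the denominator — never imputed — because the consensus must know how
many predictors actually voted. With fewer than `minAvailable = 3` usable
predictors the verdict is `insufficient`; otherwise `damaging` requires a
strict majority of the available predictors (a fixed fraction can be
configured instead). The two Tier-B arms are OR-ed, and when a variant
selected by the consensus arm classifies `vus` under ACMG it is kept with
a `vus_flag`, so both verdicts stay visible; the protocol names both
criteria without stating a precedence, and reporting both is the faithful
resolution.

## Tier C and the annex rule

Tier C keeps variants that (i) count as VUS — no ClinVar record, no
assessed-class submissions, or uncertain-significance as the strict
plurality —, (ii) have a loss-of-function consequence (nonsense,
frameshift, canonical ±2 splice site) in an exonic/splice-site region,
(iii) are rare (max AF ≤ 0.001, absent passes), and (iv) lie in a
medium/high-penetrance gene (defaulting to the panel union, since no
canonical penetrance list exists). Variants with any pathogenic-side
submission are excluded here — they are Tier-A territory. Every Tier-C hit
routes to the annex unconditionally, and that rule dominates: a rare
in-panel frameshift VUS also fires Tier B (PVS1 + PM2 ⇒ likely
pathogenic), and the hit's tier set records both, but its destination
stays `annex` because an automatically assigned PVS1 on an otherwise
unassessed variant is exactly the situation the protocol reports without
interpretation. Missense VUS meeting deleteriousness criteria surface
through Tier B's consensus arm instead, flagged as VUS.

## Categories and routing

Hits are distributed over a fixed category vocabulary (carrier status, the
five disease-panel categories, pharmacogenetics, ACMG59 secondary-findings
genes, uncategorized risks, GWAS) and routed:

* pharmacogenetic findings reach the main report iff their PharmGKB
  clinical-annotation level is 1A or 1B; all other levels stay in the
  annex;
* other findings reach the main report iff they are pathogenic-side
  (combined ACMG class, or a pathogenic / likely-pathogenic submission
  triggered them) *and* at least one category is medium/high-penetrance
  eligible; risk-factor-only and VUS findings never reach the main
  section;
* an analyst override (`include` / `exclude`) stands in for the manual
  curation and literature evaluation of the original protocol, which is
  out of automation scope.

Carrier status requires recessive (or unknown) inheritance and survival of
the rarity filter (max population AF ≤ 0.05, configurable; hits triggered
solely by risk-factor / protective / drug-response submissions are exempt,
because validated pharmacogenetic alleles are common). The protocol's
phrase for frequency "filtration" is grammatically ambiguous; this package
reads it as *retaining* rare variants, consistent with rare-disease
carrier reporting, and exposes a configuration switch to invert it.

## The synthetic cohort generator

`generateCohort()` emulates the study conditions the pipeline was built
for, with planted ground truth: a Poisson mean of four recessive
pathogenic carrier alleles per patient (making ~98% of patients carriers
of at least one — matching the near-universal carrier rates reported for
proactive screening cohorts), a 35% probability of a level-1A/1B
pharmacogenetic allele at common frequency (0.05–0.4), a 33% probability
of an actionable in-panel variant, a 20% probability of a rare
loss-of-function VUS, and 200 benign/common background variants per
patient. Planted allele frequencies straddle the pipeline's thresholds by
class (carrier 1e-5–1e-3; pharmacogenetic 0.05–0.4; background common
0.1–0.5) so both branches of every frequency rule are exercised. The
quality-noise model (10% low-QUAL, 10% low-depth, 10% single-caller)
degrades background records only; planted signal variants are generated
high-confidence so the truth table is exact and full-pipeline recall and
precision are checkable at 1.0. Genes are drawn from the bundled ~20-gene
illustrative mini-panels plus dedicated off-panel carrier, pharmacogene
and background pools, so class and category assignments are unambiguous.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: linkage and haplotype structure, star-allele
diplotypes, copy-number variation (the original protocol itself notes
CYP2D6 CNV calling as future work), multi-transcript consequence
ambiguity, platform-specific annotation noise, and the judgment calls of
manual curation. Real cohort-level fractions depend on those factors; the
synthetic defaults are calibration context, not predictions.

```{r}
co <- generateCohort(cohortSpec(nPatients = 10, seed = 7))
table(co$truth$class)
```

## Numerical and design choices

* All frequency comparisons treat an absent frequency as "not observed",
  which passes rarity filters (PM2 semantics) and fails common-allele
  rules (BA1/BS1 never fire on absent data).
* Strict plurality for uncertain-significance status breaks ties against
  VUS: equal counts do not make a VUS.
* Coordinates are 1-based (VCF convention) end to end; the GRCh37/hg19
  build label is metadata, never validated against a reference. Strand is
  ignored; alleles are taken as provided.
* Multi-allelic VCF records decompose one record per alternate allele,
  conserving allele count.
* Deterministic output ordering everywhere: category rank, then gene,
  then position; report JSON is byte-identical across runs on identical
  input.
* One seeded RNG in the generator, restoring the caller's RNG state; no
  global randomness.
* The worked-example fixture transcribes a published table of 19
  actionable variants over 13 patients; since that table prints no
  genomic coordinates, the fixture carries true chromosomes with
  placeholder kilobase-rounded positions and schematic indel alleles,
  documented in `inst/extdata/README.txt`.

The test suite runs the full pipeline on a 100-patient synthetic cohort
(about 21,000 variant records), checks the ACMG combiner on all 21,600
capped evidence-count vectors, and uses 40–200 randomized cases per
property; these sizes keep the whole suite under a minute while covering
every rule branch.

## Limitations

* No annotation is performed: the package consumes annotated tables and
  trusts gene symbols, consequences and frequencies as given.
* No HGVS validation, transcript selection or genome-build liftover.
* PVS1 assignment knows nothing about NMD escape or last-exon rules.
* Compound heterozygosity is not modelled.
* The bundled panels are illustrative subsets; clinical use requires
  curated panels supplied via `readPanels()`.
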