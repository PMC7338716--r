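# VariantTriage

Three-tier triage and clinical-style reporting of annotated germline
variants, for labs and bioinformaticians implementing proactive genomic
screening. The package turns annotated variant tables (VCF 4.x or
delimited platform exports) into categorized two-part reports — a concise
main report of actionable findings plus a tabulated annex of all selected
variants — through a reproducible, fully configurable filtering protocol.

## The method

Variants pass a dual quality gate (an all-variants pass and a
high-confidence pass retaining QUAL > 100, DP > 10, QD > 10, ≥ 2 callers;
alt-read fraction > 25% defines heterozygosity) and then three filtering
tiers:

* **Tier A — variant-centric.** Select any variant whose ClinVar
  aggregate interpretation signature (e.g.
  `Pathogenic(4);Risk factor(4);Benign(1)`) carries ≥ 1 submission in
  {pathogenic, likely pathogenic, protective, risk factor, drug
  response}; a benign majority is flagged, not disqualifying. Carrier
  status additionally applies a rarity filter (max AF ≤ 0.05) from which
  pharmacogenetic and risk-factor alleles are exempt.
* **Tier B — gene-centric.** Restrict to virtual gene panels
  (cardiovascular, hereditary cancer, neuro/psychiatric, diabetes,
  immune, ACMG59) and keep variants classifying **P/LP** under the
  ACMG/AMP evidence-combination rules (six criteria auto-assigned: PVS1,
  PM2, PP3, BP4, BA1, BS1; curated criteria merge in) **or** reaching a
  damaging strict-majority consensus across nine in-silico predictors
  (SIFT, PolyPhen-2, MutationTaster, MutationAssessor, FATHMM,
  dbscSNV-Ada, GERP, GenoCanyon, fitCons).
* **Tier C — VUS-centric.** Rare (AF ≤ 0.001) nonsense/frameshift/
  canonical-splice VUS in medium/high-penetrance genes go to the annex
  without interpretation.

Hits are distributed over fixed report categories and routed: PharmGKB
level-1A/1B pharmacogenetic findings and pathogenic-side findings in
medium/high-penetrance categories reach the main report; everything else
— including every Tier-C VUS — stays in the annex.

## Worked example

The package bundles a transcription of a published representative table
of actionable variants (19 records over 13 patients) and six illustrative
mini-panels:

```r
library(VariantTriage)
res <- runTriage(workedExampleFixture(), miniPanels())
res$reports[["52"]]
#> TriageReport for 52: 2 main finding(s), 0 annex row(s)
res$reports[["52"]]$main_findings[, c("gene", "functional_consequence",
                                      "clinvar_signature", "categories")]
#>    gene functional_consequence
#> 1 MUTYH          inframe_indel
#> 2 CHEK2               missense
#>                                                             clinvar_signature
#> 1                                                              Pathogenic(14)
#> 2 Pathogenic(9);Likely pathogenic(8);Uncertain significance(2);Risk factor(3)
#>                                 categories
#> 1  carrier_status,hereditary_cancer,acmg59
#> 2                        hereditary_cancer
```

Patient 52's recessive `MUTYH` polyposis allele and the `CHEK2`
cancer-risk allele are both pathogenic-triggered, in-panel findings and
land in the main report; their verbatim signature strings parse and
re-render canonically.

Synthetic cohorts with planted ground truth make every stage testable
without any external data:

```r
co <- generateCohort(cohortSpec(nPatients = 100, seed = 1))
res <- runTriage(co$variants, miniPanels())
res$summary$carrier_fraction        # 0.98 — Poisson(4) planted carriers
res$summary$median_carrier_variants # 4
```

A thin command-line wrapper (`inst/scripts/variant-triage.R`) exposes
`triage --config run.yaml`, `simulate`, and `summarize` subcommands over
the same functions; run configurations are single YAML files with
validated keys.

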