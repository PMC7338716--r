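Bundled plain-text fixtures
===========================

panels/*.txt
  Six illustrative virtual gene mini-panels (one gene symbol per line,
  '#' comments). Compact subsets chosen to cover the bundled worked
  examples; not exhaustive clinical panels.

worked_example_variants.csv
  Transcription of the published representative actionable-variant table
  (19 variant rows over 13 patients): gene, HGVS notation, rsID and the
  verbatim ClinVar aggregate signature strings. The source table prints
  no genomic coordinates, so positions here are documented placeholders
  (each gene's true chromosome, position rounded to the kilobase) and
  indel REF/ALT strings are schematic. Inheritance is assigned from
  standard gene-disease knowledge. Population frequencies and quality
  metrics are absent, as in the source.
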